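# Independent brute-force oracles, written against the plain gene table and
# deliberately sharing no code with the package implementation.

# ORF-rank distance on a contig of n genes (modular when circular).
oracle_rank_dist <- function(r1, r2, n, circular) {
  d <- abs(r1 - r2)
  if (circular) min(d, n - d) else d
}

# Pair-centred PUL predicate: does any CAZyme gene sit within `reach` ranks
# of the nearer of the two pair members?
oracle_pair_is_pul <- function(genes, susC_gene, susD_gene, caz_gene_ids,
                               reach = 8, circular = FALSE) {
  contig <- genes$contig_id[genes$gene_id == susC_gene]
  cg <- genes[genes$contig_id == contig, ]
  cg <- cg[order(cg$start, cg$end, cg$gene_id), ]
  n <- nrow(cg)
  rc <- which(cg$gene_id == susC_gene) - 1L
  rd <- which(cg$gene_id == susD_gene) - 1L
  for (i in seq_len(n)) {
    if (!cg$gene_id[i] %in% caz_gene_ids) next
    r <- i - 1L
    if (min(oracle_rank_dist(r, rc, n, circular),
            oracle_rank_dist(r, rd, n, circular)) <= reach) return(TRUE)
  }
  FALSE
}

# Anchor-window PUL predicate: a full SusC/D pair inside the +/-(up, down)
# rank window around the anchor, and a CAZyme within reach of the nearer
# pair member.
oracle_anchor_is_pul <- function(genes, anchor, pair_table, caz_gene_ids,
                                 up = 7, down = 7, reach = 8,
                                 circular = FALSE) {
  contig <- genes$contig_id[genes$gene_id == anchor]
  cg <- genes[genes$contig_id == contig, ]
  cg <- cg[order(cg$start, cg$end, cg$gene_id), ]
  n <- nrow(cg)
  ra <- which(cg$gene_id == anchor) - 1L
  in_window <- function(r) {
    if (circular) {
      oracle_in <- FALSE
      for (o in (-up):down) if ((ra + o) %% n == r) oracle_in <- TRUE
      oracle_in
    } else r >= ra - up && r <= ra + down
  }
  pt <- pair_table[pair_table$contig_id == contig, , drop = FALSE]
  for (k in seq_len(nrow(pt))) {
    rc <- which(cg$gene_id == pt$susC_gene[k]) - 1L
    rd <- which(cg$gene_id == pt$susD_gene[k]) - 1L
    if (!in_window(rc) || !in_window(rd)) next
    if (oracle_pair_is_pul(genes, pt$susC_gene[k], pt$susD_gene[k],
                           caz_gene_ids, reach, circular)) return(TRUE)
  }
  FALSE
}

# Exhaustive SusC/D pair scan: every (susC, susD) gene pair at consecutive
# ranks, same strand, susD immediately downstream of susC in the susC
# reading direction; greedy left-to-right, each gene in at most one pair.
oracle_suscd_pairs <- function(genes, susc_genes, susd_genes) {
  pairs <- list()
  used_d <- character(0)
  for (contig in unique(genes$contig_id)) {
    cg <- genes[genes$contig_id == contig, ]
    cg <- cg[order(cg$start, cg$end, cg$gene_id), ]
    for (i in seq_len(nrow(cg))) {
      if (!cg$gene_id[i] %in% susc_genes) next
      j <- if (cg$strand[i] == "+") i + 1L else i - 1L
      if (j < 1 || j > nrow(cg)) next
      if (!cg$gene_id[j] %in% susd_genes) next
      if (cg$gene_id[j] %in% used_d) next
      if (cg$strand[j] != cg$strand[i]) next
      used_d <- c(used_d, cg$gene_id[j])
      pairs[[length(pairs) + 1L]] <- c(susC = cg$gene_id[i],
                                       susD = cg$gene_id[j])
    }
  }
  pairs
}

# Naive motif search by explicit offset loop and per-character comparison.
oracle_motif_search <- function(sequence, motif, max_mismatch = 0) {
  sq <- strsplit(toupper(sequence), "")[[1]]
  mo <- strsplit(toupper(motif), "")[[1]]
  out <- integer(0)
  if (length(mo) > length(sq)) return(out)
  for (s in 1:(length(sq) - length(mo) + 1)) {
    mism <- 0
    for (j in seq_along(mo)) {
      ch <- sq[s + j - 1]
      if (ch == "X" || ch != mo[j]) mism <- mism + 1
    }
    if (mism <= max_mismatch) out <- c(out, s)
  }
  out
}

# Direct evaluation of the GH16 classification rule from a presence vector.
oracle_gh16_rule <- function(present) {
  required <- c("signal_peptide", "PKD", "laminarin_binding", "GH16_cat_N",
                "inserted_DUF", "GH16_cat_C", "WPA_site")
  if (all(required %in% present)) "canonical_large_laminarinase"
  else "non_canonical"
}

random_protein <- function(n, alphabet = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
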