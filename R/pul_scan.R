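# Rank distance between two ORF ranks, modular on circular contigs.
rank_dist <- function(r1, r2, n, circular) {
  d <- abs(r1 - r2)
  if (circular) pmin(d, n - d) else d
}

# Gene ids of consensus CAZymes, mapped from protein ids through the genome.
cazyme_gene_ids <- function(genome, cazyme_calls) {
  if (nrow(cazyme_calls) == 0) return(character())
  rows <- map_protein_to_gene(genome, unique(cazyme_calls$protein_id))
  rows <- rows[!is.na(rows)]
  genome$genes$gene_id[rows]
}

#' Apply the windowed PUL rule at an anchor gene
#'
#' The rule: a polysaccharide utilization locus is a SusC/D pair with at
#' least one CAZyme gene within `reach` ORF ranks. The window of `up` ORFs
#' left and `down` ORFs right of the anchor (contig rank order) is searched
#' for a SusC/D pair lying fully inside it; the verdict is `PUL` iff such a
#' pair exists and at least one consensus CAZyme lies within `reach` ranks
#' of the nearer pair member (`mode = "pair"`, the default, reflecting that
#' a PUL is a susCD-centred concept) or of the anchor itself
#' (`mode = "anchor"`). The anchor counts as a CAZyme when it has a
#' consensus call. Candidate pairs are tried in rank order and the first
#' yielding a PUL verdict is reported.
#'
#' @param genome a `genome_annotation`.
#' @param cazyme_calls data.frame from [consensus_cazyme()].
#' @param sus_pairs data.frame from [detect_suscd_pairs()].
#' @param anchor anchor gene id.
#' @param up,down window half-widths in ORFs (default 7 and 7).
#' @param reach maximum ORF-rank distance from the pair (or anchor) to a
#'   CAZyme (default 8).
#' @param mode `"pair"` (reach measured from the nearer pair member) or
#'   `"anchor"`.
#' @return list of class `pul_call` with the window, the pair evidence, the
#'   CAZymes in reach, the verdict and the bp span of all evidence genes.
#' @export
call_pul_at_anchor <- function(genome, cazyme_calls, sus_pairs, anchor,
                               up = 7, down = 7, reach = 8,
                               mode = c("pair", "anchor")) {
  mode <- match.arg(mode)
  g <- genome$genes
  ai <- match(anchor, g$gene_id)
  if (is.na(ai)) stop("unknown anchor gene: ", anchor)
  win <- neighborhood(genome, anchor, up, down)
  contig <- g$contig_id[ai]
  cg <- g[g$contig_id == contig, , drop = FALSE]
  n <- nrow(cg)
  circ <- isTRUE(genome$circular[[contig]])
  caz_genes <- cazyme_gene_ids(genome, cazyme_calls)
  caz_ranks <- cg$rank[cg$gene_id %in% caz_genes]

  cand <- sus_pairs[sus_pairs$contig_id == contig &
                      sus_pairs$susC_gene %in% win$gene_id &
                      sus_pairs$susD_gene %in% win$gene_id, , drop = FALSE]
  cand <- cand[order(pmin(cand$susC_rank, cand$susD_rank)), , drop = FALSE]

  result <- list(anchor_gene_id = anchor, window = win$gene_id,
                 pair_found = FALSE, pair_genes = NULL,
                 cazymes_in_reach = character(), verdict = "no_PUL",
                 span = NULL)
  class(result) <- "pul_call"
  if (nrow(cand) == 0) return(result)

  result$pair_found <- TRUE
  result$pair_genes <- c(susC = cand$susC_gene[1], susD = cand$susD_gene[1])
  for (k in seq_len(nrow(cand))) {
    ref_ranks <- if (mode == "pair")
      c(cand$susC_rank[k], cand$susD_rank[k]) else g$rank[ai]
    near <- vapply(caz_ranks, function(r)
      min(rank_dist(r, ref_ranks[1], n, circ),
          if (length(ref_ranks) > 1) rank_dist(r, ref_ranks[2], n, circ)
          else Inf), numeric(1))
    hit_ranks <- caz_ranks[near <= reach]
    if (length(hit_ranks) > 0) {
      result$pair_genes <- c(susC = cand$susC_gene[k],
                             susD = cand$susD_gene[k])
      result$cazymes_in_reach <- cg$gene_id[match(sort(hit_ranks), cg$rank)]
      result$verdict <- "PUL"
      ev <- cg[cg$gene_id %in% c(result$pair_genes, result$cazymes_in_reach), ,
               drop = FALSE]
      result$span <- c(start = min(ev$start), end = max(ev$end))
      break
    }
  }
  result
}

#' @export
print.pul_call <- function(x, ...) {
  cat("pul_call at", x$anchor_gene_id, "->", x$verdict, "\n")
  if (x$pair_found)
    cat("  pair:", x$pair_genes["susC"], "/", x$pair_genes["susD"],
        " cazymes in reach:", length(x$cazymes_in_reach), "\n")
  invisible(x)
}

#' Genome-wide PUL catalog
#'
#' One entry per detected SusC/D pair (pair-centred rule: PUL iff at least
#' one consensus CAZyme within `reach` ORF ranks of the nearer pair member)
#' plus, optionally, one entry per declared anchor gene evaluated with
#' [call_pul_at_anchor()]. Entries are deduplicated by contig and evidence
#' span.
#'
#' @inheritParams call_pul_at_anchor
#' @param anchors optional character vector of anchor gene ids.
#' @return data.frame with one row per catalog entry: seed (pair or
#'   anchor id), contig, pair genes, number and ids of CAZymes in reach,
#'   verdict and span.
#' @export
genome_pul_catalog <- function(genome, cazyme_calls, sus_pairs,
                               anchors = NULL, up = 7, down = 7, reach = 8) {
  g <- genome$genes
  caz_genes <- cazyme_gene_ids(genome, cazyme_calls)
  rows <- list()
  if (nrow(sus_pairs) > 0) {
    for (k in seq_len(nrow(sus_pairs))) {
      contig <- sus_pairs$contig_id[k]
      cg <- g[g$contig_id == contig, , drop = FALSE]
      n <- nrow(cg)
      circ <- isTRUE(genome$circular[[contig]])
      caz_ranks <- cg$rank[cg$gene_id %in% caz_genes]
      near <- vapply(caz_ranks, function(r)
        min(rank_dist(r, sus_pairs$susC_rank[k], n, circ),
            rank_dist(r, sus_pairs$susD_rank[k], n, circ)), numeric(1))
      hits <- sort(caz_ranks[near <= reach])
      hit_genes <- cg$gene_id[match(hits, cg$rank)]
      ev <- cg[cg$gene_id %in% c(sus_pairs$susC_gene[k],
                                 sus_pairs$susD_gene[k], hit_genes), ,
               drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        seed = sus_pairs$susC_gene[k], seed_type = "pair",
        contig_id = contig, susC_gene = sus_pairs$susC_gene[k],
        susD_gene = sus_pairs$susD_gene[k],
        n_cazymes = length(hit_genes),
        cazymes = paste(hit_genes, collapse = ","),
        verdict = if (length(hit_genes) > 0) "PUL" else "no_PUL",
        start = min(ev$start), end = max(ev$end), stringsAsFactors = FALSE)
    }
  }
  for (a in anchors) {
    pc <- call_pul_at_anchor(genome, cazyme_calls, sus_pairs, a,
                             up = up, down = down, reach = reach)
    span <- if (is.null(pc$span)) {
      ai <- match(a, g$gene_id)
      c(start = g$start[ai], end = g$end[ai])
    } else pc$span
    rows[[length(rows) + 1L]] <- data.frame(
      seed = a, seed_type = "anchor",
      contig_id = g$contig_id[match(a, g$gene_id)],
      susC_gene = if (pc$pair_found) pc$pair_genes[["susC"]] else NA_character_,
      susD_gene = if (pc$pair_found) pc$pair_genes[["susD"]] else NA_character_,
      n_cazymes = length(pc$cazymes_in_reach),
      cazymes = paste(pc$cazymes_in_reach, collapse = ","),
      verdict = pc$verdict, start = span[["start"]], end = span[["end"]],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(seed = character(), seed_type = character(),
                      contig_id = character(), susC_gene = character(),
                      susD_gene = character(), n_cazymes = integer(),
                      cazymes = character(), verdict = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  # deduplicate identical evidence spans (an anchor call restating a pair call)
  dup <- duplicated(out[, c("contig_id", "start", "end", "verdict")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dispersion summary of a pathway gene set
#'
#' Operationalises "spread over the genome, not localized in a PUL": the
#' set is `clustered` iff all genes share one contig and the minimal
#' enclosing rank window (max rank - min rank + 1) is at most `threshold`
#' ORFs; otherwise `dispersed`. The default threshold (15) is the full
#' anchor window size (7 + 1 + 7). Pairwise distances are reported in ORF
#' ranks; gene pairs on different contigs get `NA`.
#'
#' @param genome a `genome_annotation`.
#' @param gene_set character vector of gene ids.
#' @param threshold maximal enclosing window still called clustered.
#' @return list of class `dispersion_report`.
#' @export
dispersion_summary <- function(genome, gene_set, threshold = 15) {
  g <- genome$genes
  ix <- match(gene_set, g$gene_id)
  if (anyNA(ix))
    stop("unknown gene(s): ", paste(gene_set[is.na(ix)], collapse = ", "))
  contigs <- g$contig_id[ix]
  ranks <- g$rank[ix]
  k <- length(gene_set)
  dmat <- matrix(NA_integer_, k, k, dimnames = list(gene_set, gene_set))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (contigs[i] == contigs[j]) {
      n <- sum(g$contig_id == contigs[i])
      dmat[i, j] <- rank_dist(ranks[i], ranks[j], n,
                              isTRUE(genome$circular[[contigs[i]]]))
    }
  }
  one_contig <- length(unique(contigs)) == 1
  window <- if (one_contig) diff(range(ranks)) + 1L else NA_integer_
  verdict <- if (one_contig && window <= threshold) "clustered" else "dispersed"
  structure(list(gene_set = gene_set, contigs = contigs, ranks = ranks,
                 pairwise_rank_distances = dmat,
                 min_enclosing_window = window, threshold = threshold,
                 verdict = verdict),
            class = "dispersion_report")
}

#' @export
print.dispersion_report <- function(x, ...) {
  cat("dispersion_report:", length(x$gene_set), "genes ->", x$verdict, "\n")
  if (!is.na(x$min_enclosing_window))
    cat("  min enclosing window:", x$min_enclosing_window, "ORFs (threshold",
        x$threshold, ")\n")
  invisible(x)
}

#' Export PUL catalog spans as BED
#' @param catalog data.frame from [genome_pul_catalog()].
#' @param path output BED file (0-based half-open).
#' @export
write_pul_bed <- function(catalog, path) {
  puls <- catalog[catalog$verdict == "PUL", , drop = FALSE]
  bed <- coords_to_bed(data.frame(contig_id = puls$contig_id,
                                  start = puls$start, end = puls$end,
                                  name = puls$seed))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
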