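#' Read a multi-tool domain-hit table
#'
#' The dialect mirrors a dbCAN-style overview table flattened to long form:
#' one row per (protein, tool, label) hit. `hit_class` distinguishes
#' motif-specific hits from superfamily-only hits (the distinction used to
#' separate sugar-transporting SusC proteins from generic TonB-dependent
#' receptors).
#'
#' @param path TSV with columns `protein_id`, `tool`, `label` and
#'   optionally `hit_class`, `start`, `end`, `score`.
#' @return data.frame of domain hits.
#' @export
read_domain_hits <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("protein_id", "tool", "label")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("format error: hit table lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!"hit_class" %in% names(tab)) tab$hit_class <- NA_character_
  if (!"start" %in% names(tab)) tab$start <- NA_integer_
  if (!"end" %in% names(tab)) tab$end <- NA_integer_
  if (!"score" %in% names(tab)) tab$score <- NA_real_
  bad <- !is.na(tab$start) & !is.na(tab$end) & tab$end < tab$start
  if (any(bad)) stop("validation error: hit end < start for protein(s) ",
                     paste(unique(tab$protein_id[bad]), collapse = ", "))
  tab
}

cazy_family_re <- "^(GH|GT|PL|CE|AA|CBM)[0-9]+(_[0-9]+)?$"

#' Consensus CAZyme calls from multi-tool hits
#'
#' A protein is called a CAZyme of a family when at least `min_tools`
#' distinct tools of the declared tool set report that family. The vote is
#' counted at family level (GH16), not subfamily level: tools frequently
#' disagree on the subfamily while agreeing on the family. The subfamily
#' label (e.g. GH16_3) is taken from the single subfamily-capable tool.
#' Hits from tools outside `tool_set` (e.g. CDD rows for SusC/SusD in a
#' combined table) are ignored.
#'
#' @param hits data.frame as from [read_domain_hits()].
#' @param min_tools minimum number of agreeing tools (default 2).
#' @param tool_set the declared CAZyme annotation tools (default 3 engines).
#' @param subfamily_tool the tool whose labels carry subfamily resolution.
#' @return data.frame with `protein_id`, `family`, `subfamily`, `support`,
#'   sorted by protein then family (so the result is order-invariant).
#' @export
consensus_cazyme <- function(hits,
                             min_tools = 2,
                             tool_set = c("hmmer", "dbcan_sub", "diamond"),
                             subfamily_tool = "dbcan_sub") {
  if (min_tools > length(tool_set))
    stop("config error: min_tools (", min_tools,
         ") exceeds tool_set size (", length(tool_set), ")")
  hits <- hits[hits$tool %in% tool_set & grepl(cazy_family_re, hits$label), ,
               drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(protein_id = character(), family = character(),
                      subfamily = character(), support = integer(),
                      stringsAsFactors = FALSE))
  hits$family <- sub("_.*$", "", hits$label)
  key <- paste(hits$protein_id, hits$family, sep = "\r")
  votes <- tapply(hits$tool, key, function(t) length(unique(t)))
  keep <- names(votes)[votes >= min_tools]
  if (length(keep) == 0)
    return(data.frame(protein_id = character(), family = character(),
                      subfamily = character(), support = integer(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(protein_id = vapply(parts, `[`, "", 1),
                    family = vapply(parts, `[`, "", 2),
                    subfamily = "",
                    support = as.integer(votes[keep]),
                    stringsAsFactors = FALSE)
  sub_hits <- hits[hits$tool == subfamily_tool & grepl("_", hits$label), ,
                   drop = FALSE]
  if (nrow(sub_hits) > 0) {
    skey <- paste(sub_hits$protein_id, sub_hits$family, sep = "\r")
    sublab <- tapply(sub_hits$label, skey, function(l) sort(unique(l))[1])
    m <- match(paste(out$protein_id, out$family, sep = "\r"), names(sublab))
    out$subfamily[!is.na(m)] <- as.character(sublab[m[!is.na(m)]])
  }
  out <- out[order(out$protein_id, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify SusC/SusD proteins from domain hits
#'
#' SusC calls are split by evidence strength: a hit of class `specific` on
#' the sugar-transporter motif (TIGR04056 by default) gives
#' `susC_specific`; superfamily-only hits on that motif give
#' `susC_superfamily` (transporter annotation not clearly established).
#' SusD proteins are recognised by any of the configured SusD family
#' labels. A protein carrying both SusC and SusD evidence is a conflict:
#' it is excluded from the output (and from downstream pairing) and
#' reported via a warning and the `conflicts` attribute.
#'
#' @param hits data.frame as from [read_domain_hits()].
#' @param susc_motif_label motif label whose specific hit defines SusC.
#' @param susd_labels labels accepted as SusD family evidence.
#' @return data.frame with `protein_id` and `class` in
#'   `susC_specific`, `susC_superfamily`, `susD`.
#' @export
classify_sus <- function(hits,
                         susc_motif_label = "TIGR04056",
                         susd_labels = c("SusD", "SusD-like", "PF07980",
                                         "PF12741", "PF12771", "PF14322")) {
  sc <- hits[hits$label == susc_motif_label, , drop = FALSE]
  sd <- hits[hits$label %in% susd_labels, , drop = FALSE]
  susc_ids <- unique(sc$protein_id)
  susd_ids <- unique(sd$protein_id)
  conflicts <- intersect(susc_ids, susd_ids)
  if (length(conflicts) > 0) {
    warning("protein(s) with both SusC and SusD evidence excluded from pairing: ",
            paste(conflicts, collapse = ", "))
    susc_ids <- setdiff(susc_ids, conflicts)
    susd_ids <- setdiff(susd_ids, conflicts)
  }
  specific <- unique(sc$protein_id[!is.na(sc$hit_class) &
                                     sc$hit_class == "specific"])
  specific <- intersect(susc_ids, specific)
  superfam <- setdiff(susc_ids, specific)
  out <- data.frame(
    protein_id = c(specific, superfam, susd_ids),
    class = c(rep("susC_specific", length(specific)),
              rep("susC_superfamily", length(superfam)),
              rep("susD", length(susd_ids))),
    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicts
  out
}

map_protein_to_gene <- function(genome, protein_ids) {
  g <- genome$genes
  hit <- match(protein_ids, g$protein_id)
  fallback <- match(protein_ids, g$gene_id)
  hit[is.na(hit)] <- fallback[is.na(hit)]
  hit
}

#' Detect SusC/SusD tandem pairs in a genome
#'
#' Default geometry is the canonical Bacteroidota tandem: susC and susD at
#' consecutive ranks, on the same strand, with susD immediately downstream
#' of susC in the susC reading direction (rank + 1 on the plus strand,
#' rank - 1 on the minus strand). `max_intervening` relaxes adjacency to
#' allow that many ORFs between the two; `same_strand = FALSE` drops the
#' strand requirement. Pairing is resolved greedily left-to-right by susC
#' rank, and each gene joins at most one pair.
#'
#' @param genome a `genome_annotation`.
#' @param sus data.frame from [classify_sus()]; `protein_id` is matched
#'   against the genome's protein ids, falling back to gene ids.
#' @param max_intervening ORFs allowed between susC and susD (default 0).
#' @param same_strand require both genes on one strand (default TRUE).
#' @return data.frame with one row per pair: contig, gene ids, ranks,
#'   strand and the bp span covering both genes.
#' @export
detect_suscd_pairs <- function(genome, sus, max_intervening = 0,
                               same_strand = TRUE) {
  g <- genome$genes
  empty <- data.frame(contig_id = character(), susC_gene = character(),
                      susD_gene = character(), susC_rank = integer(),
                      susD_rank = integer(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(sus) == 0) return(empty)
  row_of <- map_protein_to_gene(genome, sus$protein_id)
  if (anyNA(row_of))
    stop("SusCall protein(s) not found in genome: ",
         paste(sus$protein_id[is.na(row_of)], collapse = ", "))
  susc_rows <- row_of[grepl("^susC", sus$class)]
  susd_rows <- row_of[sus$class == "susD"]
  if (length(susc_rows) == 0 || length(susd_rows) == 0) return(empty)
  susc_rows <- susc_rows[order(g$contig_id[susc_rows], g$rank[susc_rows])]
  used_d <- logical(nrow(g))
  pairs <- list()
  for (cr in susc_rows) {
    dir <- if (g$strand[cr] == "+") 1L else -1L
    for (gap in 0:max_intervening) {
      target <- g$rank[cr] + dir * (1L + gap)
      cand <- susd_rows[g$contig_id[susd_rows] == g$contig_id[cr] &
                          g$rank[susd_rows] == target & !used_d[susd_rows]]
      if (same_strand) cand <- cand[g$strand[cand] == g$strand[cr]]
      if (length(cand) > 0) {
        dr <- cand[1]
        used_d[dr] <- TRUE
        pairs[[length(pairs) + 1L]] <- data.frame(
          contig_id = g$contig_id[cr], susC_gene = g$gene_id[cr],
          susD_gene = g$gene_id[dr], susC_rank = g$rank[cr],
          susD_rank = g$rank[dr], strand = g$strand[cr],
          start = min(g$start[c(cr, dr)]), end = max(g$end[c(cr, dr)]),
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (length(pairs) == 0) return(empty)
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' Scan a protein sequence for a motif with bounded mismatches
#'
#' Reports every position where `motif` matches the sequence with at most
#' `max_mismatch` substitutions. An `X` in the sequence (unknown residue)
#' never counts as a match, whatever the motif character. A motif longer
#' than the sequence yields no matches.
#'
#' @param sequence protein string over the 20-letter alphabet plus X.
#' @param motif amino-acid pattern (plain string, no wildcards).
#' @param max_mismatch allowed substitutions (default 0 = exact).
#' @return data.frame with `start` (1-based), `mismatches`, `match`.
#' @export
scan_motif <- function(sequence, motif, max_mismatch = 0) {
  stopifnot(length(sequence) == 1, length(motif) == 1, nchar(motif) > 0)
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  L <- nchar(sequence)
  m <- nchar(motif)
  empty <- data.frame(start = integer(), mismatches = integer(),
                      match = character(), stringsAsFactors = FALSE)
  if (m > L || L == 0) return(empty)
  sq <- strsplit(sequence, "", fixed = TRUE)[[1]]
  mo <- strsplit(motif, "", fixed = TRUE)[[1]]
  n_pos <- L - m + 1L
  mism <- integer(n_pos)
  for (j in seq_len(m)) {
    sj <- sq[j:(j + n_pos - 1L)]
    mism <- mism + as.integer(sj != mo[j] | sj == "X")
  }
  ok <- which(mism <= max_mismatch)
  if (length(ok) == 0) return(empty)
  data.frame(start = ok, mismatches = mism[ok],
             match = substring(sequence, ok, ok + m - 1L),
             stringsAsFactors = FALSE)
}

#' Conserved GH16_3 laminarinase motifs
#'
#' Finger-region motifs used to separate endo-beta-1,3-laminarinases from
#' related GH16 activities: `finger3_trp` carries the two tryptophans
#' flanking finger three that are conserved in beta-1,3-glucanases;
#' `finger1_gal` is the finger-one motif of GH16 galactosidases (its
#' absence leaves room for glucose at the subsite); `wpa` is the
#' active-site WPA tripeptide.
#' @export
gh16_motifs <- list(
  finger3_trp = "GGTWPALWALGANFDEVGWP",
  finger1_gal = "WKLCTYNNAWSQ",
  wpa = "WPA")

gh16_required_domains <- c("signal_peptide", "PKD", "laminarin_binding",
                           "GH16_cat_N", "inserted_DUF", "GH16_cat_C",
                           "WPA_site")

#' Build a domain architecture record
#'
#' When `WPA_site` is absent from the domain table but a sequence is given,
#' the site is derived by an exact WPA motif scan restricted to the
#' catalytic spans (GH16_cat_N / GH16_cat_C) if annotated, else the whole
#' sequence.
#'
#' @param protein_id protein identifier.
#' @param length protein length (AA).
#' @param domains data.frame with `name`, `start`, `end` (1-based AA).
#' @param sequence optional AA string used to derive the WPA site.
#' @return list of class `domain_architecture`.
#' @export
domain_architecture <- function(protein_id, length, domains,
                                sequence = NULL) {
  domains <- as.data.frame(domains, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end") %in% names(domains)))
  if (!"WPA_site" %in% domains$name && !is.null(sequence)) {
    hits <- scan_motif(sequence, gh16_motifs$wpa, 0)
    cat_spans <- domains[domains$name %in% c("GH16_cat_N", "GH16_cat_C"), ,
                         drop = FALSE]
    if (nrow(cat_spans) > 0 && nrow(hits) > 0) {
      inside <- vapply(hits$start, function(s) {
        any(s >= cat_spans$start & s + 2 <= cat_spans$end)
      }, logical(1))
      hits <- hits[inside, , drop = FALSE]
    }
    if (nrow(hits) > 0)
      domains <- rbind(domains,
                       data.frame(name = "WPA_site", start = hits$start[1],
                                  end = hits$start[1] + 2L,
                                  stringsAsFactors = FALSE))
  }
  domains <- domains[order(domains$start, domains$end), , drop = FALSE]
  rownames(domains) <- NULL
  structure(list(protein_id = protein_id, length = as.integer(length),
                 domains = domains),
            class = "domain_architecture")
}

#' Classify a GH16 domain architecture
#'
#' The canonical large laminarinase carries a signal peptide, a PKD
#' (polycystic-kidney-disease-like) beta-sandwich, a laminarin-binding
#' domain, and a split GH16 catalytic domain (N and C parts with an
#' inserted domain of unknown function between them) containing the WPA
#' active site. The class is `canonical_large_laminarinase` iff all of
#' these are present and the catalytic split is in order; a protein length
#' outside `length_window` only raises the `length_out_of_window` flag,
#' it does not demote the class.
#'
#' Validation applies to the core ordered chain (signal peptide, PKD and
#' the catalytic split): unsorted or mutually overlapping spans there are
#' an error. The laminarin-binding domain, lipid-attachment site and WPA
#' site are inherently nested within other domains and are exempt.
#'
#' @param arch a `domain_architecture`.
#' @param length_window AA length window of known full-domain homologues.
#' @return list with `class`, `flags`, `missing`.
#' @export
classify_gh16_architecture <- function(arch, length_window = c(687, 705)) {
  stopifnot(inherits(arch, "domain_architecture"))
  d <- arch$domains
  if (nrow(d) > 0) {
    if (any(d$start < 1 | d$end > arch$length | d$end < d$start))
      stop("validation error: domain span outside [1, length] for ",
           arch$protein_id)
    core <- d[d$name %in% c("signal_peptide", "PKD", "GH16_cat_N",
                            "inserted_DUF", "GH16_cat_C"), , drop = FALSE]
    if (nrow(core) > 1) {
      core <- core[order(core$start), , drop = FALSE]
      if (any(core$start[-1] <= core$end[-nrow(core)]))
        stop("validation error: overlapping mandatory domains in ",
             arch$protein_id)
    }
  }
  present <- unique(d$name)
  missing <- setdiff(gh16_required_domains, present)
  flags <- character()
  split_ok <- all(c("GH16_cat_N", "inserted_DUF", "GH16_cat_C") %in% present)
  if (split_ok) {
    s <- function(nm) d$start[match(nm, d$name)]
    split_ok <- s("GH16_cat_N") < s("inserted_DUF") &&
      s("inserted_DUF") < s("GH16_cat_C")
    if (!split_ok) flags <- c(flags, "catalytic_split_out_of_order")
  }
  cls <- if (length(missing) == 0 && split_ok)
    "canonical_large_laminarinase" else "non_canonical"
  if (arch$length < length_window[1] || arch$length > length_window[2])
    flags <- c(flags, "length_out_of_window")
  list(class = cls, flags = flags, missing = missing)
}

#' Write annotation calls as TSV
#' @param calls data.frame of calls (CAZyme, Sus or pair table).
#' @param path output file.
#' @export
write_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
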