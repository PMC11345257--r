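#' Construct a genome annotation from a gene table
#'
#' The central coordinate system of the package: an ordered, stranded gene
#' model. Genes are ranked 0-based along each contig by ascending start
#' (ties broken by end, then `gene_id`), and every window-based analysis
#' ([neighborhood()], [call_pul_at_anchor()], [dispersion_summary()]) counts
#' distance in these ranks ("ORF ranks"), not base pairs.
#'
#' Coordinates are 1-based inclusive throughout (GenBank/GFF3 convention);
#' the only conversion to 0-based half-open lives in [coords_to_bed()].
#'
#' @param genes data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` and optionally `protein_id`, `product`.
#' @param organism free-text organism name.
#' @param circular named logical vector (by contig id) marking circular
#'   contigs; contigs not named default to linear, as do draft scaffolds.
#' @return An object of class `genome_annotation`: a list with elements
#'   `genes` (the ranked gene table), `organism` and `circular`.
#' @export
genome_annotation <- function(genes, organism = "", circular = NULL) {
  req <- c("gene_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(req, names(genes))
  if (length(miss) > 0)
    stop("gene table lacks required column(s): ", paste(miss, collapse = ", "))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(genes)) genes$protein_id <- NA_character_
  if (!"product" %in% names(genes)) genes$product <- ""
  genes$gene_id <- as.character(genes$gene_id)
  genes$contig_id <- as.character(genes$contig_id)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  genes$strand[genes$strand %in% c("−", "-1")] <- "-"
  genes$strand[genes$strand %in% c("1")] <- "+"

  if (anyNA(genes$start) || anyNA(genes$end))
    stop("validation error: non-numeric gene coordinates")
  if (any(genes$end < genes$start))
    stop("validation error: end < start for gene(s) ",
         paste(genes$gene_id[genes$end < genes$start], collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("validation error: strand must be '+' or '-'")
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0)
    stop("validation error: duplicate gene_id: ",
         paste(unique(dup), collapse = ", "))

  # deterministic rank: start, then end, then gene_id; 0-based per contig
  contig_order <- unique(genes$contig_id)
  genes <- genes[order(match(genes$contig_id, contig_order),
                       genes$start, genes$end, genes$gene_id), , drop = FALSE]
  genes$rank <- unlist(lapply(split(seq_len(nrow(genes)), genes$contig_id)[contig_order],
                              function(ix) seq_along(ix) - 1L), use.names = FALSE)
  rownames(genes) <- NULL

  circ <- setNames(rep(FALSE, length(contig_order)), contig_order)
  if (!is.null(circular)) {
    known <- intersect(names(circular), contig_order)
    circ[known] <- as.logical(circular[known])
  }
  structure(list(genes = genes, organism = organism, circular = circ),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", if (nzchar(x$organism)) x$organism else "<unnamed>",
      "\n  contigs:", length(x$circular),
      " genes:", nrow(x$genes), "\n")
  invisible(x)
}

#' Ranked gene table of a genome annotation
#' @param genome a `genome_annotation`.
#' @return data.frame with one row per gene, including the 0-based `rank`.
#' @export
gene_table <- function(genome) {
  stopifnot(inherits(genome, "genome_annotation"))
  genome$genes
}

#' Load a genome annotation from GFF3, GenBank or TSV
#'
#' GFF3 is read through rtracklayer; `gene` features are taken as gene
#' records and `CDS` features without a gene parent are promoted. GenBank
#' flat files are parsed for CDS features (outer span of joined locations).
#' The TSV dialect has columns `gene_id`, `contig` (or `contig_id`),
#' `start`, `end`, `strand` and optionally `protein_id`, `product`.
#'
#' @inheritParams genome_annotation
#' @param path annotation file.
#' @param format one of `"gff3"`, `"genbank"`, `"tsv"`.
#' @return A `genome_annotation`.
#' @export
load_genome <- function(path, format = c("gff3", "genbank", "tsv"),
                        organism = "", circular = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  genes <- switch(format,
    gff3 = parse_gff3_genes(path),
    genbank = parse_genbank_cds(path),
    tsv = parse_gene_tsv(path))
  genome_annotation(genes, organism = organism, circular = circular)
}

parse_gff3_genes <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("format error parsing GFF3 '", path,
                                          "': ", conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  get_attr <- function(ix, field) {
    if (!field %in% names(md)) return(rep(NA_character_, length(ix)))
    v <- md[[field]][ix]
    if (is.list(v) || methods::is(v, "List"))
      v <- vapply(as.list(v), function(z) if (length(z)) as.character(z[[1]]) else NA_character_, "")
    as.character(v)
  }
  gi <- which(typ == "gene")
  ci <- which(typ == "CDS")
  pick_id <- function(ix) {
    id <- get_attr(ix, "locus_tag")
    alt <- get_attr(ix, "ID")
    id[is.na(id)] <- alt[is.na(id)]
    nm <- get_attr(ix, "Name")
    id[is.na(id)] <- nm[is.na(id)]
    id
  }
  rows <- function(ix, protein_id) {
    if (length(ix) == 0) return(NULL)
    data.frame(gene_id = pick_id(ix),
               protein_id = protein_id,
               contig_id = as.character(GenomicRanges::seqnames(gr))[ix],
               start = GenomicRanges::start(gr)[ix],
               end = GenomicRanges::end(gr)[ix],
               strand = as.character(GenomicRanges::strand(gr))[ix],
               product = ifelse(is.na(get_attr(ix, "product")), "",
                                get_attr(ix, "product")),
               stringsAsFactors = FALSE)
  }
  gene_rows <- rows(gi, NA_character_)
  gene_ids <- if (is.null(gene_rows)) character() else gene_rows$gene_id
  # attach protein ids from child CDS; promote orphan CDS to gene records
  if (length(ci) > 0) {
    parent <- get_attr(ci, "Parent")
    parent_gene <- sub("^gene-", "", ifelse(is.na(parent), "", parent))
    cds_prot <- get_attr(ci, "protein_id")
    hit <- match(parent_gene, gene_ids)
    # Parent attribute may carry the gene feature's ID rather than locus_tag
    if (!is.null(gene_rows) && any(is.na(hit))) {
      alt_ids <- get_attr(gi, "ID")
      hit2 <- match(parent_gene, alt_ids)
      hit[is.na(hit)] <- hit2[is.na(hit)]
    }
    ok <- !is.na(hit) & !is.na(cds_prot)
    if (any(ok)) gene_rows$protein_id[hit[ok]] <- cds_prot[ok]
    orphan <- is.na(hit)
    if (any(orphan)) {
      orows <- rows(ci[orphan], cds_prot[orphan])
      orows$gene_id[is.na(orows$gene_id)] <- orows$protein_id[is.na(orows$gene_id)]
      gene_rows <- rbind(gene_rows, orows)
    }
  }
  if (is.null(gene_rows) || nrow(gene_rows) == 0)
    stop("format error: no gene/CDS features in '", path, "'")
  if (anyNA(gene_rows$gene_id))
    stop("format error: gene/CDS feature without identifier in '", path, "'")
  gene_rows$strand[!gene_rows$strand %in% c("+", "-")] <- "+"
  gene_rows
}

# Minimal GenBank flat-file CDS parser: locations (including
# complement()/join()) are reduced to their outer span; qualifiers
# locus_tag, protein_id and product are retained.
parse_genbank_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  contig <- NA_character_
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (grepl("^LOCUS", ln)) {
      contig <- strsplit(trimws(sub("^LOCUS", "", ln)), "\\s+")[[1]][1]
    } else if (grepl("^     CDS\\s", ln)) {
      if (is.na(contig))
        stop("format error: CDS before LOCUS at line ", i, " of '", path, "'")
      loc <- trimws(sub("^     CDS", "", ln))
      j <- i + 1L
      while (j <= n && !grepl("^\\s{21}/", lines[j]) &&
             grepl("^\\s{21}\\S", lines[j]) && !grepl("^     \\S", lines[j])) {
        loc <- paste0(loc, trimws(lines[j])); j <- j + 1L
      }
      strand <- if (grepl("complement", loc)) "-" else "+"
      pos <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      if (length(pos) < 1)
        stop("format error: unparseable CDS location at line ", i,
             " of '", path, "': ", loc)
      quals <- character()
      while (j <= n && !grepl("^     \\S", lines[j]) && !grepl("^LOCUS|^ORIGIN|^//", lines[j])) {
        quals <- c(quals, trimws(lines[j])); j <- j + 1L
      }
      qtxt <- paste(quals, collapse = " ")
      getq <- function(name) {
        m <- regmatches(qtxt, regexpr(paste0("/", name, '="[^"]*"'), qtxt))
        if (length(m) == 0) NA_character_ else sub('"$', "", sub(paste0("^/", name, '="'), "", m))
      }
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = NA_character_, protein_id = getq("protein_id"),
        contig_id = contig, start = as.integer(min(pos)),
        end = as.integer(max(pos)), strand = strand,
        product = ifelse(is.na(getq("product")), "", getq("product")),
        locus_tag = getq("locus_tag"), stringsAsFactors = FALSE)
      i <- j
      next
    }
    i <- i + 1L
  }
  if (length(recs) == 0)
    stop("format error: no CDS features found in '", path, "'")
  genes <- do.call(rbind, recs)
  genes$gene_id <- ifelse(!is.na(genes$locus_tag), genes$locus_tag,
                          genes$protein_id)
  if (anyNA(genes$gene_id))
    stop("format error: CDS without locus_tag/protein_id in '", path, "'")
  genes$locus_tag <- NULL
  genes
}

parse_gene_tsv <- function(path) {
  tab <- tryCatch(read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE),
                  error = function(e) stop("format error parsing TSV '", path,
                                           "': ", conditionMessage(e)))
  if ("contig" %in% names(tab) && !"contig_id" %in% names(tab))
    names(tab)[names(tab) == "contig"] <- "contig_id"
  req <- c("gene_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("format error: TSV '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' Extract the rank-window neighbourhood of an anchor gene
#'
#' Returns up to `up + down + 1` genes centred on the anchor, in contig rank
#' order. "Upstream/downstream" means contig order (left/right of the
#' anchor), not the anchor's reading direction, so the window is symmetric
#' under strand flips; the anchor's own strand stays available in the
#' returned table for reading-direction tests. Windows truncate at the ends
#' of linear contigs and wrap across the origin of circular ones (each gene
#' returned at most once).
#'
#' @param genome a `genome_annotation`.
#' @param anchor gene id present in the genome.
#' @param up,down number of genes to take left / right of the anchor.
#' @return data.frame of gene records in window order.
#' @export
neighborhood <- function(genome, anchor, up = 7, down = 7) {
  stopifnot(inherits(genome, "genome_annotation"), up >= 0, down >= 0)
  g <- genome$genes
  hit <- match(anchor, g$gene_id)
  if (is.na(hit)) stop("unknown anchor gene: ", anchor)
  contig <- g$contig_id[hit]
  cg <- g[g$contig_id == contig, , drop = FALSE]
  n <- nrow(cg)
  r <- g$rank[hit]
  if (isTRUE(genome$circular[[contig]])) {
    idx <- ((r - up):(r + down)) %% n
    idx <- idx[!duplicated(idx)]
  } else {
    idx <- max(0L, r - up):min(n - 1L, r + down)
  }
  out <- cg[match(idx, cg$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a gene table as TSV
#' @param genome a `genome_annotation`.
#' @param path output file.
#' @export
write_gene_table <- function(genome, path) {
  write.table(gene_table(genome), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Convert 1-based inclusive spans to BED (0-based half-open)
#'
#' The single place where the package's internal coordinate convention is
#' converted for export.
#'
#' @param df data.frame with `contig_id`, `start`, `end` (1-based inclusive)
#'   and optionally `name`.
#' @return data.frame with columns `chrom`, `chromStart`, `chromEnd`, `name`.
#' @export
coords_to_bed <- function(df) {
  data.frame(chrom = df$contig_id,
             chromStart = as.integer(df$start) - 1L,
             chromEnd = as.integer(df$end),
             name = if ("name" %in% names(df)) df$name else ".",
             stringsAsFactors = FALSE)
}
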