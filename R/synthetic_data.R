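#' Synthetic annotated genome with planted PULs and dispersed pathway genes
#'
#' Generates an ordered, stranded gene model plus a multi-tool domain-hit
#' table and a ground-truth record, emulating the two genome organisations
#' contrasted in comparative studies of laminarin utilization: transporter
#' and CAZyme genes co-located in a PUL versus the same functions dispersed
#' across the genome.
#'
#' Features are placed on anchor slots spaced 30 ORF ranks apart, so no
#' planted element can interact with another through the default 7/7/8
#' windows. Planted PULs are a susC/susD tandem (consecutive ranks, plus
#' strand) with a GH16_3 gene two ranks left of susC (3 tool votes) and a
#' GH3 gene two ranks right of susD (2 votes). Decoys exercise the negative
#' paths: susC/susD tandems without any CAZyme in reach, lone
#' superfamily-only susC genes, and CAZyme hits with a single tool vote.
#' Dispersed pathway genes are consensus-grade CAZymes placed pairwise at
#' least `min_dispersion_distance` ranks apart.
#'
#' @param seed RNG seed; equal seeds give identical output.
#' @param n_contigs,genes_per_contig genome shape (default 3 x 700).
#' @param n_planted_puls planted true PULs (default 3).
#' @param n_dispersed_pathway_genes dispersed consensus CAZymes (default 8).
#' @param min_dispersion_distance minimal pairwise ORF distance between
#'   dispersed genes on a contig (default 100).
#' @param n_decoy_pairs susC/D tandems without CAZymes (default 2).
#' @param n_lone_susc unpaired superfamily-only susC genes (default 2).
#' @param n_decoy_cazymes single-vote CAZyme decoys (default 10).
#' @param circular mark all contigs circular (default FALSE).
#' @return list with `genome` (a `genome_annotation`), `hits` (domain-hit
#'   data.frame) and `truth` (planted PULs with spans, dispersed gene set,
#'   decoy records).
#' @export
sim_genome <- function(seed, n_contigs = 3, genes_per_contig = 700,
                       n_planted_puls = 3, n_dispersed_pathway_genes = 8,
                       min_dispersion_distance = 100, n_decoy_pairs = 2,
                       n_lone_susc = 2, n_decoy_cazymes = 10,
                       circular = FALSE) {
  set.seed(seed)
  stopifnot(genes_per_contig >= 60)
  contigs <- sprintf("contig_%02d", seq_len(n_contigs))

  genes <- do.call(rbind, lapply(contigs, function(cid) {
    len <- sample(600:1500, genes_per_contig, replace = TRUE)
    gap <- sample(50:250, genes_per_contig, replace = TRUE)
    start <- cumsum(c(1L, head(len + gap, -1)))
    data.frame(gene_id = sprintf("%s_g%04d", cid, seq_len(genes_per_contig)),
               protein_id = sprintf("p_%s_g%04d", cid,
                                    seq_len(genes_per_contig)),
               contig_id = cid, start = start, end = start + len - 1L,
               strand = sample(c("+", "-"), genes_per_contig, replace = TRUE),
               product = "hypothetical protein", stringsAsFactors = FALSE)
  }))

  # feature slots: anchor ranks >= 30 apart, clear of contig ends
  slot_step <- 30L
  slots <- do.call(rbind, lapply(contigs, function(cid) {
    data.frame(contig = cid,
               rank = seq(12L, genes_per_contig - 13L, by = slot_step),
               stringsAsFactors = FALSE)
  }))

  # dispersed pathway genes first: enforce pairwise rank spacing per contig
  min_slot_gap <- ceiling(min_dispersion_distance / slot_step)
  dispersed <- data.frame(contig = character(), rank = integer())
  taken <- rep(FALSE, nrow(slots))
  ci <- 0L
  misses <- 0L
  while (nrow(dispersed) < n_dispersed_pathway_genes) {
    ci <- ci %% n_contigs + 1L
    cand <- which(!taken & slots$contig == contigs[ci])
    prev <- dispersed$rank[dispersed$contig == contigs[ci]]
    if (length(prev) > 0)
      cand <- cand[vapply(slots$rank[cand], function(r)
        all(abs(r - prev) >= min_dispersion_distance), logical(1))]
    if (length(cand) == 0) {
      misses <- misses + 1L
      if (misses >= n_contigs)
        stop("config error: not enough slots for the requested dispersion")
      next
    }
    misses <- 0L
    pick <- cand[sample.int(length(cand), 1)]
    taken[pick] <- TRUE
    dispersed <- rbind(dispersed, data.frame(contig = slots$contig[pick],
                                             rank = slots$rank[pick]))
  }
  free <- which(!taken)
  need <- n_planted_puls + n_decoy_pairs + n_lone_susc + n_decoy_cazymes
  if (length(free) < need) stop("config error: not enough feature slots")
  free <- free[sample.int(length(free))]
  take <- function(k) {
    if (k == 0) return(slots[integer(0), , drop = FALSE])
    out <- free[seq_len(k)]
    free <<- free[-seq_len(k)]
    slots[out, , drop = FALSE]
  }
  pul_slots <- take(n_planted_puls)
  decoy_pair_slots <- take(n_decoy_pairs)
  lone_slots <- take(n_lone_susc)
  decoy_caz_slots <- take(n_decoy_cazymes)

  gene_at <- function(contig, rank)
    genes$gene_id[genes$contig_id == contig][rank + 1L]
  prot_of <- function(gid) genes$protein_id[match(gid, genes$gene_id)]
  set_strand <- function(gid, s)
    genes$strand[match(gid, genes$gene_id)] <<- s
  set_product <- function(gid, p)
    genes$product[match(gid, genes$gene_id)] <<- p

  hits <- list()
  add_hit <- function(gid, tool, label, hit_class = NA_character_) {
    hits[[length(hits) + 1L]] <<- data.frame(
      protein_id = prot_of(gid), tool = tool, label = label,
      hit_class = hit_class, start = NA_integer_, end = NA_integer_,
      score = NA_real_, stringsAsFactors = FALSE)
  }
  add_cazyme <- function(gid, family, subfamily = NULL, votes = 2) {
    tools <- c("hmmer", "diamond", "dbcan_sub")[seq_len(votes)]
    for (tl in tools)
      add_hit(gid, tl, if (tl == "dbcan_sub" && !is.null(subfamily))
        subfamily else family)
  }
  plant_pair <- function(contig, rank) {
    susc <- gene_at(contig, rank); susd <- gene_at(contig, rank + 1L)
    set_strand(susc, "+"); set_strand(susd, "+")
    set_product(susc, "TonB-dependent transporter SusC")
    set_product(susd, "SusD family lipoprotein")
    add_hit(susc, "cdd", "TIGR04056", "specific")
    add_hit(susd, "cdd", "SusD")
    c(susC = susc, susD = susd)
  }

  truth_puls <- list()
  for (k in seq_len(nrow(pul_slots))) {
    contig <- pul_slots$contig[k]; r <- pul_slots$rank[k]
    pair <- plant_pair(contig, r)
    gh16 <- gene_at(contig, r - 2L)
    gh3 <- gene_at(contig, r + 3L)
    add_cazyme(gh16, "GH16", "GH16_3", votes = 3)
    set_product(gh16, "glycoside hydrolase family 16 laminarinase")
    add_cazyme(gh3, "GH3", votes = 2)
    set_product(gh3, "beta-glucosidase GH3")
    members <- c(gh16, pair[["susC"]], pair[["susD"]], gh3)
    gi <- match(members, genes$gene_id)
    truth_puls[[k]] <- data.frame(
      contig_id = contig, susC_gene = pair[["susC"]],
      susD_gene = pair[["susD"]], cazymes = paste(c(gh16, gh3),
                                                  collapse = ","),
      start = min(genes$start[gi]), end = max(genes$end[gi]),
      stringsAsFactors = FALSE)
  }
  truth_puls <- if (length(truth_puls) > 0) do.call(rbind, truth_puls) else
    data.frame(contig_id = character(), susC_gene = character(),
               susD_gene = character(), cazymes = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)

  decoy_pairs <- character(0)
  for (k in seq_len(nrow(decoy_pair_slots))) {
    pair <- plant_pair(decoy_pair_slots$contig[k], decoy_pair_slots$rank[k])
    decoy_pairs <- c(decoy_pairs, pair[["susC"]])
  }
  lone_susc <- character(0)
  for (k in seq_len(nrow(lone_slots))) {
    gid <- gene_at(lone_slots$contig[k], lone_slots$rank[k])
    add_hit(gid, "cdd", "TIGR04056", "superfamily")
    set_product(gid, "TonB-dependent receptor")
    lone_susc <- c(lone_susc, gid)
  }
  decoy_caz <- character(0)
  for (k in seq_len(nrow(decoy_caz_slots))) {
    gid <- gene_at(decoy_caz_slots$contig[k], decoy_caz_slots$rank[k])
    add_cazyme(gid, sample(c("GH13", "GH23", "GT2", "CE4"), 1), votes = 1)
    decoy_caz <- c(decoy_caz, gid)
  }
  dispersed_genes <- character(0)
  fams <- c("GH3", "GH17", "GH30", "GH2", "GT4", "CE1")
  for (k in seq_len(nrow(dispersed))) {
    gid <- gene_at(dispersed$contig[k], dispersed$rank[k])
    add_cazyme(gid, fams[(k - 1L) %% length(fams) + 1L],
               votes = sample(2:3, 1))
    set_product(gid, "dispersed pathway CAZyme")
    dispersed_genes <- c(dispersed_genes, gid)
  }

  hits <- if (length(hits) > 0) do.call(rbind, hits) else
    data.frame(protein_id = character(), tool = character(),
               label = character(), hit_class = character(),
               start = integer(), end = integer(), score = numeric(),
               stringsAsFactors = FALSE)
  genome <- genome_annotation(genes, organism = sprintf("synthetic genome (seed %d)", seed),
                              circular = setNames(rep(circular, n_contigs),
                                                  contigs))
  list(genome = genome, hits = hits,
       truth = list(puls = truth_puls, dispersed_genes = dispersed_genes,
                    decoy_pairs = decoy_pairs, lone_susc = lone_susc,
                    decoy_cazymes = decoy_caz))
}

#' Synthetic label-free quantification matrix with planted effects
#'
#' Emulates a 3-condition, 3-replicate LFQ design: per-protein base
#' abundances are log-normal (log2 ~ N(`base_mean`, `base_sd`)), replicate
#' noise is normal on the log2 scale, and a planted fraction of proteins
#' carries a log2 effect (half up, half down) in the first condition.
#' Missingness is intensity-dependent left-censoring: any log2 value below
#' `detection_limit` is unquantified (`NA`), the mechanism that motivates
#' constant-0 imputation downstream.
#'
#' @param seed RNG seed.
#' @param n_proteins number of proteins (default 2000).
#' @param conditions condition names; the effect applies to the first.
#' @param reps replicates per condition (default 3).
#' @param effect_size planted |log2| effect (default 4; 0 = null data).
#' @param fraction_affected fraction of proteins with an effect.
#' @param noise_sd replicate noise sd, log2 units (default 0.3).
#' @param base_mean,base_sd log2 abundance distribution (default 25, 2).
#' @param detection_limit log2 censoring threshold (default 21).
#' @return list with `lfq` (an `lfq_matrix` of raw intensities) and `truth`
#'   (`affected` ids, `true_difference` named vector on log2 scale).
#' @export
sim_lfq <- function(seed, n_proteins = 2000,
                    conditions = c("laminarin", "glucose", "control"),
                    reps = 3, effect_size = 4, fraction_affected = 0.05,
                    noise_sd = 0.3, base_mean = 25, base_sd = 2,
                    detection_limit = 21) {
  set.seed(seed)
  ids <- sprintf("prot_%04d", seq_len(n_proteins))
  base <- rnorm(n_proteins, base_mean, base_sd)
  n_aff <- round(fraction_affected * n_proteins)
  affected <- if (n_aff > 0 && effect_size > 0)
    sort(sample.int(n_proteins, n_aff)) else integer(0)
  sign_vec <- rep(0, n_proteins)
  if (length(affected) > 0)
    sign_vec[affected] <- rep(c(1, -1), length.out = length(affected))
  cond_vec <- rep(conditions, each = reps)
  rep_vec <- rep(seq_len(reps), times = length(conditions))
  log2m <- matrix(base, n_proteins, length(cond_vec)) +
    matrix(rnorm(n_proteins * length(cond_vec), 0, noise_sd),
           n_proteins, length(cond_vec))
  eff_cols <- which(cond_vec == conditions[1])
  log2m[, eff_cols] <- log2m[, eff_cols] + sign_vec * effect_size
  m <- 2^log2m
  m[log2m < detection_limit] <- NA
  rownames(m) <- ids
  lfq <- lfq_matrix(m, cond_vec, rep_vec)
  truth <- list(affected = ids[affected],
                true_difference = setNames(sign_vec * effect_size, ids))
  list(lfq = lfq, truth = truth)
}

#' Synthetic DAPI/substrate image pair with planted positives
#'
#' Plants `n_cells` non-overlapping disc-shaped cells (radius 3-5 px, area
#' >= 28 px) on a jittered grid. The DAPI channel shows every cell at
#' `dapi_level` over a dim background; in the substrate channel exactly
#' `round(positive_fraction * n_cells)` cells (the planted truth, not a
#' binomial draw) carry signal at `background + intensity_offset` over
#' `coverage` of their area. Gaussian pixel noise is added and values are
#' rounded and clipped to the 8-bit 0-255 range.
#'
#' @param seed RNG seed.
#' @param n_cells number of planted cells (default 150).
#' @param positive_fraction fraction of cells with substrate signal.
#' @param intensity_offset substrate signal above background, gray values
#'   (default 40, the clear positive-control phenotype).
#' @param noise_sd Gaussian pixel noise sd (default 2; 0 = noiseless).
#' @param width,height image size (default 512 x 512).
#' @param background substrate background level (default 20).
#' @param dapi_background,dapi_level DAPI background and cell levels.
#' @param coverage fraction of each positive cell's area covered by signal.
#' @param pixel_area um^2 per pixel.
#' @return list with `pair` (a `fluor_image_pair`) and `truth` (per-cell
#'   centre, radius, positivity).
#' @export
sim_images <- function(seed, n_cells = 150, positive_fraction = 0.9,
                       intensity_offset = 40, noise_sd = 2,
                       width = 512, height = 512, background = 20,
                       dapi_background = 10, dapi_level = 180,
                       coverage = 1.0, pixel_area = 0.3 / 20) {
  set.seed(seed)
  spacing <- 18L
  gx <- seq(10L, width - 10L, by = spacing)
  gy <- seq(10L, height - 10L, by = spacing)
  sites <- expand.grid(x = gx, y = gy)
  if (nrow(sites) < n_cells)
    stop("config error: image too small for ", n_cells, " cells")
  sites <- sites[sample.int(nrow(sites), n_cells), , drop = FALSE]
  cx <- sites$x + sample(-3:3, n_cells, replace = TRUE)
  cy <- sites$y + sample(-3:3, n_cells, replace = TRUE)
  r <- sample(3:5, n_cells, replace = TRUE)
  n_pos <- round(positive_fraction * n_cells)
  positive <- seq_len(n_cells) <= n_pos  # cells are already in random order

  dapi <- matrix(dapi_background, height, width)
  subs <- matrix(background, height, width)
  disc_pixels <- function(k) {
    xs <- max(1L, cx[k] - r[k]):min(width, cx[k] + r[k])
    ys <- max(1L, cy[k] - r[k]):min(height, cy[k] + r[k])
    gr <- expand.grid(y = ys, x = xs)
    keep <- (gr$x - cx[k])^2 + (gr$y - cy[k])^2 <= r[k]^2
    (gr$x[keep] - 1L) * height + gr$y[keep]
  }
  for (k in seq_len(n_cells)) {
    px <- disc_pixels(k)
    dapi[px] <- dapi_level
    if (positive[k]) {
      n_cov <- ceiling(coverage * length(px))
      subs[px[seq_len(n_cov)]] <- background + intensity_offset
    }
  }
  if (noise_sd > 0) {
    dapi <- dapi + rnorm(length(dapi), 0, noise_sd)
    subs <- subs + rnorm(length(subs), 0, noise_sd)
  }
  clip8 <- function(m) matrix(pmin(255, pmax(0, round(m))), nrow(m), ncol(m))
  pair <- fluor_image_pair(clip8(dapi), clip8(subs), pixel_area = pixel_area)
  truth <- data.frame(cell = seq_len(n_cells), cx = cx, cy = cy, r = r,
                      positive = positive)
  list(pair = pair, truth = truth)
}

#' Synthetic growth curve with known intrinsic rate
#'
#' Generates an OD600 time series with multiplicative log-normal noise.
#' `model = "logistic"` follows the logistic law
#' `od(t) = od_max / (1 + ((od_max - od0)/od0) exp(-r t))` (exponential
#' phase then plateau); `model = "exponential"` is exponential growth
#' capped at `od_max`, whose log-linear phase carries the rate exactly.
#' Sampling every 2 h reflects manual side-arm photometer cadence.
#'
#' @param seed RNG seed.
#' @param r intrinsic growth rate, h^-1 (default 0.09).
#' @param od0,od_max initial and maximal OD (defaults 0.01, 0.5).
#' @param noise_sd sd of multiplicative log-normal noise (default 0.02).
#' @param interval sampling interval, hours (default 2).
#' @param t_end last time point, hours (default 96).
#' @param model `"logistic"` or `"exponential"`.
#' @return list with `series` (data.frame `time`, `od`) and `truth` (`r`).
#' @export
sim_growth <- function(seed, r = 0.09, od0 = 0.01, od_max = 0.5,
                       noise_sd = 0.02, interval = 2, t_end = 96,
                       model = c("logistic", "exponential")) {
  model <- match.arg(model)
  set.seed(seed)
  stopifnot(od0 > 0, od_max >= od0, r >= 0)
  t <- seq(0, t_end, by = interval)
  od <- if (model == "logistic") {
    od_max / (1 + ((od_max - od0) / od0) * exp(-r * t))
  } else {
    pmin(od0 * exp(r * t), od_max)
  }
  if (noise_sd > 0) od <- od * exp(rnorm(length(t), 0, noise_sd))
  list(series = data.frame(time = t, od = od), truth = list(r = r))
}
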