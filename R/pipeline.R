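write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full synthetic end-to-end pipeline
#'
#' Exercises every stage on generated data: simulate a genome with planted
#' PULs, annotate (consensus CAZymes, SusC/SusD classes, tandem pairs),
#' build the PUL catalog and the dispersion report; simulate an LFQ matrix,
#' run detection, overlap counts and the permutation volcano; simulate an
#' image pair and score uptake; simulate a growth curve and fit the rate.
#' All outputs are written as TSV/JSON under `outdir`. Output is a pure
#' function of `seed` and the parameters: two runs with the same seed
#' produce byte-identical files.
#'
#' Sub-seeds for the four generators are small fixed offsets of `seed`.
#'
#' @param seed integer master seed.
#' @param outdir output directory (created if needed).
#' @param genome_args,lfq_args,image_args,growth_args named lists of
#'   overrides passed to the corresponding generators.
#' @return (invisibly) a named list of the in-memory stage results.
#' @export
run_pipeline <- function(seed, outdir, genome_args = list(),
                         lfq_args = list(), image_args = list(),
                         growth_args = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)

  # genome stage
  gsim <- do.call(sim_genome, c(list(seed = seed), genome_args))
  caz <- consensus_cazyme(gsim$hits)
  sus <- classify_sus(gsim$hits)
  pairs <- detect_suscd_pairs(gsim$genome, sus)
  catalog <- genome_pul_catalog(gsim$genome, caz, pairs)
  disp <- dispersion_summary(gsim$genome, gsim$truth$dispersed_genes)
  write_gene_table(gsim$genome, p("genes.tsv"))
  write_tsv(gsim$hits, p("domain_hits.tsv"))
  write_tsv(caz, p("cazyme_calls.tsv"))
  write_tsv(sus, p("sus_calls.tsv"))
  write_tsv(pairs, p("suscd_pairs.tsv"))
  write_tsv(catalog, p("pul_catalog.tsv"))
  write_pul_bed(catalog, p("pul_spans.bed"))
  write_json(list(verdict = disp$verdict,
                  min_enclosing_window = disp$min_enclosing_window,
                  threshold = disp$threshold,
                  genes = disp$gene_set), p("dispersion.json"))

  # proteomics stage
  lsim <- do.call(sim_lfq, c(list(seed = seed + 101L), lfq_args))
  conds <- unique(lsim$lfq$samples$condition)
  detected <- lapply(setNames(conds, conds),
                     function(cn) detect_expressed(lsim$lfq, cn))
  overlap <- condition_overlap(detected)
  prep <- prepare_lfq(lsim$lfq)
  de <- permutation_volcano(prep, conds[1], conds[2], s0 = 0.15,
                            fdr = 0.05, n_perm = 250, seed = seed + 202L)
  write_tsv(overlap, p("detected_overlap.tsv"))
  write_de_results(de, p("de_results.tsv"))

  # imaging stage
  isim <- do.call(sim_images, c(list(seed = seed + 303L), image_args))
  objects <- detect_objects(isim$pair$dapi,
                            pixel_area = isim$pair$pixel_area)
  scored <- score_positive(isim$pair, objects)
  frac <- positive_fraction(scored)
  write_image_channel(isim$pair$dapi, p("dapi.png"))
  write_image_channel(isim$pair$substrate, p("substrate.png"))
  write_tsv(as.data.frame(scored), p("cell_objects.tsv"))
  write_json(list(percent_positive = frac$percent,
                  n_positive = frac$n_positive, n_total = frac$n_total,
                  background_mgv = attr(scored, "background_mgv")),
             p("uptake_summary.json"))

  # growth stage
  wsim <- do.call(sim_growth, c(list(seed = seed + 404L), growth_args))
  write_tsv(wsim$series, p("growth.tsv"))
  fit <- fit_growth_rate(wsim$series$time, wsim$series$od)
  write_json(list(mu_per_h = fit$mu, r2 = fit$r2,
                  window = paste(fit$window, collapse = "-")),
             p("growth_fit.json"))

  invisible(list(genome = gsim, cazyme_calls = caz, sus_calls = sus,
                 pairs = pairs, catalog = catalog, dispersion = disp,
                 lfq = lsim, overlap = overlap, de = de,
                 imaging = isim, scored = scored, uptake = frac,
                 growth = wsim, growth_fit = fit))
}
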