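toy_lfq <- function(m, conds = c("lam", "glc"), reps = 3) {
  lfq_matrix(m, rep(conds, each = reps))
}

test_that("detection uses the at-least-min_reps rule on the raw matrix", {
  m <- rbind(none = c(NA, NA, NA, 1e6, 1e6, 1e6),
             one = c(2e6, NA, NA, 1e6, 1e6, 1e6),
             two = c(2e6, 3e6, NA, NA, NA, NA))
  x <- toy_lfq(m)
  expect_false("none" %in% detect_expressed(x, "lam"))
  expect_true("one" %in% detect_expressed(x, "lam"))      # 1 of 3 counts
  expect_false("two" %in% detect_expressed(x, "lam", min_reps = 3))
  expect_true("two" %in% detect_expressed(x, "lam", min_reps = 2))
  expect_error(detect_expressed(x, "lam", min_reps = 4), "config error")
  expect_error(detect_expressed(x, "nope"), "unknown condition")
  # imputation never creates expressed proteins
  prep <- prepare_lfq(x)
  expect_equal(detect_expressed(x, "lam"), c("one", "two"))
  expect_true(all(!is.na(prep$intensities)))
})

test_that("overlap region counts partition the union", {
  disjoint <- list(A = "a", B = "b", C = "c")
  ov <- condition_overlap(disjoint)
  expect_equal(ov$count[ov$degree == 1], c(1, 1, 1))
  expect_equal(ov$count[ov$region == "A&B&C"], 0)
  identical_sets <- list(A = letters[1:5], B = letters[1:5], C = letters[1:5])
  ov2 <- condition_overlap(identical_sets)
  expect_equal(ov2$count[ov2$region == "A&B&C"], 5)
  expect_equal(sum(ov2$count), 5)
})

test_that("overlap counts equal brute-force membership enumeration on random sets", {
  set.seed(3)
  for (i in 1:10) {
    ids <- sprintf("id%02d", 1:50)
    sets <- list(A = sample(ids, sample(10:40, 1)),
                 B = sample(ids, sample(10:40, 1)),
                 C = sample(ids, sample(10:40, 1)))
    ov <- condition_overlap(sets)
    expect_equal(sum(ov$count), length(unique(unlist(sets))))
    # brute force: per-id membership table
    union_ids <- unique(unlist(sets))
    profile <- sapply(union_ids, function(id)
      paste(names(sets)[sapply(sets, function(s) id %in% s)], collapse = "&"))
    brute <- table(profile)
    for (r in ov$region)
      expect_equal(ov$count[ov$region == r],
                   if (r %in% names(brute)) unname(brute[r]) else 0L,
                   info = r)
  }
})

test_that("preparation log2-transforms and imputes missing with constant 0", {
  m <- rbind(p1 = c(8, NA, 1, 4, 2, 16))
  x <- toy_lfq(m)
  prep <- prepare_lfq(x)
  expect_equal(unname(prep$intensities["p1", ]), c(3, 0, 0, 2, 1, 4))
  expect_equal(attr(prep, "zero_flagged"), "p1")  # raw intensity 1 collides
})

test_that("the s0 statistic reduces to the classical pooled t at s0 = 0", {
  same <- s0_t_test(c(10, 11, 12), c(10, 11, 12))
  expect_equal(same$difference, 0)
  expect_equal(same$t_s0, 0)
  expect_equal(same$p_raw, 1)
  # hand arithmetic: sp = 1, t = -3 / sqrt(2/3)
  r <- s0_t_test(c(10, 11, 12), c(13, 14, 15), s0 = 0)
  expect_equal(r$difference, -3)
  expect_equal(r$t_s0, -3 / sqrt(2 / 3))
  tt <- t.test(c(10, 11, 12), c(13, 14, 15), var.equal = TRUE)
  expect_equal(r$t_s0, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p_raw, tt$p.value, tolerance = 1e-12)
  # denominator inflation damps the statistic
  r15 <- s0_t_test(c(10, 11, 12), c(13, 14, 15), s0 = 0.15)
  expect_lt(abs(r15$t_s0), abs(r$t_s0))
  # zero variance with s0 = 0 degenerates with a warning
  expect_warning(inf <- s0_t_test(c(1, 1, 1), c(2, 2, 2), s0 = 0),
                 "zero within-group variance")
  expect_equal(inf$p_raw, 0)
})

test_that("the s0 = 0 statistic matches t.test on random 3 vs 3 draws", {
  set.seed(5)
  for (i in 1:100) {
    a <- rnorm(3, 20, 2); b <- rnorm(3, 21, 2)
    r <- s0_t_test(a, b, s0 = 0)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(r$t_s0, unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("the permutation volcano is seeded-deterministic and monotone in FDR", {
  sim <- sim_lfq(4, n_proteins = 400, effect_size = 4)
  prep <- prepare_lfq(sim$lfq)
  run <- function(fdr, n_perm = 250)
    suppressWarnings(permutation_volcano(prep, "laminarin", "glucose",
                                         fdr = fdr, n_perm = n_perm, seed = 9))
  de1 <- run(0.05); de2 <- run(0.05)
  expect_identical(de1, de2)
  sig_strict <- run(0.01)$significant
  expect_true(all(de1$significant[sig_strict]))  # stricter FDR is a subset
  expect_false(any(run(0)$significant))
  expect_error(permutation_volcano(prep, "laminarin", "glucose", n_perm = 250),
               "seed is required")
  # a smaller-than-exhaustive permutation count samples without a warning
  expect_silent(ps <- permutation_volcano(prep, "laminarin", "glucose",
                                          n_perm = 10, seed = 9))
  expect_equal(attr(ps, "n_perm_used"), 10)
})

test_that("direction calls combine significance with the sign of the difference", {
  res <- data.frame(difference = c(3.2, -2, 5, 0),
                    significant = c(TRUE, TRUE, FALSE, TRUE))
  out <- call_direction(res)
  expect_equal(out$direction, c("up", "down", "ns", "ns"))
})

test_that("planted effects are recovered in difference and direction", {
  sim <- sim_lfq(8, n_proteins = 1000, effect_size = 4, detection_limit = 0)
  prep <- prepare_lfq(sim$lfq)
  de <- suppressWarnings(permutation_volcano(prep, "laminarin", "glucose",
                                             seed = 8))
  truth <- sim$truth$true_difference[de$protein_id]
  aff <- names(truth)[truth != 0]
  # estimated difference unbiased within +/- 0.2 log2 units in expectation
  expect_lt(abs(mean(de$difference[match(aff, de$protein_id)] - truth[aff])),
            0.2)
  called_up <- de$protein_id[de$direction == "up"]
  called_down <- de$protein_id[de$direction == "down"]
  expect_gte(mean(names(truth)[truth > 0] %in% called_up), 0.95)
  expect_gte(mean(names(truth)[truth < 0] %in% called_down), 0.95)
})

test_that("MaxQuant-style and plain-matrix LFQ inputs parse to the same object", {
  sim <- sim_lfq(2, n_proteins = 20)
  m <- sim$lfq$intensities
  raw <- m; raw[is.na(raw)] <- 0
  mq <- data.frame(`Protein IDs` = rownames(m), check.names = FALSE)
  mq[paste("LFQ intensity", colnames(m))] <- as.data.frame(raw)
  f1 <- tempfile(fileext = ".tsv")
  write.table(mq, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  x1 <- read_lfq(f1, "maxquant")
  pm <- data.frame(protein_id = rownames(m), check.names = FALSE)
  pm[colnames(m)] <- as.data.frame(raw)
  f2 <- tempfile(fileext = ".tsv")
  write.table(pm, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  x2 <- read_lfq(f2, "matrix")
  expect_equal(x1$intensities, x2$intensities, tolerance = 1e-12)
  expect_equal(x1$samples, sim$lfq$samples)
  expect_equal(is.na(x1$intensities), is.na(m))
})
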