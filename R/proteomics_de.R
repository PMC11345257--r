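#' Construct a label-free quantification (LFQ) matrix
#'
#' Raw (non-log) LFQ intensities with replicate structure. Missing values
#' are encoded as `NA`; zeros in MaxQuant-style input mean "not quantified"
#' and are converted to `NA` by [read_lfq()].
#'
#' @param intensities numeric matrix, proteins x samples, rownames = protein
#'   ids, values >= 0 or `NA`.
#' @param conditions character vector, condition of each column.
#' @param replicates integer vector, replicate index of each column (1-based
#'   within condition); derived automatically when omitted.
#' @return object of class `lfq_matrix`: list with `intensities` and a
#'   `samples` data.frame (`sample`, `condition`, `replicate`).
#' @export
lfq_matrix <- function(intensities, conditions, replicates = NULL) {
  intensities <- as.matrix(intensities)
  if (length(conditions) != ncol(intensities))
    stop("conditions must name every column")
  if (is.null(replicates))
    replicates <- stats::ave(seq_along(conditions), conditions,
                             FUN = seq_along)
  if (length(unique(conditions)) < 2)
    stop("validation error: an LFQ matrix needs >= 2 conditions")
  if (any(intensities < 0, na.rm = TRUE))
    stop("validation error: negative intensities")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- paste0("protein_", seq_len(nrow(intensities)))
  samples <- data.frame(sample = paste0(conditions, "_", replicates),
                        condition = conditions,
                        replicate = as.integer(replicates),
                        stringsAsFactors = FALSE)
  colnames(intensities) <- samples$sample
  structure(list(intensities = intensities, samples = samples),
            class = "lfq_matrix")
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat("lfq_matrix:", nrow(x$intensities), "proteins x",
      ncol(x$intensities), "samples (",
      paste(unique(x$samples$condition), collapse = ", "), ")\n")
  invisible(x)
}

#' Read an LFQ matrix from TSV
#'
#' `format = "maxquant"` expects proteinGroups-style columns named
#' `LFQ intensity <condition>_<replicate>` plus a protein id column
#' (`Protein IDs` or the first column); intensities of 0 are treated as
#' missing. `format = "matrix"` expects a plain table whose first column is
#' the protein id and whose remaining columns are named
#' `<condition>_<replicate>`.
#'
#' @param path TSV file.
#' @param format `"maxquant"` or `"matrix"`.
#' @return an `lfq_matrix`.
#' @export
read_lfq <- function(path, format = c("maxquant", "matrix")) {
  format <- match.arg(format)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "maxquant") {
    lfq_cols <- grep("^LFQ intensity ", names(tab), value = TRUE)
    if (length(lfq_cols) == 0)
      stop("format error: no 'LFQ intensity' columns in '", path, "'")
    ids <- if ("Protein IDs" %in% names(tab)) tab[["Protein IDs"]] else tab[[1]]
    keys <- sub("^LFQ intensity ", "", lfq_cols)
  } else {
    ids <- tab[[1]]
    lfq_cols <- names(tab)[-1]
    keys <- lfq_cols
  }
  if (!all(grepl("_[^_]+$", keys)))
    stop("format error: sample columns must be named <condition>_<replicate>")
  conditions <- sub("_[^_]+$", "", keys)
  replicates <- sub("^.*_", "", keys)
  m <- as.matrix(tab[, lfq_cols, drop = FALSE])
  mode(m) <- "numeric"
  m[m == 0] <- NA
  rownames(m) <- ids
  lfq_matrix(m, conditions, replicates)
}

condition_columns <- function(x, condition) {
  cols <- which(x$samples$condition == condition)
  if (length(cols) == 0) stop("unknown condition: ", condition)
  cols
}

#' Detected (expressed) proteins in a condition
#'
#' A protein counts as expressed in a condition when it has a quantified
#' (non-missing, positive) intensity in at least `min_reps` of that
#' condition's replicates; the default of 1 of 3 replicates is the
#' detection rule used for building detected-proteome sets. Detection
#' always runs on the raw matrix, before any imputation.
#'
#' @param x an `lfq_matrix`.
#' @param condition condition name.
#' @param min_reps minimum replicates with a value (default 1).
#' @return character vector of protein ids.
#' @export
detect_expressed <- function(x, condition, min_reps = 1) {
  stopifnot(inherits(x, "lfq_matrix"))
  cols <- condition_columns(x, condition)
  if (min_reps > length(cols))
    stop("config error: min_reps (", min_reps, ") exceeds replicate count (",
         length(cols), ")")
  sub <- x$intensities[, cols, drop = FALSE]
  n_present <- rowSums(!is.na(sub) & sub > 0)
  rownames(sub)[n_present >= min_reps]
}

#' Overlap region counts for named sets
#'
#' Counts every exclusive region of the k-set Venn diagram (all 2^k - 1
#' non-empty membership patterns). The region counts always sum to the
#' union cardinality, which is asserted internally.
#'
#' @param sets named list of character vectors (>= 2 sets).
#' @return data.frame with `region` (set names joined by `&`), `degree`
#'   and `count`; the union size is attached as attribute `union_size`.
#' @export
condition_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  ids <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) memb <- matrix(memb, nrow = 1,
                                       dimnames = list(NULL, names(sets)))
  k <- length(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patterns) <- names(sets)
  counts <- integer(nrow(patterns))
  if (length(ids) > 0) {
    key <- apply(memb, 1, function(r) paste(as.integer(r), collapse = ""))
    pkey <- apply(patterns, 1, function(r) paste(as.integer(r), collapse = ""))
    tab <- table(key)
    counts <- as.integer(ifelse(pkey %in% names(tab), tab[pkey], 0L))
  }
  out <- data.frame(
    region = apply(patterns, 1, function(r)
      paste(names(sets)[as.logical(r)], collapse = "&")),
    degree = rowSums(patterns),
    count = counts, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  stopifnot(sum(out$count) == length(ids))
  attr(out, "union_size") <- length(ids)
  out
}

#' Log2-transform an LFQ matrix with constant-0 imputation
#'
#' Quantified intensities are log2-transformed; missing observations are
#' imputed with the constant 0 on the log2 scale (the Perseus
#' "NaN -> constant value 0" setting). A quantified raw intensity of
#' exactly 1 would collide with the imputation constant and a raw 0 is by
#' definition missing; both are flagged via the `zero_flagged` attribute.
#'
#' @param x an `lfq_matrix` of raw intensities.
#' @return an `lfq_matrix` on the log2 scale (attribute `log2 = TRUE`),
#'   with no missing values.
#' @export
prepare_lfq <- function(x) {
  stopifnot(inherits(x, "lfq_matrix"))
  m <- x$intensities
  zero_present <- which(!is.na(m) & m == 0, arr.ind = TRUE)
  collide <- which(!is.na(m) & m == 1, arr.ind = TRUE)
  flagged <- unique(rownames(m)[c(zero_present[, 1], collide[, 1])])
  m[!is.na(m) & m == 0] <- NA
  lm <- log2(m)
  lm[is.na(lm)] <- 0
  out <- x
  out$intensities <- lm
  attr(out, "log2") <- TRUE
  attr(out, "zero_flagged") <- flagged
  out
}

#' s0-moderated two-sample t-test
#'
#' The SAM/Perseus statistic: `t_s0 = (mean(a) - mean(b)) /
#' (sp * sqrt(1/na + 1/nb) + s0)` with `sp` the pooled standard deviation.
#' The offset `s0` damps spuriously large statistics from near-zero
#' variance; with `s0 = 0` the statistic reduces exactly to the classical
#' pooled two-sample t. The two-sided p-value uses Student's t with
#' `na + nb - 2` degrees of freedom.
#'
#' @param a,b numeric replicate vectors (each of length >= 2).
#' @param s0 non-negative variance offset (default 0).
#' @return list with `difference` (mean(a) - mean(b)), `t_s0`, `p_raw`.
#' @export
s0_t_test <- function(a, b, s0 = 0) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2, s0 >= 0)
  diff <- mean(a) - mean(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  se <- sqrt(sp2) * sqrt(1 / na + 1 / nb)
  if (se + s0 == 0) {
    if (diff == 0) return(list(difference = 0, t_s0 = 0, p_raw = 1))
    warning("zero within-group variance with s0 = 0: infinite statistic")
    return(list(difference = diff, t_s0 = sign(diff) * Inf, p_raw = 0))
  }
  t_s0 <- diff / (se + s0)
  list(difference = diff, t_s0 = t_s0,
       p_raw = 2 * pt(-abs(t_s0), df = na + nb - 2))
}

# Vectorised row-wise s0 statistic for a proteins x samples matrix split
# into two column groups.
row_s0_stat <- function(m, cols_a, cols_b, s0) {
  na <- length(cols_a); nb <- length(cols_b)
  ma <- rowMeans(m[, cols_a, drop = FALSE])
  mb <- rowMeans(m[, cols_b, drop = FALSE])
  va <- rowSums((m[, cols_a, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((m[, cols_b, drop = FALSE] - mb)^2) / (nb - 1)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  se <- sp * sqrt(1 / na + 1 / nb)
  diff <- ma - mb
  t_s0 <- diff / (se + s0)
  t_s0[se + s0 == 0 & diff == 0] <- 0
  list(difference = diff, t_s0 = t_s0, df = na + nb - 2)
}

#' Permutation-FDR volcano test between two conditions
#'
#' Each protein's `|t_s0|` (condition A minus condition B) is compared to a
#' null built by permuting the group labels of the compared samples. The
#' SAM-style FDR estimate at a symmetric cut `c` is
#' `median over permutations of #{|t_perm| >= c}` divided by
#' `#{|t_obs| >= c}`; the significance cut is the smallest `c` (largest
#' significant set) with estimated FDR at or below `fdr`. For a 3 vs 3
#' design only `choose(6, 3) = 20` distinct label assignments exist, so a
#' larger `n_perm` falls back to the exhaustive set with a warning;
#' otherwise `n_perm` distinct assignments are sampled under `seed`.
#' Results are deterministic for a fixed seed. `fdr = 0` accepts nothing.
#'
#' @param x a prepared (log2, imputed) `lfq_matrix` from [prepare_lfq()].
#' @param cond_a,cond_b condition names; differences are A minus B.
#' @param s0 variance offset (default 0.15).
#' @param fdr permutation FDR level (default 0.05).
#' @param n_perm requested number of label permutations (default 250).
#' @param seed RNG seed for permutation sampling (required).
#' @return data.frame of class `de_result`: `protein_id`, `difference`,
#'   `t_s0`, `p_raw`, `significant`, `direction`; the realised cut and the
#'   permutation count are attached as attributes.
#' @export
permutation_volcano <- function(x, cond_a, cond_b, s0 = 0.15, fdr = 0.05,
                                n_perm = 250, seed) {
  stopifnot(inherits(x, "lfq_matrix"), isTRUE(attr(x, "log2")),
            n_perm >= 1, fdr >= 0, s0 >= 0)
  if (missing(seed)) stop("config error: seed is required")
  cols_a <- condition_columns(x, cond_a)
  cols_b <- condition_columns(x, cond_b)
  m <- x$intensities[, c(cols_a, cols_b), drop = FALSE]
  na <- length(cols_a); nb <- length(cols_b)
  obs <- row_s0_stat(m, seq_len(na), na + seq_len(nb), s0)

  all_asn <- combn(na + nb, na)
  if (n_perm >= ncol(all_asn)) {
    if (n_perm > ncol(all_asn))
      warning("only ", ncol(all_asn), " distinct label permutations exist; ",
              "using the exhaustive set")
    asn <- all_asn
  } else {
    set.seed(seed)
    asn <- all_asn[, sample.int(ncol(all_asn), n_perm), drop = FALSE]
  }
  perm_abs <- vapply(seq_len(ncol(asn)), function(k) {
    ga <- asn[, k]
    gb <- setdiff(seq_len(na + nb), ga)
    abs(row_s0_stat(m, ga, gb, s0)$t_s0)
  }, numeric(nrow(m)))

  abs_obs <- abs(obs$t_s0)
  cuts <- sort(unique(abs_obs[is.finite(abs_obs)]), decreasing = TRUE)
  significant <- rep(FALSE, nrow(m))
  cutoff <- Inf
  if (fdr > 0 && length(cuts) > 0) {
    n <- nrow(m)
    n_obs <- vapply(cuts, function(c0) sum(abs_obs >= c0), numeric(1))
    # false positives per permutation at every cut (counts of |t_perm| >= c)
    fp <- vapply(seq_len(ncol(perm_abs)), function(k) {
      sp <- sort(perm_abs[, k])
      n - findInterval(cuts - 1e-12, sp)
    }, numeric(length(cuts)))
    if (length(cuts) == 1) fp <- matrix(fp, nrow = 1)
    est <- apply(fp, 1, median) / n_obs
    ok <- which(est <= fdr)
    if (length(ok) > 0) {
      cutoff <- cuts[max(ok)]  # smallest passing cut = largest set
      significant <- abs_obs >= cutoff
    }
  }
  out <- data.frame(protein_id = rownames(m),
                    difference = obs$difference,
                    t_s0 = obs$t_s0,
                    p_raw = 2 * pt(-abs_obs, df = obs$df),
                    significant = significant,
                    stringsAsFactors = FALSE)
  out <- call_direction(out)
  attr(out, "cutoff") <- cutoff
  attr(out, "n_perm_used") <- ncol(asn)
  attr(out, "params") <- list(s0 = s0, fdr = fdr, seed = seed,
                              cond_a = cond_a, cond_b = cond_b)
  class(out) <- c("de_result", class(out))
  out
}

#' Assign regulation direction to test results
#'
#' `up` iff significant with positive difference, `down` iff significant
#' with negative difference, `ns` otherwise (a non-significant protein is
#' `ns` whatever its difference).
#'
#' @param results data.frame with `difference` and `significant`.
#' @return the same data.frame with a `direction` column.
#' @export
call_direction <- function(results) {
  results$direction <- ifelse(!results$significant, "ns",
                              ifelse(results$difference > 0, "up",
                                     ifelse(results$difference < 0, "down",
                                            "ns")))
  results
}

#' Write differential-expression results as TSV
#' @param results a `de_result` data.frame.
#' @param path output file.
#' @export
write_de_results <- function(results, path) {
  write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
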