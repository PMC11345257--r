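#' Maximal specific growth rate from an OD time series
#'
#' Fits log(OD) against time in every sliding window of `window`
#' consecutive points and reports the steepest slope among windows whose
#' fit reaches `min_r2` -- the maximal specific growth rate mu (h^-1) of
#' the exponential phase. Windows containing non-positive OD are skipped.
#' If no window reaches `min_r2`, the steepest slope overall is returned
#' with a `r2_below_min` flag. A flat series has mu = 0 (the zero-slope
#' fit is exact, r^2 is taken as 1).
#'
#' mu is invariant under time shifts and under scaling OD by a constant.
#'
#' @param times hours, ascending.
#' @param od OD600 values (same length, >= `window` points).
#' @param window points per fit window (default 4).
#' @param min_r2 minimal r^2 for a window to count as exponential.
#' @return list with `mu` (h^-1), `window` (index range used), `r2`,
#'   `flags`.
#' @export
fit_growth_rate <- function(times, od, window = 4, min_r2 = 0.98) {
  stopifnot(length(times) == length(od), window >= 2)
  if (length(times) < window)
    stop("need at least ", window, " points")
  if (is.unsorted(times)) stop("times must be ascending")
  n <- length(times)
  slopes <- r2s <- rep(NA_real_, n - window + 1)
  for (i in seq_len(n - window + 1)) {
    j <- i + window - 1
    y <- od[i:j]
    if (any(!is.finite(y)) || any(y <= 0)) next
    x <- times[i:j]
    ly <- log(y)
    b <- cov(x, ly) / var(x)
    fit <- mean(ly) + b * (x - mean(x))
    ss_tot <- sum((ly - mean(ly))^2)
    ss_res <- sum((ly - fit)^2)
    r2s[i] <- if (ss_tot < 1e-12) 1 else 1 - ss_res / ss_tot
    slopes[i] <- b
  }
  if (all(is.na(slopes)))
    stop("no window with positive OD values")
  eligible <- which(!is.na(slopes) & r2s >= min_r2)
  flags <- character()
  if (length(eligible) == 0) {
    eligible <- which(!is.na(slopes))
    flags <- "r2_below_min"
  }
  best <- eligible[which.max(slopes[eligible])]
  list(mu = slopes[best], window = c(best, best + window - 1),
       r2 = r2s[best], flags = flags)
}

#' Cell density from counting-grid counts
#'
#' Scales the mean DAPI count per grid to the whole filter area and divides
#' by the filtered sample volume. QC flags follow standard epifluorescence
#' counting practice: fewer than 30 grids or a total of 280 cells or fewer
#' is flagged as statistically weak.
#'
#' @param grid_counts integer DAPI counts, one per grid.
#' @param grid_area area of one counting grid (same unit as `filter_area`).
#' @param filter_area effective filtration area.
#' @param sample_volume_ml filtered volume in mL.
#' @return list with `cells_per_ml`, `mean_per_grid`, `qc_flags`.
#' @export
cell_density <- function(grid_counts, grid_area, filter_area,
                         sample_volume_ml) {
  stopifnot(grid_area > 0, filter_area > 0, sample_volume_ml > 0,
            all(grid_counts >= 0))
  flags <- character()
  if (length(grid_counts) < 30) flags <- c(flags, "grids<30")
  if (sum(grid_counts) <= 280) flags <- c(flags, "total_cells<=280")
  list(cells_per_ml = mean(grid_counts) * (filter_area / grid_area) /
         sample_volume_ml,
       mean_per_grid = mean(grid_counts),
       qc_flags = flags)
}

#' Specific enzyme activity by Beer-Lambert quantification
#'
#' Converts a chromophore absorbance slope (e.g. nitrophenol at 405 nm)
#' into a specific activity. The rate of product formation is
#' `dA/dt / (epsilon * path)` (mol L^-1 s^-1), scaled by the assay volume
#' and normalised to protein: nmol s^-1 per microgram protein.
#'
#' @param dA_per_s absorbance slope, AU/s (>= 0).
#' @param epsilon molar extinction coefficient, M^-1 cm^-1 (default 7500,
#'   nitrophenol at 405 nm).
#' @param path_cm optical path length in cm (default 1).
#' @param assay_volume_l assay volume in litres.
#' @param protein_ug protein amount in the assay, micrograms.
#' @return specific activity, nmol s^-1 (ug protein)^-1.
#' @export
beer_lambert_activity <- function(dA_per_s, epsilon = 7500, path_cm = 1,
                                  assay_volume_l, protein_ug) {
  if (any(c(epsilon, path_cm, assay_volume_l, protein_ug) <= 0))
    stop("epsilon, path, volume and protein amount must be > 0")
  stopifnot(dA_per_s >= 0)
  mol_per_s <- dA_per_s / (epsilon * path_cm) * assay_volume_l
  mol_per_s * 1e9 / protein_ug
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of absorbance on concentration over at least
#' three standards; [quantify()] inverts the line and flags values outside
#' the calibrated absorbance range as extrapolated.
#'
#' @param concentration standard concentrations (>= 3 distinct values).
#' @param absorbance measured absorbances (same length).
#' @return object of class `calibration` with `slope`, `intercept`, `r2`
#'   and the calibrated absorbance range.
#' @export
linear_calibration <- function(concentration, absorbance) {
  stopifnot(length(concentration) == length(absorbance))
  if (length(unique(concentration)) < 3)
    stop("calibration needs >= 3 distinct standard concentrations")
  fit <- lm(absorbance ~ concentration)
  ss_tot <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (ss_tot < .Machine$double.eps) 1 else
    1 - sum(fit$residuals^2) / ss_tot
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = r2,
                 abs_range = range(absorbance)),
            class = "calibration")
}

#' Quantify concentrations from absorbances via a calibration
#' @param cal a `calibration` from [linear_calibration()].
#' @param absorbance absorbances to invert.
#' @return data.frame with `absorbance`, `concentration`, `extrapolated`.
#' @export
quantify <- function(cal, absorbance) {
  stopifnot(inherits(cal, "calibration"))
  data.frame(absorbance = absorbance,
             concentration = (absorbance - cal$intercept) / cal$slope,
             extrapolated = absorbance < cal$abs_range[1] |
               absorbance > cal$abs_range[2])
}

#' Substrate consumption percentage
#'
#' `100 * (initial - final) / initial`. A final concentration above the
#' initial one (apparent production) or below zero is reported but flagged.
#'
#' @param initial initial substrate concentration (> 0), g/L.
#' @param final final concentration, g/L.
#' @return list with `percent` and `qc_flags`.
#' @export
consumption_percent <- function(initial, final) {
  stopifnot(initial > 0)
  flags <- character()
  if (any(final > initial)) flags <- c(flags, "final>initial")
  if (any(final < 0)) flags <- c(flags, "final<0")
  list(percent = 100 * (initial - final) / initial, qc_flags = flags)
}
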