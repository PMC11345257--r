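#' Construct a registered DAPI/substrate image pair
#'
#' Two-channel 8-bit grayscale microscopy of the same field: a DAPI channel
#' locating cells and a labeled-substrate channel carrying the uptake
#' signal. Values are on the linear 0-255 acquisition scale (no display
#' normalisation), which is what makes mean-gray-value comparisons across
#' images meaningful.
#'
#' @param dapi,substrate integer matrices of equal dimension, values 0-255.
#' @param pixel_area area of one pixel in square micrometres (default
#'   0.015, i.e. 20 px = 0.3 um^2).
#' @return list of class `fluor_image_pair`.
#' @export
fluor_image_pair <- function(dapi, substrate, pixel_area = 0.3 / 20) {
  dapi <- as.matrix(dapi); substrate <- as.matrix(substrate)
  if (!all(dim(dapi) == dim(substrate)))
    stop("validation error: channel shapes differ")
  rng <- range(c(dapi, substrate))
  if (rng[1] < 0 || rng[2] > 255)
    stop("validation error: intensities outside [0, 255]")
  structure(list(dapi = dapi, substrate = substrate,
                 pixel_area = pixel_area),
            class = "fluor_image_pair")
}

#' Read one 8-bit grayscale channel from PNG or TIFF
#' @param path image file (`.png` or `.tif`/`.tiff`).
#' @return integer matrix with values 0-255.
#' @export
read_image_channel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * 255)
}

#' Write an 8-bit grayscale channel as PNG
#' @param channel integer matrix, values 0-255.
#' @param path output `.png` path.
#' @export
write_image_channel <- function(channel, path) {
  png::writePNG(channel / 255, path)
  invisible(path)
}

# 8-connected component labelling by vectorised BFS waves.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  remaining <- which(mask)
  cur <- 0L
  neighbours <- function(idx) {
    r <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      ok <- rr >= 1L & rr <= nr & c2 >= 1L & c2 <= nc
      if (any(ok)) out <- c(out, (c2[ok] - 1L) * nr + rr[ok])
    }
    unique(out)
  }
  for (p in remaining) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    frontier <- p
    lab[p] <- cur
    while (length(frontier) > 0) {
      nb <- neighbours(frontier)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

#' Detect cell objects in one channel
#'
#' Thresholds the channel (Otsu's method on the 8-bit histogram by
#' default, or a fixed threshold for exact reproducibility), labels
#' 8-connected components and keeps those with at least `min_area_px`
#' pixels -- the minimum-area rule that rejects sub-cellular speckle.
#'
#' @param channel integer matrix, values 0-255 (normally the DAPI channel).
#' @param min_area_px minimum object area in pixels (default 20).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold (required when `method = "fixed"`);
#'   pixels strictly above it are foreground.
#' @param pixel_area um^2 per pixel, used for the reported object area.
#' @return data.frame of class `cell_objects`: `object_id`, `area_px`,
#'   `area_um2`; pixel index sets are attached as attribute `pixels`, the
#'   image dimension as `img_dim`, the threshold used as `threshold`.
#' @export
detect_objects <- function(channel, min_area_px = 20,
                           method = c("otsu", "fixed"), threshold = NULL,
                           pixel_area = 0.3 / 20) {
  method <- match.arg(method)
  channel <- as.matrix(channel)
  if (method == "otsu") {
    threshold <- 255 * EBImage::otsu(EBImage::Image(channel / 255),
                                     range = c(0, 1), levels = 256)
  } else if (is.null(threshold)) {
    stop("config error: fixed thresholding needs a threshold")
  }
  mask <- channel > threshold
  empty <- structure(data.frame(object_id = integer(), area_px = integer(),
                                area_um2 = numeric()),
                     pixels = list(), img_dim = dim(channel),
                     threshold = threshold, class = c("cell_objects",
                                                      "data.frame"))
  if (!any(mask)) return(empty)
  lab <- label_components8(mask)
  pix <- split(which(lab > 0), lab[lab > 0])
  areas <- lengths(pix)
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0) return(empty)
  pix <- pix[keep]
  out <- data.frame(object_id = seq_along(pix),
                    area_px = as.integer(lengths(pix)),
                    area_um2 = lengths(pix) * pixel_area)
  attr(out, "pixels") <- unname(pix)
  attr(out, "img_dim") <- dim(channel)
  attr(out, "threshold") <- threshold
  class(out) <- c("cell_objects", "data.frame")
  out
}

#' Score labeled-substrate positivity of detected cells
#'
#' Background is the mean substrate gray value outside all objects after a
#' `dilate_px` morphological dilation (excluding halo bleed around cells).
#' The substrate signal mask is `substrate >= background + mgv_margin`.
#' An object is positive iff (i) at least `min_overlap` of its DAPI area
#' is covered by signal and (ii) its own mean gray value (MGV) in the
#' substrate channel is at least `mgv_margin` units above background.
#' Both criteria are evaluated independently, on the linear 0-255 scale.
#'
#' @param pair a `fluor_image_pair`.
#' @param objects `cell_objects` detected on the pair's DAPI channel.
#' @param min_overlap minimum signal-covered area fraction (default 0.30).
#' @param mgv_margin gray-value margin above background (default 10).
#' @param dilate_px dilation radius for the background exclusion zone.
#' @return the objects data.frame with `mgv_substrate`, `overlap_fraction`
#'   and `positive` columns; background MGV as attribute
#'   `background_mgv`.
#' @export
score_positive <- function(pair, objects, min_overlap = 0.30,
                           mgv_margin = 10, dilate_px = 2) {
  stopifnot(inherits(pair, "fluor_image_pair"),
            inherits(objects, "cell_objects"))
  if (!all(attr(objects, "img_dim") == dim(pair$dapi)))
    stop("objects were not detected on this image pair")
  sub <- pair$substrate
  mask <- matrix(FALSE, nrow(sub), ncol(sub))
  pix <- attr(objects, "pixels")
  mask[unlist(pix)] <- TRUE
  dil <- if (any(mask)) {
    brush <- EBImage::makeBrush(2 * dilate_px + 1, shape = "box")
    EBImage::dilate(EBImage::Image(mask * 1), brush) > 0.5
  } else mask
  bg_pix <- which(!dil)
  if (length(bg_pix) == 0)
    stop("objects cover the entire image: background undefined")
  background <- mean(sub[bg_pix])
  signal <- sub >= background + mgv_margin
  objects$mgv_substrate <- vapply(pix, function(p) mean(sub[p]), numeric(1))
  objects$overlap_fraction <- vapply(pix, function(p) mean(signal[p]),
                                     numeric(1))
  objects$positive <- objects$overlap_fraction >= min_overlap &
    objects$mgv_substrate >= background + mgv_margin
  attr(objects, "background_mgv") <- background
  objects
}

#' Fraction of DAPI objects scored positive
#' @param objects scored `cell_objects` from [score_positive()].
#' @return list with `percent` (NA with a flag when no objects),
#'   `n_positive`, `n_total`.
#' @export
positive_fraction <- function(objects) {
  if (!"positive" %in% names(objects))
    stop("objects have not been scored; run score_positive() first")
  n <- nrow(objects)
  if (n == 0)
    return(list(percent = NA_real_, n_positive = 0L, n_total = 0L,
                qc_flags = "no_objects"))
  list(percent = 100 * sum(objects$positive) / n,
       n_positive = sum(objects$positive), n_total = n,
       qc_flags = character())
}
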