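#' Construct a three-channel mosaic tile
#'
#' Bundles the registered DAPI, CK and HER2 intensity arrays of one mosaic
#' tile. All three channels must be numeric matrices of identical dimensions
#' with finite values in \[0, 1\] (images read from 8/16-bit TIFFs are
#' normalised by the dtype maximum on read).
#'
#' @param dapi,ck,her2 numeric matrices of identical dimensions, values in
#'   \[0, 1\].
#' @param tile_id integer vector `c(row, col)`, 0-based row-major grid
#'   position.
#' @return an object of class `tile_image`.
#' @export
tile_image <- function(dapi, ck, her2, tile_id = c(0L, 0L)) {
  for (nm in c("dapi", "ck", "her2")) {
    ch <- get(nm)
    if (!is.matrix(ch) || !is.numeric(ch)) {
      stop("channel '", nm, "' must be a numeric matrix")
    }
    if (!all(is.finite(ch))) stop("channel '", nm, "' contains non-finite values")
    if (any(ch < 0) || any(ch > 1)) {
      stop("channel '", nm, "' has intensities outside [0, 1]")
    }
  }
  if (!identical(dim(dapi), dim(ck)) || !identical(dim(ck), dim(her2))) {
    stop("all three channels must share identical dimensions")
  }
  tile_id <- as.integer(tile_id)
  stopifnot(length(tile_id) == 2, all(tile_id >= 0))
  structure(list(dapi = dapi, ck = ck, her2 = her2, tile_id = tile_id),
            class = "tile_image")
}

#' @export
print.tile_image <- function(x, ...) {
  cat(sprintf("<tile_image %d x %d, tile (%d, %d)>\n",
              nrow(x$ck), ncol(x$ck), x$tile_id[1], x$tile_id[2]))
  invisible(x)
}

tile_id_string <- function(tile_id) sprintf("%04d_%04d", tile_id[1], tile_id[2])

#' Otsu auto-threshold of an intensity image
#'
#' Returns the threshold that maximises the between-class variance of the
#' intensity distribution (Otsu's criterion), computed exactly over all cuts
#' between consecutive distinct intensity values rather than over a quantised
#' histogram. The threshold is reported as the midpoint of the optimal gap, so
#' that foreground is `x >= threshold`. A constant image returns its constant
#' value (the caller treats the foreground as empty in that case).
#'
#' @param x numeric array of finite intensities.
#' @return a single threshold intensity.
#' @export
#' @examples
#' img <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
#' auto_threshold(img) # 0.5: separates the two modes
auto_threshold <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("cannot threshold an empty array")
  if (anyNA(x) || !all(is.finite(x))) stop("array contains non-finite values")
  u <- sort(unique(x))
  m <- length(u)
  if (m == 1) return(u)
  counts <- tabulate(match(x, u), nbins = m)
  n <- length(x)
  # cumulative weight and mean below each cut k (classes u[1..k] | u[(k+1)..m])
  w0 <- cumsum(counts)[-m]
  s0 <- cumsum(counts * u)[-m]
  mu0 <- s0 / w0
  mu1 <- (sum(counts * u) - s0) / (n - w0)
  sigma_b <- (w0 / n) * (1 - w0 / n) * (mu0 - mu1)^2
  k <- which.max(sigma_b)
  (u[k] + u[k + 1]) / 2
}

#' Determine the epithelial, non-nuclear region of interest of a tile
#'
#' The CK channel is auto-thresholded to delineate epithelium; the DAPI
#' channel is auto-thresholded to find nuclei, which are dilated by
#' `config$dilation_radius` pixels and subtracted, since the membrane marker
#' must not be interrogated over nuclei. Two guards empty the ROI of
#' degenerate tiles: a CK foreground fraction below
#' `config$min_foreground_fraction`, or a CK threshold below
#' `config$noise_floor` (Otsu will otherwise split pure background noise in
#' stroma-only tiles). The same noise-floor guard is applied to the DAPI
#' threshold, so tiles without nuclei are not eroded by a hallucinated
#' nuclear mask.
#'
#' @param tile a [tile_image()].
#' @param config a [default_config()] list.
#' @return an object of class `roi_mask`: list with `mask` (logical matrix),
#'   `ck_threshold`, `dapi_threshold`, `roi_area`.
#' @export
compute_roi <- function(tile, config = default_config()) {
  stopifnot(inherits(tile, "tile_image"))
  th_ck <- auto_threshold(tile$ck)
  fg <- tile$ck >= th_ck
  if (length(unique(as.vector(tile$ck))) == 1 ||
      mean(fg) < config$min_foreground_fraction ||
      th_ck < config$noise_floor) {
    fg[] <- FALSE
  }
  th_dapi <- auto_threshold(tile$dapi)
  nuc <- tile$dapi >= th_dapi
  if (length(unique(as.vector(tile$dapi))) == 1 || th_dapi < config$noise_floor) {
    nuc[] <- FALSE
  }
  if (any(nuc) && config$dilation_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(config$dilation_radius) + 1L,
                                shape = "disc")
    nuc <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(nuc * 1), brush)) > 0
  }
  mask <- fg & !nuc
  structure(list(mask = mask, ck_threshold = th_ck, dapi_threshold = th_dapi,
                 roi_area = sum(mask)),
            class = "roi_mask")
}

#' Average the CK and HER2 signals of a tile over its ROI
#'
#' @param tile a [tile_image()].
#' @param roi the [compute_roi()] result for the same tile.
#' @param config a [default_config()] list; `min_roi_pixels` controls the
#'   validity flag.
#' @return a one-row data frame with columns `tile_id`, `row`, `col`,
#'   `ck_mean`, `her2_mean`, `roi_area`, `valid`. Means are `NA` when the ROI
#'   is empty.
#' @export
measure_tile <- function(tile, roi, config = default_config()) {
  stopifnot(inherits(tile, "tile_image"), inherits(roi, "roi_mask"))
  if (!identical(dim(roi$mask), dim(tile$ck))) {
    stop("ROI mask dimensions do not match the tile")
  }
  area <- roi$roi_area
  if (area > 0) {
    ck_mean <- mean(tile$ck[roi$mask])
    her2_mean <- mean(tile$her2[roi$mask])
  } else {
    ck_mean <- NA_real_
    her2_mean <- NA_real_
  }
  data.frame(
    tile_id = tile_id_string(tile$tile_id),
    row = tile$tile_id[1], col = tile$tile_id[2],
    ck_mean = ck_mean, her2_mean = her2_mean,
    roi_area = area,
    valid = area >= config$min_roi_pixels && is.finite(ck_mean) &&
      is.finite(her2_mean),
    stringsAsFactors = FALSE
  )
}

#' Measure every tile of a case
#'
#' Runs [compute_roi()] and [measure_tile()] tile by tile, preserving order.
#'
#' @param tiles list of [tile_image()] objects.
#' @param config a [default_config()] list.
#' @param verbose print a one-line summary of invalid-tile counts.
#' @return a data frame with one row per tile (columns as in
#'   [measure_tile()]).
#' @export
measure_case <- function(tiles, config = default_config(), verbose = FALSE) {
  if (length(tiles) == 0) stop("no tiles to measure")
  rows <- lapply(tiles, function(tl) {
    measure_tile(tl, compute_roi(tl, config), config)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (verbose) {
    message(sprintf("measured %d tiles (%d invalid)", nrow(out), sum(!out$valid)))
  }
  out
}
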