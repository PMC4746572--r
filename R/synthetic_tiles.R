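# Deterministic per-tile seed mixing; keeps every derived seed < 2^31.
mix_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + index * 9973 + 1) %%
               2147483629)
}

#' Imaging parameters of the synthetic mosaic generator
#'
#' Geometry and noise of the simulated acquisition, shared by all tiles of a
#' cohort. Intensities live on the \[0, 1\] scale of a normalised camera.
#'
#' @param tile_size tile edge length in pixels (tiles are square).
#' @param noise_sd per-pixel additive Gaussian noise SD, all channels.
#' @param background background intensity per channel (named: dapi, ck, her2).
#' @param ck_level epithelial CK intensity before the case staining factor.
#' @param dapi_level intranuclear DAPI intensity.
#' @param nucleus_radius nuclear disc radius, pixels.
#' @param nucleus_density nuclei per epithelial pixel (one nucleus per
#'   `1/nucleus_density` pixels of epithelium).
#' @param epithelial_area_range range of the tile-area fraction an epithelial
#'   region covers, for tiles that contain epithelium.
#' @return named list of class `imaging_params`.
#' @export
imaging_params <- function(tile_size = 128L,
                           noise_sd = 0.01,
                           background = c(dapi = 0.02, ck = 0.02, her2 = 0.02),
                           ck_level = 0.45,
                           dapi_level = 0.8,
                           nucleus_radius = 3,
                           nucleus_density = 1 / 350,
                           epithelial_area_range = c(0.3, 0.6)) {
  stopifnot(tile_size >= 16, noise_sd >= 0,
            all(background >= 0), all(background <= 1),
            ck_level > 0, ck_level <= 1, dapi_level > 0, dapi_level <= 1,
            nucleus_radius >= 1, nucleus_density > 0,
            length(epithelial_area_range) == 2,
            epithelial_area_range[1] > 0, epithelial_area_range[2] <= 1)
  structure(list(tile_size = as.integer(tile_size), noise_sd = noise_sd,
                 background = background, ck_level = ck_level,
                 dapi_level = dapi_level, nucleus_radius = nucleus_radius,
                 nucleus_density = nucleus_density,
                 epithelial_area_range = epithelial_area_range),
            class = "imaging_params")
}

#' Default tile-to-tile dispersion of the HER2 level
#'
#' Coefficient of variation of the per-tile HER2 expression draw as a
#' function of the case expression level. It increases strictly with
#' expression, emulating the wider HER2 signal dispersion of amplified
#' tumours.
#'
#' @param expression_level case mean HER2 intensity scale, >= 0.
#' @return coefficient of variation.
#' @export
default_expression_cv <- function(expression_level) {
  0.08 + 0.25 * expression_level
}

#' Ground-truth phenotype of a synthetic case
#'
#' Describes one case of the simulated cohort: its mean HER2 membrane
#' intensity scale (`expression_level`, a stand-in for protein expression
#' driven by gene copy number), the tile-to-tile dispersion of that level,
#' the fraction of tiles containing epithelium, an optional second subclone
#' for heterogeneous tumours, the rate of saturating bright artifacts, and a
#' case-level multiplicative staining-quality factor applied equally to the
#' CK and HER2 channels (so CK normalisation can cancel it).
#'
#' @param expression_level mean HER2 intensity scale, >= 0.
#' @param expression_cv tile-to-tile CV of the HER2 level; defaults to
#'   [default_expression_cv()] of `expression_level`.
#' @param epithelial_fraction fraction of tiles containing epithelium, in
#'   \[0, 1\].
#' @param n_tiles number of tiles, > 0.
#' @param subclone optional list `(expression_level, fraction)` describing a
#'   second subclone; each tile is assigned wholly to one subclone.
#' @param artifact_rate fraction of tiles receiving a saturating bright CK
#'   blob, in \[0, 1\].
#' @param stain_factor case-level staining-quality multiplier, > 0.
#' @param seed integer seed; identical (phenotype, seed) pairs generate
#'   bit-identical mosaics.
#' @return object of class `case_phenotype`.
#' @export
case_phenotype <- function(expression_level,
                           expression_cv = default_expression_cv(expression_level),
                           epithelial_fraction = 0.7,
                           n_tiles = 100L,
                           subclone = NULL,
                           artifact_rate = 0.02,
                           stain_factor = 1,
                           seed = 1L) {
  stopifnot(is.numeric(expression_level), length(expression_level) == 1,
            expression_level >= 0, is.finite(expression_level),
            expression_cv >= 0,
            epithelial_fraction >= 0, epithelial_fraction <= 1,
            n_tiles >= 1,
            artifact_rate >= 0, artifact_rate <= 1,
            stain_factor > 0)
  if (!is.null(subclone)) {
    stopifnot(is.list(subclone),
              all(c("expression_level", "fraction") %in% names(subclone)),
              subclone$expression_level >= 0,
              subclone$fraction >= 0, subclone$fraction <= 1)
    if (is.null(subclone$expression_cv)) {
      subclone$expression_cv <- default_expression_cv(subclone$expression_level)
    }
  }
  structure(list(expression_level = expression_level,
                 expression_cv = expression_cv,
                 epithelial_fraction = epithelial_fraction,
                 n_tiles = as.integer(n_tiles),
                 subclone = subclone,
                 artifact_rate = artifact_rate,
                 stain_factor = stain_factor,
                 seed = as.integer(seed)),
            class = "case_phenotype")
}

disc_mask <- function(n, cx, cy, r) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rows - cx)^2 + (cols - cy)^2 <= r^2
}

#' Generate one synthetic three-channel tile
#'
#' Renders the DAPI, CK and HER2 channels of one mosaic tile of a case.
#' A tile contains epithelium with probability `epithelial_fraction`; an
#' epithelial tile carries a disc-shaped CK+ region whose area fraction is
#' drawn from `imaging$epithelial_area_range`, DAPI+ nuclear discs inside the
#' epithelium with CK and HER2 suppressed to background, and a tile-level
#' HER2 intensity drawn from
#' `Normal(expression_level, expression_cv * expression_level)` (truncated at
#' zero) added over the HER2 background. Stromal tiles are near-background in
#' CK and HER2. With probability `artifact_rate` a saturating disc of
#' intensity 1.0 is burned into the CK channel. All channels receive additive
#' Gaussian pixel noise and are clipped to \[0, 1\].
#'
#' The ground truth is attached as `attr(tile, "truth")`: a list with
#' `is_epithelial`, `epithelium` and `nuclei` masks, the drawn tile
#' `expression`, the subclone index `clone`, and `artifact`.
#'
#' @param phenotype a [case_phenotype()].
#' @param tile_index 0-based tile index, `< n_tiles`.
#' @param imaging an [imaging_params()] list.
#' @param grid_cols number of grid columns used to derive `(row, col)` from
#'   `tile_index`; defaults to `ceiling(sqrt(n_tiles))`.
#' @return a [tile_image()] with a `"truth"` attribute.
#' @export
generate_tile <- function(phenotype, tile_index,
                          imaging = imaging_params(),
                          grid_cols = NULL) {
  stopifnot(inherits(phenotype, "case_phenotype"),
            inherits(imaging, "imaging_params"))
  if (tile_index < 0 || tile_index >= phenotype$n_tiles) {
    stop("tile_index must be in [0, n_tiles)")
  }
  if (is.null(grid_cols)) grid_cols <- ceiling(sqrt(phenotype$n_tiles))
  n <- imaging$tile_size
  bg <- imaging$background
  q <- phenotype$stain_factor

  withr::with_seed(mix_seed(phenotype$seed, tile_index), {
    is_epith <- runif(1) < phenotype$epithelial_fraction
    clone <- 1L
    e_level <- phenotype$expression_level
    e_cv <- phenotype$expression_cv
    if (!is.null(phenotype$subclone)) {
      if (runif(1) < phenotype$subclone$fraction) {
        clone <- 2L
        e_level <- phenotype$subclone$expression_level
        e_cv <- phenotype$subclone$expression_cv
      }
    }
    epith <- matrix(FALSE, n, n)
    nuc <- matrix(FALSE, n, n)
    e_tile <- 0
    if (is_epith) {
      frac <- runif(1, imaging$epithelial_area_range[1],
                    imaging$epithelial_area_range[2])
      cx <- runif(1, 0.35, 0.65) * n
      cy <- runif(1, 0.35, 0.65) * n
      epith <- disc_mask(n, cx, cy, n * sqrt(frac / pi))
      n_nuc <- max(1L, round(sum(epith) * imaging$nucleus_density))
      centers <- sample(which(epith), n_nuc)
      for (ctr in centers) {
        r0 <- (ctr - 1) %% n + 1
        c0 <- (ctr - 1) %/% n + 1
        rr <- imaging$nucleus_radius
        ri <- max(1, floor(r0 - rr)):min(n, ceiling(r0 + rr))
        ci <- max(1, floor(c0 - rr)):min(n, ceiling(c0 + rr))
        sub <- outer((ri - r0)^2, (ci - c0)^2, "+") <= rr^2
        nuc[ri, ci] <- nuc[ri, ci] | sub
      }
      nuc <- nuc & epith
      e_tile <- max(0, rnorm(1, e_level, e_cv * e_level))
    }

    dapi <- matrix(bg[["dapi"]], n, n)
    ck <- matrix(bg[["ck"]], n, n)
    her2 <- matrix(bg[["her2"]], n, n)
    ck[epith] <- q * imaging$ck_level
    her2[epith] <- bg[["her2"]] + q * e_tile
    ck[nuc] <- bg[["ck"]]
    her2[nuc] <- bg[["her2"]]
    dapi[nuc] <- imaging$dapi_level

    artifact <- runif(1) < phenotype$artifact_rate
    if (artifact) {
      art <- disc_mask(n, runif(1, 0.1, 0.9) * n, runif(1, 0.1, 0.9) * n,
                       n / 10)
      ck[art] <- 1.0
    }
    if (imaging$noise_sd > 0) {
      dapi <- dapi + matrix(rnorm(n * n, 0, imaging$noise_sd), n, n)
      ck <- ck + matrix(rnorm(n * n, 0, imaging$noise_sd), n, n)
      her2 <- her2 + matrix(rnorm(n * n, 0, imaging$noise_sd), n, n)
    }
    clip <- function(m) pmin(pmax(m, 0), 1)
    tl <- tile_image(clip(dapi), clip(ck), clip(her2),
                     tile_id = c(tile_index %/% grid_cols,
                                 tile_index %% grid_cols))
    attr(tl, "truth") <- list(is_epithelial = is_epith, epithelium = epith,
                              nuclei = nuc, expression = e_tile,
                              clone = clone, artifact = artifact)
    tl
  })
}

#' Generate all tiles of a case
#'
#' @param phenotype a [case_phenotype()].
#' @param imaging an [imaging_params()] list.
#' @return list of [tile_image()] objects in row-major tile order.
#' @export
generate_case_images <- function(phenotype, imaging = imaging_params()) {
  grid_cols <- ceiling(sqrt(phenotype$n_tiles))
  lapply(seq_len(phenotype$n_tiles) - 1L, function(i) {
    generate_tile(phenotype, i, imaging, grid_cols = grid_cols)
  })
}
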