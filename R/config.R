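#' Default analysis configuration
#'
#' Returns the full set of tunable parameters used by the ROI, filtering,
#' scoring and cohort stages. Every entry can be overridden, either
#' programmatically via `modifyList()`-style arguments or from a YAML file
#' with [read_config()]; unknown keys are rejected so typos fail loudly.
#'
#' @param ... named overrides of individual defaults.
#'
#' @details
#' Image / ROI parameters:
#' \describe{
#'   \item{min_roi_pixels}{smallest ROI (pixels) for which a tile mean is
#'     considered stable; smaller ROIs mark the tile invalid. Default 50.}
#'   \item{noise_floor}{intensity (on the \[0,1\] scale) below which an Otsu
#'     threshold is treated as noise splitting; the tile then has an empty
#'     foreground. Default 0.05.}
#'   \item{min_foreground_fraction}{minimum fraction of pixels above the CK
#'     threshold for the tile to count as containing epithelium. Default 0.01.}
#'   \item{dilation_radius}{radius (pixels) by which the DAPI nuclear mask is
#'     dilated before subtraction from the CK foreground. Default 1.}
#' }
#' Filtering / scoring parameters:
#' \describe{
#'   \item{min_tiles}{minimum number of valid (and, later, retained) tiles for
#'     a case to be scorable. Default 20.}
#'   \item{fallback_percentile}{percentile of the per-tile CK means used as the
#'     lower CK threshold when their distribution is not bimodal. Default 0.10.}
#'   \item{bimodality_cutoff}{minimum ratio of between-class to total variance
#'     at the Otsu split of the CK means for the distribution to count as
#'     bimodal. A unimodal normal reaches ~0.64 and a uniform ~0.75 at their
#'     best split, so the cutoff sits well above both; two separated tight
#'     modes approach 1. Default 0.9.}
#'   \item{lower_mode_ratio_max}{the Otsu split is accepted as a stroma /
#'     epithelium separation only if the lower-class mean is below this
#'     fraction of the upper-class mean (stroma is dim, not merely distinct).
#'     Default 0.5.}
#'   \item{upper_filter_frac}{fraction of the brightest-CK tiles removed per
#'     case as an artifact guard. Default 0.05.}
#'   \item{filter_order}{"lower_first" (default) applies the lower CK filter
#'     before the brightest-tile filter; "upper_first" reverses the order.}
#'   \item{r2_min}{adjusted R-squared below which a Gaussian fit is excluded
#'     from scoring. Default 0.5.}
#'   \item{n_bins}{number of ratio-histogram bins, or `NULL` for the
#'     Freedman-Diaconis rule (with a 50-bin fallback for degenerate spreads).}
#' }
#' Heterogeneity parameters:
#' \describe{
#'   \item{bic_margin}{BIC advantage the 2-component mixture must have over the
#'     1-component fit. Default 10.}
#'   \item{separation}{minimum separation of the two component means, in units
#'     of the pooled component SD. Default 2.}
#' }
#'
#' @return a named list of class `mtp_config`.
#' @export
#' @examples
#' cfg <- default_config(min_tiles = 10)
#' cfg$min_tiles
default_config <- function(...) {
  cfg <- list(
    min_roi_pixels = 50L,
    noise_floor = 0.05,
    min_foreground_fraction = 0.01,
    dilation_radius = 1L,
    min_tiles = 20L,
    fallback_percentile = 0.10,
    bimodality_cutoff = 0.9,
    lower_mode_ratio_max = 0.5,
    upper_filter_frac = 0.05,
    filter_order = "lower_first",
    r2_min = 0.5,
    n_bins = NULL,
    bic_margin = 10,
    separation = 2
  )
  cfg <- apply_overrides(cfg, list(...))
  validate_config(cfg)
}

apply_overrides <- function(cfg, overrides) {
  if (length(overrides) == 0) return(cfg)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  modifyList(cfg, overrides, keep.null = TRUE)
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$min_roi_pixels >= 1,
    cfg$noise_floor >= 0, cfg$noise_floor <= 1,
    cfg$min_foreground_fraction >= 0, cfg$min_foreground_fraction <= 1,
    cfg$dilation_radius >= 0,
    cfg$min_tiles >= 3,
    cfg$fallback_percentile >= 0, cfg$fallback_percentile <= 1,
    cfg$bimodality_cutoff >= 0, cfg$bimodality_cutoff <= 1,
    cfg$lower_mode_ratio_max > 0, cfg$lower_mode_ratio_max <= 1,
    cfg$upper_filter_frac >= 0, cfg$upper_filter_frac < 1,
    cfg$filter_order %in% c("lower_first", "upper_first"),
    cfg$r2_min <= 1,
    is.null(cfg$n_bins) || cfg$n_bins >= 3,
    cfg$bic_margin >= 0,
    cfg$separation >= 0
  )
  structure(cfg, class = "mtp_config")
}

#' Read an analysis configuration from a YAML file
#'
#' The file holds a (possibly partial) set of the keys documented in
#' [default_config()]; missing keys take their defaults, unknown keys are an
#' error.
#'
#' @param path path to a YAML file.
#' @return a validated `mtp_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- apply_overrides(unclass(default_config()), raw)
  validate_config(cfg)
}
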