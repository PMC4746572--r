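#' Case-specific lower CK threshold
#'
#' Tiles containing no or few epithelial cells show a low tile-averaged CK
#' signal, so the per-tile `ck_mean` distribution of a case is typically
#' bimodal (stroma vs epithelium). When the Otsu split of that distribution
#' explains at least `config$bimodality_cutoff` of its total variance the Otsu
#' threshold is used; otherwise the distribution is treated as unimodal and
#' the `config$fallback_percentile` quantile is returned (the cutoff must sit
#' well above the ~0.64 a unimodal normal attains at its best split).
#'
#' Before assessing bimodality the brightest `config$upper_filter_frac` tail
#' is set aside: a rare saturating artifact tile would otherwise read as a
#' spurious bright mode and pull the "lower" threshold above the epithelial
#' tiles it is meant to keep. Those tiles are the upper filter's concern,
#' not a CK mode.
#'
#' @param measurements data frame from [measure_case()].
#' @param config a [default_config()] list.
#' @return a single threshold intensity; tiles with `ck_mean` below it are
#'   dropped by [apply_filters()].
#' @export
lower_ck_threshold <- function(measurements, config = default_config()) {
  ck <- measurements$ck_mean[measurements$valid]
  if (length(ck) < config$min_tiles) {
    stop("unscorable case: only ", length(ck), " valid tiles (need ",
         config$min_tiles, ")")
  }
  core <- ck[ck <= quantile(ck, 1 - config$upper_filter_frac, type = 7)]
  if (length(core) < 3) core <- ck
  tot_var <- stats::var(core) * (length(core) - 1) / length(core)
  if (!is.finite(tot_var) || tot_var == 0) {
    return(unname(quantile(ck, config$fallback_percentile, type = 7)))
  }
  th <- auto_threshold(core)
  lo <- core < th
  between <- mean(lo) * (1 - mean(lo)) * (mean(core[lo]) - mean(core[!lo]))^2
  # a genuine stroma mode is dim, not merely distinct: accept the Otsu split
  # only when the lower-class mean sits well below the upper-class mean,
  # so micro-structure inside a homogeneous epithelial mode cannot trigger it
  dim_mode <- mean(core[lo]) < config$lower_mode_ratio_max * mean(core[!lo])
  if (between / tot_var >= config$bimodality_cutoff && dim_mode) th else
    unname(quantile(ck, config$fallback_percentile, type = 7))
}

filter_report <- function(n_input, n_below_lower, n_removed_upper,
                          lower_threshold, upper_threshold) {
  structure(list(
    n_input = n_input,
    n_below_lower = n_below_lower,
    n_removed_upper = n_removed_upper,
    n_retained = n_input - n_below_lower - n_removed_upper,
    lower_threshold = lower_threshold,
    upper_threshold = upper_threshold
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "<filter_report: %d tiles in, %d below CK threshold %.4g, %d brightest removed, %d retained>\n",
    x$n_input, x$n_below_lower, x$lower_threshold, x$n_removed_upper,
    x$n_retained))
  invisible(x)
}

#' Filter the tile measurements of a case
#'
#' Invalid tiles (empty or undersized ROI) are dropped first. Tiles whose
#' `ck_mean` falls below the case-specific [lower_ck_threshold()] are then
#' removed (tiles with no or few epithelial cells), and finally the
#' `floor(upper_filter_frac * n)` brightest-CK tiles among the survivors are
#' removed to guard against saturating artifacts such as fluorophore
#' agglomerates (default fraction 0.05). Ties on `ck_mean` are broken by
#' `tile_id` lexicographic order so filtering is deterministic.
#'
#' @param measurements data frame from [measure_case()].
#' @param config a [default_config()] list; `filter_order = "upper_first"`
#'   swaps the two filters.
#' @return list with `retained` (data frame subset, original order) and
#'   `report` (a `filter_report`). Uncscorable cases (fewer than
#'   `config$min_tiles` valid tiles) raise an error rather than returning an
#'   empty set.
#' @export
apply_filters <- function(measurements, config = default_config()) {
  valid <- measurements[measurements$valid, , drop = FALSE]
  if (nrow(valid) < config$min_tiles) {
    stop("unscorable case: only ", nrow(valid), " valid tiles (need ",
         config$min_tiles, ")")
  }
  n_input <- nrow(valid)

  drop_upper <- function(df) {
    n_rm <- floor(config$upper_filter_frac * nrow(df))
    if (n_rm == 0) {
      return(list(df = df, n_rm = 0L, upper = Inf))
    }
    ord <- order(-df$ck_mean, df$tile_id)
    removed <- ord[seq_len(n_rm)]
    list(df = df[-removed, , drop = FALSE], n_rm = as.integer(n_rm),
         upper = min(df$ck_mean[removed]))
  }

  if (config$filter_order == "lower_first") {
    lower <- lower_ck_threshold(measurements, config)
    keep <- valid$ck_mean >= lower
    n_below <- sum(!keep)
    up <- drop_upper(valid[keep, , drop = FALSE])
    retained <- up$df
  } else {
    up <- drop_upper(valid)
    lower <- lower_ck_threshold(measurements, config)
    keep <- up$df$ck_mean >= lower
    n_below <- sum(!keep)
    retained <- up$df[keep, , drop = FALSE]
  }
  list(
    retained = retained,
    report = filter_report(n_input, as.integer(n_below), up$n_rm, lower,
                           up$upper)
  )
}
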