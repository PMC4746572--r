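#' Tile-wise HER2/CK ratios
#'
#' The HER2 signal of each retained tile is normalised by its CK signal,
#' cancelling case-level staining-quality variation that affects both
#' channels equally.
#'
#' @param retained data frame of retained tiles from [apply_filters()].
#' @return numeric vector of `her2_mean / ck_mean`, in tile order.
#' @export
ratio_per_tile <- function(retained) {
  ck <- retained$ck_mean
  if (any(!is.finite(ck)) || any(ck <= 0)) {
    stop("internal consistency error: retained tile with ck_mean <= 0 ",
         "(the lower CK filter should exceed the noise floor)")
  }
  retained$her2_mean / ck
}

#' Ratio histogram of a case
#'
#' Bins the tile-wise HER2/CK ratios over `[0, upper]` and normalises the
#' counts by the number of tiles, so frequencies sum to 1. The bin width
#' defaults to the Freedman-Diaconis rule (falling back to 50 bins when the
#' interquartile range is degenerate); a fixed bin count can be set via
#' `config$n_bins`. `upper` should be the maximum ratio across the batch so
#' that cases of one batch share a binning.
#'
#' @param ratios numeric vector from [ratio_per_tile()].
#' @param config a [default_config()] list.
#' @param upper right edge of the histogram support; defaults to
#'   `max(ratios)`.
#' @return object of class `ratio_histogram`: list with `bin_edges`, `mids`,
#'   `frequencies`, `n_tiles`.
#' @export
build_histogram <- function(ratios, config = default_config(), upper = NULL) {
  n <- length(ratios)
  if (n < config$min_tiles) {
    stop("unscorable case: only ", n, " ratios (need ", config$min_tiles, ")")
  }
  if (any(!is.finite(ratios)) || any(ratios < 0)) {
    stop("ratios must be finite and non-negative")
  }
  if (is.null(upper)) upper <- max(ratios)
  if (upper < max(ratios)) stop("'upper' is below the largest ratio")
  if (upper <= 0) upper <- 1
  if (is.null(config$n_bins)) {
    h <- 2 * IQR(ratios) * n^(-1 / 3)
    n_bins <- if (h > 0) max(3L, ceiling(upper / h)) else 50L
    n_bins <- min(n_bins, 500L)
  } else {
    n_bins <- as.integer(config$n_bins)
  }
  edges <- seq(0, upper, length.out = n_bins + 1)
  idx <- findInterval(ratios, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(
    bin_edges = edges,
    mids = (edges[-1] + edges[-length(edges)]) / 2,
    frequencies = counts / n,
    n_tiles = n
  ), class = "ratio_histogram")
}

#' Gaussian fit to a ratio histogram
#'
#' Fits `a * exp(-(x - mu)^2 / (2 sigma^2))` to the (bin centre, frequency)
#' pairs by Levenberg-Marquardt least squares, initialised from the weighted
#' sample moments of the histogram. After an initial unweighted pass the fit
#' is repeated once with chi-square weights (the reciprocal of the binomial
#' variance the fitted model predicts for each bin frequency), which markedly
#' improves the efficiency of the width estimate on histograms built from a
#' few dozen tiles. The adjusted R-squared of the fit is the
#' quality-control statistic used by [qc_case()]; cases whose tiles do not
#' form a coherent ratio population (too few epithelial tiles, flat
#' histograms) produce low values and are excluded.
#'
#' @param hist a [build_histogram()] result.
#' @return object of class `gaussian_fit`: list with `mu`, `sigma`,
#'   `amplitude`, `adj_r2`, `converged`, `n_bins`, `reason`.
#' @export
fit_gaussian <- function(hist) {
  stopifnot(inherits(hist, "ratio_histogram"))
  x <- hist$mids
  y <- hist$frequencies
  if (sum(y > 0) < 3) {
    return(structure(list(mu = NA_real_, sigma = NA_real_,
                          amplitude = NA_real_, adj_r2 = NA_real_,
                          converged = FALSE, n_bins = length(y),
                          reason = "fewer than 3 occupied bins"),
                     class = "gaussian_fit"))
  }
  mu0 <- sum(x * y) / sum(y)
  s0 <- sqrt(sum(y * (x - mu0)^2) / sum(y))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(x)) / 10
  a0 <- max(y)
  do_fit <- function(start, w) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
        data = data.frame(x = x, y = y),
        start = start, weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  fit <- do_fit(list(a = a0, mu = mu0, s = s0), rep(1, length(y)))
  if (is.null(fit)) {
    return(structure(list(mu = mu0, sigma = s0, amplitude = a0,
                          adj_r2 = NA_real_, converged = FALSE,
                          n_bins = length(y), reason = "fit did not converge"),
                     class = "gaussian_fit"))
  }
  # goodness of fit is judged on the unweighted pass: it asks whether the
  # histogram is Gaussian-shaped at all, which the QC cut-off polices
  resid <- y - predict(fit)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  n <- length(y)
  adj_r2 <- if (is.finite(r2) && n > 4) 1 - (1 - r2) * (n - 1) / (n - 4) else r2
  p1 <- coef(fit)
  yhat <- pmin(pmax(predict(fit), 0), 0.99)
  w <- 1 / pmax(yhat * (1 - yhat) / hist$n_tiles, 1e-8)
  refit <- do_fit(as.list(p1), w)
  if (!is.null(refit)) fit <- refit
  p <- coef(fit)
  structure(list(mu = unname(p["mu"]), sigma = abs(unname(p["s"])),
                 amplitude = unname(p["a"]), adj_r2 = adj_r2,
                 converged = TRUE, n_bins = n, reason = NA_character_),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<gaussian_fit: mu = %.4g, sigma = %.4g, adj R2 = %.3f>\n",
                x$mu, x$sigma, x$adj_r2))
  } else {
    cat(sprintf("<gaussian_fit: not converged (%s)>\n", x$reason))
  }
  invisible(x)
}

#' Quality control of a case's Gaussian fit
#'
#' @param fit a [fit_gaussian()] result.
#' @param config a [default_config()] list; `r2_min` (default 0.5) is the
#'   adjusted R-squared cut-off below which the fit is rejected.
#' @return one of `"pass"`, `"excluded_low_r2"`, `"excluded_few_tiles"`,
#'   `"excluded_no_convergence"`.
#' @export
qc_case <- function(fit, config = default_config()) {
  stopifnot(inherits(fit, "gaussian_fit"))
  if (!fit$converged) {
    if (identical(fit$reason, "fewer than 3 occupied bins")) {
      return("excluded_few_tiles")
    }
    return("excluded_no_convergence")
  }
  if (!is.finite(fit$adj_r2) || fit$adj_r2 < config$r2_min) {
    return("excluded_low_r2")
  }
  "pass"
}

#' Batch-normalised M-, Sigma- and MTP-scores
#'
#' The fitted mean of a case's HER2/CK ratio histogram, normalised by the
#' fitted mean of the batch's IHC 3+ positive control, is the M-score; the
#' fitted standard deviation, normalised the same way, is the Sigma-score;
#' their product is the MTP-score. The positive control therefore scores
#' (1, 1, 1) by construction.
#'
#' @param fit a case's [fit_gaussian()] result.
#' @param pos_control_fit the positive control's fit from the same batch.
#' @param batch_id optional batch identifier carried into the result.
#' @return one-row data frame with `m_score`, `sigma_score`, `mtp_score`,
#'   `batch_id`.
#' @export
score_case <- function(fit, pos_control_fit, batch_id = NA) {
  stopifnot(inherits(fit, "gaussian_fit"),
            inherits(pos_control_fit, "gaussian_fit"))
  if (!pos_control_fit$converged || pos_control_fit$sigma <= 0) {
    stop("batch unscorable: positive-control Gaussian fit failed")
  }
  if (!fit$converged) stop("cannot score a non-converged fit")
  m <- fit$mu / pos_control_fit$mu
  s <- fit$sigma / pos_control_fit$sigma
  data.frame(m_score = m, sigma_score = s, mtp_score = m * s,
             batch_id = batch_id, stringsAsFactors = FALSE)
}
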