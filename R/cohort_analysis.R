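#' Classify a case by its mean HER2 gene copy number
#'
#' Copy-number classes used for cohort annotation: `Negative` for
#' `n_fish < 4`, `Equivocal` for `4 <= n_fish < 6`, `Positive` for
#' `n_fish >= 6`. The rule partitions the positive axis with closed lower
#' bounds, so 4.0 is Equivocal and 6.0 is Positive.
#'
#' @param n_fish copy-number value(s), > 0 (vectorised).
#' @return character vector in `{"Negative", "Equivocal", "Positive"}`.
#' @export
#' @examples
#' classify_fish(c(1.9, 4.4, 9.4)) # Negative, Equivocal, Positive
classify_fish <- function(n_fish) {
  if (any(!is.finite(n_fish)) || any(n_fish <= 0)) {
    stop("n_fish must be strictly positive")
  }
  ifelse(n_fish < 4, "Negative", ifelse(n_fish < 6, "Equivocal", "Positive"))
}

#' Correlate case scores with a FISH readout
#'
#' For each of the M-, Sigma- and MTP-scores, computes the Pearson
#' correlation against the chosen copy-number variable and the power-law
#' exponent `alpha` of `score ~ x^alpha`, fitted by ordinary least squares in
#' log-log space. Controls and QC-failed cases are excluded; cases with
#' non-positive score or x values are dropped from the log-log fit with a
#' warning.
#'
#' @param scores data frame with columns `case_id`, `m_score`, `sigma_score`,
#'   `mtp_score`, and (if present) `role`, `qc_status` used for exclusion —
#'   typically the result table of [score_cohort()].
#' @param records data frame of cohort metadata with `case_id` and the
#'   `x_variable` column (e.g. from [generate_cohort()]).
#' @param x_variable `"nfish_true"`, `"n_fish"` or `"her2_cep17"` — the
#'   column of `records` to correlate against.
#' @return data frame with one row per score: `score_name` (`M`, `Sigma`,
#'   `MTP`), `rho`, `alpha`, `n_cases`.
#' @export
correlate_scores <- function(scores, records, x_variable = "nfish_true") {
  if (!x_variable %in% names(records)) {
    stop("records has no column '", x_variable, "'")
  }
  df <- merge(scores, records[, c("case_id", x_variable)], by = "case_id")
  if ("role" %in% names(df)) df <- df[df$role == "case", , drop = FALSE]
  if ("qc_status" %in% names(df)) {
    df <- df[df$qc_status == "pass", , drop = FALSE]
  }
  x <- df[[x_variable]]
  cols <- c(M = "m_score", Sigma = "sigma_score", MTP = "mtp_score")
  out <- lapply(names(cols), function(nm) {
    y <- df[[cols[[nm]]]]
    ok <- is.finite(y) & is.finite(x)
    if (sum(ok) < 3) stop("fewer than 3 usable cases for score ", nm)
    rho <- cor(x[ok], y[ok])
    pos <- ok & y > 0 & x > 0
    n_drop <- sum(ok) - sum(pos)
    if (n_drop > 0) {
      warning(n_drop, " case(s) with non-positive values excluded from the ",
              nm, " power-law fit")
    }
    alpha <- if (sum(pos) >= 3) {
      unname(coef(lm(log(y[pos]) ~ log(x[pos])))[2])
    } else NA_real_
    data.frame(score_name = nm, rho = rho, alpha = alpha,
               n_cases = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Long-format tile table for scatter plots
#'
#' Assembles the per-tile CK and HER2 means of measured cases into one table
#' suitable for plotting case scatter clouds against the positive and
#' negative control clouds.
#'
#' @param measurements named list of [measure_case()] data frames, one per
#'   case.
#' @param records cohort metadata with `case_id` and `role`.
#' @param retained optional named list of retained-tile data frames from
#'   [apply_filters()]; tiles absent from it get `retained_flag = FALSE`.
#' @return data frame with columns `case_id`, `tile_id`, `ck_mean`,
#'   `her2_mean`, `retained_flag`, `role`.
#' @export
scatter_export <- function(measurements, records, retained = NULL) {
  stopifnot(is.list(measurements), !is.null(names(measurements)))
  rows <- lapply(names(measurements), function(id) {
    m <- measurements[[id]]
    flag <- if (!is.null(retained) && id %in% names(retained)) {
      m$tile_id %in% retained[[id]]$tile_id
    } else {
      m$valid
    }
    role <- records$role[match(id, records$case_id)]
    data.frame(case_id = id, tile_id = m$tile_id, ck_mean = m$ck_mean,
               her2_mean = m$her2_mean, retained_flag = flag,
               role = if (length(role) == 1) role else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag intratumoural heterogeneity of the ratio distribution
#'
#' Fits 1- and 2-component Gaussian mixtures (unequal variances) to the
#' tile-wise HER2/CK ratios and flags the case heterogeneous when the
#' 2-component model beats the 1-component model by more than
#' `config$bic_margin` BIC units *and* the component means are separated by
#' more than `config$separation` pooled standard deviations. Two spatially
#' distinct subclones with different HER2 expression produce exactly this
#' bimodal ratio signature.
#'
#' @param ratios numeric vector from [ratio_per_tile()].
#' @param config a [default_config()] list.
#' @return list with `flag` (logical), `means`, `sds`, `proportions` of the
#'   2-component fit, and `bic_1`, `bic_2` (mclust convention: larger is
#'   better). On fit failure the flag defaults to `FALSE`.
#' @importFrom mclust Mclust mclustBIC
#' @export
flag_heterogeneity <- function(ratios, config = default_config()) {
  if (length(ratios) < config$min_tiles) {
    stop("unscorable case: only ", length(ratios), " ratios (need ",
         config$min_tiles, ")")
  }
  res <- tryCatch({
    m1 <- mclust::Mclust(ratios, G = 1, modelNames = "V", verbose = FALSE)
    m2 <- mclust::Mclust(ratios, G = 2, modelNames = "V", verbose = FALSE)
    if (is.null(m1) || is.null(m2)) stop("mixture fit failed")
    means <- as.numeric(m2$parameters$mean)
    vars <- m2$parameters$variance$sigmasq
    if (length(vars) == 1) vars <- rep(vars, 2)
    props <- m2$parameters$pro
    pooled_sd <- sqrt(sum(props * vars))
    flag <- (m2$bic - m1$bic > config$bic_margin) &&
      (abs(diff(means)) > config$separation * pooled_sd)
    list(flag = flag, means = means, sds = sqrt(vars), proportions = props,
         bic_1 = m1$bic, bic_2 = m2$bic)
  }, error = function(e) {
    list(flag = FALSE, means = NA_real_, sds = NA_real_,
         proportions = NA_real_, bic_1 = NA_real_, bic_2 = NA_real_)
  })
  res
}
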