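new_spotting_series <- function(ag_levels, ag_signal, ab_signal, t_incubation) {
  stopifnot(length(ag_levels) == length(ag_signal),
            length(ag_signal) == length(ab_signal),
            all(ag_signal >= 0), all(ab_signal >= 0))
  structure(list(ag_levels = ag_levels, ag_signal = ag_signal,
                 ab_signal = ab_signal, t_incubation = t_incubation),
            class = "spotting_series")
}

#' @export
print.spotting_series <- function(x, ...) {
  cat(sprintf("<spotting_series: %d antigen levels, t = %g s>\n",
              length(x$ag_levels), x$t_incubation))
  invisible(x)
}

#' Simulate a spotted antigen / recognising antibody series
#'
#' Emulates a microarray in which fluorescently labelled antigen is spotted
#' at a gradient of concentrations and a recognising antibody is incubated
#' for `t_incubation` seconds. The antigen signal is proportional to the
#' spotted level (normalised to its maximum); under pseudo-first-order
#' Langmuir kinetics the antibody signal is `occupancy(params, t)` times the
#' antigen signal, perturbed by multiplicative Gaussian noise of coefficient
#' of variation `noise_cv` and clipped at zero.
#'
#' @param params a [kinetic_params()] object.
#' @param ag_levels spotted antigen concentrations, ug/mL; >= 0.
#' @param t_incubation incubation time, seconds; > 0.
#' @param noise_cv multiplicative noise CV; >= 0.
#' @param seed integer RNG seed (the global RNG state is left untouched).
#' @return a `spotting_series`.
#' @export
#' @examples
#' s <- generate_spotting_series(kinetic_params(),
#'                               ag_levels = seq(0, 1000, length.out = 11),
#'                               t_incubation = 120, noise_cv = 0.02, seed = 1)
#' linearity(s)
generate_spotting_series <- function(params,
                                     ag_levels = seq(0, 1000, length.out = 11),
                                     t_incubation = 120,
                                     noise_cv = 0.02,
                                     seed = 1L) {
  if (any(!is.finite(ag_levels)) || any(ag_levels < 0)) {
    stop("antigen concentrations must be non-negative")
  }
  stopifnot(t_incubation > 0, noise_cv >= 0)
  ag_signal <- if (max(ag_levels) > 0) ag_levels / max(ag_levels) else ag_levels
  theta <- occupancy(params, t_incubation)
  ab <- theta * ag_signal
  if (noise_cv > 0) {
    ab <- withr::with_seed(as.integer(seed), {
      pmax(0, ab * (1 + rnorm(length(ab), 0, noise_cv)))
    })
  }
  new_spotting_series(ag_levels, ag_signal, ab, t_incubation)
}

#' Saturating-response spotting series
#'
#' Long manual incubations show a sudden saturation of the antibody signal
#' with antigen concentration instead of proportionality. This model is
#' phenomenological: the bound density `b = occupancy(params, t) * ag_signal`
#' is passed through the hyperbolic response
#' `b * (1 + k_sat) / (b + k_sat)`, which saturates for `b >> k_sat` and
#' recovers the proportional model as `k_sat` tends to infinity. Because a
#' longer incubation raises the occupancy, it pushes the series deeper into
#' saturation, reproducing the short- vs long-incubation linearity contrast.
#'
#' @param params a [kinetic_params()] object.
#' @param ag_levels spotted antigen concentrations, ug/mL; >= 0.
#' @param t_incubation incubation time, seconds; > 0.
#' @param k_sat saturation constant on the bound-density scale; > 0.
#'   Default 0.2.
#' @param noise_cv multiplicative noise CV; >= 0.
#' @param seed integer RNG seed.
#' @return a `spotting_series`.
#' @export
saturation_model <- function(params,
                             ag_levels = seq(0, 1000, length.out = 11),
                             t_incubation = 3600,
                             k_sat = 0.2,
                             noise_cv = 0.02,
                             seed = 1L) {
  stopifnot(k_sat > 0)
  if (any(!is.finite(ag_levels)) || any(ag_levels < 0)) {
    stop("antigen concentrations must be non-negative")
  }
  ag_signal <- if (max(ag_levels) > 0) ag_levels / max(ag_levels) else ag_levels
  b <- occupancy(params, t_incubation) * ag_signal
  ab <- b * (1 + k_sat) / (b + k_sat)
  ab[b == 0] <- 0
  if (noise_cv > 0) {
    ab <- withr::with_seed(as.integer(seed), {
      pmax(0, ab * (1 + rnorm(length(ab), 0, noise_cv)))
    })
  }
  new_spotting_series(ag_levels, ag_signal, ab, t_incubation)
}
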