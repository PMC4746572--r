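#' Langmuir antigen-antibody kinetic constants
#'
#' Container for the rate constants of single-site surface recognition:
#' association rate `k_on` (per molar per second), dissociation rate `k_off`
#' (per second) and the bulk antibody concentration `c_bulk` (molar). Typical
#' IgG values are `k_on ~ 1e6`, `k_off ~ 1e-3`, with `c_bulk ~ 1e-8` chosen
#' high enough that antibody supply does not limit surface coverage.
#'
#' @param k_on association rate constant, M^-1 s^-1; > 0.
#' @param k_off dissociation rate constant, s^-1; > 0.
#' @param c_bulk bulk antibody concentration, M; > 0.
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_on = 1e6, k_off = 1e-3, c_bulk = 1e-8) {
  vals <- c(k_on = k_on, k_off = k_off, c_bulk = c_bulk)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("k_on, k_off and c_bulk must all be strictly positive")
  }
  structure(as.list(vals), class = "kinetic_params")
}

#' Derived Langmuir time constants and equilibrium occupancy
#'
#' From the rate constants: the desorption time `t_d = 1/k_off`, the
#' recognition time constant `tau = 1/(k_on * c_bulk + k_off)`, the
#' equilibrium dissociation constant `K_D = k_off/k_on`, and the equilibrium
#' fractional occupancy `theta_eq = c_bulk/(c_bulk + K_D)` of the Langmuir
#' isotherm. With typical IgG constants, `tau` (~1e2 s) is an order of
#' magnitude below `t_d` (~1e3 s): recognition completes well before
#' desorption matters, which is the rationale for few-minute incubations.
#'
#' @param params a [kinetic_params()] object.
#' @return list with `tau` (s), `t_d` (s), `k_d_eq` (M), `theta_eq`
#'   (dimensionless in \[0,1\]).
#' @export
#' @examples
#' derive_kinetics(kinetic_params()) # t_d = 1000 s, tau ~ 90.9 s
derive_kinetics <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  k_d <- params$k_off / params$k_on
  list(
    tau = 1 / (params$k_on * params$c_bulk + params$k_off),
    t_d = 1 / params$k_off,
    k_d_eq = k_d,
    theta_eq = params$c_bulk / (params$c_bulk + k_d)
  )
}

#' Fractional surface occupancy after an incubation time
#'
#' Pseudo-first-order Langmuir kinetics:
#' `theta(t) = theta_eq * (1 - exp(-t / tau))`. The relaxation is independent
#' of the surface antigen density, which is why the bound-antibody signal
#' stays proportional to antigen across a concentration gradient.
#'
#' @param params a [kinetic_params()] object.
#' @param t incubation time(s), seconds; >= 0 (vectorised).
#' @return occupancy fraction(s) in \[0, theta_eq\].
#' @export
occupancy <- function(params, t) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be non-negative")
  d <- derive_kinetics(params)
  d$theta_eq * (1 - exp(-t / d$tau))
}

#' Linearity of a spotting series
#'
#' Pearson correlation of the bound-antibody signal against the spotted
#' antigen signal, the regression coefficient used to judge the
#' proportionality of a short-incubation stain.
#'
#' @param series a `spotting_series` (see [generate_spotting_series()]).
#' @return Pearson correlation coefficient.
#' @export
linearity <- function(series) {
  stopifnot(inherits(series, "spotting_series"))
  if (length(unique(series$ag_signal)) < 3) {
    stop("need at least 3 distinct antigen levels")
  }
  if (sd(series$ab_signal) == 0 || sd(series$ag_signal) == 0) {
    stop("constant series: linearity undefined")
  }
  cor(series$ab_signal, series$ag_signal)
}
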