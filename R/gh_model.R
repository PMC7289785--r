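# Structural GH model.
#
# Secretion rate S(t) = baseline*kel + sum_j mass_j * drugfactor_j *
# phi(t; T_j, width) with phi the unit-mass Gaussian density; plasma GH obeys
# dC/dt = S(t) - kel*C. Because the system is linear, the response to one
# pulse has the exact Gaussian-convolved-exponential (exponentially modified
# Gaussian) form
#   mass * exp(kel^2 w^2/2 - kel (t - T)) * Phi((t - T)/w - kel w),
# and the full profile is baseline plus the superposition of pulse terms.
# The closed form is the production path; an RK45 route is kept as a
# numerical cross-check.

#' Emax multiplicative effect factor
#'
#' `1 + emax * C^gamma / (ec50^gamma + C^gamma)`; with `emax` in \[-1, 0\]
#' the factor lies in (0, 1\] and is nonincreasing in `C`.
#'
#' @param conc driving concentration (µg/L), >= 0 (vectorised).
#' @param emax maximal fractional effect in \[-1, 0\].
#' @param ec50 half-maximal concentration (µg/L).
#' @param gamma Hill coefficient.
#' @return numeric vector of multiplicative factors.
#' @export
emax_factor <- function(conc, emax, ec50, gamma = 1) {
  cg <- pmax(conc, 0)^gamma
  1 + emax * cg / (ec50^gamma + cg)
}

# EMG basis: matrix of unit-mass pulse responses at `times` for pulse
# centres `loc`, shared width w and elimination k. Computed in log space to
# avoid overflow of exp(k^2 w^2/2 - k(t-T)) when Phi underflows.
.gh_basis <- function(times, loc, w, k) {
  if (!length(loc)) return(matrix(0, length(times), 0))
  td <- outer(times, loc, "-")               # t - T
  lg <- k * k * w * w / 2 - k * td +
    pnorm(td / w - k * w, log.p = TRUE)
  exp(lg)
}

#' GH concentration-time profile
#'
#' Evaluates the structural GH model for one subject: baseline plus the
#' superposition of Gaussian secretion pulses filtered through first-order
#' elimination, with the drug scaling each pulse mass by an Emax factor of
#' the effect-site concentration at the pulse centre (default), or scaling
#' the instantaneous secretion rate pointwise (`effect = "rate"`).
#'
#' @param params a [gh_params()] (typical values are used; individual values
#'   can be supplied by overriding fields).
#' @param pulses data.frame with columns `location` (h) and optionally
#'   `mass` (ng/mL; defaults to `params$amplitude`).
#' @param times output times (h), sorted.
#' @param drug `NULL` for no drug, or a list with `times` and `cp`
#'   (tabulated plasma concentrations, µg/L) from which the effect-site
#'   concentration is computed with `params$ke0`.
#' @param effect `"mass"` (drug scales whole pulse mass, sampled at the
#'   pulse centre) or `"rate"` (pointwise scaling of the secretion rate;
#'   only available with `method = "ode"`).
#' @param method `"analytic"` (exact closed form) or `"ode"` (RK45
#'   integration of the same right-hand side).
#' @param rtol,atol tolerances for the ODE route.
#' @return numeric vector of GH concentrations (ng/mL) at `times`.
#' @examples
#' p <- gh_params()
#' gh_concentration(p, data.frame(location = c(1, 3)), times = seq(0, 6, .25))
#' @export
gh_concentration <- function(params, pulses, times, drug = NULL,
                             effect = c("mass", "rate"),
                             method = c("analytic", "ode"),
                             rtol = 1e-10, atol = 1e-12) {
  effect <- match.arg(effect)
  method <- match.arg(method)
  stopifnot(inherits(params, "gh_params"))
  loc <- if (is.null(pulses) || !nrow(pulses)) numeric(0) else pulses$location
  mass <- if (!length(loc)) numeric(0) else if ("mass" %in% names(pulses) &&
    !all(is.na(pulses$mass))) {
    ifelse(is.na(pulses$mass), params$amplitude, pulses$mass)
  } else rep(params$amplitude, length(loc))

  ce_at <- NULL
  if (!is.null(drug)) {
    ce_tab <- effect_compartment(drug$times, drug$cp, params$ke0)
    ce_at <- function(t) approx(drug$times, ce_tab, xout = t, rule = 2)$y
  }
  fac_pulse <- if (!is.null(drug) && length(loc)) {
    emax_factor(ce_at(loc), params$emax, params$ec50, params$gamma)
  } else rep(1, length(loc))

  if (method == "analytic") {
    if (effect == "rate" && !is.null(drug)) {
      stop("effect = 'rate' requires method = 'ode'")
    }
    basis <- .gh_basis(times, loc, params$width, params$kel)
    return(params$baseline + as.vector(basis %*% (mass * fac_pulse)))
  }

  # ODE route: start 2 h before the earliest of (first output, first pulse)
  # so pre-window pulse tails are captured, from the baseline steady state.
  t0 <- min(c(times[1], loc - 6 * params$width)) - 2
  sec <- function(t) {
    s <- params$baseline * params$kel
    if (length(loc)) {
      f <- if (effect == "mass") fac_pulse else if (!is.null(drug)) {
        rep(emax_factor(ce_at(t), params$emax, params$ec50, params$gamma),
            length(loc))
      } else rep(1, length(loc))
      s <- s + sum(mass * f * dnorm(t, loc, params$width))
    }
    s
  }
  rhs <- function(t, y) sec(t) - params$kel * y
  grid <- sort(unique(c(t0, times)))
  sol <- ode_rk45(rhs, params$baseline, grid, rtol = rtol, atol = atol)
  sol[match(times, grid), 1]
}
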