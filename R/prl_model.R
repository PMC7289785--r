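# Structural PRL model: precursor pool with circadian release, direct Emax
# inhibition of release by drug plasma concentration, and a saturating
# cumulative-exposure-driven decline of the synthesis rate.
#
#   pool:   dP/dt = ks * (1 - I(t)) - kr_eff(t) * P
#   plasma: dC/dt = kr_eff(t) * P  - kel * C
#   kr_eff(t) = kr * (1 + DIU24(t) + DIU12(t)) * emax_factor(Cp(t))
#   I(t)      = exposure_inhibition(cumulative plasma AUC since first dose)
#
# All times are clock-normalised (0 = 6 a.m.); a 24 h initialisation period
# precedes the first retained output and the state at its start is placed on
# the drug-free periodic orbit (computed exactly from the affine one-period
# map of the linear system).

#' Circadian cosine factor
#'
#' `amplitude * cos(2 pi (t - phase) / period)`: the diurnal deviation from
#' the mesor of a release-rate rhythm.
#'
#' @param t clock time (h), vectorised; 0 = 6 a.m.
#' @param amplitude peak height as a fraction of the mesor.
#' @param phase phase shift (h): clock time of the cosine maximum.
#' @param period cycle length (h), > 0.
#' @return dimensionless diurnal factor.
#' @export
circadian_factor <- function(t, amplitude, phase, period = 24) {
  if (period <= 0) stop("circadian_factor: period must be > 0")
  amplitude * cos(2 * pi * (t - phase) / period)
}

#' Saturating exposure-driven inhibition
#'
#' `I = x * slope / (1 + x * slope)` for cumulative exposure `x` (mg·h/L):
#' 0 at zero exposure, monotone increasing, asymptote 1.
#'
#' @param cum_exposure cumulative exposure (mg·h/L), >= 0 (vectorised).
#' @param slope steepness parameter (L/(mg·h)).
#' @return inhibition fraction in \[0, 1).
#' @export
exposure_inhibition <- function(cum_exposure, slope) {
  if (any(cum_exposure < 0)) {
    stop("exposure_inhibition: cumulative exposure must be >= 0")
  }
  xs <- cum_exposure * slope
  xs / (1 + xs)
}

# Drug-free periodic initial state of the (P, C) system at clock time t0.
# One period of the drug-free dynamics is an affine map x -> A x + c; the
# periodic state is (I - A)^{-1} c, obtained from three basis integrations.
.prl_periodic_state <- function(params, t0, dt) {
  grid <- seq(t0 - 24, t0, by = dt)
  if (tail(grid, 1) < t0) grid <- c(grid, t0)
  zero <- rep(0, length(grid))
  run <- function(P0, C0) {
    sol <- prl_integrate_cpp(grid, params$kr, params$kel, params$ks,
                             params$amp24, params$phase24,
                             params$amp12, params$phase12,
                             params$emax, params$ec50, 0,
                             zero, zero, P0, C0)
    sol[nrow(sol), ]
  }
  cc <- run(0, 0)
  A <- cbind(run(1, 0) - cc, run(0, 1) - cc)
  as.vector(solve(diag(2) - A, cc))
}

#' PRL concentration-time profile
#'
#' Evaluates the structural prolactin model for one subject. The simulation
#' starts 24 h (`run_in`) before the earliest retained output from the
#' drug-free periodic steady state; the drug plasma curve (if any) modulates
#' the release rate directly and its running AUC drives the synthesis
#' decline.
#'
#' @param params a [prl_params()].
#' @param times clock-normalised output times (h), sorted.
#' @param drug `NULL`, or a list with `times`, `cp` (µg/L) and optionally
#'   `first_dose_time` (defaults to `drug$times[1]`).
#' @param run_in initialisation period (h) before the first output.
#' @param dt integration step (h).
#' @return numeric vector of PRL concentrations (ng/mL) at `times`.
#' @examples
#' prl_concentration(prl_params(), times = seq(0, 24, 0.5))
#' @export
prl_concentration <- function(params, times, drug = NULL, run_in = 24,
                              dt = 0.05) {
  stopifnot(inherits(params, "prl_params"))
  if (is.unsorted(times)) stop("prl_concentration: times must be sorted")
  t0 <- min(times[1], if (!is.null(drug)) drug$times[1] else Inf) - run_in
  tn <- max(times)
  grid <- seq(t0, tn, by = dt)
  if (tail(grid, 1) < tn) grid <- c(grid, tn)
  if (is.null(drug)) {
    cp <- rep(0, length(grid))
    ex <- rep(0, length(grid))
  } else {
    cp <- approx(drug$times, pmax(drug$cp, 0), xout = grid, rule = 2,
                 yleft = 0)$y
    cp[grid < drug$times[1]] <- 0
    fd <- if (!is.null(drug$first_dose_time)) drug$first_dose_time else
      drug$times[1]
    ex <- cumulative_exposure(grid, cp, first_dose_time = fd)
  }
  x0 <- .prl_periodic_state(params, t0, dt)
  sol <- prl_integrate_cpp(grid, params$kr, params$kel, params$ks,
                           params$amp24, params$phase24,
                           params$amp12, params$phase12,
                           params$emax, params$ec50, params$slope,
                           cp, ex, x0[1], x0[2])
  approx(grid, sol[, 2], xout = times, rule = 2)$y
}
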