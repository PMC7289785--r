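# Drug pharmacokinetics.
#
# The drug PK (two-compartment, first-order subcutaneous absorption, linear
# plus Michaelis-Menten elimination from the central compartment) is consumed
# as configuration: the published analysis used individual post-hoc estimates
# of a previously developed PK model, which are not reproduced here. The
# shipped defaults are illustrative and every quantitative claim requires an
# explicit configuration.

#' Two-compartment PK configuration
#'
#' @param ka first-order absorption rate from the subcutaneous depot (/h).
#' @param vc,vp central and peripheral volumes (L).
#' @param q inter-compartmental clearance (L/h).
#' @param cl linear clearance (L/h).
#' @param vmax Michaelis-Menten maximal elimination rate (µg/h); 0 disables
#'   the nonlinear pathway.
#' @param km Michaelis constant (µg/L).
#' @param iiv_cv optional log-normal coefficient of variation (fraction)
#'   applied per subject to `cl`, `vc` and `vp`; 0 means identical typical
#'   PK in every subject.
#' @return an object of class `pk_config`.
#' @export
pk_config <- function(ka = 1.0, vc = 8, vp = 20, q = 5, cl = 20,
                      vmax = 50, km = 1, iiv_cv = 0) {
  vals <- c(ka = ka, vc = vc, vp = vp, q = q, cl = cl, km = km)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("pk_config: ka, vc, vp, q, cl, km must all be strictly positive")
  }
  if (vmax < 0 || iiv_cv < 0) stop("pk_config: vmax and iiv_cv must be >= 0")
  structure(list(ka = ka, vc = vc, vp = vp, q = q, cl = cl,
                 vmax = vmax, km = km, iiv_cv = iiv_cv),
            class = "pk_config")
}

#' Simulate drug plasma concentrations
#'
#' Solves the two-compartment model with first-order absorption and mixed
#' linear/Michaelis-Menten elimination for an arbitrary subcutaneous dose
#' history. Doses (mg) are converted to µg internally so concentrations come
#' out in µg/L.
#'
#' @param config a [pk_config()].
#' @param doses data.frame with columns `time` (h) and `amt` (mg).
#' @param times sorted output times (h); may start before the first dose.
#' @param rtol,atol solver tolerances passed to [ode_rk45()].
#' @return numeric vector of plasma concentrations (µg/L) at `times`.
#' @export
simulate_pk <- function(config, doses, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(config, "pk_config"))
  if (is.unsorted(times)) stop("simulate_pk: times must be sorted")
  if (is.null(doses) || nrow(doses) == 0) return(rep(0, length(times)))
  if (any(doses$amt <= 0)) stop("simulate_pk: dose amounts must be > 0")
  if (any(diff(doses$time) <= 0)) {
    stop("simulate_pk: dose times must be strictly increasing")
  }
  k10 <- config$cl / config$vc
  k12 <- config$q / config$vc
  k21 <- config$q / config$vp
  rhs <- function(t, y) {
    # y = (depot µg, central µg, peripheral µg)
    conc <- y[2] / config$vc
    mm <- if (config$vmax > 0) config$vmax * conc / (config$km + conc) else 0
    c(-config$ka * y[1],
      config$ka * y[1] - (k10 + k12) * y[2] + k21 * y[3] - mm,
      k12 * y[2] - k21 * y[3])
  }
  dose_t <- doses$time
  dose_amt <- doses$amt * 1000  # mg -> µg
  conc <- numeric(length(times))
  conc[times < dose_t[1]] <- 0
  # integrate piecewise between dose events
  y <- c(0, 0, 0)
  t_cur <- dose_t[1]
  breaks <- c(dose_t, Inf)
  for (d in seq_along(dose_t)) {
    y[1] <- y[1] + dose_amt[d]
    t_next <- breaks[d + 1]
    seg_out <- times[times >= t_cur & times < t_next]
    seg_end <- if (is.finite(t_next)) t_next else
      if (length(seg_out)) max(seg_out) else t_cur
    grid <- sort(unique(c(t_cur, seg_out, seg_end)))
    if (length(grid) >= 2) {
      sol <- ode_rk45(rhs, y, grid, rtol = rtol, atol = atol)
      if (length(seg_out)) {
        conc[match(seg_out, times)] <- sol[match(seg_out, grid), 2] / config$vc
      }
      y <- sol[nrow(sol), ]
    } else if (length(seg_out)) {
      conc[match(seg_out, times)] <- y[2] / config$vc
    }
    t_cur <- seg_end
  }
  # output times exactly at a dose time get the post-dose depot but the
  # central amount is continuous, so the concentration is well defined
  pmax(conc, 0)
}

#' Draw per-subject PK parameter sets
#'
#' Log-normal inter-individual variability on clearance and volumes with the
#' configured CV; returns a list of `pk_config` objects.
#' @param config typical [pk_config()].
#' @param n number of subjects.
#' @return list of `pk_config` objects of length `n`.
#' @keywords internal
#' @export
draw_pk_subjects <- function(config, n) {
  lapply(seq_len(n), function(i) {
    if (config$iiv_cv > 0) {
      sdlog <- sqrt(log(1 + config$iiv_cv^2))
      eta <- rlnorm(3, -sdlog^2 / 2, sdlog)
      pk_config(ka = config$ka, vc = config$vc * eta[2],
                vp = config$vp * eta[3], q = config$q,
                cl = config$cl * eta[1], vmax = config$vmax,
                km = config$km, iiv_cv = 0)
    } else config
  })
}

#' Effect-site concentration
#'
#' First-order equilibration of a hypothetical effect compartment with the
#' plasma concentration: dCe/dt = ke0 (Cp(t) - Ce), Ce(t0) = 0. The plasma
#' curve is taken as piecewise linear between the tabulated points and each
#' step is propagated exactly, so the scheme has no stability constraint.
#'
#' @param times sorted times (h) at which `cp` is tabulated.
#' @param cp plasma concentrations (µg/L) at `times`.
#' @param ke0 effect-compartment rate constant (/h), > 0.
#' @return effect-site concentrations (µg/L) at `times`.
#' @export
effect_compartment <- function(times, cp, ke0) {
  if (ke0 <= 0) stop("effect_compartment: ke0 must be > 0")
  n <- length(times)
  stopifnot(length(cp) == n)
  if (n == 1) return(0)
  dt <- diff(times)
  slope <- diff(cp) / dt
  e <- exp(-ke0 * dt)
  # exact update for linear Cp over [t_i, t_i+1]
  # Ce_{i+1} = Ce_i e + c_i (1-e) + s_i (dt - (1-e)/ke0)
  b <- cp[-n] * (1 - e) + slope * (dt - (1 - e) / ke0)
  ce <- numeric(n)
  if (length(unique(round(dt, 12))) == 1) {
    ce[-1] <- as.numeric(stats::filter(b, e[1], method = "recursive"))
  } else {
    for (i in seq_len(n - 1)) ce[i + 1] <- ce[i] * e[i] + b[i]
  }
  pmax(ce, 0)
}

#' Cumulative drug exposure
#'
#' Running trapezoidal integral of the plasma concentration from the first
#' dose, converted to mg·h/L (plasma in µg/L, factor 1e-3). Used as the
#' driver of the prolactin synthesis decline.
#'
#' @param times sorted times (h) at which `cp` is tabulated.
#' @param cp plasma concentrations (µg/L).
#' @param first_dose_time time (h) from which to integrate; exposure is 0 at
#'   and before this time.
#' @return nondecreasing exposures (mg·h/L) at `times`.
#' @export
cumulative_exposure <- function(times, cp, first_dose_time = times[1]) {
  n <- length(times)
  stopifnot(length(cp) == n)
  cp <- pmax(cp, 0)
  auc <- c(0, cumsum(diff(times) * (head(cp, -1) + tail(cp, -1)) / 2))
  # subtract the integral accumulated before the first dose
  base <- approx(times, auc, xout = first_dose_time, rule = 2)$y
  pmax(auc - base, 0) * 1e-3
}
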