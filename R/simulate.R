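# Virtual-trial generator.
#
# Emulates the phase-1 single/multiple ascending dose design: cohorts of 8
# (6 active, 2 placebo), 20-min hormone sampling windows on days 1/7/12,
# GH with log-normally varying pulse amplitudes and a 0.05 ng/mL LLOQ
# (below-LLOQ values substituted, not censored), PRL with circadian release
# and no censoring, proportional assay noise on both, and drug plasma
# curves from the two-compartment PK model.

.subject_seed <- function(master, k) {
  as.integer((as.numeric(master) * 1009 + k * 9973) %% 2147483647)
}

#' Flag and substitute below-LLOQ values
#'
#' Values strictly below `lloq` are replaced by `lloq` and flagged; values
#' at or above it are never altered, so the operation is idempotent.
#'
#' @param values numeric vector.
#' @param lloq lower limit of quantification (default GH assay, 0.05 ng/mL).
#' @return list with `value` (substituted) and `blq` (0/1 flags).
#' @export
lloq_substitute <- function(values, lloq = LLOQ_GH) {
  blq <- as.integer(values < lloq)
  list(value = ifelse(blq == 1, lloq, values), blq = blq)
}

#' Draw virtual-subject covariates
#'
#' Independent truncated normals for age, weight and height; BMI and lean
#' body mass (Boer formula, male) are derived.
#'
#' @param n number of subjects.
#' @param means,sds,lower,upper named vectors for `age` (y), `weight` (kg),
#'   `height` (cm).
#' @return data.frame with age, weight, height, bmi, lbm.
#' @export
draw_covariates <- function(n,
                            means = c(age = 30, weight = 78, height = 180),
                            sds = c(age = 8, weight = 10, height = 7),
                            lower = c(age = 18, weight = 55, height = 160),
                            upper = c(age = 55, weight = 110, height = 205)) {
  draw1 <- function(m, s, lo, hi) {
    x <- rnorm(n, m, s)
    while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), m, s)
    x
  }
  age <- draw1(means["age"], sds["age"], lower["age"], upper["age"])
  wt <- draw1(means["weight"], sds["weight"], lower["weight"],
              upper["weight"])
  ht <- draw1(means["height"], sds["height"], lower["height"],
              upper["height"])
  data.frame(age = age, weight = wt, height = ht,
             bmi = wt / (ht / 100)^2,
             lbm = 0.407 * wt + 0.267 * ht - 19.2)
}

# Individual GH profile for one occasion (no noise).
.gh_occ_profile <- function(gh, eta, kappa, pulses, st, drug) {
  p_i <- gh
  p_i$baseline <- gh$baseline * exp(eta["baseline"])
  p_i$width <- gh$width * exp(eta["width"] + kappa["width"])
  p_i$kel <- gh$kel * exp(eta["kel"] + kappa["kel"])
  gh_concentration(p_i, pulses, st, drug = drug)
}

#' Simulate a virtual ascending-dose trial
#'
#' Builds a virtual population across the requested cohorts (6 active + 2
#' placebo per cohort of 8 by default; pure-placebo cohorts are all
#' placebo), simulates drug PK, GH and PRL profiles at the design sampling
#' times, applies proportional assay noise, substitutes GH values below the
#' 0.05 ng/mL LLOQ, and assembles everything as a NONMEM-style event table.
#'
#' Per-subject random-number substreams are derived deterministically from
#' `seed`, so subject k's data do not depend on how many subjects follow.
#'
#' @param cohorts character vector of cohort names (see [cohort_names()]);
#'   recycled description of the trial arms.
#' @param n_per_cohort subjects per cohort (>= 1).
#' @param pk a [pk_config()].
#' @param gh a [gh_params()] or `NULL` to skip GH simulation.
#' @param prl a [prl_params()] or `NULL` to skip PRL simulation.
#' @param seed master seed (integer).
#' @param placebo_per_cohort placebo subjects per active cohort.
#' @param include_drug_rows add noise-free drug concentration records
#'   (DVID 1) on a 0.5 h grid, mirroring known individual PK curves.
#' @param pulse_law optional list overriding `meanlog`/`sdlog` of the
#'   pulse-interval renewal law.
#' @return an `event_table` (data.frame with columns ID, OCC, TIME, TAD, DV,
#'   DVID, AMT, EVID, MDV, BLQ) with attributes `subjects` (covariates,
#'   cohort, arm), `pk_curves` (per-subject tabulated drug curves) and
#'   `truth` (the individual random-effect draws and pulse trains used).
#' @examples
#' tab <- simulate_trial("placebo", n_per_cohort = 2, seed = 1,
#'                       prl = NULL)
#' head(tab)
#' @export
simulate_trial <- function(cohorts, n_per_cohort = 8, pk = pk_config(),
                           gh = gh_params(), prl = prl_params(),
                           seed = 1, placebo_per_cohort = 2,
                           include_drug_rows = TRUE,
                           pulse_law = NULL) {
  stopifnot(n_per_cohort >= 1)
  if (!is.null(gh) && (any(gh$omega2 < 0) || gh$sigma2 < 0)) {
    stop("invalid GH variance configuration")
  }
  meanlog <- if (!is.null(pulse_law$meanlog)) pulse_law$meanlog else
    PULSE_MEANLOG
  sdlog <- if (!is.null(pulse_law$sdlog)) pulse_law$sdlog else PULSE_SDLOG

  subj <- list()
  k <- 0
  for (co in cohorts) {
    d <- build_design(co)
    pure_placebo <- !nrow(d$doses)
    n_pl <- if (pure_placebo) n_per_cohort else
      min(placebo_per_cohort, n_per_cohort)
    for (j in seq_len(n_per_cohort)) {
      k <- k + 1
      subj[[k]] <- list(id = k, cohort = co,
                        active = !pure_placebo & j <= n_per_cohort - n_pl,
                        design = d)
    }
  }
  n <- length(subj)
  set.seed(.subject_seed(seed, 0))
  cov_tab <- cbind(id = seq_len(n), draw_covariates(n))

  rows <- list()
  pk_curves <- vector("list", n)
  truth <- vector("list", n)
  for (s in subj) {
    set.seed(.subject_seed(seed, s$id))
    d <- s$design
    all_obs_t <- sort(unlist(d$sampling))
    doses <- if (s$active) d$doses else d$doses[0, ]

    # drug PK
    drug <- NULL
    if (nrow(doses)) {
      pk_i <- draw_pk_subjects(pk, 1)[[1]]
      grid <- seq(doses$time[1], max(all_obs_t) + 1, by = 0.25)
      cp <- simulate_pk(pk_i, doses, grid)
      drug <- list(times = grid, cp = cp, first_dose_time = doses$time[1])
    }
    pk_curves[[s$id]] <- drug

    # dose records
    if (nrow(doses)) {
      rows[[length(rows) + 1]] <- data.frame(
        ID = s$id, OCC = 0, TIME = doses$time, TAD = 0, DV = NA_real_,
        DVID = 1, AMT = doses$amt, EVID = 1, MDV = 1, BLQ = 0)
    }
    if (include_drug_rows && !is.null(drug)) {
      g2 <- seq(drug$times[1], max(drug$times), by = 0.5)
      rows[[length(rows) + 1]] <- data.frame(
        ID = s$id, OCC = 0, TIME = g2,
        TAD = g2 - doses$time[1],
        DV = approx(drug$times, drug$cp, g2)$y, DVID = 1, AMT = 0,
        EVID = 0, MDV = 0, BLQ = 0)
    }

    tr <- list(cohort = s$cohort, active = s$active)

    # GH: one pulse train and one BOV draw per occasion
    if (!is.null(gh)) {
      eta <- setNames(rnorm(3, 0, sqrt(gh$omega2[c("baseline", "width",
                                                   "kel")])),
                      c("baseline", "width", "kel"))
      tr$gh_eta <- eta
      tr$gh_occ <- list()
      for (oi in seq_len(nrow(d$occasions))) {
        st <- d$sampling[[oi]]
        kappa <- setNames(rnorm(2, 0, sqrt(gh$bov2[c("width", "kel")])),
                          c("width", "kel"))
        p_t <- generate_pulse_times(duration = diff(range(st)) + 2,
                                    start = min(st) - 2,
                                    meanlog = meanlog, sdlog = sdlog)
        amp_eta <- rnorm(length(p_t), 0, sqrt(gh$omega2["amplitude"]))
        pulses <- data.frame(location = p_t,
                             mass = gh$amplitude * exp(amp_eta))
        pred <- .gh_occ_profile(gh, eta, kappa, pulses, st, drug)
        eps <- rnorm(length(st), 0, sqrt(gh$sigma2))
        obs <- lloq_substitute(pred * (1 + eps))
        tr$gh_occ[[oi]] <- list(kappa = kappa, pulses = pulses)
        rows[[length(rows) + 1]] <- data.frame(
          ID = s$id, OCC = d$occasions$occ[oi], TIME = st,
          TAD = st - d$occasions$dose_time[oi], DV = obs$value, DVID = 2,
          AMT = 0, EVID = 0, MDV = 0, BLQ = obs$blq)
      }
    }

    # PRL: one continuous simulation across occasions
    if (!is.null(prl)) {
      p_i <- prl
      eta_p <- setNames(rnorm(3, 0, sqrt(prl$omega2[c("ks", "amp24",
                                                      "amp12")])),
                        c("ks", "amp24", "amp12"))
      p_i$ks <- prl$ks * exp(eta_p["ks"])
      p_i$amp24 <- prl$amp24 * exp(eta_p["amp24"])
      p_i$amp12 <- prl$amp12 * exp(eta_p["amp12"])
      tr$prl_eta <- eta_p
      pred <- prl_concentration(p_i, all_obs_t, drug = drug)
      eps <- rnorm(length(all_obs_t), 0, sqrt(prl$sigma2))
      occ_of <- rep(d$occasions$occ, vapply(d$sampling, length, 1L))
      tad_of <- all_obs_t - rep(d$occasions$dose_time,
                                vapply(d$sampling, length, 1L))
      rows[[length(rows) + 1]] <- data.frame(
        ID = s$id, OCC = occ_of, TIME = all_obs_t, TAD = tad_of,
        DV = pred * (1 + eps), DVID = 3, AMT = 0, EVID = 0, MDV = 0,
        BLQ = 0)
    }
    truth[[s$id]] <- tr
  }

  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$ID, tab$TIME, -tab$EVID, tab$DVID), ]
  rownames(tab) <- NULL
  meta <- data.frame(id = vapply(subj, `[[`, 1, "id"),
                     cohort = vapply(subj, `[[`, "", "cohort"),
                     active = vapply(subj, `[[`, TRUE, "active"))
  meta <- merge(meta, cov_tab, by = "id")
  structure(tab, subjects = meta, pk_curves = pk_curves, truth = truth,
            class = c("event_table", "data.frame"))
}
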