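# Population models for the FOCE engine and the user-facing fit surface.
#
# GH: pulse locations come from the deconvolution (or the generator); the
# population model estimates baseline, shared secretion width, typical pulse
# mass and elimination rate on placebo data, with log-normal IIV on
# baseline/width/k_el, between-occasion variability on width/k_el, and a
# per-pulse log-normal amplitude deviation; the drug stage adds an
# effect-compartment Emax inhibition of pulse mass. PRL: pool model with
# two-cosine circadian release, direct Emax inhibition of release and a
# cumulative-exposure synthesis decline, with IIV on ks and both cosine
# amplitudes.

.gh_theta_spec <- data.frame(
  name = c("baseline", "width", "amplitude", "kel", "ke0", "iemax", "ec50"),
  transform = c("log", "log", "log", "log", "log", "logit01", "log"),
  stringsAsFactors = FALSE
)

.prl_theta_spec <- data.frame(
  name = c("kr", "kel", "ks", "amp24", "phase24", "amp12", "phase12",
           "iemax", "ec50", "slope"),
  transform = c("log", "log", "log", "log", "identity", "log", "identity",
                "logit01", "log", "log"),
  stringsAsFactors = FALSE
)

.drug_curve_for <- function(tab, id, pk_curves) {
  if (!is.null(pk_curves) && length(pk_curves) >= id &&
      !is.null(pk_curves[[id]])) {
    return(pk_curves[[id]])
  }
  dr <- tab[tab$ID == id & tab$EVID == 0 & tab$DVID == 1, ]
  if (!nrow(dr)) return(NULL)
  doses <- tab[tab$ID == id & tab$EVID == 1, ]
  list(times = dr$TIME, cp = dr$DV,
       first_dose_time = if (nrow(doses)) min(doses$TIME) else dr$TIME[1])
}

.subject_group <- function(tab, id) {
  meta <- attr(tab, "subjects")
  if (!is.null(meta) && id %in% meta$id) {
    meta$cohort[match(id, meta$id)]
  } else if (any(tab$ID == id & tab$EVID == 1)) "active" else "placebo"
}

# ---------------------------------------------------------------------------
# GH model builder

.build_gh_model <- function(tab, pulses, pk_curves = attr(tab, "pk_curves"),
                            subset = c("all", "placebo")) {
  subset <- match.arg(subset)
  stopifnot(!is.null(pulses))
  names(pulses) <- toupper(names(pulses))
  obs_all <- tab[tab$EVID == 0 & tab$DVID == 2, ]
  ids <- unique(obs_all$ID)
  if (subset == "placebo") {
    ids <- ids[!vapply(ids, function(id) any(tab$ID == id & tab$EVID == 1),
                       TRUE)]
  }
  subjects <- list()
  for (id in ids) {
    obs <- obs_all[obs_all$ID == id, ]
    drug <- .drug_curve_for(tab, id, pk_curves)
    occs <- sort(unique(obs$OCC))
    occ_rows <- lapply(occs, function(o) which(obs$OCC == o))
    occ_times <- lapply(occ_rows, function(r) obs$TIME[r])
    occ_loc <- lapply(occs, function(o) {
      pl <- pulses[pulses$ID == id & pulses$OCC == o, ]
      sort(pl$PULSE_TIME_H)
    })
    subjects[[length(subjects) + 1]] <- .gh_subject(
      id = id, obs = obs, drug = drug, occ_times = occ_times,
      occ_loc = occ_loc, group = .subject_group(tab, id))
  }
  if (!length(subjects)) stop("no GH observations for the requested subset")
  foce_model(subjects, .gh_theta_spec, name = "gh")
}

# Per-subject constructor: gives every closure its own environment (a plain
# loop would leave all subjects sharing the last iteration's layout).
.gh_subject <- function(id, obs, drug, occ_times, occ_loc, group) {
  force(obs); force(drug); force(occ_times); force(occ_loc)
  n_occ <- length(occ_times)
  npulse <- vapply(occ_loc, length, 1L)
  eta_names <- c("baseline", "width", "kel",
                 rep(c("bov_width", "bov_kel"), n_occ),
                 rep("amplitude", sum(npulse)))
  # index helpers into the eta vector
  i_bov <- matrix(3 + seq_len(2 * n_occ), nrow = 2)
  i_amp <- split(3 + 2 * n_occ + seq_len(sum(npulse)),
                 factor(rep(seq_len(n_occ), npulse),
                        levels = seq_len(n_occ)))
  ce_cache <- new.env()
  ce_at_pulses <- function(ke0) {
    key <- format(ke0, digits = 15)
    if (is.null(ce_cache[[key]])) {
      ce <- effect_compartment(drug$times, drug$cp, ke0)
      ce_cache[[key]] <- lapply(occ_loc, function(l)
        if (length(l)) approx(drug$times, ce, xout = l, rule = 2)$y else
          numeric(0))
      # keep the cache small: ke0 changes only across outer iterations
      if (length(ls(ce_cache)) > 4) {
        rm(list = setdiff(ls(ce_cache), key), envir = ce_cache)
      }
    }
    ce_cache[[key]]
  }
  core <- function(theta, eta) {
    base <- theta$baseline * exp(eta[1])
    fac <- if (!is.null(drug)) {
      ce_l <- ce_at_pulses(theta$ke0)
      lapply(ce_l, function(ce)
        emax_factor(ce, -theta$iemax, theta$ec50))
    } else lapply(occ_loc, function(l) rep(1, length(l)))
    pieces <- vector("list", n_occ)
    for (o in seq_len(n_occ)) {
      w_o <- theta$width * exp(eta[2] + eta[i_bov[1, o]])
      k_o <- theta$kel * exp(eta[3] + eta[i_bov[2, o]])
      B <- .gh_basis(occ_times[[o]], occ_loc[[o]], w_o, k_o)
      m <- theta$amplitude * exp(eta[i_amp[[o]]]) * fac[[o]]
      pieces[[o]] <- list(B = B, m = m, base = base,
                          f = base + as.vector(B %*% m))
    }
    pieces
  }
  predict_fn <- function(theta, eta) {
    unlist(lapply(core(theta, eta), `[[`, "f"))
  }
  jac_fn <- function(theta, eta, f) {
    pieces <- core(theta, eta)
    J <- matrix(0, length(f), length(eta))
    row_off <- 0
    for (o in seq_len(n_occ)) {
      rows <- row_off + seq_along(occ_times[[o]])
      pc <- pieces[[o]]
      J[rows, 1] <- pc$base
      if (length(pc$m)) {
        J[rows, i_amp[[o]]] <- pc$B * rep(pc$m, each = length(rows))
      }
      row_off <- row_off + length(rows)
    }
    # width/kel (shared + per-occasion BOV) by forward differences
    h <- 1e-4
    for (col in c(2, 3, as.vector(i_bov))) {
      e2 <- eta
      e2[col] <- e2[col] + h
      J[, col] <- (predict_fn(theta, e2) - f) / h
    }
    J
  }
  list(id = id, y = obs$DV,
       meta = obs[, c("ID", "OCC", "TIME", "TAD", "BLQ")],
       predict = predict_fn, jac = jac_fn, eta_names = eta_names,
       group = group, treated = !is.null(drug))
}

# ---------------------------------------------------------------------------
# PRL model builder

.build_prl_model <- function(tab, pk_curves = attr(tab, "pk_curves"),
                             dt = 0.1, run_in = 24) {
  obs_all <- tab[tab$EVID == 0 & tab$DVID == 3, ]
  if (!nrow(obs_all)) stop("no PRL observations in the event table")
  ids <- unique(obs_all$ID)
  subjects <- list()
  for (id in ids) {
    obs <- obs_all[obs_all$ID == id, ]
    drug <- .drug_curve_for(tab, id, pk_curves)
    t0 <- min(obs$TIME[1], if (!is.null(drug)) drug$times[1] else Inf) -
      run_in
    tn <- max(obs$TIME)
    grid <- seq(t0, tn + dt, by = dt)  # uniform; overshoots tn by < dt
    if (is.null(drug)) {
      cp <- ex <- rep(0, length(grid))
    } else {
      cp <- approx(drug$times, pmax(drug$cp, 0), xout = grid, rule = 2)$y
      cp[grid < drug$times[1]] <- 0
      fd <- if (!is.null(drug$first_dose_time)) drug$first_dose_time else
        drug$times[1]
      ex <- cumulative_exposure(grid, cp, first_dose_time = fd)
    }
    init_grid <- seq(t0 - 24, t0, by = dt)
    subjects[[length(subjects) + 1]] <- .prl_subject(
      id = id, obs = obs, grid = grid, cp = cp, ex = ex,
      init_grid = init_grid, group = .subject_group(tab, id),
      treated = !is.null(drug))
  }
  foce_model(subjects, .prl_theta_spec, name = "prl")
}

.prl_subject <- function(id, obs, grid, cp, ex, init_grid, group, treated) {
  # force every promise now: these arguments are loop variables in the
  # builder and would otherwise be resolved after the loop has moved on
  force(grid); force(cp); force(ex); force(init_grid)
  h <- grid[2] - grid[1]
  # step-midpoint values of everything that does not move with the
  # optimiser: times, drug concentration, cumulative exposure
  tm <- head(grid, -1) + h / 2
  cpm <- (head(cp, -1) + tail(cp, -1)) / 2
  exm <- (head(ex, -1) + tail(ex, -1)) / 2
  tm_init <- head(init_grid, -1) + h / 2
  n_init <- length(tm_init)
  # linear-interpolation stencil of the observation times on the grid
  i0 <- pmin(pmax(findInterval(obs$TIME, grid), 1), length(grid) - 1)
  wt <- (obs$TIME - grid[i0]) / h
  # caches keyed on the outer parameters they depend on (the inner
  # optimiser only moves ks and the two cosine amplitudes)
  cache <- new.env()
  memo <- function(key, val_fn) {
    if (is.null(cache[[key]])) {
      cache[[key]] <- val_fn()
      nm <- ls(cache)
      if (length(nm) > 12) rm(list = setdiff(nm, key), envir = cache)
    }
    cache[[key]]
  }
  predict_fn <- function(theta, eta) {
    kr <- theta$kr
    kel <- theta$kel
    ks <- theta$ks * exp(eta[1])
    a24 <- theta$amp24 * exp(eta[2])
    a12 <- theta$amp12 * exp(eta[3])
    cw <- memo(paste("cos", theta$phase24, theta$phase12), function() {
      list(c24 = cos(2 * pi * (tm - theta$phase24) / 24),
           c12 = cos(2 * pi * (tm - theta$phase12) / 12),
           c24i = cos(2 * pi * (tm_init - theta$phase24) / 24),
           c12i = cos(2 * pi * (tm_init - theta$phase12) / 12))
    })
    fac <- if (treated) {
      memo(paste("fac", theta$iemax, theta$ec50), function()
        pmax(1 - theta$iemax * cpm / (theta$ec50 + cpm), 1e-12))
    } else 1
    inh <- if (treated) {
      memo(paste("inh", theta$slope), function()
        theta$slope * exm / (1 + theta$slope * exm))
    } else 0
    ek <- exp(-kel * h)
    kfac <- (1 - ek) / kel
    run <- function(b, a, P0, C0) {
      eb <- exp(-b * h)
      prl_recur_cpp(eb, (a / b) * (1 - eb), b, ek, kfac, P0, C0)
    }
    # drug-free periodic initial state from the affine one-period map:
    # column responses are analytic for P (prod eb) and ek^n for C
    b_i <- pmax(kr * (1 + a24 * cw$c24i + a12 * cw$c12i), 1e-12)
    cc <- run(b_i, rep(ks, n_init), 0, 0)
    ccn <- cc[n_init + 1, ]
    hom <- run(b_i, rep(0, n_init), 1, 0)
    A <- cbind(hom[n_init + 1, ], c(0, ek^n_init))
    x0 <- tryCatch(as.vector(solve(diag(2) - A, ccn)),
                   error = function(e) c(ks / kr, ks / kel))
    b <- pmax(kr * (1 + a24 * cw$c24 + a12 * cw$c12) * fac, 1e-12)
    sol <- run(b, ks * (1 - inh), x0[1], x0[2])
    conc <- sol[, 2]
    conc[i0] * (1 - wt) + conc[i0 + 1] * wt
  }
  jac_fn <- function(theta, eta, f) {
    # the solution is exactly proportional to ks (source and initial state
    # both scale), so the ks column is the prediction itself; the cosine
    # amplitude columns are finite differences
    hfd <- 1e-4
    J <- matrix(0, length(f), 3)
    J[, 1] <- f
    for (k in 2:3) {
      e2 <- eta
      e2[k] <- e2[k] + hfd
      J[, k] <- (predict_fn(theta, e2) - f) / hfd
    }
    J
  }
  list(id = id, y = obs$DV,
       meta = obs[, c("ID", "OCC", "TIME", "TAD", "BLQ")],
       predict = predict_fn, jac = jac_fn,
       eta_names = c("ks", "amp24", "amp12"),
       group = group, treated = treated)
}

# ---------------------------------------------------------------------------
# default starting values (deliberately away from the published estimates)

.gh_start <- function() {
  list(theta = list(baseline = 0.1, width = 0.25, amplitude = 1.0,
                    kel = log(2) / 0.25, ke0 = 1.0, iemax = 0.5,
                    ec50 = 1.0),
       omega2 = c(baseline = 0.1, width = 0.1, kel = 0.1, amplitude = 2.0,
                  bov_width = 0.05, bov_kel = 0.05),
       sigma2 = 0.05)
}

.prl_start <- function() {
  list(theta = list(kr = 0.02, kel = 1.0, ks = 10, amp24 = 0.1,
                    phase24 = 15, amp12 = 0.05, phase12 = 8, iemax = 0.7,
                    ec50 = 1.0, slope = 1.0),
       omega2 = c(ks = 0.1, amp24 = 0.3, amp12 = 0.3),
       sigma2 = 0.05)
}

.drug_param_names <- c("theta.ke0", "theta.iemax", "theta.ec50")

#' Fit a population hormone model
#'
#' Maximum-likelihood (FOCE-style) estimation of the GH or PRL population
#' model from an event table. For GH with treated subjects the published
#' sequential protocol is followed: the system parameters and all variance
#' components are first estimated on placebo subjects only, then fixed, and
#' the drug-effect parameters (ke0, Emax, EC50) are estimated on the full
#' dataset. Observations below the GH LLOQ enter as ordinary data at
#' 0.05 ng/mL, as in the source analysis.
#'
#' @param data an `event_table` (see [simulate_trial()],
#'   [read_event_table()]).
#' @param model `"gh"` or `"prl"`.
#' @param pulses for GH: data.frame ID, OCC, PULSE_TIME_H (from
#'   [deconvolve_trial()] or the generator); ignored for PRL.
#' @param start parameter list (`theta`, `omega2`, `sigma2`); defaults are
#'   neutral values away from any published estimate.
#' @param stage `"auto"` (two-stage when treated subjects are present),
#'   `"placebo"` (placebo subjects only) or `"single"` (everything in one
#'   stage).
#' @param fix extra packed-parameter names to hold fixed.
#' @param control passed to [fit_foce()].
#' @param pk unused placeholder for a PK configuration when drug
#'   concentrations must be reconstructed rather than read from the table.
#' @return object of class `pkpd_fit`.
#' @export
pkpd_fit <- function(data, model = c("gh", "prl"), pulses = NULL,
                     start = NULL, stage = c("auto", "placebo", "single"),
                     fix = character(0), control = list(), pk = NULL) {
  model <- match.arg(model)
  stage <- match.arg(stage)
  fix_all <- identical(fix, "all")
  if (fix_all) stage <- "single"
  expand_fix <- function(m, st) {
    if (fix_all) names(.pack(st, m, character(0))) else fix
  }
  stages <- list()
  if (model == "gh") {
    if (is.null(start)) start <- .gh_start()
    any_treated <- any(data$EVID == 1)
    if (stage == "placebo" || (stage == "auto" && !any_treated)) {
      m <- .build_gh_model(data, pulses, subset = "placebo")
      fit <- fit_foce(m, start, fix = union(fix, .drug_param_names),
                      control = control)
      stages$placebo <- fit
    } else if (stage == "single") {
      m <- .build_gh_model(data, pulses, subset = "all")
      fit <- fit_foce(m, start, fix = expand_fix(m, start),
                      control = control)
    } else {
      m1 <- .build_gh_model(data, pulses, subset = "placebo")
      f1 <- fit_foce(m1, start, fix = union(fix, .drug_param_names),
                     control = control)
      stages$placebo <- f1
      m2 <- .build_gh_model(data, pulses, subset = "all")
      fixed2 <- setdiff(names(.pack(f1$params, m2, character(0))),
                        .drug_param_names)
      fit <- fit_foce(m2, f1$params, fix = union(fix, fixed2),
                      control = control)
      stages$full <- fit
    }
  } else {
    if (is.null(start)) start <- .prl_start()
    m <- .build_prl_model(data)
    fit <- fit_foce(m, start, fix = expand_fix(m, start), control = control)
  }
  structure(list(fit = fit, hormone = model, stages = stages,
                 data = data, pulses = pulses),
            class = "pkpd_fit")
}

# Natural-scale named estimates with the sign convention restored.
.flat_estimates <- function(params) {
  th <- unlist(params$theta)
  if ("iemax" %in% names(th)) {
    th <- c(th[setdiff(names(th), "iemax")], emax = -th[["iemax"]])
  }
  c(th, setNames(params$omega2, paste0("omega2.", names(params$omega2))),
    sigma2 = params$sigma2)
}

#' @export
coef.pkpd_fit <- function(object, ...) .flat_estimates(object$fit$params)

#' @export
logLik.pkpd_fit <- function(object, ...) {
  val <- -object$fit$ofv / 2
  attr(val, "df") <- length(.pack(object$fit$params, object$fit$model,
                                  object$fit$fix))
  class(val) <- "logLik"
  val
}

#' @export
print.pkpd_fit <- function(x, ...) {
  cat(sprintf("Population %s model fit (FOCE)\n", toupper(x$hormone)))
  cat(sprintf("  subjects: %d   OFV: %.3f   %s\n",
              length(x$fit$model$subjects), x$fit$ofv,
              if (x$fit$convergence == 0) "converged" else
                "NOT converged"))
  est <- .flat_estimates(x$fit$params)
  print(round(est, 4))
  invisible(x)
}

#' @export
summary.pkpd_fit <- function(object, covariance = FALSE, ...) {
  est <- .flat_estimates(object$fit$params)
  out <- list(hormone = object$hormone, estimates = est,
              ofv = object$fit$ofv,
              convergence = object$fit$convergence,
              n_subjects = length(object$fit$model$subjects),
              n_obs = sum(vapply(object$fit$model$subjects,
                                 function(s) length(s$y), 1L)),
              shrinkage = tryCatch(shrinkage(object),
                                   error = function(e) NULL),
              covariance = if (covariance)
                covariance_step(object) else NULL)
  class(out) <- "summary.pkpd_fit"
  out
}

#' @export
print.summary.pkpd_fit <- function(x, ...) {
  cat(sprintf("Population %s model (FOCE): %d subjects, %d observations\n",
              toupper(x$hormone), x$n_subjects, x$n_obs))
  cat(sprintf("  OFV %.3f (%s)\n", x$ofv,
              if (x$convergence == 0) "converged" else "not converged"))
  print(round(x$estimates, 4))
  if (!is.null(x$shrinkage)) {
    cat("eta-shrinkage (%):\n")
    print(round(x$shrinkage, 1))
  }
  if (!is.null(x$covariance) && x$covariance$status == "ok") {
    cat("RSE (%):\n")
    print(round(x$covariance$rse_pct, 1))
    cat(sprintf("condition number: %.1f\n",
                x$covariance$condition_number))
  }
  invisible(x)
}

#' @export
predict.pkpd_fit <- function(object,
                             type = c("individual", "population"), ...) {
  type <- match.arg(type)
  fit <- object$fit
  out <- list()
  for (i in seq_along(fit$model$subjects)) {
    s <- fit$model$subjects[[i]]
    eta <- if (type == "individual") fit$eta[[i]] else
      numeric(length(s$eta_names))
    out[[i]] <- cbind(s$meta,
                      PRED = s$predict(fit$params$theta, eta))
  }
  res <- do.call(rbind, out)
  names(res)[names(res) == "PRED"] <- if (type == "individual") "IPRED" else
    "PRED"
  res
}

#' @export
residuals.pkpd_fit <- function(object, type = c("cwresi", "iwres"), ...) {
  type <- match.arg(type)
  if (type == "cwresi") return(cwresi(object)$CWRESI)
  fit <- object$fit
  unlist(lapply(seq_along(fit$model$subjects), function(i) {
    s <- fit$model$subjects[[i]]
    f <- fit$detail[[i]]$f
    (s$y - f) / (sqrt(fit$params$sigma2) * pmax(f, PRED_FLOOR))
  }))
}

#' Simulate observation vectors from a fitted population model
#'
#' Draws new random effects and residual errors per subject under the
#' fitted (or supplied) population parameters, at the original observation
#' times. GH values are LLOQ-substituted like real data.
#'
#' @param object a `pkpd_fit`.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list (per subject) of `n_obs x nsim` matrices.
#' @export
simulate.pkpd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fit <- object$fit
  p <- fit$params
  lloq <- if (object$hormone == "gh") LLOQ_GH else NULL
  lapply(fit$model$subjects, function(s) {
    n <- length(s$y)
    om <- p$omega2[s$eta_names]
    out <- matrix(NA_real_, n, nsim)
    for (r in seq_len(nsim)) {
      eta <- rnorm(length(om), 0, sqrt(pmax(om, 0)))
      f <- s$predict(p$theta, eta)
      y <- f * (1 + rnorm(n, 0, sqrt(p$sigma2)))
      if (!is.null(lloq)) y <- lloq_substitute(y, lloq)$value
      out[, r] <- y
    }
    out
  })
}

#' @export
plot.pkpd_fit <- function(x, ...) {
  pr <- predict(x, type = "individual")
  y <- unlist(lapply(x$fit$model$subjects, `[[`, "y"))
  plot(pr$IPRED, y, pch = 16, cex = 0.5,
       xlab = "individual prediction", ylab = "observation", ...)
  abline(0, 1)
  invisible(x)
}

#' Reduce a fit to its serialisable summary
#'
#' Drops closures and per-subject internals so the result can be written to
#' disk by the pipeline.
#' @param fit a `pkpd_fit`.
#' @return list with estimates, OFV, convergence and counts.
#' @export
strip_fit <- function(fit) {
  f <- if (inherits(fit, "pkpd_fit")) fit$fit else fit
  list(estimates = .flat_estimates(f$params), ofv = f$ofv,
       convergence = f$convergence, counts = f$counts,
       hormone = if (inherits(fit, "pkpd_fit")) fit$hormone else NA)
}
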