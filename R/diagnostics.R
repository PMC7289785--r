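# Model-evaluation statistics: conditional weighted residuals with
# interaction (CWRESI), normalized prediction distribution errors (NPDE),
# prediction-corrected visual predictive check (pcVPC), eta-shrinkage and
# covariate screening.

#' Conditional weighted residuals with interaction
#'
#' FOCE-I residuals: per subject the model is linearised at the empirical
#' Bayes mode, the marginal mean and covariance of the linearised model are
#' formed (residual variance evaluated at the individual prediction — the
#' interaction), and the residual vector is whitened by the Cholesky factor
#' of that covariance. Under the true model CWRESI is approximately
#' standard normal.
#'
#' @param fit a `pkpd_fit` or `foce_fit`.
#' @return data.frame: ID, OCC, TIME, TAD, PRED (population prediction),
#'   IPRED (individual prediction), CWRESI.
#' @export
cwresi <- function(fit) {
  pf <- if (inherits(fit, "pkpd_fit")) fit$fit else fit
  stopifnot(inherits(pf, "foce_fit"))
  out <- list()
  for (i in seq_along(pf$model$subjects)) {
    s <- pf$model$subjects[[i]]
    d <- pf$detail[[i]]
    if (any(!is.finite(d$chol)) || any(diag(as.matrix(d$chol)) <= 0)) {
      stop("cwresi: singular conditional covariance for subject ", s$id)
    }
    cw <- backsolve(d$chol, d$e, transpose = TRUE)
    pred <- s$predict(pf$params$theta, numeric(length(s$eta_names)))
    meta <- if (!is.null(s$meta)) s$meta else
      data.frame(ID = s$id, OCC = NA, TIME = seq_along(s$y), TAD = NA,
                 BLQ = 0)
    out[[i]] <- cbind(meta[c("ID", "OCC", "TIME", "TAD")],
                      PRED = pred, IPRED = d$f, CWRESI = as.numeric(cw))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalized prediction distribution errors
#'
#' Monte-Carlo NPDE: each subject is simulated `n_sim` times under the
#' fitted population model; observations and simulations are decorrelated
#' per subject with the empirical mean and covariance of the simulations;
#' the rank of each decorrelated observation among its decorrelated
#' simulations is mapped through the inverse normal (mid-rank, clamped to
#' \[1/(2 n_sim), 1 - 1/(2 n_sim)\]). Under the true model NPDE is standard
#' normal. Summaries are stratified by treatment day (occasion).
#'
#' @param fit a `pkpd_fit`.
#' @param n_sim number of simulated replicates (>= 100).
#' @param seed RNG seed.
#' @return list of class `npde_result`: `table` (per-observation npde with
#'   ID/OCC/TIME), `by_day` (per-occasion mean, variance, Shapiro-Wilk p).
#' @export
npde <- function(fit, n_sim = 1000, seed = 1) {
  stopifnot(inherits(fit, "pkpd_fit"))
  if (n_sim < 100) stop("npde: n_sim must be >= 100")
  sims <- simulate(fit, nsim = n_sim, seed = seed)
  pf <- fit$fit
  out <- list()
  for (i in seq_along(pf$model$subjects)) {
    s <- pf$model$subjects[[i]]
    S <- sims[[i]]
    m <- rowMeans(S)
    V <- cov(t(S))
    ch <- tryCatch(chol(V), error = function(e)
      chol(V + diag(1e-8 * max(diag(V)), nrow(V))))
    ystar <- backsolve(ch, s$y - m, transpose = TRUE)
    sstar <- backsolve(ch, S - m, transpose = TRUE)
    u <- (rowSums(sstar < ystar) + 0.5 * rowSums(sstar == ystar)) / n_sim
    u <- pmin(pmax(u, 1 / (2 * n_sim)), 1 - 1 / (2 * n_sim))
    if (all(u == u[1]) && length(u) > 3 && var(s$y) == 0) {
      stop("npde: degenerate model (all ranks tied)")
    }
    meta <- s$meta
    out[[i]] <- cbind(meta[c("ID", "OCC", "TIME")],
                      NPDE = qnorm(u))
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  by_day <- do.call(rbind, lapply(split(tab, tab$OCC), function(d) {
    sw <- if (length(unique(d$NPDE)) > 3 && nrow(d) >= 4 &&
              nrow(d) <= 5000) {
      shapiro.test(d$NPDE)$p.value
    } else NA_real_
    data.frame(OCC = d$OCC[1], n = nrow(d), mean = mean(d$NPDE),
               variance = var(d$NPDE), shapiro_p = sw)
  }))
  rownames(by_day) <- NULL
  structure(list(table = tab, by_day = by_day, n_sim = n_sim),
            class = "npde_result")
}

#' @export
print.npde_result <- function(x, ...) {
  cat("NPDE (", x$n_sim, "simulations ), by treatment day:\n")
  print(x$by_day, digits = 3)
  invisible(x)
}

#' Prediction-corrected visual predictive check
#'
#' Observations and simulations are multiplied by (bin median population
#' prediction)/(own population prediction) within clock-time bins, and the
#' observed 5/50/95th percentiles per bin are compared with the Monte-Carlo
#' 95% bands of the same percentiles across simulated datasets. Pulsatile
#' GH cannot be summarised this way (the timing of pulses differs between
#' individuals), so GH requests are refused.
#'
#' @param fit a `pkpd_fit` for the PRL model.
#' @param bins number of equal-count clock-time bins (or explicit break
#'   vector on \[0, 24\]).
#' @param n_sim number of simulated datasets.
#' @param seed RNG seed.
#' @return list of class `vpc_result`: per-bin data.frame with bin centre,
#'   n, observed percentiles (`obs_p5`, `obs_p50`, `obs_p95`) and simulated
#'   band limits (`lo_p*`, `hi_p*`), plus a per-bin coverage flag.
#' @export
pcvpc <- function(fit, bins = 12, n_sim = 200, seed = 1) {
  stopifnot(inherits(fit, "pkpd_fit"))
  if (fit$hormone == "gh") {
    stop("pcVPC unsupported for pulsatile GH: the timing of secretion ",
         "pulses differs between individuals")
  }
  pf <- fit$fit
  y <- unlist(lapply(pf$model$subjects, `[[`, "y"))
  pred <- unlist(lapply(seq_along(pf$model$subjects), function(i) {
    s <- pf$model$subjects[[i]]
    s$predict(pf$params$theta, numeric(length(s$eta_names)))
  }))
  clock <- unlist(lapply(pf$model$subjects,
                         function(s) s$meta$TIME %% 24))
  if (length(bins) == 1) {
    qs <- quantile(clock, probs = seq(0, 1, length.out = bins + 1))
    qs[1] <- qs[1] - 1e-9
    brk <- unique(qs)
  } else brk <- bins
  bin <- cut(clock, brk, include.lowest = TRUE)
  keep <- !is.na(bin)
  if (any(!keep)) warning("pcvpc: ", sum(!keep),
                          " observation(s) outside the bins were dropped")
  med_pred <- tapply(pred[keep], bin[keep], median)
  pc <- function(v) {
    out <- v[keep] * med_pred[as.integer(bin[keep])] / pred[keep]
    split(out, bin[keep])
  }
  probs <- c(0.05, 0.5, 0.95)
  perc <- function(groups) t(vapply(groups, quantile, numeric(3),
                                    probs = probs, names = FALSE))
  obs_p <- perc(pc(y))
  sims <- simulate(fit, nsim = n_sim, seed = seed)
  sim_p <- array(NA_real_, c(nlevels(bin), 3, n_sim))
  for (r in seq_len(n_sim)) {
    ys <- unlist(lapply(sims, function(S) S[, r]))
    sim_p[, , r] <- perc(pc(ys))
  }
  lo <- apply(sim_p, c(1, 2), quantile, 0.025)
  hi <- apply(sim_p, c(1, 2), quantile, 0.975)
  centre <- vapply(split(clock[keep], bin[keep]), median, 0)
  n_bin <- as.integer(table(bin[keep]))
  res <- data.frame(bin = levels(bin), centre = centre, n = n_bin,
                    obs_p5 = obs_p[, 1], obs_p50 = obs_p[, 2],
                    obs_p95 = obs_p[, 3],
                    lo_p5 = lo[, 1], hi_p5 = hi[, 1],
                    lo_p50 = lo[, 2], hi_p50 = hi[, 2],
                    lo_p95 = lo[, 3], hi_p95 = hi[, 3])
  empty <- res$n == 0
  if (any(empty)) {
    warning("pcvpc: dropping ", sum(empty), " empty bin(s)")
    res <- res[!empty, ]
  }
  cov_mat <- cbind(res$obs_p5 >= res$lo_p5 & res$obs_p5 <= res$hi_p5,
                   res$obs_p50 >= res$lo_p50 & res$obs_p50 <= res$hi_p50,
                   res$obs_p95 >= res$lo_p95 & res$obs_p95 <= res$hi_p95)
  # coverage is scored per (bin, percentile) pair: each simulated band is a
  # 95% interval for one percentile, so the pairwise coverage is the
  # calibrated quantity
  res$covered <- rowMeans(cov_mat) == 1
  rownames(res) <- NULL
  structure(list(table = res, n_sim = n_sim,
                 coverage = mean(cov_mat)), class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat("pcVPC over clock time (", x$n_sim, "simulations ):\n")
  print(x$table[, c("bin", "n", "obs_p5", "obs_p50", "obs_p95", "covered")],
        digits = 3)
  cat(sprintf("bin x percentile coverage: %.1f%%\n", 100 * x$coverage))
  invisible(x)
}

#' @export
plot.vpc_result <- function(x, ...) {
  tb <- x$table
  plot(tb$centre, tb$obs_p50, type = "b", pch = 16,
       ylim = range(tb[, c("obs_p5", "obs_p95", "lo_p5", "hi_p95")]),
       xlab = "clock time (h after 6 a.m.)",
       ylab = "prediction-corrected concentration", ...)
  lines(tb$centre, tb$obs_p5, lty = 2)
  lines(tb$centre, tb$obs_p95, lty = 2)
  for (p in c("p5", "p50", "p95")) {
    lines(tb$centre, tb[[paste0("lo_", p)]],
          col = adjustcolor("steelblue", 0.7))
    lines(tb$centre, tb[[paste0("hi_", p)]],
          col = adjustcolor("steelblue", 0.7))
  }
  invisible(x)
}

#' Eta-shrinkage
#'
#' `100 * (1 - SD(EBE)/omega)` per random-effect component; empirical Bayes
#' estimates collapse toward zero (shrink) when individual data are
#' uninformative. Components with zero population variance are reported as
#' `NA`.
#'
#' @param fit a `pkpd_fit` or `foce_fit`.
#' @return named numeric vector of shrinkage percentages.
#' @export
shrinkage <- function(fit) {
  pf <- if (inherits(fit, "pkpd_fit")) fit$fit else fit
  stopifnot(inherits(pf, "foce_fit"))
  if (length(pf$model$subjects) < 2) stop("shrinkage: need >= 2 subjects")
  comp <- names(pf$params$omega2)
  ebes <- lapply(comp, function(cn) {
    unlist(lapply(seq_along(pf$model$subjects), function(i) {
      s <- pf$model$subjects[[i]]
      pf$eta[[i]][s$eta_names == cn]
    }))
  })
  names(ebes) <- comp
  vapply(comp, function(cn) {
    om <- pf$params$omega2[[cn]]
    if (om <= 0 || length(ebes[[cn]]) < 2) return(NA_real_)
    100 * (1 - sd(ebes[[cn]]) / sqrt(om))
  }, 0)
}

#' Screen covariates against empirical Bayes estimates
#'
#' Regresses each subject-level EBE on each mean-centred covariate; a
#' covariate is flagged as a candidate when r^2 exceeds the threshold.
#' When a `refit_fn` is supplied, flagged candidates are taken through
#' forward inclusion (p < `forward_alpha`) and backward deletion
#' (p < `backward_alpha`) by repeated refits and likelihood-ratio tests;
#' with no flagged candidates the stepping result is empty.
#'
#' @param fit a `pkpd_fit`.
#' @param covariates data.frame with a subject `id` column and one column
#'   per covariate.
#' @param r2_threshold candidate threshold on r^2.
#' @param refit_fn optional `function(covariate_name, eta_name) -> foce_fit`
#'   fitting the model extended with that covariate relation.
#' @param forward_alpha,backward_alpha stepping significance levels.
#' @return list of class `covariate_screen`: `r2` (long data.frame eta x
#'   covariate with r2 and flag), `candidates`, `selected`.
#' @export
covariate_screen <- function(fit, covariates, r2_threshold = 0.5,
                             refit_fn = NULL, forward_alpha = 0.05,
                             backward_alpha = 0.01) {
  pf <- if (inherits(fit, "pkpd_fit")) fit$fit else fit
  stopifnot(inherits(pf, "foce_fit"), "id" %in% names(covariates))
  subj_ids <- vapply(pf$model$subjects, function(s)
    if (!is.null(s$id)) s$id else NA_integer_, 1)
  cov_use <- covariates[match(subj_ids, covariates$id), , drop = FALSE]
  comp <- names(pf$params$omega2)
  # subject-level components only: exactly one eta per subject
  subj_level <- vapply(comp, function(cn) {
    all(vapply(pf$model$subjects, function(s)
      sum(s$eta_names == cn) == 1, TRUE))
  }, TRUE)
  rows <- list()
  for (cn in comp[subj_level & pf$params$omega2 > 0]) {
    ebe <- vapply(seq_along(pf$model$subjects), function(i) {
      s <- pf$model$subjects[[i]]
      pf$eta[[i]][s$eta_names == cn]
    }, 0)
    for (cv in setdiff(names(cov_use), "id")) {
      x <- cov_use[[cv]]
      if (length(unique(x)) < 2) {
        warning("covariate_screen: constant covariate '", cv,
                "' skipped")
        next
      }
      xc <- x - mean(x)
      r2 <- summary(lm(ebe ~ xc))$r.squared
      rows[[length(rows) + 1]] <- data.frame(
        eta = cn, covariate = cv, r2 = r2,
        candidate = r2 > r2_threshold)
    }
  }
  r2tab <- do.call(rbind, rows)
  candidates <- r2tab[r2tab$candidate, c("eta", "covariate", "r2")]
  selected <- candidates[0, ]
  if (nrow(candidates) && !is.null(refit_fn)) {
    # forward inclusion
    included <- list()
    base_ofv <- pf$ofv
    repeat {
      best <- NULL
      for (k in seq_len(nrow(candidates))) {
        key <- paste(candidates$covariate[k], candidates$eta[k])
        if (key %in% names(included)) next
        f_try <- tryCatch(refit_fn(candidates$covariate[k],
                                   candidates$eta[k]),
                          error = function(e) NULL)
        if (is.null(f_try)) next
        cmp <- lrt(base_ofv, f_try$ofv, df = 1, alpha = forward_alpha)
        if (cmp$p < forward_alpha &&
            (is.null(best) || f_try$ofv < best$ofv)) {
          best <- list(k = k, ofv = f_try$ofv, key = key)
        }
      }
      if (is.null(best)) break
      included[[best$key]] <- candidates[best$k, ]
      base_ofv <- best$ofv
    }
    # backward deletion at the stricter level
    for (key in names(included)) {
      row <- included[[key]]
      f_wo <- tryCatch(refit_fn(row$covariate, row$eta),
                       error = function(e) NULL)
      if (!is.null(f_wo)) {
        cmp <- lrt(pf$ofv, f_wo$ofv, df = 1, alpha = backward_alpha)
        if (cmp$p >= backward_alpha) included[[key]] <- NULL
      }
    }
    if (length(included)) selected <- do.call(rbind, included)
  }
  structure(list(r2 = r2tab, candidates = candidates, selected = selected),
            class = "covariate_screen")
}

#' @export
print.covariate_screen <- function(x, ...) {
  if (is.null(x$r2) || !nrow(x$r2)) {
    cat("Covariate screen: nothing to screen\n")
    return(invisible(x))
  }
  cat("Covariate screen (r^2 of EBE regressions):\n")
  print(x$r2, digits = 3)
  if (nrow(x$selected)) {
    cat("selected after forward/backward stepping:\n")
    print(x$selected, digits = 3)
  } else {
    cat("no covariates selected\n")
  }
  invisible(x)
}
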