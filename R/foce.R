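# FOCE-style nonlinear mixed-effects engine.
#
# Marginal likelihood approximation: per subject, the random effects are
# optimised to the posterior mode (inner problem, Gauss-Newton with the
# interaction terms of a proportional residual model), the model is
# linearised there, and the subject contribution is the -2 log density of
# the matching multivariate normal:
#   V = J Omega J' + R(eta_hat),  e = y - f(eta_hat) + J eta_hat,
#   OFV_i = log|V| + e' V^{-1} e + n_i log(2*pi).
# This is the classical first-order-conditional objective with interaction;
# for a model linear in eta it is exact. The contract of the estimator is
# parameter recovery, not objective-value parity with any specific tool.

PRED_FLOOR <- 1e-10
SIGMA2_FLOOR <- 1e-6

#' Construct an NLME model for the FOCE engine
#'
#' A model is a set of subjects, each carrying its observation vector and a
#' prediction function of the fixed effects and its own random-effect
#' vector, plus the declaration of the fixed-effect transforms and of which
#' variance component each random-effect coordinate draws from.
#'
#' @param subjects list; each element a list with `y` (numeric
#'   observations), `predict(theta, eta)` returning the prediction vector,
#'   `eta_names` (character: for each eta coordinate, the name of its
#'   variance component in `omega2`), and optionally `group` (bootstrap
#'   stratification label) and `jac(theta, eta, f)` returning an analytic
#'   Jacobian d f / d eta (matrix) or `NULL` to request finite differences.
#' @param theta_spec data.frame with columns `name`, `transform`
#'   (`"log"`, `"logit01"`, `"identity"`).
#' @param name model label.
#' @return object of class `foce_model`.
#' @export
foce_model <- function(subjects, theta_spec, name = "custom") {
  stopifnot(is.list(subjects), length(subjects) >= 1,
            all(c("name", "transform") %in% names(theta_spec)))
  structure(list(subjects = subjects, theta_spec = theta_spec, name = name),
            class = "foce_model")
}

# --- transforms ------------------------------------------------------------

.tr_fwd <- function(x, tr) {
  switch(tr, log = log(x), logit01 = qlogis(x), identity = x)
}
.tr_inv <- function(z, tr) {
  switch(tr, log = exp(z), logit01 = plogis(z), identity = z)
}
.tr_deriv <- function(x, tr) {  # d natural / d transformed at natural x
  switch(tr, log = x, logit01 = x * (1 - x), identity = 1)
}

.pack <- function(params, model, fix) {
  tr <- setNames(model$theta_spec$transform, model$theta_spec$name)
  v <- c(
    setNames(mapply(.tr_fwd, params$theta, tr[names(params$theta)]),
             paste0("theta.", names(params$theta))),
    setNames(log(pmax(params$omega2, 1e-12)),
             paste0("omega2.", names(params$omega2))),
    setNames(log(max(params$sigma2, SIGMA2_FLOOR)), "sigma2")
  )
  v[setdiff(names(v), fix)]
}

.unpack <- function(x, params, model, fix) {
  tr <- setNames(model$theta_spec$transform, model$theta_spec$name)
  full <- .pack(params, model, character(0))
  full[names(x)] <- x
  th <- full[grep("^theta\\.", names(full))]
  names(th) <- sub("^theta\\.", "", names(th))
  theta <- setNames(mapply(.tr_inv, th, tr[names(th)]), names(th))
  om <- exp(full[grep("^omega2\\.", names(full))])
  names(om) <- sub("^omega2\\.", "", names(om))
  # variances pinned at (numerical) zero stay zero
  om[params$omega2 == 0] <- 0
  list(theta = as.list(theta), omega2 = om,
       sigma2 = max(exp(full[["sigma2"]]), SIGMA2_FLOOR))
}

# --- inner problem ---------------------------------------------------------

.fd_jac <- function(fn, eta, f0, h = 1e-4) {
  J <- matrix(0, length(f0), length(eta))
  for (k in seq_along(eta)) {
    ek <- eta
    ek[k] <- ek[k] + h
    J[, k] <- (fn(ek) - f0) / h
  }
  J
}

.res_var <- function(f, sigma2, error) {
  if (error == "additive") rep(sigma2, length(f)) else
    sigma2 * pmax(f, PRED_FLOOR)^2
}

.inner_obj <- function(y, f, eta, om_inv, sigma2, error) {
  r <- y - f
  R <- .res_var(f, sigma2, error)
  sum(r^2 / R + log(R)) + sum(eta^2 * om_inv)
}

# Damped Gauss-Newton (Levenberg-Marquardt) maximisation of the conditional
# posterior of eta. Deterministic: the outer optimiser differentiates the
# objective numerically, so the inner solution must be a smooth function of
# the parameters.
.inner_fit <- function(y, pred_fn, jac_fn, eta0, om_inv, sigma2,
                       error = "proportional", max_iter = 60, tol = 1e-10) {
  eta <- eta0
  f <- pred_fn(eta)
  h_cur <- .inner_obj(y, f, eta, om_inv, sigma2, error)
  if (!is.finite(h_cur)) {
    eta <- 0 * eta
    f <- pred_fn(eta)
    h_cur <- .inner_obj(y, f, eta, om_inv, sigma2, error)
  }
  lam <- 1e-3
  for (it in seq_len(max_iter)) {
    J <- jac_fn(eta, f)
    fs <- pmax(f, PRED_FLOOR)
    r <- y - f
    Rinv <- 1 / .res_var(f, sigma2, error)
    # gradient; for proportional error R depends on eta (interaction)
    g <- -2 * crossprod(J, r * Rinv) + 2 * eta * om_inv
    if (error == "proportional") {
      g <- g + 2 * crossprod(J, 1 / fs - r^2 * Rinv / fs)
    }
    if (max(abs(g)) < 1e-8 * (1 + abs(h_cur))) break
    H <- 2 * crossprod(J * sqrt(Rinv)) + 2 * diag(om_inv, length(om_inv))
    dH <- pmax(diag(H), 1e-8)
    accepted <- FALSE
    for (damp in 1:20) {
      Hd <- H + lam * diag(dH, length(dH))
      step <- tryCatch(-solve(Hd, g), error = function(e) NULL)
      if (!is.null(step)) {
        # trust region: random effects live on the log scale, so huge jumps
        # only happen when the quadratic model is untrustworthy
        ms <- max(abs(step))
        if (ms > 2) step <- step * (2 / ms)
        eta_new <- as.numeric(eta + step)
        f_new <- pred_fn(eta_new)
        h_new <- .inner_obj(y, f_new, eta_new, om_inv, sigma2, error)
        if (is.finite(h_new) && h_new < h_cur) {
          accepted <- TRUE
          break
        }
      }
      lam <- lam * 10
      if (lam > 1e12) break
    }
    if (!accepted) break
    lam <- max(lam / 3, 1e-10)
    moved <- sqrt(sum((eta_new - eta)^2))
    improved <- h_cur - h_new
    eta <- eta_new
    f <- f_new
    h_cur <- h_new
    if (moved < 1e-7 || improved < tol * (abs(h_cur) + 1)) break
  }
  list(eta = eta, f = f, h = h_cur)
}

# --- objective -------------------------------------------------------------

#' FOCE objective function value
#'
#' -2 log approximate marginal likelihood of the data under the model at the
#' given parameters (extended least squares convention, including the
#' n log(2 pi) constant so that linear models match their closed-form
#' marginal normal likelihood exactly).
#'
#' @param model a [foce_model()].
#' @param params list with `theta` (named list, natural scale), `omega2`
#'   (named variances) and `sigma2` (proportional residual variance).
#' @param state optional environment carrying warm-start etas across calls.
#' @param detail return per-subject pieces (etas, linearisations) as an
#'   attribute.
#' @return numeric OFV (optionally with attribute `subjects`).
#' @export
ofv <- function(model, params, state = NULL, detail = FALSE) {
  stopifnot(inherits(model, "foce_model"))
  theta <- params$theta
  sigma2 <- max(params$sigma2, SIGMA2_FLOOR)
  total <- 0
  det_list <- if (detail) vector("list", length(model$subjects)) else NULL
  for (i in seq_along(model$subjects)) {
    s <- model$subjects[[i]]
    y <- s$y
    n <- length(y)
    err <- if (!is.null(s$error)) s$error else "proportional"
    act <- params$omega2[s$eta_names] > 0
    om <- params$omega2[s$eta_names][act]
    q <- sum(act)
    full_eta <- function(e) {
      v <- numeric(length(s$eta_names))
      v[act] <- e
      v
    }
    pred_fn <- function(e) s$predict(theta, full_eta(e))
    if (q > 0) {
      jac_fn <- if (!is.null(s$jac)) {
        function(e, f) s$jac(theta, full_eta(e), f)[, act, drop = FALSE]
      } else {
        function(e, f) .fd_jac(pred_fn, e, f)
      }
      eta0 <- rep(0, q)
      if (!is.null(state) && !is.null(state$eta[[i]]) &&
          length(state$eta[[i]]) == q) {
        eta0 <- state$eta[[i]]
      }
      res <- .inner_fit(y, pred_fn, jac_fn, eta0, 1 / om, sigma2,
                        error = err)
      if (!is.null(state)) state$eta[[i]] <- res$eta
      f <- res$f
      J <- jac_fn(res$eta, f)
      V <- J %*% (om * t(J))
      diag(V) <- diag(V) + .res_var(f, sigma2, err)
      e <- y - f + as.vector(J %*% res$eta)
      ch <- tryCatch(chol(V), error = function(err) {
        chol(V + diag(1e-8 * max(diag(V)), n))
      })
      quad <- sum(backsolve(ch, e, transpose = TRUE)^2)
      ofv_i <- 2 * sum(log(diag(ch))) + quad + n * log(2 * pi)
      if (detail) {
        det_list[[i]] <- list(eta = full_eta(res$eta), act = act, J = J,
                              f = f, V = V, e = e, chol = ch)
      }
    } else {
      f <- pred_fn(numeric(0))
      R <- .res_var(f, sigma2, err)
      r <- y - f
      ofv_i <- sum(log(R) + r^2 / R) + n * log(2 * pi)
      if (detail) {
        det_list[[i]] <- list(eta = numeric(length(s$eta_names)),
                              act = act, J = matrix(0, n, 0), f = f,
                              V = diag(R, n), e = r,
                              chol = diag(sqrt(R), n))
      }
    }
    total <- total + ofv_i
  }
  if (detail) attr(total, "subjects") <- det_list
  total
}

# --- outer optimisation ----------------------------------------------------

#' Fit a FOCE model
#'
#' Quasi-Newton minimisation of [ofv()] over the transformed unfixed
#' parameters, with warm-started inner problems.
#'
#' @param model a [foce_model()].
#' @param start parameter list as in [ofv()].
#' @param fix character vector of packed-parameter names to hold fixed
#'   (`"theta.<name>"`, `"omega2.<name>"`, `"sigma2"`), or `TRUE` entries in
#'   a named logical.
#' @param control list: `iter.max` (default 150), `rel.tol` (1e-8),
#'   `trace` (0).
#' @return list of class `foce_fit`: `params` (natural-scale estimates),
#'   `ofv`, `convergence` (0 = converged), `message`, `eta` (per-subject
#'   empirical Bayes estimates), `fix`, `model`, `counts`.
#' @export
fit_foce <- function(model, start, fix = character(0), control = list()) {
  stopifnot(inherits(model, "foce_model"))
  if (is.logical(fix)) fix <- names(fix)[fix]
  # variances started (or pinned) at zero are not estimable on the log scale
  fix <- union(fix, paste0("omega2.",
                           names(start$omega2)[start$omega2 == 0]))
  state <- new.env()
  state$eta <- vector("list", length(model$subjects))
  n_eval <- 0L
  obj <- function(x) {
    n_eval <<- n_eval + 1L
    p <- .unpack(x, start, model, fix)
    v <- tryCatch(ofv(model, p, state = state),
                  error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  x0 <- .pack(start, model, fix)
  ctl <- list(iter.max = if (!is.null(control$iter.max))
    control$iter.max else 150,
    rel.tol = if (!is.null(control$rel.tol)) control$rel.tol else 1e-8,
    trace = if (!is.null(control$trace)) control$trace else 0,
    grad_step = if (!is.null(control$grad_step)) control$grad_step else 1e-3)
  # forward-difference gradient at a step large enough to dominate the
  # residual noise of the warm-started inner problems
  last <- new.env()
  obj_memo <- function(x) {
    if (!is.null(last$x) && identical(last$x, x)) return(last$v)
    v <- obj(x)
    last$x <- x
    last$v <- v
    v
  }
  grad <- function(x) {
    f0 <- obj_memo(x)
    h <- ctl$grad_step
    vapply(seq_along(x), function(i) {
      xi <- x
      xi[i] <- xi[i] + h
      (obj(xi) - f0) / h
    }, 0)
  }
  restarts <- if (!is.null(control$restarts)) control$restarts else 3
  restart_tol <- if (!is.null(control$restart_tol))
    control$restart_tol else 0.05
  if (length(x0)) {
    x_cur <- x0
    opt <- NULL
    for (round in seq_len(1 + restarts)) {
      last$x <- NULL  # invalidate the memo across restarts
      o <- nlminb(x_cur, obj_memo, gradient = grad,
                  control = list(iter.max = ctl$iter.max,
                                 rel.tol = ctl$rel.tol,
                                 trace = ctl$trace))
      improved <- !is.null(opt) && (opt$objective - o$objective) >
        restart_tol
      better <- is.null(opt) || o$objective <= opt$objective
      if (better) {
        opt <- o
        x_cur <- o$par
      }
      # a quasi-Newton restart from the incumbent escapes "false
      # convergence" stops caused by the finite-difference gradient
      if (o$convergence == 0 || (!is.null(opt) && round > 1 && !improved)) {
        stalled <- round > 1 && !improved
        break
      }
      stalled <- FALSE
    }
    params_hat <- .unpack(setNames(opt$par, names(x0)), start, model, fix)
    # an objective stable across quasi-Newton restarts is treated as
    # converged even when nlminb reports false convergence (its gradient
    # consistency check trips on the finite-difference noise floor)
    conv <- if (opt$convergence == 0 || isTRUE(stalled)) 0 else
      opt$convergence
    msg <- if (opt$convergence != 0 && isTRUE(stalled))
      paste0(opt$message, " (objective stable across restarts)") else
      opt$message
  } else {
    params_hat <- start
    conv <- 0
    msg <- "all parameters fixed"
  }
  final <- ofv(model, params_hat, state = state, detail = TRUE)
  det <- attr(final, "subjects")
  structure(list(params = params_hat, ofv = as.numeric(final),
                 detail = det,
                 eta = lapply(det, `[[`, "eta"),
                 eta_active = lapply(det, function(d) d$eta[d$act]),
                 convergence = conv, message = msg, fix = fix,
                 model = model, start = start,
                 counts = c(evaluations = n_eval)),
            class = "foce_fit")
}

#' Likelihood-ratio comparison of nested fits
#'
#' The objective drop between nested models is referred to a chi-square
#' with `df` degrees of freedom; at the conventional alpha = 0.01 and one
#' added parameter the critical drop is 6.63 points.
#'
#' @param reduced,full `foce_fit` (or `pkpd_fit`) objects, or bare OFV
#'   numbers.
#' @param df degrees-of-freedom difference, >= 1.
#' @param alpha significance level.
#' @return list of class `nested_comparison`: `ofv_reduced`, `ofv_full`,
#'   `delta_ofv`, `df`, `critical`, `p`, `significant`.
#' @export
lrt <- function(reduced, full, df = 1, alpha = 0.01) {
  if (df < 1) stop("lrt: df must be >= 1")
  o_r <- if (is.numeric(reduced)) reduced else reduced$ofv
  o_f <- if (is.numeric(full)) full else full$ofv
  d <- o_r - o_f
  if (d < 0) {
    warning("lrt: negative OFV drop for a nested pair ",
            "(optimiser artifact?)")
  }
  crit <- qchisq(1 - alpha, df)
  structure(list(ofv_reduced = o_r, ofv_full = o_f, delta_ofv = d, df = df,
                 critical = crit, p = pchisq(max(d, 0), df,
                                             lower.tail = FALSE),
                 significant = d >= crit),
            class = "nested_comparison")
}

#' @export
print.nested_comparison <- function(x, ...) {
  cat(sprintf(
    "Nested comparison: dOFV = %.2f on %d df (critical %.2f) -> %s\n",
    x$delta_ofv, x$df, x$critical,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

# --- covariance step -------------------------------------------------------

#' Finite-difference Hessian with Richardson extrapolation
#'
#' Central second differences at two step sizes (h and h/2), combined as
#' (4 H_{h/2} - H_h)/3.
#'
#' @param fn scalar function of a numeric vector.
#' @param x evaluation point.
#' @param rel_step relative step size.
#' @param richardson use two step sizes and extrapolate.
#' @return symmetric Hessian matrix.
#' @export
fd_hessian <- function(fn, x, rel_step = 1e-4, richardson = TRUE) {
  n <- length(x)
  hess_at <- function(h) {
    H <- matrix(0, n, n)
    f0 <- fn(x)
    fp <- fm <- numeric(n)
    for (i in seq_len(n)) {
      ei <- numeric(n)
      ei[i] <- h[i]
      fp[i] <- fn(x + ei)
      fm[i] <- fn(x - ei)
      H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
    }
    if (n > 1) {
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          ei <- numeric(n)
          ej <- numeric(n)
          ei[i] <- h[i]
          ej[j] <- h[j]
          H[i, j] <- H[j, i] <-
            (fn(x + ei + ej) - fn(x + ei - ej) -
               fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h[i] * h[j])
        }
      }
    }
    H
  }
  h <- pmax(abs(x), 1) * rel_step
  H1 <- hess_at(h)
  if (!richardson) return((H1 + t(H1)) / 2)
  H2 <- hess_at(h / 2)
  H <- (4 * H2 - H1) / 3
  (H + t(H)) / 2
}

#' Covariance step: standard errors, RSEs and condition number
#'
#' Finite-difference Hessian of OFV/2 at the optimum; the covariance of the
#' estimates is its inverse. Standard errors are mapped to the natural scale
#' by the delta method; the condition number is the eigenvalue ratio of the
#' correlation matrix of the estimates.
#'
#' @param fit a `foce_fit` (or `pkpd_fit`).
#' @param rel_step finite-difference relative step.
#' @return list of class `covariance_step`: `status` ("ok"/"failed"),
#'   `se` and `rse_pct` on the natural scale, `cov` (transformed scale),
#'   `condition_number`.
#' @export
covariance_step <- function(fit, rel_step = 1e-4) {
  if (inherits(fit, "pkpd_fit")) fit <- fit$fit
  stopifnot(inherits(fit, "foce_fit"))
  model <- fit$model
  fix <- fit$fix
  x_hat <- .pack(fit$params, model, fix)
  state <- new.env()
  state$eta <- fit$eta_active
  fn <- function(x) {
    p <- .unpack(setNames(x, names(x_hat)), fit$params, model, fix)
    ofv(model, p, state = state) / 2
  }
  H <- fd_hessian(fn, x_hat, rel_step = rel_step)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    return(structure(list(status = "failed", se = NULL, rse_pct = NULL,
                          cov = NULL, condition_number = NA_real_),
                     class = "covariance_step"))
  }
  cv <- solve(H)
  se_t <- sqrt(diag(cv))
  # delta method back to the natural scale
  nat <- unlist(c(fit$params$theta, fit$params$omega2,
                  sigma2 = fit$params$sigma2))
  tr <- setNames(model$theta_spec$transform, model$theta_spec$name)
  se_nat <- vapply(seq_along(x_hat), function(i) {
    nm <- names(x_hat)[i]
    if (startsWith(nm, "theta.")) {
      pn <- sub("^theta\\.", "", nm)
      se_t[i] * abs(.tr_deriv(fit$params$theta[[pn]], tr[[pn]]))
    } else if (startsWith(nm, "omega2.")) {
      pn <- sub("^omega2\\.", "", nm)
      se_t[i] * fit$params$omega2[[pn]]
    } else se_t[i] * fit$params$sigma2
  }, 0)
  names(se_nat) <- names(x_hat)
  est_nat <- vapply(names(x_hat), function(nm) {
    if (startsWith(nm, "theta.")) {
      as.numeric(fit$params$theta[[sub("^theta\\.", "", nm)]])
    } else if (startsWith(nm, "omega2.")) {
      fit$params$omega2[[sub("^omega2\\.", "", nm)]]
    } else fit$params$sigma2
  }, 0)
  corr <- cv / tcrossprod(se_t)
  cev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  structure(list(status = "ok", se = se_nat,
                 rse_pct = 100 * se_nat / abs(est_nat),
                 cov = cv,
                 condition_number = max(cev) / min(cev)),
            class = "covariance_step")
}

# --- bootstrap -------------------------------------------------------------

#' Nonparametric bootstrap of a FOCE fit
#'
#' Resamples subjects with replacement (stratified by each subject's
#' `group` label when present), refits each replicate from the original
#' estimates, and reports per-parameter medians, 95% percentile intervals
#' and the fractions of successful minimisations and covariance steps.
#'
#' @param fit a `foce_fit` (or `pkpd_fit`).
#' @param n_samples number of bootstrap replicates, >= 1.
#' @param seed RNG seed.
#' @param identity if `TRUE`, every "resample" is the original subject set
#'   (sanity-check mode: each replicate must reproduce the original fit).
#' @param do_cov run the covariance step per replicate (slow).
#' @param refit_fn override for the per-replicate refit, mainly for testing:
#'   `function(model) -> foce_fit` (may error).
#' @param control passed to [fit_foce()].
#' @return list of class `foce_bootstrap`: `estimates` (replicate x
#'   parameter matrix), `median`, `ci` (2.5/97.5%), `minimization_success`,
#'   `covariance_success`.
#' @export
bootstrap <- function(fit, n_samples = 50, seed = 1, identity = FALSE,
                      do_cov = FALSE, refit_fn = NULL, control = list()) {
  if (inherits(fit, "pkpd_fit")) fit <- fit$fit
  stopifnot(inherits(fit, "foce_fit"), n_samples >= 1)
  model <- fit$model
  groups <- vapply(model$subjects, function(s)
    if (!is.null(s$group)) as.character(s$group) else "all", "")
  set.seed(seed)
  flat <- function(p) unlist(c(p$theta, omega2 = as.list(p$omega2),
                               sigma2 = p$sigma2))
  est <- list()
  ok_min <- ok_cov <- logical(n_samples)
  for (b in seq_len(n_samples)) {
    idx <- if (identity) seq_along(model$subjects) else {
      unlist(lapply(unique(groups), function(g) {
        pool <- which(groups == g)
        sample(pool, length(pool), replace = TRUE)
      }))
    }
    m_b <- foce_model(model$subjects[idx], model$theta_spec,
                      name = model$name)
    f_b <- tryCatch({
      if (!is.null(refit_fn)) refit_fn(m_b) else
        fit_foce(m_b, fit$params, fix = fit$fix, control = control)
    }, error = function(e) NULL)
    ok_min[b] <- !is.null(f_b) && f_b$convergence == 0
    if (!is.null(f_b)) {
      est[[length(est) + 1]] <- flat(f_b$params)
      if (do_cov) {
        cs <- tryCatch(covariance_step(f_b), error = function(e) NULL)
        ok_cov[b] <- !is.null(cs) && cs$status == "ok"
      }
    }
  }
  if (!length(est)) stop("bootstrap: all replicates failed")
  em <- do.call(rbind, est)
  structure(list(
    estimates = em,
    median = apply(em, 2, median),
    ci = apply(em, 2, quantile, c(0.025, 0.975)),
    minimization_success = mean(ok_min),
    covariance_success = if (do_cov) mean(ok_cov[ok_min]) else NA_real_),
    class = "foce_bootstrap")
}
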