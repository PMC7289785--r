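# A one-observation-per-subject linear model y = mu + eta + eps has the
# closed-form marginal -2 log likelihood sum(log(2 pi (w2+s2)) +
# (y-mu)^2/(w2+s2)); the FOCE objective must match it exactly.
linear_model <- function(y) {
  subjects <- lapply(y, function(yi) list(
    y = yi, predict = function(th, eta) th$mu + eta,
    eta_names = "mu", error = "additive"))
  foce_model(subjects, data.frame(name = "mu", transform = "identity"),
             name = "linear")
}

test_that("FOCE objective equals the closed-form marginal likelihood", {
  set.seed(3)
  y <- rnorm(25, 5, 1)
  m <- linear_model(y)
  p <- list(theta = list(mu = 5), omega2 = c(mu = 0.5), sigma2 = 0.25)
  closed <- -2 * sum(dnorm(y, 5, sqrt(0.75), log = TRUE))
  expect_equal(ofv(m, p), closed, tolerance = 1e-9)
})

test_that("the fit reaches the analytic maximum likelihood estimate", {
  set.seed(4)
  y <- rnorm(40, 3, sqrt(0.6))
  m <- linear_model(y)
  f <- fit_foce(m, list(theta = list(mu = 1), omega2 = c(mu = 0.2),
                        sigma2 = 0.25), fix = "sigma2")
  expect_equal(f$params$theta$mu, mean(y), tolerance = 1e-3)
  expect_equal(f$params$omega2[["mu"]] + f$params$sigma2,
               mean((y - mean(y))^2), tolerance = 1e-3)
  expect_equal(f$convergence, 0)
})

test_that("OFV is invariant to subject ordering and zero-omega collapses", {
  set.seed(5)
  y <- rnorm(12, 2, 0.5)
  m <- linear_model(y)
  m_rev <- foce_model(rev(m$subjects), m$theta_spec)
  p <- list(theta = list(mu = 2), omega2 = c(mu = 0.3), sigma2 = 0.2)
  expect_equal(ofv(m, p), ofv(m_rev, p))
  # omega = 0: OFV is the pure residual -2 log likelihood at typical values
  p0 <- list(theta = list(mu = 2), omega2 = c(mu = 0), sigma2 = 0.2)
  expect_equal(ofv(m, p0), -2 * sum(dnorm(y, 2, sqrt(0.2), log = TRUE)),
               tolerance = 1e-9)
})

test_that("reparameterisation leaves the objective minimum unchanged", {
  set.seed(6)
  y <- abs(rnorm(30, 4, 1)) + 1
  mk <- function(tr) {
    subjects <- lapply(y, function(yi) list(
      y = yi, predict = function(th, eta) th$mu + eta,
      eta_names = "mu", error = "additive"))
    foce_model(subjects, data.frame(name = "mu", transform = tr))
  }
  st <- list(theta = list(mu = 3), omega2 = c(mu = 0.5), sigma2 = 0.3)
  f1 <- fit_foce(mk("identity"), st, fix = "sigma2")
  f2 <- fit_foce(mk("log"), st, fix = "sigma2")
  expect_lt(abs(f1$ofv - f2$ofv), 0.1)
})

test_that("likelihood-ratio machinery matches chi-square quantiles", {
  cmp <- lrt(100, 93.36, df = 1)
  expect_equal(round(cmp$critical, 2), 6.63)
  expect_true(cmp$significant)                 # drop 6.64 >= 6.63
  expect_true(lrt(100, 44.6, df = 2)$significant)   # the reported 55.4 drop
  expect_false(lrt(100, 100, df = 1)$significant)
  for (df in 1:5) {
    expect_equal(lrt(10, 5, df = df)$critical, qchisq(0.99, df),
                 tolerance = 1e-4)
  }
  expect_warning(lrt(90, 100, df = 1), "negative")
  expect_error(lrt(10, 5, df = 0), "df")
})

test_that("finite-difference Hessian is exact on a quadratic", {
  A <- matrix(c(4, 1, 0.5, 1, 3, -0.2, 0.5, -0.2, 2), 3, 3)
  fn <- function(x) 0.5 * sum(x * (A %*% x)) + sum(x)
  H <- fd_hessian(fn, c(0.3, -0.2, 1))
  expect_equal(H, A, tolerance = 1e-6)
})

test_that("covariance step matches the closed-form information", {
  set.seed(7)
  y <- rnorm(30, 5, sqrt(0.75))
  m <- linear_model(y)
  f <- fit_foce(m, list(theta = list(mu = 4), omega2 = c(mu = 0.4),
                        sigma2 = 0.25), fix = c("sigma2", "omega2.mu"))
  cs <- covariance_step(f)
  expect_equal(cs$status, "ok")
  closed_se <- sqrt((f$params$omega2[["mu"]] + f$params$sigma2) / 30)
  expect_equal(cs$se[["theta.mu"]], closed_se, tolerance = 0.01)
  # a single estimated parameter has condition number exactly 1
  expect_equal(cs$condition_number, 1)
})

test_that("bootstrap identity mode and success accounting behave", {
  set.seed(8)
  y <- rnorm(15, 2, 0.6)
  m <- linear_model(y)
  f <- fit_foce(m, list(theta = list(mu = 2), omega2 = c(mu = 0.2),
                        sigma2 = 0.2), fix = c("sigma2", "omega2.mu"))
  b <- bootstrap(f, n_samples = 2, identity = TRUE)
  expect_equal(unname(b$median[["mu"]]), f$params$theta$mu,
               tolerance = 1e-6)
  expect_equal(b$minimization_success, 1)
  # stub refit that fails on the first replicate only
  k <- 0
  stub <- function(model) {
    k <<- k + 1
    if (k == 1) stop("forced failure")
    fit_foce(model, f$params, fix = c("sigma2", "omega2.mu"))
  }
  b2 <- bootstrap(f, n_samples = 4, refit_fn = stub)
  expect_equal(b2$minimization_success, 3 / 4)
})
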