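test_that("with all variances zero, different seeds give identical trials", {
  gh0 <- gh_params(omega2 = c(baseline = 0, width = 0, kel = 0,
                              amplitude = 0),
                   bov2 = c(width = 0, kel = 0), sigma2 = 0)
  prl0 <- prl_params(omega2 = c(ks = 0, amp24 = 0, amp12 = 0), sigma2 = 0)
  # pulse times are part of the stochastic world, so pin them by comparing
  # PRL only (GH pulse trains differ by seed by design)
  t1 <- simulate_trial("0.8mg-sad", n_per_cohort = 2, gh = NULL, prl = prl0,
                       seed = 1)
  t2 <- simulate_trial("0.8mg-sad", n_per_cohort = 2, gh = NULL, prl = prl0,
                       seed = 99)
  expect_equal(t1$DV, t2$DV)
  # zero-variance observations equal the typical-value prediction exactly
  obs <- t1[t1$DVID == 3 & t1$EVID == 0 & t1$ID == 2, ]  # placebo subject
  pred <- prl_concentration(prl0, obs$TIME)
  expect_equal(obs$DV, pred, tolerance = 1e-9)
})

test_that("LLOQ substitution is idempotent and flags correctly", {
  x <- c(0.01, 0.05, 0.2, 0.049)
  s1 <- lloq_substitute(x)
  expect_equal(s1$value, c(0.05, 0.05, 0.2, 0.05))
  expect_equal(s1$blq, c(1L, 0L, 0L, 1L))
  s2 <- lloq_substitute(s1$value)
  expect_equal(s2$value, s1$value)
  expect_equal(s2$blq, c(0L, 0L, 0L, 0L))  # already at the LLOQ, not below
})

test_that("subject k is invariant to how many subjects follow", {
  a <- simulate_trial("placebo", n_per_cohort = 2, prl = NULL, seed = 5)
  b <- simulate_trial("placebo", n_per_cohort = 6, prl = NULL, seed = 5)
  expect_equal(a[a$ID == 2, ], b[b$ID == 2, ], ignore_attr = TRUE)
})

test_that("individual parameter draws follow the configured log-normals", {
  tab <- simulate_trial("placebo", n_per_cohort = 300, prl = NULL, seed = 8,
                        gh = gh_params())
  tr <- attr(tab, "truth")
  eta_b <- vapply(tr, function(x) x$gh_eta[["baseline"]], 0)
  ks <- suppressWarnings(stats::ks.test(eta_b, "pnorm", 0, sqrt(0.0288)))
  expect_gt(ks$p.value, 0.01)
})

test_that("below-LLOQ fractions: placebo substantial, active higher", {
  tab <- simulate_trial(c("placebo", "1.5mg-sad"), n_per_cohort = 12,
                        prl = NULL, seed = 12)
  meta <- attr(tab, "subjects")
  gh <- tab[tab$EVID == 0 & tab$DVID == 2, ]
  pl <- mean(gh$BLQ[gh$ID %in% meta$id[!meta$active]])
  ac <- mean(gh$BLQ[gh$ID %in% meta$id[meta$active]])
  # the printed placebo figure is ~20%; this generator sits lower (~10%,
  # see the methods vignette) but the censoring mechanism and the
  # active > placebo direction are the tested contracts
  expect_gt(pl, 0.04)
  expect_lt(pl, 0.35)
  expect_gt(ac, pl)
})

test_that("invalid variance configurations are rejected", {
  expect_error(gh_params(omega2 = c(baseline = -1, width = 0, kel = 0,
                                    amplitude = 0)), "variances")
  expect_error(prl_params(amp24 = 0.7, amp12 = 0.4), "positive")
})

test_that("covariates stay within their physiological ranges", {
  set.seed(2)
  cv <- draw_covariates(500)
  expect_true(all(cv$age >= 18 & cv$age <= 55))
  expect_true(all(cv$weight >= 55 & cv$weight <= 110))
  expect_true(all(abs(cv$bmi - cv$weight / (cv$height / 100)^2) < 1e-12))
})
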