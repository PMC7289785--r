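# Diagnostics are exercised at the true generating parameters ("model-true"
# evaluation): this isolates the calibration of the statistics from
# estimation error. The full-scale calibration checks live in the
# acceptance suite.

prl_fit_at_truth <- function(cohorts = c("placebo", "0.8mg-sad"),
                             n = 6, seed = 21) {
  tab <- simulate_trial(cohorts, n_per_cohort = n, gh = NULL, seed = seed)
  pkpd_fit(tab, "prl", start = prl_truth(), fix = "all")
}

test_that("CWRESI is approximately standard normal under the true model", {
  fit <- prl_fit_at_truth()
  cw <- cwresi(fit)
  expect_true(all(is.finite(cw$CWRESI)))
  expect_lt(abs(mean(cw$CWRESI)), 0.15)
  expect_gte(mean(abs(cw$CWRESI) <= 2), 0.90)
  expect_true(all(c("PRED", "IPRED", "TIME") %in% names(cw)))
})

test_that("omitting the drug effect biases CWRESI during treatment", {
  tab <- simulate_trial("1.5mg-sad", n_per_cohort = 6, gh = NULL, seed = 22)
  no_drug <- prl_truth()
  no_drug$theta$iemax <- 1e-4   # essentially no inhibition in the model
  fit <- pkpd_fit(tab, "prl", start = no_drug, fix = "all")
  cw <- cwresi(fit)
  meta <- attr(tab, "subjects")
  treated <- cw$ID %in% meta$id[meta$active] & cw$TAD > 0 & cw$TAD < 8
  expect_lt(mean(cw$CWRESI[treated]), -0.2)
})

test_that("NPDE is reproducible, finite at the rank boundary, calibrated", {
  fit <- prl_fit_at_truth(n = 4)
  n1 <- npde(fit, n_sim = 150, seed = 5)
  n2 <- npde(fit, n_sim = 150, seed = 5)
  expect_identical(n1$table$NPDE, n2$table$NPDE)
  expect_true(all(is.finite(n1$table$NPDE)))
  # the 1/(2 n_sim) clamp bounds the most extreme mapped value
  expect_lte(max(abs(n1$table$NPDE)),
             abs(qnorm(1 / (2 * 150))) + 1e-9)
  expect_lt(abs(n1$by_day$mean[1]), 0.25)
  expect_error(npde(fit, n_sim = 50), ">= 100")
})

test_that("pcVPC refuses GH and behaves sensibly for PRL", {
  tabg <- simulate_trial("placebo", n_per_cohort = 2, prl = NULL, seed = 1)
  fg <- pkpd_fit(tabg, "gh", pulses = truth_pulses(tabg),
                 stage = "placebo", start = gh_truth(), fix = "all")
  expect_error(pcvpc(fg), "pcVPC unsupported for pulsatile GH")

  fit <- prl_fit_at_truth(cohorts = "placebo", n = 6)
  # a single bin covering all clock times gives one constant correction
  v1 <- pcvpc(fit, bins = c(-0.01, 24), n_sim = 60)
  expect_equal(nrow(v1$table), 1)
  v <- pcvpc(fit, bins = 6, n_sim = 80, seed = 3)
  expect_true(all(v$table$obs_p5 <= v$table$obs_p50 &
                    v$table$obs_p50 <= v$table$obs_p95))
  expect_gte(v$coverage, 0.5)  # loose here; calibrated in acceptance
})

test_that("prediction correction is the identity when IIV is zero", {
  prl0 <- prl_params(omega2 = c(ks = 0, amp24 = 0, amp12 = 0),
                     sigma2 = 0.02)
  tab <- simulate_trial("placebo", n_per_cohort = 4, gh = NULL, prl = prl0,
                        seed = 13)
  st <- prl_truth()
  st$omega2 <- c(ks = 0, amp24 = 0, amp12 = 0)
  st$sigma2 <- 0.02
  fit <- pkpd_fit(tab, "prl", start = st, fix = "all")
  # bins at the unique clock times: every observation is its bin median
  ut <- sort(unique(tab$TIME[tab$EVID == 0] %% 24))
  brk <- c(ut[1] - 1e-6, ut + 1e-6)
  v <- pcvpc(fit, bins = brk, n_sim = 60)
  y <- tab$DV[tab$EVID == 0]
  expect_equal(sort(v$table$obs_p50),
               sort(as.numeric(tapply(y, tab$TIME[tab$EVID == 0] %% 24,
                                      median))),
               tolerance = 1e-9)
})

test_that("shrinkage reflects the information content of the design", {
  set.seed(9)
  mk <- function(n_obs) {
    subjects <- lapply(1:40, function(i) {
      eta <- rnorm(1, 0, sqrt(0.5))
      y <- 5 + eta + rnorm(n_obs, 0, 1)
      list(y = y, predict = function(th, e) rep(th$mu + e, length(y)),
           eta_names = "mu", error = "additive")
    })
    m <- foce_model(subjects, data.frame(name = "mu",
                                         transform = "identity"))
    fit_foce(m, list(theta = list(mu = 5), omega2 = c(mu = 0.5),
                     sigma2 = 1),
             fix = c("theta.mu", "omega2.mu", "sigma2"))
  }
  rich <- shrinkage(mk(25))
  sparse <- shrinkage(mk(1))
  expect_lt(rich[["mu"]], 15)
  expect_gt(sparse[["mu"]], rich[["mu"]])
  # a zero-variance component is reported as missing
  f0 <- mk(2)
  f0$params$omega2[["mu"]] <- 0
  expect_true(is.na(shrinkage(f0)[["mu"]]))
})

test_that("covariate screening flags only real EBE correlates", {
  fit <- prl_fit_at_truth(cohorts = "placebo", n = 20, seed = 51)
  ids <- vapply(fit$fit$model$subjects, `[[`, 0, "id")
  ebe_ks <- vapply(seq_along(ids), function(i) fit$fit$eta[[i]][1], 0)
  set.seed(1)
  covs <- data.frame(id = ids,
                     weight = rnorm(length(ids), 78, 10),   # independent
                     marker = 70 + 12 * ebe_ks,             # exact linear
                     fixedcov = 5)                          # constant
  w <- capture_warnings(cs <- covariate_screen(fit, covs))
  expect_true(any(grepl("constant covariate", w)))
  r2 <- cs$r2
  expect_equal(r2$r2[r2$eta == "ks" & r2$covariate == "marker"], 1,
               tolerance = 1e-9)
  expect_true(all(!r2$candidate[r2$covariate == "weight"]))
  # with no flagged candidates the stepping result is empty
  cs2 <- suppressWarnings(covariate_screen(fit,
                                           covs[c("id", "weight")]))
  expect_equal(nrow(cs2$selected), 0)
})
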