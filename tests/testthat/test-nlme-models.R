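test_that("fits are self-consistent at tiny variances", {
  # data simulated essentially at the typical values must return them
  prl_tiny <- prl_params(omega2 = c(ks = 1e-4, amp24 = 1e-4, amp12 = 1e-4),
                         sigma2 = 1e-4)
  tab <- simulate_trial("placebo", n_per_cohort = 6, gh = NULL,
                        prl = prl_tiny, seed = 31)
  st <- prl_truth()
  st$omega2 <- c(ks = 1e-4, amp24 = 1e-4, amp12 = 1e-4)
  st$sigma2 <- 1e-4
  f <- pkpd_fit(tab, "prl", start = st,
                fix = c("omega2.ks", "omega2.amp24", "omega2.amp12",
                        "sigma2", "theta.iemax", "theta.ec50",
                        "theta.slope"),
                control = list(iter.max = 60, restarts = 1))
  est <- unlist(f$fit$params$theta)
  truth <- unlist(st$theta)
  for (nm in c("kr", "kel", "ks", "amp24", "phase24", "amp12", "phase12")) {
    expect_lt(abs(est[[nm]] - truth[[nm]]) / max(abs(truth[[nm]]), 0.01),
              0.02)
  }
})

test_that("pkpd_fit methods expose the fit coherently", {
  gh_small <- gh_params()
  tab <- simulate_trial("placebo", n_per_cohort = 3, prl = NULL,
                        gh = gh_small, seed = 17)
  pulses <- truth_pulses(tab)
  f <- pkpd_fit(tab, "gh", pulses = pulses, stage = "placebo",
                start = gh_truth(), fix = "all")
  expect_s3_class(f, "pkpd_fit")
  co <- coef(f)
  expect_true(all(c("baseline", "width", "kel", "emax", "sigma2") %in%
                    names(co)))
  expect_equal(co[["emax"]], -0.648)
  ll <- logLik(f)
  expect_equal(as.numeric(ll), -f$fit$ofv / 2)
  pr_pop <- predict(f, type = "population")
  pr_ind <- predict(f, type = "individual")
  expect_equal(nrow(pr_pop), sum(tab$DVID == 2 & tab$EVID == 0))
  # individual predictions track data more closely than population ones
  y <- unlist(lapply(f$fit$model$subjects, `[[`, "y"))
  expect_lt(sum((log(pr_ind$IPRED) - log(y))^2),
            sum((log(pr_pop$PRED) - log(y))^2))
  rs <- residuals(f, type = "iwres")
  expect_equal(length(rs), length(y))
  s <- summary(f)
  expect_s3_class(s, "summary.pkpd_fit")
  expect_output(print(f), "Population GH model")
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims[[1]]), c(length(f$fit$model$subjects[[1]]$y), 3))
  # GH simulations respect the assay floor
  expect_true(all(unlist(sims) >= 0.05))
})

test_that("simulating then fitting preserves the OFV preference for truth", {
  # the fitted optimum cannot be worse than a clearly wrong parameter set
  prl_tiny <- prl_params(omega2 = c(ks = 0.02, amp24 = 0.05, amp12 = 0.05),
                         sigma2 = 0.01)
  tab <- simulate_trial("placebo", n_per_cohort = 4, gh = NULL,
                        prl = prl_tiny, seed = 41)
  m <- pulsepkpd:::.build_prl_model(tab)
  good <- prl_truth()
  good$omega2 <- c(ks = 0.02, amp24 = 0.05, amp12 = 0.05)
  good$sigma2 <- 0.01
  bad <- good
  bad$theta$ks <- 30
  expect_lt(ofv(m, good), ofv(m, bad))
})
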