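test_that("circadian factor is an exact, periodic cosine", {
  expect_equal(circadian_factor(17.3, 0.168, 17.3, 24), 0.168)
  expect_equal(circadian_factor(17.3 + 12, 0.168, 17.3, 24), -0.168)
  expect_equal(circadian_factor(seq(0, 48, 3), 0, 10, 24), rep(0, 17))
  t <- seq(0, 23, 0.5)
  expect_equal(circadian_factor(t, 0.1, 5, 12),
               circadian_factor(t + 12, 0.1, 5, 12))
  expect_error(circadian_factor(1, 0.1, 0, period = 0), "period")
})

test_that("exposure inhibition is a saturating fraction", {
  expect_equal(exposure_inhibition(0, 2.73), 0)
  expect_equal(exposure_inhibition(1 / 2.73, 2.73), 0.5)
  expect_equal(exposure_inhibition(1.0, 2.73), 2.73 / 3.73)
  x <- seq(0, 50, 0.5)
  i <- exposure_inhibition(x, 2.73)
  expect_true(all(diff(i) > 0) && all(i < 1))
  expect_error(exposure_inhibition(-1, 2.73), ">= 0")
})

test_that("Emax factor obeys its algebraic anchors", {
  expect_equal(emax_factor(0, -0.648, 0.609), 1)
  expect_equal(emax_factor(0.609, -0.648, 0.609), 1 - 0.648 / 2)
  expect_equal(emax_factor(1e9, -0.91, 1.27), 0.09, tolerance = 1e-6)
  cc <- seq(0, 20, 0.1)
  expect_true(all(diff(emax_factor(cc, -0.5, 1)) <= 0))
})

test_that("GH model holds its steady state and mass balance", {
  p <- gh_params()
  tt <- seq(0, 12, 1 / 3)
  flat <- gh_concentration(p, data.frame(location = numeric(0)), tt)
  expect_equal(flat, rep(0.056, length(tt)))
  # k_el * integral of (C - baseline) equals the pulse mass
  t2 <- seq(-2, 30, 0.01)
  c1 <- gh_concentration(p, data.frame(location = 2, mass = 1.5), t2)
  integ <- sum(diff(t2) * (head(c1 - p$baseline, -1) +
                             tail(c1 - p$baseline, -1)) / 2)
  expect_equal(p$kel * integ, 1.5, tolerance = 1e-4)
})

test_that("GH pulses superpose (linear system, no drug)", {
  p <- gh_params()
  tt <- seq(0, 12, 0.25)
  single <- lapply(c(2, 5, 9), function(l) {
    gh_concentration(p, data.frame(location = l, mass = 1.2), tt) -
      p$baseline
  })
  all3 <- gh_concentration(p, data.frame(location = c(2, 5, 9),
                                         mass = rep(1.2, 3)), tt)
  expect_equal(all3, p$baseline + Reduce(`+`, single), tolerance = 1e-10)
})

test_that("drug scales pulse mass through the effect compartment", {
  p <- gh_params()
  tt <- seq(0, 12, 1 / 3)
  drug <- list(times = seq(0, 14, 0.25),
               cp = rep(100, 57))  # saturating exposure
  sup <- gh_concentration(p, data.frame(location = 6, mass = 2), tt,
                          drug = drug)
  off <- gh_concentration(p, data.frame(location = 6, mass = 2), tt)
  ratio <- (max(sup) - p$baseline) / (max(off) - p$baseline)
  expect_equal(ratio, 1 + p$emax, tolerance = 0.02)
})

test_that("PRL pool model holds its algebraic steady state", {
  pp <- prl_params(amp24 = 0, amp12 = 0)
  cc <- prl_concentration(pp, times = seq(0, 24, 0.5))
  expect_equal(cc, rep(13.3 / 1.25, length(cc)), tolerance = 1e-9)
})

test_that("drug-free PRL is 24 h periodic after the run-in", {
  pp <- prl_params()
  tt <- seq(0, 96, 0.25)
  cc <- prl_concentration(pp, tt)
  d1 <- cc[tt >= 48 & tt < 72]
  d2 <- cc[tt >= 72 & tt < 96]
  expect_lt(max(abs(d1 - d2) / d1), 1e-3)
})

test_that("PRL mass is conserved in the circadian-free drug-free case", {
  pp <- prl_params(amp24 = 0, amp12 = 0)
  tt <- seq(0, 48, 0.05)
  cc <- prl_concentration(pp, tt)
  eliminated <- pp$kel * sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2)
  produced <- pp$ks * diff(range(tt))
  # at steady state compartments do not change, so production = elimination
  expect_equal(eliminated / produced, 1, tolerance = 1e-6)
})

test_that("PRL circadian bathyphase is in the morning", {
  pp <- prl_params()
  clock <- seq(0, 23.75, 0.25)          # 0 = 6 a.m.
  cc <- prl_concentration(pp, clock + 48)
  trough <- clock[which.min(cc)]
  expect_true(trough >= 0 && trough < 6)   # 6 a.m. - noon
  morning <- mean(cc[clock < 6])
  afternoon <- mean(cc[clock >= 6 & clock < 14])
  expect_gt(afternoon, morning)
})

test_that("increasing dose never raises GH pulse mass or PRL release", {
  p <- gh_params()
  cfg <- pk_config()
  tt <- seq(0, 12, 1 / 3)
  grid <- seq(0, 14, 0.25)
  prof <- function(dose) {
    cp <- simulate_pk(cfg, data.frame(time = 0, amt = dose), grid)
    gh_concentration(p, data.frame(location = c(2, 6), mass = c(2, 2)), tt,
                     drug = list(times = grid, cp = cp))
  }
  lo <- prof(0.4)
  hi <- prof(1.5)
  expect_true(all(hi <= lo + 1e-12))
  # PRL release factor is nonincreasing in concentration
  expect_true(all(diff(emax_factor(seq(0, 50, 1), -0.91, 1.27)) <= 0))
})
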