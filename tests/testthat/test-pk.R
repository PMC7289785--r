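test_that("no doses give an all-zero concentration series", {
  cfg <- pk_config()
  expect_equal(simulate_pk(cfg, data.frame(time = numeric(0),
                                           amt = numeric(0)),
                           seq(0, 10, 0.5)),
               rep(0, 21))
})

test_that("linear-elimination PK matches the closed-form solution", {
  cfg <- pk_config(vmax = 0)
  tt <- seq(0, 24, 0.25)
  cp <- simulate_pk(cfg, data.frame(time = 0, amt = 1), tt)
  ref <- pk_linear_oracle(cfg, 1, tt)
  expect_lt(max(abs(cp - ref)), 1e-5)
})

test_that("PK superposition holds without Michaelis-Menten elimination", {
  cfg <- pk_config(vmax = 0)
  tt <- seq(0, 36, 0.25)
  two <- simulate_pk(cfg, data.frame(time = c(0, 8), amt = c(0.8, 0.8)), tt)
  one <- simulate_pk(cfg, data.frame(time = 0, amt = 0.8), tt)
  shifted <- approx(tt + 8, one, xout = tt, yleft = 0)$y
  expect_lt(max(abs(two - (one + shifted))), 1e-4 * max(two))
})

test_that("nonlinear elimination makes exposure superlinear in dose", {
  cfg <- pk_config(vmax = 200, km = 2)
  tt <- seq(0, 48, 0.1)
  auc <- function(dose) {
    cp <- simulate_pk(cfg, data.frame(time = 0, amt = dose), tt)
    sum(diff(tt) * (head(cp, -1) + tail(cp, -1)) / 2)
  }
  expect_gt(auc(1.6), 2 * auc(0.8))
})

test_that("dose amounts and times are validated", {
  cfg <- pk_config()
  expect_error(simulate_pk(cfg, data.frame(time = 0, amt = -1), 0:5),
               "amounts")
  expect_error(simulate_pk(cfg, data.frame(time = c(2, 1), amt = c(1, 1)),
                           0:5), "increasing")
  expect_error(pk_config(cl = -5), "positive")
})

test_that("effect compartment equilibrates at the first-order rate", {
  tt <- seq(0, 10, 0.01)
  # step input: half-equilibration at log(2)/ke0
  ce <- effect_compartment(tt, rep(1, length(tt)), ke0 = 1.25)
  t_half <- tt[which.min(abs(ce - 0.5))]
  expect_lt(abs(t_half - log(2) / 1.25), 0.02)
  # 95% attained by ~3/ke0
  expect_gt(ce[which.min(abs(tt - 3 / 1.25))], 0.94)
  # zero plasma gives zero effect site
  expect_equal(effect_compartment(tt, rep(0, length(tt)), 1.25),
               rep(0, length(tt)))
  expect_error(effect_compartment(tt, rep(1, length(tt)), 0), "ke0")
})

test_that("cumulative exposure is a unit-converted running trapezoid", {
  tt <- seq(0, 10, 0.5)
  # constant 1 ug/L over 10 h -> 0.01 mg*h/L
  ex <- cumulative_exposure(tt, rep(1, length(tt)))
  expect_equal(ex[1], 0)
  expect_equal(ex[length(ex)], 0.01)
  expect_true(all(diff(ex) >= 0))
  # hand-computed 3-point piecewise-linear profile
  t3 <- c(0, 2, 6)
  cp3 <- c(0, 4, 1)
  ex3 <- cumulative_exposure(t3, cp3)
  expect_equal(ex3, c(0, 4, 14) * 1e-3)
})
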