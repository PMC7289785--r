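test_that("grid regularisation relabels the documented post-dose points", {
  # 15- and 30-min points shift to 20 and 40 min after dosing
  tt <- c(seq(-2, 0, 1 / 3), 0.25, 0.5, seq(1, 3, 1 / 3))
  vv <- seq_along(tt)
  ser <- regularize_grid(tt, vv, dose_time = 0)
  expect_s3_class(ser, "uniform_series")
  expect_equal(diff(ser$times), rep(1 / 3, length(tt) - 1))
  expect_true(all(abs(ser$times[8:9] - c(1 / 3, 2 / 3)) < 1e-9))
  # values are never altered
  expect_equal(sort(ser$values), sort(vv))

  # already-uniform series pass through unchanged
  t2 <- seq(0, 4, 1 / 3)
  s2 <- regularize_grid(t2, seq_along(t2))
  expect_equal(s2$times, t2)

  # duplicate after the shift is an error
  t3 <- c(0, 1 / 3, 0.25 + 1 / 12)  # 1/3 after shiftless path duplicates
  expect_error(regularize_grid(c(0, 0.25, 1 / 3), c(1, 2, 3),
                               dose_time = 0), "duplicate")
  # undeclared off-grid point is an error naming the time
  expect_error(regularize_grid(c(0, 0.15, 2 / 3), c(1, 2, 3),
                               dose_time = 0), "0.15")
  expect_error(regularize_grid(c(0, 0.25, 2 / 3), c(1, 2, 3)),
               "no dose_time")
})

test_that("noise-free profiles deconvolve exactly", {
  p <- gh_params()
  tt <- seq(0, 12, 1 / 3)
  truth <- data.frame(location = c(2, 6, 10), mass = c(2, 1.2, 3))
  y <- gh_concentration(p, truth, tt)
  f <- deconvolve(regularize_grid(tt, y))
  expect_equal(nrow(f$events), 3)
  expect_true(all(abs(f$events$location - truth$location) < 1 / 3))
  expect_equal(f$kel, p$kel, tolerance = 0.02)
  expect_equal(f$width, p$width, tolerance = 0.05)
  expect_equal(f$basal, p$baseline * p$kel, tolerance = 0.05)
})

test_that("constant series yield no events and a basal-only model", {
  tt <- seq(0, 12, 1 / 3)
  f <- deconvolve(regularize_grid(tt, rep(0.05, length(tt))))
  expect_equal(nrow(f$events), 0)
  # basal = mean * k_el at whatever k the flat fit settles on
  expect_equal(f$basal / f$kel, 0.05, tolerance = 1e-3)
  expect_error(deconvolve(list(times = 1:4 / 3, values = rep(1, 4))),
               ">= 6")
})

test_that("event count is stable when refitting the model's own curve", {
  p <- gh_params()
  tt <- seq(0, 12, 1 / 3)
  y <- gh_concentration(p, data.frame(location = c(2, 7), mass = c(2, 2.5)),
                        tt)
  f1 <- deconvolve(regularize_grid(tt, y))
  # noise-free data from the fitted model deconvolve to the same events
  f2 <- deconvolve(regularize_grid(tt, f1$fitted))
  expect_equal(nrow(f2$events), nrow(f1$events))
  expect_equal(sort(f2$events$location), sort(f1$events$location),
               tolerance = 0.05)
})

test_that("elimination rate is recovered across noisy replicates", {
  set.seed(33)
  p <- gh_params()
  ratios <- replicate(20, {
    tt <- seq(0, 12, 1 / 3)
    pt <- generate_pulse_times(14, start = -2)
    mass <- p$amplitude * exp(rnorm(length(pt), 0, 1))  # moderate spread
    y <- gh_concentration(p, data.frame(location = pt, mass = mass), tt)
    y <- lloq_substitute(y * (1 + rnorm(length(tt), 0, 0.15)))$value
    deconvolve(regularize_grid(tt, y))$kel / p$kel
  })
  expect_lt(abs(median(ratios) - 1), 0.15)
})

test_that("gap augmentation inserts midpoints once per long gap", {
  ev <- data.frame(location = c(100, 420) / 60, mass = c(1, 1),
                   width = 0.18, p = 0, augmented = FALSE)
  out <- augment_gaps(ev)                     # gap 320 min > 300
  expect_equal(nrow(out), 3)
  expect_equal(out$location[2], 260 / 60)
  expect_true(out$augmented[2] && is.na(out$mass[2]))

  ev2 <- data.frame(location = c(100, 390) / 60)  # gap 290 <= 300
  expect_equal(nrow(augment_gaps(ev2)), 2)

  # one insertion per original gap, never recursive
  ev3 <- data.frame(location = c(0, 640) / 60)
  out3 <- augment_gaps(ev3)
  expect_equal(nrow(out3), 3)
  expect_equal(out3$location[2], 320 / 60)

  # idempotent once every gap is below threshold
  out4 <- augment_gaps(out)
  expect_equal(nrow(out4), nrow(out))
})

test_that("pulse-frequency comparison is a Poisson offset model", {
  same <- data.frame(count = rep(8, 20), group = rep(c("a", "b"), each = 10),
                     duration = 12)
  r <- pulse_frequency_test(same)
  expect_equal(r$rate_ratio, 1)
  expect_gt(r$p, 0.99)

  # identity comparison of a group with itself
  r2 <- pulse_frequency_test(data.frame(count = c(5, 7, 5, 7),
                                        group = rep(c("a", "a2"),
                                                    each = 2)))
  expect_equal(r2$rate_ratio, 1, tolerance = 1e-9)

  expect_error(pulse_frequency_test(data.frame(count = 1:3, group = "a")),
               ">= 2 groups")
  expect_error(pulse_frequency_test(
    data.frame(count = c(0, 0, 5), group = c("a", "a", "b"))),
    "zero total counts")
})

test_that("the Poisson test has power at a rate ratio of 0.5", {
  set.seed(14)
  hits <- replicate(200, {
    d <- data.frame(count = c(rpois(50, 8), rpois(50, 4)),
                    group = rep(c("ref", "trt"), each = 50),
                    duration = 1)
    pulse_frequency_test(d)$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})
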