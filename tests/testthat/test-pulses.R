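test_that("pulse generator degenerate and reproducibility contracts", {
  expect_equal(generate_pulse_times(0), numeric(0))
  set.seed(11)
  a <- generate_pulse_times(24)
  set.seed(11)
  b <- generate_pulse_times(24)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a < 24))
  expect_true(all(diff(a) > 0))
})

test_that("renewal law reproduces the printed placebo interval statistics", {
  set.seed(42)
  iv <- numeric(0)
  while (length(iv) < 1e4) {
    p <- generate_pulse_times(200)
    iv <- c(iv, diff(p) * 60)
  }
  iv <- iv[seq_len(1e4)]
  q <- quantile(iv, c(0.25, 0.5, 0.75))
  expect_lt(abs(q[[2]] - 74) / 74, 0.10)     # median 74 min
  expect_lt(abs(q[[1]] - 44) / 44, 0.20)     # IQR 44 - 160 min
  expect_lt(abs(q[[3]] - 160) / 160, 0.20)
})

test_that("interval summaries are order statistics of pooled intervals", {
  # locations 0 cumulated from the printed intervals
  f <- list(cumsum(c(0, 44, 74, 160)) / 60)
  s <- interval_summary(f)
  expect_equal(s[["median"]], 74)
  s1 <- interval_summary(list(c(0, 1)))
  expect_true(all(s1 == 60))
  expect_error(interval_summary(list(5)), "no inter-pulse")
})

test_that("generator and interval summary round-trip at the calibrated law", {
  set.seed(7)
  fits <- replicate(200, generate_pulse_times(14, start = -2),
                    simplify = FALSE)
  s <- interval_summary(fits)
  expect_lt(abs(s[["median"]] - 74) / 74, 0.10)
})
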