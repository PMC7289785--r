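test_that("published regimens are reproduced", {
  d <- build_design("1.0 mg b.i.d.")
  # twice daily at 8 h / 16 h intervals over 13 days
  expect_equal(d$doses$time[1:3], c(2, 10, 26))
  expect_equal(diff(d$doses$time)[1:4], c(8, 16, 8, 16))
  expect_equal(nrow(d$doses), 26)
  expect_true(all(d$doses$amt == 1.0))
  expect_equal(d$occasions$day, c(7, 12))

  qd <- build_design("1.2mg-qd")
  expect_equal(diff(qd$doses$time), rep(24, 12))
  expect_equal(nrow(qd$doses), 13)

  sad <- build_design("1.5 mg S.A.D.")
  expect_equal(nrow(sad$doses), 1)
  st <- sad$sampling[[1]] - sad$occasions$dose_time[1]
  expect_equal(min(st), -2)
  expect_equal(max(st), 12)
  # first post-dose hour follows the PK schedule: 15, 30, 60 min
  expect_true(all(c(0.25, 0.5, 1) %in% round(st, 6)))
  expect_false(any(abs(st - 1 / 3) < 1e-9))
  # 20-min grid elsewhere
  expect_true(all(abs(diff(st[st > 1])[1] - 1 / 3) < 1e-9))
})

test_that("placebo designs carry the full schedule and no doses", {
  p <- build_design("placebo")
  expect_equal(nrow(p$doses), 0)
  expect_equal(length(p$sampling[[1]]), 43)
  pm <- build_design("placebo-mad")
  expect_equal(nrow(pm$doses), 0)
  expect_equal(pm$occasions$day, c(7, 12))
  expect_equal(length(pm$sampling[[1]]), 37)
})

test_that("unknown cohorts are a configuration error", {
  expect_error(build_design("2.0mg-sad"), "unknown cohort")
  expect_error(build_design("nonsense"), "unknown cohort")
})
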