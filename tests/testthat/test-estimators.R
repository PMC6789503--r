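test_that("ratiometric estimator averages per-replicate ratios", {
  expect_equal(ratio_estimate(replicate_set(c(1, 2, 4), c(10, 20, 40)))$activity, 10)
  expect_equal(ratio_estimate(replicate_set(c(1, 2), c(3, 8)))$activity, 3.5)
  expect_equal(ratio_estimate(replicate_set(5, 60))$activity, 12)
  # negative Renilla values are included as-is, zeros are an error
  expect_equal(ratio_estimate(replicate_set(c(-1, 2), c(2, 2)))$activity, -0.5)
  expect_error(ratio_estimate(replicate_set(c(1, 0, 2), c(1, 1, 1))),
               "replicate\\(s\\) 2")
})

test_that("through-origin OLS matches the normal equation and a grid oracle", {
  expect_equal(ols_estimate(replicate_set(c(1, 2), c(1, 5)))$activity, 11 / 5)
  expect_equal(ols_estimate(replicate_set(2, 8))$activity, 4)
  r <- c(1, 3, 7); expect_equal(ols_estimate(replicate_set(r, 2 * r))$activity, 2)
  expect_error(ols_estimate(replicate_set(c(0, 0), c(1, 2))), "slope is undefined")
  # dense grid minimization of the vertical objective agrees with closed form
  for (seed in 1:5) {
    fx <- random_fixture(seed)
    a_grid <- seq(0, 10, by = 1e-4)
    obj <- vapply(a_grid, function(a) sum((fx$data$firefly - a * fx$data$renilla)^2),
                  numeric(1))
    expect_lt(abs(ols_estimate(fx$data)$activity - a_grid[which.min(obj)]), 1e-3)
  }
})

test_that("EIV closed form solves the orthogonal problem", {
  # zero orthogonal residuals
  r <- c(1, 2, 5); expect_equal(eiv_estimate(replicate_set(r, 3 * r))$activity, 3)
  # positive root of the quadratic: (2 + sqrt(20)) / 4
  est <- eiv_estimate(replicate_set(c(1, 1), c(0, 2)))
  expect_equal(est$activity, (2 + sqrt(20)) / 4, tolerance = 1e-12)
  expect_lt(abs(est$activity - eiv_grid_oracle(replicate_set(c(1, 1), c(0, 2)))),
            1e-3)
  # degenerate orientation
  expect_error(eiv_estimate(replicate_set(c(1, -1), c(1, 1))),
               "orientation undefined")
})

test_that("EIV transposition: swapping axes inverts the slope", {
  for (seed in 1:10) {
    fx <- random_fixture(seed)
    a <- eiv_estimate(fx$data)$activity
    a_swapped <- eiv_estimate(replicate_set(fx$data$firefly, fx$data$renilla))$activity
    expect_gt(a, 0)
    expect_equal(a_swapped, 1 / a, tolerance = 1e-9)
  }
})

test_that("EIV slope lies between the forward and inverse OLS slopes", {
  for (seed in 11:20) {
    fx <- random_fixture(seed)
    r <- fx$data$renilla; f <- fx$data$firefly
    sxx <- sum(r^2); syy <- sum(f^2); sxy <- sum(r * f)
    expect_gt(sxy, 0)
    a <- eiv_estimate(fx$data)$activity
    expect_gte(a, sxy / sxx - 1e-12)
    expect_lte(a, syy / sxy + 1e-12)
  }
})

test_that("all four estimators agree on exactly collinear positive-slope data", {
  r <- c(2, 4, 5, 9)
  rs <- replicate_set(r, 7 * r)
  for (m in c("ratio", "ols", "eiv", "reiv")) {
    expect_equal(get_estimator(m)(rs)$activity, 7, tolerance = 1e-9, label = m)
  }
})

test_that("REIV returns a degenerate zero-scale fit on collinear data", {
  r <- c(1, 2, 3, 4)
  est <- reiv_estimate(replicate_set(r, 5 * r))
  expect_equal(est$activity, 5)
  expect_identical(est$scale, 0)
  expect_true(est$degenerate)
})

test_that("REIV resists a gross outlier that corrupts OLS and EIV", {
  rs <- outlier_fixture()
  reiv <- reiv_estimate(rs)$activity
  ols <- ols_estimate(rs)$activity
  expect_lt(abs(reiv - 3), abs(ols - 3))
  expect_lt(abs(reiv - 3), 0.05)
  # 2-D oracle: no (slope, scale) pair on a lattice with the scale re-solved
  # per slope beats the returned fit's profiled scale
  a_grid <- seq(0.5, 15, by = 0.05)
  s_grid <- vapply(a_grid, function(a) {
    estimate_scale((rs$firefly - a * rs$renilla) / sqrt(1 + a^2))$s
  }, numeric(1))
  est <- reiv_estimate(rs)
  s_ret <- estimate_scale((rs$firefly - est$activity * rs$renilla) /
                            sqrt(1 + est$activity^2))$s
  # the grid hits the collinear slope A = 3 exactly, where the profiled scale
  # is exactly 0; the returned fit matches it to the optimizer's tolerance
  expect_lte(s_ret, min(s_grid) + 1e-4)
})

test_that("REIV tracks EIV on clean data", {
  set.seed(101)
  cfg <- simulation_config(true_activity = 10, n = 10, tbar = 0.75,
                           sigma11 = 3, sigma12 = 3)
  diffs <- replicate(100, {
    d <- simulate_experiment(cfg)
    reiv_estimate(d)$activity - eiv_estimate(d)$activity
  })
  # spread of the EIV estimate itself at these settings is ~0.5; the robust
  # fit must sit well inside that sampling spread
  expect_lt(stats::median(abs(diffs)), 0.1)
  expect_lt(max(abs(diffs)), 1)
})

test_that("EIV and REIV are equivariant under joint rescaling", {
  fx <- random_fixture(33)
  lambda <- 4.2
  scaled <- replicate_set(lambda * fx$data$renilla, lambda * fx$data$firefly)
  expect_equal(eiv_estimate(scaled)$activity, eiv_estimate(fx$data)$activity,
               tolerance = 1e-9)
  e1 <- reiv_estimate(fx$data); e2 <- reiv_estimate(scaled)
  expect_equal(e2$activity, e1$activity, tolerance = 1e-5)
  expect_equal(e2$scale, lambda * e1$scale, tolerance = 1e-4)
})

test_that("REIV requires at least two replicates", {
  expect_error(reiv_estimate(replicate_set(2, 6)), "at least 2 replicates")
})

test_that("replicate_set validates its inputs", {
  expect_error(replicate_set(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(replicate_set(numeric(0), numeric(0)), "at least one")
  expect_error(replicate_set(c(1, NA), c(1, 2)), "finite")
})
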