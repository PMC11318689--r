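test_that("decimation preserves DC and passband signals", {
  # DC preservation
  y <- decimate_series(rep(5, 2500), 250, 25)
  expect_length(y, 250)
  expect_equal(y, rep(5, 250), tolerance = 1e-6)
  # identity when rates match
  x <- rnorm(100)
  expect_identical(decimate_series(x, 25, 25), x)
  # 1 Hz sine at 250 Hz -> 25 Hz sine, amplitude within 1%
  t_in <- (0:(250 * 10 - 1)) / 250
  y <- decimate_series(sin(2 * pi * 1 * t_in), 250, 25)
  t_out <- (seq_along(y) - 1) / 25
  ref <- sin(2 * pi * 1 * t_out)
  core <- 26:(length(y) - 25)  # ignore filter edge transients
  expect_lt(max(abs(y[core] - ref[core])), 0.01)
  expect_error(decimate_series(x, 10, 25), "fs_in")
})

test_that("MSA matches hand computations and is orientation invariant", {
  expect_equal(compute_msa(rbind(c(0, 0, 9.81))), 0)
  expect_equal(compute_msa(rbind(c(0, 0, 19.62))), 9.81)
  expect_equal(compute_msa(rbind(c(3, 4, 0))), abs(5 - 9.81))
  # rotation invariance: random rotations leave MSA unchanged
  set.seed(1)
  acc <- matrix(rnorm(300, sd = 4), ncol = 3)
  base <- compute_msa(acc)
  for (i in 1:5) {
    qr_dec <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_dec)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    expect_equal(compute_msa(acc %*% R), base, tolerance = 1e-10)
  }
})

test_that("upper-percentile winsorization caps spikes and is idempotent", {
  expect_identical(trim_upper_percentile(rep(2, 50)), rep(2, 50))
  x <- 1:100
  y <- trim_upper_percentile(x, 95)
  cap <- sort(x)[ceiling(0.95 * length(x))]  # order-statistic oracle: 95
  expect_equal(max(y), cap)
  expect_equal(y[96:100], rep(cap, 5))
  expect_identical(y[1:95], as.numeric(1:95))
  expect_true(all(y <= x))
  # exact idempotence: capping at an order statistic leaves it in place
  expect_identical(trim_upper_percentile(y, 95), y)
  set.seed(8)
  z <- rlnorm(500)
  expect_identical(trim_upper_percentile(trim_upper_percentile(z)),
                   trim_upper_percentile(z))
  expect_error(trim_upper_percentile(x, 0), "p must")
  expect_error(trim_upper_percentile(x, 100), "p must")
})

test_that("pitch and roll follow the stated axis conventions", {
  level <- matrix(rep(c(0, 0, 9.81), each = 30), ncol = 3)
  pr <- estimate_pitch_roll(level, fs = 25, window = 1)
  expect_equal(pr$pitch, rep(0, 30), tolerance = 1e-12)
  expect_equal(pr$roll, rep(0, 30), tolerance = 1e-12)
  nose_up <- matrix(rep(c(-9.81, 0, 0), each = 30), ncol = 3)
  pr <- estimate_pitch_roll(nose_up, fs = 25, window = 1)
  expect_equal(pr$pitch, rep(pi / 2, 30), tolerance = 1e-9)
  rolled <- matrix(rep(c(0, 9.81, 0), each = 30), ncol = 3)
  pr <- estimate_pitch_roll(rolled, fs = 25, window = 1)
  expect_equal(pr$roll, rep(pi / 2, 30), tolerance = 1e-9)
  expect_true(all(pr$pitch >= -pi / 2 - 1e-12 & pr$pitch <= pi / 2 + 1e-12))
})

test_that("circular variance matches vector-mean oracle and is rotation invariant", {
  expect_equal(circular_variance(rep(1.3, 10)), 0)
  expect_equal(circular_variance(c(0, pi / 2, pi, 3 * pi / 2)), 1, tolerance = 1e-12)
  expect_equal(circular_variance(c(0, pi / 2)), 1 - sqrt(2) / 2, tolerance = 1e-12)
  set.seed(2)
  ang <- runif(50, -pi, pi)
  base <- circular_variance(ang)
  for (shift in c(0.3, 1.7, -2.5)) {
    expect_equal(circular_variance(ang + shift), base, tolerance = 1e-12)
  }
  expect_error(circular_variance(numeric(0)), "empty")
})

test_that("deployment-start trimming keeps the original clock and boundary samples", {
  rec <- list(time = seq(0, 7200, by = 0.04),
              depth = runif(180001),
              events = NULL)
  out <- trim_deployment_start(rec, 3600)
  expect_equal(out$time[1], 3600)              # half-open: t = cut retained
  expect_equal(max(out$time), 7200)
  expect_false(any(out$time < 3600))
  expect_length(out$depth, length(out$time))
  short <- list(time = seq(0, 1800, by = 0.04), depth = numeric(45001))
  expect_error(trim_deployment_start(short, 3600), "not longer")
})
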