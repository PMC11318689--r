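test_that("interval summaries enforce the purity retention rule", {
  # one pure window and one 60/40 window
  cyc <- data.frame(
    dive_start = c(0, 600, 1200, 1920),
    next_dive_start = c(600, 1200, 1920, 2400),
    cycle_duration = c(600, 600, 720, 480),
    state = c("pelagic", "pelagic", "pelagic", "nonfeeding")
  )
  out <- summarize_intervals(cyc, resp_times = c(5, 300, 1300),
                             buzzes = data.frame(start = 100, end = 100.5),
                             width = 1200)
  expect_identical(nrow(out), 2L)
  expect_true(out$retained[1])            # 100% pelagic
  expect_identical(out$majority_state[2], "pelagic")
  expect_equal(out$purity[2], 0.6)
  expect_false(out$retained[2])           # 0.60 <= 0.75
  expect_identical(out$n_respirations[1], 2L)
  expect_identical(out$n_buzzes[1], 1L)
  expect_error(summarize_intervals(cyc[, -4], 1, data.frame(start = 1, end = 2)),
               "decoded states")
})

test_that("retained fraction falls as state persistence drops", {
  set.seed(61)
  mk_cycles <- function(stay) {
    tpm <- matrix((1 - stay) / 2, 3, 3)
    diag(tpm) <- stay
    s <- simulate_state_chain(tpm, 600)
    start <- cumsum(c(0, rep(80, 599)))
    data.frame(dive_start = start, next_dive_start = start + 80,
               cycle_duration = 80, state = c("a", "b", "c")[s])
  }
  retained <- sapply(c(0.95, 0.8, 0.5), function(stay) {
    out <- summarize_intervals(mk_cycles(stay), numeric(0),
                               data.frame(start = numeric(0), end = numeric(0)))
    mean(out$retained)
  })
  expect_true(all(diff(retained) < 0))
})

test_that("nonfeeding normalization maps the reference median to one", {
  expect_equal(normalize_by_nonfeeding(rep(4, 6), rep(4, 10)), rep(1, 6))
  expect_equal(normalize_by_nonfeeding(c(1, 2, 3), c(1, 2, 3)), c(0.5, 1, 1.5))
  expect_error(normalize_by_nonfeeding(1:3, numeric(0)), "no nonfeeding")
  expect_error(normalize_by_nonfeeding(1:3, c(0, 0)), "zero")
})

test_that("activity-specific FMR reproduces the worked example and conserves energy", {
  f <- c(nonfeeding = 0.38, pelagic = 0.37, bottom = 0.25)
  m <- c(1, 1.22, 1.09)
  fmr <- activity_specific_fmr(15, f, m)
  # exact arithmetic: 566.17 and 690.73, matching the published 567/692 to
  # printed precision
  expect_equal(unname(fmr["nonfeeding"]), 625 / sum(f * m), tolerance = 1e-12)
  expect_equal(unname(fmr["nonfeeding"]), 567, tolerance = 0.005)
  expect_equal(unname(fmr["pelagic"]), 692, tolerance = 0.005)
  # all-equal multipliers: every state at the average hourly rate
  flat <- activity_specific_fmr(15, f, c(1, 1, 1))
  expect_equal(unname(flat), rep(625, 3))
  expect_equal(unname(activity_specific_fmr(15, c(a = 1), 1)), 625)
  # conservation: time-weighted rates integrate back to the daily FMR
  expect_equal(sum(f * fmr) * 24 / 1000, 15, tolerance = 1e-9)
  expect_error(activity_specific_fmr(15, c(0.5, 0.4), c(1, 1)), "sum to 1")
})

test_that("foraging efficiency follows the marginal-cost definition", {
  f <- c(0.38, 0.37, 0.25)
  fmrs <- c(567, 692, 613)
  eff <- foraging_efficiency(17, 0.9, fmrs, f, gross = TRUE)
  # hand computation: 17000 / ((660.1 - 567) * 14.88)
  expect_equal(eff, 17000 / ((sum(fmrs[2:3] * f[2:3]) / 0.62 - 567) * 14.88),
               tolerance = 1e-9)
  expect_equal(eff, 12.3, tolerance = 0.01)
  expect_equal(foraging_efficiency(17, 0.9, fmrs, f, gross = FALSE),
               eff * 0.9, tolerance = 1e-9)
  expect_equal(foraging_efficiency(0, 0.9, fmrs, f), 0)
  expect_error(foraging_efficiency(17, 0.9, c(600, 600, 600), f), "marginal")
})

test_that("energy balance closes to zero and tracks event ordering", {
  set.seed(62)
  p <- energy_params()
  for (i in 1:10) {
    resp <- sort(runif(sample(20:200, 1), 0, 86400))
    buzz <- sort(runif(sample(5:100, 1), 0, 86400))
    bal <- energy_balance(resp, buzz, p, 24)
    expect_lt(abs(bal$balance[length(bal$balance)]), 1e-9 * p$daily_fmr)
  }
  # uniform respirations, buzzes only in the second half: deficit first
  resp <- seq(100, 86300, length.out = 100)
  buzz <- seq(44000, 86000, length.out = 50)
  bal <- energy_balance(resp, buzz, p, 24)
  first_half <- bal$balance[bal$times < 43200]
  expect_true(all(first_half < 0))
  # implied gross prey mass per buzz at the canonical daily rates
  b24 <- energy_balance(resp, sort(runif(2396, 0, 86400)), p, 24)
  expect_equal(b24$prey_g_per_buzz, (15000 / 0.9 / 2396) / 4.2, tolerance = 1e-9)
  expect_error(energy_balance(resp, numeric(0), p, 24), "zero buzzes")
})

test_that("metabolic scope rounds half away from zero to one decimal", {
  expect_equal(metabolic_scope(11.0, 0.9), 12.2)
  expect_equal(metabolic_scope(2.1, 0.7), 3.0)
  expect_equal(metabolic_scope(3.14, 3.14), 1.0)
  expect_equal(metabolic_scope(1.25, 1), 1.3)   # half-away rounding
  expect_error(metabolic_scope(-1, 0.5), "positive")
})

test_that("SDA concentrated into foraging time elevates foraging FMR", {
  expect_equal(sda_scenario(0.125, 1.0), 0.125)
  expect_equal(sda_scenario(0.125, 0.62), 0.2016, tolerance = 1e-3)
  expect_equal(sda_scenario(0.125, 0.52), 0.2404, tolerance = 1e-3)
  expect_error(sda_scenario(0.125, 0), "0, 1")
})

test_that("energy parameter validation rejects impossible values", {
  expect_error(energy_params(daily_fmr = -1), "positive")
  expect_error(energy_params(assimilation = 1.2), "0, 1")
  p <- energy_params(daily_fmr = 20)
  expect_equal(p$daily_fmr, 20)
  expect_equal(p$prey_energy_density, 4.2)
})
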