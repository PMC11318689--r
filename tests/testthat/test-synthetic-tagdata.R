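test_that("deployment generation is deterministic under a fixed seed", {
  cfg <- gen_config(duration_h = 1.5, seed = 42)
  a <- generate_deployment(cfg)
  b <- generate_deployment(cfg)
  expect_identical(a$record, b$record)
  expect_identical(a$truth, b$truth)
})

test_that("zero buzz rates yield zero clicks and zero buzzes", {
  cfg <- gen_config(duration_h = 1.5, seed = 3)
  cfg$states$buzz_rate <- rep(0, 3)
  sim <- generate_deployment(cfg)
  expect_identical(nrow(sim$truth$buzzes), 0L)
  expect_length(sim$truth$click_times, 0)
})

test_that("generated depth is physical: nonnegative, surface at both ends, dives as scheduled", {
  sim <- generate_deployment(gen_config(duration_h = 1.5, seed = 11))
  rec <- sim$record
  expect_true(all(rec$depth >= 0))
  expect_lt(rec$depth[1], 0.5)
  expect_lt(rec$depth[length(rec$depth)], 0.5)
  # each true dive's rendered maximum matches the scheduled maximum depth
  for (i in seq_len(nrow(sim$truth$dives))) {
    idx <- rec$time >= sim$truth$dives$start[i] & rec$time < sim$truth$dives$end[i]
    expect_equal(max(rec$depth[idx]), sim$truth$dives$max_depth[i],
                 tolerance = 1e-6)
  }
  # clicks only inside scheduled buzz intervals
  if (length(sim$truth$click_times) > 0) {
    inside <- sapply(sim$truth$click_times, function(tc) {
      any(tc >= sim$truth$buzzes$start & tc < sim$truth$buzzes$end)
    })
    expect_true(all(inside))
  }
})

test_that("state chain frequencies match the stationary distribution (eigen oracle)", {
  tpm <- matrix(c(0.7, 0.2, 0.1,
                  0.15, 0.7, 0.15,
                  0.1, 0.3, 0.6), 3, byrow = TRUE)
  pi_star <- stationary_distribution(tpm)
  expect_equal(as.numeric(pi_star %*% tpm), as.numeric(pi_star), tolerance = 1e-12)
  set.seed(99)
  s <- simulate_state_chain(tpm, 10000)
  freq <- tabulate(s, 3) / 10000
  # 3 Monte-Carlo SEs; the chain is autocorrelated so inflate the iid SE by
  # the integrated autocorrelation bound for a persistence-0.7 chain
  se <- sqrt(pi_star * (1 - pi_star) / 10000) * sqrt((1 + 0.7) / (1 - 0.7))
  expect_true(all(abs(freq - pi_star) < 3 * se))
})

test_that("per-dive mean MSA tracks the active state's activity level", {
  sim <- generate_deployment(gen_config(duration_h = 2, seed = 5))
  rec <- sim$record
  msa <- compute_msa(rec$acc)
  st <- sim$truth$dives$state
  per_dive <- sapply(seq_len(nrow(sim$truth$dives)), function(i) {
    idx <- rec$time >= sim$truth$dives$start[i] & rec$time < sim$truth$dives$end[i]
    mean(msa[idx])
  })
  cfg_act <- gen_config()$states$activity
  for (k in unique(st)) {
    if (sum(st == k) >= 5) {
      expect_equal(mean(per_dive[st == k]), cfg_act[k], tolerance = 0.25)
    }
  }
})

test_that("dive durations configured to a bottom-feeding mean are recovered", {
  # single-state generator parameterized at a 77.5 s mean dive duration
  states <- data.frame(
    name = "bottom", dur_mean = 77.5, dur_sd = 26, depth_mean = 11.6,
    depth_sd = 4.3, surface_mean = 34.4, buzz_rate = 1.6, resp_rate = 2.7,
    activity = 1.9, activity_cv = 0.25, bottom_fraction = 0.4,
    buzz_at_bottom = TRUE, stringsAsFactors = FALSE
  )
  cfg <- gen_config(n_states = 1, states = states, duration_h = 6, seed = 21)
  sim <- generate_deployment(cfg)
  durs <- sim$truth$dives$end - sim$truth$dives$start
  expect_gt(length(durs), 100)
  se <- sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - 77.5), 2 * se)
})

test_that("respiration and buzz counts match their configured rates", {
  # day-only window so the night multiplier is inert
  cfg <- gen_config(duration_h = 5, seed = 13, t0_clock_s = 7 * 3600)
  sim <- generate_deployment(cfg)
  tr <- sim$truth
  st <- gen_config()$states
  dive_dur <- tr$dives$end - tr$dives$start
  cyc_dur <- diff(tr$dives$start)
  cyc_state <- tr$dives$state[-nrow(tr$dives)]
  expect_gt(length(cyc_dur), 100)
  # respirations over interior cycles vs Poisson expectation
  n_resp <- sum(tr$resp_times >= tr$dives$start[1] &
                  tr$resp_times < tr$dives$start[nrow(tr$dives)])
  lambda_resp <- sum(st$resp_rate[cyc_state] * cyc_dur / 60)
  expect_lt(abs(n_resp - lambda_resp), 3 * sqrt(lambda_resp) + 0.05 * lambda_resp)
  # buzzes vs Poisson expectation over dive time
  lambda_buzz <- sum(st$buzz_rate[tr$dives$state] * dive_dur / 60)
  expect_lt(abs(nrow(tr$buzzes) - lambda_buzz), 3 * sqrt(lambda_buzz))
})

test_that("dive profile construction meets its contract", {
  d <- render_dive_profile(60, 10, 0.5, 25)
  expect_length(d, 1500)
  expect_equal(max(d), 10)
  expect_lt(d[1], 0.5)
  expect_lt(d[length(d)], 0.5)
  # V-shaped dive: exactly one sample at the maximum
  v <- render_dive_profile(60, 10, 0, 25)
  expect_identical(sum(v == max(v)), 1L)
  expect_equal(max(v), 10)
  # no interior surfacing segments (scan for depth < 0.5 away from edges)
  for (prof in list(d, v, render_dive_profile(33.3, 4.7, 0.2, 25))) {
    r <- rle(prof < 0.5)
    interior <- which(r$values)
    interior <- interior[interior != 1 & interior != length(r$values)]
    expect_length(interior, 0)
  }
  expect_error(render_dive_profile(60, 10, 0.5, -1), "fs")
  expect_error(render_dive_profile(-5, 10, 0.5, 25), "positive")
})

test_that("click trains satisfy the buzz ICI structure", {
  tr <- render_click_train(c(0, 0.5), 0.003, seed = 8)
  expect_identical(length(tr), 167L)
  expect_true(all(diff(tr) > 0))
  expect_true(all(diff(tr) < 0.010))
  expect_true(all(tr >= 0 & tr < 0.5))
  # short interval: sub-threshold train with warning
  expect_warning(short <- render_click_train(c(0, 0.012), 0.003, seed = 8),
                 "sub-threshold")
  expect_identical(length(short), 5L)
  # ICI >= 10 ms violates the buzz precondition
  expect_error(render_click_train(c(0, 1), 0.012), "0.010")
  # guarantee: interval of >= 101 mean ICIs always yields >= 101 clicks
  for (s in 1:20) {
    tr2 <- render_click_train(c(0, 101 * 0.003), 0.003, seed = s)
    expect_gte(length(tr2), 101)
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(gen_config(context_tpms = list(matrix(c(0.5, 0.4, 0.3, 0.7), 2)),
                          n_states = 2), "sum to 1")
  expect_error(gen_config(duration_h = 0), "positive")
  expect_error(gen_config(buzz_ici_mean = 0.011), "0.010")
  cfg <- gen_config()
  cfg$states$dur_mean[1] <- -5
  expect_error(validate_gen_config(cfg), "positive")
})

test_that("deployment CSV round trip preserves the record", {
  sim <- generate_deployment(gen_config(duration_h = 1.2, seed = 2))
  dir <- tempfile("dep")
  write_deployment_csv(sim, dir)
  rec <- read_sensor_record_csv(dir)
  expect_equal(rec$depth, sim$record$depth, tolerance = 1e-9)
  expect_equal(unname(rec$acc[, 2]), unname(sim$record$acc[, 2]), tolerance = 1e-9)
  expect_identical(rec$animal_id, sim$record$animal_id)
  unlink(dir, recursive = TRUE)
})
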