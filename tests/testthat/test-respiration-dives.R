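test_that("respiration detector finds one breath per surfacing", {
  fs <- 25
  time <- (0:999) / fs
  # constant shallow record: exactly one respiration, at the earliest
  # minimum-depth sample
  r <- detect_respirations(time, rep(0.3, 1000))
  expect_identical(r, 0)
  # two surfacings separated by a 2 m excursion
  depth <- c(rep(0.2, 200), rep(2, 400), rep(0.25, 400))
  r <- detect_respirations(time, depth)
  expect_length(r, 2)
  # all-deep record: empty with warning
  expect_warning(r0 <- detect_respirations(time, rep(5, 1000)), "no respirations")
  expect_length(r0, 0)
  # candidates closer than the minimum interval are dropped
  depth2 <- rep(1, 1000)
  depth2[100] <- 0.1   # t = 3.96
  depth2[105] <- 0.1   # t = 4.16, 0.2 s later -> dropped
  depth2[120] <- 0.1   # t = 4.76, 0.6 s after first -> kept
  r2 <- detect_respirations(time, depth2)
  expect_equal(r2, c(3.96, 4.76))
})

test_that("respiration detection is exact on synthetic deployments", {
  sim <- generate_deployment(gen_config(duration_h = 2, seed = 17))
  det <- detect_respirations(sim$record$time, sim$record$depth)
  st <- event_match_stats(det, sim$truth$resp_times)
  expect_equal(st$recall, 1)
  expect_equal(st$precision, 1)
})

test_that("IBIs tile the record between consecutive respirations", {
  fs <- 25
  time <- (0:2499) / fs
  depth <- rep(5, 2500)
  msa <- rep(1.5, 2500)
  resp <- c(10, 40, 75)
  ib <- build_ibis(resp, time, depth, msa)
  expect_identical(nrow(ib), 2L)
  expect_equal(ib$max_depth, c(5, 5))
  expect_equal(ib$mean_msa, c(1.5, 1.5))
  expect_equal(sum(ib$duration), max(resp) - min(resp))
  expect_identical(nrow(build_ibis(c(10), time, depth, msa)), 0L)
})

test_that("mixture classification separates well-separated dive and apnea clusters", {
  set.seed(5)
  n <- 400
  # apneas: short, shallow, quiet; dives: long, deep, active (>= 5 SD apart
  # in every log feature)
  apnea <- data.frame(duration = rlnorm(n, log(6), 0.2),
                      max_depth = rlnorm(n, log(0.9), 0.2),
                      mean_msa = rlnorm(n, log(0.4), 0.2))
  dive <- data.frame(duration = rlnorm(n, log(60), 0.2),
                     max_depth = rlnorm(n, log(8), 0.2),
                     mean_msa = rlnorm(n, log(2), 0.2))
  ib <- rbind(apnea, dive)
  ib$start <- seq_len(2 * n)
  ib$end <- ib$start + ib$duration
  truth <- rep(c("apnea", "dive"), each = n)
  out <- classify_dives(ib, seed = 1)
  expect_gte(mean(out$label == truth), 0.99)
  # every dive IBI is at least as deep as the median apnea on separated data
  expect_true(all(out$max_depth[out$label == "dive"] >=
                    median(out$max_depth[out$label == "apnea"])))
})

test_that("mixture labeling is scale invariant and deterministic", {
  set.seed(6)
  n <- 150
  ib <- data.frame(
    duration = c(rlnorm(n, log(6), 0.25), rlnorm(n, log(60), 0.25)),
    max_depth = c(rlnorm(n, log(0.9), 0.25), rlnorm(n, log(8), 0.25)),
    mean_msa = c(rlnorm(n, log(0.4), 0.25), rlnorm(n, log(2), 0.25))
  )
  a <- classify_dives(ib, seed = 3)
  b <- classify_dives(ib, seed = 3)
  expect_identical(a$label, b$label)
  # positive scaling of features shifts the log means but not the labels
  ib2 <- ib
  ib2$duration <- ib2$duration * 3.7
  ib2$max_depth <- ib2$max_depth * 0.4
  ib2$mean_msa <- ib2$mean_msa * 12
  c2 <- classify_dives(ib2, seed = 3)
  expect_identical(a$label, c2$label)
})

test_that("single-cluster data still yields a unique dive class", {
  set.seed(7)
  n <- 200
  ib <- data.frame(duration = rlnorm(n, log(30), 0.3),
                   max_depth = rlnorm(n, log(5), 0.3),
                   mean_msa = rlnorm(n, log(1.5), 0.3))
  out <- classify_dives(ib, seed = 2)
  expect_true(all(out$label %in% c("dive", "apnea")))
  expect_gte(sum(out$label == "dive"), 1)
  expect_error(classify_dives(ib[1:5, ]), ">= 10")
  ib$mean_msa <- 1.5
  expect_error(classify_dives(ib), "zero variance|degenerate")
})

test_that("paper-regime deployments classify dives as a minority of IBIs", {
  sim <- generate_deployment(gen_config(duration_h = 3, seed = 23))
  rec <- sim$record
  msa <- trim_upper_percentile(compute_msa(rec$acc), 95)
  resp <- detect_respirations(rec$time, rec$depth)
  ib <- classify_dives(build_ibis(resp, rec$time, rec$depth, msa), seed = 1)
  frac <- mean(ib$label == "dive")
  expect_lt(frac, 0.5)
  # and the labeled dives line up with the scheduled ones
  dives <- ib[ib$label == "dive", ]
  expect_equal(nrow(dives), nrow(sim$truth$dives), tolerance = 0.05)
})
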