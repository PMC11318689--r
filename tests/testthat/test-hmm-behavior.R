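test_that("emission log density matches closed forms and skips missing metrics", {
  m <- make_test_hmm()
  em <- m$emissions
  em$log_mean_msa <- rbind(mean = c(0, 1, 2), sd = c(1, 1, 1))
  em$buzz_present <- rbind(prob = c(0.5, 0.5, 0.5))
  x <- data.frame(log_mean_msa = 0, rel_buzz_depth = NA, circ_var_pitch = NA,
                  circ_var_roll = NA, prop_bottom = NA, prop_surface = NA,
                  circ_var_pitch_bottom = NA, buzz_present = 1)
  expect_equal(emission_logdensity(em, 1, x),
               -0.5 * log(2 * pi) + log(0.5), tolerance = 1e-12)
  # uniform beta contributes zero
  em$prop_bottom <- rbind(shape1 = c(1, 1, 1), shape2 = c(1, 1, 1))
  x$prop_bottom <- 0.37
  expect_equal(emission_logdensity(em, 1, x),
               -0.5 * log(2 * pi) + log(0.5), tolerance = 1e-12)
  # impossible Bernoulli observation is floored, not -Inf
  em$buzz_present <- rbind(prob = c(1, 0.5, 0.5))
  x$buzz_present <- 0
  v <- emission_logdensity(em, 1, x)
  expect_true(is.finite(v))
  expect_lte(v, -690)
  # support violations are named
  x$prop_bottom <- 1.5
  expect_error(emission_logdensity(em, 1, x), "prop_bottom")
})

test_that("sequence likelihood collapses correctly in degenerate cases", {
  set.seed(41)
  X <- random_metric_matrix(20)
  # K = 1: loglik equals the sum of emission log densities
  m1 <- random_test_hmm(1, 1)
  ref <- sum(sapply(seq_len(20), function(t) {
    emission_logdensity(m1$emissions, 1, X[t, , drop = FALSE])
  }))
  expect_equal(sequence_loglik(m1, list(X)), ref, tolerance = 1e-10)
  # C = 2 with identical TPMs equals the C = 1 value for any weights
  m2 <- random_test_hmm(2, 1)
  G <- m2$Gamma[[1]]
  m2c <- mixed_hmm(2, 2, list(G, G), c(0.3, 0.7), m2$emissions)
  expect_equal(sequence_loglik(m2c, list(X)), sequence_loglik(m2, list(X)),
               tolerance = 1e-10)
  expect_error(sequence_loglik(m2, list()), "empty")
})

test_that("forward recursion agrees with exhaustive path enumeration", {
  set.seed(42)
  X <- random_metric_matrix(4)
  m <- random_test_hmm(2, 2)
  expect_equal(sequence_loglik(m, list(X)), enum_loglik(m, list(X)),
               tolerance = 1e-8)
  # a handful of further shapes (the full 100-case sweep runs in the
  # acceptance suite)
  for (i in 1:5) {
    K <- sample(1:3, 1); C <- sample(1:2, 1); Tn <- sample(2:6, 1)
    mm <- random_test_hmm(K, C)
    XX <- random_metric_matrix(Tn)
    expect_equal(sequence_loglik(mm, list(XX)), enum_loglik(mm, list(XX)),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to permuting states with their emissions", {
  set.seed(43)
  m <- random_test_hmm(3, 1)
  X <- random_metric_matrix(30)
  perm <- c(3, 1, 2)
  emp <- lapply(m$emissions, function(p) p[, perm, drop = FALSE])
  Gp <- m$Gamma[[1]][perm, perm]
  mp <- mixed_hmm(3, 1, list(Gp), 1, emp)
  expect_equal(sequence_loglik(mp, list(X)), sequence_loglik(m, list(X)),
               tolerance = 1e-9)
})

test_that("K=1 fits recover closed-form Gaussian MLEs and AIC is consistent", {
  set.seed(44)
  m <- random_test_hmm(1, 1)
  sim <- simulate_hmm_data(m, 400, seed = 4)
  fit <- fit_mixed_hmm(sim$sequences, K = 1, C = 1, n_restarts = 2, seed = 2)
  mu_hat <- unname(fit$model$emissions$log_mean_msa["mean", 1])
  expect_equal(mu_hat, mean(sim$sequences[[1]][, "log_mean_msa"]),
               tolerance = 1e-4)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik, tolerance = 1e-9)
  # parameter count: 15K emissions + C*K*(K-1) transitions + (C-1) weights
  expect_identical(fit$n_params, 15)
})

test_that("restart search only improves with more restarts (nested seeds)", {
  set.seed(45)
  m <- make_test_hmm()
  sim <- simulate_hmm_data(m, rep(150, 2), seed = 6)
  f1 <- fit_mixed_hmm(sim$sequences, 3, 1, n_restarts = 1, seed = 9, maxit = 150)
  f3 <- fit_mixed_hmm(sim$sequences, 3, 1, n_restarts = 3, seed = 9, maxit = 150)
  expect_gte(f3$loglik, f1$loglik - 1e-6)
})

test_that("model selection minimizes AIC with parsimony tie-breaks", {
  mk <- function(aic, K, C) structure(list(aic = aic, K = K, C = C),
                                      class = "hmm_fit")
  expect_identical(select_model(list(mk(10, 2, 1)))$K, 2)
  picked <- select_model(list(mk(100, 4, 1), mk(100, 3, 1)))
  expect_identical(picked$K, 3)
  picked <- select_model(list(mk(100, 3, 2), mk(100, 3, 1)))
  expect_identical(picked$C, 1)
  picked <- select_model(list(mk(90, 4, 1), mk(100, 3, 1)))
  expect_identical(picked$K, 4)
  expect_error(select_model(list()), "no fits")
})

test_that("decoding handles the single-state edge case and names states", {
  set.seed(46)
  m1 <- random_test_hmm(1, 1)
  sim <- simulate_hmm_data(m1, 50, seed = 3)
  dec <- decode_states(m1, sim$sequences)
  expect_true(all(dec$states[[1]] == 1L))
  expect_identical(unique(dec$labels[[1]]), "state1")
  # 3-state naming: lowest buzz p = nonfeeding; of the rest, higher
  # rel-buzz-depth mean = bottom
  m3 <- make_test_hmm()
  nm <- state_name_map(m3)
  expect_identical(nm, c("nonfeeding", "pelagic", "bottom"))
})

test_that("context machinery is inert at C=1 and contexts are identifiable at C=2", {
  set.seed(47)
  G1 <- matrix(c(0.9, 0.05, 0.05, 0.05, 0.9, 0.05, 0.05, 0.05, 0.9), 3, byrow = TRUE)
  G2 <- matrix(1 / 3, 3, 3)
  em <- make_test_hmm()$emissions
  m <- mixed_hmm(3, 2, list(G1, G2), c(0.5, 0.5), em)
  sim <- simulate_hmm_data(m, rep(300, 6), seed = 12)
  dec <- decode_states(m, sim$sequences)
  expect_identical(dec$context, sim$contexts)
  expect_true(all(rowSums(dec$context_posterior) - 1 < 1e-9))
  # smoothing decode agrees with Viterbi on well-separated data
  dec2 <- decode_states(m, sim$sequences, method = "smoothing")
  agree <- mean(unlist(dec$states) == unlist(dec2$states))
  expect_gte(agree, 0.95)
})

test_that("simulated metric tables respect the missingness convention", {
  sim <- simulate_hmm_data(make_test_hmm(), rep(200, 2), seed = 5)
  for (X in sim$sequences) {
    expect_identical(is.na(X[, "rel_buzz_depth"]), X[, "buzz_present"] == 0)
    expect_false(anyNA(X[, "log_mean_msa"]))
  }
})

test_that("fitted models serialize to JSON with all parameters", {
  set.seed(48)
  m <- make_test_hmm()
  sim <- simulate_hmm_data(m, 200, seed = 7)
  fit <- fit_mixed_hmm(sim$sequences, 3, 1, n_restarts = 1, seed = 2, maxit = 100)
  path <- tempfile(fileext = ".json")
  write_hmm_json(fit, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(obj$K, 3L)
  expect_equal(obj$aic, fit$aic, tolerance = 1e-9)
  expect_length(obj$state_names, 3)
  unlink(path)
})
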