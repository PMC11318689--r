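# Shared fixtures and independent oracles for the suite.

# A well-separated 3-state, 1-context model used for recovery experiments.
make_test_hmm <- function(G = matrix(c(0.8, 0.1, 0.1,
                                       0.1, 0.8, 0.1,
                                       0.1, 0.1, 0.8), 3, byrow = TRUE)) {
  em <- list(
    log_mean_msa = rbind(mean = c(0.40, 0.90, 0.55), sd = c(0.15, 0.15, 0.15)),
    rel_buzz_depth = rbind(shape1 = c(2, 2, 12), shape2 = c(2, 4, 2)),
    circ_var_pitch = rbind(shape1 = c(2, 6, 4), shape2 = c(10, 6, 4)),
    circ_var_roll = rbind(shape1 = c(2, 5, 3), shape2 = c(12, 6, 6)),
    prop_bottom = rbind(shape1 = c(2, 3, 10), shape2 = c(10, 8, 5)),
    prop_surface = rbind(shape1 = c(8, 4, 3), shape2 = c(4, 6, 9)),
    circ_var_pitch_bottom = rbind(shape1 = c(2, 4, 6), shape2 = c(8, 6, 4)),
    buzz_present = rbind(prob = c(0.05, 0.90, 0.80))
  )
  mixed_hmm(3, 1, list(G), 1, em)
}

# Random valid mixed HMM for oracle-equivalence sweeps.
random_test_hmm <- function(K, C) {
  fam <- metric_families()
  em <- lapply(fam, function(f) {
    switch(f,
      gaussian = rbind(mean = rnorm(K), sd = runif(K, 0.2, 2)),
      beta = rbind(shape1 = runif(K, 0.5, 8), shape2 = runif(K, 0.5, 8)),
      bernoulli = rbind(prob = runif(K, 0.05, 0.95))
    )
  })
  names(em) <- names(fam)
  Gs <- lapply(seq_len(C), function(c) {
    G <- matrix(rgamma(K * K, 1) + 0.05, K)
    G / rowSums(G)
  })
  w <- rgamma(C, 2) + 0.1
  mixed_hmm(K, C, Gs, w / sum(w), em)
}

# Random metric matrix (all metrics observed, beta metrics interior).
random_metric_matrix <- function(Tn) {
  fam <- metric_families()
  X <- sapply(fam, function(f) {
    switch(f,
      gaussian = rnorm(Tn),
      beta = runif(Tn, 0.05, 0.95),
      bernoulli = rbinom(Tn, 1, 0.5)
    )
  })
  X <- matrix(X, nrow = Tn, dimnames = list(NULL, names(fam)))
  X
}

# Exhaustive-path oracle for the mixed-HMM likelihood: enumerates all K^T
# state paths for every context and sums probabilities directly.
enum_loglik <- function(model, sequences) {
  total <- 0
  for (X in sequences) {
    X <- as.matrix(as.data.frame(X)[, names(metric_families())])
    Tn <- nrow(X)
    K <- model$K
    dens <- matrix(0, Tn, K)
    for (t in seq_len(Tn)) {
      for (k in seq_len(K)) {
        dens[t, k] <- exp(emission_logdensity(model$emissions, k,
                                              X[t, , drop = FALSE]))
      }
    }
    lik_animal <- 0
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
    for (c in seq_len(model$C)) {
      G <- model$Gamma[[c]]
      d0 <- model$delta[[c]]
      lik_c <- 0
      for (r in seq_len(nrow(paths))) {
        s <- paths[r, ]
        p <- d0[s[1]] * dens[1, s[1]]
        if (Tn > 1) {
          for (t in 2:Tn) p <- p * G[s[t - 1], s[t]] * dens[t, s[t]]
        }
        lik_c <- lik_c + p
      }
      lik_animal <- lik_animal + model$weights[c] * lik_c
    }
    total <- total + log(lik_animal)
  }
  total
}

# Independent brute-force buzz assembler: literal sequential application of
# the run/duration/count/merge rules, structured differently from the
# package implementation.
brute_force_buzzes <- function(times, max_ici = 0.010, min_run = 5,
                               min_dur = 0.2, min_clicks = 101,
                               merge_gap = 1.0) {
  runs <- list()
  cur <- times[1]
  for (t in times[-1]) {
    if (t - cur[length(cur)] < max_ici) {
      cur <- c(cur, t)
    } else {
      runs[[length(runs) + 1L]] <- cur
      cur <- t
    }
  }
  runs[[length(runs) + 1L]] <- cur
  runs <- Filter(function(r) length(r) >= min_run, runs)
  runs <- Filter(function(r) {
    (r[length(r)] - r[1]) >= min_dur && length(r) >= min_clicks
  }, runs)
  if (length(runs) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0), n_clicks = integer(0)))
  }
  merged <- list(list(start = runs[[1]][1], end = runs[[1]][length(runs[[1]])],
                      n = length(runs[[1]])))
  if (length(runs) > 1) {
    for (i in 2:length(runs)) {
      r <- runs[[i]]
      last <- merged[[length(merged)]]
      if (r[1] - last$end < merge_gap) {
        last$end <- r[length(r)]
        last$n <- last$n + length(r)
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1L]] <- list(start = r[1],
                                              end = r[length(r)],
                                              n = length(r))
      }
    }
  }
  data.frame(start = sapply(merged, `[[`, "start"),
             end = sapply(merged, `[[`, "end"),
             n_clicks = as.integer(sapply(merged, `[[`, "n")))
}

# Random click train with ICIs straddling every buzz threshold.
random_click_train <- function() {
  n_seg <- sample(1:6, 1)
  times <- numeric(0)
  t <- runif(1, 0, 5)
  for (s in seq_len(n_seg)) {
    n <- sample(c(2:6, 50:150), 1)
    ici <- sample(c(0.002, 0.0099, 0.010, 0.0101, 0.02), 1)
    times <- c(times, t + cumsum(rep(ici, n)))
    t <- times[length(times)] + sample(c(0.05, 0.5, 0.99, 1.0, 1.5), 1)
  }
  unique(times)
}

# Generator config with strongly separated states (activity contrast far
# beyond 3 SD, buzz-rate contrast far beyond 5x) for end-to-end recovery.
separated_gen_config <- function(duration_h = 6, seed = 1, ...) {
  states <- data.frame(
    name = c("nonfeeding", "pelagic", "bottom"),
    dur_mean = c(50, 45, 80), dur_sd = c(15, 13, 22),
    depth_mean = c(4.5, 8, 12), depth_sd = c(1.5, 2.5, 3.5),
    surface_mean = c(25, 35, 34),
    buzz_rate = c(0.1, 3.0, 2.0),
    resp_rate = c(2.4, 3.0, 2.7),
    activity = c(1.2, 3.0, 2.0), activity_cv = rep(0.12, 3),
    bottom_fraction = c(0.10, 0.15, 0.45),
    buzz_at_bottom = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  gen_config(states = states, duration_h = duration_h, seed = seed, ...)
}

# Match detected event times against truth with a +-1 sample tolerance.
event_match_stats <- function(detected, truth, fs = 25) {
  tol <- 1 / fs + 1e-9
  recall <- mean(sapply(truth, function(b) any(abs(detected - b) <= tol)))
  precision <- mean(sapply(detected, function(b) any(abs(truth - b) <= tol)))
  list(recall = recall, precision = precision)
}
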