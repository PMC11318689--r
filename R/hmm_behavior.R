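#' Construct a mixed hidden Markov model
#'
#' K behavioral states with heterogeneous emissions (Gaussian log mean MSA,
#' beta for the unit-interval metrics, Bernoulli buzz presence) and C
#' discrete "behavioral context" random-effect levels: contexts share the
#' emission parameters and differ only in their transition probability
#' matrix; each animal's sequence follows one context, drawn with
#' probabilities `weights`. Initial state distributions are fixed at the
#' stationary distribution of each context's TPM.
#'
#' @param K number of states.
#' @param C number of contexts.
#' @param Gamma list of C row-stochastic K x K matrices.
#' @param weights context probabilities, length C, summing to 1.
#' @param emissions named list over metrics (see [metric_families()]); each
#'   element a matrix with K columns and rows `mean`/`sd` (gaussian),
#'   `shape1`/`shape2` (beta) or `prob` (bernoulli).
#' @return object of class `mixed_hmm`.
#' @export
mixed_hmm <- function(K, C, Gamma, weights, emissions) {
  stopifnot(length(Gamma) == C, length(weights) == C)
  if (abs(sum(weights) - 1) > 1e-10 || any(weights < 0)) {
    stop("context weights must sum to 1")
  }
  for (G in Gamma) {
    if (!all(dim(G) == c(K, K)) || any(G < 0) ||
        any(abs(rowSums(G) - 1) > 1e-10)) {
      stop("each Gamma must be K x K row-stochastic")
    }
  }
  fam <- metric_families()
  if (!all(names(fam) %in% names(emissions))) stop("missing emission metrics")
  for (m in names(fam)) {
    p <- emissions[[m]]
    if (ncol(p) != K) stop("emission parameters must have K columns: ", m)
    if (fam[m] == "gaussian" && any(p["sd", ] <= 0)) stop("sd must be > 0")
    if (fam[m] == "beta" && any(p <= 0)) stop("beta shapes must be > 0")
    if (fam[m] == "bernoulli" && any(p < 0 | p > 1)) stop("prob must be in [0,1]")
  }
  structure(list(K = K, C = C, Gamma = Gamma, weights = weights,
                 emissions = emissions,
                 delta = lapply(Gamma, stationary_distribution)),
            class = "mixed_hmm")
}

# per-metric log-density floor (keeps the objective finite near boundaries)
.LD_FLOOR <- -700

#' Emission log density of one metric vector under one state
#'
#' Sum of per-metric log densities; missing metrics contribute nothing
#' (likelihood marginalization by omission). Each metric term is floored at
#' -700 nats.
#'
#' @param emissions emission parameter list (see [mixed_hmm()]).
#' @param state state index.
#' @param x named numeric vector or one-row data.frame of metrics.
#' @return log density (nats).
#' @export
emission_logdensity <- function(emissions, state, x) {
  if (is.matrix(x)) x <- as.data.frame(x)
  x <- unlist(x[names(metric_families())])
  if (anyNA(match(names(metric_families()), names(x)))) {
    stop("x must carry named metric values")
  }
  X <- matrix(x, nrow = 1, dimnames = list(NULL, names(metric_families())))
  .emission_logdens_matrix(emissions, X)[1, state]
}

# T x K matrix of emission log densities for a metric matrix with NAs
.emission_logdens_matrix <- function(emissions, X) {
  fam <- metric_families()
  Tn <- nrow(X)
  K <- ncol(emissions[[1]])
  ld <- matrix(0, Tn, K)
  for (m in names(fam)) {
    xm <- X[, m]
    obs <- !is.na(xm)
    if (!any(obs)) next
    p <- emissions[[m]]
    for (k in seq_len(K)) {
      term <- switch(fam[[m]],
        gaussian = stats::dnorm(xm[obs], p["mean", k], p["sd", k], log = TRUE),
        beta = {
          if (any(xm[obs] <= 0 | xm[obs] >= 1)) {
            stop("metric outside (0,1) support: ", m)
          }
          stats::dbeta(xm[obs], p["shape1", k], p["shape2", k], log = TRUE)
        },
        bernoulli = {
          if (any(!xm[obs] %in% c(0, 1))) stop("metric not in {0,1}: ", m)
          ifelse(xm[obs] == 1, log(p["prob", k]), log(1 - p["prob", k]))
        }
      )
      ld[obs, k] <- ld[obs, k] + pmax(term, .LD_FLOOR)
    }
  }
  ld
}

.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Marginal log likelihood of metric sequences under a mixed HMM
#'
#' For each animal the likelihood is a mixture over contexts:
#' `log sum_c weights_c * L_animal(Gamma_c, delta_c, emissions)`, with each
#' `L_animal` computed by the scaled forward recursion; the total is the sum
#' over animals.
#'
#' @param model a [mixed_hmm()].
#' @param sequences list of per-animal metric matrices (rows = dives,
#'   columns named as [metric_families()]).
#' @return log likelihood (nats).
#' @export
sequence_loglik <- function(model, sequences) {
  if (length(sequences) == 0) stop("empty sequence set")
  lw <- log(model$weights)
  total <- 0
  for (X in sequences) {
    X <- .as_metric_matrix(X)
    if (nrow(X) == 0) stop("empty sequence")
    ld <- .emission_logdens_matrix(model$emissions, X)
    llc <- vapply(seq_len(model$C), function(c) {
      forward_loglik_cpp(ld, model$Gamma[[c]], model$delta[[c]])
    }, numeric(1))
    total <- total + .logsumexp(lw + llc)
  }
  total
}

.as_metric_matrix <- function(X) {
  nm <- names(metric_families())
  X <- as.matrix(as.data.frame(X)[, nm])
  storage.mode(X) <- "double"
  X
}

# Precomputes per-sequence data and family codes so every likelihood
# evaluation during optimization is a single compiled call per animal.
# Numerically identical to sequence_loglik().
.make_loglik_fn <- function(sequences) {
  fam <- metric_families()
  fam_code <- unname(c(gaussian = 0L, beta = 1L, bernoulli = 2L)[fam])
  caches <- lapply(sequences, function(X) {
    X <- .as_metric_matrix(X)
    for (m in names(fam)[fam == "beta"]) {
      xm <- X[, m]
      if (any(xm <= 0 | xm >= 1, na.rm = TRUE)) {
        stop("metric outside (0,1) support: ", m)
      }
    }
    bz <- X[, "buzz_present"]
    if (any(!bz %in% c(0, 1), na.rm = TRUE)) stop("metric not in {0,1}: buzz_present")
    X
  })
  function(model) {
    mixedhmm_total_loglik_cpp(caches, fam_code,
                              unname(model$emissions[names(fam)]),
                              model$Gamma, model$delta, log(model$weights),
                              .LD_FLOOR)
  }
}

# ---- working-scale parameterization ---------------------------------------

.pack_params <- function(model) {
  fam <- metric_families()
  K <- model$K; C <- model$C
  th <- c()
  for (m in names(fam)) {
    p <- model$emissions[[m]]
    th <- c(th, switch(fam[[m]],
      gaussian = c(p["mean", ], log(p["sd", ])),
      beta = c(log(p["shape1", ]), log(p["shape2", ])),
      bernoulli = stats::qlogis(pmin(pmax(p["prob", ], 1e-9), 1 - 1e-9))
    ))
  }
  for (c in seq_len(C)) {
    G <- model$Gamma[[c]]
    for (i in seq_len(K)) {
      off <- setdiff(seq_len(K), i)
      th <- c(th, log(pmax(G[i, off], 1e-12) / pmax(G[i, i], 1e-12)))
    }
  }
  if (C > 1) th <- c(th, log(model$weights[-1] / model$weights[1]))
  unname(th)
}

.unpack_params <- function(th, K, C, validate = TRUE) {
  fam <- metric_families()
  pos <- 1L
  take <- function(n) {
    v <- th[pos:(pos + n - 1L)]
    pos <<- pos + n
    v
  }
  emissions <- list()
  for (m in names(fam)) {
    emissions[[m]] <- switch(fam[[m]],
      gaussian = rbind(mean = take(K),
                       sd = pmin(pmax(exp(take(K)), 0.05), 1e4)),
      beta = rbind(shape1 = pmin(pmax(exp(take(K)), 0.2), 100),
                   shape2 = pmin(pmax(exp(take(K)), 0.2), 100)),
      bernoulli = rbind(prob = pmin(pmax(stats::plogis(take(K)), 1e-12),
                                    1 - 1e-12))
    )
  }
  Gamma <- vector("list", C)
  for (c in seq_len(C)) {
    G <- matrix(0, K, K)
    for (i in seq_len(K)) {
      eta <- rep(0, K)
      if (K > 1) eta[setdiff(seq_len(K), i)] <- take(K - 1L)
      eta <- eta - max(eta)
      G[i, ] <- exp(eta) / sum(exp(eta))
    }
    Gamma[[c]] <- G
  }
  weights <- if (C > 1) {
    lw <- c(0, take(C - 1L))
    exp(lw - .logsumexp(lw))
  } else 1
  if (validate) return(mixed_hmm(K, C, Gamma, weights, emissions))
  structure(list(K = K, C = C, Gamma = Gamma, weights = weights,
                 emissions = emissions,
                 delta = lapply(Gamma, stationary_distribution)),
            class = "mixed_hmm")
}

# Lean working-scale unpacker for the optimizer's inner loop: precomputes
# block offsets and index maps so each call is plain vector arithmetic.
# Produces the same model as .unpack_params(th, K, C, validate = FALSE).
.make_unpacker <- function(K, C) {
  fam <- metric_families()
  sizes <- ifelse(fam == "bernoulli", K, 2L * K)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  # column-major linear indices of off-diagonal entries, in pack order
  # (row i, then columns setdiff(1:K, i))
  offdiag <- unlist(lapply(seq_len(K), function(i) {
    j <- setdiff(seq_len(K), i)
    (j - 1L) * K + i
  }))
  n_trans <- K * (K - 1L)
  trans_start <- ends[length(ends)] + 1L
  w_start <- trans_start + C * n_trans
  rn <- list(gaussian = c("mean", "sd"), beta = c("shape1", "shape2"),
             bernoulli = "prob")
  function(th) {
    emissions <- vector("list", length(fam))
    names(emissions) <- names(fam)
    for (i in seq_along(fam)) {
      v <- th[starts[i]:ends[i]]
      p <- switch(fam[[i]],
        gaussian = matrix(c(v[seq_len(K)],
                            pmin(pmax(exp(v[K + seq_len(K)]), 0.05), 1e4)),
                          2, K, byrow = TRUE),
        beta = matrix(pmin(pmax(exp(v), 0.2), 100), 2, K, byrow = TRUE),
        bernoulli = matrix(pmin(pmax(stats::plogis(v), 1e-12), 1 - 1e-12),
                           1, K)
      )
      rownames(p) <- rn[[fam[[i]]]]
      emissions[[i]] <- p
    }
    Gamma <- vector("list", C)
    delta <- vector("list", C)
    for (c in seq_len(C)) {
      eta <- matrix(0, K, K)
      if (K > 1) {
        sl <- th[(trans_start + (c - 1L) * n_trans):(trans_start + c * n_trans - 1L)]
        eta[offdiag] <- pmin(pmax(sl, -50), 50)
      }
      em <- exp(eta)
      G <- em / rowSums(em)
      Gamma[[c]] <- G
      delta[[c]] <- stationary_cpp(G)
    }
    weights <- if (C > 1) {
      lw <- c(0, pmin(pmax(th[w_start:(w_start + C - 2L)], -50), 50))
      exp(lw - .logsumexp(lw))
    } else 1
    structure(list(K = K, C = C, Gamma = Gamma, weights = weights,
                   emissions = emissions, delta = delta),
              class = "mixed_hmm")
  }
}

.count_params <- function(K, C) {
  fam <- metric_families()
  n_em <- sum(ifelse(fam == "bernoulli", K, 2 * K))
  n_em + C * K * (K - 1) + (C - 1)
}

# dive grouping used to seed emission estimates: deterministic quantile
# split of the activity metric
.init_groups_quantile <- function(Xall, K) {
  anchor <- Xall[, "log_mean_msa"]
  qs <- stats::quantile(anchor, probs = seq(0, 1, length.out = K + 1),
                        na.rm = TRUE)
  grp <- cut(anchor, unique(qs), include.lowest = TRUE, labels = FALSE)
  if (length(unique(grp)) < K) grp <- sample.int(K, length(anchor), replace = TRUE)
  grp
}

# moment-based per-group initial emission estimates
.init_emissions <- function(Xall, K, grp = NULL) {
  fam <- metric_families()
  if (is.null(grp)) grp <- .init_groups_quantile(Xall, K)
  emissions <- list()
  for (m in names(fam)) {
    xm <- Xall[, m]
    pars <- vapply(seq_len(K), function(k) {
      v <- xm[grp == k & !is.na(xm)]
      if (length(v) < 3) v <- xm[!is.na(xm)]
      mu <- mean(v)
      switch(fam[[m]],
        gaussian = c(mu, max(stats::sd(v), 0.05)),
        beta = {
          mu <- min(max(mu, 0.02), 0.98)
          vv <- max(stats::var(v), 1e-4)
          vv <- min(vv, mu * (1 - mu) * 0.9)
          conc <- mu * (1 - mu) / vv - 1
          c(max(mu * conc, 0.05), max((1 - mu) * conc, 0.05))
        },
        bernoulli = min(max(mu, 0.02), 0.98)
      )
    }, numeric(if (fam[[m]] == "bernoulli") 1 else 2))
    emissions[[m]] <- switch(fam[[m]],
      gaussian = matrix(pars, 2, K, dimnames = list(c("mean", "sd"), NULL)),
      beta = matrix(pars, 2, K, dimnames = list(c("shape1", "shape2"), NULL)),
      bernoulli = matrix(pars, 1, K, dimnames = list("prob", NULL))
    )
  }
  emissions
}

.random_tpm <- function(K, diag_w = NULL) {
  if (is.null(diag_w)) diag_w <- runif(1, 0.6, 0.9)
  G <- matrix(stats::rgamma(K * K, 1), K, K)
  G <- G / rowSums(G) * (1 - diag_w)
  diag(G) <- diag(G) + diag_w
  G / rowSums(G)
}

#' Fit a mixed hidden Markov model by multi-restart maximum likelihood
#'
#' Directly maximizes the context-marginal likelihood ([sequence_loglik()])
#' with a quasi-Newton optimizer on an unconstrained working scale
#' (log/logit transforms for emission parameters, multinomial logits for
#' TPM rows and context weights). Each restart perturbs moment-based
#' initial emission estimates (quantile splits of the activity metric) and
#' draws a Dirichlet-perturbed diagonal-dominant TPM; the best restart is
#' returned. Deterministic given `seed`.
#'
#' @param sequences list of per-animal metric matrices.
#' @param K number of states (1..4).
#' @param C number of contexts (1..4).
#' @param n_restarts number of random restarts, default 50.
#' @param seed integer seed.
#' @param maxit optimizer iteration cap per restart.
#' @return a `hmm_fit`: list with `model`, `loglik`, `n_params`, `aic`
#'   (`2 * n_params - 2 * loglik`), `n_restarts`, `converged`, `seed`, `K`,
#'   `C`.
#' @export
fit_mixed_hmm <- function(sequences, K, C = 1, n_restarts = 50, seed = 1L,
                          maxit = 300) {
  if (!K %in% 1:4 || !C %in% 1:4) stop("K and C must be in 1..4")
  sequences <- lapply(sequences, .as_metric_matrix)
  n_obs <- sum(vapply(sequences, nrow, integer(1)))
  npar <- .count_params(K, C)
  if (n_obs < 10 * npar) {
    warning("only ", n_obs, " dives for ", npar,
            " parameters; estimates may be unstable")
  }
  set.seed(seed)
  Xall <- do.call(rbind, sequences)
  base_em <- .init_emissions(Xall, K)
  llfn <- .make_loglik_fn(sequences)
  unpacker <- .make_unpacker(K, C)
  negll <- function(th) {
    v <- llfn(unpacker(th))
    if (!is.finite(v)) return(1e10)
    -v
  }
  best <- NULL
  any_conv <- FALSE
  diag_msgs <- character(0)
  for (r in seq_len(n_restarts)) {
    em <- base_em
    if (r > 1) {  # first restart runs from the unperturbed moment estimates
      for (m in names(em)) {
        p <- em[[m]]
        if (rownames(p)[1] == "mean") {
          p["mean", ] <- p["mean", ] + stats::rnorm(K, 0, 0.3 * stats::sd(Xall[, m], na.rm = TRUE))
          p["sd", ] <- p["sd", ] * exp(stats::rnorm(K, 0, 0.2))
        } else if (rownames(p)[1] == "shape1") {
          p <- p * exp(matrix(stats::rnorm(2 * K, 0, 0.3), 2, K))
        } else {
          p["prob", ] <- stats::plogis(stats::qlogis(pmin(pmax(p["prob", ], 0.02), 0.98)) +
                                         stats::rnorm(K, 0, 0.5))
        }
        em[[m]] <- p
      }
    }
    Gamma <- lapply(seq_len(C), function(c) .random_tpm(K))
    w <- if (C > 1) { v <- stats::rgamma(C, 2); v / sum(v) } else 1
    start <- .pack_params(mixed_hmm(K, C, Gamma, w, em))
    opt <- try(stats::optim(start, negll, method = "BFGS",
                            control = list(maxit = maxit, reltol = 1e-8)),
               silent = TRUE)
    if (inherits(opt, "try-error")) {
      diag_msgs <- c(diag_msgs, paste0("restart ", r, ": ", attr(opt, "condition")$message))
      next
    }
    if (opt$value >= 1e10) {
      diag_msgs <- c(diag_msgs, paste0("restart ", r, ": objective not finite"))
      next
    }
    any_conv <- any_conv || opt$convergence == 0
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop("no restart converged:\n", paste(diag_msgs, collapse = "\n"))
  }
  # polish the winning restart: re-running BFGS from its solution resets the
  # Hessian approximation and tightens convergence
  polish <- try(stats::optim(best$par, negll, method = "BFGS",
                             control = list(maxit = 50, reltol = 1e-9,
                                            ndeps = rep(1e-6, length(best$par)))),
                silent = TRUE)
  if (!inherits(polish, "try-error") && polish$value <= best$value) {
    best <- polish
  }
  model <- .unpack_params(best$par, K, C)
  # report the plain (unpenalized) likelihood at the estimate; the penalty
  # only steers optimization away from degenerate spikes
  ll <- llfn(model)
  structure(list(model = model, loglik = ll, n_params = npar,
                 aic = 2 * npar - 2 * ll, n_restarts = n_restarts,
                 converged = any_conv, seed = seed, K = K, C = C),
            class = "hmm_fit")
}

#' Select the most parsimonious model by AIC
#'
#' Minimal AIC wins; ties (within 1e-9) are broken toward the smaller
#' number of states, then the smaller number of contexts.
#'
#' @param fits nonempty list of `hmm_fit` objects.
#' @return the selected `hmm_fit`.
#' @export
select_model <- function(fits) {
  if (length(fits) == 0) stop("no fits supplied")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  Ks <- vapply(fits, function(f) f$K, numeric(1))
  Cs <- vapply(fits, function(f) f$C, numeric(1))
  cand <- which(aic <= min(aic) + 1e-9)
  cand <- cand[order(Ks[cand], Cs[cand])]
  fits[[cand[1]]]
}

#' Map fitted states to behavioral-state names
#'
#' For a three-state model: "nonfeeding" is the state with the lowest buzz
#' probability (Bernoulli p); of the remaining two, "bottom" is the one
#' whose relative-buzz-depth beta has the higher mean (buzzes concentrated
#' near the maximum dive depth) and "pelagic" the other. Other K get
#' generic `state1..K` names.
#'
#' @param model a `mixed_hmm`.
#' @return character vector of length K, names by state index.
#' @export
state_name_map <- function(model) {
  K <- model$K
  if (K != 3) return(paste0("state", seq_len(K)))
  p <- model$emissions$buzz_present["prob", ]
  nf <- which.min(p)
  rest <- setdiff(1:3, nf)
  bm <- vapply(rest, function(k) {
    a <- model$emissions$rel_buzz_depth["shape1", k]
    b <- model$emissions$rel_buzz_depth["shape2", k]
    a / (a + b)
  }, numeric(1))
  bottom <- rest[which.max(bm)]
  pelagic <- setdiff(rest, bottom)
  out <- character(3)
  out[nf] <- "nonfeeding"; out[bottom] <- "bottom"; out[pelagic] <- "pelagic"
  out
}

#' Decode behavioral states
#'
#' Computes each animal's posterior over contexts
#' (`post_c` proportional to `weights_c * L_animal(c)`), then decodes states
#' under the maximum-posterior context, by default with the Viterbi
#' algorithm ("global" decoding); `method = "smoothing"` returns the
#' per-dive maximum of the forward-backward state posteriors instead.
#'
#' @param model a fitted `mixed_hmm`.
#' @param sequences list of per-animal metric matrices.
#' @param method "viterbi" (default) or "smoothing".
#' @return list with `states` (list of integer vectors), `labels` (list of
#'   character vectors via [state_name_map()]), `context` (integer vector),
#'   `context_posterior` (animals x C matrix), `state_names`.
#' @export
decode_states <- function(model, sequences, method = c("viterbi", "smoothing")) {
  method <- match.arg(method)
  if (!inherits(model, "mixed_hmm")) stop("model must be a mixed_hmm")
  nm <- state_name_map(model)
  lw <- log(model$weights)
  states <- vector("list", length(sequences))
  ctx <- integer(length(sequences))
  post <- matrix(NA_real_, length(sequences), model$C)
  for (a in seq_along(sequences)) {
    X <- .as_metric_matrix(sequences[[a]])
    ld <- .emission_logdens_matrix(model$emissions, X)
    llc <- vapply(seq_len(model$C), function(c) {
      forward_loglik_cpp(ld, model$Gamma[[c]], model$delta[[c]])
    }, numeric(1))
    lp <- lw + llc
    post[a, ] <- exp(lp - .logsumexp(lp))
    ctx[a] <- which.max(post[a, ])
    G <- model$Gamma[[ctx[a]]]
    d <- model$delta[[ctx[a]]]
    states[[a]] <- if (method == "viterbi") {
      as.integer(viterbi_cpp(ld, G, d))
    } else {
      .smoothing_states(ld, G, d)
    }
  }
  list(states = states, labels = lapply(states, function(s) nm[s]),
       context = ctx, context_posterior = post, state_names = nm)
}

# forward-backward state posteriors (scaled), local decoding
.smoothing_states <- function(ld, G, d) {
  Tn <- nrow(ld); K <- ncol(ld)
  dens <- exp(ld - apply(ld, 1, max))
  alpha <- matrix(0, Tn, K); beta <- matrix(0, Tn, K)
  phi <- d * dens[1, ]; alpha[1, ] <- phi / sum(phi)
  for (t in 2:Tn) {
    phi <- (alpha[t - 1, ] %*% G) * dens[t, ]
    alpha[t, ] <- phi / sum(phi)
  }
  beta[Tn, ] <- 1
  for (t in (Tn - 1):1) {
    b <- G %*% (dens[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / sum(b)
  }
  p <- alpha * beta
  as.integer(apply(p, 1, which.max))
}

#' Simulate metric sequences from a mixed HMM
#'
#' Draws a context per animal, a state chain from that context's TPM
#' (started at its stationary distribution), and metrics from the state's
#' emission distributions. `rel_buzz_depth` is set missing whenever the
#' Bernoulli buzz-presence draw is 0, matching the missing-data convention
#' of the real metric tables.
#'
#' @param model a `mixed_hmm`.
#' @param n_dives integer vector: dives per animal.
#' @param seed integer seed.
#' @return list with `sequences`, `states`, `contexts`.
#' @export
simulate_hmm_data <- function(model, n_dives, seed = 1L) {
  set.seed(seed)
  fam <- metric_families()
  seqs <- vector("list", length(n_dives))
  states <- vector("list", length(n_dives))
  ctxs <- integer(length(n_dives))
  for (a in seq_along(n_dives)) {
    cc <- sample.int(model$C, 1, prob = model$weights)
    ctxs[a] <- cc
    s <- simulate_state_chain(model$Gamma[[cc]], n_dives[a])
    X <- matrix(NA_real_, n_dives[a], length(fam),
                dimnames = list(NULL, names(fam)))
    for (m in names(fam)) {
      p <- model$emissions[[m]]
      X[, m] <- switch(fam[[m]],
        gaussian = stats::rnorm(n_dives[a], p["mean", s], p["sd", s]),
        beta = stats::rbeta(n_dives[a], p["shape1", s], p["shape2", s]),
        bernoulli = stats::rbinom(n_dives[a], 1, p["prob", s])
      )
    }
    X[X[, "buzz_present"] == 0, "rel_buzz_depth"] <- NA_real_
    seqs[[a]] <- X
    states[[a]] <- s
  }
  list(sequences = seqs, states = states, contexts = ctxs)
}

#' Serialize a fitted mixed HMM to JSON
#'
#' @param fit a `hmm_fit`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_hmm_json <- function(fit, path) {
  m <- fit$model
  obj <- list(K = m$K, C = m$C, weights = m$weights,
              Gamma = lapply(m$Gamma, function(G) unclass(as.data.frame(G))),
              emissions = lapply(m$emissions, function(p) {
                stats::setNames(as.data.frame(t(p)), rownames(p))
              }),
              loglik = fit$loglik, n_params = fit$n_params, aic = fit$aic,
              n_restarts = fit$n_restarts, seed = fit$seed,
              state_names = state_name_map(m))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
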