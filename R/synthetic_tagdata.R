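#' Configuration for the synthetic deployment generator
#'
#' Builds the parameter set for [generate_deployment()]. Defaults emulate the
#' shallow-water harbor-porpoise regime: three behavioral states (nonfeeding,
#' pelagic feeding, bottom feeding) with state-dependent dive duration, depth,
#' activity, buzz and respiration rates matching published day-time state
#' means (dive durations ~51/44/78 s, depths ~4.4/8.2/11.6 m, buzz rates
#' 0.1/2.6/1.6 min^-1 of dive time, respiration rates 2.4/3.0/2.7 min^-1 of
#' cycle time, mean MSA 1.8/2.3/1.9 m s^-2), a persistent transition matrix,
#' and a diel effect applied as multipliers on the buzz rate and on the
#' pelagic-state entry probability at night.
#'
#' @param n_states number of behavioral states K (default 3).
#' @param context_tpms list of K x K row-stochastic transition matrices, one
#'   per behavioral context (C >= 1).
#' @param context_weights probabilities over contexts, summing to 1.
#' @param states data.frame with one row per state and columns `name`,
#'   `dur_mean`, `dur_sd` (s), `depth_mean`, `depth_sd` (m), `surface_mean`
#'   (s), `buzz_rate` (min^-1 of dive time), `resp_rate` (min^-1 of
#'   dive-cycle time), `activity` (mean MSA, m s^-2), `activity_cv`,
#'   `bottom_fraction`, `buzz_at_bottom` (logical).
#' @param buzz_ici_mean mean inter-click interval inside a buzz (s), < 0.010.
#' @param night_buzz_mult multiplicative night elevation of buzz rates
#'   (default 2.5, i.e. ~150% more buzzes per unit time at night).
#' @param night_pelagic_mult multiplicative night elevation of the entry
#'   probability into the pelagic state (default 2.4).
#' @param duration_h deployment duration (hours).
#' @param fs sensor sampling rate (Hz), default 25.
#' @param sunrise_s,sunset_s clock times of sunrise/sunset (s of day).
#' @param t0_clock_s clock time of deployment start (s of day).
#' @param body_length_m animal body length (m), default 1.31.
#' @param animal_id deployment identifier.
#' @param seed integer RNG seed.
#' @return an object of class `gen_config`.
#' @export
gen_config <- function(n_states = 3,
                       context_tpms = NULL,
                       context_weights = 1,
                       states = NULL,
                       buzz_ici_mean = 0.003,
                       night_buzz_mult = 2.5,
                       night_pelagic_mult = 2.4,
                       duration_h = 24,
                       fs = 25,
                       sunrise_s = 6 * 3600,
                       sunset_s = 18 * 3600,
                       t0_clock_s = 12 * 3600,
                       body_length_m = 1.31,
                       animal_id = "sim01",
                       seed = 1L) {
  if (is.null(states)) {
    states <- data.frame(
      name = c("nonfeeding", "pelagic", "bottom")[seq_len(min(n_states, 3))],
      dur_mean = c(50.7, 44.4, 77.5)[seq_len(min(n_states, 3))],
      dur_sd = c(18, 16, 26)[seq_len(min(n_states, 3))],
      depth_mean = c(4.4, 8.2, 11.6)[seq_len(min(n_states, 3))],
      depth_sd = c(1.7, 3.1, 4.3)[seq_len(min(n_states, 3))],
      surface_mean = c(25.1, 35.7, 34.4)[seq_len(min(n_states, 3))],
      buzz_rate = c(0.1, 2.6, 1.6)[seq_len(min(n_states, 3))],
      resp_rate = c(2.4, 3.0, 2.7)[seq_len(min(n_states, 3))],
      activity = c(1.8, 2.3, 1.9)[seq_len(min(n_states, 3))],
      activity_cv = rep(0.25, min(n_states, 3)),
      bottom_fraction = c(0.10, 0.15, 0.40)[seq_len(min(n_states, 3))],
      buzz_at_bottom = c(FALSE, FALSE, TRUE)[seq_len(min(n_states, 3))],
      stringsAsFactors = FALSE
    )
  }
  if (nrow(states) != n_states) stop("states must have one row per state")
  if (is.null(context_tpms)) {
    tpm <- matrix(0.2 / max(1, n_states - 1), n_states, n_states)
    diag(tpm) <- if (n_states > 1) 0.8 else 1
    context_tpms <- list(tpm)
  }
  cfg <- structure(list(
    n_states = as.integer(n_states), context_tpms = context_tpms,
    context_weights = context_weights, states = states,
    buzz_ici_mean = buzz_ici_mean, night_buzz_mult = night_buzz_mult,
    night_pelagic_mult = night_pelagic_mult, duration_h = duration_h,
    fs = fs, sunrise_s = sunrise_s, sunset_s = sunset_s,
    t0_clock_s = t0_clock_s, body_length_m = body_length_m,
    animal_id = animal_id, seed = as.integer(seed)
  ), class = "gen_config")
  validate_gen_config(cfg)
  cfg
}

#' @rdname gen_config
#' @param cfg a `gen_config` object.
#' @export
validate_gen_config <- function(cfg) {
  K <- cfg$n_states
  if (length(cfg$context_tpms) < 1) stop("need at least one context TPM")
  for (tpm in cfg$context_tpms) {
    if (!all(dim(tpm) == c(K, K))) stop("TPM dimensions must be K x K")
    if (any(tpm < 0) || any(abs(rowSums(tpm) - 1) > 1e-12)) {
      stop("each TPM row must be nonnegative and sum to 1")
    }
  }
  if (length(cfg$context_weights) != length(cfg$context_tpms) ||
      abs(sum(cfg$context_weights) - 1) > 1e-12 || any(cfg$context_weights < 0)) {
    stop("context_weights must be probabilities over the TPMs summing to 1")
  }
  s <- cfg$states
  if (any(s$dur_mean <= 0) || any(s$depth_mean <= 0)) {
    stop("duration and depth means must be positive")
  }
  if (any(s$buzz_rate < 0) || any(s$resp_rate < 0) || any(s$activity < 0)) {
    stop("rates and activity levels must be >= 0")
  }
  if (cfg$duration_h <= 0) stop("deployment duration must be positive")
  if (cfg$buzz_ici_mean >= 0.010) stop("buzz_ici_mean must be < 0.010 s")
  if (cfg$fs <= 0) stop("sample rate must be positive")
  invisible(cfg)
}

# lognormal meanlog/sdlog from arithmetic mean and sd
.lnorm_pars <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Sample a behavioral-state Markov chain
#'
#' Draws `n` states from the chain defined by a row-stochastic transition
#' matrix, starting from its stationary distribution. Used by the deployment
#' generator and directly testable against the eigen-decomposition stationary
#' distribution.
#'
#' @param tpm K x K row-stochastic matrix.
#' @param n number of steps.
#' @param init optional initial distribution; default stationary.
#' @return integer vector of states in 1..K.
#' @export
simulate_state_chain <- function(tpm, n, init = NULL) {
  K <- nrow(tpm)
  if (any(abs(rowSums(tpm) - 1) > 1e-12) || any(tpm < 0)) {
    stop("tpm rows must be nonnegative and sum to 1")
  }
  if (is.null(init)) init <- stationary_distribution(tpm)
  s <- integer(n)
  s[1] <- sample.int(K, 1, prob = init)
  for (i in seq_len(n - 1L)) {
    s[i + 1L] <- sample.int(K, 1, prob = tpm[s[i], ])
  }
  s
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the row-stochastic matrix for eigenvalue 1,
#' normalized to sum to 1.
#'
#' @param tpm K x K row-stochastic matrix.
#' @return numeric vector of length K.
#' @export
stationary_distribution <- function(tpm) {
  e <- eigen(t(tpm))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Render a piecewise descent-bottom-ascent dive profile
#'
#' Deterministic depth profile: linear descent from the surface to
#' `max_depth`, a flat bottom phase occupying `bottom_fraction` of the
#' duration, and a linear ascent. First and last samples are at the surface
#' (< 0.5 m). If sampling would miss the apex (e.g. a V-shaped dive), the
#' sample nearest the apex is set to `max_depth`, so the profile maximum
#' equals `max_depth` exactly.
#'
#' @param duration dive duration (s), > 0.
#' @param max_depth maximum depth (m), > 0.
#' @param bottom_fraction proportion of the dive at the bottom, in \[0, 1).
#' @param fs sampling rate (Hz), > 0.
#' @return numeric depth vector of `round(duration * fs)` samples.
#' @examples
#' d <- render_dive_profile(60, 10, 0.5, 25)
#' length(d)  # 1500
#' max(d)     # 10
#' @export
render_dive_profile <- function(duration, max_depth, bottom_fraction, fs) {
  if (duration <= 0 || max_depth <= 0) stop("duration and max_depth must be positive")
  if (bottom_fraction < 0 || bottom_fraction >= 1) stop("bottom_fraction must be in [0, 1)")
  if (fs <= 0) stop("fs must be positive")
  n <- max(4L, round(duration * fs))
  tt <- (seq_len(n) - 1L) / fs
  edge <- 0.2
  t_desc <- duration * (1 - bottom_fraction) / 2
  t_bot <- t_desc + duration * bottom_fraction
  kx <- c(0, t_desc, t_bot, tt[n])
  ky <- c(edge, max_depth, max_depth, edge)
  # collapse duplicated knots for V-shaped dives
  keep <- !duplicated(kx)
  depth <- stats::approx(kx[keep], ky[keep], xout = tt, rule = 2)$y
  if (max(depth) < max_depth) depth[which.max(depth)] <- max_depth
  depth
}

#' Render a buzz click train
#'
#' Generates strictly increasing click times inside a buzz interval with
#' inter-click intervals jittered around `ici_mean` but always below the
#' 10 ms buzz criterion. When the interval holds at least 101 mean intervals
#' the train is guaranteed to contain >= 101 clicks, i.e. to be detectable as
#' a buzz. Intervals shorter than five mean ICIs produce a sub-threshold
#' train with a warning (useful as a negative control).
#'
#' @param interval numeric length-2 vector `(start, end)` in seconds.
#' @param ici_mean mean inter-click interval (s), must be < 0.010.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return numeric vector of click times in `[start, end)`.
#' @export
render_click_train <- function(interval, ici_mean = 0.003, seed = NULL) {
  if (ici_mean >= 0.010) stop("ici_mean must be < 0.010 s (buzz ICI criterion)")
  if (ici_mean <= 0) stop("ici_mean must be positive")
  if (!is.null(seed)) set.seed(seed)
  len <- interval[2] - interval[1]
  if (len <= 0) stop("empty buzz interval")
  if (len < 5 * ici_mean) {
    warning("buzz interval shorter than 5 mean ICIs; emitting sub-threshold train")
  }
  m <- floor(len / ici_mean)
  jmax <- min(0.15 * ici_mean, 0.45 * (0.010 - ici_mean))
  j <- runif(m + 1L, -jmax, jmax)
  j[1] <- abs(j[1])
  times <- interval[1] + (0:m) * ici_mean + j
  times[times < interval[2]]
}

#' Generate a synthetic tag deployment with ground truth
#'
#' Simulates a deployment of continuous short, shallow dives: a Markov chain
#' over behavioral states (one transition matrix drawn per deployment from
#' the configured contexts), per-state dive duration/depth/activity/buzz/
#' respiration distributions, respirations during inter-dive surfacings
#' (spaced >= 0.4 s, each in its own sub-0.5 m surfacing separated by shallow
#' submersion bumps), echolocation clicks confined to scheduled buzz
#' intervals, and a triaxial acceleration series whose minimum specific
#' acceleration tracks the active state's activity level and whose low-pass
#' component encodes pitch from the dive-profile slope. Night (sunset to
#' sunrise) multiplies buzz rates and the pelagic-state entry probability.
#'
#' @param config a [gen_config()] object.
#' @return list with `record` (class `sensor_record`: `time`, `depth`, `acc`,
#'   `fs`, `animal_id`, `body_length_m`, `t0_clock_s`, `sunrise_s`,
#'   `sunset_s`) and `truth` (class `ground_truth`: `dives` data.frame with
#'   `start`, `end`, `state`, `max_depth`; `resp_times`; `click_times`;
#'   `buzzes` data.frame with `start`, `end`, `dive_id`).
#' @export
generate_deployment <- function(config) {
  validate_gen_config(config)
  set.seed(config$seed)
  K <- config$n_states
  st <- config$states
  fs <- config$fs
  total_s <- config$duration_h * 3600
  pel_idx <- match("pelagic", st$name)

  ctx <- sample.int(length(config$context_tpms), 1, prob = config$context_weights)
  tpm <- config$context_tpms[[ctx]]

  # --- schedule dives, surfacings, respirations and buzz intervals ---------
  dive_start <- dive_end <- dive_state <- dive_depth <- dive_bf <- numeric(0)
  surf_start <- surf_end <- numeric(0)
  resp_times <- numeric(0)
  buzz_start <- buzz_end <- buzz_dive <- numeric(0)

  is_night <- function(t) {
    clock <- (config$t0_clock_s + t) %% 86400
    clock >= config$sunset_s | clock < config$sunrise_s
  }
  trans_row <- function(prev, night) {
    row <- tpm[prev, ]
    if (night && !is.na(pel_idx) && config$night_pelagic_mult != 1) {
      row[pel_idx] <- row[pel_idx] * config$night_pelagic_mult
      row <- row / sum(row)
    }
    row
  }

  # initial surfacing so the record starts at the surface
  t <- 0
  state <- sample.int(K, 1, prob = stationary_distribution(tpm))
  init_surf <- max(6, stats::rlnorm(1, .lnorm_pars(12, 4)$meanlog, .lnorm_pars(12, 4)$sdlog))
  n0 <- max(1L, stats::rpois(1, st$resp_rate[state] * init_surf / 60))
  n0 <- min(n0, floor(init_surf / 1.5))
  surf_start <- c(surf_start, t); surf_end <- c(surf_end, t + init_surf)
  resp_times <- c(resp_times, .place_respirations(t, t + init_surf, n0))
  t <- t + init_surf

  repeat {
    night <- is_night(t)
    state <- sample.int(K, 1, prob = trans_row(state, night))
    lp <- .lnorm_pars(st$dur_mean[state], st$dur_sd[state])
    dur <- max(8, stats::rlnorm(1, lp$meanlog, lp$sdlog))
    dp <- .lnorm_pars(st$depth_mean[state], st$depth_sd[state])
    dep <- max(1.5, stats::rlnorm(1, dp$meanlog, dp$sdlog))
    sp <- .lnorm_pars(st$surface_mean[state], 0.4 * st$surface_mean[state])
    surf <- max(4, stats::rlnorm(1, sp$meanlog, sp$sdlog))
    if (t + dur + surf > total_s) break

    di <- length(dive_start) + 1L
    dive_start <- c(dive_start, t); dive_end <- c(dive_end, t + dur)
    dive_state <- c(dive_state, state); dive_depth <- c(dive_depth, dep)
    bf <- st$bottom_fraction[state]
    dive_bf <- c(dive_bf, bf)

    # buzz intervals inside the dive
    brate <- st$buzz_rate[state] * if (night) config$night_buzz_mult else 1
    nb <- stats::rpois(1, brate * dur / 60)
    if (nb > 0) {
      win <- if (st$buzz_at_bottom[state] && bf > 0) {
        c(t + dur * (1 - bf) / 2, t + dur * (1 + bf) / 2)
      } else {
        c(t + 1, t + dur - 1)
      }
      iv <- .place_buzzes(win, nb)
      if (nrow(iv) > 0) {
        buzz_start <- c(buzz_start, iv$start)
        buzz_end <- c(buzz_end, iv$end)
        buzz_dive <- c(buzz_dive, rep(di, nrow(iv)))
      }
    }

    # surfacing with respirations
    cyc <- dur + surf
    nr <- max(1L, stats::rpois(1, st$resp_rate[state] * cyc / 60))
    nr <- min(nr, floor(surf / 1.5))
    nr <- max(nr, 1L)
    surf_start <- c(surf_start, t + dur); surf_end <- c(surf_end, t + dur + surf)
    resp_times <- c(resp_times, .place_respirations(t + dur, t + dur + surf, nr))
    t <- t + cyc
  }
  if (length(dive_start) == 0) stop("deployment too short to contain a dive cycle")
  total_actual <- t

  # clicks inside buzz intervals
  click_times <- numeric(0)
  if (length(buzz_start) > 0) {
    for (b in seq_along(buzz_start)) {
      click_times <- c(click_times,
                       render_click_train(c(buzz_start[b], buzz_end[b]),
                                          config$buzz_ici_mean))
    }
  }

  # --- render depth ---------------------------------------------------------
  n <- floor(total_actual * fs)
  time <- (seq_len(n) - 1L) / fs
  depth <- numeric(n)
  for (d in seq_along(dive_start)) {
    i0 <- floor(dive_start[d] * fs) + 1L
    i1 <- min(n, floor(dive_end[d] * fs))
    prof <- render_dive_profile(dive_end[d] - dive_start[d], dive_depth[d],
                                dive_bf[d], fs)
    nsamp <- i1 - i0 + 1L
    if (length(prof) < nsamp) {
      prof <- c(prof, rep(prof[length(prof)], nsamp - length(prof)))
    }
    depth[i0:i1] <- prof[seq_len(nsamp)]
  }
  for (s in seq_along(surf_start)) {
    idx0 <- floor(surf_start[s] * fs) + 1L
    idx1 <- min(n, ceiling(surf_end[s] * fs))
    if (idx1 < idx0) next
    rr <- resp_times[resp_times >= surf_start[s] & resp_times < surf_end[s]]
    depth[idx0:idx1] <- .render_surfacing(time[idx0:idx1], rr,
                                          surf_start[s], surf_end[s])
  }
  # pin the sample nearest each respiration to the breath depth so the
  # minimum of every surfacing segment falls at the scheduled breath even
  # where the sampling grid straddles the narrow dip
  ri <- pmin(n, pmax(1L, round(resp_times * fs) + 1L))
  depth[ri] <- 0.05

  # --- render acceleration --------------------------------------------------
  g <- STANDARD_GRAVITY
  slope <- c(0, diff(depth)) * fs
  pitch <- atan2(-slope, 1.4)
  roll <- .moving_average(stats::rnorm(n, 0, 0.25), max(1L, round(0.5 * fs)))
  msa_scale <- rep(0.4, n)  # quiet surface baseline
  for (d in seq_along(dive_start)) {
    i0 <- floor(dive_start[d] * fs) + 1L
    i1 <- min(n, floor(dive_end[d] * fs))
    act <- st$activity[dive_state[d]]
    cv <- st$activity_cv[dive_state[d]]
    ap <- .lnorm_pars(act, cv * act)
    msa_scale[i0:i1] <- stats::rlnorm(1, ap$meanlog, ap$sdlog)
  }
  # specific acceleration aligned with gravity: MSA is exactly |s * e|
  e <- stats::rnorm(n)
  s_amp <- msa_scale * sqrt(pi / 2)
  fac <- pmax(0.01, 1 + s_amp * e / g)
  acc <- cbind(
    x = -g * sin(pitch) * fac,
    y = g * cos(pitch) * sin(roll) * fac,
    z = g * cos(pitch) * cos(roll) * fac
  )

  record <- structure(list(
    time = time, depth = depth, acc = acc, fs = fs,
    animal_id = config$animal_id, body_length_m = config$body_length_m,
    t0_clock_s = config$t0_clock_s, sunrise_s = config$sunrise_s,
    sunset_s = config$sunset_s
  ), class = "sensor_record")

  truth <- structure(list(
    dives = data.frame(start = dive_start, end = dive_end,
                       state = dive_state, max_depth = dive_depth),
    resp_times = sort(resp_times),
    click_times = sort(click_times),
    buzzes = data.frame(start = buzz_start, end = buzz_end,
                        dive_id = buzz_dive),
    context = ctx
  ), class = "ground_truth")
  .validate_ground_truth(truth)
  list(record = record, truth = truth)
}

# respirations evenly spread over the surfacing with small jitter, keeping
# >= 0.4 s spacing by construction (nominal gaps are >= 1.5 s)
.place_respirations <- function(t0, t1, nr) {
  len <- t1 - t0
  centers <- t0 + (seq_len(nr) - 0.5) / nr * len
  gap <- len / nr
  centers + runif(nr, -0.2 * gap, 0.2 * gap)
}

# non-overlapping buzz intervals with >= 1.2 s separation inside a window;
# extras that cannot be placed are dropped
.place_buzzes <- function(win, nb) {
  durs <- runif(nb, 0.35, 0.7)
  starts <- numeric(0); ends <- numeric(0)
  avail_len <- win[2] - win[1]
  for (k in seq_len(nb)) {
    ok <- FALSE
    for (try in 1:20) {
      s0 <- win[1] + runif(1, 0, max(0, avail_len - durs[k]))
      if (all(s0 >= ends + 1.2 | s0 + durs[k] <= starts - 1.2)) { ok <- TRUE; break }
    }
    if (ok) { starts <- c(starts, s0); ends <- c(ends, s0 + durs[k]) }
  }
  o <- order(starts)
  data.frame(start = starts[o], end = ends[o])
}

# surfacing depth: dips to ~5 cm at each respiration, shallow submersion
# bumps (> 0.5 m) between respirations so every breath sits in its own
# surfacing segment; edges stay below 0.5 m to join the dive profile edges
.render_surfacing <- function(tt, resp, t0, t1) {
  if (length(resp) == 0) return(rep(0.3, length(tt)))
  kx <- c(t0, resp[1] - 0.01)
  ky <- c(0.45, 0.45)
  for (i in seq_along(resp)) {
    kx <- c(kx, resp[i])
    ky <- c(ky, 0.05)
    if (i < length(resp)) {
      mid <- (resp[i] + resp[i + 1]) / 2
      kx <- c(kx, mid)
      ky <- c(ky, runif(1, 0.7, 1.4))
    }
  }
  kx <- c(kx, min(resp[length(resp)] + 0.01, t1), t1)
  ky <- c(ky, 0.45, 0.45)
  o <- order(kx)
  kx <- kx[o]; ky <- ky[o]
  keep <- !duplicated(kx)
  stats::approx(kx[keep], ky[keep], xout = tt, rule = 2)$y
}

.validate_ground_truth <- function(truth) {
  stopifnot(!is.unsorted(truth$resp_times, strictly = TRUE),
            !is.unsorted(truth$click_times, strictly = TRUE))
  if (nrow(truth$buzzes) > 0) {
    d <- truth$dives[truth$buzzes$dive_id, ]
    stopifnot(all(truth$buzzes$start >= d$start),
              all(truth$buzzes$end <= d$end))
  }
  invisible(truth)
}

#' Write a sensor record and ground truth to CSV
#'
#' The record is written long-format (`time_s, depth_m, ax, ay, az`) with a
#' sidecar JSON of scalar metadata; ground-truth events as one table
#' (`type, start_s, end_s, state`).
#'
#' @param x list with `record` and `truth` as returned by
#'   [generate_deployment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_deployment_csv <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- x$record
  rec_path <- file.path(dir, "sensor_record.csv")
  utils::write.csv(data.frame(time_s = rec$time, depth_m = rec$depth,
                              ax = rec$acc[, 1], ay = rec$acc[, 2],
                              az = rec$acc[, 3]),
                   rec_path, row.names = FALSE)
  meta_path <- file.path(dir, "sensor_meta.json")
  jsonlite::write_json(rec[c("fs", "animal_id", "body_length_m",
                             "t0_clock_s", "sunrise_s", "sunset_s")],
                       meta_path, auto_unbox = TRUE, digits = NA)
  tr <- x$truth
  ev <- rbind(
    data.frame(type = "dive", start_s = tr$dives$start, end_s = tr$dives$end,
               state = tr$dives$state),
    data.frame(type = "respiration", start_s = tr$resp_times,
               end_s = tr$resp_times, state = NA_integer_),
    data.frame(type = "buzz", start_s = tr$buzzes$start,
               end_s = tr$buzzes$end, state = NA_integer_),
    data.frame(type = "click", start_s = tr$click_times,
               end_s = tr$click_times, state = NA_integer_)
  )
  ev_path <- file.path(dir, "ground_truth.csv")
  utils::write.csv(ev, ev_path, row.names = FALSE)
  invisible(c(rec_path, meta_path, ev_path))
}

#' Read a sensor record written by [write_deployment_csv()]
#'
#' @param dir directory holding `sensor_record.csv` and `sensor_meta.json`.
#' @return a `sensor_record` list.
#' @export
read_sensor_record_csv <- function(dir) {
  df <- utils::read.csv(file.path(dir, "sensor_record.csv"))
  meta <- jsonlite::read_json(file.path(dir, "sensor_meta.json"),
                              simplifyVector = TRUE)
  structure(c(list(time = df$time_s, depth = df$depth_m,
                   acc = cbind(x = df$ax, y = df$ay, z = df$az)),
              meta), class = "sensor_record")
}
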