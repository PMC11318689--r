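#' Detect echolocation clicks in an envelope series
#'
#' Peak detection with a dynamic intensity threshold: a sample is accepted
#' as a click iff it is a local maximum of the (Hilbert-magnitude style)
#' envelope, exceeds `max(noise + threshold_margin, floor_db)` in dB re clip
#' level, and falls at least `blanking` seconds after the previously accepted
#' click (suppressing surface reflections). The noise estimate is the running
#' median of the envelope over `noise_window`, which is robust to click
#' contamination.
#'
#' @param envelope nonnegative linear-amplitude envelope (1 = clip level).
#' @param fs envelope sampling rate (Hz); must give >= 2 samples per ms.
#' @param noise_window running-median window for the noise level (s).
#' @param threshold_margin detection margin above the noise level (dB).
#' @param floor_db minimum absolute threshold (dB re clip), default -60.
#' @param blanking dead time after an accepted click (s), default 0.001.
#' @return a `click_list`: data.frame with `time` (s, strictly increasing)
#'   and `amp_db` (dB re clip, <= 0).
#' @export
detect_clicks <- function(envelope, fs, noise_window = 0.5,
                          threshold_margin = 15, floor_db = -60,
                          blanking = 0.001) {
  if (any(envelope < 0)) stop("envelope must be nonnegative")
  if (fs * blanking < 2) stop("fs too low: blanking interval must span >= 2 samples")
  n <- length(envelope)
  env_db <- 20 * log10(pmax(envelope, 1e-12))
  w <- max(3L, round(noise_window * fs))
  if (w %% 2L == 0L) w <- w + 1L
  noise_db <- 20 * log10(pmax(stats::runmed(envelope, w), 1e-12))
  thresh <- pmax(noise_db + threshold_margin, floor_db)
  is_peak <- c(FALSE, envelope[2:(n - 1)] > envelope[1:(n - 2)] &
                 envelope[2:(n - 1)] >= envelope[3:n], FALSE)
  cand <- which(is_peak & env_db > thresh)
  # blanking: greedy accept in time order
  keep <- integer(0)
  last <- -Inf
  bl <- blanking * fs
  for (i in cand) {
    if (i - last >= bl) { keep <- c(keep, i); last <- i }
  }
  structure(data.frame(time = (keep - 1L) / fs, amp_db = env_db[keep]),
            class = c("click_list", "data.frame"))
}

#' Render a synthetic click envelope
#'
#' Builds a linear-amplitude envelope with exponentially decaying peaks at
#' given click times over a constant noise floor, for exercising
#' [detect_clicks()] without synthesizing broadband audio.
#'
#' @param click_times click times (s).
#' @param duration envelope duration (s).
#' @param fs envelope sampling rate (Hz).
#' @param click_db peak level of each click (dB re clip).
#' @param noise_db noise floor level (dB re clip).
#' @param decay exponential decay time constant of each click (s).
#' @return numeric envelope vector of `round(duration * fs)` samples.
#' @export
render_click_envelope <- function(click_times, duration, fs,
                                  click_db = -40, noise_db = -75,
                                  decay = 1e-4) {
  n <- round(duration * fs)
  env <- rep(10^(noise_db / 20), n)
  amp <- 10^(click_db / 20)
  for (tc in click_times) {
    i0 <- floor(tc * fs) + 1L
    if (i0 > n) next
    i1 <- min(n, i0 + ceiling(5 * decay * fs))
    tt <- (seq.int(i0, i1) - i0) / fs
    seg <- amp * exp(-tt / decay)
    env[i0:i1] <- pmax(env[i0:i1], seg)
  }
  env
}

#' Assemble validated foraging buzzes from a click list
#'
#' Applies the buzz definition in four steps: (i) partition clicks into
#' maximal runs whose internal inter-click intervals are all below
#' `max_ici`; (ii) discard runs of fewer than `min_run` clicks; (iii) retain
#' runs lasting at least `min_dur` seconds and containing at least
#' `min_clicks` clicks; (iv) merge retained runs separated by less than
#' `merge_gap` seconds into single buzzes (click counts summed, spans
#' unioned), reducing double counting of prolonged chases.
#'
#' @param clicks numeric vector of strictly increasing click times (s), or a
#'   `click_list` from [detect_clicks()].
#' @param max_ici maximum within-buzz inter-click interval (s), default 0.010.
#' @param min_run minimum consecutive clicks for run candidacy, default 5.
#' @param min_dur minimum buzz duration (s), default 0.2.
#' @param min_clicks minimum click count (default 101, i.e. "more than 100").
#' @param merge_gap maximum separation merged into one buzz (s), default 1.
#' @return data.frame with `start`, `end`, `n_clicks`.
#' @export
assemble_buzzes <- function(clicks, max_ici = 0.010, min_run = 5,
                            min_dur = 0.2, min_clicks = 101, merge_gap = 1.0) {
  if (is.data.frame(clicks)) clicks <- clicks$time
  if (length(clicks) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0), n_clicks = integer(0)))
  }
  if (is.unsorted(clicks, strictly = TRUE)) stop("click times must be strictly increasing")
  # (i) maximal runs of ICI < max_ici
  brk <- which(diff(clicks) >= max_ici)
  run_start <- c(1L, brk + 1L)
  run_end <- c(brk, length(clicks))
  n_run <- run_end - run_start + 1L
  dur <- clicks[run_end] - clicks[run_start]
  # (ii) + (iii)
  keep <- n_run >= min_run & dur >= min_dur & n_run >= min_clicks
  if (!any(keep)) {
    return(data.frame(start = numeric(0), end = numeric(0), n_clicks = integer(0)))
  }
  s <- clicks[run_start[keep]]
  e <- clicks[run_end[keep]]
  cnt <- n_run[keep]
  # (iv) merge retained runs with gaps < merge_gap
  out_s <- s[1]; out_e <- e[1]; out_n <- cnt[1]
  res <- list()
  for (i in seq_along(s)[-1]) {
    if (s[i] - out_e < merge_gap) {
      out_e <- e[i]; out_n <- out_n + cnt[i]
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e, out_n)
      out_s <- s[i]; out_e <- e[i]; out_n <- cnt[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e, out_n)
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2], n_clicks = as.integer(m[, 3]))
}

#' Attach buzz depths from the depth series
#'
#' Sets each buzz's `median_depth` to the depth at the buzz's temporal
#' midpoint (nearest sample). Buzzes outside the depth record are dropped
#' with a message.
#'
#' @param buzzes data.frame from [assemble_buzzes()].
#' @param time numeric sample times (s) of the depth series.
#' @param depth numeric depth series (m).
#' @return `buzzes` with a `median_depth` column.
#' @export
attach_buzz_depth <- function(buzzes, time, depth) {
  if (nrow(buzzes) == 0) {
    buzzes$median_depth <- numeric(0)
    return(buzzes)
  }
  mid <- (buzzes$start + buzzes$end) / 2
  inside <- mid >= time[1] & mid <= time[length(time)]
  if (any(!inside)) {
    message(sum(!inside), " buzz(es) outside the depth record dropped")
    buzzes <- buzzes[inside, , drop = FALSE]
    mid <- mid[inside]
  }
  fs <- 1 / (time[2] - time[1])
  idx <- pmin(length(depth), pmax(1L, round((mid - time[1]) * fs) + 1L))
  buzzes$median_depth <- depth[idx]
  buzzes
}
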