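#' Squeeze unit-interval values away from the boundaries
#'
#' Standard transformation `(x * (n - 1) + 0.5) / n` mapping \[0, 1\] into
#' (0, 1), required for beta-distributed emission metrics whose density is
#' undefined at the boundaries. `x = 0.5` is a fixed point.
#'
#' @param x values in \[0, 1\].
#' @param n sample size used for the squeeze, >= 1.
#' @return values strictly inside (0, 1).
#' @examples
#' squeeze_unit_interval(c(0, 0.5, 1), 100)  # 0.005 0.5 0.995
#' @export
squeeze_unit_interval <- function(x, n) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("x must lie in [0, 1]")
  if (n < 1) stop("n must be >= 1")
  (x * (n - 1) + 0.5) / n
}

#' Compute the behavioral-state metrics for one dive
#'
#' Derives the eight per-dive metrics used by the mixed HMM: log mean MSA;
#' median buzz depth relative to maximum dive depth; circular variance of
#' pitch and of roll over the dive; proportions of the dive spent at the
#' bottom (within one body length of the maximum depth) and at the surface
#' (within two body lengths of the surface); circular variance of pitch over
#' the bottom phase; and presence/absence of a buzz. `rel_buzz_depth` is
#' missing when the dive has no buzz; `circ_var_pitch_bottom` is missing
#' when no samples fall in the bottom band.
#'
#' @param dive_start,dive_end dive interval (s), half-open.
#' @param buzzes buzz table with `start`, `end`, `median_depth` (midpoint
#'   membership decides which buzzes belong to the dive).
#' @param time,depth,msa,pitch,roll kinematic series covering the dive.
#' @param body_length animal body length (m), > 0.
#' @return one-row data.frame with the eight metrics (raw, pre-squeeze).
#' @export
compute_metrics <- function(dive_start, dive_end, buzzes, time, depth, msa,
                            pitch, roll, body_length) {
  if (body_length <= 0) stop("body_length must be positive")
  idx <- which(time >= dive_start & time < dive_end)
  if (length(idx) == 0) stop("dive contains no samples")
  d <- depth[idx]
  maxd <- max(d)
  in_bottom <- d >= maxd - body_length
  prop_bottom <- mean(in_bottom)
  prop_surface <- mean(d <= 2 * body_length)
  bmid <- (buzzes$start + buzzes$end) / 2
  inb <- bmid >= dive_start & bmid < dive_end
  buzz_present <- as.integer(any(inb))
  rel_buzz_depth <- if (buzz_present == 1L) {
    r <- stats::median(buzzes$median_depth[inb]) / maxd
    min(max(r, 0), 1)
  } else NA_real_
  cv_pitch_bottom <- if (any(in_bottom)) {
    circular_variance(pitch[idx][in_bottom])
  } else NA_real_
  data.frame(
    log_mean_msa = log(mean(msa[idx])),
    rel_buzz_depth = rel_buzz_depth,
    circ_var_pitch = circular_variance(pitch[idx]),
    circ_var_roll = circular_variance(roll[idx]),
    prop_bottom = prop_bottom,
    prop_surface = prop_surface,
    circ_var_pitch_bottom = cv_pitch_bottom,
    buzz_present = buzz_present
  )
}

#' Metric names and emission families used by the mixed HMM
#' @return character vector of family names keyed by metric.
#' @export
metric_families <- function() {
  c(log_mean_msa = "gaussian", rel_buzz_depth = "beta",
    circ_var_pitch = "beta", circ_var_roll = "beta",
    prop_bottom = "beta", prop_surface = "beta",
    circ_var_pitch_bottom = "beta", buzz_present = "bernoulli")
}

#' Build the metric table for all dives of a deployment
#'
#' Applies [compute_metrics()] to every dive and squeezes all beta-family
#' metrics into the open unit interval with [squeeze_unit_interval()] using
#' the number of dives as the squeeze sample size.
#'
#' @param dives data.frame with `start`, `end` (one row per dive).
#' @param buzzes buzz table with `median_depth`.
#' @param kin list with `time`, `depth`, `msa`, `pitch`, `roll`.
#' @param body_length body length (m).
#' @return data.frame of squeezed metrics, one row per dive.
#' @export
build_metric_table <- function(dives, buzzes, kin, body_length) {
  # uniform time base: slice each dive by index arithmetic instead of
  # scanning the whole record per dive
  fs <- 1 / (kin$time[2] - kin$time[1])
  t0 <- kin$time[1]
  n <- length(kin$time)
  rows <- lapply(seq_len(nrow(dives)), function(i) {
    i0 <- max(1L, ceiling((dives$start[i] - t0) * fs - 1e-9) + 1L)
    i1 <- min(n, floor((dives$end[i] - t0) * fs - 1e-9) + 1L)
    idx <- i0:i1
    compute_metrics(dives$start[i], dives$end[i], buzzes,
                    kin$time[idx], kin$depth[idx], kin$msa[idx],
                    kin$pitch[idx], kin$roll[idx], body_length)
  })
  met <- do.call(rbind, rows)
  n <- nrow(met)
  beta_cols <- names(metric_families())[metric_families() == "beta"]
  for (cl in beta_cols) met[[cl]] <- squeeze_unit_interval(met[[cl]], n)
  met
}

#' Build dive cycles and per-cycle behavioral rates
#'
#' A dive cycle runs from the start of a dive to the start of the next dive
#' (dive + subsequent surface period); the last dive has no cycle.
#' Respirations are counted over the half-open cycle interval; buzzes are
#' counted by midpoint membership in the dive; the buzz rate is buzzes per
#' minute of *dive* duration while the respiration rate is respirations per
#' minute of *cycle* duration.
#'
#' @param dives data.frame with `start`, `end`, ordered, non-overlapping.
#' @param resp_times respiration times (s), ordered.
#' @param buzzes buzz table with `start`, `end`.
#' @return data.frame with `dive_start`, `dive_end`, `next_dive_start`,
#'   `cycle_duration`, `n_respirations`, `resp_rate`, `n_buzzes`,
#'   `buzz_rate` (rates in min^-1).
#' @export
build_dive_cycles <- function(dives, resp_times, buzzes) {
  nd <- nrow(dives)
  if (nd < 2) stop("need >= 2 dives to form a cycle")
  if (is.unsorted(dives$start) || any(dives$end[-nd] > dives$start[-1])) {
    stop("dives must be ordered and non-overlapping")
  }
  ds <- dives$start[-nd]
  de <- dives$end[-nd]
  nxt <- dives$start[-1]
  cyc <- nxt - ds
  n_resp <- vapply(seq_along(ds), function(i) {
    sum(resp_times >= ds[i] & resp_times < nxt[i])
  }, integer(1))
  bmid <- (buzzes$start + buzzes$end) / 2
  n_buzz <- vapply(seq_along(ds), function(i) {
    sum(bmid >= ds[i] & bmid < de[i])
  }, integer(1))
  data.frame(
    dive_start = ds, dive_end = de, next_dive_start = nxt,
    cycle_duration = cyc,
    n_respirations = n_resp, resp_rate = n_resp / (cyc / 60),
    n_buzzes = n_buzz, buzz_rate = n_buzz / ((de - ds) / 60)
  )
}
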