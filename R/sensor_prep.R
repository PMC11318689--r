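#' Decimate a sensor series to a lower sampling rate
#'
#' Anti-alias filters and downsamples a uniformly sampled series, e.g. from a
#' tag's native accelerometer rate to the 25 Hz analysis rate. Integer
#' decimation factors use an FIR anti-alias filter; non-integer rational
#' factors use polyphase resampling.
#'
#' @param x numeric vector, uniformly sampled at `fs_in`.
#' @param fs_in input sampling rate (Hz).
#' @param fs_out output sampling rate (Hz), default 25.
#' @return numeric vector of length `ceiling(length(x) * fs_out / fs_in)`.
#' @examples
#' length(decimate_series(rep(5, 250), 250, 25))  # 25 samples, all ~5
#' @export
decimate_series <- function(x, fs_in, fs_out = 25) {
  stopifnot(is.numeric(x), length(x) > 0)
  if (fs_in < fs_out) stop("fs_in must be >= fs_out")
  if (fs_in == fs_out) return(x)
  n_out <- ceiling(length(x) * fs_out / fs_in)
  q <- fs_in / fs_out
  if (abs(q - round(q)) < 1e-9) {
    q <- as.integer(round(q))
    # zero-phase FIR anti-alias (unit DC gain), reflection-padded to tame
    # edge transients, then keep every q-th sample
    ord <- 10L * q
    if (ord %% 2L == 1L) ord <- ord + 1L
    b <- signal::fir1(ord, 1 / q)
    b <- b / sum(b)
    np <- min(ord, length(x) - 1L)
    xp <- c(rev(x[seq_len(np) + 1L]), x,
            rev(x[seq.int(length(x) - np, length(x) - 1L)]))
    yf <- stats::filter(xp, b, sides = 2)
    y <- yf[np + seq_along(x)]
    y <- y[seq.int(1L, length(x), by = q)]
  } else {
    # rational ratio: polyphase resample by p/q
    fr <- .as_rational(fs_out / fs_in)
    y <- signal::resample(x, fr$p, fr$q)
    y <- y[seq_len(min(n_out, length(y)))]
  }
  as.numeric(y[seq_len(min(n_out, length(y)))])
}

.as_rational <- function(r, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(list(p = as.integer(round(p)), q = q))
  }
  stop("sampling-rate ratio is not rational within tolerance")
}

#' Minimum specific acceleration (MSA)
#'
#' MSA is the absolute difference between the Euclidean norm of the measured
#' triaxial acceleration and gravity, a lower bound on the magnitude of
#' specific (non-gravitational) acceleration and a standard activity proxy
#' for tagged cetaceans. It is invariant to tag orientation.
#'
#' @param acc numeric matrix with 3 columns (x, y, z accelerations, m s^-2).
#' @param g gravitational acceleration (m s^-2).
#' @return numeric vector, `abs(sqrt(rowSums(acc^2)) - g)`, NA where input is NA.
#' @examples
#' compute_msa(rbind(c(0, 0, 9.81), c(3, 4, 0)))  # 0, 4.81
#' @export
compute_msa <- function(acc, g = STANDARD_GRAVITY) {
  acc <- .as_acc_matrix(acc)
  msa <- abs(sqrt(rowSums(acc^2)) - g)
  if (anyNA(msa)) warning(sum(is.na(msa)), " NA samples in MSA output")
  msa
}

.as_acc_matrix <- function(acc) {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3) stop("acc must have 3 columns (x, y, z)")
  storage.mode(acc) <- "double"
  acc
}

#' Winsorize the upper tail of a series
#'
#' Values above the p-th percentile are replaced by the percentile value
#' itself (upper winsorization), damping transient spikes while keeping the
#' series length and time alignment intact. The percentile is the empirical
#' order statistic (`stats::quantile` type 1), computed over the whole
#' series; capping at an order statistic leaves that order statistic in
#' place, which makes the operation exactly idempotent.
#'
#' @param x numeric vector.
#' @param p percentile in (0, 100), default 95.
#' @return numeric vector of the same length, `pmin(x, quantile(x, p/100))`.
#' @export
trim_upper_percentile <- function(x, p = 95) {
  if (length(x) == 0) stop("empty series")
  if (!is.numeric(p) || p <= 0 || p >= 100) stop("p must be in (0, 100)")
  cap <- stats::quantile(x, p / 100, na.rm = TRUE, names = FALSE, type = 1)
  pmin(x, cap)
}

#' Estimate pitch and roll from triaxial acceleration
#'
#' Low-pass filters the acceleration (moving average over `window` seconds)
#' to isolate the gravity component, then derives orientation under the tag
#' frame convention x forward, y left, z up with depth positive down:
#' `pitch = -asin(ax / |a|)` (nose-up positive) and `roll = atan2(ay, az)`.
#'
#' @param acc numeric matrix with 3 columns (m s^-2).
#' @param fs sampling rate (Hz).
#' @param window smoothing window (s), default 5; must span >= 1 sample.
#' @return list with numeric vectors `pitch` in \[-pi/2, pi/2\] and `roll`
#'   in (-pi, pi\]; samples where the filtered norm is zero are NaN.
#' @export
estimate_pitch_roll <- function(acc, fs, window = 5) {
  acc <- .as_acc_matrix(acc)
  w <- max(1L, round(window * fs))
  sm <- apply(acc, 2, .moving_average, w = w)
  if (is.null(dim(sm))) sm <- matrix(sm, ncol = 3)
  nrm <- sqrt(rowSums(sm^2))
  bad <- !is.na(nrm) & nrm == 0
  nrm[bad] <- NA_real_
  pitch <- -asin(pmin(1, pmax(-1, sm[, 1] / nrm)))
  roll <- atan2(sm[, 2], sm[, 3])
  pitch[bad] <- NaN
  roll[bad] <- NaN
  list(pitch = pitch, roll = roll)
}

# centred moving average with shrinking windows at the edges
.moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Circular variance of a set of angles
#'
#' Returns `1 - Rbar`, where `Rbar` is the length of the mean resultant
#' vector of the unit vectors `(cos(theta), sin(theta))`. Zero for identical
#' angles, one for a balanced antipodal set; invariant to rotating all
#' angles by a constant.
#'
#' @param angles numeric vector of angles (rad), finite, nonempty.
#' @return dimensionless variance in \[0, 1\].
#' @examples
#' circular_variance(c(0, pi / 2))  # 1 - sqrt(2)/2
#' @export
circular_variance <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0) stop("empty angle set")
  if (any(!is.finite(angles))) stop("angles must be finite")
  rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  max(0, min(1, 1 - rbar))
}

#' Remove the start of a deployment
#'
#' Drops all samples and events before `cut` seconds (default one hour) to
#' limit the influence of capture and handling on downstream behavior.
#' Times are kept on the original deployment clock (not re-zeroed); the cut
#' is half-open, so a sample at exactly `cut` is retained.
#'
#' @param record a `sensor_record` (see [generate_deployment()]) or any list
#'   with a numeric `time` vector and equal-length series components.
#' @param cut seconds to remove from the start, default 3600.
#' @return the record with all samples at `time < cut` removed.
#' @export
trim_deployment_start <- function(record, cut = 3600) {
  tmax <- max(record$time)
  if (tmax <= cut) {
    stop("record (", round(tmax), " s) is not longer than the cut (", cut, " s)")
  }
  keep <- record$time >= cut
  n <- length(record$time)
  for (nm in names(record)) {
    v <- record[[nm]]
    if (is.matrix(v) && nrow(v) == n) {
      record[[nm]] <- v[keep, , drop = FALSE]
    } else if (is.atomic(v) && length(v) == n) {
      record[[nm]] <- v[keep]
    }
  }
  record
}
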