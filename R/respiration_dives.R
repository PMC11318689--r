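#' Detect respirations from the depth trace
#'
#' Finds maximal surfacing segments with depth below `surface_threshold`,
#' places one candidate respiration at each segment's minimum-depth sample
#' (earliest sample on ties), then enforces a minimum inter-respiration
#' interval by dropping candidates closer than `min_iri` to the previously
#' accepted one.
#'
#' @param time numeric sample times (s), uniform.
#' @param depth numeric depth series (m, positive down).
#' @param surface_threshold surfacing depth criterion (m), default 0.5.
#' @param min_iri minimum inter-respiration interval (s), default 0.4.
#' @return numeric vector of respiration times (s), strictly increasing.
#' @export
detect_respirations <- function(time, depth, surface_threshold = 0.5,
                                min_iri = 0.4) {
  at_surface <- depth < surface_threshold
  if (!any(at_surface)) {
    warning("no samples above the surfacing criterion; no respirations found")
    return(numeric(0))
  }
  r <- rle(at_surface)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  surf <- which(r$values)
  cand <- vapply(surf, function(s) {
    idx <- seg_start[s]:seg_end[s]
    idx[which.min(depth[idx])]
  }, integer(1))
  times <- time[cand]
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= min_iri) { keep[i] <- TRUE; last <- times[i] }
  }
  times[keep]
}

#' Build the interbreath-interval (IBI) table
#'
#' One IBI per consecutive respiration pair: duration, maximum depth and
#' mean (winsorized) MSA over the half-open interval `[start, end)`. IBIs
#' tile the record between the first and last respiration.
#'
#' @param resp_times respiration times (s), >= 2, strictly increasing.
#' @param time sample times (s) of the kinematic series.
#' @param depth depth series (m).
#' @param msa MSA series (m s^-2), typically already winsorized.
#' @return data.frame with `start`, `end`, `duration`, `max_depth`,
#'   `mean_msa`.
#' @export
build_ibis <- function(resp_times, time, depth, msa) {
  if (length(resp_times) < 2) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), max_depth = numeric(0),
                      mean_msa = numeric(0)))
  }
  n <- length(resp_times)
  start <- resp_times[-n]
  end <- resp_times[-1]
  bin <- findInterval(time, resp_times, left.open = FALSE)
  inr <- bin >= 1L & bin < n
  idx <- bin[inr]
  max_depth <- rep(NA_real_, n - 1L)
  mean_msa <- rep(NA_real_, n - 1L)
  md <- tapply(depth[inr], idx, max)
  mm <- tapply(msa[inr], idx, mean)
  max_depth[as.integer(names(md))] <- md
  mean_msa[as.integer(names(mm))] <- mm
  data.frame(start = start, end = end, duration = end - start,
             max_depth = max_depth, mean_msa = mean_msa)
}

#' Separate dives from near-surface apneas
#'
#' Fits full-covariance Gaussian multivariate mixtures on log-transformed
#' IBI duration, maximum depth and mean MSA, selecting the number of
#' components by BIC, and labels as dives all IBIs assigned (maximum
#' posterior) to the component whose mean is largest in all three features
#' simultaneously — the longest, deepest, most active group. If no component
#' dominates all three features, the component with the largest mean log
#' maximum depth is used (depth separates dives from surface apneas most
#' cleanly). Zeros in any feature are offset by half its smallest positive
#' value before the log.
#'
#' @param ibis IBI table from [build_ibis()].
#' @param n_components_range candidate component counts, default 2:5.
#' @param seed integer seed (the mixture initialization is deterministic;
#'   the seed is set for strict reproducibility of any downstream draws).
#' @return `ibis` with columns `label` ("dive"/"apnea"), `posterior` (dive-
#'   component posterior probability) and attribute `mixture` (the fit).
#' @importFrom mclust Mclust mclustBIC
#' @export
classify_dives <- function(ibis, n_components_range = 2:5, seed = 1L) {
  if (nrow(ibis) < 10) stop("need >= 10 IBIs to fit the mixture")
  feats <- c("duration", "max_depth", "mean_msa")
  X <- as.matrix(ibis[, feats])
  if (anyNA(X)) stop("IBI features contain NA")
  for (j in seq_len(ncol(X))) {
    pos <- X[, j] > 0
    if (!any(pos)) stop("degenerate feature (all zero): ", feats[j])
    if (any(!pos)) X[!pos, j] <- min(X[pos, j]) / 2
  }
  if (any(apply(X, 2, stats::sd) == 0)) stop("degenerate feature with zero variance")
  lX <- log(X)
  set.seed(seed)
  fit <- mclust::Mclust(lX, G = n_components_range, modelNames = "VVV",
                        verbose = FALSE)
  if (is.null(fit)) {
    fit <- mclust::Mclust(lX, G = n_components_range, verbose = FALSE)
  }
  mu <- fit$parameters$mean  # features x components
  dominant <- which(apply(mu, 2, function(m) all(m >= apply(mu, 1, max) - 1e-12)))
  dive_comp <- if (length(dominant) >= 1) dominant[1] else which.max(mu[2, ])
  label <- ifelse(fit$classification == dive_comp, "dive", "apnea")
  ibis$label <- label
  ibis$posterior <- fit$z[, dive_comp]
  attr(ibis, "mixture") <- list(G = fit$G, model = fit$modelName,
                                bic = fit$bic, dive_component = dive_comp)
  ibis
}
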