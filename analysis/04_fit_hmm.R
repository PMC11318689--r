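#!/usr/bin/env Rscript

# Stage 4 — behavioral-state classification with the mixed HMM.
#
# Computes the eight per-dive metrics for every animal, pools the cohort's
# sequences, fits mixed HMMs over a small (K, C) grid by multi-restart
# maximum likelihood, selects by AIC (ties toward fewer states, then fewer
# contexts), decodes states per animal under its maximum-posterior context,
# and names states from the fitted emissions (lowest buzz probability =
# nonfeeding; higher relative buzz depth = bottom feeding). Restart count
# is deliberately modest here; the full 50-restart protocol is a config
# switch away.

suppressPackageStartupMessages(library(divebudget))

args <- commandArgs(trailingOnly = TRUE)
n_restarts <- if (length(args) >= 1) as.integer(args[1]) else 6L

ids <- list.dirs("scratch/sim", recursive = FALSE)
if (length(ids) == 0) stop("run analysis/01_simulate.R first")

seqs <- list()
dive_tabs <- list()
for (dir in ids) {
  rec <- read_sensor_record_csv(dir)
  ib <- read.csv(file.path(dir, "ibis_labeled.csv"))
  buzz <- read.csv(file.path(dir, "buzzes_detected.csv"))
  dives <- ib[ib$label == "dive", ]
  pr <- estimate_pitch_roll(rec$acc, rec$fs)
  kin <- list(time = rec$time, depth = rec$depth,
              msa = trim_upper_percentile(compute_msa(rec$acc), 95),
              pitch = pr$pitch, roll = pr$roll)
  seqs[[rec$animal_id]] <- build_metric_table(dives, buzz, kin,
                                              rec$body_length_m)
  dive_tabs[[rec$animal_id]] <- cbind(animal_id = rec$animal_id,
                                      dives[, c("start", "end", "duration",
                                                "max_depth")],
                                      dir = dir)
}

fits <- list()
for (K in 2:4) for (C in 1) {
  f <- suppressWarnings(
    fit_mixed_hmm(seqs, K = K, C = C, n_restarts = n_restarts,
                  seed = 100 * K + C, maxit = 300))
  cat(sprintf("K=%d C=%d: loglik %.1f, %d params, AIC %.1f\n",
              K, C, f$loglik, f$n_params, f$aic))
  fits[[length(fits) + 1L]] <- f
}
best <- select_model(fits)
cat(sprintf("Selected K=%d, C=%d by AIC.\n", best$K, best$C))
dec <- decode_states(best$model, seqs)

dir.create("results", showWarnings = FALSE)
write_hmm_json(best, "results/04_hmm_model.json")
all_dives <- do.call(rbind, Map(function(tab, lab) {
  tab$state <- lab
  tab
}, dive_tabs, dec$labels))
write.csv(all_dives[, setdiff(names(all_dives), "dir")],
          "results/04_decoded_dives.csv", row.names = FALSE)
for (a in seq_along(ids)) {
  sub <- all_dives[all_dives$dir == ids[a], ]
  write.csv(sub[, setdiff(names(sub), "dir")],
            file.path(ids[a], "dives_decoded.csv"), row.names = FALSE)
}
tab <- table(all_dives$state)
cat("Decoded state counts:\n")
print(tab)
cat("Model and decoded dive tables in results/04_*.\n")
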