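#' Pipeline configuration
#'
#' Collects every stage parameter with defaults at the standard published
#' values for porpoise DTAG analysis: 25 Hz analysis rate, first hour
#' removed, 0.5 m surfacing criterion, 0.4 s minimum inter-respiration
#' interval, 10 ms / 5 clicks / 0.2 s / >100 clicks / 1 s merge buzz rules,
#' 1 ms click blanking, -60 dB detector floor, 95th-percentile MSA
#' winsorization, bottom and surface bands of 1 and 2 body lengths, 20-min
#' intervals with >0.75 purity, and 50 HMM restarts.
#'
#' @param ... overrides of any default, by name.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fs_out = 25, start_cut = 3600,
    surface_threshold = 0.5, min_iri = 0.4,
    max_ici = 0.010, min_run = 5, min_dur = 0.2, min_clicks = 101,
    merge_gap = 1.0, blanking = 0.001, floor_db = -60,
    noise_window = 0.5, threshold_margin = 15,
    trim_percentile = 95, pitch_window = 5,
    bottom_band_lengths = 1, surface_band_lengths = 2,
    mixture_components = 2:5,
    K_range = 3, C_range = 1, n_restarts = 50, hmm_maxit = 300,
    interval_width = 1200, purity_min = 0.75,
    energy = energy_params(),
    stages = c("prep", "events", "dives", "metrics", "hmm", "energy"),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Round-trip a pipeline configuration through YAML
#'
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @return for `write_`: invisibly `path`; for `read_`: the config.
#' @export
write_pipeline_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$energy <- unclass(out$energy)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$energy <- do.call(energy_params, raw$energy)
  do.call(pipeline_config, raw)
}

#' Day/night labels from sunrise and sunset clock times
#'
#' An event is night iff its clock time lies in the half-open interval
#' from sunset to the next sunrise: an event exactly at sunset is night,
#' exactly at sunrise is day.
#'
#' @param times event times (s from deployment start).
#' @param sunrise_s,sunset_s clock times (s of day); recycled daily.
#' @param t0_clock_s clock time of deployment start (s of day).
#' @return character vector "day"/"night".
#' @export
diel_split <- function(times, sunrise_s, sunset_s, t0_clock_s = 0) {
  clock <- (t0_clock_s + times) %% 86400
  ifelse(clock >= sunset_s | clock < sunrise_s, "night", "day")
}

# tiny polynomial content hash for run provenance
.config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline on one deployment
#'
#' Executes prep (trim, MSA, pitch/roll), event detection (respirations from
#' depth, buzzes from the click list), dive/apnea separation, per-dive
#' metrics and dive cycles, mixed-HMM fitting and decoding over the
#' configured (K, C) grid, and the energy summaries (20-min intervals,
#' nonfeeding-normalized rates, diel buzz rates, cumulative balance). Rerun
#' with the same config and inputs is bit-identical.
#'
#' @param record a `sensor_record`.
#' @param click_times detected click times (s), or NULL for no acoustics.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory to write tables, model JSON, report
#'   and log.
#' @return list with all stage outputs and a scalar `report`.
#' @export
run_pipeline <- function(record, click_times, config = pipeline_config(),
                         out_dir = NULL) {
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  note("config hash ", .config_hash(config), " seed ", config$seed)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  st <- config$stages
  out <- list(config = config)

  # ---- prep ---------------------------------------------------------------
  kin <- run_stage("prep", {
    rec <- if (config$start_cut > 0) {
      trim_deployment_start(record, config$start_cut)
    } else record
    msa <- compute_msa(rec$acc)
    msa <- trim_upper_percentile(msa, config$trim_percentile)
    pr <- estimate_pitch_roll(rec$acc, rec$fs, config$pitch_window)
    list(time = rec$time, depth = rec$depth, msa = msa,
         pitch = pr$pitch, roll = pr$roll, fs = rec$fs,
         animal_id = rec$animal_id, body_length_m = rec$body_length_m,
         t0_clock_s = rec$t0_clock_s, sunrise_s = rec$sunrise_s,
         sunset_s = rec$sunset_s)
  })
  out$kin <- kin
  note("prep: ", length(kin$time), " samples retained after ",
       config$start_cut, " s cut")
  if (!"events" %in% st) return(.finish_pipeline(out, log_lines, out_dir))

  # ---- events -------------------------------------------------------------
  ev <- run_stage("events", {
    resp <- detect_respirations(kin$time, kin$depth,
                                config$surface_threshold, config$min_iri)
    clicks <- if (is.null(click_times)) numeric(0) else {
      click_times[click_times >= kin$time[1]]
    }
    buzz <- assemble_buzzes(clicks, config$max_ici, config$min_run,
                            config$min_dur, config$min_clicks,
                            config$merge_gap)
    buzz <- attach_buzz_depth(buzz, kin$time, kin$depth)
    list(resp = resp, clicks = clicks, buzzes = buzz)
  })
  out$respirations <- ev$resp
  out$buzzes <- ev$buzzes
  note("events: ", length(ev$resp), " respirations, ", length(ev$clicks),
       " clicks, ", nrow(ev$buzzes), " buzzes")
  if (!"dives" %in% st) return(.finish_pipeline(out, log_lines, out_dir))

  # ---- dives --------------------------------------------------------------
  ibis <- run_stage("dives", {
    tab <- build_ibis(ev$resp, kin$time, kin$depth, kin$msa)
    classify_dives(tab, config$mixture_components, config$seed)
  })
  out$ibis <- ibis
  dives <- ibis[ibis$label == "dive", c("start", "end", "duration", "max_depth")]
  rownames(dives) <- NULL
  out$dives <- dives
  note("dives: ", nrow(ibis), " IBIs, ", nrow(dives), " classified as dives")
  if (!"metrics" %in% st) return(.finish_pipeline(out, log_lines, out_dir))

  # ---- metrics ------------------------------------------------------------
  mt <- run_stage("metrics", {
    met <- build_metric_table(dives, ev$buzzes, kin, kin$body_length_m)
    cyc <- build_dive_cycles(dives, ev$resp, ev$buzzes)
    list(metrics = met, cycles = cyc)
  })
  out$metrics <- mt$metrics
  out$cycles <- mt$cycles
  note("metrics: ", nrow(mt$metrics), " metric vectors, ",
       nrow(mt$cycles), " dive cycles")
  if (!"hmm" %in% st) return(.finish_pipeline(out, log_lines, out_dir))

  # ---- hmm ----------------------------------------------------------------
  hm <- run_stage("hmm", {
    seqs <- list(mt$metrics)
    fits <- list()
    for (K in config$K_range) for (C in config$C_range) {
      fits[[length(fits) + 1L]] <-
        fit_mixed_hmm(seqs, K, C, config$n_restarts,
                      seed = config$seed + 100L * K + C,
                      maxit = config$hmm_maxit)
    }
    best <- select_model(fits)
    dec <- decode_states(best$model, seqs)
    list(fits = fits, best = best, decoded = dec)
  })
  out$fit <- hm$best
  out$decoded <- hm$decoded
  out$dives$state <- hm$decoded$labels[[1]]
  n_cyc <- nrow(mt$cycles)
  out$cycles$state <- hm$decoded$labels[[1]][seq_len(n_cyc)]
  note("hmm: selected K=", hm$best$K, " C=", hm$best$C,
       " AIC=", round(hm$best$aic, 2))
  if (!"energy" %in% st) return(.finish_pipeline(out, log_lines, out_dir))

  # ---- energy -------------------------------------------------------------
  en <- run_stage("energy", {
    intervals <- summarize_intervals(out$cycles, ev$resp, ev$buzzes, kin,
                                     config$interval_width, config$purity_min)
    hours <- (max(kin$time) - min(kin$time)) / 3600
    diel <- .diel_buzz_rates(ev$buzzes, kin)
    bal <- if (nrow(ev$buzzes) > 0 && length(ev$resp) > 0) {
      energy_balance(ev$resp, (ev$buzzes$start + ev$buzzes$end) / 2,
                     config$energy, hours)
    } else NULL
    list(intervals = intervals, diel = diel, balance = bal, hours = hours)
  })
  out$intervals <- en$intervals
  out$diel <- en$diel
  out$balance <- en$balance
  note("energy: ", sum(en$intervals$retained), "/", nrow(en$intervals),
       " intervals retained; night:day buzz-rate ratio ",
       round(en$diel$ratio, 3))

  out$report <- list(
    animal_id = kin$animal_id,
    analyzed_hours = en$hours,
    n_respirations = length(ev$resp),
    n_ibis = nrow(ibis),
    n_dives = nrow(dives),
    n_buzzes = nrow(ev$buzzes),
    prop_time_diving = sum(dives$end - dives$start) /
      (max(kin$time) - min(kin$time)),
    mean_dive_duration_s = mean(dives$end - dives$start),
    buzzes_per_day = nrow(ev$buzzes) / en$hours * 24,
    night_day_buzz_ratio = en$diel$ratio,
    hmm_K = out$fit$K, hmm_C = out$fit$C, hmm_aic = out$fit$aic,
    state_time_fractions = .state_time_fractions(out$cycles),
    config_hash = .config_hash(config), seed = config$seed
  )
  .finish_pipeline(out, log_lines, out_dir)
}

.state_time_fractions <- function(cycles) {
  if (is.null(cycles$state)) return(NULL)
  tt <- tapply(cycles$cycle_duration, cycles$state, sum)
  as.list(tt / sum(tt))
}

# buzzes per hour at night vs day, using the record's diel coverage
.diel_buzz_rates <- function(buzzes, kin) {
  grid <- seq(min(kin$time), max(kin$time), by = 1)
  lab <- diel_split(grid, kin$sunrise_s, kin$sunset_s, kin$t0_clock_s)
  hours_night <- sum(lab == "night") / 3600
  hours_day <- sum(lab == "day") / 3600
  bmid <- (buzzes$start + buzzes$end) / 2
  blab <- diel_split(bmid, kin$sunrise_s, kin$sunset_s, kin$t0_clock_s)
  n_night <- sum(blab == "night")
  n_day <- sum(blab == "day")
  rate_n <- if (hours_night > 0) n_night / hours_night else NA_real_
  rate_d <- if (hours_day > 0) n_day / hours_day else NA_real_
  list(n_night = n_night, n_day = n_day, hours_night = hours_night,
       hours_day = hours_day, rate_night = rate_n, rate_day = rate_d,
       ratio = rate_n / rate_d)
}

.finish_pipeline <- function(out, log_lines, out_dir) {
  out$log <- log_lines
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(df, name) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
    if (!is.null(out$ibis)) wcsv(out$ibis, "ibis.csv")
    if (!is.null(out$dives)) wcsv(out$dives, "dives.csv")
    if (!is.null(out$cycles)) wcsv(out$cycles, "dive_cycles.csv")
    if (!is.null(out$buzzes)) wcsv(out$buzzes, "buzzes.csv")
    if (!is.null(out$respirations)) {
      wcsv(data.frame(time_s = out$respirations), "respirations.csv")
    }
    if (!is.null(out$intervals)) wcsv(out$intervals, "intervals.csv")
    if (!is.null(out$fit)) write_hmm_json(out$fit, file.path(out_dir, "model.json"))
    if (!is.null(out$report)) {
      jsonlite::write_json(out$report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  out
}
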