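#' Energetic parameter set
#'
#' Defaults describe a representative adult 40-kg harbor porpoise: daily
#' field metabolic rate 15 MJ, 90% assimilation efficiency, prey calorific
#' value 4.2 kJ g^-1 (small fish), and specific dynamic action at 12.5% of
#' the FMR.
#'
#' @param daily_fmr field metabolic rate (MJ day^-1).
#' @param assimilation assimilation efficiency in (0, 1].
#' @param prey_energy_density prey calorific value (kJ g^-1).
#' @param sda_fraction SDA as a proportion of FMR.
#' @param body_mass body mass (kg).
#' @return list of class `energy_params`.
#' @export
energy_params <- function(daily_fmr = 15, assimilation = 0.90,
                          prey_energy_density = 4.2, sda_fraction = 0.125,
                          body_mass = 40) {
  if (daily_fmr <= 0 || prey_energy_density <= 0 || sda_fraction <= 0 ||
      body_mass <= 0) stop("all energetic parameters must be positive")
  if (assimilation <= 0 || assimilation > 1) stop("assimilation must be in (0, 1]")
  structure(list(daily_fmr = daily_fmr, assimilation = assimilation,
                 prey_energy_density = prey_energy_density,
                 sda_fraction = sda_fraction, body_mass = body_mass),
            class = "energy_params")
}

#' Summarize behavior and energy proxies over fixed intervals
#'
#' Splits the record into non-overlapping contiguous windows (default
#' 20 min, about ten dive cycles) and, per window, computes the time spent
#' in each behavioral state from dive-cycle overlap, the majority state and
#' its purity, and event counts (respirations, buzzes) by timestamp. Windows
#' are retained for energetic comparison only when one state occupies more
#' than `purity_min` of the window, so mixed-behavior windows do not dilute
#' state-specific costs.
#'
#' @param cycles dive-cycle table with `dive_start`, `next_dive_start` and a
#'   `state` column (decoded labels).
#' @param resp_times respiration times (s).
#' @param buzzes buzz table with `start`, `end`.
#' @param kin optional kinematic series (`time`, `msa`) for a per-window
#'   summed MSA.
#' @param width window width (s), default 1200.
#' @param purity_min retention threshold on the majority-state share,
#'   default 0.75 (strict inequality).
#' @return data.frame with `start`, `width`, `majority_state`, `purity`,
#'   `n_respirations`, `n_buzzes`, `total_msa`, `retained`.
#' @export
summarize_intervals <- function(cycles, resp_times, buzzes, kin = NULL,
                                width = 1200, purity_min = 0.75) {
  if (nrow(cycles) == 0) {
    return(data.frame(start = numeric(0), width = numeric(0),
                      majority_state = character(0), purity = numeric(0),
                      n_respirations = integer(0), n_buzzes = integer(0),
                      total_msa = numeric(0), retained = logical(0)))
  }
  if (is.null(cycles$state)) stop("cycles must carry decoded states")
  t0 <- cycles$dive_start[1]
  t1 <- max(cycles$next_dive_start)
  n_win <- ceiling((t1 - t0) / width - 1e-9)
  starts <- t0 + width * (seq_len(n_win) - 1L)
  states <- unique(cycles$state)
  bmid <- (buzzes$start + buzzes$end) / 2
  out <- lapply(starts, function(w0) {
    w1 <- w0 + width
    ov <- pmin(cycles$next_dive_start, w1) - pmax(cycles$dive_start, w0)
    ov[ov < 0] <- 0
    by_state <- tapply(ov, cycles$state, sum)
    by_state <- by_state[!is.na(by_state)]
    tot <- sum(by_state)
    if (tot <= 1e-9) return(NULL)
    maj <- names(by_state)[which.max(by_state)]
    purity <- max(by_state) / tot
    data.frame(
      start = w0, width = width, majority_state = maj, purity = purity,
      n_respirations = sum(resp_times >= w0 & resp_times < w1),
      n_buzzes = sum(bmid >= w0 & bmid < w1),
      total_msa = if (!is.null(kin)) {
        sum(kin$msa[kin$time >= w0 & kin$time < w1])
      } else NA_real_,
      retained = purity > purity_min
    )
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Normalize a metric by the animal's nonfeeding reference
#'
#' Divides each value by the animal's median over nonfeeding dives, so the
#' nonfeeding median maps to exactly 1 and state contrasts are expressed as
#' relative elevations.
#'
#' @param values numeric metric values.
#' @param reference_values the same metric over the animal's nonfeeding
#'   dives; must be nonempty with nonzero median.
#' @return `values / median(reference_values)`.
#' @export
normalize_by_nonfeeding <- function(values, reference_values) {
  if (length(reference_values) == 0) stop("no nonfeeding reference dives")
  ref <- stats::median(reference_values)
  if (!is.finite(ref) || ref == 0) stop("nonfeeding reference median is zero or undefined")
  values / ref
}

#' Activity-specific field metabolic rates
#'
#' Distributes a daily FMR over behavioral states given the fraction of
#' total time spent in each state and each state's relative metabolic rate
#' (reference state = 1, e.g. respiration-rate elevations): solves
#' `base * sum(f_s * m_s) = daily_fmr / 24` for the base hourly rate and
#' returns `base * m_s` per state, in kJ h^-1. Energy is conserved:
#' the time-weighted rates integrate back to the daily FMR.
#'
#' @param daily_fmr daily field metabolic rate (MJ day^-1).
#' @param time_fractions per-state fractions of total time, summing to 1.
#' @param multipliers per-state relative rates, positive, reference = 1.
#' @return named numeric vector of per-state FMRs (kJ h^-1).
#' @examples
#' activity_specific_fmr(15, c(nonfeeding = 0.38, pelagic = 0.37,
#'                             bottom = 0.25), c(1, 1.22, 1.09))
#' @export
activity_specific_fmr <- function(daily_fmr, time_fractions, multipliers) {
  if (abs(sum(time_fractions) - 1) > 1e-9) stop("time fractions must sum to 1")
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  hourly_kj <- daily_fmr * 1000 / 24
  base <- hourly_kj / sum(time_fractions * multipliers)
  stats::setNames(base * multipliers, names(time_fractions))
}

#' Foraging efficiency
#'
#' The energy acquired while foraging divided by the marginal cost of
#' foraging — the excess of foraging expenditure over what the same hours
#' would have cost at the nonfeeding rate. All ingestion is attributed to
#' foraging time; `gross = FALSE` multiplies the intake by the assimilation
#' efficiency before the ratio (both conventions are in circulation, and
#' printed inputs do not pin one down, so the flag is explicit).
#'
#' @param intake daily ingested energy (MJ day^-1).
#' @param assimilation assimilation efficiency in (0, 1].
#' @param state_fmrs per-state FMRs (kJ h^-1) named or ordered as
#'   `time_fractions`; the first element must be the nonfeeding state.
#' @param time_fractions per-state fractions of total time (first element
#'   nonfeeding), summing to 1.
#' @param gross if TRUE (default) use gross intake; else assimilated.
#' @return dimensionless efficiency ratio.
#' @export
foraging_efficiency <- function(intake, assimilation, state_fmrs,
                                time_fractions, gross = TRUE) {
  if (abs(sum(time_fractions) - 1) > 1e-9) stop("time fractions must sum to 1")
  f_forage <- time_fractions[-1]
  if (sum(f_forage) <= 0) stop("no foraging time")
  fmr_nf <- state_fmrs[1]
  fmr_forage <- sum(state_fmrs[-1] * f_forage) / sum(f_forage)
  marginal_rate <- fmr_forage - fmr_nf  # kJ h^-1
  if (marginal_rate <= 0) stop("zero or negative marginal cost of foraging: efficiency undefined")
  forage_hours <- 24 * sum(f_forage)
  marginal_daily <- marginal_rate * forage_hours  # kJ day^-1
  acquired <- intake * 1000 * if (gross) 1 else assimilation
  acquired / marginal_daily
}

#' Cumulative energy balance from respirations and buzzes
#'
#' Allocates the deployment's total metabolic expenditure evenly over
#' respirations and its total assimilated intake evenly over buzzes
#' (prey-capture attempts), then accumulates gains minus expenditures over
#' time. By construction the balance returns to zero at the end of the
#' deployment; the trajectory shows when the animal runs an energetic
#' deficit or surplus. The implied gross energy per buzz is
#' `total_fmr / assimilation / n_buzzes`, convertible to prey mass via the
#' prey energy density.
#'
#' @param resp_times respiration times (s), nonempty.
#' @param buzz_times buzz times (s, e.g. midpoints), nonempty.
#' @param params an [energy_params()].
#' @param deployment_hours deployment duration (h).
#' @return list with `times`, `balance` (MJ, event-ordered cumulative),
#'   `per_resp_kj`, `per_buzz_kj_assimilated`, `per_buzz_kj_gross`,
#'   `prey_g_per_buzz`.
#' @export
energy_balance <- function(resp_times, buzz_times, params, deployment_hours) {
  if (length(resp_times) == 0) stop("need at least one respiration")
  if (length(buzz_times) == 0) stop("energy per buzz undefined with zero buzzes")
  total_mj <- params$daily_fmr * deployment_hours / 24
  per_resp <- total_mj * 1000 / length(resp_times)     # kJ
  per_buzz <- total_mj * 1000 / length(buzz_times)     # kJ assimilated
  ev <- rbind(data.frame(t = resp_times, dE = -per_resp),
              data.frame(t = buzz_times, dE = per_buzz))
  ev <- ev[order(ev$t), ]
  list(times = ev$t, balance = cumsum(ev$dE) / 1000,
       per_resp_kj = per_resp,
       per_buzz_kj_assimilated = per_buzz,
       per_buzz_kj_gross = per_buzz / params$assimilation,
       prey_g_per_buzz = per_buzz / params$assimilation / params$prey_energy_density)
}

#' Metabolic scope
#'
#' Ratio of mass-specific maximal oxygen consumption to mass-specific
#' average FMR, rounded half-away-from-zero to one decimal, the convention
#' of published cross-species comparisons.
#'
#' @param vo2max mass-specific VO2max (L O2 h^-1 kg^-1), > 0.
#' @param fmr mass-specific FMR (L O2 h^-1 kg^-1), > 0.
#' @return scope factor, one decimal.
#' @examples
#' metabolic_scope(11.0, 0.9)  # 12.2
#' @export
metabolic_scope <- function(vo2max, fmr) {
  if (any(vo2max <= 0) || any(fmr <= 0)) stop("inputs must be positive")
  r <- vo2max / fmr
  sign(r) * floor(abs(r) * 10 + 0.5) / 10
}

#' Relative FMR increase during foraging attributable to SDA
#'
#' If all digestion (specific dynamic action, a fixed fraction of daily
#' FMR) is concentrated into the foraging hours, the foraging-time FMR is
#' elevated by `sda_fraction / foraging_time_fraction` relative to the
#' average FMR.
#'
#' @param sda_fraction SDA as a proportion of daily FMR, in (0, 1].
#' @param foraging_time_fraction proportion of time spent foraging, (0, 1].
#' @return relative increase (proportion).
#' @examples
#' sda_scenario(0.125, 0.52)  # ~0.24
#' @export
sda_scenario <- function(sda_fraction, foraging_time_fraction) {
  if (sda_fraction <= 0 || sda_fraction > 1 ||
      foraging_time_fraction <= 0 || foraging_time_fraction > 1) {
    stop("fractions must be in (0, 1]")
  }
  sda_fraction / foraging_time_fraction
}
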