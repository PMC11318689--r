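# divebudget

Behavioral states and time–energy budgets from biologging tag data.

Small marine mammal predators such as harbor porpoises carry high field
metabolic rates (FMRs) yet live on prey a thousandth their size, which they
can only afford by hunting almost continuously at low marginal cost.
Quantifying that strategy from archival tag (DTAG-style) records means
walking a long chain: calibrated depth and triaxial acceleration at 25 Hz,
plus echolocation click times, must become respirations, foraging buzzes,
dives, behavioral states and finally state-specific energetic rates.
`divebudget` implements the whole chain for R users working with dive-scale
biologging data, together with a synthetic deployment generator carrying
full ground truth so that every stage is verifiable.

## What it computes

- **Kinematics** — minimum specific acceleration `MSA = | ||a|| − g |`
  (orientation-free activity proxy, winsorized at the record's 95th
  percentile), pitch/roll from the 5 s low-passed gravity component,
  circular variances.
- **Events** — respirations (one per sub-0.5 m surfacing, ≥ 0.4 s apart)
  and buzzes: maximal click runs with inter-click intervals < 10 ms, ≥ 5
  consecutive clicks, duration ≥ 0.2 s, > 100 clicks, merged below 1 s
  separation.
- **Dives** — interbreath intervals split into true dives vs near-surface
  apneas by a full-covariance Gaussian mixture on (log duration, log max
  depth, log mean MSA), BIC-selected, the long/deep/active component
  labeled dive.
- **States** — a mixed hidden Markov model over eight per-dive metrics
  (Gaussian log MSA; beta relative buzz depth, pitch/roll circular
  variances, bottom/surface proportions, bottom-phase pitch variance;
  Bernoulli buzz presence), with C discrete "behavioral context" levels
  sharing emissions but owning their transition matrices. Direct marginal
  maximum likelihood with multi-restart BFGS, AIC selection, Viterbi
  decoding, and naming of states from their emissions (nonfeeding /
  pelagic feeding / bottom feeding).
- **Energetics** — dive cycles and 20-min interval summaries (> 75% purity
  rule), nonfeeding-normalized contrasts, activity-specific FMRs,
  foraging efficiency, cumulative energy balance, metabolic scope, and a
  specific-dynamic-action scenario.

## Worked example

Simulate a deployment under the default three-state shallow-water regime,
run the pipeline, and look at the report:

```r
library(divebudget)

cfg <- gen_config(duration_h = 4, seed = 7)
sim <- generate_deployment(cfg)
pc  <- pipeline_config(start_cut = 0, n_restarts = 3, seed = 5)
res <- run_pipeline(sim$record, sim$truth$click_times, pc)
cat(res$log, sep = "\n")
#> config hash 206a0429 seed 5
#> prep: 358729 samples retained after 0 s cut
#> events: 678 respirations, 35074 clicks, 197 buzzes
#> dives: 677 IBIs, 165 classified as dives
#> metrics: 165 metric vectors, 164 dive cycles
#> hmm: selected K=3 C=1 AIC=-3957.81
#> energy: 6/12 intervals retained; night:day buzz-rate ratio NA
```

All 678 scheduled respirations and all 165 scheduled dives were recovered
(the generator guarantees detector separability), the mixture classified a
minority of interbreath intervals as dives (165 of 677 — the rest are
surface apneas between breaths), and the HMM settled on three states. The
diel ratio is `NA` here because this short deployment starts at noon and
never reaches nighttime.

The energetic arithmetic is available directly. A representative 40 kg
porpoise at 15 MJ/day spends 625 kJ/h on average; with 38/37/25% of time
in nonfeeding/pelagic/bottom states and respiration-rate elevations of
22% and 9% over nonfeeding:

```r
activity_specific_fmr(15, c(nonfeeding = .38, pelagic = .37, bottom = .25),
                      c(1, 1.22, 1.09))
#> nonfeeding    pelagic     bottom
#>   566.1745   690.7329   617.1302
metabolic_scope(11.0, 0.9)   # coyote: 12.2
metabolic_scope(2.0, 1.1)    # harbor seal: 1.8
```

## Analysis workflow

`analysis/` holds the numbered drivers that reproduce the full study flow
on a simulated cohort (bulky sensor records go to `scratch/`, derived
tables to `results/`):

```sh
Rscript analysis/01_simulate.R        # cohort of synthetic deployments
Rscript analysis/02_detect_events.R   # respirations + buzzes, scored vs truth
Rscript analysis/03_classify_dives.R  # IBI mixture -> dive tables
Rscript analysis/04_fit_hmm.R         # mixed HMM, AIC selection, decoding
Rscript analysis/05_energy_budget.R   # time-energy budgets and scalars
```

## Vignette

`vignettes/divebudget-methods.Rmd` documents the model and the design
decisions: emission families and the missing-metric policy, the context
random effect, restart initialization and numerical floors, the
winsorization and percentile conventions, what the synthetic generator
does and does not emulate, and the package's known limitations.
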