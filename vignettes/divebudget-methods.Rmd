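---
title: "From tag records to time-energy budgets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tag records to time-energy budgets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divebudget)
```

## The problem

Small cetaceans such as harbor porpoises are expensive animals: a high
surface-to-volume ratio in cold water forces a high field metabolic rate
(FMR), yet they subsist on prey orders of magnitude smaller than themselves.
Quantifying how such an animal allocates time and energy across behaviors
requires going from raw tag sensor streams — depth and triaxial acceleration
at tens of hertz, plus echolocation clicks — to behavioral states and
state-specific energetic rates. `divebudget` implements that chain as
testable stages:

1. **Kinematics** — minimum specific acceleration (MSA), pitch, roll.
2. **Events** — respirations from the depth trace; foraging buzzes from
   click trains.
3. **Dives** — interbreath intervals (IBIs) split into true dives and
   near-surface apneas with a Gaussian multivariate mixture.
4. **States** — a mixed hidden Markov model (HMM) over per-dive metrics.
5. **Energetics** — interval summaries, activity-specific FMRs, foraging
   efficiency, cumulative energy balance.

Because no public deployment accompanies the analysis, a synthetic tag-data
generator with complete ground truth is a first-class part of the package:
every stage is validated against data whose answer is known.

## Kinematic preprocessing

MSA is `| ||a|| - g |`, a lower bound on the specific (non-gravitational)
acceleration magnitude that needs no orientation correction; it is the
activity proxy throughout. MSA above the record's 95th percentile is
winsorized (replaced by the percentile value) rather than deleted: deletion
would desynchronize the MSA series from depth, while winsorizing preserves
time alignment. The percentile is the empirical order statistic (type 1)
and is computed per deployment, since transient tag spikes are a
record-level artifact. The order-statistic convention is chosen over
interpolated quantiles deliberately: capping at an order statistic leaves
that order statistic in place, so winsorization is exactly idempotent —
under interpolated conventions a second pass would keep nibbling at the
tail. The suite checks idempotence exactly.

Pitch and roll come from the gravity component of acceleration, isolated
with a 5 s moving average — long relative to porpoise stroke cycles
(roughly 1–2 Hz), short relative to dive phases. The tag frame is x
forward, y left, z up, depth positive down, giving `pitch = -asin(ax/||a||)`
(nose-up positive) and `roll = atan2(ay, az)`. Only circular variances of
these angles enter the HMM, so downstream results are insensitive to the
sign convention up to reflection. Circular variance is `1 - Rbar`, the
standard dispersion of unit vectors, bounded in [0, 1] and invariant to
rotating all angles.

The first deployment hour is removed (half-open cut; times stay on the
original clock) to limit handling effects; records are decimated to a 25 Hz
analysis rate with an anti-alias FIR filter before any feature extraction.

## Event detection

**Respirations.** Each maximal surfacing segment (depth < 0.5 m) yields one
candidate at its minimum-depth sample (earliest on ties); candidates closer
than 0.4 s to the previous accepted breath are dropped. On synthetic
records, whose breaths are spaced >= 0.4 s with > 0.5 m submersion bumps
between them, recall and precision are exactly 1 at a one-sample tolerance
— the detector's acceptance is crisp by design of the generator.

**Clicks and buzzes.** The click detector operates on a linear amplitude
envelope: a sample is a click iff it is a local maximum exceeding
`max(noise + margin, -60 dB)` re clip level and at least 1 ms after the
previous accepted click (suppressing surface reflections). The dynamic
noise term is a running median over 0.5 s, robust to the clicks themselves;
the margin (default +15 dB) and window are configuration, since published
dynamic-threshold detectors differ in the exact statistic. Buzzes — the
terminal echolocation phase marking prey-capture attempts — are assembled
from click times in four steps: (i) maximal runs with all inter-click
intervals < 10 ms, (ii) runs of >= 5 clicks, (iii) retained if lasting
>= 0.2 s with > 100 clicks, (iv) retained runs closer than 1 s merged (the
thresholds apply *before* merging; the alternative order is not
distinguishable from published descriptions, so the choice is explicit).
A merged buzz counts as one buzz everywhere downstream. The implementation
is checked for exact agreement with an independent brute-force application
of rules (i)–(iv) on a thousand random click trains straddling every
threshold.

## Dives versus apneas

Porpoises take repeated breaths between dives, so consecutive-respiration
intervals mix true dives with brief surface apneas. A full-covariance
Gaussian mixture on log IBI duration, log maximum depth and log mean MSA
(all three logged — the features are right-skewed and positive) separates
them; the component count (2–5) is chosen by BIC via `mclust`, whose
deterministic hierarchical initialization makes the fit reproducible
without restarts. The dive class is the component whose mean is largest in
*all three* features; when no component dominates, the deepest-mean
component wins, depth being the cleanest separator of dives from surface
apneas. Zeros are offset by half the smallest positive value before
logging. The dominance rule is invariant to positive rescaling of the raw
features (a log-shift), which the suite verifies.

## The mixed hidden Markov model

Each dive contributes eight metrics: log mean MSA (Gaussian); median buzz
depth relative to maximum dive depth, circular variances of pitch and roll,
proportions of the dive within one body length of the maximum depth
("bottom") and within two body lengths of the surface, circular variance of
pitch over the bottom phase (all beta); and buzz presence (Bernoulli).
Unit-interval metrics are squeezed to `(x(n-1)+0.5)/n` so beta densities
are finite. Relative buzz depth is missing when no buzz occurred and the
bottom-phase pitch variance when no sample lies in the bottom band; missing
metrics simply contribute no emission term (marginalization by omission —
the Bernoulli term already carries presence information, so this is
missing-at-random by construction).

States are shared across animals, but individuals may follow different
transition regimes: the model has C "behavioral contexts", discrete
random-effect levels each owning a transition matrix, with mixture weights
summing to one. Emissions are shared across contexts — contexts differ
only in their dynamics. Each animal's likelihood marginalizes over
contexts; the initial distribution is the stationary distribution of each
context's matrix, the natural choice for records much longer than the
mixing time. At C = 1 the machinery reduces exactly to a standard HMM.

Fitting maximizes the marginal likelihood directly with BFGS on an
unconstrained working scale (log/logit for emissions, multinomial logits
for transition rows and weights) rather than EM: the context mixture makes
the direct marginal likelihood the cleaner objective, and it matches a
multi-restart protocol naturally. The default is 50 restarts; restart
initializations perturb moment estimates from quantile splits of the
activity metric and draw Dirichlet-perturbed diagonal-dominant transition
matrices. Per-metric log densities are floored at -700 nats to keep the
objective finite near support boundaries, and emission concentration is
bounded: Gaussian standard deviations at >= 0.05 on the log-MSA scale and
beta shapes in [0.2, 100]. Without these bounds the likelihood is unbounded
— a state can collapse onto a single dive's metric values (the classic
degenerate spike of Gaussian mixtures, equally present for spiky betas),
which both corrupts fits and lets an extra state buy spurious AIC
improvements. The bounds encode that behavioral states are modes of
behavior, not point masses: no state concentrates a unit-interval metric
into a sub-3% band or log activity into a 0.05-nat band. Convergence uses
a relative tolerance of 1e-8 with a 300-iteration cap per restart,
followed by a short polishing run from the best restart with tighter
finite-difference steps, which brings moment-matching collapses (e.g. the
single-state Gaussian mean) to within ~1e-6 of their closed forms. The forward
recursion and Viterbi decoder are compiled (Rcpp); the forward pass is
verified against exhaustive path enumeration to 1e-8 nats.

Model selection is by AIC (`2p - 2logLik` with `p = 15K + CK(K-1) + (C-1)`),
ties broken toward fewer states and then fewer contexts — a parsimony
preference that matters because label symmetries make near-ties common.
Decoding is Viterbi under each animal's maximum-posterior context
(forward-backward smoothing is available as an option; on well-separated
data the two agree almost everywhere). Fitted states are mapped to names by
their emissions: lowest buzz probability = nonfeeding; of the remainder the
higher relative-buzz-depth mean = bottom feeding; the other = pelagic
feeding. This rule doubles as a canonical ordering that resolves
label switching.

## Energetics

Dive cycles run from a dive's start to the next dive's start. Respiration
rate is breaths per minute of *cycle*; buzz rate is buzzes per minute of
*dive* duration. Twenty-minute windows (about ten cycles, long enough to
absorb cost spillover between successive dives) receive the state occupying
most of their time and are retained only when that share exceeds 75%, so
mixed-behavior windows do not dilute state contrasts; counts are assigned
by event timestamp, not prorated, to stay consistent with count-based
rates. Per-animal normalization divides by the animal's nonfeeding median,
mapping that reference to exactly 1.

Activity-specific FMRs distribute a daily FMR over states: given fractions
of total time `f_s` and relative rates `m_s` (reference state 1), the base
rate solves `base * sum(f_s m_s) = FMR/24`, so the time-weighted rates
integrate back to the daily FMR exactly. For a representative 40 kg
porpoise at 15 MJ/day with 38/37/25% of time in nonfeeding/pelagic/bottom
states and respiration-rate elevations of 22% and 9%, this yields ~566, 691
and 617 kJ/h — the fractions are read as fractions of *total* time, the
only reading that reproduces the published 567/692 values (the published
bottom-state 613 appears to reflect unrounded upstream inputs; the package
reports its computed value). Foraging efficiency divides the energy
acquired while foraging by the marginal cost of foraging (excess of
foraging expenditure over the nonfeeding rate for the same hours); whether
intake enters gross or after the 90% assimilation efficiency is a flag,
both conventions being defensible and the published "~9" not derivable
from printed inputs under either. The cumulative energy balance allocates
the deployment's total expenditure evenly across respirations and its
total assimilated intake evenly across buzzes, so the final balance is
zero by construction and the trajectory shows when deficits accumulate;
with 15 MJ/day, 2396 buzzes/day, 4.2 kJ/g prey and 90% assimilation the
implied prey mass is ~1.7 g per capture attempt. The specific-dynamic-
action scenario concentrates a 12.5%-of-FMR digestion cost into the
foraging hours, elevating foraging FMR by `0.125/f_foraging`. Metabolic
scope is VO2max/FMR rounded half-away-from-zero to one decimal, matching
published cross-species tables.

## The synthetic generator

The generator simulates at the dive level — the HMM's unit of analysis —
rather than in continuous time: a Markov chain over states (one transition
matrix drawn per deployment from the configured contexts) emits dives whose
duration, depth, activity, buzz and respiration statistics follow the
active state. Defaults mirror the published day-time state estimates for
the three-state porpoise regime (durations ~51/44/78 s, depths
~4.4/8.2/11.6 m, buzz rates 0.1/2.6/1.6 per dive-minute, respiration rates
2.4/3.0/2.7 per cycle-minute, mean MSA 1.8/2.3/1.9 m/s^2). Dispersions
are not published; lognormal shapes with coefficients of variation of
roughly 0.35 for durations and depths and 0.25 for per-dive activity were
chosen once as typical of right-skewed dive statistics and left alone. The
default transition matrix is diagonal-dominant (0.8 persistence), a free
parameter since the fitted matrix is not printed in the source material.
The diel pattern is imposed directly — multipliers on buzz rate (default
2.5, matching the reported ~150% night elevation) and on pelagic-state
entry probability (default 2.4) between sunset and sunrise — rather than
modeling light.

Depth is rendered as piecewise descent–bottom–ascent profiles with
surfacing bouts between dives; each scheduled breath dips to 0.05 m in its
own sub-0.5 m segment, with >0.5 m submersion bumps between breaths, so
respiration detection can be exact. Clicks exist only inside scheduled
buzz intervals, jittered around a 3 ms mean ICI with every interval below
the 10 ms criterion, and a buzz interval longer than 101 mean ICIs is
guaranteed detectable. Specific acceleration is drawn along the gravity
axis so that MSA is exactly the simulated activity noise, making per-dive
mean MSA an unbiased realization of the state's activity level.

What the generator does *not* emulate: prey fields and hydrodynamics,
sensor noise and calibration error, tag slippage, sound propagation, and
the autocorrelation of real within-state behavior beyond the Markov
assumption. Passing tests therefore demonstrate that the pipeline's logic
is correct under its stated assumptions — not that those assumptions
exhaust real data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run deliberately scaled-down
versions of the validation experiments: parameter recovery uses 5,000
simulated dives across 5 animals with 5 restarts; model selection uses 20
replicates of 400 dives with restarts reduced to 4; the end-to-end diel
check runs a single 24 h deployment (~1,000 dives) with a 3x night buzz
multiplier and 3 restarts. The end-to-end state-recovery experiment keeps
the full 50-restart protocol: on pipeline-derived metric tables the
marginal likelihood has strong merged-state local optima, and that
experiment is precisely the one that exercises the multimodality the
restart protocol exists for. These sizes keep the full validation suite
self-contained while leaving the estimators' behavior representative; the
50-restart, multi-deployment protocol is a configuration change, not a
code change.

Degenerate inputs are handled explicitly: all-deep records yield an empty
respiration list with a warning; fewer than two respirations yield an
empty IBI table; mixtures refuse zero-variance features; impossible
Bernoulli observations hit the -700 nat floor instead of -Inf; zero buzzes
make per-buzz energy undefined and are rejected. Ties: the earliest sample
wins within a surfacing; AIC ties prefer smaller K then C; the dominance
rule falls back to the deepest mixture component.

## Known limitations

The transition-context posterior is a point assignment (maximum posterior)
at decoding time; dives near context boundaries inherit that hard choice.
No standard errors are produced for HMM parameters. The click detector
assumes an envelope or click list as input — raw 500 kHz audio decoding is
out of scope. Sunrise/sunset are inputs, not computed ephemeris. Absolute
energetics inherit the daily-FMR input: the package apportions energy, it
does not estimate FMR from respiration physiology.
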