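---
title: "Detecting lambing events from GPS collar data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lambing events from GPS collar data: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lambwatch` infers parturition (lambing) events in collared ungulates from
movement alone. Bighorn sheep are a "follower" species: a ewe is nearly
stationary for only about two days around birth, after which the lamb travels
with her. That brief, episodic signal defeats single change-point methods on
step length, so the pipeline characterizes movement with three complementary
metrics, segments them with a hidden Markov model (HMM), and calls an event
with an explicit decision rule. This vignette records the models, their
assumptions, and every design choice that was genuinely open.

## The pipeline at a glance

```{r}
library(lambwatch)

herd <- simulate_herd(n_parturient = 13, n_nonparturient = 8, seed = 1,
                      inject_errors = TRUE)
clean <- screen_fixes(herd$trajectories)
met <- movement_metrics(clean$trajectory)
part <- herd$events$animal_id[herd$events$parturient]
model <- label_states(fit_hmm(met[met$animal_id %in% part, ],
                              n_restarts = 10, seed = 2))
calls <- detect_lambing(viterbi(model, met))
```

## GPS error screening

Three rules, applied in order to each animal's time series:

1. drop fixes with a 2D fix class (fewer than 4 satellites);
2. drop fixes whose incoming travel speed exceeds 5 km/h — faster than a
   ewe sustains over a 2-h interval;
3. drop "spike" fixes whose incoming **and** outgoing speeds exceed 2 km/h
   while the cosine of the turning angle is below −0.97 — the out-and-back
   signature of a positional error.

Removing a spike changes its neighbours' speeds, so rules 2–3 are recomputed
on the surviving sequence and iterated to a fixed point. Whether to iterate
was an open choice; a single pass leaves paired spikes intact, so the fixed
point matches the intent of spike removal and makes screening idempotent.
Track endpoints lack a neighbour on one side and are never removed by rules
2–3, and a zero-length step makes the turning cosine undefined, in which case
rule 3 conservatively cannot fire. The 2 km/h spike threshold is exposed as a
configurable constant (it is an empirical upper quantile of real datasets,
which we do not recompute from the data at hand).

## Movement metrics

Each fix receives three per-fix metrics, the HMM observation vector:

* **DIST** (m): Euclidean distance to the *next* fix (forward convention).
  The final fix's missing value is imputed from the preceding one and
  flagged, so every row is a complete observation.
* **RT100** (h): residence time — the forward plus backward time before the
  animal leaves a 100 m circle centred on the fix for more than 2 h
  (strictly). Circle entry/exit times are interpolated linearly along each
  segment; excursions of at most 2 h do not stop accumulation and their
  duration counts (an elapsed-time convention). Values truncated by the
  track ends are reported as computed and flagged; the HMM uses them as-is,
  since no edge policy is implied by the estimator's definition.
* **HR** (ha): area of a 95% minimum convex polygon over all fixes within a
  24-h window centred on the fix. The 24-h window smooths diurnal cycles.
  Trimming removes the `floor(0.05 n)` fixes farthest from the arithmetic
  centroid of the window (the standard MCP convention); among tied
  distances, earlier fixes are retained. Windows with fewer than three
  distinct retained points get area 0 and a flag.

These conventions (interpolation rule, trimming rule, edge policy) are
pinned by brute-force oracle tests rather than by equivalence to any other
implementation.

## The hidden Markov model

A 3-state HMM with **independent gamma emissions** per channel: given the
state, DIST, RT100 and HR are conditionally independent, each gamma with a
state-specific mean and shape. No cross-channel covariance and no covariates
on the transition probabilities. States are fitted freely and labelled
afterwards from their emission means:

* **non-movement** — highest RT100 mean (the parturition signature);
* **high-movement** — highest DIST mean among the remaining two;
* **low-movement** — the remainder.

Near-tied means abort labelling and demand a refit, since they signal
degenerate states.

Fitting is Baum–Welch EM over all training animal-seasons jointly: each
sequence gets its own forward–backward pass; the initial distribution,
transition matrix and emissions are shared across animals (sequences are
independent per ewe-season; no cross-animal continuity). The gamma M-step
updates the mean in closed form and solves for the shape with the standard
digamma Newton iteration on the weighted sufficient statistics. The
forward–backward and Viterbi recursions are small C++ kernels (scaled
probabilities; log-space for Viterbi, ties broken toward the lower state
index).

Numerical choices:

* **Zeros.** Gamma support excludes 0 but DIST is 0 at stationary fixes.
  All channels are floored at half the smallest positive observed value per
  channel; the floors are stored in the model and re-applied at decode time.
* **Initialization.** A tercile split of RT100 assigns provisional states;
  method-of-moments gives per-state emission parameters; transitions start
  sticky (diagonal 0.9). Restart 1 uses this initialization; the remaining
  `n_restarts − 1` (default 10 total) jitter the log-means and log-shapes
  (sd 0.4). The best restart by final log-likelihood wins.
* **Convergence.** Relative log-likelihood change below 1e−6 or 500
  iterations; non-convergence returns the best iterate with a warning.
  Per-iteration log-likelihood is non-decreasing (a property the tests
  assert at 1e−8).

## The decision rule

A window of 48 h slides across the decoded sequence one fix at a time
(windows are closed on the left, open on the right, and only starts whose
window fits inside the track are scanned). Per window, the proportion of
fixes labelled non-movement is computed over fix counts — fixes are
near-uniform at 2 h, so interpolating time would change nothing but the
tie structure. The maximum-proportion window is the candidate; the event is
called iff that proportion **strictly exceeds 0.5**, and the reported
lambing time is the window's start fix. Ties between equal-proportion
windows break to the earliest — calendar-day pairs would be coarser than
the ±6 h agreement granularity used in validation, which is why the window
slides at fix resolution. Only the global maximum is reported (ewes can
enter non-movement more than once per season); all windows above threshold
are attached as diagnostics. Calendar dates are reported in a configurable
timezone, default UTC.

Validation protocols:

* **LOOCV** — for each of the parturient animals: fit on the others, label,
  decode the held-out animal, apply the rule. Success means an event is
  called and its date falls inside the animal's field-estimated birth
  interval. Fold errors are recorded without aborting the other folds.
* **Out-of-sample** — the full-data model is applied to animals outside the
  training set; for non-parturient animals success means no call.

## Habitat analyses

* **LSD (latent selection difference)**: rows are a parturient ewe's fixes
  15 days before (response 0) and after (response 1) the called lambing
  time, the call timestamp itself belonging to the postpartum side.
* **RSF (resource selection function)**: used sites are all fixes of one
  reproductive status; availability is a 95% MCP pooled over all animals
  (the same habitat is available to every ewe), sampled uniformly at 10
  available points per used point by rejection from the polygon's bounding
  box, allocated to animals in proportion to their used counts.

Both designs share covariate handling: values are extracted at the raster
cell containing each coordinate; distance-to-road and distance-to-trail
pass through `exp(−3 d / 500 m)` — the saturation range was stated, the
functional form was open, and the constant 3 puts the value at ≈5% of its
maximum at 500 m; continuous covariates are z-scored over the pooled table
so coefficient magnitudes are comparable (raw-scale fitting via
`standardize = FALSE`).

Models are logistic regressions with a Gaussian random intercept per animal
(`lme4::glmer`, adaptive Gauss–Hermite quadrature with 10 nodes), reported
with 95% Wald intervals — chosen over profile intervals for speed and
determinism. Selection is compared between reproductive statuses per
covariate by estimate difference and CI overlap. A coefficient with an
absurd standard error raises a complete-separation error naming the
covariate.

The covariate roster is configuration-driven. The synthetic landscape
provides eleven layers: five smooth standardized fields (elevation,
ruggedness, snow depth, heat load, crown cover) plus slope, and five
distance rasters (roads, trails, escape terrain, barren ground, herbaceous
cover). Real analyses substitute their own layers; the roster identities do
not affect the machinery.

## What the simulator emulates — and what it does not

`simulate_ewe()` generates a correlated random walk at a 2-h fix interval
over a May 15 – July 15 season: per-fix regimes from a 3-state Markov
chain, gamma step lengths and wrapped-Cauchy turning angles per regime, a
deterministic 48-h non-movement bout at the event time (so true event times
are exact, rather than approximate as they would be under a transition-
probability mechanism), and 24 h of doubled step-length means beforehand —
prepartum movement increases are real but unquantified, so the ×2/24 h
boost is a simulation knob, not an estimate.

Default calibration: step-length means 30/150/600 m per 2-h step
(non-movement / low / high), chosen so daily averages bracket the ~60 m
daily minimum typical of postpartum ewes; step shapes 1.5/2.5/2.5; turning
concentrations 0.1/0.5/0.8. The background chain makes non-movement rare
and brief outside bouts (entry probability 0.003, self-transition 0.5, so
background runs last about two fixes ≈ 4 h): non-parturient ewes in the
system this emulates spend essentially no time in that state, and the first
draft of the generator — whose low-movement regime lingered enough to
produce multi-hour stationary stretches — contradicted that description, so
the calm regimes were re-anchored to it during generator design.

GPS errors are injected as 2D-class downgrades and positional spikes
(7–9 km displacement, redrawn until the realized geometry carries the
rule-3 signature exactly). The landscape generator produces smoothed
standardized white-noise fields and distance rasters to random polylines
and patches on a metric grid; `simulate_selected_points()` draws used
points with probability proportional to `exp(x·β)` for known β.

Passing tests on these simulations show that the pipeline recovers what it
assumes: gamma-emission regimes, a single deterministic bout, independent
sequences, stationary landscapes. Real collars add tortuosity within
states, diurnal rhythms, fix-rate drift, social travel (non-parturient ewes
following parturient ones to lambing areas — a documented false-positive
mechanism), and undetected neonate mortality, none of which the generator
reproduces. Results on synthetic data bound what field data can show, they
do not replace it.

## Problem sizes and seeds used by the test-suite

The test suite and the acceptance script exercise: a 13 + 8 ewe-season herd
for fitting and LOOCV (5 EM restarts per fold — the informative
initialization makes additional restarts change the optimum only rarely,
and 13 refits are involved); a fresh 50 + 50 herd for out-of-sample
detection; 2000-fix sequences for parameter recovery (10 restarts);
200 random models at T ≤ 8 for exact enumeration checks; and 100 replicates
of 10-animal × 60-row tables for mixed-model recovery. All randomness is
seeded; the acceptance script derives every sub-seed from its `--seed`
argument.

## Known limitations

* Viterbi is the only decoder; posterior (forward–backward) state
  probabilities are available internally but are not the primary output.
* The HMM has no covariates on transitions and no hierarchical structure;
  a dedicated parturition state with constrained transitions could reduce
  false positives from repeated non-movement episodes.
* MCP home ranges ignore utilization density; no kernel or autocorrelated
  estimators are provided.
* The LSD contrasts use, not selection: when availability shifts (an
  animal moves to a distinct area), its coefficients must not be read as
  selection.
* Wald intervals can misbehave near separation; the fitter errors rather
  than reporting them.
* All coordinates are assumed projected and metric; there is no geographic
  (lon/lat) handling anywhere.
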