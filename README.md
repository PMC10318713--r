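# lambwatch

Remote detection of parturition (lambing) events in collared ungulates from
GPS telemetry, with downstream habitat-use and habitat-selection analyses.

Bighorn sheep (*Ovis canadensis*) are a "follower" species: a ewe is nearly
stationary for only ~2 days around birth, then travels with her lamb. That
brief, episodic signal defeats change-point methods on step length alone.
`lambwatch` implements a multivariate pipeline for wildlife managers and
movement ecologists who need lambing dates without intensive field
observation:

1. **Screening** — three rules remove erroneous fixes: 2D fix classes,
   incoming speed > 5 km/h, and out-and-back spikes (incoming and outgoing
   speed > 2 km/h with turning-angle cosine < −0.97), iterated to a fixed
   point.
2. **Movement metrics** per fix: step length *DIST* (m), residence time
   *RT100* (h) inside a 100 m circle with a 2-h exit tolerance, and day
   home range *HR* (ha), a 95% minimum convex polygon over a rolling 24-h
   window.
3. **State segmentation** — a 3-state hidden Markov model with independent
   gamma emissions per metric, fitted by Baum–Welch EM across animals with
   shared parameters and decoded with the Viterbi algorithm. States are
   labelled *high-movement*, *low-movement*, *non-movement* from their
   emission means; the non-movement state is the parturition signature.
4. **Decision rule** — slide a 48-h window across the decoded sequence; the
   maximum-proportion window calls a lambing event iff more than 50% of its
   fixes are non-movement, the window start being the lambing time.
   Validation by leave-one-out cross-validation against field birth windows
   and by out-of-sample application to non-parturient animals.
5. **Habitat** — latent selection difference (prepartum vs postpartum use,
   15 days each side) and resource selection functions (used vs available
   at 10:1 inside the pooled 95% MCP home range), both as random-intercept
   logistic regressions with z-scored covariates and an exponential decay
   transform `exp(−3d/500)` on distance-to-road/trail.

A correlated-random-walk simulator (gamma step lengths, wrapped-Cauchy
turns, a forced 48-h bout, injected GPS errors) and a synthetic landscape
generator with known selection coefficients make the whole pipeline
testable end to end without field data.

## Worked example

```r
library(lambwatch)

herd  <- simulate_herd(n_parturient = 13, n_nonparturient = 8, seed = 1,
                       inject_errors = TRUE)
clean <- screen_fixes(herd$trajectories)
clean$report
#> GPS screening report
#>   fixes in:        15393
#>   removed (2D):    13
#>   removed (speed): 0
#>   removed (spike): 16
#>   fraction removed: 0.1884%

met   <- movement_metrics(clean$trajectory)
part  <- herd$events$animal_id[herd$events$parturient]
model <- label_states(fit_hmm(met[met$animal_id %in% part, ],
                              n_restarts = 10, seed = 2))
model
#> 3-state gamma-emission HMM (dist, rt100, hr)
#> log-likelihood: -129954.6 after 24 EM iterations (converged)
#>   high-movement  means: dist=471, rt100=1.83, hr=206
#>   low-movement   means: dist=164, rt100=3.72, hr=49.5
#>   non-movement   means: dist=36.2, rt100=24.6, hr=10.8

calls <- detect_lambing(viterbi(model, met))
dplyr::count(calls, parturient = grepl("^P", animal_id), detected)
#> # A tibble: 2 × 3
#>   parturient detected     n
#> 1 FALSE      FALSE        8
#> 2 TRUE       TRUE        13
```

0.19% of fixes are flagged as errors. The fitted non-movement state has a
very high residence time (~25 h), short steps (~36 m) and a small day home
range (~11 ha) — the stationarity signature of a birth event. Every
simulated parturient ewe is called and no non-parturient ewe is: for P01
the call (`lambing_date` 2022-07-10, window proportion 1.0) lands within
hours of that animal's true simulated event (2022-07-10 05:06 UTC).

`plot_state_series(viterbi(model, met[met$animal_id == "P01", ]))` shows
the three metrics coloured by decoded state; `autoplot(model)` draws the
per-state emission densities; `tidy()`/`glance()` methods return model
summaries as tibbles. `run_pipeline(out_dir, seed = 1)` executes every
stage (including the LSD/RSF habitat fits on a synthetic landscape) and
writes all intermediates plus a manifest.

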