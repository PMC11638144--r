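# winterCMR

Multievent (hidden-Markov) capture–recapture models for migratory seabirds
whose wintering area is observed only when an archival geolocator is
recovered.

## The problem

Scopoli's shearwaters breeding in the Mediterranean winter in one of four
Atlantic areas — the Canary Current, the pelagic Equatorial Atlantic, the
Gulf of Guinea and the Angola–Benguela Front. Does the choice of wintering
area carry a survival cost? Geolocators answer *where* but only for birds
that survive, return and are recaptured; colony capture–recapture answers
*whether birds survive* but not where they wintered. `winterCMR` combines
both in one likelihood: the wintering area is a hidden Markov state,
revealed sporadically by device recoveries.

Hidden states cross wintering area (4) × device status (none, functioning,
failed) × trap-awareness (aware, unaware), plus an absorbing dead state —
4 × 3 × 2 + 1 = 25 states; 23 annual occasions split into arrival and
departure occasions give 45 coded occasions. The annual transition
factorises as

φ_a(t)  →  area change c(t)  →  device update (ρ)  →  detection (p_aware / p_unaware)

with logit-linear climate covariates (annual SOI on survival, winter NAO on
the change probability), a multiplicative first-interval survival reduction
φ·(1 − δ), and *deterministic* emissions given the state — detection
randomness lives inside the transition, keeping the model first-order. The
likelihood is the conditional-on-first-release forward algorithm, maximised
over link-scale coefficients; model structures are ranked by QAICc under a
variance-inflation factor ĉ estimated from Cormack–Jolly–Seber
goodness-of-fit components (trap-dependence and transience). Wintering-site
fidelity is summarised from the recovered tracks and quantified with
Krippendorff's alpha (individuals as units, bootstrap interval).

The package also ships a synthetic encounter-history generator mirroring
the field design (1104 marked adults, 2000–2022, geolocator deployment in
2002 and 2009–2014, ~258 deployments), with truth logs, so every estimator
is testable end to end without the field data.

## Worked example

Simulate a 600-bird study with mean adult survival 0.841 and a first-year
excess mortality of 0.088, then refit the generating structure:

```r
library(winterCMR)

cfg <- default_study_config("constant", n_individuals = 600, seed = 42)
sim <- simulate_dataset(cfg)
sim
#> <cmr_simulation> 600 individuals, 23 years, 1656 captures, 142 tracked winters

spec <- model_spec(survival = "constant", first_encounter = "constant",
                   change = "constant", initial = "canary_others",
                   recapture = "trap", rho = "estimate")
fit <- fit_model(sim$data, spec, n_starts = 2, seed = 1)
fit
#> <cmr_fit> logLik -2122.472 deviance 4244.944 np 7
#>             term estimate conf.low conf.high
#>      phi[Canary]    0.839    0.817     0.858
#>  phi[Equatorial]    0.839    0.817     0.858
#>      phi[Guinea]    0.839    0.817     0.858
#>      phi[Angola]    0.839    0.817     0.858
#>            delta    0.126    0.074     0.207
#>                c    0.134    0.056     0.288
#>       pi[Canary]    0.380    0.084     0.803
#>   pi[Equatorial]    0.207    0.095     0.393
#>       pi[Guinea]    0.207    0.095     0.393
#>       pi[Angola]    0.207    0.095     0.393
#>         p[aware]    0.613    0.582     0.644
#>       p[unaware]    0.347    0.302     0.395
#>              rho    0.853    0.766     0.911
```

Survival is recovered tightly (0.839, CI 0.817–0.858, truth 0.841); the
change probability and initial distribution are honest but wide at this
sample size — only the ~140 revealed winters inform them. Trap-dependence
is detected by the goodness-of-fit machinery, as built into the generator:

```r
gof_cjs(sim$data)
#> <cmr_gof> CJS goodness of fit
#>             test      chi2 df        z      p_value
#>  trap_dependence 108.34990 19 9.488917 1.604104e-14
#>       transience  30.61041 21 3.281914 8.039074e-02
#> total chi2 138.960 on 40 df; c-hat 3.474 (excluding trap: 1.458)

fidelity_summary(sim$assignments)
#> <fidelity_summary> 142 tracks from 70 individuals
#>   tracked >1x: 33 (consistent 19, changed 14; 57.6% consistent)

alpha_bootstrap_ci(sim$assignments, n_boot = 500, seed = 1)
#> # A tibble: 1 × 4
#>   alpha conf.low conf.high n_boot
#> 1 0.537    0.359     0.715    500
```

`tidy()`, `glance()` and `autoplot()` methods follow the broom/ggplot2
conventions; `run_model_set()` returns a QAICc ranking with Akaike weights;
`derived_parameter()` gives delta-method intervals for quantities such as
the stay probability 1 − 3c. A thin command-line wrapper
(`inst/cli/wintercmr.R`) exposes `simulate`, `fit`, `select`, `gof` and
`repeatability` subcommands driven by a YAML config.

See the vignette (`vignettes/multievent-wintering-models.Rmd`) for the full
model description, design decisions and limitations.

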