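# kddsync

Lake monitoring programmes measure phytoplankton abundance *P*, zooplankton
abundance *Z* and water temperature month by month — but never the quantity
ecologists reason about most, the intrinsic phytoplankton **growth rate**.
`kddsync` recovers that growth rate as a time series by inserting the
monitoring series directly into a discrete prey–predator model and solving
the model algebraically for its unknown functional term
(knowledge-and-data-driven modelling), then quantifies how strongly the
recovered series is **phase locked** to water temperature. It is written for
limnologists and ecological time-series analysts working with seasonal
monitoring records that have winter gaps and occasional missing values.

## The method in brief

The model, on one-month steps with ΔX(n) = X(n+1) − X(n):

    ΔP(n)/P(n) = G(n) − f(n) Z(n)
    ΔZ(n)/Z(n) = β f(n) P(n) − α

With *P* and *Z* given by the data, the unknown growth rate has the exact
closed form

    G(n) = (β ΔP(n) + ΔZ(n) + α Z(n)) / (β P(n))

and the trophic function follows as f(n) = (ΔZ(n)/Z(n) + α)/(β P(n)).
Here α (month⁻¹) is predator decline unrelated to grazing and β the
prey-to-predator conversion efficiency (≈ 0.1 by Lindeman's 10 % law).
Steps that straddle the unsampled winter are dropped, not bridged.

Synchronization is measured on oscillation phases interpolated between
detected maxima, φ(t) = 2π(m + (t − t_k)/(t_{k+1} − t_k)), through the
phase-locking index PLI = |(1/N) Σ e^{iΔφ(j)}| ∈ [0, 1], with significance
from shuffle surrogates: the series are randomly permuted, the whole
pipeline re-run, and the observed PLI ranked against the surrogate
distribution (p ≥ 95 % ⇒ phase-synchronized). `sync_sweep()` repeats this
over an (α, β) grid to map where in parameter space synchronization occurs.

## Worked example

```r
library(kddsync)

spec <- sim_spec(seed = 42)          # 10 years, 6-month seasons, coupled G*
sim  <- forward_simulate(spec)       # P, Z, temperature + ground truth
G    <- growth_rate(sim$P, sim$Z, spec$params)
G
#> Derived series G(n): 50 valid steps in 10 season runs (alpha = 0.5, beta = 0.1)
#>   year month       value run_id
#> 1 2001     5 -0.11836173      1
#> 2 2001     6  0.10926153      1
#> 3 2001     7  0.52909119      1
#> ...
```

Fifty growth-rate values: ten seasons of six samples each yield five
within-season steps per run; the value for May 2001 is the growth realized
between the May and June samples. Now the phase-locking test against
temperature:

```r
al <- align_series(G, sim$temperature)
st <- surrogate_test(al$a$value, al$b$value, n_surrogates = 200, seed = 7)
st
#>     Phase-locking index with shuffle-surrogate test
#>
#> PLI = 1.0000 over N = 46 common indices
#> significance p = 100.0% (200 surrogates, shuffle = both)
#> surrogate PLI: min 0.0264, median 0.2017, max 0.5490
#> verdict: phase-synchronized (p >= 95%)
```

The derived growth rate locks perfectly to temperature (the generator
coupled them through the seasonal phase), while every one of 200 shuffled
surrogates scores lower — chance alignment alone reaches a median PLI of
only 0.20 here. A sensitivity sweep shows the verdict is not an artifact of
one (α, β) choice:

```r
sm <- sync_sweep(sim$P, sim$Z, sim$temperature,
                 alpha_grid = c(0.5, 1, 2, 4, 8),
                 beta_grid  = c(0.06, 0.10, 0.14),
                 n_surrogates = 100, seed = 7)
sm
#> Synchronization map: 5 x 3 grid (alpha x beta), threshold p >= 95%
#> synchronized cells: 15 / 15 (area 1.000)
plot(sm)
```

Real CSV inputs (`year,month,value`, `NA` for missing) go through the same
path — `read_series()`, `impute_seasonal()`, `align_series()` — or the whole
analysis can be driven from a YAML config with `run_pipeline()`. See the
methods vignette (`vignettes/kdd-phase-synchronization.Rmd`) for the model,
the numerical conventions and the generator's assumptions.

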