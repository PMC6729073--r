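# ltcfdea

Two-stage efficiency benchmarking of long-term care facilities (or any set
of comparable decision-making units, DMUs) in R:

1. **Data envelopment analysis (DEA).** Input-oriented radial models under
   constant and variable returns to scale (CCR / BCC) with lexicographic
   two-phase slack maximisation; decomposition of technical efficiency into
   pure technical and scale efficiency (`TE = PTE × SE`); returns-to-scale
   classification from the min/max interval of the intensity sum Σλ over
   the CRS optimal face; the input-oriented slacks-based measure
   `ρ = 1 − (1/m) Σᵢ sᵢ⁻/xᵢₒ`, which penalises mix inefficiency that radial
   scores miss; super-efficiency SBM for ranking efficient units; and
   frontier projections with per-indicator adjustment tables
   (`NA = actual − projection`, proportion `NA/actual × 100%`).
2. **Two-limit Tobit regression.** Efficiency scores pile up at 1, so the
   second stage regresses them on facility covariates with a
   censored-normal model `y = min(max(x'β + ε, 0), 1)` estimated by maximum
   likelihood (BFGS with analytic gradient, observed-information standard
   errors, likelihood-ratio test against the intercept-only null).

Undesirable outputs (fall rate, unhandled-complaint rate, accident
incidence — lower is better) are handled by a monotone decreasing
translation `u' = max(u) + κ − u` (or optionally moved to the input side)
before any solve. The LPs are solved by a built-in dense two-phase simplex
with Bland's anti-cycling rule; DEA programs at these sizes are tiny and
heavily degenerate, which is exactly that method's sweet spot.

The package also ships the published per-facility result tables of a
32-facility study (`ltcf_table3()`, `ltcf_table4()`) as verbatim fixtures —
the underlying survey matrix is not public — plus synthetic-data generators
with known ground truth (`simulate_frontier()`, `simulate_ltcf()`,
`simulate_tobit()`) so that every stage is testable end to end.

## Worked example

Four facilities, two inputs, one output:

```r
library(ltcfdea)
d <- dmu_data(inputs  = cbind(staff = c(1, 2, 4, 2), beds = c(1, 2, 4, 4)),
              outputs = cbind(residents = c(1, 4, 6, 4)),
              dmu_ids = c("A", "B", "C", "D"))
fit <- dea(d, sbm_rts = "crs")
fit
#> DEA efficiency analysis: 4 DMUs, 2 inputs, 1 outputs
#>  dmu   te pte   se rts  sbm super_sbm rank
#>    A 0.50   1 0.50 IRS 0.50     0.500    4
#>    B 1.00   1 1.00 CRS 1.00     1.333    1
#>    C 0.75   1 0.75 DRS 0.75     0.750    2
#>    D 1.00   1 1.00 CRS 0.75     0.750    3
```

Reading the table: every facility is efficient under variable returns
(`pte = 1`), but A uses only half of what the best-practice ratio needs
(`te = 0.50`) and is too small (`rts = IRS`), while C is too large
(`rts = DRS`). D shows why the slacks-based measure is worth having: it is
radially efficient (`te = 1`) yet wastes two beds, so `sbm = 0.75`. B is the
only fully efficient unit and keeps a super-efficiency score above one
(1.333), which ranks it first. The adjustment table quantifies the input
reductions for the facilities under decreasing returns:

```r
adjustment_table(fit)
#>   dmu indicator actual projection na    pct
#>     C     staff      4          3  1 25.00%
#>     C      beds      4          3  1 25.00%
#>  Mean     staff      4          3  1 25.00%
#>  Mean      beds      4          3  1 25.00%
```

The packaged published table reproduces the 32-facility study's headline
block:

```r
summarize_efficiency(ltcf_table3())
#> n = 32 DMUs; efficient: 17 (53.1%)
#> mean TE 0.963 | mean PTE 0.979 | mean SE 0.984 | mean SBM 0.813
#> returns to scale: 19 CRS, 5 IRS, 8 DRS
```

A second stage on simulated scores with a known planted effect:

```r
sim <- simulate_tobit(200, beta = c(0.3, 0.6), sigma = 0.2, seed = 1)
fit2 <- tobit(score ~ x1, sim$data, lower = 0, upper = 1)
summary(fit2)   # recovers beta ~ (0.3, 0.6), sigma ~ 0.2, LR test, pseudo-R2
```

A full pipeline (`validate → CCR/BCC → RTS → SBM → super-SBM → projections →
Tobit`) is driven by `run_pipeline()` from a YAML config, or from the shell
via the thin CLI in `inst/scripts/ltcfdea` (subcommands `validate`, `run`,
`summarize`, `simulate`). See the vignette
`vignettes/efficiency-benchmarking.Rmd` for the models, numerics and design
choices.

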