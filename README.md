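# boldwvar

Scale-resolved wavelet-variance analysis of regional fMRI BOLD time
series, with the group-comparison and (epi)genetic regression workflow
of a clinical imaging-genetics study and a fully seeded synthetic
cohort generator.

## What it computes

A BOLD signal mixes slow resting-state drifts and fast task-related
dynamics; total variance confounds them. `boldwvar` decomposes a
series `X` of length `N` (sampling interval Δt, default 0.8 s) with
the maximal overlap discrete wavelet transform (MODWT, least-asymmetric
LA(8) filters by default) into full-length coefficient series
`W_1..W_J0, V_J0`, satisfying the exact identities

    ||X||² = Σ_j ||W_j||² + ||V_J0||²
    σ̂²_X  = Σ_j (1/N)||W_j||² + (1/N)||V_J0||² − X̄²

Level `j` covers the octave band `[1/(2^(j+1)Δt), 1/(2^j Δt)]` Hz
(scale `τ_j = 2^(j−1)Δt`). The **wavelet variance** at level `j` is
estimated unbiasedly from the `M_j = N − L_j + 1` coefficients free of
circular-boundary contamination (`L_j = (2^j−1)(L−1)+1`), with
chi-square confidence intervals based on the conservative equivalent
degrees of freedom `η₃ = max(M_j/2^j, 1)`.

Downstream, the package provides Type-III factorial ANCOVA with
partial η² per (region, level), split-plot repeated-measures ANOVA for
cognitive load, pooled/paired post-hoc t-tests, Benjamini–Hochberg FDR,
Fisher r-to-z comparison of correlations, blockwise stepwise multiple
regression (forced genotype/age/sex block + competing CpG methylation
sites), and an exact Hardy–Weinberg test.

## Worked example

Simulate one rest-like signal (variance concentrated at low
frequencies) and profile it:

```r
library(boldwvar)

spec <- simulation_spec(450, level_variances = c(0.012, 0.028, 0.056,
                                                 0.048, 0.058), seed = 42)
x <- simulate_signal(spec)
prof <- wvar_profile(x, filter = "la8", J0 = 5, dt = 0.8)
as.data.frame(prof)[, c("level", "tau_s", "band", "M", "estimate",
                        "edof", "ci_lo", "ci_hi")]
#>   level tau_s             band   M estimate   edof   ci_lo  ci_hi
#> 1     1   0.8 0.3125-0.6250 Hz 443   0.0116 221.50 0.00972 0.0141
#> 2     2   1.6 0.1562-0.3125 Hz 429   0.0300 107.25 0.02331 0.0399
#> 3     3   3.2 0.0781-0.1562 Hz 401   0.0676  50.12 0.04734 0.1044
#> 4     4   6.4 0.0390-0.0781 Hz 345   0.0632  21.56 0.03760 0.1276
#> 5     5  12.8 0.0195-0.0390 Hz 233   0.0836   7.28 0.03703 0.3338
```

Each row is one octave band: `M` non-boundary coefficients enter the
estimate, `edof` the chi-square degrees of freedom, and the interval
widens as `M` shrinks with level — at level 5 only 233 of the 450
coefficients survive the 218-tap equivalent filter, hence the wide
interval. The dominant scales (here 3–5, i.e. below 0.16 Hz) identify
where this series' variance lives; `autoplot(prof)` draws the profile.

A full 2×2 cohort analysis:

```r
co  <- simulate_cohort(cohort_spec(n_per_cell = 18, seed = 11))
wt  <- cohort_wvar(co, J0 = 5)                   # subjects × conditions × ROI × level
an  <- wvar_anova(wt, covariates = c("age", "sex"))
subset(an, roi == "FPN.l.LPFC" & level == 3 & term == "group:condition")
#> F = 53.9, df = 1/138, p = 1.6e-11, partial η² = 0.28 (large), significant after FDR
```

The default generator encodes the study conditions it emulates:
controls show higher 0.08–0.16 Hz prefrontal variance at rest than
under task, patients the reverse, so the group×condition interaction is
the expected detection. `blockwise_stepwise_regression()` then relates
per-subject wavelet variance or behavior to genotype and CpG
methylation.

A thin command-line wrapper over these functions ships in
`inst/cli/boldwvar.R` (`simulate`, `decompose`, `mra`, `wvar`,
`cohort-wvar`, `compare`, `regress`).

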