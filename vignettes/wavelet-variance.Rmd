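---
title: "Scale-resolved wavelet variance for BOLD time series: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-resolved wavelet variance for BOLD time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldwvar)
```

## The problem

Regional fMRI BOLD signals fluctuate on several time scales at once:
slow "resting-state" drifts below 0.04 Hz, intermediate fluctuations,
and faster task-related dynamics up to the Nyquist limit of the
acquisition. A single variance number confounds all of them. This
package implements a scale-resolved variability marker: the maximal
overlap discrete wavelet transform (MODWT) splits a series into octave
frequency bands, and the *wavelet variance* quantifies how much each
band contributes, with an honest confidence interval per band. On top
of the estimator sits the inferential workflow of a typical clinical
imaging-genetics study — factorial models over a patient/control by
rest/task design, repeated-measures models over task blocks of
increasing cognitive load, FDR control, and regressions of the marker
on genotype and CpG-methylation covariates — plus a synthetic cohort
generator so that every stage can be exercised and calibrated without
access to subject data.

## Transform and decomposition

Given $X = \{X_t : t = 0, \dots, N-1\}$ sampled every $\Delta t$
seconds, the MODWT with filters of length $L$ produces $J_0$ wavelet
coefficient series $W_j$ and one scaling series $V_{J_0}$, all of
length $N$ (no decimation), by circular filtering; the level-$j$
equivalent filter has $L_j = (2^j - 1)(L - 1) + 1$ taps. We implement
the standard pyramid recursion (per-stage filters upsampled by
zero-insertion, each stage rescaled by $1/\sqrt 2$) and verify against
direct circular filtering with the cascaded equivalent filters; the
two routes agree to $10^{-10}$.

Two exact identities anchor the decomposition and are enforced by
tests at relative $10^{-10}$:

* energy: $\lVert X\rVert^2 = \sum_j \lVert W_j\rVert^2 +
  \lVert V_{J_0}\rVert^2$;
* variance: $\hat\sigma^2_X = \frac1N\sum_j \lVert W_j\rVert^2 +
  \bigl(\frac1N\lVert V_{J_0}\rVert^2 - \bar X^2\bigr)$.

When $N = 2^{J_0}$ the scaling term vanishes identically; we allow
$J_0 = \log_2 N$ (not only $J_0 < \log_2 N$) precisely so that this
degenerate case is reachable, and verify it numerically.

The default filter is the length-8 least-asymmetric Daubechies filter
("LA(8)"), chosen because its near-linear phase lets synthesized
components be aligned in time with the input. Tap values are the
published double-precision constants; the wavelet filter is derived
from the scaling filter by the quadrature-mirror relation in the
orientation $h_l = (-1)^{l+1} g_{L-1-l}$. Orientation conventions
differ between texts (the mirror relation is only determined up to
sign); we fixed the orientation that reproduces the conventional
printed decomposition high-pass values, e.g. tap 5 $= -0.8037$.
Admissibility (zero sum for the wavelet filter, $\sqrt 2$ sum for the
scaling filter, unit energy, even-shift orthogonality) is enforced at
absolute tolerance $10^{-10}$.

Multiresolution components $D_j$ and $A_{J_0}$ are synthesized by
inverting the transform with all other coefficients zeroed. The net
transfer function of each component is then the *squared* gain of its
level filter — real and non-negative — so the components are zero-phase
by construction; the unit-impulse test checks that every LA(8) detail
peaks within $\pm 2$ samples of the impulse. The `phase_shift` field
of a level filter is reported as the (negated, rounded) energy
centroid of the equivalent filter rather than the closed-form
least-asymmetric shift constants: the integer is only informational
here (components need no explicit shifting), and the centroid
definition extends uniformly to every supported family. For LA(8) the
centroid-based advances at levels 1–5 are
`r paste(vapply(1:5, function(j) level_filter(wavelet_filter("la8")$wavelet, j)$phase_shift, integer(1)), collapse = ", ")`.

## The wavelet-variance estimator

Level $j$ corresponds to scale $\tau_j = 2^{j-1}\Delta t$ and the
nominal band $[1/(2^{j+1}\Delta t),\, 1/(2^j \Delta t)]$ Hz. At
$\Delta t = 0.8$ s, levels 3–5 cover 0.0781–0.1562, 0.0391–0.0781 and
0.0195–0.0391 Hz — the three bands conventionally reported for
task-related and resting BOLD fluctuations. The band edges are exact
dyadic numbers; display strings truncate to 4 decimals. Note that the
octave "band-pass" is an approximation: quadrature of the LA(8)
level-3 squared gain puts 73% of the total gain inside the nominal
band (the tests freeze this computed value, not a rounder aspiration).

The unbiased estimator discards the $L_j - 1$ leading coefficients
contaminated by circular wrap-around and averages the remaining
$M_j = N - L_j + 1$ squared coefficients:
$\hat\nu^2(\tau_j) = \frac{1}{M_j}\sum_{t=L_j-1}^{N-1} W_{j,t}^2$.
For the series lengths typical of a 0.8-s protocol after scrubbing
(task $N = 1063$, rest $N = 450$) this yields the counts
1056/1042/1014/958/846 and 443/429/401/345/233 at levels 1–5 —
reproduced exactly by the tests. Confidence intervals use the
conservative equivalent-degrees-of-freedom rule
$\eta_3 = \max(M_j/2^j, 1)$, appropriate for short series, with the
chi-square construction
$[\eta\hat\nu^2 / Q_{1-\alpha/2},\ \eta\hat\nu^2 / Q_{\alpha/2}]$.
For white noise the estimator's expectation is $\sigma^2/2^j$
(verified by Monte Carlo within 3 standard errors over 500
replicates), and the nominal 95% intervals cover the truth in at
least 90% of replicates — over-coverage is expected and accepted,
because $\eta_3$ deliberately understates the degrees of freedom.

Tunable parameters and defaults: `dt = 0.8` s (sampling interval),
`filter = "la8"` (also `"d4"`, `"haar"`), `J0 = 5` levels (five octaves
reach 0.02 Hz at 0.8 s), `confidence = 0.95`. Per-block analyses
(cognitive load) transform each block segment separately; blocks are
never concatenated, and each segment must satisfy $M_j \ge 2$ or the
offending level is named in an error.

## The synthetic generator

`simulate_signal()` draws Gaussian noise, filters it circularly
through each level's equivalent wavelet filter, and adds an optional
AR(1)-spectrum background synthesized as a circularly stationary
Gaussian process. Because every ingredient is circularly stationary,
the expected wavelet variance at level $j$ is available exactly from
the filters' squared gains: for component amplitudes $a_k$,
$E\hat\nu^2(\tau_j) = \sum_k a_k^2 B_{jk} + \frac1N\sum_f
|H_j(f)|^2 S_{\mathrm{AR}}(f)$ with
$B_{jk} = \frac1N\sum_f |H_j(f)|^2 |H_k(f)|^2$. The amplitudes are
obtained by solving $B a^2 = $ targets, so the expected profile equals
the requested one whenever a non-negative mix exists. Neighbouring
octave bands overlap ($B_{j,j\pm1} > 0$), so some profiles — a level
sitting far below both neighbours — are unreachable; in that case the
non-negative least-squares projection is used and `expected_wvar()`
reports the realized expectation, which the Monte-Carlo
self-consistency test checks within 3 standard errors. Filtered noise
was chosen over sinusoids to mimic stochastic BOLD fluctuations; the
generator does not model hemodynamic convolution, physiological noise,
scanner drift or motion, so passing tests demonstrate estimator and
pipeline correctness on stationary Gaussian surrogates, not robustness
to real-data artifacts.

`simulate_cohort()` assembles a full study: two diagnostic groups by
two genotype classes (G-allele homozygotes "GG" versus T-carriers
"T+", drawn at $P(\mathrm{GG}) = 0.485$), rest and task recordings of
450 and 1063 samples, per-region cell-mean wavelet-variance profiles,
and covariates. The default cell means encode the pattern the
generator emulates: in controls the 0.08–0.16 Hz variance of
prefrontal regions is higher at rest than under task, in patients the
pattern reverses; rest profiles are dominated by high levels and task
profiles by low levels. Between-subject heterogeneity is a lognormal
multiplicative jitter on the whole profile with unit mean and
coefficient of variation 0.5 (default), reproducing cell SDs of
roughly half the cell mean as seen in developmental samples; the
within-subject correlation of the jitter across conditions is exposed
as `rho_cond` with default 0, since no empirical value is available
for it. Ages are uniform on 8–18 years and 10% of subjects are female,
matching the child/adolescent ADHD setting the defaults emulate.
CpG methylation fractions at six sites are truncated normals
(SD 0.08); site 3 is linked, in patients only by default, to one
target regional wavelet variance through a log-scale slope
(mean-compensated so cell means stay calibrated) and to premature
responses through a linear slope. Reaction-time means per
group-by-genotype cell default to 467/415/486/433 ms (SD 96/46/90/51)
with the longest times in T-carrier patients. The behavioral
`accuracy` score implements the error-rate form
$((\text{misses}+\text{errors})/\text{trials})\times 100$ verbatim
from the source task's scoring sheet — 0 means flawless — and the
complementary `percent_correct` is emitted alongside to prevent
misreading.

## Inferential workflow

The factorial stage is implemented as univariate ANCOVAs per (region,
level) dependent variable — sum-to-zero coding, Type-III F tests via
`car::Anova`, age and sex as nuisance covariates — with
Benjamini–Hochberg FDR across the family of all (region, level) tests
per effect, the form in which such designs are conventionally reported
(one F per region and band); a true multivariate statistic is out of
scope. Partial $\eta^2 =
SS_\mathrm{eff}/(SS_\mathrm{eff}+SS_\mathrm{err})$ is labelled by the
0.01/0.06/0.14 convention. Cognitive-load analyses use the classical
split-plot ANOVA (between-subject group, within-subject block),
excluding listwise — with a logged warning — subjects missing any
block. Post-hoc t-tests default to pooled-variance two-tailed Student
tests (the era-typical software default), Welch and paired variants
available. The blockwise stepwise regression forces genotype
(coded GG = 0, T+ = 1), age and sex into the first block and lets the
six CpG sites compete by forward entry at $p \le 0.05$ and backward
removal at $p > 0.10$ (the classic defaults of the stepwise
tradition), ties broken by smallest entry p then declared order. The
Hardy–Weinberg check is the exact conditional test by full enumeration
of heterozygote counts. Calibration tests hold each procedure's
type-I error in $[0.03, 0.07]$ at $\alpha = 0.05$ under matched null
simulations, and parameter-recovery tests confirm the CpG site with a
true effect is selected in $\ge 90\%$ of runs at $n = 50$ — note that
with five null candidates competing at entry level 0.05, about one run
in four admits an additional null site; that is a property of stepwise
selection itself, not a defect.

## Numerical choices and problem sizes

Tolerances: $10^{-10}$ absolute for filter admissibility and the two
decomposition identities; $10^{-8}$ relative for reconstruction and
MRA additivity (error accumulates over $2 J_0$ filtering stages).
Degenerate inputs: constant series produce zero details and zero
variance estimates; zero-variance candidates never enter the stepwise
model; a collinear forced block (condition number $> 10^8$) is
rejected. The test suite sizes its simulations to the smallest runs
that still separate signal from Monte-Carlo noise: 500 replicates for
estimator means and stepwise recovery, 1000 for interval coverage, 30
cohorts at 35 subjects per group for end-to-end interaction power,
direct lognormal table simulation (500 runs) for the null calibration
of the inferential layer.

## Known limitations

* Circular boundary treatment is built in (the estimator compensates
  by discarding boundary coefficients); reflection padding is not
  offered.
* Only `la8`, `d4` and `haar` filters are shipped; arbitrary
  Daubechies lengths would require spectral factorization, which is
  out of scope.
* The wavelet variance is reported per level only; wavelet
  cross-covariance between regions and running-window (time-varying)
  variants are not implemented.
* The generator's surrogates are stationary and Gaussian; conclusions
  about robustness to nonstationarity, motion or physiological noise
  cannot be drawn from these tests.
* `splitplot_anova` assumes sphericity (no Greenhouse–Geisser
  correction); with four within-subject levels and the moderate
  designs simulated here the calibration tests stay nominal.
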