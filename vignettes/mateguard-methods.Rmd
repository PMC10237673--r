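---
title: "Methods: the mate-guarding model and the assay statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mate-guarding model and the assay statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mateguard)
```

## The problem

Male *Drosophila melanogaster* shorten their copulation duration after prior
sexual experience with females (shorter-mating-duration, SMD). Most of a
fly's copulation is post-ejaculatory and is interpreted as mate guarding:
time invested to secure paternity against subsequent rival males. `mateguard`
packages two things: (i) a marginal-value-theorem (MVT) style cost–benefit
model of how long a male should guard, used to ask when a *shorter* optimal
guarding time can be favored by experience, and (ii) the statistical pipeline
such behavioral studies apply to their assays, exercised on seeded synthetic
data so that every stage is testable without raw recordings.

## The guarding model

A guarding male accrues a fertilization benefit and a guarding cost, both
increasing in guarding time $t$:

$$B(t) = \frac{e}{\alpha}\left(1 - e^{-\beta t}\right), \qquad
  C(t) = \gamma t, \qquad N(t) = B(t) - C(t), \quad t \in [0, t_{\max}].$$

* $\alpha > 0$ is an inverse-capacity parameter: the total number of eggs the
  male can ever fertilize through guarding is $e/\alpha$, so a larger
  $\alpha$ means fewer fertilizable eggs in total (the situation of an
  experienced male whose sperm or seminal-fluid stores are depleted).
* $\beta > 0$ (1/time) sets how fast the benefit saturates; the benefit has
  strictly diminishing returns, the ingredient the MVT needs for an interior
  optimum.
* $\gamma \ge 0$ is the cost accrual rate — predation risk and foregone
  mating or foraging opportunity per unit guarding time. $C$ is linear in
  both $t$ and $\gamma$.

Maximizing $N$ gives the closed-form optimum
$t^\* = \tfrac{1}{\beta}\log\!\big(e\beta/(\alpha\gamma)\big)$ clamped to
$[0, t_{\max}]$. Two boundaries in $\gamma$ organize the comparative statics,
and both are exact algebraic consequences of the forms above:

* $t^\* > 0$ exactly when $\gamma < e\,\beta/\alpha$: above this the optimum
  collapses to the corner $t^\* = 0$ (guarding never pays);
* $t^\* > 1/\beta$ (one benefit time constant — long guarding) exactly when
  $\gamma < \beta/\alpha$.

`classify_regime()` reports `below_window` ($\gamma \le \beta/\alpha$),
`scenario_C_window` ($\beta/\alpha < \gamma \le e\beta/\alpha$) and
`scenario_D_window` ($\gamma > e\beta/\alpha$), with exact boundary values
resolved into the lower-labelled regime so tests are deterministic.

### On the choice of functional forms

Only the regime inequalities and the qualitative scenario statements are
available as constraints on the model; the forms above are this package's own
instantiation, chosen as the *simplest* concave-benefit/linear-cost pair that
reproduces every one of those constraints exactly (the factor $e$ in $B$ is
what places the guarding-abolished boundary at $e\beta/\alpha$ instead of
$\beta/\alpha$). They are housed in a single seam,
`guarding_model()`, so an alternative algebra can be substituted without
touching the solver or any downstream code, and the grid-search route works
for any substituted form.

### The four scenarios

`predict_smd()` compares the optimal guarding time under "naive" and
"experienced" parameter sets; `smd_scenarios()` builds the four canonical
single-parameter shifts:

* **A** — $\alpha$ increases (fewer fertilizable eggs in total): the interior
  optimum $t^\*$ strictly decreases. Predicts SMD.
* **B** — $\beta$ decreases: for $\gamma > \beta/\alpha$ (the C window),
  $\partial t^\*/\partial\beta = -\log(\beta/(\alpha\gamma))/\beta^2 > 0$,
  so a smaller $\beta$ strictly shortens guarding. Predicts SMD.
* **C** — $\gamma$ increases within $(\beta/\alpha,\ e\beta/\alpha)$:
  $\partial t^\*/\partial\gamma = -1/(\beta\gamma) < 0$. Predicts SMD.
* **D** — $\gamma$ decreases while staying above $e\beta/\alpha$: here the
  optimum is the corner $t^\* = 0$ on both sides of the shift, so the
  difference is zero and SMD is *not* predicted.

Scenario D deserves a frank note. For *any* objective $B(t) - \gamma h(t)$
with an accumulating cost ($h$ non-decreasing), an interior maximum satisfies
$\mathrm{d}t^\*/\mathrm{d}\gamma = h'(t^\*)/N''(t^\*) \le 0$: lowering the
cost rate can never strictly shorten the optimal guarding time. A "cheaper
guarding ⇒ shorter guarding" prediction therefore cannot hold under the cost
structure the model (and its own curve invariants) assume; the package
implements the model faithfully and reports the zero difference rather than
forcing the prediction. The corresponding scenario check in the test suite
documents this as a failing expectation by design. Note also that
"costs accumulating faster in experienced males" — the verbal version of the
fourth scenario — corresponds to $\gamma$ *increasing*, which is scenario C's
mechanics; under that reading the fourth panel is covered by the C window.

### Numerics

The solver uses a uniform grid (default 10,000 points, minimum 1,000) on
$[0, t_{\max}]$, followed by golden-section refinement of the bracketed
argmax to an absolute tolerance of $10^{-8}$ in $t$ (500-iteration cap with
an explicit solver error on non-convergence). Corner solutions are detected
by the argmax landing on the first or last grid point. The default horizon is
$t_{\max} = 10/\beta$, several benefit time constants, which captures
saturation without an unbounded search; closed-form and grid-search routes
agree to $10\times$ the tolerance on random interior parameter sets (this is
a standing test). Grid search near the $e\beta/\alpha$ boundary deserves
care: just below it the interior optimum is smaller than one grid step and
is legitimately reported as the zero corner; the boundary-detection checks
use a $10^5$-point grid for that reason.

## The synthetic assay generators

Each generator is a pure function of its design object (which includes the
seed), so identical inputs give byte-identical tables.

* **Mating duration** (`simulate_md_assay()`): per-group normal durations —
  the assays this mimics report normally distributed durations — floored at
  60 s and rounded to the nearest 10 s, the recording accuracy of such
  assays. The experienced mean is `naive * (1 - percent_reduction/100)`;
  default cohorts are 36 males per group, the minimum cohort size used for
  these assays. Copulation latency is lognormal (right-skewed, positive),
  and only males mating within 1 h (3600 s, boundary inclusive) are flagged
  as included. Defaults `md_mean_naive = 1500` s and `md_sd = 300` s are
  realistic magnitudes for wild-type copulations (~25 min); the sources this
  emulates do not print per-strain variances, so no synthetic default should
  be read as reproducing a specific figure's spread.
* **Exposure time**: effect size as a function of hours of exposure follows
  the observed threshold behavior — no effect at 6 h or less, full effect at
  12 h or more (`exposure_percent_reduction()`); intermediate exposures are
  interpolated linearly as a declared convention, not an observed curve.
* **Fecundity** (`simulate_fecundity()`): Poisson eggs per female per 24 h
  (negative-binomial optionally, since real counts may be overdispersed)
  and binomial survival of eggs to eclosed adults, so `progeny <= eggs`
  always holds.
* **Two-sire crosses** (`simulate_paternity()`): per-female Poisson progeny,
  each sired by the first male with probability `first_sire_share`, with eye
  color following the recessive sepia marker (sepia-eyed progeny require a
  `se` allele from both parents; a `se/se` mother makes the sire's genotype
  fully informative).
* **Fluorescence** (`simulate_calexa()`): lognormal reporter and
  autofluorescence intensities per condition and tarsal segment; the default
  configures an experience-dependent increase in T5 only, mirroring the
  segment-specific contrast of activity reporters in these neurons.

What the generators deliberately do **not** emulate: courtship
micro-behavior, video-derived trajectories, image-level fluorescence,
between-day batch effects, or any correlation between metrics within a fly.
Tests passing on these generators therefore show that the *pipeline*
recovers what it assumes — not that real data satisfy those assumptions.

## The statistical pipeline

* **Student's t** (`students_t()`): the classic pooled-variance test
  (`df = n_a + n_b - 2`), matching the named test rather than Welch's
  variant, which remains available via `var_equal = FALSE`. Zero pooled
  variance is handled by convention: equal means give `p = 1`, unequal means
  `p = 0`, both flagged degenerate.
* **Percent reduction** (`percent_reduction()`): the naive (reference) group
  mean is the denominator, matching how shortening is phrased relative to
  naive males.
* **Normality** (`ks_normality()`): KS against a normal law with estimated
  parameters, Lilliefors-corrected by default because the naive
  fully-specified KS is anticonservative when parameters are estimated; the
  naive mode is kept as an option since the convention used by the original
  graphing software is not documented. A lognormality mode tests log values.
* **Kruskal–Wallis + Dunn** (`kruskal_wallis()`,
  `dunns_multiple_comparison()`): tie-corrected H with the chi-square
  approximation; Dunn z statistics on the joint ranks with the classical
  Bonferroni adjustment over the comparisons actually performed —
  control-versus-all by default, all-pairs optionally, since multi-panel
  figures do not state which family was used. The hash flag (adjusted
  p < 0.05) mirrors the number-sign annotation convention.
* **Estimation statistics** (`bootstrap_mean_difference()`): unpaired mean
  difference with a seeded percentile bootstrap CI (5,000 resamples by
  default); BCa is available. Percentile is the default because it is the
  simplest to verify against a coverage simulation.
* **Annotation** (`significance_annotation()`): strict thresholds
  `***` < 0.001, `**` < 0.01, `*` < 0.05, else `ns`.
* **Orchestration** (`compare_experiment()`, `run_pipeline()`): filter to
  the 1 h window → per-group normality → t (2 groups) or KW+Dunn (>2) →
  bootstrap estimation against the internal control → annotation. Pipeline
  runs are deterministic given the global seed (per-block seeds are derived
  from it), and a failing block records a structured error without aborting
  the rest.

## Problem sizes used by the standing checks

The package's own verification runs use desk-scale sizes chosen to make
Monte-Carlo error small relative to the tolerance being asserted: 50 random
parameter sets for the closed-form/grid cross-check (a $10^6$-point grid);
10,000 null replicates for the t-test type-I error (band $0.05 \pm 0.007$);
1,000 simulated datasets of 30 flies per group with 1,999 resamples each for
bootstrap coverage (band $0.95 \pm 0.02$); 1,000 replicates of n = 500
samples for the normality-check calibration, where a well-calibrated test
retains normal samples at the nominal 95% rate (asserted within three
binomial standard errors) and rejects exponential samples essentially
always; and cohorts of 1,000–2,000 flies per group for recovering configured
effect sizes within three standard errors.

## Known limitations

* The guarding model is comparative statics only: no evolutionary dynamics,
  no fitting of $(\alpha, \beta, \gamma)$ to behavioral data.
* Scenario D is reported as not predicting SMD (see above); users who want a
  cost structure in which lowering $\gamma$ shortens guarding would need a
  qualitatively different objective, which can be injected through
  `guarding_model()` but is not shipped.
* Paternity pooling weights females by brood size (progeny-pooled), with
  per-female shares reported alongside; females with zero progeny are
  excluded from per-female statistics but counted in `n_females`. Whether
  zero-progeny females were excluded in the original percentage calculations
  is not documented; this is a declared choice.
* The generators draw metrics independently within a fly; real courtship,
  latency and duration measures are correlated.
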