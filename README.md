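# mateguard

Cost–benefit modelling and estimation statistics for *Drosophila*
mating-duration assays.

Sexually experienced male *Drosophila melanogaster* copulate for less time
than naive males (shorter-mating-duration, SMD). Because most of a
copulation is post-ejaculatory mate guarding, the phenomenon invites an
optimality question — when should a male guard *less*? — and an empirical
one — how are such behavioral effects quantified? `mateguard` addresses
both, for researchers analyzing fly mating assays and for anyone who wants
a fully testable, seedable reference implementation of this analysis style:

* a **marginal-value-theorem guarding model**: a male guarding for time
  `t` gains a saturating fertilization benefit
  `B(t) = (e/α)(1 − exp(−βt))` (total fertilizable eggs `e/α`; accrual
  rate `β`) and pays a linear cost `C(t) = γt`. Maximizing `B − C` gives
  the optimal guarding time `t* = log(eβ/(αγ))/β`, clamped to
  `[0, t_max]`. The optimum is long (`t* > 1/β`) when `γ ≤ β/α`, interior
  and shrinking in `γ` inside the window `β/α < γ < e·β/α`, and collapses
  to zero beyond `e·β/α`. Functions cover the payoff curves, the optimum
  (closed form and grid search), regime classification, scenario
  predictions for experience-dependent parameter shifts, and parameter
  sweeps.
* **seeded synthetic assay generators** for mating-duration cohorts
  (normal durations recorded to 10 s, 1 h inclusion window, n = 36 per
  group by default), egg/progeny counts (Poisson + binomial survival),
  two-sire sperm-competition crosses with the recessive *sepia* eye
  marker, and activity-reporter fluorescence with autofluorescence
  normalization.
* the **assay statistics pipeline**: inclusion filtering,
  percent-reduction effect sizes, pooled-variance Student's t,
  Lilliefors-corrected KS normality (and lognormality), Kruskal–Wallis
  with Dunn's Bonferroni-adjusted post hoc, bootstrap estimation
  statistics (percentile / BCa), star and hash significance annotation,
  courtship index, locomotion velocity, and paternity-share accounting.

## Worked example

Simulate a default SMD cohort (36 naive and 36 experienced males, a 15%
configured reduction) and run the full comparison route:

```r
library(mateguard)

tab <- simulate_md_assay(assay_design(percent_reduction = 15, seed = 42))
compare_experiment(tab, n_resamples = 5000, seed = 42)
#> <comparison_result> naive / experienced (n = 36 / 36)
#>   means: 1.52e+03 / 1.28e+03
#>   percent reduction vs naive: 15.8%
#>   Student's t = 3.249 (df 70), p = 0.00178 **
```

The experienced cohort mates for 15.8% less time than the naive internal
control (close to the configured 15%), the pooled-variance t test flags the
difference at the `**` (p < 0.01) level, and the bootstrap estimation view
of the same comparison reports the effect size with its uncertainty:

```r
compare_experiment(tab, seed = 42)$estimation$experienced
#> <estimation_result> mean difference -240.556 [-385.285, -92.5] (95% percentile CI, 5000 resamples)
```

On the modelling side, place a naive male inside the cost window and ask
what a cost increase does to its optimal guarding time:

```r
p <- guarding_params(alpha = 1, beta = 1, gamma = 1.5)
p
#> <guarding_params> alpha = 1, beta = 1, gamma = 1.5, t_max = 10
#>   regime boundaries: beta/alpha = 1, e*beta/alpha = 2.71828 (scenario_C_window)
optimal_guarding_time(p)
#> <optimal_guarding> t* = 0.594535 (interior, closed_form), net payoff 0.326479
predict_smd(p, guarding_params(1, 1, 2.2))
#> <scenario_prediction> C_gamma_larger: t*(naive) = 0.594535, t*(exp.) = 0.211543, delta = -0.382992 -> SMD predicted
```

Guarding time drops from 0.59 to 0.21 benefit time constants — shorter
mating duration is the optimal response to the higher guarding cost.
`run_pipeline(demo_config())` chains generators, statistics, fecundity /
paternity accounting and the model scenarios into one machine-readable
report (`write_report()`).

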