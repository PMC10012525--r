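---
title: "Multi-trait genotype selection with stability indices and measurement-driven AHP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait genotype selection with stability indices and measurement-driven AHP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mahpselect)
```

## The problem

Breeders evaluating a set of families (or other genotypic entries) in
replicated trials under a normal and a stress condition face a multivariate
decision: which entries to advance when many traits matter at once, the
target traits (say, yield and fruit quality) have complex inheritance, and
trait behaviour changes under stress. `mahpselect` implements a pipeline
that (1) quantifies, per trait and condition, how much of the observed
variation is genetic, (2) quantifies how stable each trait's expression and
genetic control are across the condition pair, (3) converts those genetic
parameters into trait weights through principal eigenvectors of
measurement-driven pairwise-comparison matrices, and (4) scores and ranks
the families.

The package ships the summary tables of a 57-family tomato drought-stress
trial (`tomato_case_study()`) as plain-text fixtures; the raw plot data are
not public, so these tables serve as golden references for the estimators
rather than as a rerunnable dataset.

## Data model

All functions consume a long-format tibble with columns `family`,
`replicate`, `condition` (`normal` / `stress`), `trait`, `value` — one row
per plot measurement, fully balanced. Balance is a hard requirement: the
variance-component algebra below assumes every family appears once per
block per condition, so missing cells raise errors rather than being
imputed. Identifier order is always first-seen order, never sorted, so
eigenvector and weight tables align positionally with the input.

## Genetic parameters from the RCBD analysis

For each trait and condition, `rcbd_anova()` fits the randomized
complete-block decomposition (replication + families + error; no
interaction term, since each family-block cell is a single plot). With $g$
families, $r$ blocks, family mean square $MS_f$ and error mean square
$MS_e$, `variance_components()` derives family-mean-basis components:

$$\sigma^2_g = \frac{MS_f - MS_e}{r}, \qquad
  \sigma^2_e = \frac{MS_e}{r}, \qquad
  \sigma^2_p = \sigma^2_g + \sigma^2_e = \frac{MS_f}{r},$$

$$h^2_b = \frac{\sigma^2_g}{\sigma^2_p} = 1 - \frac{MS_e}{MS_f}.$$

The raw estimate $h^2_{raw}$ can be negative when families vary less than
the error expectation; it is clamped to $[0, 1]$ for reporting but the raw
value is retained because the heritability-stability ratio below is defined
on it.

`expected_genetic_advance()` uses the standard truncation-selection
prediction $EGA = k \, h^2_b \, \sigma_p$ with $EGA\%$ = $100\,EGA/\bar{x}$
and default $k = 2.063$, the standardized selection differential at 5%
selected fraction. Both $k$ and the family-mean basis for $\sigma_p$ are
reconstructions of standard practice: the case-study tables print $EGA\%$
but neither $k$ nor the grand means, so these two constants cannot be
golden-tested and are exposed as arguments.

`genetic_correlation()` applies the same decomposition to mean
cross-products: $cov_g = (MCP_f - MCP_e)/r$ and
$r_g = cov_g / \sqrt{|\sigma^2_{g,X}|\,|\sigma^2_{g,Y}|}$. Absolute values
in the denominator keep the estimator defined when a variance component is
negative (the raw, sign-allowed components are used deliberately). $r_g$ is
a ratio of estimates and is **not** bounded by 1; the uncapped value feeds
the weighting step, while a `[-1, 1]`-clipped copy is provided for
reporting, matching how such tables are conventionally printed.

## Trait stability

Two statistics summarize a trait's behaviour across the condition pair:

* **SI (Stability Index)** — the absolute OLS slope of the stress-condition
  family means regressed on the normal-condition family means
  (`stability_index()`). Slope near zero means stress expression is
  unrelated to normal expression: maximal stability under this convention.
  Note this differs from genotype-stability regressions where slope 1 is
  the neutral reference; the package implements the definition literally.
  The regression runs on family means (not pooled plot data): the method
  operates at the family level throughout, and family means are the
  quantity with a defined generator truth (see below). The regression keeps
  its intercept.
* **SIBH** — the ratio $BH_2 / BH_1$ of stress to normal broad-sense
  heritability (`sibh()`), computed on the *unclamped* estimates with the
  absolute value reported. The unclamped convention matters: a trait whose
  normal-condition component is negative (clamped to "≈ 0" in reports)
  still has a well-defined, continuous SIBH, and this is the only rule
  under which the bundled case-study SIBH values (e.g. single fruit weight,
  0.094) are reproducible from the published mean squares. SIBH is
  undefined only at exactly $BH_1 = 0$; the pipeline then logs the trait
  and zeroes its SIBH contribution rather than failing.

## Measurement-driven AHP

Classical AHP elicits pairwise-comparison matrices from expert judgment and
must police their consistency. Here the matrices are built from measured
values: given a parameter vector $v$ over traits, $A_{ij} = v_i / v_j$
(`comparison_matrix()`). Such a matrix is reciprocal and rank one, its
principal eigenvalue is exactly $N$, and its principal eigenvector is
proportional to $v$ — consistency holds by construction, so no
consistency-ratio check is needed, and `principal_eigenpair()` can use the
closed form (the dense eigendecomposition path is kept and cross-checked in
the tests).

Numerical conventions, each fixed by agreement with the bundled case-study
weight table:

* **Normalization** is unit Euclidean norm, not AHP's sum-to-one. L2
  normalization of the published SIBH column reproduces the published
  eigenvector column entry-for-entry; sum-to-one does not.
* **Combination** of the per-parameter eigenvectors into a trait's final
  weight is the plain (unweighted) row sum, which reproduces the published
  final weights within the precision their printed inputs carry.
* **Negative entries** (correlation columns) pass through unchanged — an
  eigenvector entry and its weight contribution may be negative.
* **Sign**: eigenvectors are oriented along the generating vector. A ratio
  matrix is invariant to $v \to cv$ (including $c < 0$), so when only a
  matrix is supplied the sign is fixed by a largest-entry-positive
  convention.

Lower-is-better variables (phenological earliness traits; the SI parameter)
are reflected about their maximum before normalization:
$TD_i = \max(D) - D_i$ (`lower_better_transform()`). Two switches control
reproduction versus recommended behaviour:

* `si_lower_better` in `mahp_selection()` defaults to `TRUE` (SI is defined
  so that small is good, so it should be reflected). The published
  case-study SI eigenvector column, however, is the *untransformed*
  normalized vector; `si_lower_better = FALSE` reproduces that mode.
* `standardize` (z-scoring parameter columns before the eigenvector step)
  is off by default: the unit-norm step already removes scale, and there is
  no evidence the published tables applied a separate standardization.

`family_scores()` applies the same machinery across families: per retained
trait, reflect if lower-better, take the unit-norm eigenvector of the
condition-averaged family means, and combine as the weighted sum with the
final trait weights. Scoring on the condition average follows the
case-study practice of selecting on the average when trait behaviour is
similar across conditions. Exact reproduction of the published family
scores is not attempted — it requires the raw plot data and combination
details that are not public — so scoring is validated by structural
invariants (unit-norm columns, score = weighted sum, scale invariance) and
by the published-score ranking check: ranking the printed scores recovers
the published top-10 family set exactly.

`select_top()` sorts descending and selects `count` or
`ceiling(fraction * n)` families; ties keep input order, making selection
deterministic.

## Trait filtering

`filter_traits()` drops a trait only when it shows no heritable variation
in either condition: family effect non-significant (default
$\alpha = 0.05$) *and* clamped $h^2_b = 0$ in both conditions. The two
symptoms are nearly equivalent — a significant family F implies
$MS_f > MS_e$ and hence $h^2_b > 0$ — but requiring both keeps the marginal
trait whose families differ modestly (non-significant F) while still
yielding a positive variance-component estimate. In the bundled case study
this rule retains single fruit weight (non-significant in both conditions
but with a small positive stress-condition heritability) and drops plant
height, cluster number and fruit number, matching the published trait set.
A dropped-or-retained decision near $h^2 \approx 0$ is sensitive to
sampling noise: on simulated data a truly non-heritable trait's estimate is
positive about half the time, so such traits can survive filtering with
tiny weights. Every exclusion is logged with its reason, and the retained
plus excluded sets always partition the input traits.

## The synthetic generator

`sim_spec()` / `simulate_trial()` generate balanced trials under exactly
the assumptions the estimators rely on: Gaussian family effects
(multivariate across traits with a specified genetic correlation matrix),
Gaussian block effects, Gaussian plot residuals, and stress family effects
produced by the slope model
$g^{(s)}_t = a_t\, g^{(n)}_t + \varepsilon_t$. The slope model is the
generator's *definition* of trait stability, giving SI a known truth
($|a_t|$); note the family-mean regression estimates
$a_t\,\sigma^2_g/(\sigma^2_g + \sigma^2_e/r)$, so within-family error
attenuates the slope — recovery tests therefore use small error variance
relative to the genetic variance. A single integer seed governs all draws
and the global RNG state is restored afterwards.

`case_study_spec()` instantiates the generator with the published
architecture: 57 families, 3 blocks, 18 traits, variance components and
block variances derived from the printed mean squares, stress slopes from
the published SI values, and stress noise variances chosen so the stress
genetic variances match the stress-condition table. Grand means are not
printed; where $EGA\%$ is printed they are backed out of it
($\bar{x} = 100\,k\,h^2\,\sigma_p / EGA\%$ with $k = 2.063$), otherwise
plausible tomato values are used (plant height 120 cm, 30 clusters, 60
fruits, single fruit weight ≈ 68 g). The genetic correlation matrix
defaults to the identity: the published tables constrain only correlations
with yield and total soluble solids, which under-determines the full 18×18
matrix. What the generator deliberately does **not** emulate: non-Gaussian
traits, genotype-by-environment structure beyond the slope model, spatial
field trends, and unbalancedness — so passing recovery tests demonstrate
estimator correctness under the model's own assumptions, not robustness to
real-field pathologies.

`recovery_report()` wraps the loop "simulate, estimate, compare to truth"
and reports mean estimate, bias and RMSE per statistic. The test suite runs
it at, e.g., 100 families × 3 blocks × 200 replicates for heritability
(bias tolerance ±0.03), 100 replicates for SI (±0.05 at slope 0.5) and 40
replicates at 200 families for genetic correlation (±0.1 at ρ = 0.7) —
sizes chosen to make Monte-Carlo error comfortably smaller than the
tolerance being checked.

## Degenerate inputs and numerical edge cases

* Fewer than 2 families or blocks: hard error (no degrees of freedom).
* Zero error mean square (perfectly replicated data): F and p degenerate
  to their limits rather than erroring.
* $MS_f = 0$: heritability reported as 0 with a warning.
* Zero genetic variance in a correlation: explicit error naming the trait
  (the pipeline excludes the column and logs).
* Constant vectors: reflection yields all zeros, which the normalization
  step rejects as degenerate; constant normal-condition means make SI
  undefined (error).
* Golden comparisons against the bundled tables treat printed values as
  intervals of ±half an ulp: a statistic recomputed from rounded inputs is
  checked to printed precision only where the input rounding supports it,
  and by interval containment otherwise.

## Known limitations

* Estimation is ANOVA method-of-moments only; no REML/mixed models, no
  narrow-sense heritability, no dominance decomposition.
* The model is defined for exactly one condition pair; multi-environment
  series are out of scope.
* Trait stability only — genotype-stability methods (Eberhart–Russell for
  genotypes, AMMI, GGE) are not provided.
* Uncapped genetic correlations can be arbitrarily large when a
  denominator component is near zero, which can dominate the weight
  columns; inspect `tidy(fit, "correlations")` when a trait's heritability
  is marginal.
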