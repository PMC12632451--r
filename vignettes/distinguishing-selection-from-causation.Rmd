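---
title: "Distinguishing positive selection from cancer causation with carceff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing positive selection from cancer causation with carceff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carceff)
library(dplyr)
```

## The problem

Positive selection in a cancer genome is routinely read as evidence of
causation, but positively selected clones also expand in normal, never-
malignant tissue. A mutation can therefore be common in cancers either
because it raises a cell's probability of initiating cancer or because it
was already common in the tissue the cancer arose from. carceff implements
a statistical framework that separates the two.

The central quantity is a mutation's **carcinogenic effect** `w`: the per-
cell hazard ratio for cancer initiation, `w = r1/r0`, where `r1` and `r0`
are the initiation rates of otherwise identical cells with and without the
mutation. `w = 1` means the mutation does not cause cancer regardless of
how strongly it is selected in normal tissue; `w < 1` is protective.

## Estimating carcinogenic effects

If fraction `x` of normal tissue cells and fraction `y` of cancer founder
cells carry the mutation, the odds ratio

$$\hat w = \frac{y/(1-y)}{x/(1-x)}$$

estimates `w`. The package provides four estimators around this identity:

* `estimate_matched()` — the odds ratio computed from a cancer cohort
  (`y` = fraction of samples with a qualifying mutation) and a
  deep-sequenced normal cohort (`x` = cohort-mean mutant cell fraction from
  VAFs), with a percentile bootstrap over donors (default 1000 resamples,
  resampling each cohort independently).
* `estimate_length_benchmark()` — for tissues where normal-state mutations
  are unobservable (childhood blood): mutation frequency in normal tissue
  is approximated as proportional to coding length `L`, giving *relative*
  effects `L⁻¹ f̂/(1−f̂)` (units 1/bp), comparable only by rank.
* `fit_hybrid_beta()` — a four-parameter joint model `(a, b, φ, w)` in
  which the expected normal-tissue mutant fraction at age `t` is
  `1/(1+e^{a+bt})`, the realised fraction is Beta-distributed with
  precision `e^φ`, fractions below a detection floor `x0` are observed as
  zero (and contribute the Beta CDF at `x0` to the likelihood), and a
  cancer sample at age `t` is mutated with probability `w/(w+e^{a+bt})`.
* `fit_logistic_effect()` — mutation probability
  `w^χ/(w^χ + e^{a+bt+cm})` with age `t`, burden `m` and cancer indicator
  `χ`; equivalently a logistic regression whose group coefficient is
  `log w`, fitted with `glm()` and profiled for a 95% interval by deviance
  bisection (each endpoint sits exactly at a `χ²₁(0.95)/2` log-likelihood
  drop).

VAFs are converted to cell fractions by `vaf_to_cell_fraction()` (doubling
under diploidy/heterozygosity, capped at the VAF itself when doubling
exceeds one, and hemizygous for the male X); multiple mutations of a gene
in one sample are combined by `gene_sample_fraction()` (sum, falling back
to the maximum when the sum exceeds one). Note the combination rule is
deliberately not monotone in its inputs: pushing the summed configuration
past one switches the interpretation from disjoint clones to nested ones.

Zero cells are reported as exact `0`/`Inf` with flags; a Haldane–Anscombe
0.5 correction is available behind `zero_correction = TRUE` but off by
default, because an unobserved mutation in normal tissue is informative
(the matched estimator's `Inf` mirrors genuinely extreme effects).

## The branching-process model

The mechanistic backbone is a birth–death-with-immigration model: a
constant pool of `N0` wild-type cells acquires mutation z at per-cell rate
`v`; mutant cells divide at `a1` and are lost at `b1` (selective effect
`s = a1 − b1`); cancer initiates at per-cell hazard `r0(t)` (wild-type)
or `w·r0(t)` (mutant). Writing `p_k(t, T)` for the probability of no
mutant-initiated cancer in `(t, T)` given `k` mutant cells, the backward
Kolmogorov system (with its T-differentiated companion) is integrated by
the explicit Euler method, and

* `cancer_mutation_odds()` returns the odds that a cancer at age `T`
  carries the mutation,
* `normal_tissue_odds()` the odds for a normal cell at age `T`,

whose ratio is algebraically `w` — the identity the framework rests on,
guarded by a regression test at relative tolerance 1e-6.

Two numerical points deserve note. First, the two-cell state factorises
over immigrant clones (`p_k = F φ^k`), so the quadratic term in the `p1`
equation is `p1²/p0`, not `p1²`; at realistic parameters `p0 ≈ 1` and the
distinction is invisible, but at the reduced scales used for Monte Carlo
cross-checks it is required for the closed-form mean `E N1(T) =
N0 v (e^{sT}−1)/s` to be reproduced to 1e-3. Second, the default Euler
step is `dt = 5e-4` years, chosen so that halving the step moves both
`p0` and its T-derivative by less than 1e-4 relative
(`check_euler_step()` exposes the diagnostic); an unstable configuration
raises an error advising a smaller step rather than returning numbers.

`simulate_trajectories()` is an exact Gillespie-style simulator of the
same process (inter-event carcinogenesis times are inverted from the
closed-form cumulative hazard, so there is no discretisation anywhere).
It exists as the independent oracle for the ODE solution; the tests
compare the two within Monte Carlo error at a reduced scale (`N0 = 10³`,
`v = 10⁻⁵`), where events are frequent enough to simulate in bulk.

`age_profile()` turns the solution into age statistics: the age density
of cancers carrying the mutation versus a neutral reference with the same
acquisition rate, their mean-age difference, and the ratio of their
frequencies among cancers. The baseline hazard defaults to the power-law
mixture `r0(t) = 10^u t³` with `u` uniform on (−16, −13) across people,
integrated by 64-point midpoint quadrature rather than Monte Carlo so the
profiles are deterministic. Directionally: selection in normal tissue
(`s > 0`, `w = 1`) pushes the mutation towards *older* cancers, while
carcinogenicity (`w ≫ 1`) pushes it towards *younger* ones. At `s = 0`
the rejuvenation from `w` alone is small in absolute years (the mutant
subpopulation is tiny, so conditioning bites weakly) but strictly
negative; with `s > 0` the effect strengthens.

## The null hypothesis of no carcinogenicity

The null class is wider than the branching process: clones may grow along
exponential, Gompertz, logistic or polynomial expectation curves
(`growth_curve()`), initiated as a Poisson process, with the cancer
founder drawn proportionally to cell fractions (`w = 1`).
`null_family_age_shift()` computes the mean-age shift and frequency ratio
versus neutral for any curve; for every positively selected curve the
z-carrying cancers' age distribution stochastically dominates the neutral
one (asserted CDF-wise on the grid), and both statistics collapse to
(0, 1) at zero selection. Carrying capacities default to `K = 10⁴` cells
and the polynomial exponent to 2; these are declared defaults, not values
taken from any external source, and all conclusions drawn from the family
are directional.

This yields the falsifiable prediction the cohort-side test uses: a
mutation that is *both* enriched above the neutral background *and*
young-age-biased cannot be explained by selection without causation.

## Age statistics and the permutation test

On the cancer-genome side, `weighted_mean_age()` computes the
mutation-weighted mean patient age (each mutation contributes its
sample's age once) with a Wald interval; because mutations within a
sample share an age, a cluster-robust variant (`cluster = "sample"`) is
provided. `age_divergence()` normalises the mutation-weighted
between-gene variance of those means by the cohort's population age
variance and attaches a Kruskal–Wallis p-value (midranks, standard tie
correction). `age_difference_vs_synonymous()` benchmarks a gene's
non-synonymous ages against exome-wide synonymous ages, and
`permutation_test()` ranks the observed difference within a null
distribution obtained by permuting age labels among samples (mutation
assignments fixed; default 1000 permutations; one-sided young quantile
reported alongside the two-sided p; Benjamini–Hochberg q-values across
the gene list; the p floor is `1/(n_perm+1)`).

A calibration subtlety: permuting ages is an *exact* test only when ages
are exchangeable with respect to the mutation table. In a cohort where
both driver and synonymous mutation counts accumulate with age — the
neutral expectation, and the realistic regime — the burden–age
correlation shrinks the observed statistic's variance relative to the
permutation distribution, making the test mildly conservative (measured
type-I ≈ 0.036 at nominal 0.05 in the clock-null simulations below).
Under an exchangeable null the measured type-I error is 0.050 and the
permutation quantiles are uniform. Both regimes are exercised in the
tests; users should read borderline q-values accordingly.

`rank_biserial_age_bias()` implements the age-bias effect size
`r = 2U/(n₁n₂) − 1` (ties as halves; positive = carriers older), checked
against brute-force pair enumeration, and `scna_snv_bias_table()` applies
it to copy-number versus point alterations per gene: the SNV bias is
computed among samples with no SCNA in the gene and the role-matched SCNA
bias (deletions for tumour suppressors, amplifications for oncogenes)
among samples with no non-synonymous SNV/indel, so co-occurring samples
are excluded from both sides; gene–role pairs are kept when each
alteration type reaches 5% frequency by default.

## The multi-hit model

`multihit_model()` specifies the minimal many-mutation picture:
mutations arrive along a lineage as a rate-`v` Poisson process, each
carries an i.i.d. Gamma(2, 1) carcinogenic effect, and the transformation
hazard is the baseline `r_base` times the product of effects (accumulated
in log space). `simulate_lineages()` is exact: between arrivals the
hazard is constant, so transformation times come from competing
exponentials.

At the headline parameters (`v = 0.005`, `r_base = 10⁻⁹`) transformation
is a ~10⁻⁷-per-lifetime event, so unconditional simulation produces
essentially no cancers. `sample_cancers()` therefore samples from the
exact conditional-on-transformation law: lineage mutation histories are
drawn unconditionally, each is weighted by its closed-form probability of
transforming within the lifespan, cancers are resampled proportionally to
those weights, and transformation times are inverted from the truncated
piecewise-exponential CDF. This is an exact sampler, not an
approximation, and it is validated against brute-force conditioning at an
inflated baseline rate (Kolmogorov–Smirnov agreement in the tests).

The model's qualitative predictions all hold in the package's runs:
driver counts grow with age in normal lineages (≈ `vt`) and faster in
cancers; incidence rises with age; cancers at older ages carry more
drivers; and cancers with fewer drivers, or at younger ages, carry
stronger ones. The last rank correlation (effect versus age) is real but
tiny at these parameters (Spearman ≈ −0.005), because most cancers carry
zero or one driver and single-driver size-biasing is age-independent to
first order; its sign test therefore runs on ~10⁶ effect-bearing
conditional cancers, where the sign is stable across seeds.

## Synthetic cohorts

`synth_matched_cohort()`, `synth_vaf_table()`, `synth_age_cohort()` and
`synth_scna_table()` generate every fixture the estimators and tests
need, each seeded and accompanied by a truth table. Design choices:

* Normal-tissue fractions are Beta-distributed around the true `x` with
  precision 50, so estimators are exercised under over-dispersion and the
  hybrid model's assumed law.
* Cancer mutation frequencies follow the inverted odds formula
  `y = wx/(1−x+wx)`.
* Ages default to Uniform(36, 90), an adult-blood-like span.
* The age-cohort generator's null mode gives planted genes Poisson counts
  with the *same* linear-in-age rate profile as the synonymous background
  — the neutral null the permutation test embodies. A gene whose
  mutations did not accumulate with age at all would be genuinely
  young-biased relative to neutral mutations, not null.
* Read noise is binomial at a stated depth, with censoring below the
  detection floor applied on the cell-fraction scale.

What these generators do *not* emulate: mutational signatures and
trinucleotide context, copy-number-driven VAF distortion, sample purity,
clonal interference between genes, and donor-level confounding between
normal-tissue selection and cancer risk. Passing tests therefore
demonstrate correctness of the estimators under the stated model, not
robustness to everything real cohorts contain — the matched design's
caveats (epistasis, heterogeneous mutagenesis) carry over.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run: the odds identity on the
full (s, w) grid at `T = 80`; ODE-versus-simulation agreement with 10⁵
trajectories at reduced scale; 1000 null cohorts of 500 samples × 20
genes × 200 permutations for calibration; 100 seeded replicates per
planted `w ∈ {1, 10, 100}` at n = 2000 per cohort for each estimator
(bootstrap B = 500 for the matched estimator); and 3×10⁶ conditional
cancers from 6×10⁶ lineage histories for the multi-hit sign tests.

## A worked example

```{r example}
genes <- tibble::tibble(gene = c("NEUTRAL", "MODERATE", "STRONG"),
                        x = c(0.05, 0.02, 0.01), w = c(1, 10, 100))
syn <- synth_matched_cohort(genes, n_cancer = 2000, n_normal = 2000,
                            seed = 5)
estimate_matched(syn$cancer, syn$normal, genes$gene, B = 1000, seed = 7)
```

```{r profile}
age_profile(s = 0.1, w = 1, age_step = 2, dt = 0.02, n_u = 16)
age_profile(s = 0, w = 100, age_step = 2, dt = 0.02, n_u = 16)
```

## Known limitations

* Effects are per gene, not per variant; hypermutators are out of scope
  (use the burden filters).
* The matched odds ratio inherits every caveat of observational
  case–control comparisons; unmatched cohorts add donor-level
  confounding that the estimator cannot remove.
* The hybrid Beta likelihood treats the detection floor as sharp; real
  variant-calling sensitivity decays smoothly near the limit.
* The Euler solver is explicit; pathologically stiff parameterisations
  (per-cell hazards approaching the division rate) are rejected rather
  than integrated.
* The growth-curve null family's carrying capacities and exponents are
  declared defaults; conclusions from that family are directional only.
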