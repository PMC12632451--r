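# carceff

Distinguishing positive selection from cancer causation in somatic
mutation data.

Cancer genomes are full of positively selected mutations, but positive
selection is also ubiquitous in normal, never-malignant tissue. For most
recurrent mutations it is unresolved whether they appear in cancers
because they *cause* cancer or because they had already expanded in the
normal tissue the cancer arose from and were passively inherited. carceff
is a toolkit for researchers in cancer genomics and somatic evolution who
want to make that distinction quantitatively — from paired cancer/normal
cohorts where such data exist, and from cancer genomes plus patient ages
where they do not.

## The model in brief

A mutation's **carcinogenic effect** is the per-cell hazard ratio for
cancer initiation, `w = r1/r0`, comparing otherwise identical cells with
and without the mutation. If fraction `x` of normal tissue cells and
fraction `y` of cancer founder cells carry the mutation, then

    ŵ = [ y/(1−y) ] / [ x/(1−x) ]

estimates `w`. The package provides this matched odds-ratio estimator
(donor bootstrap CIs), a gene-length benchmark for tissues whose normal
state is unobservable, a hybrid Beta regression sharing a logit-linear
age trend between cancer presence data and normal-tissue cell fractions,
and a logistic regression with age and burden covariates
(`w^χ/(w^χ + e^{a+bt+cm})`, profile-likelihood CIs).

Underneath sits a birth–death branching process with mutation influx
(transitions `i → i+1` at rate `N0·v + i·a1`, `i → i−1` at rate `i·b1`,
selective effect `s = a1 − b1`) and age-dependent carcinogenesis hazards
`r0(t)` / `w·r0(t)`, solved via backward Kolmogorov equations and
cross-checked by an exact stochastic simulator. Its key identity — the
cancer-versus-normal odds ratio at any age equals `w` exactly — grounds
the estimators; its age profiles show that selection without causation
pushes mutations towards *older* patients' cancers (a stochastic-
dominance property that holds across exponential, Gompertz, logistic and
polynomial clonal-growth nulls) while strong carcinogenicity pushes them
towards *younger* ones. A permutation test on mutation-weighted mean
ages versus exome-wide synonymous mutations operationalises this for
cancer-only cohorts, and a multi-hit simulator (Poisson mutation
arrivals, Gamma-distributed effects multiplying the transformation
hazard) reproduces the joint age/driver-burden/effect-strength patterns.
Synthetic-cohort generators with known truths make every component
testable without external data.

## Worked example

Generate a matched cancer/normal pair with three planted genes — neutral
(`w = 1`), moderate (`w = 10`, the range typical of common clonal
hematopoiesis drivers) and strong (`w = 100`) — and recover the effects:

```r
library(carceff)
genes <- tibble::tibble(gene = c("NEUTRAL", "MODERATE", "STRONG"),
                        x = c(0.05, 0.02, 0.01), w = c(1, 10, 100))
syn <- synth_matched_cohort(genes, n_cancer = 2000, n_normal = 2000,
                            seed = 5)
estimate_matched(syn$cancer, syn$normal, genes$gene, B = 1000, seed = 7)
#> # A tibble: 3 × 10
#>   gene     method      w_hat ci_low ci_high      y      x n_cancer n_normal
#> 1 NEUTRAL  odds_ratio   1.20  0.993    1.45 0.0585 0.0492     2000     2000
#> 2 MODERATE odds_ratio  10.1   8.95    11.4  0.172  0.0201     2000     2000
#> 3 STRONG   odds_ratio 100.   90.2    112.   0.510  0.0103     2000     2000
```

`y` is each gene's mutated fraction among cancers, `x` its cohort-mean
mutant cell fraction in normal tissue, and `w_hat` the odds-ratio
estimate with its 95% donor-bootstrap interval — all three planted
effects are recovered within their intervals.

Age profiles from the branching process show the two signatures the
framework separates:

```r
age_profile(s = 0.1, w = 1)   # selected, not carcinogenic
#> <bp_age_profile> s = 0.1, w = 1: mean age 73.99 (neutral 67.33,
#>   shift +6.67), freq ratio 174
age_profile(s = 0, w = 100)   # carcinogenic, not selected
#> <bp_age_profile> s = 0, w = 100: mean age 67.32 (neutral 67.33,
#>   shift -0.01), freq ratio 99.9
```

Both mutations are ~100× enriched among cancers relative to a neutral
mutation — frequency alone cannot tell them apart — but the selected one
sits nearly seven years *older* than neutral while the carcinogenic one
does not: age carries the causal signal.

A thin command-line wrapper over the same functions is installed at
`inst/cli/carceff` (subcommands `validate`, `cell-fractions`,
`estimate-effect`, `age-bias`, `simulate-bp`, `simulate-multihit`,
`synth`); run it with `Rscript` and `--help` for usage.

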