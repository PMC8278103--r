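---
title: "Models and methods behind gcablup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gcablup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A single-cross hybrid breeding program crosses a small panel of female
testers (male-sterile lines, so that every seed on them is hybrid) to a
large panel of male restorer lines and asks three questions:

1. Which untested crosses are worth making? (prediction of **hybrid
   genetic value**)
2. Which parents transmit the best average performance? (**general
   combining ability**, GCA, with the cross-specific remainder called
   **specific combining ability**, SCA)
3. Is parental genetic distance a useful proxy for hybrid vigor?
   (**mid-parent heterosis**, MPH, against the squared difference in
   allele frequency, **SDAF**)

gcablup implements the complete statistical pathway for these questions
on plot-level trial data and genome-wide marker dosages, together with a
population simulator that reproduces the relevant structure of such a
program, so every stage of the pipeline can be exercised and tested with
no external data.

# Mixed models

All analyses are linear mixed models fit by restricted maximum
likelihood (REML).  `model_catalog()` assembles the stage-specific
specification:

* **Hybrid value**: `y = mu + H + E + HE + B(E) + e` with `H` the hybrid
  genotype effect, `E` environment, `HE` their interaction, and `B(E)`
  blocks nested in environments.  In the *genomic* variant
  `H ~ N(0, G_H sigma2_H)` with `G_H` the hybrid relationship matrix;
  otherwise `H` is i.i.d.
* **GCA**: `y = mu + F + M + E + B(E) + FE + ME + e`, with female and
  male GCA effects carrying the parental kernels `G_F`, `G_M` in the
  genomic variant.
* **GCA + SCA**: adds `FM ~ N(0, G_FM sigma2_FM)` with `G_FM` the
  Kronecker product of the parental kernels (restricted to the observed
  female-male pairs when the full product is not needed).
* **Genotype value (heterosis stage)**: hybrids *and* inbreds together,
  with a fixed inbred-vs-F1 indicator absorbing the heterotic mean
  difference and a random genotype effect; genotype values are composed
  as `mu + class effect + genotype BLUP`.

Traits observed in a single environment automatically drop the
environment term and its interactions.  Environments are modeled as
random by default — with two levels this component is weakly estimable
and routinely lands on the boundary, which is reported rather than
hidden — and `env_fixed = TRUE` moves the environment main effect to the
fixed part for users who prefer that convention.

## REML engine

`fit_reml()` maximizes the restricted likelihood over the variance
components using Henderson's mixed-model equations (MME).  With
`C = [X'X, X'Z; Z'X, Z'Z]/sigma2_e + blockdiag(0, K_t^{-1}/sigma2_t)`,
one Cholesky factorization per evaluation yields the solutions, the
restricted deviance through
`log|V| + log|X'V^{-1}X| = n log sigma2_e + sum_t (q_t log sigma2_t +
log|K_t|) + log|C|`, and — from the inverse of `C` — the prediction
error variances (PEV) of every BLUP.  Scores and the average-information
(AI) matrix are computed with the standard MME identities, so no `n x n`
matrix is ever formed.

Numerical choices, each of which matters in practice:

* **Updates**: AI steps with step halving, restrained to at most a
  tenfold change per component per iteration.  Unrestrained AI steps can
  pin a genuinely positive component at the variance floor in a single
  overshoot — a local trap in which an interaction term absorbs the
  variance — and the restraint removes that failure mode.  The first
  iteration is an EM step; EM is also the fallback whenever the AI
  proposal does not improve the likelihood (EM never decreases it).
* **Floor**: components are clamped at `1e-8` times the phenotypic
  variance and flagged as boundary estimates.  Boundary components with
  negative scores are excluded from the AI system.
* **Convergence**: relative change of every component below `1e-6` with
  log-likelihood change below `1e-8`; in addition, a likelihood that is
  flat to `1e-7` for three iterations, or EM progress below `1e-5` per
  iteration for ten iterations, is accepted as converged (the EM rate is
  linear and such tails are immaterial).  Cap: 200 iterations, with a
  warning and `converged = FALSE` when hit.
* **Initialization**: equal split of the phenotypic variance across all
  components — deterministic and scale-free.  Warm starts (used by the
  cross-validation refits) snap near-floor carries to the floor of the
  new data.
* **Model comparison**: `AIC = -2 logL + 2k` and
  `BIC = -2 logL + k log n` with `k` the number of variance parameters
  only; REML criteria are comparable only across models with the same
  fixed structure, which holds for every comparison the package makes.
* **Missing data**: complete-case per trait (rows with a missing
  response are dropped), matching unbalanced trials with missing
  replicates.

The engine is verified in the test suite against an independent
generalized-least-squares oracle on the explicit marginal covariance
(fixed effects, BLUPs, PEVs and the deviance agree to `1e-8` on random
small instances), against closed-form ANOVA estimators on balanced
one-way designs, and against lme4 on identity-kernel models.

## Kernels

`grm()` implements the VanRaden / Endelman-Jannink estimator
`G = WW' / (2 sum p(1-p))` on dosages centered by twice the panel
allele frequency; monomorphic sites contribute nothing, and a diagonal
ridge (`1e-6`, logged) restores positive semidefiniteness when floating
point noise produces a negative eigenvalue.  `infer_hybrid_genotypes()`
builds expected F1 dosages `(female + male)/2` — fractional values are
deliberate, since the result feeds covariance estimation.
`sca_kernel()` / `sca_kernel_pairs()` build the Kronecker SCA kernel in
female-major pair order, the latter as a principal submatrix without
forming the full product.

`scale_kernel()` divides a kernel by `(tr G - sum(G)/q)/(q-1)`, the
expected sample variance of one MVN(0, G) draw across its levels, so a
variance component attached to the scaled kernel is directly the
expected realized variance of its effects.  The simulator uses scaled
kernels for exactly this interpretability, and `model_catalog()` applies
the same standardization to SCA kernels it builds internally: the
Kronecker product of two standardized kernels is itself no longer
standardized (for these panels its factor is about 0.8), and without the
correction `sigma2_FM` would be reported on a different scale than
`sigma2_F` and `sigma2_M`.  Fits, predictions and information criteria
are invariant to this scalar; only the component's reported scale
changes.  User-supplied `G_FM` kernels are used untouched.

# Heritability, reliability, accuracy

* **Entry-mean heritability** for the unbalanced RCBD:
  `H2 = sigma2_H / (sigma2_H + sigma2_HE/h_j + sigma2_e/h_t)`, with
  `h_j` the harmonic mean of observations per genotype within an
  environment and `h_t` per genotype overall
  (`design_harmonic_means()`); single-environment traits drop the
  interaction term.  Standard errors come from the delta method on the
  AI covariance of the components; a delete-one-genotype jackknife is
  available (`se_method = "jackknife"`) at the cost of one refit per
  genotype.
* **Narrow-sense heritability** on a single-plant basis:
  `h2 = sigma2_H / (sigma2_H + sigma2_HE + sigma2_e)` with `sigma2_H`
  from the *genomic* hybrid-value fit; the function refuses components
  from an identity-kernel fit, whose `sigma2_H` is total rather than
  additive genetic variance.
* **Reliability** of a BLUP: `r2 = 1 - PEV/sigma2`, clipped to [0, 1]
  (REML noise can push a PEV marginally above its component; clipping is
  counted and reported), averaged over levels with data; undefined when
  the component sits at the floor.  **Phenotypic selection accuracy** is
  the square root of the mean reliability; **genomic prediction
  accuracy** divides a cross-validated predictive ability by the
  full-data correlation between the genomic and the conventional BLUP of
  the same effects.

# Cross-validation designs

`male_gca_cv()` partitions the phenotyped males into ten folds, masks
all hybrid progeny plots of the held-out males, refits the genomic
stage, and correlates the masked-fit GBLUPs of male GCA with the
full-data conventional BLUPs; the fold-mean ability divided by the
full-data GBLUP-BLUP correlation is the accuracy.  A `fold_size` option
draws fixed-size random masks with replacement across folds instead of
partitioning, for emulating designs whose fold arithmetic exceeds the
male count.  Abilities are averaged across folds without Fisher
transformation (plain averaging; the alternative changes nothing at
these magnitudes).  Degenerate folds (< 3 males) switch to pooling
predictions across folds before correlating — never a correlation of
one point.

`hybrid_tset_cv()` runs the replicated training-set design: per
replicate, sample females and males, then a fixed-size training set of
their phenotyped hybrids constrained so every sampled parent has at
least one training progeny.  Pure rejection sampling almost never
satisfies that constraint when the training set is barely larger than
the male sample (with 127 males and 150 training slots the probability
of covering every male by chance is essentially zero), so after a
bounded rejection budget the sampler switches to a constructive draw:
one progeny per uncovered parent, remainder uniform.  Predicted genetic
values of all phenotyped non-training hybrids (female GCA + male GCA,
plus SCA when modeled) are correlated with their full-data hybrid-value
BLUPs — the truth proxy — within the strata T2 (both parents in
training), T1F / T1M (only the female / male), their union T1, and T0
(neither).  A leakage assertion verifies on every replicate that no
training hybrid is evaluated.  Per-replicate seeds are drawn once from
the master seed, so replicates are independent and order-insensitive,
and refits are warm-started from the full-data components (a
deterministic speedup that does not change the optimum).

# Heterosis and SDAF

`fit_genotype_model()` fits the genotype-value model and composes
per-genotype values as `mu + class effect + genotype BLUP`, plus the
mean environment and block BLUPs so values sit on the trial-mean scale
(those means are ~0 in any regular fit; the term matters only when the
residual variance degenerates and the environment mean becomes
confounded with the intercept).  `mph()` and `crp()` are the ratio
definitions `(H - MP)/MP` and `(H - C)/C`; CMS females are phenotyped
through their maintainer lines, and the TGMS female through its own
records (the maintainer substitution only applies to CMS cytoplasm, so
the TGMS line's own value is the natural choice).  Inbred checks enter
the model with the same inbred indicator level as the parents — both are
inbreds, and the indicator models inbreeding depression of the mean, not
pedigree role.  `sdaf_mph_tests()` reports Pearson r with
`t = r sqrt((n-2)/(1-r^2))`, exact two-sided P values (display-level
formatting such as "< 0.001" is left to the caller), and Fisher-z 95%
confidence intervals — the standard construction, chosen because
symmetric-in-r intervals misbehave near |r| = 1.

# The simulator

`simulate_study()` generates the population structure the analysis
assumes:

* **Males**: BC1F5 backcross introgression lines — per-site i.i.d.
  mosaics of one recurrent-parent haplotype and one of 11 donor
  haplotypes (donor probability 0.25), nearly homozygous with residual
  heterozygosity 1/2^5 at segregating donor-origin sites.  Sites are
  exchangeable (no genetic map): the analysis consumes only genome-wide
  relationship summaries, which do not depend on linkage.
* **Females**: a small tester panel descending along a random genealogy
  (each line branches off a previously generated one at 5% per-site
  mutation).  The genealogy matters: a star phylogeny (i.i.d.
  perturbations of one founder) leaves no differential relatedness after
  GRM centering, which would make the female side of T0 prediction pure
  noise; real tester panels are nested.  The female-pool founder differs
  from the recurrent parent at 15% of sites, which places female-male
  SDAF in the 0.20-0.28 window reported for elite two-pool rice
  germplasm.
* **Crossing design**: an unbalanced incomplete factorial.  The default
  reproduces the study histogram of females per male (85/108/124/60/5
  males crossed to 1-5 females; 938 tested hybrids from 6 females by 382
  males); note that this histogram is the self-consistent reading of the
  published design, whose "137 males" headcount cannot produce 938
  crosses of 6 females.  The generator enforces no male crossed to every
  female and pairwise female overlap, and exposes all counts as free
  parameters (the published "10,716 possible hybrids" likewise
  disagrees with 13 x 564 = 7,332, so no single count is hard-coded).
* **Phenotypes**: drawn from the GCA + SCA model with marker-driven
  covariances (`sigma2_F G_F`, `sigma2_M G_M`,
  `sigma2_FM G_F (x) G_M`), independent environment, block, F-by-E,
  M-by-E and plot-error effects, one plot per block per environment with
  5% dropout, and single-environment traits recorded in environment 1
  only.  Inbred parents (males directly, CMS females via maintainer
  lines, the TGMS female itself) and six checks are phenotyped too;
  hybrids receive a configurable mean shift so MPH is tunable.  A
  parent's inbred genetic value is twice its GCA — the GCA being the
  effect transmitted to progeny — and check values are independent draws
  on the total-GCA scale.

**Conditional sampling.**  Genetic-effect vectors are MVN draws rescaled
to their configured variance exactly, and environment/block effects are
centered across their realized levels (environments also rescaled).
Both choices trade a little unconditional realism for interpretability:
with six females, the chi-square magnitude noise of an unconditional
draw has one or two effective degrees of freedom, so "the simulated
sigma2_F" would otherwise be a poorly defined quantity; and with two
environments, the unconditional environment-mean noise (sd about 9
g/plant for yield) would randomly shift the realized trial mean that
heterosis percentages are ratios against.  Directions of all draws
remain MVN, so relatedness-driven prediction behavior is unchanged.  The
scaled kernels used for generation are stored on the study object and
should be the ones passed to downstream fits of simulated data.

**Trait defaults** mirror a two-environment yield trial: means 85 cm
(height), 14 (tillers), 226 mm (panicle length), 0.757 (proportion of
spikelets filled), 36 and 54 g/plant (yield, potential yield), with
variance ratios chosen so entry-mean heritabilities span roughly
0.3-0.9 and the last two traits observed in one environment only.
These are plausibility choices, not a reproduction of any dataset.

**What the simulator does not emulate** — and hence what passing tests
do not establish about real data: linkage and recombination maps,
selection during line development, any QTL architecture beyond the
infinitesimal GCA/SCA model, epistasis, dominance-by-distance
relationships (simulated SDAF and MPH are structurally independent, so
their correlation in any one simulated study is a finite-sample
artifact of female-level confounding — itself a caution the real
analysis needs), genotyping error, and spatial field trend.

# Problem sizes

The test suite and the acceptance script run the pipeline at desk
scale, chosen as the largest sizes that keep the whole suite
comfortably interactive: a 6-female x 140-male study with 700 tested
hybrids (the feasible maximum under the no-complete-crossing
constraint), 2,000 markers, 20 simulation seeds for parameter recovery,
50 replicates per cross-validation contrast, and 200 datasets for the
null calibration of the correlation test.  The simulator's population
defaults (13 females, 564 males, 938 tested hybrids) remain those of
the full-scale design.

# Known limitations

* The environment component with two levels is at best weakly estimable;
  it frequently lands on the boundary and its share of variance is then
  absorbed by interactions and error.  This mirrors the design being
  emulated rather than a defect of the engine, but single-trial users
  should treat `sigma2_E` as a nuisance, not an estimate.
* Reliability-based accuracies assume the variance component in the
  denominator is well estimated; with six females,
  `phenotypic_selection_accuracy(fit, "F")` inherits the full
  uncertainty of `sigma2_F`.
* `impute_naive()` is a per-site mean/mode imputer, adequate for
  relationship matrices at the missingness levels of filtered panels; it
  is not a substitute for haplotype-aware imputation if downstream uses
  need individual genotype calls.
* No multi-trait, dominance-kernel, or spatial extensions; the SCA
  kernel is the only non-additive term.
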