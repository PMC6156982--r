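---
title: "Models, calibration and design choices in gxmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, calibration and design choices in gxmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxmeth)
```

`gxmeth` couples a synthetic-data generator for family-based
SNP-by-methylation interaction studies with the analysis pipeline such
studies use. This vignette is the package's account of the science: what
is simulated and why, how the generator is calibrated, which estimators
are implemented and the numerical choices inside them, and what the
package's tests do and do not establish about real data.

## 1. The generating model

A study consists of a fixed pedigree of nuclear families (two founders
plus 1–4 children, 680 individuals by default), fixed genotypes drawn once
(Hardy–Weinberg founders at each SNP's minor allele frequency, Mendelian
gamete transmission to offspring, unlinked loci), and per-replicate draws
of methylation and phenotypes. Keeping genotypes fixed across replicates
mirrors the design of treatment-response studies in which genotypes are
measured once while the phenotype simulation is replicated, and it makes
per-locus summaries meaningful as properties of one realized design.

Methylation β-values are marginally Beta distributed (default mean 0.6,
concentration 10) at two visits coupled by a Gaussian copula with
correlation ρ = 0.9, so both visits keep exact Beta marginals in [0, 1].
At the five treatment-responsive CpGs the visit-4 mean is shifted by −0.05
(drug-induced demethylation).

With `Pre` and `Post` the averages of natural-log triglycerides at visits
1–2 and 3–4, the post-treatment trait is generated as

$$Post = \beta_0 + \sum_{k=1}^{5}\big[\beta_{1k}\,SNP_k +
\beta_{2k}\,(1-CpG_k) + \beta_{3k}\,SNP_k(1-CpG_k)\big] +
\sum_{j=1}^{100}\beta_j\,SNP_j + \beta_C C + \gamma\,Pre + g +
\varepsilon$$

where $C$ collects age, age², sex; $g \sim MVN(0,\,2\Phi\sigma^2_{poly})$
with $\Phi$ the recursive-kinship matrix; and methylation enters as
$1-CpG$ because lower methylation implies higher expression of the
modified gene. Visit-level log-TG values add independent measurement noise
around the latent `Pre`/`Post` values and are exponentiated, so TG is
strictly positive and `Post` as *observed* (the log-mean of TG3/TG4)
carries half of the per-visit noise variance — the calibration accounts
for this explicitly.

The CpG β-value entering the generating model (and, by default, models
1a/1b at analysis time) is the **visit-4** value: the post-treatment trait
responds to the post-treatment methylation state. This is a documented
choice (`cpg_visit` in `effect_config()`); visit 2 is available.

## 2. Calibration

The generator is parameterized by recoverable targets, not raw
coefficients. Working on the scale of the covariate-adjusted phenotypic
variance $V_{adj}$ (default 0.25, i.e. an SD of 0.5 on the log-TG scale):

* **Pre–Post coupling.** `Pre` has variance $V_{adj}$ and enters with
  $\gamma = 0.7$, so $corr(Pre, Post_{adj}) \approx 0.7$ and the `Pre`
  pathway contributes $\gamma^2 V_{adj} = 0.49\,V_{adj}$. The remaining
  $0.51\,V_{adj} \equiv V_{b2}$ is the denominator scale of per-SNP b²
  values (which are computed after adjusting for `Pre` as well).
* **Per-locus contributions.** The five causal loci target b² values of
  0.0210, 0.0008, 0.0070, 0.0004, 0.0090 — the profile of one strong, two
  moderate and two near-null loci. Each background SNP contributes 0.1% of
  $V_{b2}$ through a main effect only.
* **Effect routing.** A causal SNP's marginal standardized effect
  $\alpha_k$ is split between main effect and interaction by
  `interaction_share` (default 0.8): $\beta_{3k} =
  0.8\,\alpha_k/\overline{m}_k$ with $\overline{m}_k = E[1-CpG_k]$, and
  $\beta_{1k} = 0.2\,\alpha_k$. The causal sites are thus predominantly
  interaction-driven, consistent with reduced (interaction-only) models
  retaining substantial power at such sites. Each causal CpG main effect
  contributes 0.2% of $V_{b2}$.
* **Heritability.** $\sigma^2_{poly}$ is solved so that (polygenic + SNP
  additive) variance equals $0.43\,V_{adj}$. Under unlinked loci the SNP
  additive covariance between relatives is exactly $2\Phi$-structured, so
  a kinship REML fit attributes it to the genetic component; the
  interaction residual $SNP\cdot((1-CpG)-\overline{m})$ and the CpG main
  effects are uncorrelated between relatives and land on the environmental
  side. The residual $\varepsilon$ absorbs whatever variance remains, half
  of the per-visit noise reaching `Post` included; the configuration
  errors out if the budget is infeasible.

Two finite-sample corrections make the targets *estimator* targets rather
than population ones:

1. **b² estimator bias.** The squared correlation estimator satisfies
   $E[\hat r^2] \approx \rho^2 + tr(R_x R_y)/n^2$ under family clustering,
   where $R_x = 2\Phi$ is the dosage correlation among relatives and $R_y$
   the residual correlation. With the default pedigree this is ≈ 0.0023 —
   half again as large as the naive $1/n$ — and the true per-locus
   contributions are deflated accordingly (floored at 10% of the target so
   every causal locus keeps a real effect).
2. **Realized-design moments.** Because genotypes are fixed, each locus's
   realized dosage variance and its chance correlations with the other 104
   effect-carrying loci and with the fixed covariates shift its marginal
   slope by a study-specific constant (up to ±10%). `effect_config()`
   therefore solves the five marginal-moment equations in the realized
   covariate-projected dosage cross-products, so that each causal locus's
   implied marginal effect hits its target on the design actually drawn.
   Both corrections use only design quantities (genotypes, pedigree,
   covariates), never outcomes.

## 3. Derived traits and interaction designs

`derive_traits()` computes `Pre`, `Post`, their difference, and per-CpG
visit-4 − visit-2 differences (natural logs throughout; the log base only
rescales coefficients, not test statistics). `build_design()` lays out the
four parameterizations: the generating model **1a**
(`Post ~ SNP + (1−CpG) + SNP·(1−CpG) + age + age² + sex + Pre`), the
reduced **1b** (interaction only), and the change-on-change models **2a** /
**2b** (`ΔTG ~ … SNP·ΔCpG …`, covariates age, age², sex without `Pre`).
Age² is uncentred; sex is coded 0 = female / 1 = male. Column counts
(8/6/7/5 with intercept) and the exact product structure of the
interaction column are enforced by tests.

## 4. Association methods

**Method I** is least squares with the family identifier as a categorical
term. Inside a least-squares procedure a "family effect" is operationally
a fixed absorption of family means, and that is what is implemented; the
genuinely random-effects treatment is Method II, and both are present so
the distinction is testable. The interaction p-value is the two-sided t
test on the interaction coefficient with residual degrees of freedom.

**Method II** is a linear mixed model with a per-family random intercept
estimated by REML (via `lme4`), Wald test on the interaction coefficient.
The normal reference is the default; with ~150 families a residual-df t
reference is practically identical and is available (`df_method =
"wald_t"`). A kinship-covariance variant (`fit_mixed(..., kinship = )`)
replaces the family intercept with the full $2\Phi\sigma^2_g$ structure,
reusing the heritability module's REML machinery.

Degenerate inputs are a first-class outcome: a monomorphic SNP or constant
methylation regressor yields an `applicable = FALSE` result with an `NA`
p-value — *untestable* is never conflated with *null* (p = 1), and batch
summaries count the two separately. Any other rank deficiency is a hard
error naming the collinear columns; the batch runner converts such
edge-case failures (e.g. a single-carrier SNP whose interaction column is
proportional to its dosage) into not-applicable rows rather than aborting
a replicate sweep.

`sandwich_se()` recomputes interaction p-values under family-clustered
sandwich covariance. It is deliberately non-default: with low minor allele
counts the cluster-robust variance is itself poorly estimated and the test
becomes anticonservative, a behaviour the test suite checks directionally
(MAC < 20 inflates Type-I error relative to model-based errors).

## 5. Empirical null and evaluation

Chromosomes 21–22 carry effect-free SNPs and CpGs. The pairing rule —
process SNPs in ascending position, pair each with the nearest CpG at a
strictly higher base-pair position, never reuse a CpG — is one
deterministic formalization of "an adjacent CpG downstream of the SNP";
it reproduces the qualitative property that far fewer pairs form than
there are SNPs, and an exhaustive brute-force oracle verifies it in the
tests. The minor-allele-count filter is strict (`MAC > 50`), computed over
all simulated individuals. `summarize_replicates()` reports, per category
× model × method, the number of applicable tests and the proportion with
p strictly below α (default 0.05, two reported decimals by default). No
multiple-testing correction is applied anywhere: the pipeline evaluates
nominal-α operating characteristics.

## 6. Heritability and b²

`polygenic_h2()` fits $y = X\beta + g + \varepsilon$,
$cov(g) = 2\Phi\sigma^2_g$, by REML: one eigendecomposition of $2\Phi$
rotates the model to independent observations, total variance is profiled
out in closed form, and the restricted likelihood is maximized over
$h^2 \in [0,1]$ by golden-section search (`stats::optimize`, tolerance
1e-8) with explicit endpoint comparison; boundary estimates are flagged,
not errors. Covariates for the polygenic model are age, age², sex — `Pre`
is deliberately excluded, so the `Pre` pathway counts as environmental
variance; this is the documented reading of "heritability of Post
itself". `snp_b2()` residualizes the response on covariates (here
including `Pre`), z-scores residuals and dosage with the n−1 convention,
and squares the standardized slope — algebraically the squared Pearson
correlation, which the tests assert exactly.

## 7. Trees and forests

The regression tree and random forest are built on an in-package CART
engine (C++): variance-reduction splits, every leaf at least `min_leaf`
observations (10 for the Method III tree, 5 — the regression convention —
for forest trees), deterministic tie-breaks (lowest feature index, then
lowest threshold). Importance is summed split-wise impurity (SS)
reduction per feature, max-normalized, with ranks broken by descending
score then predictor name. The engine exists in-package because the
analyses need three things together that off-the-shelf fits do not expose:
exact leaf-size control, re-evaluation of a fitted tree's splits on a
held-out partition (the "validation importance" column of combined-
replicate analyses), and a forest whose single-tree, no-bootstrap,
all-features configuration degenerates *exactly* to the tree fit. An
independent implementation (`ranger`) serves as a cross-check in the test
suite, never as the implementation.

Forests use bootstrap sampling and per-split feature subsampling with
`mtry = ⌈P/3⌉`. On generator output the canonical feature set is `Pre`,
age, sex, the 5 causal SNPs and CpGs, and the 100 background SNPs — 113
predictors. The combined-replicates tree partition is a seeded 40/30/30
training/validation/test split by individual. Expected qualitative
behaviour, asserted by the acceptance tests: `Pre` ranks first in every
default-configuration replicate, and causal CpGs outrank the SNPs they
modify (the CpG term carries more of the interaction variance because
$SNP\cdot(1-CpG)$ co-varies more smoothly with the CpG than with the
discrete dosage).

## 8. Problem sizes and what the tests show

The test suite exercises the full study scale where the claim depends on
it (Type-I calibration: 100 null pairs × 20 replicates of n = 680, i.e.
2,000 tests per method; heritability: 50 replicates; b²: 200 replicates;
forests: 200 trees per replicate) and reduced sizes elsewhere (forests of
tens to hundreds of trees, simulation grids of a few hundred fits) — sizes
chosen so each check has the statistical resolution it needs. Monte-Carlo
oracles use 100,000 gene drops (kinship) and dense grids (REML).

Passing tests establish calibration and recovery *under the generator's
assumptions*: unlinked loci, no LD between SNPs or between SNPs and their
paired CpGs (pairing is positional, not mechanistic — no mQTL effects), no
missing data, no X chromosome, Beta-copula methylation, a non-heritable
`Pre`, and Gaussian residuals. Real cohorts violate several of these
(notably LD, methylation batch structure, and heritable baselines), so
power numbers transfer only qualitatively.

A note on one test's formulation: for a trait simulated with
$\sigma^2_g = 0$, REML estimates pile up on the boundary and the replicate
mean of $\hat h^2$ is strictly positive with a small SE, so "mean within
k·SE of zero" is not a coherent null check; the suite instead asserts that
the mean is small and that a majority of estimates sit at the boundary.

## 9. Known limitations

* Method II models a family random intercept (or full kinship), not a
  repeated-measures residual covariance across visits; visit-level noise
  is absorbed into the trait averages.
* The empirical-null pairing rule is one formalization; alternatives
  (distance caps, many-to-one pairing) would change the pair count, though
  a configurable distance cap is provided.
* Exact power values at the causal sites depend on effect sizes that are
  calibration choices here, and are not comparable digit-for-digit with
  any particular real study; the recoverable quantities (heritability,
  b² profile, null calibration, importance orderings) are.
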