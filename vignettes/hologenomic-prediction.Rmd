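---
title: "Hologenomic prediction of pig traits: models, kernels and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hologenomic prediction of pig traits: models, kernels and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Feed and digestive efficiency in growing pigs are shaped both by the
host genome and by the gut microbiota, and the microbiota is in turn
shaped by diet and by the shared breeding environment (batch).
`holopred` implements the full analysis chain for asking how much each
information source contributes to phenotype prediction: covariance
kernels built from SNP genotypes and from 16S OTU count tables,
Bayesian linear mixed models combining them, and a diet-stratified
forward cross-validation design with a post-hoc analysis of the design
factors. Because the motivating data (a purebred Large White
population of full-sib pairs split across a conventional and a
high-fiber diet) are not public, the package ships a first-class
synthetic-data generator reproducing that design, and every claim the
package makes is exercised against simulation truth.

## The model

For a trait vector $\mathbf{y}$ on $n$ animals the full model is

$$\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{u} + \mathbf{m} + \mathbf{e},
\qquad
\mathbf{u} \sim N(\mathbf{0}, \mathbf{G}\sigma_u^2),\quad
\mathbf{m} \sim N(\mathbf{0}, \mathbf{M}\sigma_m^2),\quad
\mathbf{e} \sim N(\mathbf{0}, \mathbf{I}\sigma_e^2),$$

with the incidence matrices of the random terms equal to identity
because every fitted animal has genomic and microbiota records. Model
*Gen* drops $\mathbf{m}$, model *Micro* drops $\mathbf{u}$, and model
*Micro+Gen* keeps both with the covariance between $\mathbf{u}$ and
$\mathbf{m}$ fixed at zero. Heritability and microbiability are
$h^2 = \sigma_u^2 / (\sigma_u^2+\sigma_m^2+\sigma_e^2)$ and
$m^2 = \sigma_m^2 / (\sigma_u^2+\sigma_m^2+\sigma_e^2)$.

### Kernels

* **M matrix** (`build_m_matrix()`): counts are transformed as
  $\log(c+1)$ (ones added so zero counts stay defined), each OTU
  column is centered and scaled to unit sample standard deviation
  ($n-1$ denominator), and $\mathbf{M} = \mathbf{S}\mathbf{S}^T/n$
  with $n$ the number of OTUs actually used. The mean diagonal is
  $(p-1)/p$ by construction. Before this, `filter_otus()` retains
  OTUs present in strictly more than 5 samples with mean relative
  abundance strictly above 0.001% — both thresholds read literally
  and exposed as arguments. Zero-variance columns (possible on small
  synthetic tables, never informative) are dropped with a warning and
  excluded from $n$.
* **G matrix** (`build_g_matrix()`): VanRaden method 1,
  $\mathbf{G} = \mathbf{Z}\mathbf{Z}^T / (2\sum_k p_k(1-p_k))$ with
  columns centered at twice the observed allele frequency.
  `qc_genotypes()` first applies the conventional chip QC: individual
  and SNP call rates strictly above 95%, minor allele frequency
  removal strictly below 5% (the 0.05 boundary is retained), a
  1-df goodness-of-fit Hardy–Weinberg chi-square at $P < 10^{-6}$,
  and removal of sex-chromosome or unmapped SNPs; residual missing
  dosages are imputed to $2\hat p$, the value compatible with the
  VanRaden centering.

### Priors and sampler

Variance components get scaled-inverse chi-square priors with
$\nu_0 = 5$ degrees of freedom and scale tied to the sample phenotype
variance: each random term receives the share $R^2/K$ of
$\mathrm{var}(y)$ (default $R^2 = 0.5$ split over the $K$ random
terms) so that the prior mode sits at that share, and the residual
receives $1 - R^2$. Fixed effects get a $N(0, 10^{10})$ prior,
effectively flat.

`fit_gibbs()` samples $\boldsymbol\beta$ jointly from its Gaussian
full conditional; each random vector is sampled in the eigenbasis of
its kernel, where the full-conditional precision
$\mathbf{I}/\sigma_e^2 + \mathbf{K}^{-1}/\sigma_k^2$ is diagonal, so
one $n \times n$ eigendecomposition per kernel is paid once per fit
and each sweep costs a handful of matrix–vector products. Eigenvalues
below $10^{-8}$ of the largest are floored at that threshold before
inversion — both M and G are rank-deficient at small $n$, and the
floor makes the quadratic forms $\mathbf{u}^T\mathbf{K}^{-1}\mathbf{u}$
finite without changing the data-informed directions. Each variance is
then drawn from its scaled-inverse chi-square full conditional with
$\nu_0 + n$ degrees of freedom. Default chain settings are 60,000
iterations, 10,000 burn-in, thinning 10; the tests and the acceptance
experiments use 1,500–20,000 iterations, which the convergence checks
(effective sample sizes, agreement with closed forms) show is ample at
the problem sizes used there.

Two independent checks pin the sampler down. With variance sampling
disabled, its posterior mean of $\mathbf{u}$ matches the closed-form
mixed-model-equation solution
$(\mathbf{I} + \mathbf{G}^{-1}\sigma_e^2/\sigma_u^2)^{-1}(\mathbf{y} -
\mathbf{X}\hat{\boldsymbol\beta})$ to a correlation above 0.999.
With variances sampled, its posterior mean of $h^2$ on null data
matches a two-dimensional grid integration of the exact marginal
posterior. That oracle also settles a point worth documenting: under
this prior ($\nu_0 = 5$, $R^2 = 0.5$) the posterior mean of $h^2$ on
pure-noise data at $n \approx 300$ is about 0.26, not near zero — the
prior keeps substantial mass away from the origin and the sib-family
kernel only partly overcomes it. Shrinkage to very small $h^2$ on null
data should not be expected at these sample sizes.

### Prediction and validation animals

Training animals are predicted by their posterior mean effects
(EBV for $\mathbf{u}$, EMV for $\mathbf{m}$, or their sum).
Validation animals are predicted by the kernel projection
$\mathbf{K}_{vt}\mathbf{K}_{tt}^{-1}\hat{\mathbf{u}}_t$ using the
floored spectral inverse — the standard kernel-regression extension.
The alternative, a joint fit in which validation phenotypes are
treated as missing and imputed each Gibbs sweep, is available through
`fit_gibbs(mask = ...)` and `run_cv(predict_method = "joint")`; the two
routes agree on test fixtures.

Phenotypes are adjusted for fixed effects once per (trait, model,
adjustment variant) from a full-dataset fit, $y^* = y -
\mathbf{X}\hat{\boldsymbol\beta}$, and accuracy is the Pearson
correlation between $y^*$ and the prediction over validation animals.
Computing $y^*$ on the whole dataset leaks information relative to a
strict hold-out; it is kept deliberately as a faithfulness choice, as
is fitting one $y^*$ per model.

### Cross-validation design

Five diet scenarios (CO→CO, HF→HF, CO→HF, HF→CO, and the combined
scenario with equal diet proportions on both sides), four folds of 310
reference and 45 validation animals, and two connectivity modes. The
design is forward in batch time: reference animals come from the first
three quarters of the chronological batches. *Connected* validation
animals are drawn from batches no earlier than the midpoint of the
reference window, so batches — and, because paternal families occupy
adjacent batches, sires — overlap; *unconnected* validation animals
come only from strictly later, disjoint batches. The time rule itself
is a design choice (the forward label does not pin one down); it is
what `make_folds()` implements and `validate_folds()` audits. Folds
are random within these pools and deliberately overlap across
samplings; `fold_overlap()` reports the shared-animal percentages.
Undefined correlations (zero-variance predictions on degenerate
draws) are recorded as NA and excluded from fold averages, never
imputed as zero.

### Post-hoc analysis

`anova_accuracy()` regresses per-fold accuracy on the five design
main effects (scenario, SBE connectivity, trait family, model,
adjustment variant) with Type-II sums of squares — the default of the
`car::Anova()` route — giving residual df 1670 on the full
$5\times2\times2\times3\times7\times4$ grid. `welch_pairwise()` runs
unequal-variance t tests with Satterthwaite df per pair and a
Bonferroni correction capped at 1, and reduces exactly to
`pairwise.t.test(pool.sd = FALSE)`. Accuracies are banded low
($< 0.40$), moderate ($0.40$–$0.60$, both ends inclusive) and high
($> 0.60$).

## The synthetic-data generator

`sim_config()` defaults are the study-scale design: 171 sires × 3
full-sib pairs (1026 animals), each pair from its own dam and split
CO/HF, 32 contiguous batches with paternal families in adjacent
batches, OTU tables rarefied to 10,000 counts per sample, and traits
generated under the mixed model above.

* **Genotypes**: founder allele frequencies uniform on [0.05, 0.5],
  unlinked loci, fair Mendelian gamete sampling. This reproduces the
  relationship structure that matters for G (full sibs ≈ 0.5, half
  sibs ≈ 0.25, unrelated ≈ 0) without linkage disequilibrium; LD,
  genetic maps and selection are out of scope.
* **OTU table**: per-OTU log-normal base abundances (sd 1.5), a diet
  shift for 20% of OTUs (sd 1 by default), per-batch shifts (sd 0.5)
  and animal-level noise (sd 0.6), pushed through a softmax and
  multinomial sampling at the rarefaction depth. This is a minimal
  model producing overdispersed rarefied counts with environmental
  structure; it has no phylogeny, no true zero-inflation beyond
  sampling zeros, and no compositional interactions, so passing tests
  say nothing about those features of real 16S data.
* **Phenotypes**: $u$, $m$, $e$ drawn from the configured kernels and
  variance fractions; fixed effects are a diet contrast (0.5 trait
  SD), batch effects (sd 0.3) and one standardized covariate per
  trait family (0.3 per SD), mirroring the adjustment sets: daily
  feed intake for the digestibility coefficients, end-of-post-weaning
  weight for ADG and FCR, end-of-test weight for DFI and RFI.
  Covariates are independent normals; no growth-curve model is
  attempted. Because the digestibility traits are adjusted for DFI,
  the generator produces DFI first and uses the simulated values as
  their covariate. An optional host-genetic effect on a fraction of
  OTUs (`geno_on_otu_frac`) is off by default.
* **Traits**: RFI is derived by one joint OLS regression of DFI on
  ADG, lean meat percentage, carcass yield and average metabolic body
  weight across both diets. The metabolic exponent is not fixed by
  convention in this literature; 0.60 is the default and it is an
  argument.

Realized variance fractions track the configured ones to within ±0.05
over 50 replicate draws, and every stage is bit-reproducible from the
run seed (each stage derives its own stream, so any stage can be
replayed in isolation).

## Problem sizes and numerical choices in the experiments

The experiment functions (`experiment_*`) define the package's
evaluation battery and are what `scripts/acceptance.R` and the
acceptance tests run:

* sampler-vs-closed-form at $n = 100$, 20,000 draws;
* variance recovery at truth (0.3, 0.4, 0.3) on 498 animals
  (83 sires × 3 pairs), 300 OTUs, 2000 SNPs, 10 replicates with
  6,000-iteration chains;
* the Micro-vs-Gen contrast on one population carrying a
  microbiota-driven trait ($m^2 = 0.5$, $h^2 = 0.05$) and a
  genetics-driven trait ($h^2 = 0.35$, $m^2 = 0.05$), combined-diet
  scenario, 310/45 folds;
* the SBE contrast on 10 replicate simulations.

The SBE experiment deserves its rationale spelled out. In this
generative model the microbiota value is a linear functional of the
animal's *measured* OTU profile, so once the validation animal's
microbiota is observed, most of its microbiota value transfers through
the kernel projection regardless of batch overlap. Environmental
connectivity adds predictive value through phenotype batch effects
that a batch-structured M kernel can absorb — a mechanism that only
operates when phenotypes are not corrected for batch. The experiment
therefore instantiates the strong shared-breeding-environment world it
is meant to probe: per-OTU batch shifts on the scale of the base
abundance spread (sd 1.5), phenotype batch effects of 0.7 trait SD,
and the base adjustment variant (no batch correction in $y^*$). The
generator defaults are untouched; this configuration belongs to the
experiment, and the direction of the contrast — connected above
unconnected — is the claim under test.

## Known limitations

* The sampler stores dense kernels and one eigendecomposition per
  kernel; it is comfortable to a few thousand animals, not beyond.
* Posterior variance components at $n \le 500$ carry wide intervals;
  single-replicate recovery can miss by more than 0.1, which is why
  the recovery experiments average replicates.
* No covariance between genetic and microbiota effects is modelled
  (fixed at zero), no REML alternative is provided, and
  variable-selection priors are out of scope.
* The OTU filter operates on the rarefied table; on these tables the
  before/after-rarefaction distinction for the abundance threshold
  vanishes, but the flag order matters if unrarefied tables are fed
  in.
* The preliminary screen that selected the real study's fixed-effect
  sets is not reproducible; the per-trait adjustment sets in
  `fem_adjustment_sets()` are taken as given.
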