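---
title: "Multi-trait genomic selection with Smith optimum indices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait genomic selection with Smith optimum indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the tunable parameters that matter, what the synthetic-data generator does
and does not emulate, and the numerical and design choices that were
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The analysis pipeline

The package implements a two-step genomic selection-index analysis for a
plant breeding panel evaluated in augmented multi-environment trials:

1. **Phenotypes.** Plot measurements are converted to traits
   (DMC% = dry/wet × 100; DMY t ha⁻¹ = 10 · plot wet weight (kg) · dry
   fraction / plot area (m²); PH is measured directly). Within each trial,
   Federer adjusted means remove additive block effects estimated from the
   replicated checks; across trials, a two-way model
   $y_{ik} = \mu + G_i + E_k + (GE+\varepsilon)_{ik}$ with fixed
   environment effects yields one value per genotype and trait.
2. **Genomic model.** A multi-trait GBLUP is fitted by Gibbs sampling
   (Section 3), giving posterior-mean genetic ($\Sigma_g$) and residual
   ($\Sigma_e$) trait covariances and GEBVs for every genotype in the
   kinship matrix, phenotyped or not.
3. **Index.** The Smith optimum index is built from
   $(\Sigma_g, \Sigma_g + \Sigma_e)$ and an economic-weight vector, and
   its three statistics — index heritability, genetic correlation with the
   net merit, accuracy — summarize expected selection performance.
4. **Validation.** Repeated 70/30 hold-out validation and named
   train→test trial scenarios (seed year → ratoon regrowth years).

## 2. Marker quality control and the relationship matrix

Variants are read from VCF (via `vcfR`) and filtered in the order
biallelic → site quality → missingness → minor allele frequency, each
threshold inclusive, with per-step removal counts logged. MAF is computed
over non-missing calls — the only defensible denominator before
imputation. Missing calls are then replaced by the per-marker mean dosage,
and the relationship matrix is the centered cross-product
$G = WW'/\sum_j 2p_j(1-p_j)$ (VanRaden method 1) with allele frequencies
estimated from the data.

**Kinship normalization.** For panels of inbred lines the raw VanRaden
diagonal approaches 2, and genetic variance components estimated against
such a matrix live on half the phenotypic scale, which makes the usual
per-trait heritability $h^2_j = \Sigma_{g,jj}/(\Sigma_{g,jj} +
\Sigma_{e,jj})$ uninterpretable. `compute_grm()` therefore rescales to
unit mean diagonal by default (`normalize = FALSE` recovers the raw
matrix, for which the cross-product trace identity is tested). If the
smallest eigenvalue is negative, a diagonal jitter of
$10^{-6}\cdot\overline{\mathrm{diag}}$ is added once.

## 3. The multi-trait Bayesian model

`mtgblup()` fits
$$y_{ij} = \mu_j + g_{ij} + e_{ij}, \qquad
  \mathrm{vec}(g) \sim N(0, \Sigma_g \otimes K), \qquad
  e_{i\cdot} \sim N(0, \Sigma_e),$$
with intercept-only fixed effects: environments are already absorbed in
the phenotype stage, which is the point of the two-step design.

**Sampling scheme.** $K = U\,\mathrm{diag}(d)\,U'$ is eigendecomposed
once; eigenvalues below $10^{-8}$ of the largest are dropped and the
genetic values are sampled in the retained subspace (their conditional
distribution has no mass outside it). Within each cycle, a simultaneous
diagonalization of the current $\Sigma_e = TT'$ and
$\Sigma_g = T\,\mathrm{diag}(\lambda)\,T'$ reduces the conditional of the
$n \times t$ genetic-value matrix to independent scalar updates with
weights $d_i\lambda_k/(1 + d_i\lambda_k)$, so a full cycle is a handful of
dense matrix products — no per-individual solves. Update order: genetic
values, intercepts (flat prior), missing phenotype entries, $\Sigma_g$,
$\Sigma_e$.

**Missing data.** Masked entries are redrawn each cycle from their
conditional normal given the observed traits of the same individual
(grouped by missingness pattern). This is what lets a fully unphenotyped
test set receive GEBVs through $K$, and it is exactly how the hold-out
validation masks test genotypes — all traits at once, mirroring selection
candidates that were never phenotyped.

**Priors.** Both covariances carry inverse-Wishart priors, by default
$\nu = t + 2$ and scale $0.5\,\mathrm{diag}(\widehat{\mathrm{var}}(Y))$,
so the prior splits the phenotypic variance evenly and properly. Two
consequences worth knowing:

* an IW prior at this scale soft-floors each residual variance near
  $S_{jj}/\nu \approx 0.1\,\mathrm{var}(y_j)$ — in a noiseless-data limit
  the estimated $h^2$ saturates around 0.9 unless the residual prior
  scale is driven to zero as well (the `prior_scale_e` argument);
* in the exact noiseless limit the data augmentation couples masked
  phenotypes one-to-one with their genetic values and the chain loses its
  kinship anchor for unobserved rows, so empirical test-set correlations
  are meaningless there. Both behaviours are exercised in the tests.

**Chain lengths.** Production analyses should use long chains
(35,000 cycles, 5,000 burn-in — the package default). The test suite and
the acceptance script use 2,000/500 (5,000/1,000 for parameter recovery),
which we found adequate for the structures tested: the sampler was
validated against brute-force numerical integration of the marginal
posterior on a small single-trait problem, against the closed-form GBLUP
solution at fixed variance components (r ≥ 0.99), and for invariance
under rotation to the eigenbasis. Effective sample sizes are reported
(`$ess`) but not gated on.

## 4. The Smith optimum index

With measured traits $x$ and selection targets $y$ (here the same three
traits, but the `cov_set` container keeps $G_x$, $G_y$, $G_{xy}$, $P_x$
separate so unequal sets remain expressible), the index
$I_i = \beta'x_i$ maximizing the correlation with the net genetic merit
$H_i = \alpha'g_{y,i}$ has
$$\hat\beta = P_x^{-1}G_{xy}\,\alpha,$$
computed as a linear solve, never an explicit inverse. The statistics:
$$h_I^2 = \frac{\beta'G_x\beta}{\beta'P_x\beta}, \qquad
  \mathrm{gencor} = \frac{\beta'G_{xy}\alpha}
  {\sqrt{(\alpha'G_y\alpha)(\beta'G_x\beta)}}, \qquad
  \mathrm{acc} = \mathrm{gencor}\cdot h_I.$$
The gencor denominator is the only reading that yields a quantity bounded
by 1 and consistent with the classical index literature; it is asserted to
$10^{-10}$ together with the identity $acc = \mathrm{gencor}\sqrt{h_I^2}$
on every index the package ever constructs.

**Economic weights.** Two conventions circulate: unit weights on raw
trait scales, and equal weights per phenotypic standard deviation
($1/\sigma_P$). The package's default is `inverse_phenotypic_sd`, which
equals unit weights on traits standardized to unit phenotypic SD — the
reading that reconciles both conventions; raw-scale unit weights and
custom vectors are available. Single-trait prediction targets are
expressed inside the same machinery as unit target vectors
($\alpha = e_j$), for which all three statistics are invariant to the
scale of $\alpha$.

## 5. Cross-validation and scenario design

`run_holdout()` re-fits the model for every random 70/30 split (masking
test genotypes entirely) and reports, per prediction target (three
single-trait targets and the three-trait GSI):

* the **formula statistics** $h_I^2$, gencor, acc from the training-fit
  covariances — the headline columns; and
* the **empirical predictive correlation** between the index evaluated on
  test-set GEBVs and the observed phenotypic index, as `pred_accuracy`.

Both are reported because they answer different questions: the formula
statistics describe the index the training data implies; the empirical
correlation measures realized genomic prediction transfer. Splits can be
stratified by subpopulation, per-repeat seeds are derived deterministically
from the master seed, individual repeat failures are tolerated up to 10 %,
and variance components are re-estimated in every repeat (the conservative
reading of estimating parameters in the training set).

`run_scenario()` trains on the combination of named training trials only
and validates against each test trial separately. Because test-trial
values never enter the fit, the training-fit formula statistics cannot
vary across test years; the year-specific quantity is the empirical
predictive correlation against each test trial's adjusted means. For the
seed→regrowth design this is the column in which trait-specific carryover
decay is visible.

A structural note on composite targets: the optimum index for a
single-trait target maximizes that target's accuracy over all coefficient
vectors, so whenever one trait's genetic carryover is high while the
others' decay, the multi-trait GSI — whose target mixes the decayed
traits — cannot out-predict the stable trait's own index in the decayed
year. Under this package's carryover defaults the year-2 GSI accuracy
therefore sits between the decayed and the stable single-trait
accuracies; field studies that report the opposite pattern are reporting
covariance estimates from data this generator's truth does not produce.

## 6. The synthetic panel generator

`sim_config()` encodes the study conditions; defaults were chosen once,
as follows, and are not data-dependent:

* **Panel**: 180 + 189 fully inbred lines in two subpopulations ("SB",
  "SH"), arranged in biparental families (30 × 6 and 27 × 7); founder
  allele frequencies uniform on [0.05, 0.5] with Balding–Nichols
  subpopulation divergence F = 0.05. Marginal genotype frequencies stay
  at the founder law, but individuals are inbred and related within
  families — deliberately so: an unstructured Hardy–Weinberg panel gives
  hold-out accuracies of ~0.25–0.35 and essentially unidentifiable
  variance components, far from the 0.36–0.59 range a real structured
  panel supports. The SH subpopulation's genetic deviations are shrunk by
  $\sqrt{0.6}$ to emulate its narrower genetic base (one consequence,
  visible in the tests: a single-$\Sigma_g$ model attributes that
  heterogeneity to residual variance).
* **Traits**: DMY, PH, DMC with means (30 t/ha, 300 cm, 28 %) and
  phenotypic SDs (5, 40, 4) — typical biomass-sorghum scales — and
  combined-scale heritabilities 0.60/0.70/0.65 with genetic correlations
  0.60 (DMY–PH), 0.23 (DMY–DMC), −0.35 (PH–DMC). Residual correlations
  default to zero.
* **Trials**: three seed-year environments in augmented RCBD (6 checks ×
  6 blocks), environment shifts (−0.5, 0, +0.5) σ_P, block SD 0.3 of the
  plot residual SD. The plot residual variance is calibrated so that the
  across-environment mean of Federer-adjusted values realizes the
  configured heritabilities, *including* the variance the block-effect
  estimate adds back ($\sigma^2_{plot}/n_{checks}$). One seed trial is
  unscored for DMC, emulating a trait not recorded in one year — this is
  why DMC is the weakest prediction target on both metrics.
* **Regrowth**: two ratoon years with carryover correlations
  $g_{rg} = \rho\,g_{seed} + \sqrt{1-\rho^2}\,g_{new}$ per trait;
  defaults ρ = (0.95, 0.95) for DMY, (0.90, 0.50) for PH,
  (0.85, 0.55) for DMC — a stable-yield / decaying-height-and-moisture
  pattern.
* **Moment calibration** (`exact_moments = TRUE`): after drawing marker
  effects, genetic values are linearly recalibrated so their covariance
  in the kinship metric equals $\Sigma_g$ exactly; residual draws are
  variance-matched; regrowth innovations are orthogonalized so realized
  carryover equals ρ exactly. This makes "generating truth" well-defined
  for recovery tests, in the same spirit as the variance matching done by
  breeding simulators. Raw plot measurements are back-calculated so
  `derive_traits()` inverts them exactly (plot geometry 5 m × 0.75 m).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: linkage disequilibrium from recombination maps
(markers are exchangeable given the family structure), dominance and
epistasis, genotype-specific GE beyond an iid deviation absorbed into the
plot residual, selection over cycles, spatial field trends beyond additive
block effects, and call-rate or quality artifacts correlated with
genotype. Real GBS data also identifies variance components less cleanly
than the moment-calibrated truth here.

**Problem sizes.** The test suite fits most models on a 123-line panel
with 500 markers and short chains; the cross-validation and regrowth
checks use the full 369-line default panel with 2,000 markers, 20 repeats
and 2,000/500 chains; parameter recovery uses a homogeneous 400-line,
100-family, 1,000-marker panel with a 5,000/1,000 chain. These sizes were
chosen so the full suite completes in a few minutes while keeping every
scientific check at a scale where its expected behaviour is unambiguous.
With ~400 individuals and three traits the posterior SD of a genetic
correlation is ≈ 0.10 and of a heritability ≈ 0.05–0.08; recovery
tolerances of ±0.15 and ±0.10 are therefore checks at roughly 1.5
posterior SDs, and the 100-family layout was selected (over 25/50/200)
precisely because it minimizes that posterior SD.

## 7. Numerical choices and degenerate inputs

* Eigenvalues of $K$ below $10^{-8}$ of the maximum are truncated, not
  jittered, inside the sampler; `compute_grm()`'s jitter guarantees PSD
  on the way in.
* $P_x$ is never inverted; all index solves go through `solve()` on the
  PSD-validated matrix, and `cov_set()` rejects asymmetric or indefinite
  inputs, including $P_x - G_x$.
* $h_I^2$ and gencor violations beyond $10^{-10}$ of their ranges raise;
  smaller ones are clipped.
* Ties in candidate ranking break lexicographically by genotype ID.
* Variance components in `combine_trials()` come from an unbalanced
  one-way ANOVA method of moments, floored at zero; with a single
  observation per genotype the residual variance is undefined and
  unshrunken means are returned. The genomic stage consumes *unshrunken*
  environment-centered means: shrinking first and then fitting a model
  that shrinks again would compress the phenotypic variance the model is
  supposed to partition. (The shrunken predictor remains available via
  `combine_trials(shrink = TRUE)`.) A related wrinkle is inherited from
  the field's terminology: genotype effects are treated as random while
  the combined values are used like BLUEs; both outputs exist and the
  choice is documented rather than resolved.
* All stochastic components (generator, splits, chains) restore the
  caller's RNG state and derive per-component seeds from a single master
  seed, so every pipeline output is reproducible bit for bit.

## 8. Known limitations

* The Gibbs sampler is single-chain; convergence is summarized by ESS,
  not enforced. Thinning defaults to 1.
* No REML/EM alternative, pedigree kinships, marker-effect priors
  (BayesB-type), or explicit G×E covariance structures.
* The augmented-design adjustment assumes additive block effects
  estimated from checks; no spatial row–column modelling.
* Index machinery assumes the covariance estimates are the truth;
  uncertainty in $\Sigma_g$ propagates into the reported statistics only
  through the cross-validation replication, not analytically.
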