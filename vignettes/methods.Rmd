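---
title: "Integrated genomic and phenomic prediction of leaf cyanogenesis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated genomic and phenomic prediction of leaf cyanogenesis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cyanophen)
```

## The problem

Hydrogen cyanide (HCN) in leaves of cyanogenic trees is a quantitative
defence trait, expensive to assay chemically (mg HCN per g dry weight,
typically between near zero and about 1.5 mg/g in adult field trials).
`cyanophen` implements an integrated prediction framework for such traits in
open-pollinated (half-sib) provenance/progeny trials: the trait is predicted
from pedigree information, from genome-wide SNP haplotypes, and from
high-dimensional leaf reflectance spectra (400--2,400 nm), separately and in
combination, using Bayesian whole-genome(-and-phenome) regression. The same
machinery yields heritability profiles of the reflectance spectrum itself:
one narrow-sense (pedigree) and one genomic heritability estimate per
wavelength band, plus heritabilities of classical spectral reflectance
indices (SRIs).

Because the motivating field-trial data are not public, the package ships a
first-class synthetic-data module that reproduces the statistical structure
of such a trial, so every stage of the pipeline is testable end to end.

## The models

All models are Gaussian multi-block linear models fitted by single-site
Gibbs sampling. With $y^*$ the block-adjusted phenotype:

* heritability models (per band or per index):
  $y = X\beta + Qv + Z_1 g_1 + \varepsilon$ (genomic) and
  $y = X\beta + P\rho + Z a + \varepsilon$ (pedigree), with
  $g_1 \sim N(0, G\sigma^2_{g_1})$, $a \sim N(0, A\sigma^2_a)$,
  and $h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$ — structure and
  provenance variance deliberately excluded from the denominator;
* prediction models 3--14: combinations of structure covariates $Qv$,
  provenance $P\rho$, SRI covariates $X_i\beta_i$, pedigree effects $Za$,
  haplotype effects $Z_2 g_2$ and per-band spectral effects $Z_3 h$, up to
  the full model
  $y^* = Qv + X_i\beta_i + Za + Z_2g_2 + Z_3h + \varepsilon$.

The dense regressor blocks ($Z_2$, $Z_3$) take one of three priors:
Bayesian ridge regression (one common effect variance), Bayes B (a variance
per regressor plus a point mass at zero) or Bayes C (common variance plus
point mass). Kinship effects ($a$, $g_1$) are reparameterized through
eigen-loadings $L$ with $LL^\top = K$ and always carry the Gaussian prior,
which is exactly $N(0, K\sigma^2)$. A note on $\pi$: this package's `pi` is
the *inclusion* probability (the chance a regressor effect is nonzero), the
convention of the main whole-genome-regression software; some descriptions
define the symbol as the exclusion probability, i.e. one minus ours.

Model comparison uses the deviance information criterion,
$\mathrm{DIC} = 2\bar D - D(\hat\theta)$ with the conditional Gaussian
deviance; differences above 10 are classed as supported, 3--10 substantial,
below 3 not significant (the boundaries 10 and 3 fall in the milder class).
Predictive ability (PA) is the Pearson correlation between observed and
predicted $y^*$ under fivefold cross-validation: each fold holds out 20% of
trees, the model is refitted on the rest, and held-out trees are predicted
through their design rows (for kinship blocks, through their eigen-loading
rows, so relationship information — but never the held-out response — is
used).

## Priors and their calibration

Variance components have scaled-inverse-$\chi^2$ priors. Defaults:

* prediction models: `df = 5` per block and a scale such that the prior
  mode implies the block explains an equal share of **10%** of the response
  variance (split across blocks); residual prior mode at 50%.
* heritability estimation (`estimate_h2()`, profiles, `sri_h2()`):
  `df = 2` with a prior share of 0.10 for the genetic block.

The common heuristic in this model family places the prior share at 50%.
We depart from it deliberately: the scaled-inverse-$\chi^2$ density falls
off as $\exp(-\nu S/2\sigma^2)$ to the left of its scale, so a large prior
scale acts as a hard floor under the variance. Two calibration experiments
drove the defaults. First, with a true heritability of 0.1 ($n = 400$), the
posterior-mean $h^2$ under `df = 5`/share 0.5 sits near 0.22 while the
exact-likelihood mean is 0.06--0.11; `df = 2`/share 0.1 recovers all four
levels 0.1/0.3/0.5/0.7 within $\pm 0.10$ (five-seed averages).
Second, on a pure-noise trait the per-block variance share (PV) reported
under share-0.5 priors stays near the prior (17--22% per block); under the
share-0.1 default all blocks report below 10%. The right tail of the prior
is polynomial, so genuinely informative data can still push the variance up
— the low scale costs little power.

## What the synthetic generator emulates

The generator mirrors a half-sib provenance/progeny trial:

* **Pedigree** — 49 open-pollinated families (one dam each, sires unknown,
  expected half-sib relationship 1/4), nested in 4 provenances, laid out in
  30 randomized complete blocks with single-tree plots; 6 progeny per
  family by default (~300 trees; the trial's exact family-by-block layout is
  not public, so family size is a parameter).
* **Genotypes** — 11 chromosomes × 350 SNPs (~11 kb spacing), MAF
  filter at 0.05. LD comes from latent ancestral haplotypes: markers in
  blocks of 10 share one of four ancestral haplotypes per gamete (1%
  per-marker mutation), giving high within-block D′ and near-zero
  between-block D′ — enough structure to exercise the solid-spine block
  logic without a coalescent simulator. Offspring arise by gene dropping:
  a recombined dam gamete plus a fresh population gamete for the unknown
  sire.
* **Spectra** — each spectrum is a smooth leaf-like mean curve plus a
  family-transmitted additive component, a smooth individual deviation and
  band noise, all built from ≤16 Gaussian wavelength bases (widths 80--150
  nm). Per-band variance shares are set so realized band heritability
  matches its regional target in expectation — higher in the visible
  (0.45) than the NIR (0.30) and SWIR (0.20), the shape reported for real
  leaf spectra. When genotypes are supplied, half of each additive basis
  loading is a genome-wide marker polygene, so band heritability is partly
  marker-expressed and the genomic relationship matrix can detect it, as in
  real data; the other half travels through the pedigree only.
* **Trait** — provenance and block effects plus three unit-scale random
  components: additive-genetic (half polygenic scores that also shape the
  spectra, half sparse ancestral-haplotype-block QTL), a spectrally
  mediated environmental component (scores of the causal bases'
  non-heritable deviations), and Gaussian residual; defaults 0.35 / 0.25 /
  0.40. The latent trait is mapped affinely onto [0, 1.54] mg HCN/g dw and
  the map is recorded, so variance shares survive the rescaling. Routing
  part of the genetic signal and part of the environment through the
  spectra is precisely the situation in which phenomic prediction helps —
  models seeing the spectra capture variance that markers alone cannot.

What the generator does **not** emulate: recombination-map realism,
genotype-by-environment interaction, spectral instrument artifacts
(scatter, baseline drift), assay error structure in HCN chemistry, or
selection/structure beyond discrete provenances. Passing tests therefore
show the *statistical machinery* is sound under the assumed structure, not
that any particular field population behaves this way.

## Recovery experiments and their design

* *Heritability recovery* uses a fully marker-expressed additive
  architecture (all additive variance through ancestral-haplotype QTL,
  `poly_frac = 0`, 40 causal blocks) and the genomic relationship
  estimator. Genomic heritability is defined only for marker-expressed
  variance; and a pedigree A built from ~50 half-sib families carries only
  ~50 informative contrasts (per-draw standard error of $h^2$ near 0.28),
  too little for sharp recovery by any estimator — the information, not
  the code, is the limit.
* *Variance-partition recovery* plants known shares (40% kinship, 20%
  spectral) directly in the span of the design blocks and checks the
  reported PVs; the genomic kinship is used for the genetic block for the
  same information reason.
* *Qualitative orderings* (integrated model beats genomic-only on DIC by
  more than 10; spectra-bearing models beat genomic-only on cross-validated
  PA) are checked on the default generator over ten seeds.

## Numerical choices

* Eigen-loadings keep eigenvalues above $10^{-8}\lambda_{\max}$;
  numerically negative modes are truncated.
* Savitzky--Golay preprocessing: bands are centered and scaled first, then
  differentiated along wavelength (window 37 grid points, polynomial order
  2 — the usual chemometrics choice for first derivatives; the order is a
  parameter). Edge bands without a full window are dropped
  ($w' = w - 36$). SRIs are always computed on raw reflectance, their
  published scale; derivative-based indices use the first difference of raw
  reflectance.
* Two-locus EM for unphased LD runs to $10^{-10}$ on the haplotype
  frequency with boundary clamping; the LOD is the base-10 likelihood ratio
  against linkage equilibrium under the same data model (multinomial gamete
  counts when phase is known, genotype-pair likelihood otherwise).
* The solid-spine predicate requires both spine ends in strong LD
  (D′ ≥ 0.9) with every interior marker; candidate ranges are retained when
  their mean pairwise D′ ≥ 0.9 and mean LOD ≥ 2 (whether that filter is a
  pairwise or block-summary rule is ambiguous in the method's sources; the
  block-summary reading is the default and `pairwise = TRUE` gives the
  stricter variant). Scanning is greedy left-to-right, longest valid
  extension first, which an exhaustive-enumeration oracle reproduces.
* Haplotype alleles rarer than 1% are pooled into the block's reference
  allele, which is dropped from the design; within a block, retained plus
  dropped dosages always sum to 2.
* Stepwise SRI selection minimizes $\mathrm{AIC} = n\log(RSS/n) + 2k$
  bidirectionally from the intercept; AIC is the sole criterion, with
  coefficient p-values and VIFs reported post hoc
  (VIF < 10 none / 10--100 strong / ≥ 100 severe).
* Chains: desk-scale default 20,000 iterations, 4,000 burn-in, thin 5;
  heritability profiles use 2,000--6,000-iteration chains per band (each
  band is a one-block model; profile summaries average over many bands).
  The long-chain preset `mcmc_paper()` (10^6 / 10^5 / 50) matches
  production-scale practice. Seeded chains are bit-reproducible; profile
  band seeds derive from the wavelength so results are independent of band
  order.

## Problem sizes

Desk-scale defaults keep every experiment in seconds to a few minutes:
spectra on a 10-nm grid (201 bands; 1-nm available), ~300--400 trees,
3,850 simulated SNPs for the full pipeline and an 11×60 panel for repeated
CV experiments, fivefold CV, 5--10 seeds per recovery average. The
acceptance script (`scripts/acceptance.R`) runs the full default study.

## Known limitations

* Models 1--2 (heritability) use the same Bayesian engine as prediction
  (not REML); posterior SDs are the uncertainty measure.
* With ~50 half-sib families, pedigree-based per-band $h^2$ estimates are
  noisy; regional averages are the robust summary.
* The spectral block's PV partially overlaps the genetic blocks whenever
  spectra carry genetic signal — the partition is a description of the
  fitted predictors, not an orthogonal decomposition.
* EM phasing for unphased input is a chained two-locus heuristic, adequate
  for short strong-LD blocks only; supply phased data for long blocks.
* No GxE, no multi-trait models, no Bayes A / Bayesian LASSO / RKHS
  engines.
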