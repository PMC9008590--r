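# cyanophen

Integrated genomic and phenomic prediction of leaf hydrogen-cyanide (HCN)
content in half-sib tree populations.

## What this package is for

Cyanogenic trees store cyanogenic glucosides (chiefly prunasin in
*Eucalyptus cladocalyx*) and release HCN on tissue damage. The trait is
quantitative, heritable and expensive to assay. In an open-pollinated
provenance/progeny trial three information sources are available per tree:
its pedigree (dam known, sire unknown — half-sib families), genome-wide SNP
genotypes, and a leaf reflectance spectrum (400–2,400 nm). `cyanophen`
implements, for breeders and quantitative geneticists:

- **Heritability profiling of the spectrum itself** — per 1-nm (or strided)
  wavelength band, the narrow-sense heritability
  `h_a^2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)` from the pedigree
  relationship matrix **A** and the genomic heritability
  `h_g^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` from the VanRaden genomic
  relationship matrix **G**, plus heritabilities of named spectral
  reflectance indices (SRIs: NPCI, SR10, NDLI, NDNI, ARI, LRDSI1, ...).
- **Twelve prediction models** for the block-adjusted trait `y*`,
  combining structure covariates `Qv`, provenance `P rho`, SRI covariates
  `X_i beta_i`, pedigree effects `Za` (`a ~ N(0, A sigma_a^2)`),
  haplotype-block effects `Z2 g2` and per-band spectral effects `Z3 h` — up
  to the full model `y* = Qv + X_i beta_i + Za + Z2 g2 + Z3 h + e` — each
  fitted by from-scratch Gibbs samplers under Bayesian ridge regression,
  Bayes B and Bayes C priors.
- **Model comparison**: deviance information criterion (DIC; differences
  > 10 supported, 3–10 substantial, < 3 not significant), per-block percent
  of phenotypic variance (PV), and fivefold cross-validated predictive
  ability (PA, the correlation between observed and predicted `y*`).
- **Supporting machinery**: solid-spine haplotype blocks from D′/LOD
  statistics (two-locus EM for unphased data), Savitzky–Golay spectral
  preprocessing (window 37, first derivative), stepwise-AIC index selection
  with VIF screening, and a synthetic-data generator that reproduces the
  statistical structure of a half-sib trial (49 families, ~300 trees,
  ~3,850 block-LD SNPs on 11 chromosomes, family-structured spectra,
  an HCN-like trait on the 0–1.54 mg/g scale) so the whole pipeline is
  testable without any external data.

Everything is tibble-first and pipe-friendly; fitted models have
`tidy()`/`glance()` methods and result types have `autoplot()` methods.

## A worked example

Simulate a trial, build the design bundle (kinships, LD blocks, haplotypes,
processed spectra, index selection), fit the genomic-only, spectra-only and
integrated models, and cross-validate:

```r
library(cyanophen)

pop    <- simulate_population(wavelength_step = 5, seed = 1)
bundle <- build_bundle(pop)

fits <- lapply(c(3, 7, 13), function(m)
  fit_model(model_spec(m, engine = "BayesB"), bundle,
            mcmc = mcmc_settings(10000, 2500, 5, seed = m)))
cvs <- lapply(c(3, 7, 13), function(m)
  cross_validate(model_spec(m, engine = "BayesB"), bundle, k = 5, seed = m,
                 mcmc = mcmc_settings(5000, 1500, 5)))
compare_models(fits, cvs)
```

```
#> # A tibble: 3 × 10
#>   model engine sri     dic  pv_g pv_sr  pv_a delta_dic support             pa
#>   <dbl> <chr>  <chr> <dbl> <dbl> <dbl> <dbl>     <dbl> <chr>            <dbl>
#> 1    13 BayesB -     -13.3  7.39  11.9  7.25      0    not significant 0.340
#> 2     7 BayesB -     -11.7 NA     19.6 NA         1.69 not significant 0.376
#> 3     3 BayesB -      33.2 22.7   NA   NA        46.5  supported       0.0876
```

Reading the table: the integrated model 13 and the spectra-only model 7
fit almost equally well (their DIC difference of 1.7 is below the
"not significant" boundary of 3), while the genomic-only model 3 trails
them by 46 DIC units — far beyond the "supported" threshold of 10.
Cross-validated predictive ability is 0.34–0.38 for the models that see
the spectra versus 0.09 for haplotype information alone: the generator
routes part of the genetic signal and part of the environment through the
spectra, which is exactly the situation in which phenomic prediction
outperforms marker-only prediction.

Per-band heritability profile (pedigree-based), with the visible region
more heritable than the shortwave infrared:

```r
AL   <- bundle$A_load
prof <- wavelength_h2_profile(pop$spectra, AL, ids = bundle$ids,
                              mcmc = mcmc_settings(2000, 600, 2, seed = 2))
dplyr::summarise(dplyr::group_by(prof, region), h2 = mean(h2))
autoplot(prof)
```

```
#> # A tibble: 3 × 2
#>   region     h2
#>   <chr>   <dbl>
#> 1 nir     0.316
#> 2 swir    0.243
#> 3 visible 0.320
```

The ordering (visible above SWIR) matches the generator's regional targets
(0.45 / 0.30 / 0.20), though at ~300 trees in 49 half-sib families the
pedigree carries only ~50 informative family contrasts, so per-band
estimates are strongly compressed toward their common mean; with larger
families (say 8 progeny in 50 families, n = 400) the same profile spreads
to roughly 0.45 versus 0.20 between visible and SWIR.

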