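Package: cyanophen
Title: Integrated Genomic and Phenomic Prediction of Leaf Cyanogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting leaf hydrogen-cyanide (HCN) content in
    half-sib tree populations by combining pedigree, genomic-haplotype and
    hyperspectral leaf-reflectance information. Provides a synthetic-data
    generator for half-sib provenance/progeny trials (pedigree, block-LD SNP
    genotypes, family-structured reflectance spectra, an HCN-like trait);
    pedigree (A) and VanRaden genomic (G) relationship matrices; solid-spine
    haplotype-block construction from D' and LOD statistics; Savitzky-Golay
    spectral preprocessing and a registry of spectral reflectance indices with
    stepwise-AIC selection and VIF screening; from-scratch Gibbs samplers for
    Bayesian ridge regression, Bayes B and Bayes C over multi-block linear
    models; per-wavelength heritability profiling; and a model-comparison
    pipeline with fivefold cross-validated predictive ability and DIC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
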