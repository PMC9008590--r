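test_that("pedigree has the half-sib trial structure and is seed-deterministic", {
  ped <- simulate_pedigree(49, 6, 30, 4, seed = 1)
  expect_equal(nrow(ped), 49 + 49 * 6)
  expect_equal(sum(ped$generation == 0), 49)
  # half-sib design: every offspring's sire unknown, dam known
  off <- ped[ped$generation == 1, ]
  expect_true(all(is.na(off$sire)))
  expect_true(all(!is.na(off$dam)))
  expect_true(all(off$block %in% 1:30))
  # one dam per family, families nested in provenances
  expect_equal(dplyr::n_distinct(ped$family[ped$generation == 0]), 49)
  fam_prov <- dplyr::distinct(ped, family, provenance)
  expect_equal(nrow(fam_prov), 49)
  expect_identical(ped, simulate_pedigree(49, 6, 30, 4, seed = 1))
  expect_error(simulate_pedigree(0, 6, 30, 4), class = "cyanophen_invalid_argument")

  # two half sibs share one dam
  ped2 <- simulate_pedigree(1, 2, 2, 1, seed = 7)
  off2 <- ped2[ped2$generation == 1, ]
  expect_equal(off2$dam[1], off2$dam[2])
})

test_that("simulated genotypes respect the MAF filter and seed determinism", {
  pop <- small_pop()
  gen <- pop$genotypes
  maf <- pmin(gen$map$freq, 1 - gen$map$freq)
  expect_true(all(maf >= 0.05))
  expect_false(anyNA(gen$dosage))
  expect_true(all(gen$dosage %in% 0:2))
  expect_identical(gen$dosage, gen$h1 + gen$h2)
  # positions strictly increasing within chromosome
  for (cc in unique(gen$map$chrom)) {
    expect_true(all(diff(gen$map$pos[gen$map$chrom == cc]) > 0))
  }
  # nearly all simulated markers survive the filter
  expect_gt(ncol(gen$dosage), 0.9 * 3 * 60)
  g2 <- simulate_genotypes(pop$pedigree, n_chrom = 3, snps_per_chrom = 60,
                           seed = 42 + 101L)
  expect_identical(gen$dosage, g2$dosage)
  expect_error(simulate_genotypes(pop$pedigree, maf_min = 0.6),
               class = "cyanophen_invalid_argument")
})

test_that("within-LD-block D' exceeds between-block D' on simulated founders", {
  ped <- simulate_pedigree(100, 1, 2, 1, seed = 9)
  gen <- simulate_genotypes(ped, n_chrom = 1, snps_per_chrom = 60, seed = 10)
  ld <- pairwise_ld(gen)
  same_block <- gen$map$ld_block[ld$i] == gen$map$ld_block[ld$j]
  expect_gt(mean(ld$dprime[same_block]), mean(ld$dprime[!same_block]))
  expect_gt(mean(ld$dprime[same_block]), 0.6)
})

test_that("spectra have region-structured heritability recoverable by dam-offspring regression", {
  ped <- simulate_pedigree(50, 8, 30, 4, seed = 31)
  spc <- simulate_spectra(ped, region_h2 = c(visible = 0.45, nir = 0.30, swir = 0.20),
                          seed = 32)
  expect_true(all(spc$reflectance > 0 & spc$reflectance < 1))
  # oracle: band h2 = 2 * cov(dam, offspring) / var(phenotype)
  off <- ped[ped$generation == 1, ]
  po_h2 <- vapply(seq_along(spc$wavelength), function(k) {
    x <- spc$reflectance[off$dam, k]
    y <- spc$reflectance[off$id, k]
    2 * stats::cov(x, y) / stats::var(spc$reflectance[, k])
  }, numeric(1))
  reg <- tapply(po_h2, spectral_region(spc$wavelength), mean)
  expect_gt(reg[["visible"]], reg[["swir"]])
  expect_gt(reg[["visible"]], 0.3)
  expect_lt(reg[["swir"]], 0.35)
  # zero heritability everywhere: spectra differ only through environment
  spc0 <- simulate_spectra(ped, region_h2 = c(visible = 0, nir = 0, swir = 0),
                           seed = 33)
  po0 <- vapply(c(10, 100, 180), function(k) {
    2 * stats::cov(spc0$reflectance[off$dam, k], spc0$reflectance[off$id, k]) /
      stats::var(spc0$reflectance[, k])
  }, numeric(1))
  expect_true(all(abs(po0) < 0.2))
  expect_identical(spc$reflectance,
                   simulate_spectra(ped, seed = 32)$reflectance)
  expect_error(simulate_spectra(ped, region_h2 = c(visible = 0.4)),
               class = "cyanophen_invalid_argument")
})

test_that("trait components are bookkept exactly and live on the HCN scale", {
  pop <- small_pop()
  tr <- simulate_trait(pop$pedigree, pop$genotypes, pop$spectra,
                       h2_additive = 0.4, spectral_share = 0.2, seed = 5)
  expect_true(all(tr$trait$hcn >= 0))
  expect_equal(max(tr$trait$hcn), 1.54)
  cmp <- tr$true$components
  # stored components reassemble the latent trait to numerical precision
  rebuilt <- cmp$provenance_effect + cmp$block_effect + cmp$additive +
    cmp$spectral + cmp$residual
  expect_lt(max(abs(rebuilt - cmp$latent)), 1e-10)
  # affine map back to the latent scale
  aff <- tr$true$affine
  expect_lt(max(abs(cmp$latent * aff["scale"] + aff["shift"] - tr$trait$hcn)), 1e-10)
  expect_error(simulate_trait(pop$pedigree, pop$genotypes, pop$spectra,
                              h2_additive = 0.7, spectral_share = 0.5),
               class = "cyanophen_invalid_argument")
})

test_that("realized additive share matches its target on average", {
  pop <- small_pop()
  shares <- vapply(1:20, function(s) {
    tr <- simulate_trait(pop$pedigree, pop$genotypes, pop$spectra,
                         h2_additive = 0.4, spectral_share = 0.2, seed = s)
    cmp <- tr$true$components
    stats::var(cmp$additive) / stats::var(cmp$additive + cmp$spectral + cmp$residual)
  }, numeric(1))
  expect_lt(abs(mean(shares) - 0.4), 0.05)
})

test_that("null trait carries no genetic or spectral component", {
  pop <- small_pop()
  tr <- simulate_trait(pop$pedigree, pop$genotypes, pop$spectra,
                       h2_additive = 0, spectral_share = 0, seed = 3)
  expect_equal(stats::var(tr$true$components$additive), 0)
  expect_equal(stats::var(tr$true$components$spectral), 0)
})

test_that("half sibs resemble each other at about a quarter of the additive share", {
  ped <- simulate_pedigree(60, 10, 30, 2, seed = 77)
  gen <- simulate_genotypes(ped, n_chrom = 3, snps_per_chrom = 60, seed = 78)
  spc <- simulate_spectra(ped, seed = 79)
  tr <- simulate_trait(ped, gen, spc, h2_additive = 0.6, spectral_share = 0,
                       block_sd = 0, provenance_sd = 0, seed = 80)
  z <- tr$true$components$latent
  fam <- tr$trait$family
  icc <- (stats::anova(stats::aov(z ~ fam))[["Mean Sq"]][1] -
            stats::anova(stats::aov(z ~ fam))[["Mean Sq"]][2]) /
    (stats::anova(stats::aov(z ~ fam))[["Mean Sq"]][1] +
       9 * stats::anova(stats::aov(z ~ fam))[["Mean Sq"]][2])
  expect_lt(abs(icc - 0.6 / 4), 0.07)
})
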