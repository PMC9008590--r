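#' Simulate a half-sib provenance/progeny trial pedigree
#'
#' Builds the pedigree of an open-pollinated progeny trial: unrelated dams
#' (one per family, families nested within provenances) and their offspring,
#' laid out over complete randomized blocks with single-tree plots. Sires are
#' unknown (open pollination), so every pair of within-family progeny are half
#' sibs with expected additive relationship 1/4.
#'
#' @param n_families Number of half-sib families (one dam each).
#' @param progeny_per_family Offspring per family.
#' @param n_blocks Number of randomized complete blocks (single-tree plots).
#' @param n_provenances Number of seed-source provenances the families are
#'   nested in.
#' @param seed Integer seed; the function is a pure function of its arguments.
#'
#' @return A tibble with one row per individual and columns `id`, `sire`,
#'   `dam` (`NA` = unknown parent), `family`, `provenance`, `block`
#'   (`NA` for founders, which are not planted in the trial) and `generation`
#'   (0 = founder). Parents always precede offspring.
#' @examples
#' ped <- simulate_pedigree(10, 4, 8, 2, seed = 1)
#' dplyr::count(ped, generation)
#' @export
simulate_pedigree <- function(n_families = 49, progeny_per_family = 6,
                              n_blocks = 30, n_provenances = 4, seed = 1) {
  counts <- c(n_families, progeny_per_family, n_blocks, n_provenances)
  if (any(counts < 1) || any(counts != round(counts))) {
    rlang::abort("all counts must be positive integers",
                 class = "cyanophen_invalid_argument")
  }
  withr_seed(seed)
  fam_ids <- sprintf("F%02d", seq_len(n_families))
  dam_ids <- sprintf("D%02d", seq_len(n_families))
  # families nested in provenances, split as evenly as possible
  prov_of_family <- sprintf(
    "P%d", rep(seq_len(n_provenances), length.out = n_families)[sample.int(n_families)]
  )
  dams <- tibble::tibble(
    id = dam_ids, sire = NA_character_, dam = NA_character_,
    family = fam_ids, provenance = prov_of_family,
    block = NA_integer_, generation = 0L
  )
  off <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    # single-tree plots: a family occupies distinct blocks where possible
    if (progeny_per_family <= n_blocks) {
      blocks <- sample.int(n_blocks, progeny_per_family)
    } else {
      blocks <- c(rep(seq_len(n_blocks), progeny_per_family %/% n_blocks),
                  sample.int(n_blocks, progeny_per_family %% n_blocks))
    }
    off[[f]] <- tibble::tibble(
      id = sprintf("%s_O%02d", fam_ids[f], seq_len(progeny_per_family)),
      sire = NA_character_, dam = dam_ids[f],
      family = fam_ids[f], provenance = prov_of_family[f],
      block = as.integer(blocks), generation = 1L
    )
  }
  dplyr::bind_rows(dams, dplyr::bind_rows(off))
}

#' Simulate SNP genotypes with block linkage disequilibrium
#'
#' Founder gametes are mosaics of a small pool of ancestral haplotypes per LD
#' block, so markers inside a block are in strong D' while blocks are
#' independent. Offspring genotypes are produced by gene dropping: one
#' recombined gamete from the known dam and one fresh population gamete for
#' the unknown sire. Markers failing the minor-allele-frequency filter are
#' removed, mirroring the upstream SNP quality control the analysis assumes.
#'
#' @param pedigree Pedigree tibble from [simulate_pedigree()] (parents before
#'   offspring).
#' @param n_chrom Number of chromosomes.
#' @param snps_per_chrom Markers simulated per chromosome (before MAF
#'   filtering).
#' @param ld_block_len Markers per ancestral LD block.
#' @param maf_min Minimum minor allele frequency retained (must be < 0.5).
#' @param n_ancestral Ancestral haplotypes per block (controls haplotype
#'   diversity).
#' @param mutation_rate Per-marker probability that a gamete deviates from its
#'   ancestral haplotype (keeps D' high but below 1).
#' @param recomb_per_chrom Expected crossovers per chromosome per meiosis.
#' @param mean_spacing_bp Mean distance between adjacent markers in bp.
#' @param seed Integer seed.
#'
#' @return An object of class `cyp_geno`: a list with `dosage` (n x m matrix,
#'   rownames = individual ids, values 0/1/2), `map` (tibble: `marker`,
#'   `chrom`, `pos`, `freq`, `ld_block`), phased gametes `h1`/`h2` (n x m 0/1
#'   matrices), and `anc1`/`anc2` (per-block ancestral haplotype origin of
#'   each gamete, generator ground truth used for simulating causal
#'   haplotype effects).
#' @export
simulate_genotypes <- function(pedigree, n_chrom = 11, snps_per_chrom = 350,
                               ld_block_len = 10, maf_min = 0.05,
                               n_ancestral = 4, mutation_rate = 0.01,
                               recomb_per_chrom = 1.2,
                               mean_spacing_bp = 11000, seed = 1) {
  if (maf_min >= 0.5) {
    rlang::abort("maf_min must be < 0.5", class = "cyanophen_invalid_argument")
  }
  check_pedigree_order(pedigree)
  withr_seed(seed)
  n <- nrow(pedigree)
  ids <- pedigree$id
  dam_idx <- match(pedigree$dam, ids)

  m_per <- snps_per_chrom
  m_tot <- n_chrom * m_per
  # block layout: ld_block_len consecutive markers per block, per chromosome
  blocks_per_chrom <- ceiling(m_per / ld_block_len)
  block_of_marker <- integer(m_tot)
  chrom_of_marker <- rep(seq_len(n_chrom), each = m_per)
  pos <- numeric(m_tot)
  blk0 <- 0L
  for (cc in seq_len(n_chrom)) {
    idx <- which(chrom_of_marker == cc)
    block_of_marker[idx] <- blk0 + rep(seq_len(blocks_per_chrom),
                                       each = ld_block_len)[seq_len(m_per)]
    pos[idx] <- cumsum(round(stats::runif(m_per, 0.6, 1.4) * mean_spacing_bp))
    blk0 <- blk0 + blocks_per_chrom
  }
  n_blocks <- blk0

  # ancestral haplotype pool: per block, n_ancestral binary haplotypes; every
  # marker segregates among the ancestors (allele 1 on 1..n_ancestral-1 of
  # them), which keeps nearly all markers above the MAF filter
  anc <- matrix(0L, nrow = n_ancestral, ncol = m_tot)
  k_carriers <- sample(seq_len(n_ancestral - 1), m_tot, replace = TRUE)
  for (mm in seq_len(m_tot)) {
    anc[sample.int(n_ancestral, k_carriers[mm]), mm] <- 1L
  }
  # mildly uneven ancestral weights per block
  w <- matrix(stats::rgamma(n_blocks * n_ancestral, shape = 3), nrow = n_blocks)
  w <- w / rowSums(w)

  marker_idx_of_block <- split(seq_len(m_tot), block_of_marker)

  # a population gamete: per block choose an ancestral haplotype, then mutate
  draw_gametes <- function(k) {
    g <- matrix(0L, nrow = k, ncol = m_tot)
    a_id <- matrix(0L, nrow = k, ncol = n_blocks)
    for (b in seq_len(n_blocks)) {
      cols <- marker_idx_of_block[[b]]
      pick <- sample.int(n_ancestral, k, replace = TRUE, prob = w[b, ])
      g[, cols] <- anc[pick, cols, drop = FALSE]
      a_id[, b] <- pick
    }
    flip <- matrix(stats::runif(k * m_tot) < mutation_rate, nrow = k)
    g[flip] <- 1L - g[flip]
    list(g = g, anc = a_id)
  }

  h1 <- matrix(0L, n, m_tot, dimnames = list(ids, NULL))
  h2 <- matrix(0L, n, m_tot, dimnames = list(ids, NULL))
  anc1 <- matrix(0L, n, n_blocks, dimnames = list(ids, NULL))
  anc2 <- matrix(0L, n, n_blocks, dimnames = list(ids, NULL))

  founder <- is.na(dam_idx)
  nf <- sum(founder)
  fg1 <- draw_gametes(nf); fg2 <- draw_gametes(nf)
  h1[founder, ] <- fg1$g; anc1[founder, ] <- fg1$anc
  h2[founder, ] <- fg2$g; anc2[founder, ] <- fg2$anc

  # meiosis: copy-choice along each chromosome with Haldane-style switching
  r_switch <- recomb_per_chrom / m_per
  meiose <- function(ha, hb, aa, ab) {
    out <- integer(m_tot); anc_out <- integer(n_blocks)
    for (cc in seq_len(n_chrom)) {
      idx <- which(chrom_of_marker == cc)
      state <- cumsum(c(sample(0:1, 1), stats::runif(length(idx) - 1) < r_switch)) %% 2
      out[idx] <- ifelse(state == 0, ha[idx], hb[idx])
      # block ancestral origin follows the source of the block's first marker
      first <- idx[!duplicated(block_of_marker[idx])]
      bids <- block_of_marker[first]
      anc_out[bids] <- ifelse(state[match(first, idx)] == 0, aa[bids], ab[bids])
    }
    list(g = out, anc = anc_out)
  }

  off_rows <- which(!founder)
  if (length(off_rows)) {
    sire_g <- draw_gametes(length(off_rows))
    for (k in seq_along(off_rows)) {
      i <- off_rows[k]
      d <- dam_idx[i]
      mg <- meiose(h1[d, ], h2[d, ], anc1[d, ], anc2[d, ])
      h1[i, ] <- mg$g; anc1[i, ] <- mg$anc
      h2[i, ] <- sire_g$g[k, ]; anc2[i, ] <- sire_g$anc[k, ]
    }
  }

  dosage <- h1 + h2
  freq <- colMeans(dosage) / 2
  keep <- pmin(freq, 1 - freq) >= maf_min
  map <- tibble::tibble(
    marker = sprintf("chr%02d_%07d", chrom_of_marker, as.integer(pos)),
    chrom = chrom_of_marker, pos = pos, freq = freq,
    ld_block = block_of_marker
  )[keep, ]
  structure(
    list(dosage = dosage[, keep, drop = FALSE],
         map = map,
         h1 = h1[, keep, drop = FALSE], h2 = h2[, keep, drop = FALSE],
         anc1 = anc1, anc2 = anc2, n_ld_blocks = n_blocks),
    class = "cyp_geno"
  )
}

#' @export
print.cyp_geno <- function(x, ...) {
  cat(sprintf("<cyp_geno> %d individuals x %d SNPs on %d chromosomes (phased)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.cyp_geno <- function(x) dim(x$dosage)

#' Convert genotypes to a wide tibble of dosages
#' @param x A `cyp_geno` object.
#' @param ... Unused.
#' @export
as_tibble.cyp_geno <- function(x, ...) {
  out <- tibble::as_tibble(x$dosage, .name_repair = "minimal")
  names(out) <- x$map$marker
  dplyr::bind_cols(tibble::tibble(id = rownames(x$dosage)), out)
}

#' Spectral region of a wavelength
#'
#' Classifies wavelengths (nm) into the three conventional regions:
#' visible (< 700), near infrared (700-1400) and shortwave infrared
#' (>= 1400).
#'
#' @param wavelength Numeric vector of wavelengths in nm.
#' @return Character vector (`"visible"`, `"nir"`, `"swir"`).
#' @export
spectral_region <- function(wavelength) {
  dplyr::case_when(
    wavelength < 700 ~ "visible",
    wavelength < 1400 ~ "nir",
    TRUE ~ "swir"
  )
}

# smooth leaf-reflectance-like mean curve on [400, 2400] nm
mean_reflectance_curve <- function(wl) {
  gauss <- function(mu, s) exp(-0.5 * ((wl - mu) / s)^2)
  r <- 0.08 +
    0.06 * gauss(550, 40) +                      # green peak
    0.38 / (1 + exp(-(wl - 715) / 14)) -         # red edge to NIR plateau
    0.12 * gauss(1450, 60) -                     # water absorption
    0.16 * gauss(1940, 80) -
    0.08 * gauss(2200, 120) -
    0.06 * pmax(wl - 1500, 0) / 900              # gentle SWIR decline
  pmin(pmax(r, 0.06), 0.95)
}

#' Simulate family-structured leaf reflectance spectra
#'
#' Each spectrum is a smooth mean curve plus a family-transmitted additive
#' component, a smooth individual (environmental) deviation and per-band
#' noise. Smoothness comes from a small set of Gaussian wavelength bases;
#' heritable and non-heritable variance are balanced per band so the realized
#' band heritability matches `region_h2` in expectation, with higher values
#' in the visible region than in the SWIR by default. Additive basis loadings
#' are dam-transmitted (offspring loading = 1/2 dam loading + Mendelian
#' deviate), so twice the dam-offspring regression of a band recovers its
#' target heritability.
#'
#' @param pedigree Pedigree tibble (dams receive spectra too, so
#'   parent-offspring regressions are possible on the simulated output).
#' @param region_h2 Named fractions in `[0, 1)` for regions `visible`
#'   (400-700 nm), `nir` (700-1400 nm) and `swir` (1400-2400 nm).
#' @param genotypes Optional `cyp_geno` for the same pedigree. When given,
#'   a fraction `marker_share` of each additive basis loading is a genome-wide
#'   marker polygene (small effects on all SNP dosages), so band heritability
#'   is partly marker-expressed and a genomic relationship matrix can see it —
#'   as in real data; the rest is transmitted through the pedigree only.
#' @param marker_share Fraction of the additive basis variance carried by the
#'   marker polygene (ignored without `genotypes`).
#' @param n_basis Number of Gaussian wavelength bases (<= 16 is plenty).
#' @param wavelength_step Grid stride in nm (1 = full 2,001-band grid;
#'   default 10 keeps downstream models fast).
#' @param band_sd Total per-band phenotypic standard deviation on the
#'   reflectance scale.
#' @param smooth_env_share Fraction of non-heritable band variance carried by
#'   the smooth individual deviation (the rest is white noise).
#' @param seed Integer seed.
#'
#' @return Object of class `cyp_spectra`: `reflectance` (n x w matrix in
#'   (0,1), rownames = ids), `wavelength`, `h2_band` (target band h2, ground
#'   truth), `basis`, and the additive (`add_loadings`) and environmental
#'   (`env_loadings`) basis scores used (generator ground truth).
#' @export
simulate_spectra <- function(pedigree,
                             region_h2 = c(visible = 0.45, nir = 0.30, swir = 0.20),
                             genotypes = NULL, marker_share = 0.5,
                             n_basis = 16, wavelength_step = 10,
                             band_sd = 0.02, smooth_env_share = 0.6,
                             seed = 1) {
  need <- c("visible", "nir", "swir")
  if (!all(need %in% names(region_h2))) {
    rlang::abort("region_h2 must name regions visible, nir and swir",
                 class = "cyanophen_invalid_argument")
  }
  if (any(region_h2 < 0 | region_h2 >= 1)) {
    rlang::abort("region_h2 values must lie in [0, 1)",
                 class = "cyanophen_invalid_argument")
  }
  withr_seed(seed)
  wl <- seq(400, 2400, by = wavelength_step)
  w <- length(wl)
  n <- nrow(pedigree)
  ids <- pedigree$id

  centers <- seq(400, 2400, length.out = n_basis)
  widths <- stats::runif(n_basis, 80, 150)
  B <- sapply(seq_len(n_basis), function(b) exp(-0.5 * ((wl - centers[b]) / widths[b])^2))
  bnorm <- sqrt(rowSums(B^2))
  bnorm <- pmax(bnorm, 1e-6)

  h2_band <- unname(region_h2[spectral_region(wl)])

  # dam-transmitted additive loadings
  A <- matrix(0, n, n_basis, dimnames = list(ids, NULL))
  dam_idx <- match(pedigree$dam, ids)
  founder <- is.na(dam_idx)
  A[founder, ] <- stats::rnorm(sum(founder) * n_basis)
  for (i in which(!founder)) {
    A[i, ] <- 0.5 * A[dam_idx[i], ] + sqrt(0.75) * stats::rnorm(n_basis)
  }
  if (!is.null(genotypes)) {
    # marker polygene per basis: genome-wide small effects on centered dosages
    X <- scale(genotypes$dosage[ids, , drop = FALSE], scale = FALSE)
    Wm <- matrix(stats::rnorm(ncol(X) * n_basis), ncol(X), n_basis)
    Z <- X %*% Wm
    Z <- scale(Z)   # unit variance per basis
    A <- sqrt(1 - marker_share) * A + sqrt(marker_share) * Z
  }
  C <- matrix(stats::rnorm(n * n_basis), n, n_basis, dimnames = list(ids, NULL))

  smooth_g <- sweep(A %*% t(B), 2, bnorm, "/")
  smooth_e <- sweep(C %*% t(B), 2, bnorm, "/")
  white <- matrix(stats::rnorm(n * w), n, w)

  gscale <- sqrt(h2_band) * band_sd
  escale <- sqrt(1 - h2_band) * band_sd
  env <- sqrt(smooth_env_share) * smooth_e + sqrt(1 - smooth_env_share) * white

  refl <- matrix(rep(mean_reflectance_curve(wl), each = n), n, w) +
    sweep(smooth_g, 2, gscale, "*") + sweep(env, 2, escale, "*")
  refl <- pmin(pmax(refl, 1e-4), 1 - 1e-4)
  dimnames(refl) <- list(ids, sprintf("wl_%04d", wl))

  structure(
    list(reflectance = refl, wavelength = wl, h2_band = h2_band,
         basis = B, basis_norm = bnorm, band_sd = band_sd,
         smooth_env_share = smooth_env_share,
         add_loadings = A, env_loadings = C),
    class = "cyp_spectra"
  )
}

#' @export
print.cyp_spectra <- function(x, ...) {
  cat(sprintf("<cyp_spectra> %d individuals x %d bands (%d-%d nm, step %g nm)\n",
              nrow(x$reflectance), length(x$wavelength),
              min(x$wavelength), max(x$wavelength),
              if (length(x$wavelength) > 1) diff(x$wavelength[1:2]) else NA))
  invisible(x)
}

#' @export
dim.cyp_spectra <- function(x) dim(x$reflectance)

#' Convert spectra to a wide tibble (`id`, `wl_0400`, ...)
#' @param x A `cyp_spectra` object.
#' @param ... Unused.
#' @export
as_tibble.cyp_spectra <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(id = rownames(x$reflectance)),
                   tibble::as_tibble(x$reflectance))
}

#' Simulate an HCN-like quantitative trait
#'
#' The trait combines provenance and block (fixed) effects with three random
#' components on a unit-variance latent scale: an additive-genetic part
#' (half pedigree-transmitted polygenic scores that also load on the causal
#' spectral bases, half sparse ancestral-haplotype-block effects), a
#' spectrally mediated environmental part (scores of the causal spectral
#' bases' non-heritable deviations), and a Gaussian residual. Because the
#' polygenic scores are the same basis loadings that shape the spectra, the
#' spectra carry trait-relevant genetic signal -- the situation phenomic
#' prediction exploits. The latent trait is finally mapped affinely onto the
#' field-observed HCN scale `[0, 1.54]` mg HCN per g dry weight; the affine
#' map is recorded so variance shares are preserved.
#'
#' @param pedigree,genotypes,spectra Outputs of the other `simulate_*`
#'   functions (same pedigree).
#' @param h2_additive Additive-genetic share of the latent trait variance.
#' @param spectral_share Spectrally mediated (non-genetic) share; must satisfy
#'   `h2_additive + spectral_share < 1`.
#' @param poly_frac Fraction of the additive share carried by the polygenic
#'   (spectra-linked) component; the rest is haplotype-block QTL.
#' @param n_causal_blocks Number of causal ancestral LD blocks.
#' @param n_causal_basis Number of causal spectral bases.
#' @param block_sd,provenance_sd Fixed-effect SDs on the latent scale.
#' @param hcn_max Upper end of the rescaled HCN range (mg/g dw).
#' @param seed Integer seed.
#'
#' @return A list with `trait` (tibble: `id`, `hcn`, `block`, `family`,
#'   `provenance`, `group`; offspring only, since founders are not in the
#'   trial) and `true` (class `cyp_trueparams`: shares, causal identities,
#'   per-individual component vectors and the affine rescaling).
#' @export
simulate_trait <- function(pedigree, genotypes, spectra,
                           h2_additive = 0.35, spectral_share = 0.25,
                           poly_frac = 0.5,
                           n_causal_blocks = 20, n_causal_basis = 3,
                           block_sd = 0.25, provenance_sd = 0.25,
                           hcn_max = 1.54, seed = 1) {
  if (h2_additive < 0 || spectral_share < 0 ||
      h2_additive >= 1 || spectral_share >= 1 ||
      h2_additive + spectral_share >= 1) {
    rlang::abort("h2_additive and spectral_share must lie in [0,1) and sum to < 1",
                 class = "cyanophen_invalid_argument")
  }
  withr_seed(seed)
  off <- pedigree[pedigree$generation > 0, ]
  n <- nrow(off)
  ids <- off$id

  n_basis <- ncol(spectra$add_loadings)
  causal_basis <- sample.int(n_basis, min(n_causal_basis, n_basis))

  standardize <- function(v) {
    s <- stats::sd(v)
    if (s < 1e-12) v * 0 else (v - mean(v)) / s
  }

  # polygenic: dam-transmitted scores on the causal spectral bases
  poly <- rowSums(spectra$add_loadings[ids, causal_basis, drop = FALSE])
  poly <- standardize(poly)

  # sparse haplotype-block QTL: dosage of one ancestral allele per causal block
  nb <- genotypes$n_ld_blocks
  causal_blocks <- sample.int(nb, min(n_causal_blocks, nb))
  causal_anc <- sample.int(max(genotypes$anc1), length(causal_blocks), replace = TRUE)
  qdos <- sapply(seq_along(causal_blocks), function(k) {
    b <- causal_blocks[k]
    (genotypes$anc1[ids, b] == causal_anc[k]) + (genotypes$anc2[ids, b] == causal_anc[k])
  })
  beta_q <- stats::rnorm(length(causal_blocks))
  qtl <- standardize(as.numeric(qdos %*% beta_q))

  additive <- sqrt(h2_additive) *
    (sqrt(poly_frac) * poly + sqrt(1 - poly_frac) * qtl)

  # spectrally mediated environmental component: causal-basis env scores
  spec_env <- rowSums(spectra$env_loadings[ids, causal_basis, drop = FALSE])
  spec_env <- sqrt(spectral_share) * standardize(spec_env)

  resid_share <- 1 - h2_additive - spectral_share
  resid <- sqrt(resid_share) * standardize(stats::rnorm(n))

  prov_levels <- sort(unique(off$provenance))
  rho <- stats::setNames(stats::rnorm(length(prov_levels), 0, provenance_sd), prov_levels)
  blk_levels <- sort(unique(off$block))
  beta_blk <- stats::setNames(stats::rnorm(length(blk_levels), 0, block_sd),
                              as.character(blk_levels))

  latent <- rho[off$provenance] + beta_blk[as.character(off$block)] +
    additive + spec_env + resid
  a0 <- min(latent); b0 <- max(latent)
  scale <- hcn_max / (b0 - a0)
  hcn <- (latent - a0) * scale

  trait <- tibble::tibble(
    id = ids, hcn = as.numeric(hcn), block = off$block,
    family = off$family, provenance = off$provenance, group = off$provenance
  )
  true <- structure(list(
    h2_additive = h2_additive, spectral_share = spectral_share,
    resid_share = resid_share, poly_frac = poly_frac,
    causal_basis = causal_basis, causal_blocks = causal_blocks,
    causal_anc = causal_anc,
    components = tibble::tibble(
      id = ids, additive = as.numeric(additive),
      spectral = as.numeric(spec_env), residual = as.numeric(resid),
      provenance_effect = as.numeric(rho[off$provenance]),
      block_effect = as.numeric(beta_blk[as.character(off$block)]),
      latent = as.numeric(latent)
    ),
    provenance_effects = rho, block_effects = beta_blk,
    affine = c(shift = -a0 * scale, scale = scale),
    seed = seed
  ), class = "cyp_trueparams")
  list(trait = trait, true = true)
}

#' @export
print.cyp_trueparams <- function(x, ...) {
  cat(sprintf(
    "<cyp_trueparams> shares: additive %.2f, spectral %.2f, residual %.2f; %d causal blocks, %d causal bases\n",
    x$h2_additive, x$spectral_share, x$resid_share,
    length(x$causal_blocks), length(x$causal_basis)))
  invisible(x)
}

#' Simulate a complete synthetic study population
#'
#' Convenience wrapper chaining [simulate_pedigree()], [simulate_genotypes()],
#' [simulate_spectra()] and [simulate_trait()] with a single master seed
#' (sub-seeds are derived deterministically).
#'
#' @param n_families,progeny_per_family,n_blocks,n_provenances Trial layout.
#' @param n_chrom,snps_per_chrom,ld_block_len,maf_min Genotype settings.
#' @param region_h2,wavelength_step Spectra settings.
#' @param h2_additive,spectral_share Trait settings.
#' @param seed Master seed.
#' @param ... Further arguments forwarded to [simulate_trait()].
#' @return A list with `pedigree`, `genotypes`, `spectra`, `trait`, `true`.
#' @export
simulate_population <- function(n_families = 49, progeny_per_family = 6,
                                n_blocks = 30, n_provenances = 4,
                                n_chrom = 11, snps_per_chrom = 350,
                                ld_block_len = 10, maf_min = 0.05,
                                region_h2 = c(visible = 0.45, nir = 0.30, swir = 0.20),
                                wavelength_step = 10,
                                h2_additive = 0.35, spectral_share = 0.25,
                                seed = 1, ...) {
  ped <- simulate_pedigree(n_families, progeny_per_family, n_blocks,
                           n_provenances, seed = seed)
  gen <- simulate_genotypes(ped, n_chrom = n_chrom,
                            snps_per_chrom = snps_per_chrom,
                            ld_block_len = ld_block_len, maf_min = maf_min,
                            seed = seed + 101L)
  spc <- simulate_spectra(ped, region_h2 = region_h2, genotypes = gen,
                          wavelength_step = wavelength_step,
                          seed = seed + 202L)
  tr <- simulate_trait(ped, gen, spc, h2_additive = h2_additive,
                       spectral_share = spectral_share,
                       seed = seed + 303L, ...)
  list(pedigree = ped, genotypes = gen, spectra = spc,
       trait = tr$trait, true = tr$true)
}
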