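test_that("LD statistics hit their limiting values on toy haplotypes", {
  # perfectly coupled loci: only AB and ab gametes
  h <- cbind(rep(c(1, 0), each = 10), rep(c(1, 0), each = 10))
  g <- mk_geno(h[1:10, , drop = FALSE], h[11:20, , drop = FALSE])
  ld <- pairwise_ld(g)
  expect_equal(ld$dprime, 1)
  expect_equal(ld$r2, 1)
  expect_gt(ld$lod, 2)
  # independent loci: D' near 0, LOD near 0
  set.seed(2)
  h1 <- cbind(rbinom(400, 1, 0.5), rbinom(400, 1, 0.4))
  h2 <- cbind(rbinom(400, 1, 0.5), rbinom(400, 1, 0.4))
  ld0 <- pairwise_ld(mk_geno(h1, h2))
  expect_lt(ld0$dprime, 0.2)
  expect_lt(ld0$lod, 1)
  # allele relabelling leaves D' unchanged
  ldf <- pairwise_ld(mk_geno(1 - h1[, c(1, 2)], 1 - h2[, c(1, 2)]))
  expect_equal(ldf$dprime, ld0$dprime, tolerance = 1e-12)
  # monomorphic marker pairs are skipped
  hm <- cbind(rep(1L, 20), rbinom(20, 1, 0.5))
  ldm <- pairwise_ld(mk_geno(hm, hm))
  expect_equal(nrow(ldm), 0)
})

test_that("two-locus EM matches the grid-search likelihood oracle on a hand-counted table", {
  # 20 gametes: AB x8, Ab x4, aB x3, ab x5, paired into 10 diploids
  haps <- c(rep("11", 8), rep("10", 4), rep("01", 3), rep("00", 5))
  set.seed(3)
  haps <- sample(haps)
  tohap <- function(ss) do.call(rbind, lapply(ss, function(s)
    as.integer(strsplit(s, "")[[1]])))
  g <- mk_geno(tohap(haps[1:10]), tohap(haps[11:20]))
  g$h1 <- NULL; g$h2 <- NULL            # force the EM path
  ld <- pairwise_ld(g, use_phase = FALSE)
  gi <- g$dosage[, 1]; gj <- g$dosage[, 2]
  pa <- mean(gi) / 2; pb <- mean(gj) / 2
  grid <- seq(max(0, pa + pb - 1) + 1e-6, min(pa, pb) - 1e-6,
              length.out = 20001)
  ll <- vapply(grid, function(p11)
    cyanophen:::genopair_loglik(gi, gj, p11, pa, pb), numeric(1))
  p11_hat <- grid[which.max(ll)]
  dp_oracle <- cyanophen:::unphased_dprime(p11_hat, pa, pb)
  lod_oracle <- (max(ll) -
                   cyanophen:::genopair_loglik(gi, gj, pa * pb, pa, pb)) / log(10)
  expect_lt(abs(ld$dprime - dp_oracle), 1e-3)
  expect_lt(abs(ld$lod - lod_oracle), 1e-3)
  expect_gte(ld$lod, 0)
})

test_that("solid-spine scan equals the exhaustive enumeration oracle", {
  set.seed(10)
  for (rep in 1:6) {
    m <- 40
    Dp <- matrix(runif(m * m, 0.5, 1), m, m)
    Dp <- (Dp + t(Dp)) / 2
    diag(Dp) <- 1
    Lod <- matrix(runif(m * m, 0, 6), m, m)
    Lod <- (Lod + t(Lod)) / 2
    got <- solid_spine_blocks(mk_ld(Dp, Lod))
    want <- spine_oracle(Dp, Lod)
    got_m <- cbind(as.numeric(got$start_idx), as.numeric(got$end_idx))
    expect_equal(unname(got_m), unname(want), ignore_attr = TRUE)
  }
  # three markers in perfect LD form one block
  one <- solid_spine_blocks(mk_ld(matrix(1, 3, 3), matrix(5, 3, 3)))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start_idx, one$end_idx), c(1, 3))
  # no LD, no blocks
  none <- solid_spine_blocks(mk_ld(diag(3), matrix(0, 3, 3)))
  expect_equal(nrow(none), 0)
})

test_that("haplotype design keeps per-block dosage bookkeeping", {
  pop <- small_pop()
  gen <- pop$genotypes
  ld <- pairwise_ld(gen)
  blocks <- solid_spine_blocks(ld)
  expect_gt(nrow(blocks), 0)
  hd <- haplotype_design(gen, blocks)
  expect_equal(nrow(hd$design), nrow(gen$dosage))
  expect_true(all(hd$design %in% 0:2))
  # retained + dropped reference dosages sum to 2 within every block
  for (b in unique(hd$map$block)) {
    cols <- hd$map$column[hd$map$block == b]
    kept <- rowSums(hd$design[, cols, drop = FALSE])
    expect_true(all(kept <= 2))
    rng <- blocks$start_idx[b]:blocks$end_idx[b]
    hap1 <- apply(gen$h1[, rng, drop = FALSE], 1, paste0, collapse = "")
    hap2 <- apply(gen$h2[, rng, drop = FALSE], 1, paste0, collapse = "")
    freq <- sort(table(c(hap1, hap2)) / (2 * nrow(hd$design)), decreasing = TRUE)
    ref <- names(freq)[1]
    ref_dos <- (hap1 == ref) + (hap2 == ref)
    pooled <- setdiff(names(freq)[freq < 0.01], ref)
    pooled_dos <- if (length(pooled)) {
      rowSums(sapply(pooled, function(al) (hap1 == al) + (hap2 == al)))
    } else 0
    expect_true(all(kept + ref_dos + pooled_dos == 2))
  }
  # column count is sum over blocks of (retained alleles - 1)
  expect_equal(ncol(hd$design), nrow(hd$map))
})

test_that("chained EM phasing supports haplotype design for unphased input", {
  pop <- small_pop()
  gen <- pop$genotypes
  ld <- pairwise_ld(gen)
  blocks <- solid_spine_blocks(ld)
  gu <- gen
  gu$h1 <- NULL; gu$h2 <- NULL
  hd <- haplotype_design(gu, blocks[1:5, ])
  expect_true(all(hd$design %in% 0:2))
  for (b in unique(hd$map$block)) {
    cols <- hd$map$column[hd$map$block == b]
    expect_true(all(rowSums(hd$design[, cols, drop = FALSE]) <= 2))
  }
})
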