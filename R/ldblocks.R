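#' Pairwise linkage disequilibrium statistics
#'
#' Computes D', LOD and r2 for intra-chromosome marker pairs within a bp
#' window. With phased input (the synthetic generator stores gametes)
#' haplotype frequencies are counted directly; for unphased dosages they are
#' estimated by the standard two-locus EM over the double-heterozygote
#' ambiguity. `D = p_AB - p_A p_B`; `D' = |D| / D_max`; the LOD score is the
#' log10 likelihood ratio of the estimated haplotype frequencies against
#' linkage equilibrium. Pairs involving a monomorphic marker are skipped.
#'
#' @param genotypes A `cyp_geno` object (phased), or a dosage matrix plus
#'   `map` (unphased; EM used).
#' @param max_pair_distance Maximum bp distance between pair members.
#' @param map Marker map tibble (`chrom`, `pos`) when `genotypes` is a bare
#'   matrix.
#' @param use_phase Use stored gametes when available.
#' @return A tibble of class `cyp_ld`: `chrom`, `i`, `j` (column indices into
#'   the dosage matrix), `pos_i`, `pos_j`, `dprime`, `lod`, `r2`.
#' @export
pairwise_ld <- function(genotypes, max_pair_distance = 5e5, map = NULL,
                        use_phase = TRUE) {
  if (inherits(genotypes, "cyp_geno")) {
    map <- genotypes$map
    phased <- use_phase && !is.null(genotypes$h1)
    H <- if (phased) rbind(genotypes$h1, genotypes$h2) else NULL
    X <- genotypes$dosage
  } else {
    if (is.null(map)) rlang::abort("map required for matrix input",
                                   class = "cyanophen_invalid_argument")
    phased <- FALSE
    X <- as.matrix(genotypes)
  }
  out <- vector("list", length(unique(map$chrom)))
  ci <- 0L
  for (cc in sort(unique(map$chrom))) {
    idx <- which(map$chrom == cc)
    pos <- map$pos[idx]
    m <- length(idx)
    if (m < 2) next
    pairs <- which(outer(pos, pos, function(a, b) b - a) > 0 &
                     outer(pos, pos, function(a, b) abs(b - a)) <= max_pair_distance,
                   arr.ind = TRUE)
    if (!nrow(pairs)) next
    ii <- idx[pairs[, 1]]; jj <- idx[pairs[, 2]]
    if (phased) {
      Hc <- H[, idx, drop = FALSE]
      nh <- nrow(Hc)
      C11 <- crossprod(Hc)          # counts of 1-1 gametes for all pairs
      pA <- colMeans(Hc)
      p11 <- C11[cbind(pairs[, 1], pairs[, 2])] / nh
      pa <- pA[pairs[, 1]]; pb <- pA[pairs[, 2]]
      stats_tab <- ld_from_p11(p11, pa, pb, nh)
    } else {
      stats_tab <- t(vapply(seq_along(ii), function(k) {
        em_ld(X[, ii[k]], X[, jj[k]])
      }, numeric(3)))
      colnames(stats_tab) <- c("dprime", "lod", "r2")
      stats_tab <- tibble::as_tibble(stats_tab)
    }
    keep <- !is.na(stats_tab$dprime)
    ci <- ci + 1L
    out[[ci]] <- tibble::tibble(
      chrom = cc, i = ii, j = jj,
      pos_i = map$pos[ii], pos_j = map$pos[jj],
      dprime = stats_tab$dprime, lod = stats_tab$lod, r2 = stats_tab$r2
    )[keep, ]
  }
  res <- dplyr::bind_rows(out[seq_len(ci)])
  class(res) <- c("cyp_ld", class(res))
  attr(res, "map") <- map
  res
}

# D', r2 and multinomial LOD from haplotype frequency p11 and allele
# frequencies, with nh observed gametes
ld_from_p11 <- function(p11, pa, pb, nh) {
  mono <- pa <= 0 | pa >= 1 | pb <= 0 | pb >= 1
  D <- p11 - pa * pb
  dmax <- ifelse(D >= 0, pmin(pa * (1 - pb), (1 - pa) * pb),
                 pmin(pa * pb, (1 - pa) * (1 - pb)))
  dprime <- ifelse(dmax > 0, abs(D) / dmax, 0)
  dprime <- pmin(dprime, 1)
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  # haplotype class frequencies
  f11 <- p11; f10 <- pa - p11; f01 <- pb - p11; f00 <- 1 - pa - pb + p11
  e11 <- pa * pb; e10 <- pa * (1 - pb); e01 <- (1 - pa) * pb
  e00 <- (1 - pa) * (1 - pb)
  term <- function(f, e) ifelse(f > 0, nh * f * (log10(pmax(f, 1e-300)) - log10(e)), 0)
  lod <- term(f11, e11) + term(f10, e10) + term(f01, e01) + term(f00, e00)
  tibble::tibble(dprime = ifelse(mono, NA_real_, dprime),
                 lod = ifelse(mono, NA_real_, pmax(lod, 0)),
                 r2 = ifelse(mono, NA_real_, r2))
}

# two-locus EM from unphased dosages; returns c(dprime, lod, r2)
em_ld <- function(gi, gj, max_iter = 100, tol = 1e-10) {
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  n <- length(gi)
  pa <- mean(gi) / 2; pb <- mean(gj) / 2
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) return(c(NA_real_, NA_real_, NA_real_))
  # haplotype freqs p11,p10,p01,p00; start at equilibrium
  p11 <- pa * pb
  ndh <- sum(gi == 1 & gj == 1)   # double heterozygotes
  # fixed counts of unambiguous gametes
  n11 <- sum((gi == 2) * (gj == 2) * 2 + (gi == 2) * (gj == 1) + (gi == 1) * (gj == 2))
  n10 <- sum((gi == 2) * (gj == 0) * 2 + (gi == 2) * (gj == 1) + (gi == 1) * (gj == 0))
  n01 <- sum((gi == 0) * (gj == 2) * 2 + (gi == 0) * (gj == 1) + (gi == 1) * (gj == 2))
  n00 <- sum((gi == 0) * (gj == 0) * 2 + (gi == 0) * (gj == 1) + (gi == 1) * (gj == 0))
  for (it in seq_len(max_iter)) {
    p10 <- pa - p11; p01 <- pb - p11; p00 <- 1 - pa - pb + p11
    num <- p11 * p00
    den <- p11 * p00 + p10 * p01
    w <- if (den > 0) num / den else 0.5
    p11_new <- (n11 + w * ndh) / (2 * n)
    p11_new <- min(max(p11_new, max(0, pa + pb - 1) + 1e-12), min(pa, pb) - 1e-12)
    if (abs(p11_new - p11) < tol) { p11 <- p11_new; break }
    p11 <- p11_new
  }
  c(dprime = unphased_dprime(p11, pa, pb),
    lod = unphased_lod(gi, gj, p11, pa, pb),
    r2 = (p11 - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

unphased_dprime <- function(p11, pa, pb) {
  D <- p11 - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb) else min(pa * pb, (1 - pa) * (1 - pb))
  if (dmax <= 0) 0 else min(abs(D) / dmax, 1)
}

# genotype-pair log-likelihood under haplotype freqs (p11, pa, pb)
genopair_loglik <- function(gi, gj, p11, pa, pb) {
  p10 <- pa - p11; p01 <- pb - p11; p00 <- 1 - pa - pb + p11
  h <- c(`11` = p11, `10` = p10, `01` = p01, `00` = p00)
  h <- pmax(h, 1e-300)
  gp <- function(a, b) {
    # probability of unphased genotype pair (a,b), a,b in 0:2
    if (a == 1 && b == 1) return(2 * h["11"] * h["00"] + 2 * h["10"] * h["01"])
    p_g <- switch(paste(a, b),
      "2 2" = h["11"]^2, "2 1" = 2 * h["11"] * h["10"], "2 0" = h["10"]^2,
      "1 2" = 2 * h["11"] * h["01"], "1 0" = 2 * h["10"] * h["00"],
      "0 2" = h["01"]^2, "0 1" = 2 * h["01"] * h["00"], "0 0" = h["00"]^2)
    p_g
  }
  tab <- table(factor(gi, 0:2), factor(gj, 0:2))
  ll <- 0
  for (a in 0:2) for (b in 0:2) {
    cnt <- tab[a + 1, b + 1]
    if (cnt > 0) ll <- ll + cnt * log(gp(a, b))
  }
  as.numeric(ll)
}

unphased_lod <- function(gi, gj, p11, pa, pb) {
  l1 <- genopair_loglik(gi, gj, p11, pa, pb)
  l0 <- genopair_loglik(gi, gj, pa * pb, pa, pb)
  max((l1 - l0) / log(10), 0)
}

#' Solid-spine haplotype blocks
#'
#' Finds maximal contiguous marker ranges `[i..j]` whose end markers are in
#' strong LD with every interior marker (`D'(i,k) >= dprime_min` and
#' `D'(k,j) >= dprime_min` for all interior `k`), scanning each chromosome
#' left to right and taking the longest valid extension from each start.
#' A candidate range is retained only if its mean pairwise D' is at least
#' `dprime_min` and its mean LOD at least `lod_min` (block-summary
#' interpretation of the retention filter); `pairwise = TRUE` instead
#' requires every pair in the range to pass both thresholds.
#'
#' @param ld A `cyp_ld` tibble from [pairwise_ld()].
#' @param dprime_min,lod_min Retention thresholds.
#' @param pairwise Apply the thresholds to every pair instead of the block
#'   summary.
#' @param max_markers Upper bound on markers per block (scan cap).
#' @return A tibble of class `cyp_blocks`: `chrom`, `start_idx`, `end_idx`
#'   (dosage-matrix column indices), `start_pos`, `end_pos`, `n_markers`,
#'   `mean_dprime`, `mean_lod`.
#' @export
solid_spine_blocks <- function(ld, dprime_min = 0.9, lod_min = 2.0,
                               pairwise = FALSE, max_markers = 50) {
  res <- list()
  for (cc in sort(unique(ld$chrom))) {
    sub <- ld[ld$chrom == cc, ]
    mk <- sort(unique(c(sub$i, sub$j)))
    m <- length(mk)
    if (m < 2) next
    li <- match(sub$i, mk); lj <- match(sub$j, mk)
    Dp <- matrix(NA_real_, m, m); Lod <- matrix(NA_real_, m, m)
    Dp[cbind(li, lj)] <- sub$dprime; Dp[cbind(lj, li)] <- sub$dprime
    Lod[cbind(li, lj)] <- sub$lod; Lod[cbind(lj, li)] <- sub$lod
    pos <- rep(NA_real_, m)
    pos[li] <- sub$pos_i; pos[lj] <- sub$pos_j

    i <- 1L
    while (i < m) {
      best_j <- NA_integer_
      jmax <- min(m, i + max_markers - 1L)
      for (j in seq(i + 1L, jmax)) {
        if (spine_valid(Dp, i, j, dprime_min) &&
            block_retained(Dp, Lod, i, j, dprime_min, lod_min, pairwise)) {
          best_j <- j
        }
      }
      if (!is.na(best_j)) {
        rng <- i:best_j
        prs <- utils::combn(rng, 2)
        dvals <- Dp[t(prs)]
        lvals <- Lod[t(prs)]
        res[[length(res) + 1L]] <- tibble::tibble(
          chrom = cc, start_idx = mk[i], end_idx = mk[best_j],
          start_pos = pos[i], end_pos = pos[best_j],
          n_markers = best_j - i + 1L,
          mean_dprime = mean(dvals), mean_lod = mean(lvals)
        )
        i <- best_j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  out <- if (length(res)) dplyr::bind_rows(res) else tibble::tibble(
    chrom = integer(), start_idx = integer(), end_idx = integer(),
    start_pos = numeric(), end_pos = numeric(), n_markers = integer(),
    mean_dprime = numeric(), mean_lod = numeric())
  class(out) <- c("cyp_blocks", class(out))
  out
}

spine_valid <- function(Dp, i, j, t) {
  if (j - i < 2) return(TRUE)    # no interior markers
  ks <- (i + 1L):(j - 1L)
  a <- Dp[i, ks]; b <- Dp[ks, j]
  !anyNA(a) && !anyNA(b) && all(a >= t) && all(b >= t)
}

block_retained <- function(Dp, Lod, i, j, dprime_min, lod_min, pairwise) {
  prs <- utils::combn(i:j, 2)
  d <- Dp[t(prs)]; l <- Lod[t(prs)]
  if (anyNA(d) || anyNA(l)) return(FALSE)
  if (pairwise) all(d >= dprime_min) && all(l >= lod_min)
  else mean(d) >= dprime_min && mean(l) >= lod_min
}

#' Haplotype-allele design matrix
#'
#' Enumerates the haplotype alleles observed in each block, counts per
#' individual copies (0/1/2), pools alleles rarer than `rare_freq` into the
#' reference class, and drops the most frequent (reference) allele per
#' block; within a block the retained plus dropped dosages always sum to 2.
#' Requires phased input (the generator stores gametes); unphased dosages
#' are phased per block by a chained two-locus EM heuristic first.
#'
#' @param genotypes A `cyp_geno`.
#' @param blocks A `cyp_blocks` tibble.
#' @param rare_freq Alleles below this frequency are pooled into the
#'   reference.
#' @return A list of class `cyp_haplo`: `design` (n x H dosage matrix),
#'   `map` (tibble: `column`, `block`, `allele`, `freq`).
#' @export
haplotype_design <- function(genotypes, blocks, rare_freq = 0.01) {
  if (is.null(genotypes$h1)) {
    genotypes <- phase_chained(genotypes)
  }
  n <- nrow(genotypes$dosage)
  cols <- list(); mapr <- list()
  for (b in seq_len(nrow(blocks))) {
    rng <- which(seq_len(ncol(genotypes$dosage)) >= blocks$start_idx[b] &
                   seq_len(ncol(genotypes$dosage)) <= blocks$end_idx[b] &
                   genotypes$map$chrom == blocks$chrom[b])
    if (length(rng) < 2) next
    hap1 <- apply(genotypes$h1[, rng, drop = FALSE], 1, paste0, collapse = "")
    hap2 <- apply(genotypes$h2[, rng, drop = FALSE], 1, paste0, collapse = "")
    freq <- sort(table(c(hap1, hap2)) / (2 * n), decreasing = TRUE)
    common <- names(freq)[freq >= rare_freq]
    if (length(common) < 1) common <- names(freq)[1]
    # rare alleles pooled into the reference (the most frequent allele)
    keep <- setdiff(common, names(freq)[1])
    if (!length(keep)) {
      rlang::warn(sprintf("block %d has a single (or only rare) haplotype: no columns", b))
      next
    }
    for (al in keep) {
      cols[[length(cols) + 1L]] <- (hap1 == al) + (hap2 == al)
      mapr[[length(mapr) + 1L]] <- tibble::tibble(
        block = b, allele = al, freq = as.numeric(freq[al]))
    }
  }
  if (!length(cols)) {
    design <- matrix(numeric(0), nrow = n, ncol = 0)
    rownames(design) <- rownames(genotypes$dosage)
    return(structure(list(design = design,
                          map = tibble::tibble(column = character(),
                                               block = integer(),
                                               allele = character(),
                                               freq = numeric())),
                     class = "cyp_haplo"))
  }
  design <- do.call(cbind, cols)
  map <- dplyr::bind_rows(mapr)
  map$column <- sprintf("blk%03d_%s", map$block, map$allele)
  colnames(design) <- map$column
  rownames(design) <- rownames(genotypes$dosage)
  structure(list(design = design, map = map[, c("column", "block", "allele", "freq")]),
            class = "cyp_haplo")
}

#' @export
print.cyp_haplo <- function(x, ...) {
  cat(sprintf("<cyp_haplo> %d individuals x %d haplotype-allele columns (%d blocks)\n",
              nrow(x$design), ncol(x$design), length(unique(x$map$block))))
  invisible(x)
}

# chained two-locus EM phasing of a dosage-only cyp_geno (per chromosome).
# Greedy: the first heterozygous locus is phased arbitrarily; each further
# locus is oriented to favour the more frequent two-locus haplotype with its
# predecessor (EM-estimated). Adequate for the short, strong-LD blocks the
# design matrix needs.
phase_chained <- function(genotypes) {
  X <- genotypes$dosage
  map <- genotypes$map
  n <- nrow(X); m <- ncol(X)
  h1 <- matrix(0L, n, m, dimnames = dimnames(X))
  h2 <- matrix(0L, n, m, dimnames = dimnames(X))
  for (cc in sort(unique(map$chrom))) {
    idx <- which(map$chrom == cc)
    prev <- NULL
    for (l in idx) {
      g <- X[, l]
      hom <- g != 1
      h1[hom, l] <- as.integer(g[hom] / 2)
      h2[hom, l] <- as.integer(g[hom] / 2)
      het <- which(g == 1)
      if (!length(het)) { prev <- l; next }
      if (is.null(prev)) {
        h1[het, l] <- 1L
      } else {
        st <- em_ld(X[, prev], X[, l])
        D <- NULL
        pa <- mean(X[, prev]) / 2; pb <- mean(g) / 2
        # orient each double-het to the coupling implied by sign of D
        p11 <- pa * pb
        if (!anyNA(st)) {
          # recover signed D from dprime is lossy; re-run EM to get p11
          p11 <- em_p11(X[, prev], X[, l])
        }
        coupling <- p11 >= pa * pb
        for (i in het) {
          if (X[i, prev] == 1) {
            # align allele 1 with whichever previous gamete has allele 1
            if (coupling) {
              if (h1[i, prev] == 1) h1[i, l] <- 1L else h2[i, l] <- 1L
            } else {
              if (h1[i, prev] == 1) h2[i, l] <- 1L else h1[i, l] <- 1L
            }
          } else {
            h1[i, l] <- 1L
          }
        }
      }
      prev <- l
    }
  }
  genotypes$h1 <- h1
  genotypes$h2 <- h2
  genotypes
}

em_p11 <- function(gi, gj) {
  pa <- mean(gi) / 2; pb <- mean(gj) / 2
  st <- tryCatch({
    p11 <- pa * pb
    n <- length(gi)
    ndh <- sum(gi == 1 & gj == 1)
    n11 <- sum((gi == 2) * (gj == 2) * 2 + (gi == 2) * (gj == 1) + (gi == 1) * (gj == 2))
    for (it in 1:100) {
      p10 <- pa - p11; p01 <- pb - p11; p00 <- 1 - pa - pb + p11
      den <- p11 * p00 + p10 * p01
      w <- if (den > 0) p11 * p00 / den else 0.5
      p11n <- (n11 + w * ndh) / (2 * n)
      p11n <- min(max(p11n, max(0, pa + pb - 1) + 1e-12), min(pa, pb) - 1e-12)
      if (abs(p11n - p11) < 1e-10) { p11 <- p11n; break }
      p11 <- p11n
    }
    p11
  }, error = function(e) pa * pb)
  st
}
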