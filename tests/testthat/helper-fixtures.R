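# shared fixtures and independent oracles, all built in code

# wrap phased haplotype matrices as a genotype object
mk_geno <- function(h1, h2, chrom = 1L, spacing = 1000) {
  m <- ncol(h1)
  ids <- sprintf("i%03d", seq_len(nrow(h1)))
  rownames(h1) <- rownames(h2) <- ids
  g <- structure(list(
    dosage = h1 + h2,
    map = tibble::tibble(marker = sprintf("m%d", seq_len(m)),
                         chrom = chrom, pos = seq_len(m) * spacing,
                         freq = colMeans(h1 + h2) / 2)
  ), class = "cyp_geno")
  g$h1 <- h1
  g$h2 <- h2
  g
}

# wrap symmetric D'/LOD matrices as an LD table
mk_ld <- function(Dp, Lod, pos = seq_len(nrow(Dp)) * 1000) {
  m <- nrow(Dp)
  prs <- t(utils::combn(m, 2))
  tb <- tibble::tibble(chrom = 1L, i = prs[, 1], j = prs[, 2],
                       pos_i = pos[prs[, 1]], pos_j = pos[prs[, 2]],
                       dprime = Dp[prs], lod = Lod[prs], r2 = Dp[prs]^2)
  class(tb) <- c("cyp_ld", class(tb))
  tb
}

# exhaustive-enumeration oracle for solid-spine blocks (independent of the
# scanning implementation): enumerate every valid+retained range, then apply
# the same greedy leftmost-longest selection
spine_oracle <- function(Dp, Lod, t = 0.9, lmin = 2) {
  m <- nrow(Dp)
  valid <- function(i, j) {
    if (j - i >= 2) {
      for (k in (i + 1):(j - 1)) {
        if (is.na(Dp[i, k]) || is.na(Dp[k, j]) ||
            Dp[i, k] < t || Dp[k, j] < t) return(FALSE)
      }
    }
    prs <- t(utils::combn(i:j, 2))
    d <- Dp[prs]; l <- Lod[prs]
    !anyNA(d) && !anyNA(l) && mean(d) >= t && mean(l) >= lmin
  }
  cand <- list()
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    if (valid(i, j)) cand[[length(cand) + 1L]] <- c(i, j)
  }
  blocks <- list()
  cur <- 1L
  while (cur < m) {
    ends <- vapply(cand, function(cc) if (cc[1] == cur) cc[2] else NA_real_,
                   numeric(1))
    ends <- ends[!is.na(ends)]
    if (length(ends)) {
      blocks[[length(blocks) + 1L]] <- c(cur, max(ends))
      cur <- as.integer(max(ends)) + 1L
    } else {
      cur <- cur + 1L
    }
  }
  if (length(blocks)) do.call(rbind, blocks) else matrix(0, 0, 2)
}

# recursive-kinship (path-counting) oracle for additive relationships,
# independent of the tabular recurrence
kinship_oracle <- function(pedigree) {
  ids <- pedigree$id
  s <- match(pedigree$sire, ids)
  d <- match(pedigree$dam, ids)
  n <- length(ids)
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + phi(ifelse(is.na(s[i]), 0, s[i]), ifelse(is.na(d[i]), 0, d[i])))
    } else {
      # j is the younger (later) individual by topological order
      0.5 * (phi(i, ifelse(is.na(s[j]), 0, s[j])) +
               phi(i, ifelse(is.na(d[j]), 0, d[j])))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- A[j, i] <- 2 * phi(i, j)
  }
  A
}

# random multi-generation pedigree in topological order
random_pedigree <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("x%02d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > 2 && stats::runif(1) < 0.75) {
      pp <- sample(i - 1L, 2)
      sire[i] <- ids[pp[1]]
      if (stats::runif(1) < 0.8) dam[i] <- ids[pp[2]]
    }
  }
  tibble::tibble(id = ids, sire = sire, dam = dam,
                 family = "f", provenance = "p",
                 block = 1L, generation = as.integer(!is.na(sire)))
}

# small shared population, built once per test run
small_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_population(
        n_families = 25, progeny_per_family = 6, n_blocks = 10,
        n_provenances = 2, n_chrom = 3, snps_per_chrom = 60,
        wavelength_step = 10, seed = 42)
    }
    cache
  }
})
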