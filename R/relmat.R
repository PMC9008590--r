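#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the expected additive relationship matrix A by the tabular
#' recurrence: for individual `i` with parents `s`, `d` (unknown parents
#' contribute zero relationship and no inbreeding),
#' `a_ii = 1 + a_sd / 2` and `a_ij = (a_js + a_jd) / 2` for earlier `j`.
#' Founders are assumed unrelated and non-inbred.
#'
#' @param pedigree Pedigree tibble (`id`, `sire`, `dam`; `NA` = unknown),
#'   parents before offspring.
#' @return An n x n `cyp_relmat` matrix (kind `"pedigree"`), dimnames = ids.
#' @examples
#' ped <- simulate_pedigree(3, 2, 2, 1, seed = 1)
#' a_matrix(ped)["D01", "F01_O01"] # parent-offspring = 0.5
#' @export
a_matrix <- function(pedigree) {
  check_pedigree_order(pedigree)
  ids <- pedigree$id
  n <- length(ids)
  s <- match(pedigree$sire, ids)
  d <- match(pedigree$dam, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    asd <- if (!is.na(s[i]) && !is.na(d[i])) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rel <- 0.5 * ((if (!is.na(s[i])) A[j, s[i]] else 0) +
                      (if (!is.na(d[i])) A[j, d[i]] else 0))
      A[j, i] <- rel
      A[i, j] <- rel
    }
  }
  new_relmat(A, kind = "pedigree")
}

#' Gene-dropping Monte-Carlo estimate of additive relationships
#'
#' Drops uniquely labelled founder alleles through the pedigree `nreps`
#' times (unknown parents contribute a fresh unrelated allele) and counts
#' identity-by-descent sharing; the per-replicate sharing score averages to
#' the additive relationship. Serves as an independent stochastic oracle for
#' [a_matrix()].
#'
#' @param pedigree Pedigree tibble, parents before offspring.
#' @param nreps Number of gene-dropping replicates.
#' @return List with matrices `mean` (estimated relationships) and `se`
#'   (Monte-Carlo standard errors).
#' @export
gene_drop_oracle <- function(pedigree, nreps = 1e6) {
  check_pedigree_order(pedigree)
  ids <- pedigree$id
  s <- match(pedigree$sire, ids)
  d <- match(pedigree$dam, ids)
  out <- gene_drop_relationship(ifelse(is.na(s), 0L, s),
                                ifelse(is.na(d), 0L, d), as.integer(nreps))
  dimnames(out$mean) <- dimnames(out$se) <- list(ids, ids)
  out
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 scaling with observed allele frequencies:
#' `G = W W' / (2 * sum(p * (1 - p)))` where `W` is the dosage matrix with
#' column means `2p` subtracted. Under Hardy-Weinberg founders the mean
#' diagonal is close to 1, putting G on the same scale as the pedigree A.
#'
#' @param genotypes A `cyp_geno` object or a numeric dosage matrix (0/1/2,
#'   rownames = ids), no missing values.
#' @return An n x n `cyp_relmat` matrix (kind `"genomic"`).
#' @export
g_matrix <- function(genotypes) {
  X <- if (inherits(genotypes, "cyp_geno")) genotypes$dosage else as.matrix(genotypes)
  if (anyNA(X)) {
    rlang::abort("dosage matrix must have no missing values",
                 class = "cyanophen_invalid_input")
  }
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) {
    rlang::abort("need at least 2 polymorphic markers",
                 class = "cyanophen_invalid_input")
  }
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(X, 2, 2 * p)
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(X), rownames(X))
  new_relmat(G, kind = "genomic")
}

new_relmat <- function(K, kind) {
  structure(K, class = c("cyp_relmat", class(matrix())), kind = kind)
}

#' @export
print.cyp_relmat <- function(x, ...) {
  cat(sprintf("<cyp_relmat kind=%s> %d x %d, mean diag %.3f\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

#' Population-structure covariates
#'
#' Either treatment-coded group indicators (reference level dropped) from a
#' vector of group labels, or the leading principal components of a centered
#' relationship matrix. These play the role of the structure covariates `Q`
#' in the prediction models; in synthetic runs the structure groups are the
#' provenances.
#'
#' @param source A character/factor vector of group labels, or a
#'   `cyp_relmat`.
#' @param n_components Number of principal components in PC mode.
#' @param ids Individual ids (required for label mode if `source` unnamed).
#' @return An n x q numeric matrix (possibly zero columns) with named
#'   columns, rows aligned to the input order.
#' @export
structure_covariates <- function(source, n_components = 2, ids = NULL) {
  if (inherits(source, "cyp_relmat")) {
    K <- unclass(source)
    n <- nrow(K)
    Jc <- diag(n) - matrix(1 / n, n, n)
    Kc <- Jc %*% K %*% Jc
    ev <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
    r <- min(n_components, n)
    Q <- ev$vectors[, seq_len(r), drop = FALSE]
    dimnames(Q) <- list(rownames(K), sprintf("PC%d", seq_len(r)))
    return(Q)
  }
  labels <- as.character(source)
  if (is.null(ids)) ids <- names(source)
  lv <- sort(unique(labels))
  if (length(lv) < 2) {
    rlang::warn("single structure group: no covariate columns")
    Q <- matrix(numeric(0), nrow = length(labels), ncol = 0)
    rownames(Q) <- ids
    return(Q)
  }
  f <- factor(labels, levels = lv)
  Q <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(Q) <- paste0("group_", lv[-1])
  rownames(Q) <- ids
  Q
}

#' Eigen factor loadings of a relationship matrix
#'
#' Factorizes a symmetric PSD matrix `K = U L U'` and returns
#' `L = U_r diag(sqrt(lambda_r))` over the eigenvalues above
#' `tol * lambda_max` (numerically negative modes are dropped), so that
#' `L L' ~ K`. A random effect `g ~ N(0, K sigma^2)` is then fitted as
#' `g = L u` with iid `u ~ N(0, sigma^2)`, which lets the regression
#' samplers handle kinship effects on the same code path as marker and
#' spectral regressors.
#'
#' @param K A `cyp_relmat` (or symmetric matrix).
#' @param tol Relative eigenvalue truncation tolerance.
#' @return Object of class `cyp_loadings`: `L` (n x r), `values`, `kind`.
#' @export
decompose <- function(K, tol = 1e-8) {
  kind <- attr(K, "kind") %||% "custom"
  K <- unclass(as.matrix(K))
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    rlang::abort("K must be symmetric", class = "cyanophen_invalid_input")
  }
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- ev$values > tol * max(ev$values)
  L <- ev$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev$values[keep]),
                                                 nrow = sum(keep))
  rownames(L) <- rownames(K)
  colnames(L) <- sprintf("u%d", seq_len(ncol(L)))
  structure(list(L = L, values = ev$values[keep], kind = kind),
            class = "cyp_loadings")
}

#' @export
print.cyp_loadings <- function(x, ...) {
  cat(sprintf("<cyp_loadings kind=%s> %d x %d (rank kept)\n",
              x$kind, nrow(x$L), ncol(x$L)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
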