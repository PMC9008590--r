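#' Heritability from variance components
#'
#' Narrow-sense (pedigree) or genomic heritability as the ratio of the
#' genetic variance to genetic-plus-residual variance; structure and
#' provenance variance is deliberately excluded from the denominator.
#'
#' @param var_g Genetic variance (>= 0).
#' @param var_e Residual variance (> 0 unless `var_g > 0`).
#' @return `var_g / (var_g + var_e)`.
#' @examples
#' h2_from_varcomps(2, 3) # 0.4
#' @export
h2_from_varcomps <- function(var_g, var_e) {
  if (any(var_g < 0) || any(var_e < 0)) {
    rlang::abort("variances must be non-negative", class = "cyanophen_invalid_argument")
  }
  if (any(var_g + var_e == 0)) {
    rlang::abort("var_g and var_e cannot both be zero", class = "cyanophen_invalid_input")
  }
  var_g / (var_g + var_e)
}

#' Estimate heritability of one response from a kinship
#'
#' Fits `y = intercept + covariates + Z g + e`, `g ~ N(0, K sigma2_g)`, via
#' the eigen-loadings of K and returns the posterior mean and SD of
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)`. The variance priors default to a
#' weakly-informative setting (df 2, prior variance share 0.1): the
#' scaled-inverse-chi-square left tail otherwise suppresses small variance
#' ratios and inflates h2 estimates near zero.
#'
#' @param y Numeric response.
#' @param loadings `cyp_loadings` rows aligned to `y`.
#' @param covariates Optional fixed covariates.
#' @param mcmc Chain settings.
#' @param df,r2 Genetic-variance prior degrees of freedom and prior share.
#' @return List with `mean`, `sd` and the underlying `fit`.
#' @export
estimate_h2 <- function(y, loadings, covariates = NULL,
                        mcmc = mcmc_settings(6000, 1500, 5, seed = 1),
                        df = 2, r2 = 0.1) {
  L <- if (inherits(loadings, "cyp_loadings")) loadings$L else as.matrix(loadings)
  fit <- fit_bayes(scale(y)[, 1], fixed = covariates,
                   random = list(gen = bayes_block(L, "BRR", df = df, r2 = r2)),
                   df_e = df, mcmc = mcmc)
  out <- h2_posterior(fit, "gen")
  out$fit <- fit
  out
}

#' Per-wavelength heritability profile
#'
#' Fits, independently for every band, the single-kinship animal model
#' `band = intercept + covariates + Z g + e` with `g ~ N(0, K sigma2_g)`
#' through the eigen-loadings of K, and assembles the posterior-mean
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)` into a profile. The kinship may
#' be the pedigree A (narrow-sense profile) or the genomic G (genomic
#' profile). Bands are processed independently, so results do not depend on
#' band order; each band's chain seed is derived from the base seed and the
#' band's wavelength.
#'
#' @param spectra A `cyp_spectra` object, `cyp_processed`, or matrix plus
#'   `wavelength`.
#' @param loadings `cyp_loadings` of the relationship matrix (rows must
#'   cover the spectra individuals).
#' @param covariates Optional fixed covariates (block design, structure or
#'   provenance indicators), rows aligned to spectra.
#' @param mcmc Chain settings; profiles use short chains by default since
#'   each band is a small model.
#' @param ids Restrict to these individuals (default: rows shared by
#'   spectra and loadings).
#' @return A tibble of class `cyp_h2profile`: `wavelength`, `h2`, `sd`,
#'   `kind`, `region`.
#' @export
wavelength_h2_profile <- function(spectra, loadings, covariates = NULL,
                                  mcmc = mcmc_settings(4000, 1000, 2, seed = 1),
                                  ids = NULL) {
  if (inherits(spectra, "cyp_spectra")) {
    X <- spectra$reflectance; wl <- spectra$wavelength
  } else if (inherits(spectra, "cyp_processed")) {
    X <- spectra$values; wl <- spectra$wavelength
  } else {
    X <- as.matrix(spectra)
    wl <- as.numeric(sub("wl_", "", colnames(X)))
  }
  ids <- ids %||% intersect(rownames(X), rownames(loadings$L))
  X <- X[ids, , drop = FALSE]
  L <- loadings$L[ids, , drop = FALSE]
  if (!is.null(covariates)) covariates <- as.matrix(covariates)[ids, , drop = FALSE]
  kind <- if (loadings$kind == "pedigree") "pedigree" else "genomic"

  res <- purrr::map(seq_along(wl), function(k) {
    y <- X[, k]
    if (stats::sd(y) < 1e-12) {
      return(tibble::tibble(wavelength = wl[k], h2 = NA_real_, sd = NA_real_,
                            flag = "zero-variance"))
    }
    est <- estimate_h2(
      y, loadings = L, covariates = covariates,
      mcmc = mcmc_settings(mcmc$iterations, mcmc$burnin, mcmc$thin,
                           seed = (mcmc$seed + round(wl[k])) %% .Machine$integer.max)
    )
    tibble::tibble(wavelength = wl[k], h2 = est$mean, sd = est$sd, flag = "ok")
  })
  out <- dplyr::bind_rows(res)
  out$kind <- kind
  out$region <- spectral_region(out$wavelength)
  class(out) <- c("cyp_h2profile", class(out))
  out
}

#' Heritability of spectral reflectance indices
#'
#' Applies the same single-kinship animal model to each index column and
#' reports the posterior mean and SD of h2 per index.
#'
#' @param sri Tibble from [compute_sri()] (`id` + index columns).
#' @param loadings,covariates,mcmc As in [wavelength_h2_profile()].
#' @return A tibble: `index`, `h2`, `sd`, `kind`.
#' @export
sri_h2 <- function(sri, loadings, covariates = NULL,
                   mcmc = mcmc_settings(6000, 1500, 2, seed = 1)) {
  ids <- intersect(sri$id, rownames(loadings$L))
  sri <- sri[match(ids, sri$id), ]
  L <- loadings$L[ids, , drop = FALSE]
  if (!is.null(covariates)) covariates <- as.matrix(covariates)[ids, , drop = FALSE]
  kind <- if (loadings$kind == "pedigree") "pedigree" else "genomic"
  cols <- setdiff(names(sri), "id")
  res <- purrr::map(seq_along(cols), function(k) {
    y <- sri[[cols[k]]]
    if (anyNA(y) || stats::sd(y) < 1e-12) {
      return(tibble::tibble(index = cols[k], h2 = NA_real_, sd = NA_real_))
    }
    # one shared chain seed: identical columns get identical estimates
    est <- estimate_h2(y, loadings = L, covariates = covariates, mcmc = mcmc)
    tibble::tibble(index = cols[k], h2 = est$mean, sd = est$sd)
  })
  out <- dplyr::bind_rows(res)
  out$kind <- kind
  out
}

#' Plot a heritability profile
#'
#' h2 against wavelength with the visible / NIR / SWIR regions annotated.
#'
#' @param object A `cyp_h2profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyp_h2profile <- function(object, ...) {
  regions <- tibble::tibble(
    region = c("visible", "NIR", "SWIR"),
    xmin = c(400, 700, 1400), xmax = c(700, 1400, 2400)
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavelength, y = .data$h2,
                                       colour = .data$kind)) +
    ggplot2::geom_rect(data = regions, inherit.aes = FALSE, alpha = 0.08,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = expression(h^2),
                  colour = NULL, fill = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
plot.cyp_h2profile <- function(x, ...) print(autoplot(x, ...))

#' Plot reflectance spectra
#' @param object A `cyp_spectra` object.
#' @param n_curves Number of individual curves to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyp_spectra <- function(object, n_curves = 30, ...) {
  take <- seq_len(min(n_curves, nrow(object$reflectance)))
  df <- tidyr::pivot_longer(as_tibble(object)[take, ],
                            -"id", names_to = "band", values_to = "reflectance")
  df$wavelength <- as.numeric(sub("wl_", "", df$band))
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$reflectance,
                                   group = .data$id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance") +
    ggplot2::theme_minimal()
}
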