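#' Tidy a fitted Bayesian model
#'
#' @param x A `cyp_fit`.
#' @param what `"varcomp"` (posterior variance components, default),
#'   `"effects"` (regressor effects with inclusion frequencies) or
#'   `"fixed"` (fixed-effect coefficients).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cyp_fit <- function(x, what = c("varcomp", "effects", "fixed"), ...) {
  what <- match.arg(what)
  if (what == "varcomp") {
    vc <- x$varcomp_samples
    tb <- tibble::tibble(
      term = c(colnames(vc), "sigma2_e"),
      estimate = c(colMeans(vc), mean(x$sige_samples)),
      std_error = c(apply(vc, 2, stats::sd), stats::sd(x$sige_samples))
    )
    pi_mean <- colMeans(x$pi_samples)
    tb$pi <- c(pi_mean, NA_real_)
    return(tb)
  }
  if (what == "fixed") {
    return(tibble::tibble(term = names(x$fixed_mean),
                          estimate = unname(x$fixed_mean),
                          std_error = unname(x$fixed_sd)))
  }
  purrr::map_dfr(x$block_names, function(b) {
    tibble::tibble(
      block = b,
      term = colnames(x$designs[[b]]) %||% sprintf("%s_%d", b, seq_along(x$effect_mean[[b]])),
      estimate = x$effect_mean[[b]],
      std_error = x$effect_sd[[b]],
      inclusion = x$inclusion[[b]]
    )
  })
}

#' One-row summary of a fitted Bayesian model
#'
#' @param x A `cyp_fit`.
#' @param ... Unused.
#' @return A tibble with DIC, effective parameter count, residual variance
#'   and chain bookkeeping.
#' @export
glance.cyp_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, dic = x$dic, p_d = x$pD, d_bar = x$d_bar,
    sigma2_e = mean(x$sige_samples),
    n_blocks = length(x$block_names), n_saved = x$nsave,
    iterations = x$mcmc$iterations, burnin = x$mcmc$burnin, thin = x$mcmc$thin
  )
}

#' @export
tidy.cyp_cv <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.cyp_cv <- function(x, ...) {
  tibble::tibble(model = x$model[1], engine = x$engine[1],
                 mean_pa = attr(x, "mean_pa"), k = nrow(x))
}
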