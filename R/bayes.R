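#' MCMC settings
#'
#' Desk-scale default chains (20,000 iterations, 4,000 burn-in, thin 5) keep
#' a full model fit in the low seconds; [mcmc_paper()] gives the long-chain
#' preset (1,000,000 / 100,000 / 50) used for production-scale runs.
#'
#' @param iterations,burnin,thin Chain length, burn-in and thinning.
#' @param seed Integer seed; chains are bit-reproducible given a seed.
#' @return A list of class `cyp_mcmc`.
#' @export
mcmc_settings <- function(iterations = 20000, burnin = 4000, thin = 5, seed = 1) {
  if (burnin >= iterations) {
    rlang::abort("burnin must be smaller than iterations",
                 class = "cyanophen_invalid_argument")
  }
  if (thin < 1) rlang::abort("thin must be >= 1", class = "cyanophen_invalid_argument")
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "cyp_mcmc")
}

#' @rdname mcmc_settings
#' @export
mcmc_paper <- function(seed = 1) mcmc_settings(1e6, 1e5, 50, seed)

#' Specify a regressor block for the Bayesian engine
#'
#' @param X Design matrix (n x p). For kinship random effects pass the eigen
#'   loadings from [decompose()] (use `$L`); the Gaussian (BRR) prior on the
#'   loading scores is then exactly `g ~ N(0, K sigma^2)`.
#' @param prior One of `"BRR"`, `"BayesB"`, `"BayesC"`. BRR shrinks all
#'   effects with one common variance; Bayes B gives each regressor its own
#'   variance plus a point mass at zero; Bayes C combines a common variance
#'   with the point mass.
#' @param df,scale Scaled-inverse-chi-square prior degrees of freedom and
#'   scale for the effect variance(s). `scale = NULL` picks the scale so the
#'   prior mode implies the block explains its share of `r2` of the response
#'   variance (see [fit_bayes()]).
#' @param r2 Prior variance share used when `scale` is `NULL` (defaults to an
#'   equal split of 0.5 across random blocks, set inside [fit_bayes()]).
#' @param var_fixed,var0 Fix the effect variance at `var0` instead of
#'   sampling it (used for closed-form checks).
#' @param pi Inclusion probability, i.e. the prior probability that a
#'   regressor has a nonzero effect (Bayes B/C). The complementary
#'   probability is the chance the effect is exactly zero. Default: estimated
#'   with a Beta(5, 5) full conditional (prior mean 0.5, prior weight 10).
#' @param pi_fixed If `TRUE`, hold `pi` at its value instead of sampling.
#' @return A list describing the block.
#' @export
bayes_block <- function(X, prior = c("BRR", "BayesB", "BayesC"),
                        df = 5, scale = NULL, r2 = NULL,
                        var_fixed = FALSE, var0 = 1,
                        pi = 0.5, pi_fixed = FALSE) {
  prior <- match.arg(prior)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  list(X = X, prior = prior, df = df, scale = scale, r2 = r2,
       var_fixed = var_fixed, var0 = var0, pi = pi, pi_fixed = pi_fixed)
}

#' Fit a multi-block Bayesian linear model by Gibbs sampling
#'
#' The engine behind all prediction models: a Gaussian linear model
#' `y = F b + sum_b X_b m_b + e` with flat priors on the fixed columns `F`
#' and BRR / Bayes B / Bayes C priors on each regressor block. Effect
#' variances get scaled-inverse-chi-square full conditionals, Bayes B/C
#' inclusion indicators the Bernoulli conditional with the effect integrated
#' out, and the inclusion probability a Beta full conditional when estimated.
#'
#' Default hyperparameters follow the whole-genome-regression heuristic:
#' `df = 5` for every variance prior, and the prior scale chosen so the
#' prior mode implies the block explains an equal share of 50% of the
#' response variance (divided by the prior inclusion probability for
#' Bayes B/C); the residual prior mode is set at 50% of the response
#' variance.
#'
#' @param y Numeric response (no missing values).
#' @param fixed Fixed-effect design matrix (an intercept column is prepended
#'   automatically unless one is present), or `NULL` for intercept only.
#' @param random Named list of blocks built with [bayes_block()].
#' @param mcmc [mcmc_settings()].
#' @param df_e,scale_e Residual variance prior; `scale_e = NULL` uses the
#'   heuristic above.
#' @param sige_fixed,sige0 Fix the residual variance (closed-form checks).
#' @param save_effects Keep the thinned effect samples (memory-heavy; only
#'   for small models / diagnostics).
#' @return Object of class `cyp_fit`; see [tidy.cyp_fit()], [glance.cyp_fit()],
#'   [variance_partition()], [dic()].
#' @export
fit_bayes <- function(y, fixed = NULL, random = list(),
                      mcmc = mcmc_settings(),
                      df_e = 5, scale_e = NULL,
                      sige_fixed = FALSE, sige0 = 1,
                      save_effects = FALSE) {
  y <- as.numeric(y)
  if (anyNA(y) || any(!is.finite(y))) {
    rlang::abort("response must be finite and complete",
                 class = "cyanophen_invalid_input")
  }
  n <- length(y)
  vy <- stats::var(y)
  Xf <- build_fixed(fixed, n)
  nb <- length(random)
  if (nb > 0 && is.null(names(random))) names(random) <- paste0("b", seq_len(nb))

  blocks <- lapply(random, function(bl) {
    prior_code <- match(bl$prior, c("BRR", "BayesB", "BayesC")) - 1L
    r2b <- bl$r2 %||% (0.5 / max(nb, 1))
    Sb <- bl$scale
    if (is.null(Sb)) {
      msx <- sum(apply(bl$X, 2, stats::var))
      msx <- max(msx, 1e-12)
      Sb <- vy * r2b * (bl$df + 2) / (bl$df * msx)
      if (prior_code > 0) Sb <- Sb / bl$pi
    }
    list(X = bl$X, prior = prior_code, df = bl$df, S = Sb,
         var_fixed = bl$var_fixed, var0 = bl$var0,
         pi_est = (prior_code > 0) && !bl$pi_fixed,
         pi0 = bl$pi, pi_a = 5, pi_b = 5)
  })
  S_e <- scale_e %||% (vy * 0.5 * (df_e + 2) / df_e)

  set.seed(mcmc$seed)
  raw <- gibbs_sampler(y, Xf, unname(blocks), df_e, S_e,
                       sige_fixed, sige0,
                       mcmc$iterations, mcmc$burnin, mcmc$thin, save_effects)

  block_names <- names(random)
  colnames(raw$varcomp) <- block_names
  colnames(raw$pi) <- block_names
  colnames(raw$var_eta) <- block_names
  colnames(raw$eta_block_mean) <- block_names
  names(raw$effect_mean) <- block_names
  names(raw$effect_sd) <- block_names
  names(raw$inclusion) <- block_names
  names(raw$fixed_mean) <- colnames(Xf)
  names(raw$fixed_sd) <- colnames(Xf)

  # DIC: posterior-mean deviance minus deviance at the posterior mean
  sige_hat <- mean(raw$sige)
  eta_hat <- raw$eta_mean
  d_hat <- n * log(2 * pi * sige_hat) + sum((y - eta_hat)^2) / sige_hat
  d_bar <- mean(raw$deviance)
  dic_val <- 2 * d_bar - d_hat

  structure(list(
    y = y, n = n, fixed_names = colnames(Xf),
    block_names = block_names,
    priors = vapply(random, function(b) b$prior, character(1)),
    fixed_mean = raw$fixed_mean, fixed_sd = raw$fixed_sd,
    effect_mean = raw$effect_mean, effect_sd = raw$effect_sd,
    inclusion = raw$inclusion,
    varcomp_samples = raw$varcomp, pi_samples = raw$pi,
    sige_samples = as.numeric(raw$sige),
    deviance_samples = as.numeric(raw$deviance),
    var_eta_samples = raw$var_eta,
    eta_mean = as.numeric(raw$eta_mean),
    eta_block_mean = raw$eta_block_mean,
    effect_samples = if (save_effects) raw$effect_samples else NULL,
    dic = dic_val, d_bar = d_bar, d_hat = d_hat, pD = d_bar - d_hat,
    mcmc = mcmc, nsave = raw$nsave,
    designs = lapply(random, function(b) b$X), Xf = Xf
  ), class = "cyp_fit")
}

build_fixed <- function(fixed, n) {
  if (is.null(fixed)) {
    Xf <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    Xf <- as.matrix(fixed)
    has_const <- any(apply(Xf, 2, function(cc) stats::sd(cc) < 1e-12 & cc[1] != 0))
    if (!has_const) {
      Xf <- cbind(`(Intercept)` = 1, Xf)
    }
  }
  storage.mode(Xf) <- "double"
  Xf
}

#' @export
print.cyp_fit <- function(x, ...) {
  cat(sprintf("<cyp_fit> n = %d, blocks: %s; DIC = %.2f (pD = %.1f), %d saved samples\n",
              x$n,
              if (length(x$block_names)) {
                paste(sprintf("%s[%s]", x$block_names, x$priors), collapse = ", ")
              } else "(none)",
              x$dic, x$pD, x$nsave))
  invisible(x)
}

#' Deviance information criterion of a fit
#'
#' `DIC = 2 * mean(D_saved) - D(posterior-mean predictor, posterior-mean
#' residual variance)`, with `D = -2 sum log N(y_i | eta_i, sigma2_e)`
#' (conditional, residual-level likelihood). Lower is better; differences
#' above 10 are conventionally treated as decisive support.
#'
#' @param fit A `cyp_fit`.
#' @return A single number.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "cyp_fit"))
  fit$dic
}

#' Per-block percent of phenotypic variance (PV)
#'
#' For each regressor block, 100 times the posterior mean of the variance
#' (over individuals) of the block's linear predictor, divided by the
#' variance of the response; the residual share is reported as the
#' remainder.
#'
#' @param fit A `cyp_fit`.
#' @return A tibble with `block` and `pv` (percent).
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "cyp_fit"))
  vy <- stats::var(fit$y)
  if (vy <= 0) {
    rlang::abort("response has zero variance", class = "cyanophen_invalid_input")
  }
  pv <- 100 * colMeans(fit$var_eta_samples) / vy
  tibble::tibble(
    block = c(names(pv), "residual"),
    pv = c(unname(pv), max(0, 100 - sum(pv)))
  )
}

#' Posterior-mean heritability from a fit
#'
#' Computes `h2 = s2_block / (s2_block + s2_e)` per saved sample for a named
#' (BRR/kinship) block and summarizes the posterior. Structure and
#' provenance fixed effects are excluded from the denominator, matching the
#' narrow-sense and genomic heritability definitions used for per-band
#' profiles.
#'
#' @param fit A `cyp_fit`.
#' @param block Name of the random block carrying the genetic variance.
#' @return A list with `mean` and `sd` of the posterior h2 samples.
#' @export
h2_posterior <- function(fit, block) {
  stopifnot(inherits(fit, "cyp_fit"))
  s2g <- fit$varcomp_samples[, block]
  h2 <- s2g / (s2g + fit$sige_samples)
  list(mean = mean(h2), sd = stats::sd(h2))
}

#' Predict from a fitted multi-block model
#'
#' @param object A `cyp_fit`.
#' @param newdata Named list: optionally `fixed` (matrix, same columns as the
#'   fitted fixed design, intercept added if absent) and one design matrix
#'   per random block (rows = individuals to predict). For kinship blocks
#'   pass the corresponding rows of the eigen loadings, which propagates
#'   relationship information to unphenotyped individuals.
#' @param ... Unused.
#' @return Numeric vector of posterior-mean predictions.
#' @export
predict.cyp_fit <- function(object, newdata, ...) {
  nr <- NULL
  eta <- NULL
  add <- function(e, v) if (is.null(e)) v else e + v
  if (!is.null(newdata$fixed)) {
    Xf <- as.matrix(newdata$fixed)
    if (ncol(Xf) == length(object$fixed_mean) - 1) Xf <- cbind(1, Xf)
    eta <- add(eta, as.numeric(Xf %*% object$fixed_mean))
    nr <- nrow(Xf)
  }
  for (b in object$block_names) {
    if (!is.null(newdata[[b]])) {
      Xb <- as.matrix(newdata[[b]])
      eta <- add(eta, as.numeric(Xb %*% object$effect_mean[[b]]))
      nr <- nr %||% nrow(Xb)
    }
  }
  if (is.null(eta)) rlang::abort("newdata provides no design blocks")
  if (is.null(newdata$fixed)) eta <- eta + object$fixed_mean[["(Intercept)"]]
  eta
}
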