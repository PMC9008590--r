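test_that("seeded chains are bit-reproducible", {
  set.seed(1)
  X <- matrix(rnorm(60 * 10), 60)
  y <- as.numeric(X %*% rnorm(10, 0, 0.5) + rnorm(60))
  f1 <- fit_bayes(y, random = list(b = bayes_block(X, "BayesB")),
                  mcmc = mcmc_settings(1500, 500, 2, seed = 9))
  f2 <- fit_bayes(y, random = list(b = bayes_block(X, "BayesB")),
                  mcmc = mcmc_settings(1500, 500, 2, seed = 9))
  expect_identical(f1$varcomp_samples, f2$varcomp_samples)
  expect_identical(f1$eta_mean, f2$eta_mean)
  expect_identical(f1$dic, f2$dic)
})

test_that("intercept-only model recovers the response variance and Gaussian deviance", {
  set.seed(5)
  y <- rnorm(200, 3, 2)
  fit <- fit_bayes(y, mcmc = mcmc_settings(6000, 1000, 5, seed = 1))
  expect_lt(abs(mean(fit$sige_samples) - var(y)) / var(y), 0.1)
  expect_lt(abs(fit$dic - (200 * log(2 * pi * var(y)) + 200)), 15)
  # DIC identity with the stored traces
  expect_equal(fit$dic, 2 * fit$d_bar - fit$d_hat)
  expect_gt(fit$pD, 0)
})

test_that("Bayes C with inclusion probability 1 reproduces BRR", {
  set.seed(42)
  X <- matrix(rnorm(120 * 30), 120)
  y <- as.numeric(X %*% rnorm(30, 0, 0.3) + rnorm(120))
  fb <- fit_bayes(y, random = list(b = bayes_block(X, "BRR")),
                  mcmc = mcmc_settings(8000, 2000, 5, seed = 3))
  fc <- fit_bayes(y, random = list(b = bayes_block(X, "BayesC", pi = 1,
                                                   pi_fixed = TRUE)),
                  mcmc = mcmc_settings(8000, 2000, 5, seed = 3))
  expect_gt(cor(fb$eta_mean, fc$eta_mean), 0.999)
  # Bayes B collapses to the same fit when inclusion is forced and the
  # per-regressor variance is pinned to a common value
  fbb <- fit_bayes(y, random = list(b = bayes_block(X, "BayesB", pi = 1,
                                                    pi_fixed = TRUE,
                                                    var_fixed = TRUE, var0 = 0.1)),
                   mcmc = mcmc_settings(8000, 2000, 5, seed = 3))
  fbr <- fit_bayes(y, random = list(b = bayes_block(X, "BRR",
                                                    var_fixed = TRUE, var0 = 0.1)),
                   mcmc = mcmc_settings(8000, 2000, 5, seed = 3))
  expect_gt(cor(fbb$eta_mean, fbr$eta_mean), 0.999)
})

test_that("posterior residual variance is consistent at n = 400", {
  set.seed(13)
  n <- 400
  X <- matrix(rnorm(n * 50), n)
  y <- as.numeric(X %*% rnorm(50, 0, 0.2) + rnorm(n, 0, sqrt(0.8)))
  fit <- fit_bayes(y, random = list(b = bayes_block(X, "BRR")),
                   mcmc = mcmc_settings(6000, 1500, 5, seed = 2))
  expect_lt(abs(mean(fit$sige_samples) - 0.8) / 0.8, 0.10)
})

test_that("DIC strongly favours the model containing a real signal block", {
  set.seed(21)
  n <- 300
  X <- matrix(rnorm(n * 40), n)
  y <- as.numeric(X %*% rnorm(40, 0, 0.4) + rnorm(n))
  f0 <- fit_bayes(y, mcmc = mcmc_settings(5000, 1000, 5, seed = 1))
  f1 <- fit_bayes(y, random = list(b = bayes_block(X, "BRR")),
                  mcmc = mcmc_settings(5000, 1000, 5, seed = 2))
  expect_gt(f0$dic - f1$dic, 10)
})

test_that("kinship random effect via loadings matches the closed-form BLUP", {
  ped <- simulate_pedigree(20, 6, 10, 2, seed = 6)
  A <- a_matrix(ped)
  AL <- decompose(A)
  ids <- ped$id[ped$generation > 0]
  K <- unclass(A)[ids, ids]
  L <- AL$L[ids, ]
  set.seed(8)
  g <- as.numeric(chol(K + diag(1e-8, nrow(K))) %*% rnorm(nrow(K))) * sqrt(0.5)
  y <- g + rnorm(length(ids), 0, sqrt(0.5))
  ghat <- as.numeric(K %*% solve(K + diag(1, nrow(K)), y - mean(y)))
  fit <- fit_bayes(y, random = list(a = bayes_block(L, "BRR",
                                                    var_fixed = TRUE, var0 = 0.5)),
                   sige_fixed = TRUE, sige0 = 0.5,
                   mcmc = mcmc_settings(20000, 4000, 2, seed = 4))
  expect_gt(cor(fit$eta_block_mean[, "a"], ghat), 0.999)
})

test_that("exchanging regressor columns leaves the fit statistically unchanged", {
  set.seed(31)
  X <- matrix(rnorm(150 * 20), 150)
  beta <- rnorm(20, 0, 0.4)
  y <- as.numeric(X %*% beta + rnorm(150))
  Xs <- X[, c(2, 1, 3:20)]
  f1 <- fit_bayes(y, random = list(b = bayes_block(X, "BRR")),
                  mcmc = mcmc_settings(6000, 1500, 5, seed = 5))
  f2 <- fit_bayes(y, random = list(b = bayes_block(Xs, "BRR")),
                  mcmc = mcmc_settings(6000, 1500, 5, seed = 6))
  expect_gt(cor(f1$eta_mean, f2$eta_mean), 0.99)
  expect_lt(abs(f1$effect_mean$b[1] - f2$effect_mean$b[2]), 0.1)
})

test_that("variance partition is calibrated at its extremes", {
  set.seed(17)
  n <- 400
  X <- matrix(rnorm(n * 10), n)
  # all signal, no noise
  y <- as.numeric(X %*% rnorm(10))
  fit <- fit_bayes(y, random = list(b = bayes_block(X, "BRR")),
                   mcmc = mcmc_settings(4000, 1000, 5, seed = 1))
  pv <- variance_partition(fit)
  expect_gt(pv$pv[pv$block == "b"], 95)
  # a pure-noise block stays small
  Z <- matrix(rnorm(n * 30), n)
  y2 <- as.numeric(X %*% rnorm(10) + rnorm(n))
  fit2 <- fit_bayes(y2, random = list(sig = bayes_block(X, "BRR", r2 = 0.05),
                                      noise = bayes_block(Z, "BRR", r2 = 0.05)),
                    mcmc = mcmc_settings(6000, 1500, 5, seed = 2))
  pv2 <- variance_partition(fit2)
  expect_lt(pv2$pv[pv2$block == "noise"], 5)
})

test_that("variance partition recovers known shares through kinship and spectra blocks", {
  pop <- small_pop()
  bundle <- build_bundle(pop, select_sri = FALSE)
  ids <- bundle$ids
  L <- bundle$G_load$L[ids, ]
  H <- scale(bundle$spectra_proc$values[ids, ])
  res <- vapply(1:5, function(s) {
    set.seed(700 + s)
    ya <- scale(as.numeric(L %*% rnorm(ncol(L))))[, 1] * sqrt(0.4)
    yh <- scale(as.numeric(H %*% rnorm(ncol(H))))[, 1] * sqrt(0.2)
    y <- ya + yh + rnorm(length(ids), 0, sqrt(0.4))
    fit <- fit_bayes(y, random = list(g = bayes_block(L, "BRR", r2 = 0.05),
                                      h = bayes_block(H, "BayesB", r2 = 0.05)),
                     mcmc = mcmc_settings(8000, 2000, 5, seed = s))
    pv <- variance_partition(fit)
    c(pv$pv[pv$block == "g"], pv$pv[pv$block == "h"])
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 40), 8)
  expect_lt(abs(mean(res[2, ]) - 20), 8)
})

test_that("tidy and glance summarize fits in broom shape", {
  set.seed(3)
  X <- matrix(rnorm(80 * 5), 80, dimnames = list(NULL, paste0("m", 1:5)))
  y <- as.numeric(X %*% rnorm(5) + rnorm(80))
  fit <- fit_bayes(y, random = list(b = bayes_block(X, "BayesC")),
                   mcmc = mcmc_settings(1500, 500, 2, seed = 1))
  vc <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error") %in% names(vc)))
  expect_true("sigma2_e" %in% vc$term)
  ef <- tidy(fit, "effects")
  expect_equal(nrow(ef), 5)
  expect_true(all(ef$inclusion >= 0 & ef$inclusion <= 1))
  gl <- glance(fit)
  expect_equal(gl$n, 80)
  expect_true(is.finite(gl$dic))
})

test_that("fit_bayes validates its inputs", {
  expect_error(fit_bayes(c(1, NA, 3)), class = "cyanophen_invalid_input")
  expect_error(mcmc_settings(100, 200), class = "cyanophen_invalid_argument")
  expect_error(mcmc_settings(thin = 0), class = "cyanophen_invalid_argument")
})
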