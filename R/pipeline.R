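#' Adjust phenotypes for the experimental (block) design
#'
#' Ordinary least squares of the trait on block indicators; the adjusted
#' phenotype `y* = intercept + residual` removes block effects and is the
#' response of all prediction models.
#'
#' @param trait Trait tibble with `id`, the response column and `block`.
#' @param response Response column name.
#' @return The trait tibble with an added `y_star` column; attributes
#'   `block_effects` (named vector) and `adj_r2`.
#' @export
adjust_phenotypes <- function(trait, response = "hcn") {
  if (!all(c("id", response, "block") %in% names(trait))) {
    rlang::abort("trait needs id, response and block columns",
                 class = "cyanophen_invalid_argument")
  }
  y <- trait[[response]]
  f <- factor(trait$block)
  if (nlevels(f) < 2) {
    fit <- stats::lm(y ~ 1)
  } else {
    fit <- stats::lm(y ~ f)
  }
  out <- trait
  out$y_star <- as.numeric(stats::coef(fit)[1] + stats::residuals(fit))
  attr(out, "block_effects") <- stats::coef(fit)[-1]
  attr(out, "adj_r2") <- summary(fit)$r.squared
  out
}

#' Prediction model presets
#'
#' Declarative description of the twelve prediction models (numbers 3-14)
#' and the two heritability models (1-2), in terms of their fixed
#' components (structure covariates Q, provenance P, selected spectral
#' indices) and random blocks (pedigree kinship `a`, haplotype dosages
#' `g2`, processed spectral bands `h`, SNP-based kinship `g1`). The engine
#' prior (BRR, Bayes B or Bayes C) applies to the dense regressor blocks
#' (`g2`, `h`); kinship blocks always use the Gaussian (BRR) prior, matching
#' their `N(0, K sigma2)` definition.
#'
#' @param model Model number (1-14).
#' @param engine `"BayesB"`, `"BayesC"` or `"BRR"` for the dense blocks.
#' @param sri `"all"` (the stepwise-selected set), a character vector of
#'   index names, or `NULL` (models without index covariates ignore this).
#' @return A list of class `cyp_modelspec`.
#' @export
model_spec <- function(model, engine = c("BayesB", "BayesC", "BRR"),
                       sri = "all") {
  engine <- match.arg(engine)
  if (!model %in% 1:14) {
    rlang::abort("model must be between 1 and 14", class = "cyanophen_invalid_argument")
  }
  comp <- switch(as.character(model),
    "1" = list(fixed = c("X", "Q"), random = "g1"),
    "2" = list(fixed = c("X", "P"), random = "a"),
    "3" = list(fixed = "Q", random = "g2"),
    "4" = list(fixed = "P", random = "a"),
    "5" = list(fixed = "Q", random = "a"),
    "6" = list(fixed = "Q", random = c("a", "g2")),
    "7" = list(fixed = "Q", random = "h"),
    "8" = list(fixed = "Q", random = c("g2", "h")),
    "9" = list(fixed = "Q", random = c("a", "h")),
    "10" = list(fixed = c("Q", "sri"), random = "g2"),
    "11" = list(fixed = c("Q", "sri"), random = "h"),
    "12" = list(fixed = c("Q", "sri"), random = c("a", "g2")),
    "13" = list(fixed = "Q", random = c("a", "g2", "h")),
    "14" = list(fixed = c("Q", "sri"), random = c("a", "g2", "h"))
  )
  structure(list(model = model, engine = engine, sri = sri,
                 fixed = comp$fixed, random = comp$random),
            class = "cyp_modelspec")
}

#' @export
print.cyp_modelspec <- function(x, ...) {
  cat(sprintf("<cyp_modelspec> model %d (%s): fixed {%s}, random {%s}%s\n",
              x$model, x$engine, paste(x$fixed, collapse = ", "),
              paste(x$random, collapse = ", "),
              if ("sri" %in% x$fixed) sprintf(", SRI = %s",
                                              paste(x$sri, collapse = "/")) else ""))
  invisible(x)
}

# assemble fixed matrix and random block list for a spec from a data bundle
assemble_design <- function(spec, data, engine_prior = NULL,
                            prior_df = 5, prior_share = 0.1) {
  ids <- data$ids
  fixed_parts <- list()
  for (f in spec$fixed) {
    mat <- switch(f,
      X = data$X_block, Q = data$Q, P = data$P,
      sri = {
        sel <- if (identical(spec$sri, "all")) data$sri_selected else spec$sri
        if (is.null(sel) || !length(sel)) NULL
        else scale(as.matrix(data$sri_tab[match(ids, data$sri_tab$id), sel, drop = FALSE]))
      })
    if (!is.null(mat) && ncol(mat) > 0) fixed_parts[[f]] <- as.matrix(mat)[ids_rows(mat, ids), , drop = FALSE]
  }
  Xf <- if (length(fixed_parts)) do.call(cbind, fixed_parts) else NULL

  prior <- engine_prior %||% spec$engine
  nb <- length(spec$random)
  r2b <- prior_share / max(nb, 1)
  random <- list()
  for (r in spec$random) {
    random[[r]] <- switch(r,
      a = bayes_block(data$A_load$L[ids, , drop = FALSE], prior = "BRR",
                      df = prior_df, r2 = r2b),
      g1 = bayes_block(data$G_load$L[ids, , drop = FALSE], prior = "BRR",
                       df = prior_df, r2 = r2b),
      g2 = bayes_block(data$haplo$design[ids, , drop = FALSE], prior = prior,
                       df = prior_df, r2 = r2b),
      h = bayes_block(data$spectra_proc$values[ids, , drop = FALSE], prior = prior,
                      df = prior_df, r2 = r2b)
    )
  }
  list(fixed = Xf, random = random)
}

ids_rows <- function(mat, ids) {
  if (!is.null(rownames(mat))) match(ids, rownames(mat)) else seq_along(ids)
}

#' Build the data bundle consumed by the model presets
#'
#' Precomputes everything the model presets need: block and structure
#' designs, kinship eigen-loadings, the haplotype design, processed spectra
#' and (optionally) the stepwise-selected index set.
#'
#' @param pop A population list ([simulate_population()] output or
#'   equivalently named real data).
#' @param wavelength_window Savitzky-Golay window for the spectral block.
#' @param select_sri Run [stepwise_select()] to pick index covariates.
#' @param ld_window Bp window for pairwise LD.
#' @return A list (class `cyp_bundle`) with aligned design components for
#'   the phenotyped individuals.
#' @export
build_bundle <- function(pop, wavelength_window = 37, select_sri = TRUE,
                         ld_window = 5e5) {
  trait <- adjust_phenotypes(pop$trait)
  ids <- trait$id
  A <- a_matrix(pop$pedigree)
  G <- g_matrix(pop$genotypes)
  A_load <- decompose(A)
  G_load <- decompose(G)
  ld <- pairwise_ld(pop$genotypes, max_pair_distance = ld_window)
  blocks <- solid_spine_blocks(ld)
  haplo <- haplotype_design(pop$genotypes, blocks)
  spectra_proc <- preprocess(pop$spectra, window = wavelength_window)
  sri_tab <- tryCatch(compute_sri(pop$spectra),
                      cyanophen_missing_band = function(e) NULL)
  sri_selected <- NULL
  if (select_sri && !is.null(sri_tab)) {
    sel <- stepwise_select(sri_tab[match(ids, sri_tab$id), ], trait,
                           response = "y_star")
    sri_selected <- sel$selected
  }
  Q <- structure_covariates(stats::setNames(trait$group, ids))
  P <- structure_covariates(stats::setNames(trait$provenance, ids))
  X_block <- structure_covariates(stats::setNames(as.character(trait$block), ids))
  structure(list(
    ids = ids, trait = trait, y_star = trait$y_star,
    A_load = A_load, G_load = G_load, haplo = haplo,
    spectra_proc = spectra_proc, sri_tab = sri_tab,
    sri_selected = sri_selected, Q = Q, P = P, X_block = X_block,
    ld_blocks = blocks
  ), class = "cyp_bundle")
}

#' Fit one prediction model preset
#'
#' @param spec A [model_spec()].
#' @param data A bundle from [build_bundle()].
#' @param mcmc Chain settings.
#' @param y Optional response override (defaults to the bundle's adjusted
#'   phenotype `y*`).
#' @param prior_df,prior_share Variance-prior degrees of freedom and total
#'   prior variance share split equally across random blocks.
#' @return A `cyp_fit` with the spec attached.
#' @export
fit_model <- function(spec, data, mcmc = mcmc_settings(), y = NULL,
                      prior_df = 5, prior_share = 0.1) {
  des <- assemble_design(spec, data, prior_df = prior_df,
                         prior_share = prior_share)
  y <- y %||% data$y_star
  fit <- fit_bayes(y, fixed = des$fixed, random = des$random,
                   df_e = prior_df, mcmc = mcmc)
  fit$spec <- spec
  fit
}

#' Fivefold cross-validated predictive ability
#'
#' Random k-fold partition of the phenotyped individuals; for each fold the
#' model is refitted on the training individuals only and the held-out
#' adjusted phenotypes are predicted (kinship blocks reach the test
#' individuals through their eigen-loading rows, haplotype and spectral
#' blocks through their own regressor rows). Predictive ability is the
#' Pearson correlation between observed and predicted `y*` per fold.
#'
#' @param spec A [model_spec()].
#' @param data A bundle from [build_bundle()].
#' @param k Number of folds (each test fold is about `1/k` of the
#'   population; `k = 5` holds out 20%).
#' @param seed Fold-assignment and chain seed.
#' @param mcmc Chain settings per fold fit.
#' @param stratify `"none"` (simple random folds) or `"family"`
#'   (family-stratified; half-sib structure inflates naive PA).
#' @return A tibble of class `cyp_cv`: per-fold `pa` and sizes, plus
#'   attributes `mean_pa`, `predictions`.
#' @export
cross_validate <- function(spec, data, k = 5, seed = 1,
                           mcmc = mcmc_settings(), stratify = c("none", "family")) {
  stratify <- match.arg(stratify)
  n <- length(data$ids)
  if (k < 2 || n < 5 * k) {
    rlang::abort("need k >= 2 and n >= 5k", class = "cyanophen_invalid_argument")
  }
  withr_seed(seed)
  fold <- if (stratify == "family") {
    unsplit(lapply(split(seq_len(n), data$trait$family),
                   function(ix) sample(rep_len(seq_len(k), length(ix)))),
            data$trait$family)
  } else {
    sample(rep_len(seq_len(k), n))
  }
  des <- assemble_design(spec, data)
  y <- data$y_star
  preds <- rep(NA_real_, n)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(fold == f); train <- which(fold != f)
    fx_tr <- if (!is.null(des$fixed)) des$fixed[train, , drop = FALSE] else NULL
    rnd_tr <- lapply(des$random, function(b) {
      b$X <- b$X[train, , drop = FALSE]; b
    })
    fit <- fit_bayes(y[train], fixed = fx_tr, random = rnd_tr,
                     mcmc = mcmc_settings(mcmc$iterations, mcmc$burnin,
                                          mcmc$thin, seed = seed + f))
    nd <- lapply(des$random, function(b) b$X[test, , drop = FALSE])
    if (!is.null(des$fixed)) nd$fixed <- des$fixed[test, , drop = FALSE]
    yhat <- predict(fit, nd)
    preds[test] <- yhat
    pa <- if (stats::sd(y[test]) < 1e-12 || stats::sd(yhat) < 1e-12) {
      NA_real_
    } else stats::cor(y[test], yhat)
    rows[[f]] <- tibble::tibble(fold = f, n_test = length(test), pa = pa)
  }
  out <- dplyr::bind_rows(rows)
  out$model <- spec$model
  out$engine <- spec$engine
  class(out) <- c("cyp_cv", class(out))
  attr(out, "mean_pa") <- mean(out$pa, na.rm = TRUE)
  attr(out, "predictions") <- tibble::tibble(id = data$ids, fold = fold,
                                             y_star = y, y_hat = preds)
  out
}

#' DIC support class for a DIC difference
#'
#' Differences above 10 are "supported" (the lower-DIC model is supported
#' against the other), between 3 and 10 "substantial", below 3
#' "not significant"; the boundaries themselves fall into the milder class
#' whose range is stated inclusively (3 and 10 are both "substantial").
#'
#' @param delta Non-negative DIC difference(s).
#' @return Character vector of classes.
#' @export
dic_support <- function(delta) {
  dplyr::case_when(
    delta > 10 ~ "supported",
    delta >= 3 ~ "substantial",
    TRUE ~ "not significant"
  )
}

#' Compare fitted prediction models
#'
#' Collects DIC, variance partitions and (optionally) cross-validated
#' predictive abilities into the standard comparison layout: one row per
#' model x engine, sorted by DIC, with the DIC difference to the best model
#' and its support class.
#'
#' @param fits List of `cyp_fit` objects from [fit_model()] (same response).
#' @param cvs Optional list of `cyp_cv` results matched by model + engine.
#' @return A tibble of class `cyp_comparison`.
#' @export
compare_models <- function(fits, cvs = NULL) {
  ys <- vapply(fits, function(f) sum(f$y), numeric(1))
  if (max(abs(ys - ys[1])) > 1e-8) {
    rlang::abort("fits must share the same response", class = "cyanophen_invalid_input")
  }
  rows <- purrr::map(fits, function(f) {
    pv <- variance_partition(f)
    getpv <- function(b) if (b %in% pv$block) pv$pv[pv$block == b] else NA_real_
    tibble::tibble(
      model = f$spec$model, engine = f$spec$engine,
      sri = if ("sri" %in% f$spec$fixed) paste(f$spec$sri, collapse = "/") else "-",
      dic = f$dic,
      pv_g = getpv("g2") %||% NA_real_,
      pv_sr = getpv("h"), pv_a = getpv("a")
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$dic)
  out$delta_dic <- out$dic - out$dic[1]
  out$support <- dic_support(out$delta_dic)
  if (!is.null(cvs)) {
    pa_tab <- purrr::map_dfr(cvs, function(cv) tibble::tibble(
      model = cv$model[1], engine = cv$engine[1], pa = attr(cv, "mean_pa")))
    out <- dplyr::left_join(out, pa_tab, by = c("model", "engine"))
  }
  class(out) <- c("cyp_comparison", class(out))
  out
}

#' Plot a model comparison (DIC vs predictive ability)
#' @param object A `cyp_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyp_comparison <- function(object, ...) {
  df <- object
  df$label <- sprintf("M%d", df$model)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dic,
                                        y = if ("pa" %in% names(df)) .data$pa else .data$delta_dic,
                                        colour = .data$engine)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.6, size = 3) +
    ggplot2::labs(x = "DIC (lower is better)",
                  y = if ("pa" %in% names(df)) "predictive ability" else "delta DIC") +
    ggplot2::theme_minimal()
  p
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a population, builds relationship matrices,
#' haplotype blocks, processed spectra and index covariates, fits the
#' requested model presets under the requested engines, cross-validates
#' them, and returns the comparison table alongside all intermediate
#' objects.
#'
#' @param pop Population list (see [simulate_population()]); `NULL`
#'   simulates one with `sim_args`.
#' @param models Model numbers to fit (subset of 3-14).
#' @param engines Engines to run per model.
#' @param mcmc Chain settings.
#' @param cv_k Folds for cross-validation (0 skips CV).
#' @param seed Master seed (simulation, folds, chains).
#' @param sim_args List of arguments for [simulate_population()].
#' @param wavelength_window Savitzky-Golay window for the spectral block.
#' @return A list of class `cyp_report`: `comparison`, `fits`, `cvs`,
#'   `bundle`, `pop`.
#' @export
run_pipeline <- function(pop = NULL, models = c(3, 7, 13),
                         engines = "BayesB", mcmc = mcmc_settings(),
                         cv_k = 5, seed = 1,
                         sim_args = list(wavelength_step = 5),
                         wavelength_window = 37) {
  if (is.null(pop)) {
    pop <- do.call(simulate_population, c(list(seed = seed), sim_args))
  }
  bundle <- build_bundle(pop, wavelength_window = wavelength_window)
  grid <- expand.grid(model = models, engine = engines,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  cvs <- if (cv_k >= 2) vector("list", nrow(grid)) else NULL
  for (g in seq_len(nrow(grid))) {
    spec <- model_spec(grid$model[g], engine = grid$engine[g])
    fits[[g]] <- fit_model(spec, bundle,
                           mcmc = mcmc_settings(mcmc$iterations, mcmc$burnin,
                                                mcmc$thin, seed = seed + g))
    if (cv_k >= 2) {
      cvs[[g]] <- cross_validate(spec, bundle, k = cv_k, seed = seed + 1000 + g,
                                 mcmc = mcmc)
    }
  }
  comparison <- compare_models(fits, cvs)
  structure(list(comparison = comparison, fits = fits, cvs = cvs,
                 bundle = bundle, pop = pop, seed = seed),
            class = "cyp_report")
}

#' @export
print.cyp_report <- function(x, ...) {
  cat("<cyp_report>\n")
  print(as.data.frame(x$comparison[, setdiff(names(x$comparison), c())]))
  invisible(x)
}
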