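#' Preprocess reflectance spectra (normalize + Savitzky-Golay derivative)
#'
#' Each band is first centered and scaled over individuals (normalization);
#' the Savitzky-Golay least-squares polynomial derivative is then taken
#' across wavelengths within each individual. Edge bands without a full
#' filter window are dropped, so the output has `w - (window - 1)` bands.
#' The default window of 37 grid points with a quadratic polynomial and
#' first derivative is the standard chemometrics setting for reflectance
#' curves of this kind.
#'
#' @param spectra A `cyp_spectra` object, or a numeric matrix (rows =
#'   individuals) with `wavelength` supplied.
#' @param window Odd filter window length (grid points).
#' @param polyorder Fitting polynomial order (`window > polyorder >=
#'   derivative`).
#' @param derivative Derivative order (0 = smoothing only).
#' @param normalize Center and scale each band before filtering.
#' @param wavelength Wavelength grid when `spectra` is a bare matrix.
#' @return Object of class `cyp_processed`: `values` (n x w' matrix),
#'   `wavelength` (trimmed grid), `descriptor` (window/polyorder/derivative).
#' @export
preprocess <- function(spectra, window = 37, polyorder = 2, derivative = 1,
                       normalize = TRUE, wavelength = NULL) {
  if (inherits(spectra, "cyp_spectra")) {
    X <- spectra$reflectance
    wl <- spectra$wavelength
  } else {
    X <- as.matrix(spectra)
    wl <- wavelength
    if (is.null(wl)) rlang::abort("wavelength grid required",
                                  class = "cyanophen_invalid_argument")
  }
  w <- length(wl)
  if (window %% 2 == 0 || window <= polyorder || polyorder < derivative) {
    rlang::abort("need odd window > polyorder >= derivative",
                 class = "cyanophen_invalid_argument")
  }
  if (window >= w) {
    rlang::abort("window must be smaller than the number of bands",
                 class = "cyanophen_invalid_argument")
  }
  steps <- diff(wl)
  if (max(abs(steps - steps[1])) > 1e-8) {
    rlang::abort("wavelength grid must be uniform",
                 class = "cyanophen_invalid_input")
  }
  step <- steps[1]
  if (normalize) {
    sds <- apply(X, 2, stats::sd)
    sds[sds < 1e-12] <- 1
    X <- scale(X, center = TRUE, scale = sds)
  }
  # central-row Savitzky-Golay convolution coefficients on the interior
  Fm <- signal::sgolay(p = polyorder, n = window, m = derivative, ts = step)
  cf <- Fm[(window + 1) / 2, ]
  half <- (window - 1) / 2
  interior <- (half + 1):(w - half)
  out <- matrix(0, nrow(X), length(interior))
  for (k in seq_along(cf)) {
    out <- out + cf[k] * X[, interior + (k - half - 1), drop = FALSE]
  }
  dimnames(out) <- list(rownames(X), sprintf("wl_%04d", wl[interior]))
  structure(list(values = out, wavelength = wl[interior],
                 descriptor = list(window = window, polyorder = polyorder,
                                   derivative = derivative,
                                   normalized = normalize)),
            class = "cyp_processed")
}

#' @export
print.cyp_processed <- function(x, ...) {
  d <- x$descriptor
  cat(sprintf("<cyp_processed> %d x %d bands; SG window %d, polyorder %d, derivative %d%s\n",
              nrow(x$values), ncol(x$values), d$window, d$polyorder,
              d$derivative, if (d$normalized) ", normalized" else ""))
  invisible(x)
}

# --- spectral reflectance index registry -----------------------------------

# registry environment: name -> function(r, dmax) where r(wl) returns
# reflectance at the nearest band and dmax(lo, hi) the maximum of the first
# derivative of raw reflectance over [lo, hi] nm
.sri_registry <- new.env(parent = emptyenv())

register_sri_internal <- function(name, fun) assign(name, fun, envir = .sri_registry)

local({
  register_sri_internal("LRDSI1", function(r, dmax) 6.9 * (r(605) / r(455)) - 1.2)
  register_sri_internal("ARI", function(r, dmax) 1 / r(550) - 1 / r(700))
  register_sri_internal("BRI", function(r, dmax) r(450) / r(690))
  register_sri_internal("SR7", function(r, dmax) r(440) / r(690))
  register_sri_internal("BGI", function(r, dmax) r(450) / r(550))
  register_sri_internal("EGFN", function(r, dmax) {
    (dmax(650, 750) - dmax(500, 550)) / (dmax(650, 750) + dmax(500, 550))
  })
  register_sri_internal("EGFNR", function(r, dmax) dmax(650, 750) / dmax(500, 550))
  register_sri_internal("GMI1", function(r, dmax) r(750) / r(550))
  register_sri_internal("SR3", function(r, dmax) r(750) / r(550))
  register_sri_internal("SR10", function(r, dmax) r(685) / r(655))
  register_sri_internal("NDLI", function(r, dmax) {
    (log(1 / r(1754)) - log(1 / r(1680))) / (log(1 / r(1754)) + log(1 / r(1680)))
  })
  register_sri_internal("NDNI", function(r, dmax) {
    (log(1 / r(1510)) - log(1 / r(1680))) / (log(1 / r(1510)) + log(1 / r(1680)))
  })
  register_sri_internal("NPCI", function(r, dmax) {
    (r(680) - r(430)) / (r(680) + r(430))
  })
})

#' Spectral reflectance index registry
#'
#' The registry ships the named core set used for heritability profiling and
#' trait prediction (simple ratios, normalized differences and
#' derivative-based greenness indices); [register_sri()] plugs in further
#' formulas.
#'
#' @return Character vector of registered index names.
#' @export
sri_registry <- function() sort(ls(.sri_registry))

#' @rdname sri_registry
#' @param name Index name.
#' @param fun A function `(r, dmax)` where `r(wl)` returns raw reflectance at
#'   the band nearest `wl` and `dmax(lo, hi)` the maximum first derivative of
#'   raw reflectance over `[lo, hi]` nm; returns a numeric vector over
#'   individuals.
#' @export
register_sri <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  register_sri_internal(name, fun)
  invisible(name)
}

#' Compute spectral reflectance indices
#'
#' Indices are evaluated on raw (unprocessed) reflectance, their published
#' scale; derivative-based indices use the first difference of raw
#' reflectance over the wavelength grid. Band lookup is nearest-band within
#' `tol_nm`; a missing band raises an error naming the index and band.
#'
#' @param spectra A `cyp_spectra` object or matrix plus `wavelength`.
#' @param names Indices to compute (default: the whole registry).
#' @param tol_nm Nearest-band tolerance in nm.
#' @param wavelength Grid when `spectra` is a bare matrix.
#' @return A tibble: `id` plus one column per index.
#' @examples
#' pop <- simulate_pedigree(5, 4, 5, 1, seed = 1)
#' sp <- simulate_spectra(pop, wavelength_step = 5, seed = 2)
#' head(compute_sri(sp, c("NPCI", "SR10")))
#' @export
compute_sri <- function(spectra, names = NULL, tol_nm = 2, wavelength = NULL) {
  if (inherits(spectra, "cyp_spectra")) {
    X <- spectra$reflectance
    wl <- spectra$wavelength
  } else {
    X <- as.matrix(spectra)
    wl <- wavelength
  }
  names <- names %||% sri_registry()
  missing_idx <- setdiff(names, sri_registry())
  if (length(missing_idx)) {
    rlang::abort(sprintf("unknown indices: %s", paste(missing_idx, collapse = ", ")),
                 class = "cyanophen_invalid_argument")
  }
  step <- if (length(wl) > 1) diff(wl)[1] else 1
  deriv <- t(apply(X, 1, function(row) diff(row) / diff(wl)))
  wl_d <- (wl[-1] + wl[-length(wl)]) / 2

  make_r <- function(idx_name) {
    function(target) {
      k <- which.min(abs(wl - target))
      if (abs(wl[k] - target) > tol_nm) {
        rlang::abort(sprintf("index %s needs band %g nm (nearest grid band %g nm)",
                             idx_name, target, wl[k]),
                     class = "cyanophen_missing_band")
      }
      X[, k]
    }
  }
  dmax <- function(lo, hi) {
    cols <- which(wl_d >= lo & wl_d <= hi)
    if (!length(cols)) {
      rlang::abort(sprintf("no derivative bands in [%g, %g] nm", lo, hi),
                   class = "cyanophen_missing_band")
    }
    apply(deriv[, cols, drop = FALSE], 1, max)
  }
  vals <- lapply(names, function(nm) {
    f <- get(nm, envir = .sri_registry)
    v <- unname(f(make_r(nm), dmax))
    ifelse(is.finite(v), v, NA_real_)
  })
  out <- tibble::as_tibble(stats::setNames(vals, names))
  dplyr::bind_cols(tibble::tibble(id = rownames(X)), out)
}

#' Variance inflation factors of a design
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing column `j` on the others. The
#' conventional reading: below 10 no strong multicollinearity, 10-100
#' strong, at or above 100 severe. Exact collinearity reports `Inf`.
#'
#' @param design Numeric matrix or data frame (>= 2 columns).
#' @return A tibble: `variable`, `vif`, `class`.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) < 2) rlang::abort("need at least two columns",
                                class = "cyanophen_invalid_argument")
  v <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(
    variable = colnames(X) %||% paste0("V", seq_len(ncol(X))),
    vif = v,
    class = dplyr::case_when(v >= 100 ~ "severe", v >= 10 ~ "strong",
                             TRUE ~ "none")
  )
}

#' Stepwise AIC selection of spectral indices
#'
#' Bidirectional stepwise ordinary least squares from the intercept-only
#' model, minimizing `AIC = n log(RSS / n) + 2k`, over standardized index
#' candidates. AIC is the sole selection criterion; coefficient p-values and
#' VIFs of the selected set are reported post hoc.
#'
#' @param sri Tibble from [compute_sri()] (`id` + index columns) or a plain
#'   matrix/data frame of candidates.
#' @param trait Trait tibble with `id` and the response column, or a numeric
#'   response aligned to `sri` rows.
#' @param response Name of the response column (default `hcn`).
#' @return Object of class `cyp_selection`: `selected`, `aic_path`,
#'   `vif`, `coefficients` (estimates, p-values), `r2`.
#' @export
stepwise_select <- function(sri, trait, response = "hcn") {
  if (is.data.frame(sri) && "id" %in% names(sri)) {
    ids <- sri$id
    Xc <- as.matrix(sri[setdiff(names(sri), "id")])
  } else {
    ids <- NULL
    Xc <- as.matrix(sri)
  }
  if (is.numeric(trait)) {
    yy <- trait
  } else {
    if (!is.null(ids)) {
      trait <- trait[match(ids, trait$id), ]
    }
    yy <- trait[[response]]
  }
  ok_col <- apply(Xc, 2, function(v) stats::sd(v, na.rm = TRUE) > 1e-12 && !anyNA(v))
  if (any(!ok_col)) {
    rlang::warn(sprintf("dropping constant/NA candidates: %s",
                        paste(colnames(Xc)[!ok_col], collapse = ", ")))
  }
  Xc <- Xc[, ok_col, drop = FALSE]
  Xs <- scale(Xc)
  dat <- data.frame(.y = yy, Xs, check.names = FALSE)
  null_fit <- stats::lm(.y ~ 1, data = dat)
  scope <- stats::as.formula(paste("~", paste(sprintf("`%s`", colnames(Xs)),
                                              collapse = " + ")))
  sel <- stats::step(null_fit, scope = list(lower = ~1, upper = scope),
                     direction = "both", trace = 0, k = 2)
  selected <- setdiff(all.vars(stats::formula(sel)), ".y")
  aic_path <- tibble::tibble(
    step = seq_len(nrow(sel$anova)),
    move = trimws(as.character(sel$anova$Step)),
    aic = sel$anova$AIC
  )
  sm <- summary(sel)
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    std_error = sm$coefficients[, 2],
    p_value = sm$coefficients[, 4]
  )
  vtab <- if (length(selected) >= 2) {
    vif(Xs[, selected, drop = FALSE])
  } else {
    tibble::tibble(variable = selected,
                   vif = rep(1, length(selected)),
                   class = rep("none", length(selected)))
  }
  structure(list(selected = selected, aic_path = aic_path, vif = vtab,
                 coefficients = coefs, r2 = sm$r.squared, model = sel),
            class = "cyp_selection")
}

#' @export
print.cyp_selection <- function(x, ...) {
  cat(sprintf("<cyp_selection> %d indices selected (R2 = %.3f): %s\n",
              length(x$selected), x$r2, paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.cyp_selection <- function(x, ...) {
  dplyr::left_join(x$coefficients,
                   dplyr::rename(x$vif, term = "variable"), by = "term")
}
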