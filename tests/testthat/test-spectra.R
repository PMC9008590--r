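test_that("Savitzky-Golay derivative matches analytic derivatives", {
  wl <- seq(400, 2400, by = 10)
  a <- 2e-9; b <- -1e-6; cc <- 3e-4; d <- 0.1
  X <- rbind(a * wl^3 + b * wl^2 + cc * wl + d,
             2 * (a * wl^3 + b * wl^2 + cc * wl + d))
  pr <- preprocess(X, window = 37, polyorder = 3, derivative = 1,
                   normalize = FALSE, wavelength = wl)
  analytic <- 3 * a * pr$wavelength^2 + 2 * b * pr$wavelength + cc
  expect_lt(max(abs(pr$values[1, ] - analytic)), 1e-8)
  # edge loss: w' = w - (window - 1)
  expect_equal(ncol(pr$values), length(wl) - 36)
  # linear spectrum: constant derivative equal to the slope
  Xl <- rbind(0.1 + 5e-5 * wl, 0.2 + 5e-5 * wl)
  pl <- preprocess(Xl, window = 37, polyorder = 2, derivative = 1,
                   normalize = FALSE, wavelength = wl)
  expect_lt(max(abs(pl$values - 5e-5)), 1e-12)
  # constant spectrum: zero derivative
  p0 <- preprocess(matrix(0.3, 2, length(wl)), window = 37, polyorder = 2,
                   derivative = 1, normalize = FALSE, wavelength = wl)
  expect_lt(max(abs(p0$values)), 1e-12)
})

test_that("smoothing with derivative 0 and maximal polyorder reproduces the input", {
  wl <- seq(400, 500, by = 2)
  set.seed(6)
  X <- matrix(runif(3 * length(wl)), 3)
  pr <- preprocess(X, window = 7, polyorder = 6, derivative = 0,
                   normalize = FALSE, wavelength = wl)
  interior <- 4:(length(wl) - 3)
  expect_lt(max(abs(pr$values - X[, interior])), 1e-8)
})

test_that("preprocess validates its inputs", {
  wl <- seq(400, 500, by = 2)
  X <- matrix(runif(2 * length(wl)), 2)
  expect_error(preprocess(X, window = 36, wavelength = wl),
               class = "cyanophen_invalid_argument")
  expect_error(preprocess(X, window = 101, wavelength = wl),
               class = "cyanophen_invalid_argument")
  expect_error(preprocess(X, wavelength = c(wl[-1], 1e4)),
               class = "cyanophen_invalid_input")
  # normalized stage: band means 0, variances 1
  pr <- preprocess(X, window = 5, polyorder = 2, derivative = 0,
                   normalize = TRUE, wavelength = wl)
  Xn <- scale(X)
  expect_lt(max(abs(colMeans(Xn))), 1e-8)
  expect_lt(max(abs(apply(Xn, 2, stats::sd) - 1)), 1e-8)
})

test_that("spectral index registry reproduces hand arithmetic", {
  wl <- 400:2400
  refl <- 0.1 + 0.2 * (sin((wl - 400) / 300) + 1) / 2
  sp <- matrix(refl, 1, dimnames = list("t1", NULL))
  r <- function(w) refl[match(w, wl)]
  s <- compute_sri(sp, c("LRDSI1", "ARI", "NPCI", "SR10", "NDLI", "NDNI",
                         "BRI", "SR7", "BGI", "GMI1", "SR3"),
                   wavelength = wl)
  expect_equal(s$LRDSI1, 6.9 * (r(605) / r(455)) - 1.2, tolerance = 1e-12)
  expect_equal(s$ARI, 1 / r(550) - 1 / r(700), tolerance = 1e-12)
  expect_equal(s$NPCI, (r(680) - r(430)) / (r(680) + r(430)), tolerance = 1e-12)
  expect_equal(s$SR10, r(685) / r(655), tolerance = 1e-12)
  expect_equal(s$NDLI,
               (log(1 / r(1754)) - log(1 / r(1680))) /
                 (log(1 / r(1754)) + log(1 / r(1680))), tolerance = 1e-12)
  expect_equal(s$NDNI,
               (log(1 / r(1510)) - log(1 / r(1680))) /
                 (log(1 / r(1510)) + log(1 / r(1680))), tolerance = 1e-12)
  expect_equal(s$BRI, r(450) / r(690), tolerance = 1e-12)
  expect_equal(s$SR3, s$GMI1)
  # worked constants: flat bands
  sp2 <- matrix(0.1, 1, length(wl), dimnames = list("t2", NULL))
  sp2[1, match(605, wl)] <- 0.2
  s2 <- compute_sri(sp2, "LRDSI1", wavelength = wl)
  expect_equal(s2$LRDSI1, 6.9 * 2 - 1.2)   # = 12.6
  s3 <- compute_sri(sp2, "NPCI", wavelength = wl)
  expect_equal(s3$NPCI, 0)                 # R680 = R430
})

test_that("compute_sri is invariant to row order and errors on missing bands", {
  pop <- small_pop()
  sp <- pop$spectra
  s1 <- compute_sri(sp, c("ARI", "GMI1"))
  perm <- rev(seq_len(nrow(sp$reflectance)))
  sp2 <- sp
  sp2$reflectance <- sp$reflectance[perm, ]
  s2 <- compute_sri(sp2, c("ARI", "GMI1"))
  expect_equal(s1$ARI, rev(s2$ARI))
  # 10-nm grid cannot resolve the 605/455 nm bands within +/-2 nm
  expect_error(compute_sri(sp, "LRDSI1"), class = "cyanophen_missing_band")
  # plug-in registry
  register_sri("TESTIDX", function(r, dmax) r(700) / r(400))
  st <- compute_sri(sp, "TESTIDX")
  expect_equal(st$TESTIDX,
               unname(sp$reflectance[, match(700, sp$wavelength)] /
                        sp$reflectance[, match(400, sp$wavelength)]))
})

test_that("VIF follows its closed form and flags collinearity", {
  set.seed(8)
  # columns orthogonal to each other and to the intercept
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 3), 100))))[, -1]
  v <- vif(Q)
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-8)
  # two columns with exact sample correlation 0.9
  x <- scale(rnorm(200))[, 1]
  z <- scale(resid(lm(rnorm(200) ~ x)))[, 1]
  y <- 0.9 * x + sqrt(1 - 0.81) * z
  v2 <- vif(cbind(x = x, y = y))
  expect_equal(v2$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-6)
  expect_equal(v2$class, c("none", "none"))
  # identical columns
  v3 <- vif(cbind(a = x, b = x))
  expect_true(all(is.infinite(v3$vif)))
  expect_equal(v3$class, c("severe", "severe"))
  expect_error(vif(cbind(x)), class = "cyanophen_invalid_argument")
})

test_that("stepwise AIC selection finds true effects and respects the null", {
  # power: 30 candidates, 3 with standardized effects 0.3 at n = 400
  hits <- vapply(1:10, function(s) {
    set.seed(900 + s)
    X <- matrix(rnorm(400 * 30), 400)
    colnames(X) <- sprintf("c%02d", 1:30)
    y <- 0.3 * (X[, 1] + X[, 2] + X[, 3]) + rnorm(400)
    sel <- stepwise_select(X, y)
    all(c("c01", "c02", "c03") %in% sel$selected)
  }, logical(1))
  expect_gte(sum(hits), 8)
  # null: a single uncorrelated candidate is selected rarely
  null_sel <- vapply(1:20, function(s) {
    set.seed(700 + s)
    X <- matrix(rnorm(500), 500, 1, dimnames = list(NULL, "x"))
    length(stepwise_select(X, rnorm(500))$selected) > 0
  }, logical(1))
  expect_lt(mean(null_sel), 0.2)
  # selection is invariant to affine rescaling of candidates
  set.seed(55)
  X <- matrix(rnorm(300 * 5), 300)
  colnames(X) <- paste0("v", 1:5)
  y <- 0.5 * X[, 2] + rnorm(300)
  s1 <- stepwise_select(X, y)
  X2 <- sweep(sweep(X, 2, c(2, 0.1, 5, 1, 3), "*"), 2, c(1, -4, 0, 2, 7), "+")
  colnames(X2) <- colnames(X)
  s2 <- stepwise_select(X2, y)
  expect_setequal(s1$selected, s2$selected)
  # AIC non-increasing along the accepted path
  expect_true(all(diff(s1$aic_path$aic) <= 1e-8))
})

test_that("duplicated candidates: one of the pair is selected, both flagged if forced", {
  set.seed(77)
  x <- rnorm(300)
  X <- cbind(a = x, b = x, c = rnorm(300))
  y <- 0.6 * x + rnorm(300)
  sel <- stepwise_select(X, y)
  expect_equal(sum(c("a", "b") %in% sel$selected), 1)
  v <- vif(cbind(a = x, b = x))
  expect_true(all(v$class == "severe"))
})
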