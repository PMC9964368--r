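test_that("pretreatment specs validate their parameters", {
  expect_equal(pretreatment_spec("msc", "detrend")$label, "MSC + Detrend")
  expect_error(pretreatment_spec("mc", "mc"), "one mean-centering")
  expect_error(pretreatment_spec(list(type = "d1", window = 10)), "odd")
  expect_error(pretreatment_spec(list(type = "d1", window = 5,
                                      polyorder = 5)), "polyorder")
  expect_error(pretreatment_spec(list(type = "d2", window = 5,
                                      polyorder = 1)), "<= polyorder")
})

test_that("MSC recovers affine scatter and matches least squares", {
  # every row equal to the mean spectrum: identity with a = 0, b = 1
  w <- seq(1100, 1200, by = 4)
  shape <- 0.5 + 0.2 * sin((w - 1100) / 30)
  s_const <- spectra_set(rbind(shape, shape, shape), w,
                         sample_ids = c("r1", "r2", "r3"))
  f <- msc_fit(s_const)
  expect_equal(unname(f$fitted$a), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(f$fitted$b), rep(1, 3), tolerance = 1e-12)
  expect_spectra_equal(f$corrected, s_const, tol = 1e-12)

  # a new spectrum that is an exact affine transform of the stored
  # reference is mapped back onto the reference
  new <- spectra_set(rbind(1.5 * shape + 0.2, 2 * shape), w)
  corr <- msc_apply(new, f$fitted)
  expect_lt(max(abs(sweep(corr$absorbance, 2, shape))), 1e-12)
  cf <- mealwormNIRS:::msc_coefficients(new$absorbance, f$fitted$reference)
  expect_equal(unname(cf$a), c(0.2, 0), tolerance = 1e-12)
  expect_equal(unname(cf$b), c(1.5, 2), tolerance = 1e-12)

  # random spectra: coefficients match a per-row lm() normal-equations fit
  s <- random_spectra(n = 6, p = 30, seed = 3)
  fit <- msc_fit(s)
  ref <- colMeans(s$absorbance)
  for (i in 1:6) {
    co <- coef(lm(s$absorbance[i, ] ~ ref))
    expect_lt(abs(fit$fitted$a[i] - co[1]), 1e-10)
    expect_lt(abs(fit$fitted$b[i] - co[2]), 1e-10)
  }

  # transforming the calibration set reproduces the fit output
  expect_spectra_equal(msc_apply(s, fit$fitted), fit$corrected, tol = 1e-12)

  # degenerate flat spectrum is refused by name
  flat <- spectra_set(rbind(s$absorbance[1:2, ], 0.4), s$wavelengths,
                      c("a", "b", "flatling"))
  expect_error(msc_fit(flat), "flatling")
})

test_that("MSC is idempotent on its own scatter model", {
  s <- affine_family_spectra(n = 8, seed = 21)
  once <- msc_fit(s)$corrected
  twice <- msc_fit(once)$corrected
  expect_spectra_equal(once, twice, tol = 1e-9)
})

test_that("detrend removes exact polynomials and is a projection", {
  w <- seq(1100, 1300, by = 4)
  lambda <- w
  poly2 <- 3 + 0.01 * lambda + 1e-5 * lambda^2
  s <- spectra_set(rbind(poly2, 2 * poly2), w)
  expect_lt(max(abs(detrend(s, 2)$absorbance)), 1e-9)

  # order 0 subtracts the row mean
  r <- random_spectra(n = 4, p = length(w), seed = 8, lo = 1100, hi = 1300)
  d0 <- detrend(r, 0)
  expect_equal(d0$absorbance,
               r$absorbance - rowMeans(r$absorbance), tolerance = 1e-12)

  # order 2 equals per-row polynomial regression residuals
  d2 <- detrend(r, 2)
  for (i in 1:4) {
    res <- resid(lm(r$absorbance[i, ] ~ poly(w, 2)))
    expect_lt(max(abs(d2$absorbance[i, ] - res)), 1e-9)
  }

  # projection: applying twice equals applying once
  expect_spectra_equal(detrend(d2, 2), d2, tol = 1e-9)

  expect_error(detrend(r, length(w)), "below the number")
})

test_that("mean centering stores calibration means and replays them", {
  cal <- random_spectra(n = 10, p = 20, seed = 13)
  f <- mean_center_fit(cal)
  expect_lt(max(abs(colMeans(f$centered$absorbance))), 1e-12)
  expect_equal(f$means, colMeans(cal$absorbance))

  # a validation row equal to the calibration mean maps to zero
  val <- spectra_set(rbind(f$means, cal$absorbance[1, ] + 1),
                     cal$wavelengths)
  cv <- mean_center_apply(val, f$means)
  expect_lt(max(abs(cv$absorbance[1, ])), 1e-12)
  expect_equal(unname(cv$absorbance[2, ]),
               unname(cal$absorbance[1, ] + 1 - f$means))
})

test_that("Savitzky-Golay derivatives match analytic and windowed fits", {
  w <- seq(1100, 1200, by = 2)
  p <- length(w)

  # constant spectrum: both derivatives vanish everywhere
  s_const <- spectra_set(matrix(0.8, 2, p), w)
  expect_lt(max(abs(sg_derivative(s_const, 1)$absorbance)), 1e-12)
  expect_lt(max(abs(sg_derivative(s_const, 2)$absorbance)), 1e-12)

  # lambda^2 on a 2 nm grid: second derivative is exactly 2 per nm^2
  sq <- spectra_set(matrix((w / 100)^2 * 1e4, 1, p), w)  # = w^2, scaled
  d2 <- sg_derivative(sq, 2, window = 7, polyorder = 3)
  interior <- 4:(p - 3)
  expect_lt(max(abs(d2$absorbance[1, interior] - 2)), 1e-6)
  # and the first derivative is 2*lambda
  d1 <- sg_derivative(sq, 1, window = 7, polyorder = 3)
  expect_lt(max(abs(d1$absorbance[1, interior] - 2 * w[interior])), 1e-6)

  # random spectrum: interior points equal a direct local polynomial fit
  r <- random_spectra(n = 1, p = p, seed = 31)
  for (deriv in 1:2) {
    got <- sg_derivative(r, deriv, window = 11, polyorder = 3)
    m <- 5
    for (j in c(m + 1, 25, p - m)) {
      idx <- (j - m):(j + m)
      fit <- lm(r$absorbance[1, idx] ~ poly(w[idx] - w[j], 3, raw = TRUE))
      expect_lt(abs(got$absorbance[1, j] -
                      factorial(deriv) * coef(fit)[deriv + 1]), 1e-8)
    }
  }

  expect_error(sg_derivative(r, 1, window = 8), "odd")
})

test_that("interior SG derivative agrees with signal::sgolayfilt", {
  skip_if_not_installed("signal")
  w <- seq(1100, 1200, by = 2)
  r <- random_spectra(n = 1, p = length(w), seed = 77)
  got <- sg_derivative(r, 1, window = 11, polyorder = 3)
  ref <- signal::sgolayfilt(r$absorbance[1, ], p = 3, n = 11, m = 1,
                            ts = 2)
  interior <- 6:(length(w) - 5)
  expect_lt(max(abs(got$absorbance[1, interior] - ref[interior])), 1e-8)
})

test_that("pipelines compose steps in order and fit on calibration only", {
  cal <- random_spectra(n = 8, p = 30, seed = 41)
  val <- random_spectra(n = 4, p = 30, seed = 42)

  # [none] is the identity
  id <- fit_pretreatment(pretreatment_spec("none"), cal, list(val))
  expect_spectra_equal(id$cal, cal, tol = 1e-15)
  expect_spectra_equal(id$others[[1]], val, tol = 1e-15)

  # msc + mc equals manual sequential application
  pp <- fit_pretreatment(pretreatment_spec("msc", "mc"), cal, list(val))
  m1 <- msc_fit(cal)
  v1 <- msc_apply(val, m1$fitted)
  m2 <- mean_center_fit(m1$corrected)
  v2 <- mean_center_apply(v1, m2$means)
  expect_spectra_equal(pp$cal, m2$centered, tol = 1e-12)
  expect_spectra_equal(pp$others[[1]], v2, tol = 1e-12)

  # fitted state must not depend on the validation data
  other_val <- random_spectra(n = 4, p = 30, seed = 43)
  pp2 <- fit_pretreatment(pretreatment_spec("msc", "mc"), cal,
                          list(other_val))
  expect_identical(pp$fitted$state, pp2$fitted$state)

  # replay on new spectra equals the pipeline's own transform
  expect_spectra_equal(apply_pretreatment(pp$fitted, val), pp$others[[1]],
                       tol = 1e-12)

  # grid mismatch is refused
  off_grid <- random_spectra(n = 2, p = 30, seed = 44, lo = 1100, hi = 1229)
  expect_error(fit_pretreatment(pretreatment_spec("msc"), cal,
                                list(off_grid)), "grid")
  expect_error(apply_pretreatment(pp$fitted, off_grid), "grid")
})

test_that("centering and detrend are linear transforms", {
  s1 <- random_spectra(n = 5, p = 24, seed = 51)
  s2 <- random_spectra(n = 5, p = 24, seed = 52)
  a <- 0.7; b <- -1.3
  combo <- spectra_set(a * s1$absorbance + b * s2$absorbance,
                       s1$wavelengths)
  d_combo <- detrend(combo, 2)
  d_sep <- a * detrend(s1, 2)$absorbance + b * detrend(s2, 2)$absorbance
  expect_lt(max(abs(d_combo$absorbance - d_sep)), 1e-9)
})
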