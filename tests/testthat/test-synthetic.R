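test_that("reference generation honours group parameters and the seed", {
  fa <- setNames(c(1, 5, 21, 2, 3, 38, 27, 3), names(fa_classification()))
  g_const <- group_spec("G", fat_mean = 12, fat_sd = 0, fa_means = fa)
  ref0 <- generate_reference(list(g_const), n_per_group = 6, seed = 1)
  expect_equal(ref0$fat, rep(12, 6))
  expect_equal(unname(as.matrix(ref0[, names(fa)])),
               matrix(rep(fa, each = 6), 6), tolerance = 1e-12)

  g <- group_spec("G", 12, 1.5, fa)
  r1 <- generate_reference(list(g), 20, seed = 42)
  r2 <- generate_reference(list(g), 20, seed = 42)
  expect_identical(r1, r2)
  r3 <- generate_reference(list(g), 20, seed = 43)
  expect_false(identical(r1$fat, r3$fat))

  # profiles renormalise to 100 and class sums are consistent
  expect_lt(max(abs(rowSums(r1[, names(fa)]) - 100)), 1e-9)
  expect_equal(r1$SFA + r1$MUFA + r1$PUFA, rep(100, 20), tolerance = 1e-9)

  # Monte-Carlo check of the truncated-normal fat draw
  big <- generate_reference(list(g), 10000, seed = 7)
  se_mean <- 1.5 / sqrt(10000)
  expect_lt(abs(mean(big$fat) - 12), 3 * se_mean)
  expect_lt(abs(sd(big$fat) - 1.5), 3 * 1.5 / sqrt(2 * 9999))

  expect_error(group_spec("bad", 12, 1, fa, fat_bounds = c(13, 14)),
               "infeasible")
  expect_error(group_spec("bad", 12, 1, fa / 2), "sum")
})

test_that("spectra follow the band model exactly when noise-free", {
  fa <- setNames(c(1, 5, 21, 2, 3, 38, 27, 3), names(fa_classification()))
  g <- group_spec("G", 12, 2, fa)
  ref <- generate_reference(list(g), 5, seed = 3)
  cfg <- synthetic_config(scatter_a = c(0, 0), scatter_b = c(1, 1),
                          noise_sd = 0)
  sp <- generate_spectra(ref, cfg, seed = 1)
  w <- cfg$wavelengths
  closed_form <- function(i) {
    out <- cfg$baseline[1] + cfg$baseline[2] * (w - 1100)
    for (nm in names(cfg$constituents)) {
      for (b in cfg$constituents[[nm]]) {
        out <- out + ref[[nm]][i] * b$amplitude *
          exp(-(w - b$center)^2 / (2 * b$width^2))
      }
    }
    out
  }
  for (i in c(1, 5)) {
    expect_lt(max(abs(sp$absorbance[i, ] - closed_form(i))), 1e-12)
  }

  # doubling fat doubles the fat-band contribution above baseline
  cfg_fat <- synthetic_config(constituents = list(
    fat = list(band_spec(1727, 35, 0.018))),
    scatter_a = c(0, 0), scatter_b = c(1, 1), noise_sd = 0)
  ref2 <- ref; ref2$fat <- 2 * ref$fat
  s1 <- generate_spectra(ref, cfg_fat, seed = 1)
  s2 <- generate_spectra(ref2, cfg_fat, seed = 1)
  base <- cfg$baseline[1] + cfg$baseline[2] * (w - 1100)
  j <- which.min(abs(w - 1727))
  expect_equal(s2$absorbance[, j] - base[j],
               2 * (s1$absorbance[, j] - base[j]), tolerance = 1e-12)

  expect_error(generate_spectra(ref[, c("sample_id", "fat")], cfg, 1),
               "constituent")
})

test_that("scatter hides the fat signal and MSC recovers it", {
  groups <- default_group_specs()
  ref <- generate_reference(groups, 4, seed = 11)
  w <- synthetic_config()$wavelengths
  j <- which.min(abs(w - 1727))

  clean_cfg <- synthetic_config(scatter_a = c(0, 0), scatter_b = c(1, 1),
                                noise_sd = 0)
  clean <- generate_spectra(ref, clean_cfg, seed = 12)
  r_clean <- cor(clean$absorbance[, j], ref$fat)
  expect_gt(r_clean, 0.9)

  # strong multiplicative scatter degrades the raw correlation ...
  messy_cfg <- synthetic_config(scatter_a = c(-0.1, 0.1),
                                scatter_b = c(0.6, 1.4), noise_sd = 0.002)
  messy <- generate_spectra(ref, messy_cfg, seed = 12)
  r_messy <- cor(messy$absorbance[, j], ref$fat)
  expect_lt(r_messy, r_clean)

  # ... and MSC restores most of it
  fixed <- msc_fit(messy)$corrected
  r_fixed <- cor(fixed$absorbance[, j], ref$fat)
  expect_gt(r_fixed, 0.9)
})

test_that("the canonical case study is a stratified 80/40 split", {
  cs <- make_case_study(seed = 114)
  expect_equal(nrow(cs$calibration$reference), 80)
  expect_equal(nrow(cs$validation$reference), 40)
  expect_equal(dim(cs$calibration$spectra), c(80L, 501L))
  expect_equal(dim(cs$validation$spectra), c(40L, 501L))

  # every feeding group appears in both sets
  expect_setequal(unique(cs$calibration$reference$group),
                  names(default_group_specs()))
  expect_setequal(unique(cs$validation$reference$group),
                  names(default_group_specs()))

  # spectra align with reference rows by id
  expect_equal(rownames(cs$calibration$spectra$absorbance),
               cs$calibration$reference$sample_id)

  # the same seed reproduces byte-identical CSV output
  t1 <- tempfile(fileext = ".csv"); t2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(t1, t2)))
  write_spectra_csv(cs$calibration$spectra, t1)
  write_spectra_csv(make_case_study(seed = 114)$calibration$spectra, t2)
  expect_identical(readLines(t1), readLines(t2))

  # fat spans a realistic range with the expected pooled spread
  all_fat <- c(cs$calibration$reference$fat, cs$validation$reference$fat)
  expect_gt(sd(all_fat), 1.8)
  expect_lt(sd(all_fat), 3.2)
  expect_gt(min(all_fat), 5)
  expect_lt(max(all_fat), 18)
})

test_that("more noise means worse median fat prediction", {
  msc_mc <- list(MSCMC = pretreatment_spec("msc", "mc"))
  med_r2p <- vapply(c(0.001, 0.02, 0.2), function(nsd) {
    r2 <- vapply(1:5, function(s) {
      groups <- default_group_specs()
      ref <- generate_reference(groups, 3, seed = 1000 + s)
      cfg <- synthetic_config(noise_sd = nsd)
      sp <- generate_spectra(ref, cfg, seed = 2000 + s)
      cal_i <- seq(1, nrow(ref), by = 3)
      val_i <- setdiff(seq_len(nrow(ref)), cal_i)
      run <- run_calibration(sp[cal_i], ref[cal_i, ], sp[val_i],
                             ref[val_i, ], analytes = "fat",
                             pretreatments = msc_mc)
      run$fat$report$r2_p
    }, numeric(1))
    median(r2)
  }, numeric(1))
  expect_true(all(diff(med_r2p) < 0))
})
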