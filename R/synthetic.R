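# RNG hygiene: every generator takes an explicit seed and restores the
# caller's RNG state, so a single pipeline seed expands to reproducible
# per-stage child seeds (stage offsets documented in make_case_study).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Gaussian absorption band
#'
#' @param center band centre in nm (must lie on/within the working grid).
#' @param width Gaussian sigma in nm, > 0.
#' @param amplitude absorbance contribution per unit constituent
#'   concentration at the band centre.
#' @return list of class `band_spec`.
#' @export
band_spec <- function(center, width, amplitude) {
  if (width <= 0) stop("band width must be > 0", call. = FALSE)
  if (center < 1100 || center > 2100) {
    stop("band centre must lie within 1100-2100 nm", call. = FALSE)
  }
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "band_spec")
}

#' Synthetic spectra configuration
#'
#' Describes how constituent concentrations map to clean absorbance spectra
#' and how measurement artefacts are added. A clean spectrum is a smooth
#' baseline plus, for each constituent, concentration times a sum of Gaussian
#' absorption bands; the observed spectrum is `a + b * clean + noise` with
#' per-sample additive offset `a`, multiplicative slope `b` and iid Gaussian
#' noise — the scatter structure that multiplicative scatter correction is
#' designed to remove.
#'
#' The default band set mirrors the features seen in living-larva spectra:
#' fat-linked bands at 1205, 1727 and 1797 nm and water/protein bands at 1454
#' and 1930 nm. Fatty-acid constituents (keys like `"C18:1w9"`) use the
#' acid's relative percentage scaled by total fat as concentration, so
#' fat-correlated and fat-independent acids can both be emulated.
#'
#' @param wavelengths wavelength grid (default 1100-2100 nm at 2 nm).
#' @param constituents named list; each element a list of [band_spec()]s.
#'   Names must be columns of the reference table.
#' @param fa_bands named list of band lists for fatty-acid keys (may be
#'   empty).
#' @param baseline numeric `c(intercept, slope_per_nm)` of the smooth
#'   baseline (slope applied to nm above 1100).
#' @param scatter_a,scatter_b ranges (length-2) of the uniform additive /
#'   multiplicative scatter; `scatter_b` must be bounded away from 0.
#' @param noise_sd additive noise standard deviation, >= 0 (absorbance
#'   units).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(wavelengths = seq(1100, 2100, by = 2),
                             constituents = list(
                               fat = list(band_spec(1205, 30, 0.010),
                                          band_spec(1727, 35, 0.018),
                                          band_spec(1797, 40, 0.012)),
                               water = list(band_spec(1454, 50, 0.006),
                                            band_spec(1930, 60, 0.009)),
                               protein = list(band_spec(1454, 45, 0.004),
                                              band_spec(1930, 55, 0.003))),
                             fa_bands = list(),
                             baseline = c(0.35, 2.5e-4),
                             scatter_a = c(-0.05, 0.05),
                             scatter_b = c(0.8, 1.2),
                             noise_sd = 0.002) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (min(scatter_b) <= 0) {
    stop("multiplicative scatter range must stay away from 0", call. = FALSE)
  }
  for (bl in c(constituents, fa_bands)) {
    for (b in bl) stopifnot(inherits(b, "band_spec"))
  }
  structure(list(wavelengths = wavelengths, constituents = constituents,
                 fa_bands = fa_bands, baseline = baseline,
                 scatter_a = scatter_a, scatter_b = scatter_b,
                 noise_sd = noise_sd),
            class = "synthetic_config")
}

#' Group specification for the reference generator
#'
#' @param label feeding-group label.
#' @param fat_mean,fat_sd group fat content mean / SD, g/100 g fresh weight.
#' @param fa_means named numeric vector of mean fatty-acid relative
#'   percentages (should sum to about 100; `NA` = not detected, kept at 0).
#' @param concentration Dirichlet concentration controlling the
#'   compositional jitter of the fatty-acid profile (larger = tighter).
#' @param fat_bounds truncation bounds for the fat draw.
#' @return list of class `group_spec`.
#' @export
group_spec <- function(label, fat_mean, fat_sd, fa_means,
                       concentration = 2500, fat_bounds = c(5, 18)) {
  if (fat_sd < 0) stop("fat_sd must be >= 0", call. = FALSE)
  if (fat_bounds[1] >= fat_bounds[2] ||
      fat_mean < fat_bounds[1] || fat_mean > fat_bounds[2]) {
    stop("infeasible truncation bounds for group ", label, call. = FALSE)
  }
  s <- sum(fa_means, na.rm = TRUE)
  if (abs(s - 100) > 2) {
    stop("fatty-acid means for ", label, " sum to ", round(s, 1),
         ", expected about 100", call. = FALSE)
  }
  structure(list(label = label, fat_mean = fat_mean, fat_sd = fat_sd,
                 fa_means = fa_means, concentration = concentration,
                 fat_bounds = fat_bounds),
            class = "group_spec")
}

#' Default feeding-group specifications
#'
#' One [group_spec()] per feeding group. Fatty-acid mean profiles come from
#' the bundled larval composition table; group fat means are fixed values
#' spanning the observed larval range (about 7.4-16.2 g/100 g, pooled SD
#' about 2.3) with the coconut- and flaxseed-enriched groups at the top and
#' the high-protein groups at the bottom, and a within-group SD of 0.4.
#'
#' @return named list of `group_spec` objects (15 feeding groups).
#' @export
default_group_specs <- function() {
  fat_means <- c(CF5 = 11.5, CF10 = 14.0, CF15 = 16.1, CF20 = 15.9,
                 FSF5 = 10.5, FSF10 = 12.5, FSF15 = 14.5, FSF20 = 14.0,
                 GP4 = 9.5, HPF5 = 10.0, HPF8 = 8.5, RHH4 = 9.8,
                 PPF5 = 8.8, PPF6 = 7.6, WB = 10.8)
  fa <- larval_fa_profiles()
  fa_keys <- names(fa_classification())
  specs <- lapply(names(fat_means), function(g) {
    row <- fa[fa$group == g, , drop = FALSE]
    means <- as.numeric(row[1, fa_keys])
    names(means) <- fa_keys
    group_spec(g, fat_means[[g]], 0.4, means)
  })
  names(specs) <- names(fat_means)
  specs
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
    guard <- guard + 1
    if (guard > 1000) stop("truncation bounds reject almost all draws",
                           call. = FALSE)
  }
  out[seq_len(n)]
}

#' Generate synthetic reference chemistry
#'
#' Per group, fat is drawn from a truncated normal and the fatty-acid profile
#' from a Dirichlet distribution centred on the group mean profile (scaled by
#' the concentration parameter) and renormalised to 100%. Not-detected acids
#' stay exactly 0. Additional constituents emulating the rest of the larval
#' matrix are included for spectra generation: `water` and `protein` (% fresh
#' weight) and `inert`, a band-free tracer drawn independently of fat, useful
#' for probing what a calibration cannot learn.
#'
#' @param groups list of [group_spec()]s.
#' @param n_per_group samples per group, >= 1.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return a [reference_table()] with `group`, fatty-acid, `SFA`/`MUFA`/
#'   `PUFA`, `water`, `protein` and `inert` columns.
#' @export
generate_reference <- function(groups, n_per_group, seed) {
  stopifnot(n_per_group >= 1)
  with_seed(seed, {
    fa_keys <- names(fa_classification())
    rows <- lapply(groups, function(g) {
      fat <- rtruncnorm1(n_per_group, g$fat_mean, g$fat_sd,
                         g$fat_bounds[1], g$fat_bounds[2])
      means <- g$fa_means
      present <- !is.na(means) & means > 0
      prof <- matrix(0, n_per_group, length(fa_keys),
                     dimnames = list(NULL, fa_keys))
      if (g$concentration <= 0 || g$fat_sd == 0) {
        prof[, present] <- matrix(rep(means[present], each = n_per_group),
                                  n_per_group)
      } else {
        shape <- g$concentration * means[present] / 100
        draws <- matrix(stats::rgamma(n_per_group * sum(present),
                                      shape = rep(shape, each = n_per_group)),
                        n_per_group)
        prof[, present] <- 100 * draws / rowSums(draws)
      }
      data.frame(group = g$label, fat = fat, prof, check.names = FALSE,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    n <- nrow(df)
    df$sample_id <- sprintf("%s_%02d", df$group,
                            stats::ave(seq_len(n), df$group, FUN = seq_along))
    cls <- fa_classification()
    fa_mat <- as.matrix(df[, fa_keys])
    df$SFA <- rowSums(fa_mat[, cls[fa_keys] == "SFA", drop = FALSE])
    df$MUFA <- rowSums(fa_mat[, cls[fa_keys] == "MUFA", drop = FALSE])
    df$PUFA <- rowSums(fa_mat[, cls[fa_keys] == "PUFA", drop = FALSE])
    df$water <- stats::rnorm(n, 62, 1.5)
    df$protein <- stats::rnorm(n, 19, 1)
    df$inert <- stats::rnorm(n, 2, 0.4)
    args <- c(list(sample_ids = df$sample_id, fat = df$fat),
              as.list(df[c(fa_keys, "SFA", "MUFA", "PUFA",
                           "water", "protein", "inert")]),
              list(group = df$group))
    do.call(reference_table, args)
  })
}

#' Generate synthetic NIR spectra from reference chemistry
#'
#' See [synthetic_config()] for the generative model. Deterministic under
#' `seed`.
#'
#' @param ref a `reference_table` containing every constituent column the
#'   config references.
#' @param config a `synthetic_config`.
#' @param seed integer seed for scatter and noise.
#' @return a [spectra_set()] aligned with `ref`.
#' @export
generate_spectra <- function(ref, config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  w <- config$wavelengths
  n <- nrow(ref)
  need <- names(config$constituents)
  missing <- setdiff(need, names(ref))
  if (length(missing)) {
    stop("reference table lacks constituent column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  missing_fa <- setdiff(names(config$fa_bands), names(ref))
  if (length(missing_fa)) {
    stop("reference table lacks fatty-acid column(s): ",
         paste(missing_fa, collapse = ", "), call. = FALSE)
  }
  band_profile <- function(bands) {
    prof <- numeric(length(w))
    for (b in bands) {
      prof <- prof + b$amplitude * exp(-(w - b$center)^2 / (2 * b$width^2))
    }
    prof
  }
  clean <- matrix(rep(config$baseline[1] + config$baseline[2] * (w - 1100),
                      each = n), n)
  for (nm in need) {
    clean <- clean + outer(ref[[nm]], band_profile(config$constituents[[nm]]))
  }
  for (nm in names(config$fa_bands)) {
    conc <- ref[[nm]] * ref$fat / 100  # relative % scaled by total fat
    clean <- clean + outer(conc, band_profile(config$fa_bands[[nm]]))
  }
  with_seed(seed, {
    a <- stats::runif(n, config$scatter_a[1], config$scatter_a[2])
    b <- stats::runif(n, config$scatter_b[1], config$scatter_b[2])
    obs <- a + b * clean
    if (config$noise_sd > 0) {
      obs <- obs + matrix(stats::rnorm(n * length(w), 0, config$noise_sd), n)
    }
    spectra_set(obs, w, sample_ids = ref$sample_id)
  })
}

#' The canonical synthetic case study
#'
#' Generates reference chemistry and spectra for all fifteen feeding groups
#' (8 samples each, 120 in total) and splits them 2:1 into a calibration set
#' of 80 and a validation set of 40, stratified so every group appears in
#' both sets. Child seeds are derived from the single `seed` by fixed
#' offsets (`seed * 100 + 1` reference, `+ 2` spectra, `+ 3` split), so each
#' stage is independently reproducible.
#'
#' @param seed integer master seed (default 114, the fixture used
#'   throughout the package tests).
#' @param config a [synthetic_config()].
#' @return list with elements `calibration` and `validation`, each a list
#'   with `spectra` (a `spectra_set`) and `reference` (a `reference_table`).
#' @export
make_case_study <- function(seed = 114, config = synthetic_config()) {
  groups <- default_group_specs()
  ref <- generate_reference(groups, n_per_group = 8, seed = seed * 100 + 1)
  spec <- generate_spectra(ref, config, seed = seed * 100 + 2)
  # 80/20 split per group: 8 samples -> 5 calibration, plus one extra for
  # the first five groups so the totals are exactly 80 and 40
  cal_idx <- with_seed(seed * 100 + 3, {
    unlist(lapply(seq_along(groups), function(k) {
      idx <- which(ref$group == groups[[k]]$label)
      take <- if (k <= 5) 6 else 5
      sort(sample(idx, take))
    }))
  })
  val_idx <- setdiff(seq_len(nrow(ref)), cal_idx)
  subset_ref <- function(i) {
    out <- ref[i, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(calibration = list(spectra = spec[cal_idx],
                          reference = subset_ref(cal_idx)),
       validation = list(spectra = spec[val_idx],
                         reference = subset_ref(val_idx)))
}
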