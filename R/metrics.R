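#' Root mean square error
#'
#' Used as RMSEC on the calibration set and RMSEP on the validation set.
#'
#' @param y_true,y_pred numeric vectors of equal nonzero length.
#' @return sqrt(mean((y_true - y_pred)^2)).
#' @export
rmse <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  sqrt(mean((y_true - y_pred)^2))
}

#' Coefficient of determination
#'
#' Computed as 1 - SSE/SST with SST about the mean of `y_true`, which keeps
#' R2, RMSE and RPD mutually consistent on the same sample set. May be
#' negative for models worse than the mean.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return 1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2).
#' @export
r_squared <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  sst <- sum((y_true - mean(y_true))^2)
  if (sst < 1e-24) stop("zero-variance reference: R2 undefined",
                        call. = FALSE)
  1 - sum((y_true - y_pred)^2) / sst
}

#' Ratio of performance to deviation
#'
#' RPD = (validation-set reference standard deviation) / RMSEP, the standard
#' chemometric usefulness index (RPD >= 3 is conventionally fit for routine
#' analysis). The SD uses the n - 1 denominator and must come from the
#' validation set, which is what makes published SD/RMSEP/RPD triplets
#' internally consistent.
#'
#' @param reference_sd standard deviation of the validation reference values.
#' @param rmsep root mean square error of prediction, > 0.
#' @return reference_sd / rmsep.
#' @export
rpd <- function(reference_sd, rmsep) {
  if (!is.finite(rmsep) || rmsep <= 0) stop("rmsep must be > 0",
                                            call. = FALSE)
  if (!is.finite(reference_sd) || reference_sd < 0) {
    stop("reference_sd must be >= 0", call. = FALSE)
  }
  reference_sd / rmsep
}

#' Squared correlation of a fatty acid with total fat
#'
#' The R2_F diagnostic: the squared Pearson correlation between a fatty
#' acid's relative concentration (% of total FA) and the total fat content
#' across samples. It separates calibrations that merely ride on the fat
#' signal from those drawing on the acid's own absorption features.
#'
#' @param fa_values numeric vector of relative FA concentrations.
#' @param fat_values numeric vector of total fat, same length (>= 3).
#' @return squared Pearson correlation; 0 (with a warning) if either input
#'   has zero variance.
#' @export
r2_fat_correlation <- function(fa_values, fat_values) {
  fa_values <- as.numeric(fa_values); fat_values <- as.numeric(fat_values)
  if (length(fa_values) != length(fat_values) || length(fa_values) < 3) {
    stop("need two equal-length vectors with >= 3 values", call. = FALSE)
  }
  if (stats::var(fa_values) < 1e-24 || stats::var(fat_values) < 1e-24) {
    warning("zero variance: R2_F undefined, reporting 0")
    return(0)
  }
  stats::cor(fa_values, fat_values)^2
}

#' Assemble a calibration report across pretreatments
#'
#' One row per pretreatment with the calibration/validation statistics of a
#' fitted PLS model, shaped like published NIR model-comparison tables:
#' pretreatment label, number of latent variables, R2_C, RMSEC, R2_P, RMSEP,
#' RPD and (for fatty acids) R2_F. RPD uses the validation reference SD. The
#' best row by [select_best_model()] is marked `chosen`.
#'
#' @param analyte analyte name.
#' @param results named list, one element per pretreatment, each a list with
#'   `n_lv`, `cal_pred`, `val_pred` (numeric prediction vectors).
#' @param cal_ref,val_ref calibration / validation reference values.
#' @param fat_values optional validation-set total fat values for R2_F (use
#'   for fatty-acid analytes; omit for fat itself).
#' @return data.frame of class `calibration_report` with attribute `analyte`.
#' @export
build_report <- function(analyte, results, cal_ref, val_ref,
                         fat_values = NULL) {
  if (length(results) == 0) stop("no fitted models to report", call. = FALSE)
  if (is.null(names(results)) || any(names(results) == "")) {
    stop("results must be a named list (pretreatment labels)", call. = FALSE)
  }
  if (missing(val_ref) || length(val_ref) == 0) {
    stop("validation reference values are required", call. = FALSE)
  }
  val_sd <- summarize_reference(val_ref)$sd
  r2f <- if (is.null(fat_values)) NA_real_ else
    r2_fat_correlation(val_ref, fat_values)
  rows <- lapply(names(results), function(lbl) {
    r <- results[[lbl]]
    rmsep <- rmse(val_ref, r$val_pred)
    data.frame(
      pretreatment = lbl,
      n_lv = as.integer(r$n_lv),
      r2_c = r_squared(cal_ref, r$cal_pred),
      rmsec = rmse(cal_ref, r$cal_pred),
      r2_p = r_squared(val_ref, r$val_pred),
      rmsep = rmsep,
      rpd = if (rmsep > 0) rpd(val_sd, rmsep) else Inf,
      r2_f = r2f,
      stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report$chosen <- FALSE
  report$chosen[select_best_model(report, index = TRUE)] <- TRUE
  attr(report, "analyte") <- analyte
  attr(report, "val_sd") <- val_sd
  class(report) <- c("calibration_report", "data.frame")
  report
}

#' Select the best calibration among pretreatments
#'
#' Ranks by RPD (descending); ties are broken by lower RMSEP, then by fewer
#' latent variables — the usual "high R2 and RPD, low RMSE, few factors"
#' model-choice rule.
#'
#' @param report a `calibration_report` (or data.frame with columns `rpd`,
#'   `rmsep`, `n_lv`).
#' @param index if `TRUE` return the row index instead of the row.
#' @return the chosen row (or its index).
#' @export
select_best_model <- function(report, index = FALSE) {
  if (nrow(report) == 0) stop("empty report", call. = FALSE)
  ord <- order(-report$rpd, report$rmsep, report$n_lv)
  if (index) ord[1] else report[ord[1], , drop = FALSE]
}

#' @export
print.calibration_report <- function(x, digits = 3, ...) {
  cat("Calibration report:", attr(x, "analyte"), "\n")
  shown <- as.data.frame(x)
  for (cl in c("r2_c", "rmsec", "r2_p", "rmsep", "r2_f")) {
    shown[[cl]] <- round(shown[[cl]], digits)
  }
  shown$rpd <- round(shown$rpd, 2)
  shown$chosen <- ifelse(shown$chosen, "*", "")
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Write a calibration report as CSV
#'
#' Columns follow the published table order (pretreatment, latent variables,
#' calibration then validation statistics). Stored values keep full
#' precision unless `round = TRUE`.
#'
#' @param report a `calibration_report`.
#' @param path output path.
#' @param round round for display (3 decimals for R2/RMSE, 2 for RPD).
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path, round = FALSE) {
  out <- as.data.frame(report)
  out <- cbind(analyte = attr(report, "analyte"), out)
  if (round) {
    for (cl in c("r2_c", "rmsec", "r2_p", "rmsep", "r2_f")) {
      out[[cl]] <- round(out[[cl]], 3)
    }
    out$rpd <- round(out$rpd, 2)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
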