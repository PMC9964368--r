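grid_signature <- function(wavelengths) {
  p <- length(wavelengths)
  sprintf("grid:%d:%s:%s:%s", p, format_wavelength(wavelengths[1]),
          format_wavelength(wavelengths[p]),
          format_wavelength(if (p > 1) wavelengths[2] - wavelengths[1] else 0))
}

#' Run the full calibration workflow
#'
#' For each analyte and each candidate pretreatment: fit the pretreatment on
#' the calibration spectra, replay it on the validation spectra, pick the
#' number of latent variables by cross-validation (capped), fit the PLS1
#' model, predict the validation set and assemble the evaluation statistics
#' into a [build_report()] table. The best pretreatment per analyte is chosen
#' by [select_best_model()].
#'
#' PLS centering follows the pretreatment: a pipeline containing the `mc`
#' step yields a centered regression, any other pipeline runs PLS on the raw
#' (pretreated) absorbances, so "None" and "MC" are genuinely different
#' candidate models.
#'
#' @param cal_spectra,val_spectra `spectra_set`s on a common grid.
#' @param cal_reference,val_reference `reference_table`s; aligned to the
#'   spectra by sample id (never row order).
#' @param analytes character vector of reference column names to calibrate
#'   (default: fat).
#' @param pretreatments named list of [pretreatment_spec()]s; defaults to
#'   [standard_pretreatments()].
#' @param lv_cap cap on latent variables (default 10).
#' @param force_n_lv optionally force a fixed number of latent variables for
#'   every model instead of cross-validated selection.
#' @param scheme a [cv_scheme()] for latent-variable selection.
#' @param fat_column reference column holding total fat, used for the R2_F
#'   diagnostic of fatty-acid analytes (set `NULL` to skip).
#' @return object of class `calibration_run`: named list (per analyte) of
#'   lists with `report` (a `calibration_report`), `best` (chosen row) and
#'   `models` (per-pretreatment list with the fitted pretreatment, the
#'   `pls1_model` and the prediction vectors).
#' @export
run_calibration <- function(cal_spectra, cal_reference, val_spectra,
                            val_reference, analytes = "fat",
                            pretreatments = standard_pretreatments(),
                            lv_cap = 10, force_n_lv = NULL,
                            scheme = cv_scheme("venetian", 10),
                            fat_column = "fat") {
  cal <- align_samples(cal_spectra, cal_reference)
  val <- align_samples(val_spectra, val_reference)
  missing <- setdiff(analytes, names(cal$reference))
  if (length(missing)) {
    stop("analyte(s) not in the reference table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- lapply(analytes, function(analyte) {
    y_cal <- cal$reference[[analyte]]
    y_val <- val$reference[[analyte]]
    if (stats::var(y_cal) < 1e-24) {
      stop("zero-variance reference for analyte '", analyte, "'",
           call. = FALSE)
    }
    models <- list()
    results <- list()
    for (lbl in names(pretreatments)) {
      pre <- fit_pretreatment(pretreatments[[lbl]], cal$spectra,
                              list(val$spectra))
      centered <- any(vapply(pretreatments[[lbl]]$steps,
                             function(s) s$type == "mc", logical(1)))
      Xc <- pre$cal$absorbance
      Xv <- pre$others[[1]]$absorbance
      n_lv <- if (is.null(force_n_lv)) {
        cross_validate(Xc, y_cal, max_lv = lv_cap, scheme = scheme,
                       cap = lv_cap, center = centered)$n_lv
      } else as.integer(force_n_lv)
      fit <- fit_pls1(Xc, y_cal, n_lv, center = centered)
      models[[lbl]] <- list(pretreatment = pre$fitted, pls = fit,
                            cal_pred = fit$fitted_values,
                            val_pred = predict(fit, Xv))
      results[[lbl]] <- list(n_lv = n_lv,
                             cal_pred = models[[lbl]]$cal_pred,
                             val_pred = models[[lbl]]$val_pred)
    }
    fat_vals <- if (!is.null(fat_column) && analyte != fat_column &&
                    fat_column %in% names(val$reference)) {
      val$reference[[fat_column]]
    } else NULL
    report <- build_report(analyte, results, y_cal, y_val,
                           fat_values = fat_vals)
    list(report = report, best = select_best_model(report), models = models)
  })
  names(out) <- analytes
  structure(out, class = "calibration_run")
}

#' @export
print.calibration_run <- function(x, ...) {
  for (analyte in names(x)) {
    print(x[[analyte]]$report)
    cat("\n")
  }
  invisible(x)
}

#' Serialize a calibration model to JSON
#'
#' Stores the PLS regression vector, centering parameters, the fitted
#' pretreatment state and a wavelength-grid signature, so a saved model can
#' be applied to new spectra files and refuses grids it was not built for.
#'
#' @param model element of a `calibration_run` (list with `pretreatment` and
#'   `pls`), or a bare `pls1_model`.
#' @param path output JSON path.
#' @param wavelengths the calibration wavelength grid.
#' @param analyte analyte name recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, wavelengths, analyte = "fat") {
  if (inherits(model, "pls1_model")) {
    model <- list(pretreatment = NULL, pls = model)
  }
  pls <- model$pls
  pre <- model$pretreatment
  doc <- list(
    analyte = analyte,
    grid_signature = grid_signature(wavelengths),
    wavelengths = wavelengths,
    n_lv = pls$n_lv,
    center = pls$center,
    b = as.vector(pls$b),
    intercept = pls$intercept,
    x_means = as.vector(pls$x_means),
    y_mean = pls$y_mean,
    pretreatment = if (is.null(pre)) NULL else list(
      label = pre$spec$label,
      steps = pre$spec$steps,
      state = lapply(pre$state, function(s) {
        if (is.null(s)) NULL
        else lapply(s, function(v) if (is.numeric(v)) as.vector(v) else v)
      })))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a serialized calibration model
#'
#' @param path JSON path written by [write_model_json()].
#' @return list of class `serialized_model`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  doc$b <- as.numeric(doc$b)
  doc$x_means <- as.numeric(doc$x_means)
  structure(doc, class = "serialized_model")
}

#' Predict new spectra with a serialized model
#'
#' Replays the stored pretreatment (MSC reference, column means, derivative
#' settings) and applies the stored regression vector. Refuses spectra whose
#' wavelength grid does not match the model's grid signature.
#'
#' @param model a `serialized_model` from [read_model_json()] (or a path).
#' @param spectra a `spectra_set` (or path to a spectra CSV).
#' @return data.frame with `sample_id` and `predicted`.
#' @export
predict_from_model <- function(model, spectra) {
  if (is.character(model)) model <- read_model_json(model)
  if (is.character(spectra)) spectra <- read_spectra_csv(spectra)
  if (!identical(grid_signature(spectra$wavelengths),
                 model$grid_signature)) {
    stop("spectra grid (", grid_signature(spectra$wavelengths),
         ") does not match the model grid (", model$grid_signature, ")",
         call. = FALSE)
  }
  x <- spectra
  if (!is.null(model$pretreatment) && length(model$pretreatment)) {
    steps <- model$pretreatment$steps
    state <- model$pretreatment$state
    for (k in seq_along(steps)) {
      s <- steps[[k]]
      st <- if (k <= length(state)) state[[k]] else NULL
      x <- switch(s$type,
        none = x,
        msc = msc_apply(x, list(reference = as.numeric(st$reference))),
        mc = mean_center_apply(x, as.numeric(st$means)),
        detrend = detrend(x, as.integer(s$order)),
        d1 = sg_derivative(x, 1L, as.integer(s$window),
                           as.integer(s$polyorder)),
        d2 = sg_derivative(x, 2L, as.integer(s$window),
                           as.integer(s$polyorder)))
    }
  }
  pred <- as.vector(x$absorbance %*% model$b) + model$intercept
  data.frame(sample_id = sample_ids(spectra), predicted = pred,
             stringsAsFactors = FALSE)
}
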