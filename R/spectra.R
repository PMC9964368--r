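#' Construct a spectra set
#'
#' A `spectra_set` holds an `n_samples x n_wavelengths` absorbance matrix on a
#' shared wavelength grid. The grid must be strictly increasing, uniformly
#' spaced, and lie within the working range of the instrument (1100--2100 nm,
#' the range over which living-larva spectra are recorded).
#'
#' @param absorbance numeric matrix, one row per sample, one column per
#'   wavelength. Unitless absorbance.
#' @param wavelengths numeric vector of wavelengths in nm, one per column.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the rownames of `absorbance`.
#' @return An object of class `spectra_set`: a list with elements
#'   `wavelengths`, `absorbance` (rownames are the sample ids).
#' @export
spectra_set <- function(absorbance, wavelengths,
                        sample_ids = rownames(absorbance)) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%03d", seq_len(nrow(absorbance)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(absorbance)) {
    stop("number of sample ids does not match spectra rows", call. = FALSE)
  }
  rownames(absorbance) <- sample_ids
  if (length(wavelengths) == ncol(absorbance)) {
    colnames(absorbance) <- format_wavelength(wavelengths)
  }
  x <- structure(list(wavelengths = wavelengths, absorbance = absorbance),
                 class = "spectra_set")
  validate_spectra_set(x)
  x
}

format_wavelength <- function(w) {
  sub("\\.?0+$", "", sprintf("%.6f", w))
}

validate_spectra_set <- function(x) {
  w <- x$wavelengths
  A <- x$absorbance
  if (length(w) != ncol(A)) {
    stop("number of wavelengths (", length(w),
         ") does not match spectra columns (", ncol(A), ")", call. = FALSE)
  }
  if (length(w) >= 2) {
    d <- diff(w)
    if (any(d <= 0)) stop("wavelength grid must be strictly increasing",
                          call. = FALSE)
    if (max(d) - min(d) > 1e-9) {
      stop("wavelength grid must be uniformly spaced (step varies by ",
           format(max(d) - min(d)), " nm)", call. = FALSE)
    }
  }
  if (any(w < 1100 - 1e-9) || any(w > 2100 + 1e-9)) {
    stop("wavelengths must lie within 1100-2100 nm", call. = FALSE)
  }
  if (any(!is.finite(A))) {
    bad <- which(!is.finite(A), arr.ind = TRUE)[1, ]
    stop("non-finite absorbance for sample '", rownames(A)[bad[1]],
         "' at ", format_wavelength(w[bad[2]]), " nm", call. = FALSE)
  }
  ids <- rownames(A)
  if (anyDuplicated(ids)) {
    stop("duplicate sample id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " samples x ",
      length(x$wavelengths), " wavelengths (",
      format_wavelength(min(x$wavelengths)), "-",
      format_wavelength(max(x$wavelengths)), " nm)\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set by sample
#'
#' @param x a `spectra_set`.
#' @param i sample index or character vector of sample ids.
#' @param ... ignored.
#' @return a `spectra_set` with the selected rows.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$absorbance[i, , drop = FALSE], x$wavelengths)
}

sample_ids <- function(x) rownames(x$absorbance)

#' Read a wide spectra CSV
#'
#' Expected layout: first column `sample_id`, remaining column headers are
#' wavelengths in nm. Comma separator, dot decimal, header required.
#'
#' @param path path to the CSV file.
#' @return a validated [spectra_set()]; wavelength columns sorted ascending.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) stop("spectra CSV needs a sample id column plus at least ",
                         "one wavelength column", call. = FALSE)
  w <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(w)) {
    stop("wavelength headers not parseable as numbers: ",
         paste(names(df)[-1][is.na(w)], collapse = ", "), call. = FALSE)
  }
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(num), arr.ind = TRUE)
    stop("non-numeric or missing absorbance for sample '", ids[bad[1, 1]],
         "' in column '", names(df)[-1][bad[1, 2]], "'", call. = FALSE)
  }
  ord <- order(w)
  spectra_set(num[, ord, drop = FALSE], w[ord], sample_ids = ids)
}

#' Write a spectra set as wide CSV
#'
#' Inverse of [read_spectra_csv()]; values are written with 15 significant
#' digits so that a read/write round trip is the identity to well below 1e-9.
#'
#' @param x a `spectra_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  df <- data.frame(sample_id = sample_ids(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(apply(x$absorbance, 2, function(col)
    formatC(col, digits = 15, format = "g")), check.names = FALSE)
  names(vals) <- formatC(x$wavelengths, digits = 15, format = "g")
  utils::write.csv(cbind(df, vals), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average replicate spectra into per-sample spectra
#'
#' Each living larva sample is scanned repeatedly (quintuplicate measurements,
#' 50 scans in total per sample) and the replicate spectra are averaged into a
#' single spectrum per sample before calibration.
#'
#' @param x a `spectra_set` whose rows are replicate scans.
#' @param groups named character vector mapping replicate id (names) to output
#'   sample id (values).
#' @return a `spectra_set` with one row per distinct output sample, each the
#'   arithmetic mean of its replicate rows. Output samples appear in order of
#'   first occurrence.
#' @export
average_replicates <- function(x, groups) {
  stopifnot(inherits(x, "spectra_set"))
  ids <- sample_ids(x)
  unknown <- setdiff(names(groups), ids)
  if (length(unknown)) {
    stop("unknown replicate id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(ids, names(groups))
  if (length(missing)) {
    stop("replicate id(s) without group assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out_ids <- unique(unname(groups[ids]))
  M <- t(vapply(out_ids, function(s) {
    reps <- ids[groups[ids] == s]
    colMeans(x$absorbance[reps, , drop = FALSE])
  }, numeric(length(x$wavelengths))))
  spectra_set(M, x$wavelengths, sample_ids = out_ids)
}

#' Convert reflectance spectra to absorbance
#'
#' Applies the usual log10(1/R) transform. The calibration pipeline assumes
#' absorbance input; this helper is for instruments that export reflectance.
#'
#' @param x a `spectra_set` holding reflectance values in (0, 1].
#' @return a `spectra_set` of absorbance values.
#' @export
absorbance_from_reflectance <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  if (any(x$absorbance <= 0)) stop("reflectance must be positive",
                                   call. = FALSE)
  spectra_set(log10(1 / x$absorbance), x$wavelengths, sample_ids(x))
}

#' Summary statistics for a reference constituent
#'
#' Mean, minimum, maximum and sample standard deviation (n - 1 denominator),
#' as reported for calibration/validation reference chemistry.
#'
#' @param values numeric vector with at least two finite values.
#' @return object of class `summary_stats` with fields `mean`, `minimum`,
#'   `maximum`, `sd`, `n`.
#' @export
summarize_reference <- function(values) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("non-finite reference values",
                                    call. = FALSE)
  if (length(values) < 2) {
    stop("need at least 2 values to summarise (got ", length(values), ")",
         call. = FALSE)
  }
  structure(list(mean = mean(values), minimum = min(values),
                 maximum = max(values), sd = stats::sd(values),
                 n = length(values)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d  mean = %.4g  min = %.4g  max = %.4g  sd = %.4g\n",
              x$n, x$mean, x$minimum, x$maximum, x$sd))
  invisible(x)
}
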