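#' Construct a reference chemistry table
#'
#' Per-sample wet-chemistry references: total fat (g/100 g fresh weight) and,
#' optionally, further constituent columns such as fatty-acid relative
#' percentages (% of total fatty acids, dry-matter basis) or any other
#' analyte the calibration should target.
#'
#' @param sample_ids character vector of unique sample ids.
#' @param fat numeric vector of fat content, g/100 g fresh weight, >= 0.
#' @param ... further named numeric columns (same length), e.g. `"C18:1w9"`.
#' @param group optional character vector of feeding-group labels.
#' @return a data.frame of class `reference_table` with a `sample_id` column.
#' @export
reference_table <- function(sample_ids, fat, ..., group = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  fat <- as.numeric(fat)
  if (length(fat) != length(sample_ids)) {
    stop("fat must have one value per sample", call. = FALSE)
  }
  if (any(!is.finite(fat)) || any(fat < 0)) {
    stop("fat must be finite and >= 0", call. = FALSE)
  }
  df <- data.frame(sample_id = sample_ids, fat = fat,
                   stringsAsFactors = FALSE, check.names = FALSE)
  extra <- list(...)
  for (nm in names(extra)) {
    v <- as.numeric(extra[[nm]])
    if (length(v) != length(sample_ids)) {
      stop("column '", nm, "' must have one value per sample", call. = FALSE)
    }
    df[[nm]] <- v
  }
  if (!is.null(group)) df$group <- as.character(group)
  class(df) <- c("reference_table", "data.frame")
  df
}

#' Read / write reference chemistry CSV
#'
#' Wide CSV with a `sample_id` column, a `fat` column and optional further
#' analyte columns (fatty acids use keys such as `C12:0`, `C18:1w9`).
#'
#' @param path CSV path.
#' @return for `read_reference_csv`, a `reference_table`.
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "fat") %in% names(df))) {
    stop("reference CSV must have 'sample_id' and 'fat' columns",
         call. = FALSE)
  }
  num_cols <- setdiff(names(df), c("sample_id", "group"))
  args <- c(list(sample_ids = df$sample_id, fat = df$fat),
            as.list(df[setdiff(num_cols, "fat")]))
  if ("group" %in% names(df)) args$group <- df$group
  do.call(reference_table, args)
}

#' @rdname read_reference_csv
#' @param x a `reference_table`.
#' @export
write_reference_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align spectra and reference chemistry by sample id
#'
#' Joins on explicit sample ids (never row order) and errors listing the
#' offending ids when the two sources do not match one-to-one.
#'
#' @param spectra a `spectra_set`.
#' @param reference a `reference_table`.
#' @return list with the `spectra_set` and `reference_table` reordered to the
#'   spectra's sample order.
#' @export
align_samples <- function(spectra, reference) {
  sid <- sample_ids(spectra)
  rid <- reference$sample_id
  only_s <- setdiff(sid, rid)
  only_r <- setdiff(rid, sid)
  if (length(only_s) || length(only_r)) {
    stop("sample id mismatch between spectra and reference.",
         if (length(only_s)) paste0(" Spectra only: ",
                                    paste(only_s, collapse = ", "), "."),
         if (length(only_r)) paste0(" Reference only: ",
                                    paste(only_r, collapse = ", "), "."),
         call. = FALSE)
  }
  ref2 <- reference[match(sid, rid), , drop = FALSE]
  rownames(ref2) <- NULL
  list(spectra = spectra, reference = ref2)
}
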