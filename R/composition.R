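#' Fatty-acid class membership
#'
#' The default classification covers the eight fatty acids detected in
#' mealworm larval fat. It is data, not code: supply an extended map to
#' classify longer-chain acids without touching the class-sum logic.
#'
#' @return named character vector mapping fatty-acid key to class
#'   (`"SFA"`, `"MUFA"`, `"PUFA"`).
#' @export
fa_classification <- function() {
  c("C12:0" = "SFA",    # lauric
    "C14:0" = "SFA",    # myristic
    "C16:0" = "SFA",    # palmitic
    "C16:1" = "MUFA",   # palmitoleic
    "C18:0" = "SFA",    # stearic
    "C18:1w9" = "MUFA", # oleic
    "C18:2w6" = "PUFA", # linoleic
    "C18:3w3" = "PUFA") # alpha-linolenic
}

#' Convert GC peak areas to a relative fatty-acid profile
#'
#' Each fatty acid's relative concentration is its percentage share of the
#' total peak area, the standard area-normalisation used when FAME peaks are
#' quantified without response factors. Output values sum to 100.
#'
#' @param areas named numeric vector of raw peak areas, all >= 0, total > 0.
#'   A fatty acid absent from the chromatogram (not detected) is simply
#'   omitted.
#' @return named numeric vector of relative percentages (class `fa_profile`).
#' @export
peak_areas_to_percent <- function(areas) {
  areas <- unlist(areas)
  if (is.null(names(areas)) || any(names(areas) == "")) {
    stop("areas must be named by fatty-acid key", call. = FALSE)
  }
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop("peak areas must be finite and >= 0", call. = FALSE)
  }
  total <- sum(areas)
  if (total <= 0) stop("all peak areas are zero", call. = FALSE)
  structure(100 * areas / total, class = "fa_profile")
}

validate_fa_profile <- function(profile) {
  v <- unclass(unlist(profile))
  if (length(v) && (any(!is.finite(v)) || any(v < 0))) {
    stop("fatty-acid percentages must be finite and >= 0", call. = FALSE)
  }
  if (sum(v) > 100 + 0.5) {
    stop("fatty-acid percentages sum to ", round(sum(v), 2),
         ", above 100 (tolerance 0.5)", call. = FALSE)
  }
  invisible(v)
}

#' Sum a fatty-acid profile into SFA / MUFA / PUFA classes
#'
#' A fatty acid absent from the profile (not detected) contributes zero.
#' Unknown keys are rejected unless the supplied classification covers them.
#'
#' @param profile named numeric vector of relative percentages (% of total
#'   fatty acids); `NA` entries are treated as not detected.
#' @param classification named map from fatty-acid key to class; defaults to
#'   [fa_classification()].
#' @return object of class `class_sums`: list with `sfa`, `mufa`, `pufa`.
#' @export
class_sums <- function(profile, classification = fa_classification()) {
  profile <- unlist(profile)
  profile <- profile[!is.na(profile)]
  validate_fa_profile(profile)
  unknown <- setdiff(names(profile), names(classification))
  if (length(unknown)) {
    stop("no class known for fatty acid(s): ",
         paste(unknown, collapse = ", "),
         " (extend the classification map)", call. = FALSE)
  }
  cls <- classification[names(profile)]
  sums <- vapply(c(SFA = "SFA", MUFA = "MUFA", PUFA = "PUFA"),
                 function(k) sum(profile[cls == k]), numeric(1))
  if (sum(sums) > 100 + 1.0) {
    stop("class sums exceed 100% beyond tolerance", call. = FALSE)
  }
  structure(list(sfa = unname(sums["SFA"]), mufa = unname(sums["MUFA"]),
                 pufa = unname(sums["PUFA"])), class = "class_sums")
}

#' @export
print.class_sums <- function(x, ...) {
  cat(sprintf("SFA %.2f%%  MUFA %.2f%%  PUFA %.2f%%\n",
              x$sfa, x$mufa, x$pufa))
  invisible(x)
}

#' Check a profile against printed class sums
#'
#' Quality control for published-table-style inputs: recomputes the class
#' sums from the individual fatty acids and reports every class deviating
#' from the printed sum by more than `tol`. Useful for surfacing
#' typesetting or unlisted-minor-component discrepancies.
#'
#' @param profile named numeric vector of fatty-acid percentages.
#' @param printed_sums a `class_sums` object (or list with `sfa`, `mufa`,
#'   `pufa`) holding the printed values.
#' @param tol nonnegative tolerance in percentage points.
#' @param classification class map, defaults to [fa_classification()].
#' @return data.frame with one row per discrepant class (`class`,
#'   `recomputed`, `printed`, `deviation`); zero rows if consistent.
#' @export
validate_profile_consistency <- function(profile, printed_sums, tol = 0.2,
                                         classification = fa_classification()) {
  if (tol < 0) stop("tol must be >= 0", call. = FALSE)
  got <- class_sums(profile, classification)
  classes <- c(sfa = "SFA", mufa = "MUFA", pufa = "PUFA")
  rows <- lapply(names(classes), function(k) {
    printed <- printed_sums[[k]]
    if (is.null(printed) || is.na(printed)) return(NULL)
    dev <- got[[k]] - printed
    if (abs(dev) > tol) {
      data.frame(class = classes[[k]], recomputed = got[[k]],
                 printed = printed, deviation = dev,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(class = character(), recomputed = numeric(),
                      printed = numeric(), deviation = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Bundled larval fatty-acid profiles
#'
#' The per-group mean fatty-acid composition of mealworm larvae (relative %
#' of total fatty acids, dry-matter basis) for the fifteen feeding groups and
#' the start larvae, together with the printed SFA/MUFA/PUFA class sums.
#' Not-detected acids are `NA`.
#'
#' @return data.frame with a `group` column, one column per fatty-acid key
#'   and `SFA`, `MUFA`, `PUFA` columns.
#' @export
larval_fa_profiles <- function() {
  path <- system.file("extdata", "larval_fatty_acid_profiles.csv",
                      package = "mealwormNIRS", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
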