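#' Define a spectral pretreatment pipeline
#'
#' A pretreatment spec is an ordered list of steps drawn from:
#' \describe{
#'   \item{`none`}{identity.}
#'   \item{`msc`}{multiplicative scatter correction against the calibration
#'     mean spectrum.}
#'   \item{`detrend`}{subtract a per-spectrum least-squares polynomial in
#'     wavelength (default order 2, the classic detrend).}
#'   \item{`mc`}{mean centering with calibration column means.}
#'   \item{`d1`, `d2`}{first / second Savitzky-Golay derivative (default
#'     window 11 points, polynomial order 2 for `d1`, 3 for `d2`).}
#' }
#' Stateful steps (`msc`, `mc`) are fitted on the calibration set only and
#' replayed unchanged on validation or prediction spectra.
#'
#' @param ... step tokens as strings, or lists with element `type` plus
#'   parameters (`order` for detrend; `window`, `polyorder` for derivatives).
#' @param label display label; defaults to the tokens joined by " + ".
#' @return an object of class `pretreatment_spec`.
#' @examples
#' pretreatment_spec("msc", "mc")
#' pretreatment_spec(list(type = "detrend", order = 1))
#' @export
pretreatment_spec <- function(..., label = NULL) {
  raw <- list(...)
  if (length(raw) == 1 && is.list(raw[[1]]) && is.null(raw[[1]]$type)) {
    raw <- raw[[1]]  # allow a single list of steps
  }
  steps <- lapply(raw, function(s) {
    if (is.character(s)) s <- list(type = s)
    type <- match.arg(s$type, c("none", "msc", "detrend", "mc", "d1", "d2"))
    step <- switch(type,
      none = list(type = "none"),
      msc = list(type = "msc"),
      mc = list(type = "mc"),
      detrend = list(type = "detrend",
                     order = if (is.null(s$order)) 2L else as.integer(s$order)),
      d1 = list(type = "d1",
                window = if (is.null(s$window)) 11L else as.integer(s$window),
                polyorder = if (is.null(s$polyorder)) 2L
                            else as.integer(s$polyorder)),
      d2 = list(type = "d2",
                window = if (is.null(s$window)) 11L else as.integer(s$window),
                polyorder = if (is.null(s$polyorder)) 3L
                            else as.integer(s$polyorder)))
    step
  })
  if (length(steps) == 0) steps <- list(list(type = "none"))
  if (sum(vapply(steps, function(s) s$type == "mc", logical(1))) > 1) {
    stop("at most one mean-centering step is allowed", call. = FALSE)
  }
  for (s in steps) {
    if (s$type %in% c("d1", "d2")) {
      deriv <- if (s$type == "d1") 1L else 2L
      if (s$window %% 2 == 0) stop("derivative window must be odd",
                                   call. = FALSE)
      if (s$polyorder >= s$window) stop("polyorder must be < window",
                                        call. = FALSE)
      if (deriv > s$polyorder) stop("derivative order must be <= polyorder",
                                    call. = FALSE)
    }
    if (s$type == "detrend" && s$order < 0) stop("detrend order must be >= 0",
                                                 call. = FALSE)
  }
  if (is.null(label)) {
    label <- paste(vapply(steps, function(s)
      c(none = "None", msc = "MSC", detrend = "Detrend", mc = "MC",
        d1 = "1D", d2 = "2D")[s$type], character(1)), collapse = " + ")
  }
  structure(list(steps = steps, label = label), class = "pretreatment_spec")
}

#' @export
print.pretreatment_spec <- function(x, ...) {
  cat("<pretreatment_spec>", x$label, "\n")
  invisible(x)
}

#' The candidate pretreatments screened for every analyte
#'
#' The five single treatments routinely compared (none, MSC, MC, 1D, 2D) plus
#' detrend and the MSC + detrend combination, each under its report label.
#'
#' @param extended if `FALSE` (default) return the five single treatments;
#'   if `TRUE` also include `Detrend` and `MSC + Detrend`.
#' @return named list of `pretreatment_spec` objects.
#' @export
standard_pretreatments <- function(extended = FALSE) {
  base <- list(
    "None" = pretreatment_spec("none"),
    "MSC"  = pretreatment_spec("msc"),
    "MC"   = pretreatment_spec("mc"),
    "1D"   = pretreatment_spec("d1"),
    "2D"   = pretreatment_spec("d2"))
  if (extended) {
    base[["Detrend"]] <- pretreatment_spec("detrend")
    base[["MSC + Detrend"]] <- pretreatment_spec("msc", "detrend")
  }
  base
}

# ---- individual transforms ------------------------------------------------

msc_coefficients <- function(M, ref) {
  # per-row least squares s ~ a + b * ref
  rc <- ref - mean(ref)
  denom <- sum(rc^2)
  if (denom < 1e-24) stop("MSC reference spectrum has no variance",
                          call. = FALSE)
  b <- as.vector(M %*% rc) / denom  # = cov(s, ref)/var(ref) row-wise
  a <- rowMeans(M) - b * mean(ref)
  bad <- which(abs(b) < 1e-12)
  if (length(bad)) {
    stop("degenerate spectrum (flat against MSC reference): ",
         paste(rownames(M)[bad], collapse = ", "), call. = FALSE)
  }
  list(a = a, b = b)
}

#' Multiplicative scatter correction
#'
#' Fits, for each spectrum s, the affine model s ~ a + b * reference by least
#' squares against the calibration mean spectrum and returns (s - a) / b.
#' The reference and the per-spectrum coefficients are stored so validation
#' spectra are corrected against the same calibration reference.
#'
#' @param cal calibration `spectra_set` (>= 2 spectra).
#' @return list with elements `corrected` (a `spectra_set`) and `fitted`
#'   (list with `reference`, `a`, `b`).
#' @export
msc_fit <- function(cal) {
  stopifnot(inherits(cal, "spectra_set"))
  if (nrow(cal$absorbance) < 2) {
    stop("MSC needs at least 2 calibration spectra", call. = FALSE)
  }
  ref <- colMeans(cal$absorbance)
  cf <- msc_coefficients(cal$absorbance, ref)
  corrected <- (cal$absorbance - cf$a) / cf$b
  list(corrected = spectra_set(corrected, cal$wavelengths, sample_ids(cal)),
       fitted = list(reference = ref, a = cf$a, b = cf$b))
}

#' @rdname msc_fit
#' @param new a `spectra_set` to correct with a stored MSC fit.
#' @param fitted the `fitted` element returned by `msc_fit`.
#' @export
msc_apply <- function(new, fitted) {
  stopifnot(inherits(new, "spectra_set"))
  if (length(fitted$reference) != length(new$wavelengths)) {
    stop("wavelength grid does not match the MSC reference", call. = FALSE)
  }
  cf <- msc_coefficients(new$absorbance, fitted$reference)
  spectra_set((new$absorbance - cf$a) / cf$b, new$wavelengths,
              sample_ids(new))
}

#' Polynomial detrend
#'
#' Subtracts from each spectrum its least-squares polynomial of the given
#' order in wavelength (order 2 is the classic detrend). Stateless: the same
#' projection applies to any set.
#'
#' @param x a `spectra_set`.
#' @param order polynomial order, `0 <= order < n_wavelengths`.
#' @return the detrended `spectra_set`.
#' @export
detrend <- function(x, order = 2) {
  stopifnot(inherits(x, "spectra_set"))
  order <- as.integer(order)
  p <- length(x$wavelengths)
  if (order < 0) stop("order must be >= 0", call. = FALSE)
  if (order >= p) stop("detrend order (", order, ") must be below the number ",
                       "of wavelengths (", p, ")", call. = FALSE)
  D <- if (order == 0) matrix(1, p, 1) else
    cbind(1, stats::poly(x$wavelengths, degree = order, raw = FALSE))
  Q <- qr.Q(qr(D))
  resid <- x$absorbance - (x$absorbance %*% Q) %*% t(Q)
  spectra_set(resid, x$wavelengths, sample_ids(x))
}

#' Mean centering
#'
#' `mean_center_fit` stores the calibration column means and returns the
#' centered calibration set; `mean_center_apply` subtracts those same means
#' from new spectra.
#'
#' @param cal calibration `spectra_set` (>= 2 spectra).
#' @return list with `centered` (a `spectra_set`) and `means` (numeric).
#' @export
mean_center_fit <- function(cal) {
  stopifnot(inherits(cal, "spectra_set"))
  if (nrow(cal$absorbance) < 2) {
    stop("mean centering needs at least 2 calibration spectra", call. = FALSE)
  }
  m <- colMeans(cal$absorbance)
  list(centered = mean_center_apply(cal, m), means = m)
}

#' @rdname mean_center_fit
#' @param new a `spectra_set`.
#' @param means calibration column means from `mean_center_fit`.
#' @export
mean_center_apply <- function(new, means) {
  stopifnot(inherits(new, "spectra_set"))
  if (length(means) != length(new$wavelengths)) {
    stop("column means do not match the wavelength grid", call. = FALSE)
  }
  spectra_set(sweep(new$absorbance, 2, means), new$wavelengths,
              sample_ids(new))
}

sg_weights <- function(offsets, polyorder, deriv, h) {
  # least-squares polynomial fit over the window; derivative at offset 0
  A <- outer(offsets * h, 0:polyorder, `^`)
  G <- solve(crossprod(A), t(A))        # (p+1) x window
  factorial(deriv) * G[deriv + 1, ]
}

#' Savitzky-Golay derivative
#'
#' Local least-squares polynomial differentiation with respect to wavelength
#' (the grid step in nm is accounted for, so a first derivative is in
#' absorbance per nm). Edge points are handled by refitting the polynomial on
#' the window truncated at the spectrum boundary.
#'
#' @param x a `spectra_set`.
#' @param deriv derivative order, 1 or 2.
#' @param window odd window length in points (> polyorder).
#' @param polyorder polynomial order of the local fit (>= deriv).
#' @return a `spectra_set` of derivative spectra.
#' @export
sg_derivative <- function(x, deriv, window = 11, polyorder = max(2, deriv)) {
  stopifnot(inherits(x, "spectra_set"))
  deriv <- as.integer(deriv); window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (!deriv %in% c(1L, 2L)) stop("deriv must be 1 or 2", call. = FALSE)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  if (deriv > polyorder) stop("deriv must be <= polyorder", call. = FALSE)
  p <- length(x$wavelengths)
  if (window > p) stop("window longer than the spectrum", call. = FALSE)
  h <- if (p > 1) x$wavelengths[2] - x$wavelengths[1] else 1
  m <- (window - 1L) %/% 2L
  A <- x$absorbance
  out <- matrix(0, nrow(A), p)
  w_int <- sg_weights(-m:m, polyorder, deriv, h)
  for (j in seq_len(p)) {
    if (j > m && j <= p - m) {
      out[, j] <- A[, (j - m):(j + m), drop = FALSE] %*% w_int
    } else {
      idx <- max(1L, j - m):min(p, j + m)
      if (length(idx) <= polyorder) {
        stop("truncated edge window too short for polyorder", call. = FALSE)
      }
      w <- sg_weights(idx - j, polyorder, deriv, h)
      out[, j] <- A[, idx, drop = FALSE] %*% w
    }
  }
  spectra_set(out, x$wavelengths, sample_ids(x))
}

# ---- pipeline -------------------------------------------------------------

#' Fit a pretreatment pipeline on calibration spectra and replay it
#'
#' Applies the steps of a [pretreatment_spec()] in order. Stateful steps
#' (`msc`, `mc`) estimate their parameters from the calibration set only; the
#' stored state is replayed identically on every other set, so validation and
#' prediction spectra never influence the fit.
#'
#' @param spec a `pretreatment_spec`.
#' @param cal calibration `spectra_set`.
#' @param others list of further `spectra_set`s (e.g. validation) transformed
#'   with the calibration-fitted state.
#' @return list with `cal` (transformed calibration set), `others`
#'   (list of transformed sets) and `fitted` (a `fitted_pretreatment`
#'   usable with [apply_pretreatment()]).
#' @export
fit_pretreatment <- function(spec, cal, others = list()) {
  stopifnot(inherits(spec, "pretreatment_spec"), inherits(cal, "spectra_set"))
  if (inherits(others, "spectra_set")) others <- list(others)
  for (o in others) {
    if (!isTRUE(all.equal(o$wavelengths, cal$wavelengths, tolerance = 1e-9))) {
      stop("all spectra sets must share the calibration wavelength grid",
           call. = FALSE)
    }
  }
  state <- vector("list", length(spec$steps))
  for (k in seq_along(spec$steps)) {
    s <- spec$steps[[k]]
    if (s$type == "msc") {
      f <- msc_fit(cal)
      cal <- f$corrected
      others <- lapply(others, msc_apply, fitted = f$fitted)
      state[[k]] <- f$fitted
    } else if (s$type == "mc") {
      f <- mean_center_fit(cal)
      cal <- f$centered
      others <- lapply(others, mean_center_apply, means = f$means)
      state[[k]] <- list(means = f$means)
    } else if (s$type == "detrend") {
      cal <- detrend(cal, s$order)
      others <- lapply(others, detrend, order = s$order)
    } else if (s$type %in% c("d1", "d2")) {
      d <- if (s$type == "d1") 1L else 2L
      cal <- sg_derivative(cal, d, s$window, s$polyorder)
      others <- lapply(others, sg_derivative, deriv = d, window = s$window,
                       polyorder = s$polyorder)
    }
  }
  fitted <- structure(list(spec = spec, state = state,
                           wavelengths = cal$wavelengths),
                      class = "fitted_pretreatment")
  list(cal = cal, others = others, fitted = fitted)
}

#' Replay a fitted pretreatment on new spectra
#'
#' @param fitted a `fitted_pretreatment` from [fit_pretreatment()].
#' @param x a `spectra_set` on the same wavelength grid.
#' @return the transformed `spectra_set`.
#' @export
apply_pretreatment <- function(fitted, x) {
  stopifnot(inherits(fitted, "fitted_pretreatment"),
            inherits(x, "spectra_set"))
  if (!isTRUE(all.equal(x$wavelengths, fitted$wavelengths,
                        tolerance = 1e-9))) {
    stop("wavelength grid does not match the fitted pretreatment",
         call. = FALSE)
  }
  for (k in seq_along(fitted$spec$steps)) {
    s <- fitted$spec$steps[[k]]
    x <- switch(s$type,
      none = x,
      msc = msc_apply(x, fitted$state[[k]]),
      mc = mean_center_apply(x, fitted$state[[k]]$means),
      detrend = detrend(x, s$order),
      d1 = sg_derivative(x, 1L, s$window, s$polyorder),
      d2 = sg_derivative(x, 2L, s$window, s$polyorder))
  }
  x
}
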