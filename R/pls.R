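#' Fit a PLS1 regression model by NIPALS
#'
#' Single-response partial least squares. Components are extracted by the
#' classical NIPALS sequence: the weight vector is the (normalised) covariance
#' of the predictors with the response, scores are the projection of X onto
#' it, and X and y are deflated by the rank-one score/loading outer product
#' before the next component. With one response the weight vector is exact in
#' a single pass, so no inner iteration is needed; the algorithm is fully
#' deterministic.
#'
#' Centering is part of the model: `center = TRUE` (the default) subtracts
#' the calibration column means of X and the mean of y and refits them at
#' prediction time; `center = FALSE` runs NIPALS on the raw cross products,
#' the behaviour a calibration without a mean-centering pretreatment gets.
#'
#' @param X numeric matrix (samples x variables) or a `spectra_set`.
#' @param y numeric response vector, one value per row of X.
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param center logical; see Details.
#' If the deflated predictors run out of covariance with the response before
#' `n_lv` components are extracted (rank-deficient X), extraction stops at
#' `n_lv_effective` and the remaining components contribute nothing.
#'
#' @return object of class `pls1_model` with components `n_lv`,
#'   `n_lv_effective`, `W` (weights),
#'   `P` (x-loadings), `q` (y-loadings), `scores`, `b` (regression vector in
#'   original units), `intercept`, `x_means`, `y_mean`, `center`,
#'   `fitted_values`, and `coefficients_by_lv` (p x n_lv matrix of regression
#'   vectors using 1..n_lv components).
#' @export
fit_pls1 <- function(X, y, n_lv, center = TRUE) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in X or y", call. = FALSE)
  }
  if (stats::var(y) < 1e-24) stop("zero-variance response: nothing to model",
                                  call. = FALSE)
  n_lv <- as.integer(n_lv)
  max_lv <- if (center) min(n - 1L, p) else min(n, p)
  if (n_lv < 1 || n_lv > max_lv) {
    stop("n_lv must be between 1 and ", max_lv, " for this data",
         call. = FALSE)
  }
  x_means <- if (center) colMeans(X) else numeric(p)
  y_mean <- if (center) mean(y) else 0
  Xc <- sweep(X, 2, x_means)
  yc <- y - y_mean

  W <- P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  Xd <- Xc; yd <- yc
  # deflation exhaustion threshold, relative to the problem scale
  cov_tol <- 1e-12 * max(sqrt(sum(Xc^2)) * sqrt(sum(yc^2)), 1e-300)
  n_eff <- n_lv
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw <= cov_tol) {
      # residual predictors carry no covariance with the residual response;
      # later components would be numerical noise, so they are left empty
      # and contribute nothing to the regression vector
      n_eff <- a - 1L
      break
    }
    w <- w / nw
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-24) { n_eff <- a - 1L; break }
    p_a <- crossprod(Xd, t_a) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - t_a %*% t(p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
  }
  if (n_eff == 0L) {
    stop("X carries no covariance with y: nothing to fit", call. = FALSE)
  }
  # rotations R = W (P'W)^{-1}, built incrementally; cumulative b per LV
  R <- matrix(0, p, n_lv)
  B <- matrix(0, p, n_lv)
  b_acc <- numeric(p)
  for (a in seq_len(n_lv)) {
    if (a <= n_eff) {
      r <- W[, a]
      if (a > 1) {
        proj <- crossprod(P[, seq_len(a - 1), drop = FALSE], W[, a])
        r <- r - R[, seq_len(a - 1), drop = FALSE] %*% proj
      }
      R[, a] <- r
      b_acc <- b_acc + q[a] * R[, a]
    }
    B[, a] <- b_acc
  }
  b <- B[, n_lv]
  intercept <- y_mean - sum(x_means * b)
  fitted <- as.vector(X %*% b) + intercept
  structure(list(n_lv = n_lv, n_lv_effective = n_eff, W = W, P = P, q = q,
                 scores = Tm, b = b,
                 intercept = intercept, x_means = x_means, y_mean = y_mean,
                 center = center, fitted_values = fitted,
                 coefficients_by_lv = B),
            class = "pls1_model")
}

#' @export
print.pls1_model <- function(x, ...) {
  cat("<pls1_model> ", x$n_lv, " latent variable(s), ",
      length(x$b), " predictors, ",
      if (x$center) "centered" else "uncentered", "\n", sep = "")
  invisible(x)
}

#' Predict from a PLS1 model
#'
#' @param object a `pls1_model`.
#' @param newdata numeric matrix or `spectra_set` with the model's number of
#'   predictor columns (apply the same pretreatment first).
#' @param n_lv optionally predict with fewer components than the model stores.
#' @param ... ignored.
#' @return numeric vector of predictions in original response units.
#' @export
predict.pls1_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$absorbance
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$b)) {
    stop("newdata has ", ncol(newdata), " variables but the model expects ",
         length(object$b), call. = FALSE)
  }
  n_lv <- as.integer(n_lv)
  if (n_lv < 1 || n_lv > object$n_lv) {
    stop("n_lv out of range for this model", call. = FALSE)
  }
  b <- object$coefficients_by_lv[, n_lv]
  intercept <- object$y_mean - sum(object$x_means * b)
  as.vector(newdata %*% b) + intercept
}

#' Cross-validation fold schemes
#'
#' \describe{
#'   \item{venetian}{interleaved ("venetian blinds") folds: fold i holds
#'     samples i, i + k, i + 2k, ...}
#'   \item{blocks}{contiguous blocks of (nearly) equal size.}
#'   \item{loo}{leave-one-out.}
#' }
#'
#' @param type one of `"venetian"`, `"blocks"`, `"loo"`.
#' @param k number of folds (ignored for `loo`).
#' @return object of class `cv_scheme`; its `folds(n)` element returns a list
#'   of held-out index vectors partitioning `1:n`.
#' @export
cv_scheme <- function(type = c("venetian", "blocks", "loo"), k = 10) {
  type <- match.arg(type)
  k <- as.integer(k)
  folds <- switch(type,
    venetian = function(n) {
      kk <- min(k, n)
      lapply(seq_len(kk), function(i) seq(i, n, by = kk))
    },
    blocks = function(n) {
      kk <- min(k, n)
      split(seq_len(n), cut(seq_len(n), kk, labels = FALSE))
    },
    loo = function(n) as.list(seq_len(n)))
  label <- if (type == "loo") "leave-one-out" else
    paste0(type, " (", k, " splits)")
  structure(list(type = type, k = k, folds = folds, label = label),
            class = "cv_scheme")
}

#' Cross-validate a PLS1 calibration over latent-variable counts
#'
#' For each fold the model is refitted from scratch on the retained samples
#' (the pretreatment is assumed already applied; its state is not refitted per
#' fold) and the held-out samples are predicted with 1..`max_lv` components.
#' RMSECV per component count is pooled over all held-out predictions. The
#' component count minimising RMSECV, capped, is chosen.
#'
#' @param X numeric matrix or `spectra_set`.
#' @param y numeric response.
#' @param max_lv maximum number of latent variables to assess.
#' @param scheme a [cv_scheme()]; default venetian blinds with 10 splits.
#' @param cap cap on the chosen number of latent variables (default 10,
#'   keeping models below ten factors).
#' @param center passed to [fit_pls1()].
#' @return object of class `cv_result`: list with `rmsecv` (one value per LV),
#'   `n_lv` (chosen), `scheme` label.
#' @export
cross_validate <- function(X, y, max_lv, scheme = cv_scheme("venetian", 10),
                           cap = 10, center = TRUE) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (max_lv < 1) stop("max_lv must be >= 1", call. = FALSE)
  folds <- scheme$folds(n)
  sizes <- lengths(folds)
  if (any(n - sizes < 2)) {
    stop("cross-validation scheme leaves a training fold with < 2 samples",
         call. = FALSE)
  }
  lv_feasible <- min(max_lv, min(n - sizes) - 1, ncol(X))
  press <- numeric(lv_feasible)
  for (idx in folds) {
    fit <- fit_pls1(X[-idx, , drop = FALSE], y[-idx], lv_feasible,
                    center = center)
    for (a in seq_len(lv_feasible)) {
      pred <- predict(fit, X[idx, , drop = FALSE], n_lv = a)
      press[a] <- press[a] + sum((y[idx] - pred)^2)
    }
  }
  rmsecv <- sqrt(press / n)
  res <- structure(list(rmsecv = rmsecv, scheme = scheme$label,
                        n_lv = NA_integer_), class = "cv_result")
  res$n_lv <- select_n_lv(res, cap = cap)
  res
}

#' Choose the number of latent variables from cross-validation
#'
#' Returns the component count with minimal RMSECV among those not exceeding
#' the cap; ties go to the smaller count (parsimony).
#'
#' @param cv a `cv_result` (or plain numeric vector of RMSECV values).
#' @param cap maximum admissible number of latent variables.
#' @return integer number of latent variables.
#' @export
select_n_lv <- function(cv, cap = 10) {
  rmsecv <- if (inherits(cv, "cv_result")) cv$rmsecv else as.numeric(cv)
  if (length(rmsecv) == 0) stop("empty cross-validation result",
                                call. = FALSE)
  k <- min(length(rmsecv), as.integer(cap))
  as.integer(which.min(rmsecv[seq_len(k)]))
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$scheme, "; chosen n_lv = ", x$n_lv, "\n", sep = "")
  print(round(x$rmsecv, 5))
  invisible(x)
}
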