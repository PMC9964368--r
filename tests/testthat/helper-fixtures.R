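# Shared fixture builders and independent oracles.

# smooth-ish random spectra on a small grid
random_spectra <- function(n = 6, p = 26, seed = 1, lo = 1100, hi = 1200) {
  set.seed(seed)
  w <- seq(lo, hi, length.out = p)
  base <- 0.5 + 1e-3 * (w - lo)
  A <- t(replicate(n, base + cumsum(rnorm(p, 0, 0.01))))
  spectra_set(A, w)
}

# spectra that follow the MSC scatter model exactly:
# s_i = a_i + b_i * shape
affine_family_spectra <- function(n = 8, p = 41, seed = 2) {
  set.seed(seed)
  w <- seq(1100, 1300, length.out = p)
  shape <- 0.6 + 0.3 * sin((w - 1100) / 40) + 1e-3 * (w - 1100)
  a <- runif(n, -0.05, 0.05)
  b <- runif(n, 0.8, 1.2)
  spectra_set(outer(a, rep(1, p)) + outer(b, shape), w)
}

# independent NIPALS PLS1 oracle: naive power-iteration loop, scalar code,
# no shared internals with fit_pls1
nipals_oracle <- function(X, y, n_lv, center = TRUE, tol = 1e-13) {
  X <- as.matrix(X); y <- as.numeric(y)
  xm <- if (center) colMeans(X) else rep(0, ncol(X))
  ym <- if (center) mean(y) else 0
  E <- sweep(X, 2, xm); f <- y - ym
  W <- P <- NULL; Tm <- NULL; qv <- c()
  for (a in seq_len(n_lv)) {
    u <- f
    w_old <- rep(0, ncol(E))
    for (it in 1:500) {
      w <- as.vector(t(E) %*% u)
      w <- w / sqrt(sum(w * w))
      tt <- as.vector(E %*% w)
      q <- sum(f * tt) / sum(tt * tt)
      u <- f * q
      if (sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w
    }
    p_a <- as.vector(t(E) %*% tt) / sum(tt * tt)
    E <- E - outer(tt, p_a)
    f <- f - q * tt
    W <- cbind(W, w); P <- cbind(P, p_a); Tm <- cbind(Tm, tt)
    qv <- c(qv, q)
  }
  b <- W %*% solve(t(P) %*% W, qv)
  list(W = W, P = P, q = qv, scores = Tm, b = as.vector(b),
       intercept = ym - sum(xm * b))
}

# textbook two-pass variance
twopass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

expect_spectra_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$absorbance - b$absorbance)), tol)
}
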