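# NIPALS PLS-1 regression, written from scratch.
#
# For a single response the NIPALS recursion is finite (no inner iteration):
# on mean-centred X, y, for each latent variable a
#   w_a = X'y / ||X'y||      (weights; sign-fixed, see below)
#   t_a = X w_a              (scores)
#   p_a = X't_a / t_a't_a    (x-loadings)
#   q_a = y't_a / t_a't_a    (y-loading)
#   X <- X - t_a p_a' ;  y <- y - t_a q_a
# The regression vector on centred data is b = W (P'W)^{-1} q. The NIPALS
# sign is arbitrary, so w_a is flipped to make its largest-magnitude element
# positive; loadings are then reproducible across runs and platforms.

#' Fit a PLS-1 model by NIPALS
#'
#' @param X Numeric matrix, n samples x p predictors (typically derivative
#'   spectra), n >= 2.
#' @param y Numeric response vector of length n.
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param wavelengths Optional wavelength grid attached to the model for
#'   loading plots and grid checks.
#' @param scale If `TRUE`, predictors are autoscaled to unit variance in
#'   addition to mean centring. Default `FALSE`: centring only, the standard
#'   choice for derivative spectra where amplitude carries information.
#' @return An object of class `pls1_model` with components `x_mean`,
#'   `y_mean`, `weights` (p x A), `x_loadings` (p x A), `y_loadings` (A),
#'   `scores` (n x A), `score_variances`, `coefficients` (p), `intercept`,
#'   `explained_x_variance`, `explained_y_variance`.
#' @export
fit_pls1 <- function(X, y, n_lv, wavelengths = NULL, scale = FALSE) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stopf("need at least 2 samples")
  if (length(y) != n) stopf("length(y) != nrow(X)")
  if (any(!is.finite(X)) || any(!is.finite(y))) stopf("X and y must be finite")
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > min(n - 1L, p)) {
    stopf("n_lv must be in [1, min(n - 1, p)] = [1, %d]", min(n - 1L, p))
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  x_scale <- rep(1, p)
  Xc <- sweep(X, 2L, x_mean)
  if (scale) {
    x_scale <- apply(Xc, 2L, sd)
    x_scale[x_scale == 0] <- 1
    Xc <- sweep(Xc, 2L, x_scale, `/`)
  }
  yc <- y - y_mean
  ssx_total <- sum(Xc^2)
  ssy_total <- sum(yc^2)
  if (ssy_total == 0) stopf("response has zero variance")

  W <- P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  ex <- ey <- numeric(n_lv)
  cov0 <- sqrt(sum(crossprod(Xc, yc)^2))

  Xd <- Xc; yd <- yc
  for (a in seq_len(n_lv)) {
    wv <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(wv^2))
    if (!is.finite(nw) || nw <= 1e-12 * max(cov0, 1e-300)) {
      stopf("rank exhausted at latent variable %d (response orthogonal to remaining X)", a)
    }
    wv <- wv / nw
    j <- which.max(abs(wv))
    if (wv[j] < 0) wv <- -wv
    tv <- drop(Xd %*% wv)
    tt <- sum(tv^2)
    if (tt <= 0) stopf("degenerate scores at latent variable %d", a)
    pv <- drop(crossprod(Xd, tv)) / tt
    qa <- sum(yd * tv) / tt
    W[, a] <- wv; P[, a] <- pv; q[a] <- qa; Tm[, a] <- tv
    ex[a] <- tt * sum(pv^2) / ssx_total
    ey[a] <- tt * qa^2 / ssy_total
    Xd <- Xd - tcrossprod(tv, pv)
    yd <- yd - tv * qa
  }

  PtW <- crossprod(P, W)
  b <- drop(W %*% solve(PtW, q)) / x_scale
  b0 <- y_mean - sum(x_mean * b)

  structure(
    list(n_lv = n_lv, n = n, p = p,
         x_mean = x_mean, y_mean = y_mean, x_scale = x_scale,
         weights = W, x_loadings = P, y_loadings = q,
         scores = Tm, score_variances = apply(Tm, 2L, var),
         coefficients = b, intercept = b0,
         explained_x_variance = ex, explained_y_variance = ey,
         wavelengths = if (!is.null(wavelengths)) as.numeric(wavelengths),
         scaled = scale),
    class = "pls1_model"
  )
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("<pls1_model> %d LVs, %d samples x %d predictors\n",
              x$n_lv, x$n, x$p))
  cat(sprintf("  explained X variance: %.1f%%; explained y variance: %.1f%%\n",
              100 * sum(x$explained_x_variance),
              100 * sum(x$explained_y_variance)))
  invisible(x)
}

#' Predict from a PLS-1 model
#'
#' @param object A `pls1_model`.
#' @param newdata Numeric matrix with `object$p` columns (or a vector of
#'   length p for a single spectrum).
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.pls1_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  if (ncol(X) != object$p) {
    stopf("newdata has %d columns, model expects %d", ncol(X), object$p)
  }
  drop(object$intercept + X %*% object$coefficients)
}

# Projection matrix R = W (P'W)^{-1}: scores of new (centred, scaled) data
# are t = x0 R.
pls1_rotation <- function(m) {
  m$weights %*% solve(crossprod(m$x_loadings, m$weights))
}

# Scores of new data in the model's latent space.
pls1_scores <- function(m, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != m$p) stopf("X has %d columns, model expects %d", ncol(X), m$p)
  Xc <- sweep(sweep(X, 2L, m$x_mean), 2L, m$x_scale, `/`)
  Xc %*% pls1_rotation(m)
}

#' Per-latent-variable explained variance
#'
#' The X fraction for LV a is the squared Frobenius norm of the rank-one
#' reconstruction t_a p_a' relative to centred X; the y fraction is the
#' incremental R-squared contributed by LV a. Both are accumulated during the
#' NIPALS recursion, so the sequences sum to at most 1.
#'
#' @param m A `pls1_model`.
#' @return Data frame with columns `lv`, `x_fraction`, `y_fraction`.
#' @export
explained_variance <- function(m) {
  stopifnot(inherits(m, "pls1_model"))
  data.frame(lv = seq_len(m$n_lv),
             x_fraction = m$explained_x_variance,
             y_fraction = m$explained_y_variance)
}

#' Loading spectrum of one latent variable
#'
#' @param m A `pls1_model` fitted with `wavelengths` attached (or any model;
#'   wavelengths default to the column index).
#' @param a Latent-variable index, `1 <= a <= m$n_lv`.
#' @return Data frame with columns `wavelength` and `loading` (the x-loading
#'   vector p_a).
#' @export
loading_spectrum <- function(m, a) {
  stopifnot(inherits(m, "pls1_model"))
  a <- as.integer(a)
  if (a < 1L || a > m$n_lv) stopf("latent-variable index %d out of range [1, %d]", a, m$n_lv)
  data.frame(wavelength = m$wavelengths %||% seq_len(m$p),
             loading = m$x_loadings[, a])
}

# Regression vectors for every truncation 1..A of the latent space, as a
# p x A matrix (column a = coefficients using the first a LVs), plus the
# matching intercepts. Lets the LV grid search fit once per fold.
pls1_coef_path <- function(m) {
  A <- m$n_lv
  B <- matrix(0, m$p, A)
  b0 <- numeric(A)
  for (a in seq_len(A)) {
    Wa <- m$weights[, seq_len(a), drop = FALSE]
    Pa <- m$x_loadings[, seq_len(a), drop = FALSE]
    qa <- m$y_loadings[seq_len(a)]
    B[, a] <- drop(Wa %*% solve(crossprod(Pa, Wa), qa)) / m$x_scale
    b0[a] <- m$y_mean - sum(m$x_mean * B[, a])
  }
  list(coefficients = B, intercepts = b0)
}

#' Serialize a PLS-1 model to JSON
#'
#' Versioned plain-text representation (grid, means, weights, loadings,
#' regression vector) so fitted models can be stored in a repository and
#' reused for validation.
#'
#' @param m A `pls1_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pls1 <- function(m, path) {
  stopifnot(inherits(m, "pls1_model"))
  doc <- list(format = "wetspec-pls1", version = 1L,
              model = m[setdiff(names(m), "scores")],
              scores = m$scores)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a serialized PLS-1 model
#' @param path Path written by [write_pls1()].
#' @return A `pls1_model`.
#' @export
read_pls1 <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "wetspec-pls1")) stopf("%s is not a wetspec PLS-1 model file", path)
  m <- doc$model
  m$scores <- matrix(doc$scores, nrow = m$n, ncol = m$n_lv)
  for (nm in c("weights", "x_loadings")) m[[nm]] <- matrix(m[[nm]], nrow = m$p)
  m$wavelengths <- m$wavelengths %||% NULL
  structure(m, class = "pls1_model")
}
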