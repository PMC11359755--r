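# Calibration outlier screening: Q residuals (squared distance from the
# latent subspace) and Hotelling's T-squared (Mahalanobis distance within it),
# with confidence limits at a configurable level.

#' Q residuals of spectra under a PLS-1 model
#'
#' Each row is centred, projected onto the model's latent subspace via the
#' rotation W(P'W)^-1, reconstructed from the x-loadings, and the squared
#' Euclidean norm of the reconstruction residual is returned.
#'
#' @param m A `pls1_model`.
#' @param X Numeric matrix on the model's predictor grid.
#' @return Numeric vector of Q values (>= 0), one per row.
#' @export
q_residuals <- function(m, X) {
  stopifnot(inherits(m, "pls1_model"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != m$p) stopf("X has %d columns, model expects %d", ncol(X), m$p)
  Xc <- sweep(sweep(X, 2L, m$x_mean), 2L, m$x_scale, `/`)
  Tn <- Xc %*% pls1_rotation(m)
  E <- Xc - tcrossprod(Tn, m$x_loadings)
  rowSums(E^2)
}

#' Hotelling T-squared of spectra under a PLS-1 model
#'
#' `T2_i = sum_a t_ia^2 / s2_a`, where `s2_a` is the (n-1)-denominator
#' variance of the calibration scores of latent variable a.
#'
#' @inheritParams q_residuals
#' @return Numeric vector of T-squared values (>= 0), one per row.
#' @export
hotelling_t2 <- function(m, X) {
  stopifnot(inherits(m, "pls1_model"))
  if (any(m$score_variances <= 0)) stopf("degenerate model: zero score variance")
  Tn <- pls1_scores(m, X)
  rowSums(sweep(Tn^2, 2L, m$score_variances, `/`))
}

#' Confidence limits for Q and T-squared
#'
#' The T-squared limit is the classical F-based limit
#' `A(n-1)(n+1) / (n(n-A)) * qf(confidence, A, n-A)`. The Q limit is by
#' default the empirical `confidence` quantile of the calibration Q values
#' (distribution-free, robust to the non-Gaussian residuals of derivative
#' spectra); `method = "jackson"` uses the Jackson-Mudholkar closed form
#' based on the residual covariance eigenvalues.
#'
#' @param m A `pls1_model`.
#' @param X_cal Calibration matrix the model was fitted on.
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @param method Q-limit rule: `"empirical"` (default) or `"jackson"`.
#' @return List with elements `q_limit` and `t2_limit`.
#' @export
control_limits <- function(m, X_cal, confidence = 0.95,
                           method = c("empirical", "jackson")) {
  stopifnot(inherits(m, "pls1_model"))
  method <- match.arg(method)
  if (confidence <= 0 || confidence >= 1) stopf("confidence must be in (0, 1)")
  A <- m$n_lv; n <- nrow(as.matrix(X_cal))
  if (n <= A) stopf("need n > n_lv for the T-squared limit (n = %d, A = %d)", n, A)
  t2_limit <- A * (n - 1) * (n + 1) / (n * (n - A)) * qf(confidence, A, n - A)
  qv <- q_residuals(m, X_cal)
  q_limit <- if (method == "empirical") {
    as.numeric(quantile(qv, confidence, type = 7, names = FALSE))
  } else {
    jackson_mudholkar_limit(m, X_cal, confidence)
  }
  list(q_limit = q_limit, t2_limit = t2_limit)
}

# Jackson-Mudholkar Q limit from the eigenvalues of the residual covariance.
jackson_mudholkar_limit <- function(m, X_cal, confidence) {
  X <- as.matrix(X_cal)
  Xc <- sweep(sweep(X, 2L, m$x_mean), 2L, m$x_scale, `/`)
  Tn <- Xc %*% pls1_rotation(m)
  E <- Xc - tcrossprod(Tn, m$x_loadings)
  lam <- eigen(crossprod(E) / (nrow(E) - 1), symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam) * 1e-12]
  th1 <- sum(lam); th2 <- sum(lam^2); th3 <- sum(lam^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 <= 0) h0 <- 1e-3
  z <- qnorm(confidence)
  th1 * (z * sqrt(2 * th2 * h0^2) / th1 + 1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

#' Screen calibration samples for outliers
#'
#' Fits a PLS-1 model with `n_lv` latent variables, computes per-sample Q and
#' T-squared with their confidence limits, and flags samples according to
#' `rule`: `"both_exceed"` (default; a sample must violate both limits --
#' conservative, removes fewer borderline samples) or `"either_exceeds"`.
#' Screening is a single pass; no refit-and-rescreen iteration.
#'
#' @param X Calibration predictor matrix.
#' @param y Calibration response vector.
#' @param n_lv Latent variables for the screening model.
#' @param confidence Confidence level (default 0.95).
#' @param rule Flagging rule.
#' @param q_method Passed to [control_limits()].
#' @param sample_id Optional identifiers carried into the report.
#' @return An `outlier_report`: data frame with columns `sample_id`, `q`,
#'   `t2`, `flagged`, plus attributes `q_limit`, `t2_limit`, `rule`,
#'   `confidence` and the screening `model`.
#' @export
flag_outliers <- function(X, y, n_lv, confidence = 0.95,
                          rule = c("both_exceed", "either_exceeds"),
                          q_method = "empirical", sample_id = NULL) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  m <- fit_pls1(X, y, n_lv)
  qv <- q_residuals(m, X)
  t2 <- hotelling_t2(m, X)
  lim <- control_limits(m, X, confidence, q_method)
  over_q <- qv > lim$q_limit
  over_t <- t2 > lim$t2_limit
  flagged <- if (rule == "both_exceed") over_q & over_t else over_q | over_t
  rep <- data.frame(
    sample_id = as.character(sample_id %||% seq_len(nrow(X))),
    q = qv, t2 = t2, flagged = flagged,
    stringsAsFactors = FALSE
  )
  attr(rep, "q_limit") <- lim$q_limit
  attr(rep, "t2_limit") <- lim$t2_limit
  attr(rep, "rule") <- rule
  attr(rep, "confidence") <- confidence
  attr(rep, "model") <- m
  class(rep) <- c("outlier_report", "data.frame")
  rep
}

#' Write an outlier report to CSV
#' @param x An `outlier_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outlier_report <- function(x, path) {
  df <- as.data.frame(x)
  df$q_limit <- attr(x, "q_limit")
  df$t2_limit <- attr(x, "t2_limit")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
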