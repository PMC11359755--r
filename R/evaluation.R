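# Splitting, cross-validation, latent-variable selection, validation metrics
# and the Malley / Williams classification tiers.

#' Group-aware calibration/validation split
#'
#' Whole groups (farm bunkers) are assigned to the validation side in random
#' order until the validation sample count first reaches
#' `validation_fraction * n`; the remainder form the calibration set. No
#' group ever straddles the two sides, keeping validation independent of
#' calibration.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param group Group (bunker) label per sample.
#' @param validation_fraction Target validation fraction in (0, 1);
#'   default 0.10.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A `split_plan`: list with `calibration_ids`, `validation_ids`,
#'   `seed`.
#' @export
group_split <- function(sample_id, group, validation_fraction = 0.10, seed) {
  sample_id <- as.character(sample_id); group <- as.character(group)
  stopifnot(length(sample_id) == length(group))
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stopf("validation_fraction must be in (0, 1)")
  }
  gs <- unique(group)
  if (length(gs) < 2L) stopf("need at least 2 distinct groups to split")
  n <- length(sample_id)
  target <- validation_fraction * n
  order_g <- with_seed(seed, sample(gs))
  sizes <- table(group)[order_g]
  taken <- cumsum(sizes)
  k <- which(taken >= target)[1L]
  if (k == length(gs)) k <- length(gs) - 1L  # keep calibration non-empty
  val_groups <- order_g[seq_len(k)]
  val <- group %in% val_groups
  structure(list(calibration_ids = sample_id[!val],
                 validation_ids = sample_id[val],
                 validation_groups = val_groups,
                 seed = seed),
            class = "split_plan")
}

#' Group-aware k-fold cross-validation folds
#'
#' Partitions the calibration samples into k folds without splitting any
#' group across folds. Groups are shuffled (seeded) and greedily assigned,
#' largest first, to the currently smallest fold, yielding near-equal fold
#' sizes. With all-singleton groups this reduces to ordinary k-fold.
#'
#' @param sample_id Calibration sample identifiers.
#' @param group Group label per sample.
#' @param k Number of folds (>= 2); default 5.
#' @param seed Integer seed.
#' @return List of k folds, each a list with `train_ids` and `held_ids`;
#'   the `held_ids` partition the input.
#' @export
kfold_cv <- function(sample_id, group, k = 5L, seed) {
  sample_id <- as.character(sample_id); group <- as.character(group)
  stopifnot(length(sample_id) == length(group))
  k <- as.integer(k)
  if (k < 2L) stopf("k must be >= 2")
  gs <- unique(group)
  if (length(gs) < k) stopf("only %d group(s) for %d folds", length(gs), k)
  gs <- with_seed(seed, sample(gs))
  sizes <- as.integer(table(group)[gs])
  ord <- order(sizes, decreasing = TRUE)
  fold_of <- integer(length(gs))
  fold_n <- integer(k)
  for (i in ord) {
    f <- which.min(fold_n)
    fold_of[i] <- f
    fold_n[f] <- fold_n[f] + sizes[i]
  }
  lapply(seq_len(k), function(f) {
    held_groups <- gs[fold_of == f]
    held <- group %in% held_groups
    list(train_ids = sample_id[!held], held_ids = sample_id[held])
  })
}

#' Prediction performance metrics
#'
#' Computes the standard NIRS calibration metrics: bias (mean of
#' predicted - reference), RMSE, bias-corrected standard error
#' `SE = sqrt(sum((e - bias)^2) / (n - 1))`, coefficient of determination
#' `R2 = 1 - SSE/SST`, the least-squares slope and intercept of predicted on
#' reference, and the ratio of performance to deviation
#' `RPD = SD(reference; n-1 denominator) / SE` (an `sd_reference` override is
#' available for reporting RPD against a different population SD).
#'
#' @param y_ref Reference values.
#' @param y_pred Predicted values (same length, n >= 2).
#' @param sd_reference Optional SD to use in the RPD numerator instead of
#'   `sd(y_ref)`.
#' @return An `evaluation_report`: one-row data frame with columns `n`,
#'   `rmse`, `bias`, `se`, `r2`, `slope`, `intercept`, `rpd`.
#' @export
compute_metrics <- function(y_ref, y_pred, sd_reference = NULL) {
  y_ref <- as.numeric(y_ref); y_pred <- as.numeric(y_pred)
  n <- length(y_ref)
  if (length(y_pred) != n) stopf("y_ref and y_pred lengths differ")
  if (n < 2L) stopf("need at least 2 observations")
  if (any(!is.finite(y_ref)) || any(!is.finite(y_pred))) stopf("values must be finite")
  sst <- sum((y_ref - mean(y_ref))^2)
  if (sst == 0) stopf("reference values have zero variance; R2 and RPD undefined")
  e <- y_pred - y_ref
  bias <- mean(e)
  rmse <- sqrt(mean(e^2))
  se <- sqrt(sum((e - bias)^2) / (n - 1))
  r2 <- 1 - sum(e^2) / sst
  fit <- stats::lm.fit(cbind(1, y_ref), y_pred)
  sd_y <- sd_reference %||% sd(y_ref)
  rpd <- if (se == 0) Inf else sd_y / se
  out <- data.frame(n = n, rmse = rmse, bias = bias, se = se, r2 = r2,
                    slope = unname(fit$coefficients[2L]),
                    intercept = unname(fit$coefficients[1L]),
                    rpd = rpd)
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Malley level-of-success tier for a calibration R-squared
#'
#' Tiers: R2 < 0.80 "Not useful"; 0.80-0.90 "Moderately Successful";
#' 0.90-0.95 "Successful"; >= 0.95 "Excellent" (intervals half-open on the
#' left boundary of the next tier).
#'
#' @param r2 Numeric vector of R-squared values.
#' @return Character vector of tier labels.
#' @export
classify_success <- function(r2) {
  stopifnot(is.numeric(r2), all(is.finite(r2)))
  cut_labels(r2, c(0.80, 0.90, 0.95),
             c("Not useful", "Moderately Successful", "Successful", "Excellent"))
}

#' Williams classification tier for an RPD value
#'
#' Tiers: RPD < 2.0 "Very poor"; 2.0-2.5 "Poor"; 2.5-3.0 "Fair"; 3.0-3.5
#' "Good"; 3.5-4.0 "Very good"; >= 4.0 "Excellent".
#'
#' @param rpd Numeric vector of non-negative RPD values.
#' @return Character vector of tier labels.
#' @export
classify_rpd <- function(rpd) {
  stopifnot(is.numeric(rpd), all(rpd >= 0 | is.infinite(rpd)))
  cut_labels(rpd, c(2.0, 2.5, 3.0, 3.5, 4.0),
             c("Very poor", "Poor", "Fair", "Good", "Very good", "Excellent"))
}

cut_labels <- function(x, breaks, labels) {
  idx <- findInterval(x, breaks) + 1L
  labels[idx]
}

#' Latent-variable grid search under cross-validation
#'
#' For each latent-variable count 1..`max_lv`, computes the calibration RMSE
#' (single full-calibration fit, coefficient path) and the cross-validated
#' RMSE from held-out predictions pooled across folds. The selected count
#' minimizes the CV RMSE, ties broken toward fewer latent variables;
#' `selection = "one_se"` instead picks the smallest count whose CV RMSE is
#' within one standard error (across folds) of the minimum.
#'
#' @param X Calibration predictor matrix.
#' @param y Calibration response vector.
#' @param sample_id Identifiers aligned with the rows of `X`, matching the
#'   ids in `cv_folds`.
#' @param cv_folds Folds from [kfold_cv()].
#' @param max_lv Largest latent-variable count to scan (default 20). If a
#'   fold exhausts the predictor rank earlier the scan is truncated and a
#'   warning is recorded in the result.
#' @param selection `"min"` (default) or `"one_se"`.
#' @return An `lv_search` list: `table` (data frame lv, rmse_cal, rmse_cv),
#'   `selected_lv`, `criterion`, `cv_predictions` (pooled held-out
#'   predictions per scanned LV, rows aligned with `X`), `warnings`.
#' @export
grid_search_lvs <- function(X, y, sample_id, cv_folds, max_lv = 20L,
                            selection = c("min", "one_se")) {
  selection <- match.arg(selection)
  X <- as.matrix(X); y <- as.numeric(y)
  sample_id <- as.character(sample_id)
  stopifnot(nrow(X) == length(y), length(sample_id) == length(y))
  warnings <- character()
  max_feasible <- function(n_rows) max(1L, min(max_lv, n_rows - 1L, ncol(X)))

  fit_capped <- function(Xs, ys, cap) {
    a <- cap
    repeat {
      m <- tryCatch(fit_pls1(Xs, ys, a), error = function(e) e)
      if (!inherits(m, "error")) return(m)
      if (a <= 1L) stop(m)
      a <- a - 1L
    }
  }

  m_full <- fit_capped(X, y, max_feasible(nrow(X)))
  if (m_full$n_lv < max_lv) {
    warnings <- c(warnings, sprintf("calibration scan truncated at %d latent variables",
                                    m_full$n_lv))
  }
  path <- pls1_coef_path(m_full)
  A_cal <- m_full$n_lv
  pred_cal <- sweep(X %*% path$coefficients, 2L, path$intercepts, `+`)
  rmse_cal <- sqrt(colMeans((pred_cal - y)^2))

  k <- length(cv_folds)
  A_folds <- integer(k)
  cv_pred <- matrix(NA_real_, nrow(X), A_cal)
  fold_rmse <- matrix(NA_real_, k, A_cal)
  for (f in seq_len(k)) {
    tr <- sample_id %in% cv_folds[[f]]$train_ids
    he <- sample_id %in% cv_folds[[f]]$held_ids
    mf <- fit_capped(X[tr, , drop = FALSE], y[tr], max_feasible(sum(tr)))
    A_folds[f] <- mf$n_lv
    pf <- pls1_coef_path(mf)
    a_use <- min(mf$n_lv, A_cal)
    ph <- sweep(X[he, , drop = FALSE] %*% pf$coefficients[, seq_len(a_use), drop = FALSE],
                2L, pf$intercepts[seq_len(a_use)], `+`)
    cv_pred[he, seq_len(a_use)] <- ph
    fold_rmse[f, seq_len(a_use)] <- sqrt(colMeans((ph - y[he])^2))
  }
  A <- min(A_cal, A_folds)
  if (A < A_cal) {
    warnings <- c(warnings, sprintf("CV scan truncated at %d latent variables", A))
    cv_pred <- cv_pred[, seq_len(A), drop = FALSE]
    fold_rmse <- fold_rmse[, seq_len(A), drop = FALSE]
  }
  rmse_cv <- sqrt(colMeans((cv_pred - y)^2))

  selected <- if (selection == "min") {
    which.min(rmse_cv)                      # first minimum = fewest LVs
  } else {
    se_min <- sd(fold_rmse[, which.min(rmse_cv)]) / sqrt(k)
    which(rmse_cv <= min(rmse_cv) + se_min)[1L]
  }
  structure(list(
    table = data.frame(lv = seq_len(A),
                       rmse_cal = rmse_cal[seq_len(A)],
                       rmse_cv = rmse_cv),
    selected_lv = as.integer(selected),
    criterion = selection,
    cv_predictions = cv_pred,
    warnings = warnings
  ), class = "lv_search")
}

#' Cross-validation error metrics from pooled held-out predictions
#'
#' SECV is the bias-corrected standard error of the pooled held-out
#' predictions, R2CV the corresponding 1 - SSE/SST, and RPDCV the calibration
#' reference SD divided by SECV. Pooling (rather than averaging per-fold
#' errors) is the reported convention throughout.
#'
#' @param y_cal Calibration reference values.
#' @param cv_pred Pooled held-out predictions aligned with `y_cal`; must be
#'   complete (every calibration sample predicted exactly once).
#' @return List with `secv`, `r2cv`, `rpdcv`.
#' @export
secv_metrics <- function(y_cal, cv_pred) {
  y_cal <- as.numeric(y_cal); cv_pred <- as.numeric(cv_pred)
  if (length(cv_pred) != length(y_cal) || any(!is.finite(cv_pred))) {
    stopf("pooled CV predictions must cover every calibration sample")
  }
  mm <- compute_metrics(y_cal, cv_pred)
  list(secv = mm$se, r2cv = mm$r2,
       rpdcv = if (mm$se == 0) Inf else sd(y_cal) / mm$se)
}
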