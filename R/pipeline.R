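# End-to-end orchestration: resample -> log(1/R) -> Savitzky-Golay ->
# replicate averaging -> bunker-aware split -> outlier screen -> LV grid
# search under group-aware CV -> final fit -> calibration and validation
# report tables.

#' Pipeline configuration
#'
#' @param grid Harmonized wavelength grid as `c(start, stop, step)` in nm;
#'   default 1454-2446 nm at 4 nm, the intersection of the default
#'   instruments' ranges at the fixed step.
#' @param sg Savitzky-Golay parameters ([sg_params()]); default window 4,
#'   polyorder 3, first derivative.
#' @param replicate_policy `"mean"` (default) or `"keep_all"`.
#' @param validation_fraction Group-wise validation fraction (default 0.10).
#' @param k Cross-validation folds (default 5).
#' @param max_lv Largest latent-variable count scanned (default 20).
#' @param recommended_lv_cap Selections above this count trigger a logged
#'   warning about likely overfitting (default 10).
#' @param outlier_lv Latent variables of the screening model (default 10).
#' @param confidence Confidence level of the outlier limits (default 0.95).
#' @param outlier_rule `"both_exceed"` (default) or `"either_exceeds"`.
#' @param constituents Constituents to calibrate (default all six).
#' @param seed Seed controlling the split and fold assignment.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid = c(1454, 2446, 4),
                            sg = sg_params(4L, 3L, 1L),
                            replicate_policy = "mean",
                            validation_fraction = 0.10,
                            k = 5L, max_lv = 20L, recommended_lv_cap = 10L,
                            outlier_lv = 10L, confidence = 0.95,
                            outlier_rule = "both_exceed",
                            constituents = FORAGE_CONSTITUENTS,
                            seed = 1L) {
  structure(list(grid = grid, sg = sg, replicate_policy = replicate_policy,
                 validation_fraction = validation_fraction, k = as.integer(k),
                 max_lv = as.integer(max_lv),
                 recommended_lv_cap = as.integer(recommended_lv_cap),
                 outlier_lv = as.integer(outlier_lv), confidence = confidence,
                 outlier_rule = outlier_rule, constituents = constituents,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Shared preprocessing: resample on reflectance, log(1/R), SG derivative,
# then replicate aggregation. Returns a spectra_set with one row per sample.
preprocess_stream <- function(spectra, cfg) {
  s <- resample_to_grid(spectra, cfg$grid[1L], cfg$grid[2L], cfg$grid[3L])
  s <- to_absorbance(s)
  s <- apply_sg(s, cfg$sg)
  aggregate_replicates(s, cfg$replicate_policy)
}

#' Calibrate PLS-1 models for every stream and constituent
#'
#' For each (instrument, scan mode) stream and each configured constituent:
#' preprocesses the spectra, splits samples by group into calibration and
#' validation sets (the same split for every stream, since it is derived
#' from the shared reference table and seed), screens the calibration set for
#' Q/T-squared outliers, selects the latent-variable count by grid search
#' under group-aware k-fold cross-validation, and fits the final model.
#' Failures in one stream are recorded and do not abort the others.
#'
#' @param spectra_list Named list of `spectra_set` objects (one per stream,
#'   names like `"instrument.mode"`), e.g. the `spectra` element of
#'   [make_campaign()].
#' @param reference A `reference_table` covering the scanned samples.
#' @param cfg A [pipeline_config()].
#' @return A `calibration_result`: list with `table` (one row per
#'   stream x constituent: RMSE, Bias, SE, SECV, R2, R2CV, RPD, RPDCV, LVs,
#'   outliers removed), `models` (nested list stream -> constituent ->
#'   `pls1_model`), `split` (the [group_split()] plan), `lv_search` curves,
#'   `log` (character), and `config`.
#' @export
run_calibrate <- function(spectra_list, reference, cfg = pipeline_config()) {
  stopifnot(inherits(reference, "reference_table"), inherits(cfg, "pipeline_config"))
  split <- group_split(reference$sample_id, reference$group,
                       cfg$validation_fraction, cfg$seed)
  cal_ref <- reference[reference$sample_id %in% split$calibration_ids, ]
  folds <- kfold_cv(cal_ref$sample_id, cal_ref$group, cfg$k,
                    seed = derive_seed(cfg$seed, 1L))
  log_lines <- c(
    sprintf("seed=%d validation_fraction=%.2f k=%d max_lv=%d",
            cfg$seed, cfg$validation_fraction, cfg$k, cfg$max_lv),
    sprintf("split: %d calibration / %d validation samples (%d validation groups)",
            length(split$calibration_ids), length(split$validation_ids),
            length(split$validation_groups))
  )
  rows <- list(); models <- list(); curves <- list()
  for (stream in names(spectra_list)) {
    prep <- tryCatch(preprocess_stream(spectra_list[[stream]], cfg),
                     error = function(e) e)
    if (inherits(prep, "error")) {
      log_lines <- c(log_lines, sprintf("stream %s: FAILED preprocessing (%s)",
                                        stream, conditionMessage(prep)))
      next
    }
    in_cal <- prep$meta$sample_id %in% split$calibration_ids
    X_cal <- prep$values[in_cal, , drop = FALSE]
    id_cal <- prep$meta$sample_id[in_cal]
    ord <- match(id_cal, cal_ref$sample_id)
    models[[stream]] <- list(); curves[[stream]] <- list()
    for (cc in cfg$constituents) {
      res <- tryCatch({
        y <- cal_ref[[cc]][ord]
        screen <- flag_outliers(X_cal, y, min(cfg$outlier_lv, nrow(X_cal) - 1L),
                                cfg$confidence, cfg$outlier_rule,
                                sample_id = id_cal)
        keep <- !screen$flagged
        Xk <- X_cal[keep, , drop = FALSE]; yk <- y[keep]; idk <- id_cal[keep]
        search <- grid_search_lvs(Xk, yk, idk, folds, cfg$max_lv)
        a <- search$selected_lv
        m <- fit_pls1(Xk, yk, a, wavelengths = prep$wavelengths)
        cvm <- secv_metrics(yk, search$cv_predictions[, a])
        mm <- compute_metrics(yk, predict(m, Xk))
        list(model = m, search = search,
             n_outliers = sum(screen$flagged),
             row = data.frame(
               stream = stream, constituent = cc, n = mm$n,
               rmse = mm$rmse, bias = mm$bias, se = mm$se, secv = cvm$secv,
               r2 = mm$r2, r2cv = cvm$r2cv, rpd = mm$rpd, rpdcv = cvm$rpdcv,
               lv = a, n_outliers = sum(screen$flagged),
               stringsAsFactors = FALSE
             ))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        log_lines <- c(log_lines, sprintf("stream %s %s: FAILED (%s)",
                                          stream, cc, conditionMessage(res)))
        next
      }
      rows[[paste(stream, cc)]] <- res$row
      models[[stream]][[cc]] <- res$model
      curves[[stream]][[cc]] <- res$search
      log_lines <- c(log_lines,
                     sprintf("stream %s %s: %d outlier(s) removed, selected %d LV(s)",
                             stream, cc, res$n_outliers, res$row$lv))
      if (res$row$lv > cfg$recommended_lv_cap) {
        log_lines <- c(log_lines,
                       sprintf("stream %s %s: selected LVs (%d) above recommended cap (%d); risk of overfitting",
                               stream, cc, res$row$lv, cfg$recommended_lv_cap))
      }
    }
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 models = models, split = split, lv_search = curves,
                 log = log_lines, config = cfg),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d fitted model(s)\n",
              if (is.null(x$table)) 0L else nrow(x$table)))
  if (!is.null(x$table)) print(format_metric_table(x$table))
  invisible(x)
}

format_metric_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 3))
  df
}

#' Evaluate calibrated models on the held-out validation set
#'
#' Applies the preprocessing of the calibration run, predicts the validation
#' samples of each stream x constituent, and reports validation metrics with
#' Malley / Williams classifications, plus a best-per-constituent summary
#' (minimum validation RMSE across streams).
#'
#' @param calibration A `calibration_result` from [run_calibrate()].
#' @param spectra_list The stream spectra (may be the same object passed to
#'   [run_calibrate()]; only validation samples are used).
#' @param reference The `reference_table`.
#' @return A `validation_result`: list with `table` (per stream x
#'   constituent: n, RMSE, Bias, SE, R2, slope, intercept, RPD, success and
#'   classification labels) and `best` (one row per constituent).
#' @export
run_validate <- function(calibration, spectra_list, reference) {
  stopifnot(inherits(calibration, "calibration_result"))
  cfg <- calibration$config
  split <- calibration$split
  val_ref <- reference[reference$sample_id %in% split$validation_ids, ]
  rows <- list()
  for (stream in names(calibration$models)) {
    if (is.null(spectra_list[[stream]])) next
    prep <- preprocess_stream(spectra_list[[stream]], cfg)
    in_val <- prep$meta$sample_id %in% split$validation_ids
    X_val <- prep$values[in_val, , drop = FALSE]
    ord <- match(prep$meta$sample_id[in_val], val_ref$sample_id)
    for (cc in names(calibration$models[[stream]])) {
      m <- calibration$models[[stream]][[cc]]
      if (length(prep$wavelengths) != m$p) {
        stopf("stream %s: validation grid (%d points) does not match model grid (%d)",
              stream, length(prep$wavelengths), m$p)
      }
      mm <- compute_metrics(val_ref[[cc]][ord], predict(m, X_val))
      rows[[paste(stream, cc)]] <- data.frame(
        stream = stream, constituent = cc, n = mm$n,
        rmse = mm$rmse, bias = mm$bias, se = mm$se, r2 = mm$r2,
        slope = mm$slope, intercept = mm$intercept, rpd = mm$rpd,
        lv = m$n_lv,
        success = classify_success(mm$r2),
        classification = classify_rpd(max(mm$rpd, 0)),
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  best <- NULL
  if (!is.null(tab)) {
    best <- do.call(rbind, lapply(split(tab, tab$constituent), function(d) {
      d[which.min(d$rmse), , drop = FALSE]
    }))
    rownames(best) <- NULL
  }
  structure(list(table = tab, best = best), class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result>\n")
  if (!is.null(x$best)) {
    cat("best model per constituent:\n")
    print(format_metric_table(x$best))
  }
  invisible(x)
}
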