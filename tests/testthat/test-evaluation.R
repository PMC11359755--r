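test_that("group splits keep bunkers intact and are deterministic", {
  # two-group atomicity: validation is exactly one whole group
  ids <- c("a", "b", "c"); grp <- c("g1", "g1", "g2")
  for (seed in 1:20) {
    sp <- group_split(ids, grp, 0.33, seed)
    expect_true(identical(sort(sp$validation_ids), c("a", "b")) ||
                  identical(sp$validation_ids, "c"))
  }

  # realistic sizes: ~10% validation, no group on both sides
  set.seed(9)
  n <- 600L
  grp <- sample(sprintf("bunker%03d", 1:111), n, replace = TRUE)
  ids <- sprintf("s%03d", 1:n)
  sp <- group_split(ids, grp, 0.10, seed = 4)
  expect_gte(length(sp$validation_ids), 60L)
  expect_lt(length(sp$validation_ids), 120L)
  expect_length(intersect(unique(grp[ids %in% sp$calibration_ids]),
                          unique(grp[ids %in% sp$validation_ids])), 0L)

  # determinism
  expect_identical(sp, group_split(ids, grp, 0.10, seed = 4))
  expect_error(group_split(ids, rep("g", n), 0.1, 1), "group")
})

test_that("group-aware k-fold CV partitions exactly with near-equal folds", {
  set.seed(10)
  n <- 540L
  grp <- sample(sprintf("b%03d", 1:99), n, replace = TRUE)
  ids <- sprintf("s%03d", 1:n)
  folds <- kfold_cv(ids, grp, 5L, seed = 2)
  held <- unlist(lapply(folds, `[[`, "held_ids"))
  expect_setequal(held, ids)
  expect_equal(length(held), n)              # pairwise disjoint
  sizes <- vapply(folds, function(f) length(f$held_ids), integer(1))
  expect_true(all(abs(sizes - n / 5) < 25))  # ~108 each
  for (f in folds) {
    expect_length(intersect(unique(grp[ids %in% f$train_ids]),
                            unique(grp[ids %in% f$held_ids])), 0L)
    expect_setequal(c(f$train_ids, f$held_ids), ids)
  }

  # singleton groups reduce to ordinary k-fold
  folds1 <- kfold_cv(ids, ids, 4L, seed = 3)
  sizes1 <- vapply(folds1, function(f) length(f$held_ids), integer(1))
  expect_true(max(sizes1) - min(sizes1) <= 1L)
  expect_error(kfold_cv(ids, rep(c("x", "y"), n / 2), 5L, 1), "fold")
})

test_that("evaluation metrics satisfy their defining identities", {
  set.seed(11)
  y <- rnorm(60, 50, 5)
  pred <- y + rnorm(60, 0.3, 2)
  m <- compute_metrics(y, pred)
  # bias-corrected SE identity
  expect_equal(m$se^2, m$n * (m$rmse^2 - m$bias^2) / (m$n - 1), tolerance = 1e-10)
  expect_gte(m$rmse, abs(m$bias))
  expect_equal(m$rpd, sd(y) / m$se, tolerance = 1e-12)
  # slope/intercept are the OLS fit of predicted on reference
  fit <- lm(pred ~ y)
  expect_equal(m$slope, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(m$intercept, unname(coef(fit)[1]), tolerance = 1e-10)

  # perfect prediction
  mp <- compute_metrics(y, y)
  expect_equal(mp[c("rmse", "bias", "intercept")], list(rmse = 0, bias = 0, intercept = 0),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mp$r2, 1); expect_equal(mp$slope, 1, tolerance = 1e-10)
  expect_identical(mp$rpd, Inf)

  # constant prediction anchors R2 <= 0 and RPD ~ 1
  mc <- compute_metrics(y, rep(mean(y), 60))
  expect_lte(mc$r2, 0)
  expect_equal(mc$rpd, 1, tolerance = 1e-12)

  expect_error(compute_metrics(rep(1, 10), rnorm(10)), "variance")
  # sd_reference override changes only the RPD numerator
  mo <- compute_metrics(y, pred, sd_reference = 10)
  expect_equal(mo$rpd, 10 / mo$se, tolerance = 1e-12)
})

test_that("classification tiers are total, monotone step functions", {
  r2_grid <- seq(0, 1, by = 0.001)
  lab <- classify_success(r2_grid)
  expect_false(anyNA(lab))
  ord <- c("Not useful", "Moderately Successful", "Successful", "Excellent")
  expect_true(all(diff(match(lab, ord)) >= 0))
  expect_identical(classify_success(c(0.799999, 0.80, 0.90, 0.95)),
                   c("Not useful", "Moderately Successful", "Successful", "Excellent"))

  rpd_grid <- seq(0, 6, by = 0.01)
  labr <- classify_rpd(rpd_grid)
  expect_false(anyNA(labr))
  ordr <- c("Very poor", "Poor", "Fair", "Good", "Very good", "Excellent")
  expect_true(all(diff(match(labr, ordr)) >= 0))
  expect_identical(classify_rpd(c(1.999, 2.0, 2.5, 3.0, 3.5, 4.0)),
                   c("Very poor", "Poor", "Fair", "Good", "Very good", "Excellent"))
})

test_that("LV grid search selects parsimoniously and reports sane curves", {
  set.seed(12)
  n <- 120L; p <- 40L
  S <- matrix(rnorm(n * 3), n, 3)
  X <- S %*% matrix(rnorm(3 * p), 3, p) + matrix(rnorm(n * p, 0, 0.05), n, p)
  y <- drop(S %*% c(2, -1, 0.5)) + rnorm(n, 0, 0.3)
  ids <- sprintf("s%03d", 1:n)
  folds <- kfold_cv(ids, ids, 5L, seed = 1)
  gs <- grid_search_lvs(X, y, ids, folds, max_lv = 12L)

  expect_true(all(diff(gs$table$rmse_cal) <= 1e-10))
  expect_true(abs(gs$selected_lv - 3L) <= 1L)
  # pooled CV predictions cover every sample
  expect_false(anyNA(gs$cv_predictions))

  # max_lv = 1 degenerate search
  gs1 <- grid_search_lvs(X, y, ids, folds, max_lv = 1L)
  expect_identical(gs1$selected_lv, 1L)

  # SECV metrics from pooled predictions; pooled != fold-averaged in general
  cv <- secv_metrics(y, gs$cv_predictions[, gs$selected_lv])
  expect_gte(cv$secv, 0)
  expect_equal(cv$rpdcv, sd(y) / cv$secv, tolerance = 1e-12)
  per_fold <- vapply(folds, function(f) {
    i <- ids %in% f$held_ids
    sqrt(mean((gs$cv_predictions[i, gs$selected_lv] - y[i])^2))
  }, numeric(1))
  expect_false(isTRUE(all.equal(mean(per_fold),
                                sqrt(mean((gs$cv_predictions[, gs$selected_lv] - y)^2)))))

  # held-out error exceeds resubstitution error at the same LV
  expect_gte(gs$table$rmse_cv[gs$selected_lv], gs$table$rmse_cal[gs$selected_lv])

  # perfect CV predictions
  cvp <- secv_metrics(y, y)
  expect_equal(cvp$secv, 0); expect_equal(cvp$r2cv, 1)
  expect_error(secv_metrics(y, c(NA, y[-1])), "cover")
})
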