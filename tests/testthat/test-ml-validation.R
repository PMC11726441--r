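test_that("split construction satisfies the bookkeeping identities", {
  sim <- small_sim()
  md <- sim$metadata
  pair <- c("omnivore", "vegan")
  # lodo over 3 cohorts: one split per target, train = other cohorts
  for (tc in unique(md$cohort)) {
    sp <- make_splits(md, pair, "lodo", tc)
    expect_length(sp, 1L)
    expect_setequal(sp[[1]]$test,
                    md$sample_id[md$cohort == tc & md$diet %in% pair])
    expect_length(intersect(sp[[1]]$train, sp[[1]]$test), 0L)
  }
  # cross-lodo: train size = (k-1)/k of target pair + all other pair samples
  n_target <- sum(md$cohort == "cohort1" & md$diet %in% pair)
  n_other <- sum(md$cohort != "cohort1" & md$diet %in% pair)
  suppressWarnings(
    sp <- make_splits(md, pair, "cross_lodo", "cohort1", n_repeats = 2,
                      n_folds = 4, seed = 3))
  for (s in sp) {
    expect_equal(length(s$train) + length(s$test) - n_other, n_target)
    expect_length(intersect(s$train, s$test), 0L)
    # test ids only ever come from the target cohort
    expect_true(all(md$cohort[match(s$test, md$sample_id)] == "cohort1"))
  }
  # folds partition the target cohort within each repetition
  reps <- split(sp, vapply(sp, `[[`, 1L, "repetition"))
  for (r in reps) {
    expect_setequal(unlist(lapply(r, `[[`, "test")),
                    md$sample_id[md$cohort == "cohort1" & md$diet %in% pair])
  }
  # identical seeds reproduce identical splits
  suppressWarnings(sp2 <- make_splits(md, pair, "cross_lodo", "cohort1",
                                      n_repeats = 2, n_folds = 4, seed = 3))
  expect_identical(sp, sp2)
  # a cohort too small for the requested folds reduces them with a warning
  expect_warning(make_splits(md, pair, "cv", "cohort3", n_folds = 10),
                 "reducing folds")
})

test_that("AUC behaves at the extremes of separability", {
  set.seed(9)
  n <- 120
  feats <- data.frame(good = c(rnorm(n / 2, 0), rnorm(n / 2, 6)),
                      noise = rnorm(n))
  rownames(feats) <- paste0("s", 1:n)
  labels <- setNames(factor(rep(c("a", "b"), each = n / 2), c("a", "b")),
                     rownames(feats))
  train <- rownames(feats)[c(1:40, 61:100)]
  test <- setdiff(rownames(feats), train)
  # a feature that perfectly separates classes
  res <- fit_predict_auc(feats, labels, train, test, rf_spec("scaled"), seed = 1)
  expect_equal(res$auc, 1.0)
  # constant features are uninformative
  feats2 <- data.frame(x = rep(1, n), y = rep(2, n),
                       row.names = rownames(feats))
  res2 <- fit_predict_auc(feats2, labels, train, test, rf_spec("scaled"), seed = 1)
  expect_true(abs(res2$auc - 0.5) < 0.25)
  # single-class test set is skipped
  expect_message(
    out <- fit_predict_auc(feats, labels, train,
                           rownames(feats)[41:60], rf_spec("scaled")),
    "single-class")
  expect_null(out)
})

test_that("ROC averaging anchors endpoints and collapses identical curves", {
  rc <- data.frame(fpr = c(0, 0.2, 0.5, 1), tpr = c(0, 0.6, 0.8, 1))
  avg <- average_roc(list(rc, rc, rc))
  expect_equal(avg$tpr_mean[avg$fpr == 0], 0)
  expect_equal(avg$tpr_mean[avg$fpr == 1], 1)
  expect_equal(avg$tpr_lo, avg$tpr_hi, tolerance = 1e-12)  # zero-width band
  expect_equal(avg$tpr_mean[avg$fpr == 0.2], 0.6, tolerance = 1e-9)
  # band width shrinks roughly as 1/sqrt(number of tests)
  set.seed(4)
  curves_n <- function(k) lapply(1:k, function(i) {
    data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 0.7 + rnorm(1, 0, 0.05), 1))
  })
  w <- vapply(c(8, 32), function(k) {
    a <- average_roc(curves_n(k), seed = 2)
    mean(a$tpr_hi - a$tpr_lo, na.rm = TRUE)
  }, numeric(1))
  expect_gt(w[1] / w[2], 1.4)
  # a single curve has no band
  expect_true(all(is.na(average_roc(list(rc))$tpr_lo)))
})

test_that("diet classification separates a planted strong signature", {
  sim <- small_sim()  # 5 features at d = 1.0
  vr <- run_diet_classification(sim$abundance, sim$metadata,
                                c("omnivore", "vegan"), scheme = "cross_lodo",
                                rf = rf_spec("scaled", n_repeats = 2),
                                seed = 11)
  expect_gt(vr$mean_auc, 0.7)
  expect_true(all(vr$per_test$auc >= 0 & vr$per_test$auc <= 1))
  expect_equal(vr$mean_auc, mean(vr$per_test$auc))
  # determinism: identical seeds give identical per-test AUCs
  vr2 <- run_diet_classification(sim$abundance, sim$metadata,
                                 c("omnivore", "vegan"), scheme = "cross_lodo",
                                 rf = rf_spec("scaled", n_repeats = 2),
                                 seed = 11)
  expect_identical(vr$per_test, vr2$per_test)
})

test_that("FFQ-coupled presence is predictable, uncoupled is not", {
  sim <- small_sim()
  dairy_feat <- sim$truth$food_features$feature_id[
    sim$truth$food_features$category == "dairy"][1]
  # pick a mid-prevalence feature with no FFQ coupling as the null case
  prev <- colMeans(unclass(sim$abundance) > 0)
  null_feat <- setdiff(names(prev)[prev > 0.3 & prev < 0.7],
                       c(sim$truth$food_features$feature_id,
                         sim$truth$effects$feature_id))[1]
  res <- predict_presence_from_ffq(
    sim$abundance, sim$ffq, sim$metadata,
    features = c(dairy_feat, null_feat),
    rf = rf_spec("scaled", n_repeats = 2, n_folds = 3), seed = 21)
  m <- res$meta
  expect_gt(m$pooled_auc[m$feature_id == dairy_feat], 0.7)
  expect_lt(abs(m$pooled_auc[m$feature_id == null_feat] - 0.5), 0.12)
  # a feature above 90% prevalence in every cohort is excluded outright
  tab2 <- unclass(sim$abundance)
  tab2[, null_feat] <- pmax(tab2[, null_feat], 1e-6)  # make it ubiquitous
  expect_error(
    predict_presence_from_ffq(abundance_table(100 * tab2 / rowSums(tab2)),
                              sim$ffq, sim$metadata, features = null_feat,
                              rf = rf_spec("scaled", n_repeats = 1,
                                           n_folds = 3), seed = 3),
    "prevalence window")
})
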