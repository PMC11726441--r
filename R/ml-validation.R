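#' Random-forest hyperparameter specification
#'
#' The full-fidelity profile matches the study configuration: 1,000 trees,
#' 10 samples per leaf, no depth limit, Gini impurity, 10 percent of the
#' features tried at each split, 10-times 10-fold cross-validation. The
#' scaled profile (200 trees, 5-times 5-fold) is a first-class desk-scale
#' configuration used by the packaged experiments and tests.
#'
#' @param profile `"full"` or `"scaled"`.
#' @param n_trees,min_node_size,n_repeats,n_folds,mtry_fraction overrides.
#' @return list of class `rf_spec`.
#' @export
rf_spec <- function(profile = c("full", "scaled"), n_trees = NULL,
                    min_node_size = 10L, n_repeats = NULL, n_folds = NULL,
                    mtry_fraction = 0.10) {
  profile <- match.arg(profile)
  defaults <- if (profile == "full") list(trees = 1000L, rep = 10L, folds = 10L)
              else list(trees = 200L, rep = 5L, folds = 5L)
  spec <- list(profile = profile,
               n_trees = as.integer(n_trees %||% defaults$trees),
               min_node_size = as.integer(min_node_size),
               n_repeats = as.integer(n_repeats %||% defaults$rep),
               n_folds = as.integer(n_folds %||% defaults$folds),
               mtry_fraction = mtry_fraction)
  if (spec$n_trees < 1L) stop("n_trees must be >= 1")
  class(spec) <- "rf_spec"
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stratified fold assignment: within each class, shuffle and deal
# round-robin so folds differ in size by at most one per class
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Build train/test splits for a validation scheme
#'
#' Three schemes over a two-diet comparison. `cv`: stratified repeated
#' k-fold within the target cohort. `lodo`: a single split per target
#' cohort, training on all other cohorts. `cross_lodo`: the cv folds of the
#' target cohort with every pair-labelled sample of all other cohorts
#' appended to each training set as support. Test sets only ever contain
#' target-cohort samples and never intersect their training set. If the
#' rarer class of the target cohort cannot populate the requested number of
#' folds, the fold count is reduced with a warning.
#'
#' @param metadata a [sample_metadata()].
#' @param diet_pair `c(reference, comparison)` diet labels.
#' @param scheme `"cv"`, `"lodo"` or `"cross_lodo"`.
#' @param target_cohort cohort whose samples are tested.
#' @param n_repeats,n_folds cross-validation geometry (cv / cross_lodo).
#' @param seed RNG seed for the fold draws.
#' @return list of splits, each `list(train, test, repetition, fold)` of
#'   sample ids.
#' @export
make_splits <- function(metadata, diet_pair, scheme = c("cv", "lodo", "cross_lodo"),
                        target_cohort, n_repeats = 10L, n_folds = 10L,
                        seed = 1L) {
  scheme <- match.arg(scheme)
  md <- metadata[metadata$diet %in% diet_pair, , drop = FALSE]
  tgt <- md[md$cohort == target_cohort, , drop = FALSE]
  if (length(unique(tgt$diet[!is.na(tgt$diet)])) < 2L) {
    stop("target cohort lacks one of the two diet classes")
  }
  rest_ids <- md$sample_id[md$cohort != target_cohort]
  if (scheme == "lodo") {
    if (length(rest_ids) == 0L) stop("lodo needs at least one other cohort")
    return(list(list(train = rest_ids, test = tgt$sample_id,
                     repetition = 1L, fold = 1L)))
  }
  min_class <- min(table(droplevels(tgt$diet)))
  if (min_class < n_folds) {
    warning(sprintf("target cohort '%s': rarer class has %d samples; reducing folds from %d to %d",
                    target_cohort, min_class, n_folds, min_class))
    n_folds <- max(2L, as.integer(min_class))
  }
  with_seed(seed, {
    splits <- list()
    for (r in seq_len(n_repeats)) {
      fold <- stratified_folds(as.character(tgt$diet), n_folds)
      for (f in seq_len(n_folds)) {
        test <- tgt$sample_id[fold == f]
        train <- tgt$sample_id[fold != f]
        if (scheme == "cross_lodo") train <- c(train, rest_ids)
        splits[[length(splits) + 1L]] <-
          list(train = train, test = test, repetition = r, fold = f)
      }
    }
    splits
  })
}

# rank-based AUC of scores for the positive class
auc_from_scores <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC step-curve points from scores (fpr, tpr), ascending fpr
roc_points <- function(scores, is_pos) {
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(is_pos[o]); fp <- cumsum(!is_pos[o])
  data.frame(fpr = c(0, fp / max(fp[length(fp)], 1)),
             tpr = c(0, tp / max(tp[length(tp)], 1)))
}

#' Fit a random forest on a split and score the test set
#'
#' Trains a probability random forest (via [ranger::ranger()]) per the
#' hyperparameter spec and returns the test AUC of the predicted
#' class-probability of the second (comparison) diet level, with the ROC
#' points needed for curve averaging. Returns `NULL` (after a message) when
#' the test set holds a single class, in which case the split is skipped.
#'
#' @param features numeric matrix/data frame, samples x features (rownames
#'   are sample ids).
#' @param labels factor of two levels named by sample via `names(labels)`
#'   or aligned to `rownames(features)`.
#' @param train,test sample-id vectors.
#' @param rf an [rf_spec()].
#' @param seed seed forwarded to the forest.
#' @return list with `auc` and `roc` (data frame fpr/tpr), or `NULL`.
#' @export
fit_predict_auc <- function(features, labels, train, test, rf = rf_spec("scaled"),
                            seed = 1L) {
  features <- as.data.frame(features)
  if (is.null(names(labels))) names(labels) <- rownames(features)
  ytr <- droplevels(factor(labels[train]))
  if (nlevels(ytr) < 2L) stop("training set holds a single class")
  yte <- factor(labels[test], levels = levels(ytr))
  if (length(unique(yte)) < 2L) {
    message("single-class test set; split skipped")
    return(NULL)
  }
  dtr <- cbind(.label = ytr, features[train, , drop = FALSE])
  fit <- ranger::ranger(dependent.variable.name = ".label", data = dtr,
                        num.trees = rf$n_trees,
                        mtry = max(1L, round(rf$mtry_fraction * ncol(features))),
                        min.node.size = rf$min_node_size,
                        probability = TRUE, num.threads = 1L, seed = seed)
  pos <- levels(ytr)[2L]
  prob <- stats::predict(fit, features[test, , drop = FALSE],
                         num.threads = 1L)$predictions[, pos]
  is_pos <- yte == pos
  list(auc = auc_from_scores(prob, is_pos), roc = roc_points(prob, is_pos))
}

#' Average per-test ROC curves with a bootstrap-t confidence band
#'
#' Each test's ROC step curve is linearly interpolated onto a common
#' false-positive-rate grid; the mean true-positive rate per grid point is
#' the averaged curve, anchored at (0,0) and (1,1). The band is
#' mean +/- t-quantile x bootstrap standard error of the mean, obtained by
#' resampling tests with replacement, clamped to \[0, 1\].
#'
#' @param roc_list list of data frames with columns `fpr`, `tpr`.
#' @param grid FPR grid.
#' @param ci_level confidence level.
#' @param n_boot bootstrap resamples of the test set.
#' @param seed RNG seed for the bootstrap.
#' @return data frame with `fpr`, `tpr_mean`, `tpr_lo`, `tpr_hi`.
#' @export
average_roc <- function(roc_list, grid = seq(0, 1, by = 0.01),
                        ci_level = 0.95, n_boot = 200L, seed = 1L) {
  if (length(roc_list) == 0L) stop("no ROC curves to average")
  interp <- vapply(roc_list, function(rc) {
    y <- stats::approx(rc$fpr, rc$tpr, xout = grid, ties = max, rule = 2)$y
    y[1L] <- 0  # anchor the averaged curve at the ROC endpoints
    y[length(y)] <- 1
    y
  }, numeric(length(grid)))
  interp <- matrix(interp, nrow = length(grid))
  m <- rowMeans(interp)
  if (ncol(interp) < 2L) {
    return(data.frame(fpr = grid, tpr_mean = m, tpr_lo = NA_real_,
                      tpr_hi = NA_real_))
  }
  se <- with_seed(seed, {
    boot_means <- replicate(n_boot, {
      rowMeans(interp[, sample.int(ncol(interp), replace = TRUE), drop = FALSE])
    })
    apply(boot_means, 1L, stats::sd)
  })
  tq <- stats::qt(1 - (1 - ci_level) / 2, df = ncol(interp) - 1L)
  data.frame(fpr = grid, tpr_mean = m,
             tpr_lo = pmax(0, m - tq * se), tpr_hi = pmin(1, m + tq * se))
}

#' Diet-pair classification experiment
#'
#' Runs one full validation experiment: builds the splits of the requested
#' scheme for every eligible target cohort, fits a probability random
#' forest on the feature table (optionally with sex/age/BMI appended),
#' collects per-test AUCs, and averages ROC curves. Setting
#' `permute_labels = TRUE` randomly permutes the diet labels within each
#' cohort before splitting — the negative control for leakage and
#' overfitting.
#'
#' @param table an [abundance_table()] (or any numeric feature matrix with
#'   sample rownames).
#' @param metadata a [sample_metadata()].
#' @param diet_pair `c(reference, comparison)`.
#' @param scheme `"cv"`, `"lodo"` or `"cross_lodo"`.
#' @param rf an [rf_spec()].
#' @param with_covariates append sex, age and BMI to the features.
#' @param permute_labels permute diet labels within cohort (negative
#'   control).
#' @param seed master seed for folds, forests and the permutation.
#' @return list of class `validation_result`: `scheme`, `diet_pair`,
#'   `per_test` (target_cohort, repetition, fold, auc), `mean_auc`,
#'   `per_cohort` summary, and `roc` (averaged curve with CI band).
#' @export
run_diet_classification <- function(table, metadata,
                                    diet_pair = c("omnivore", "vegan"),
                                    scheme = c("cross_lodo", "cv", "lodo"),
                                    rf = rf_spec("scaled"),
                                    with_covariates = FALSE,
                                    permute_labels = FALSE, seed = 1L) {
  scheme <- match.arg(scheme)
  al <- align_samples(table, metadata)
  table <- al$table; metadata <- al$metadata
  if (permute_labels) {
    metadata <- with_seed(child_seed(seed, 555557L), {
      for (co in unique(metadata$cohort)) {
        idx <- which(metadata$cohort == co)
        metadata$diet[idx] <- sample(metadata$diet[idx])
      }
      metadata
    })
  }
  feats <- as.data.frame(unclass(table))
  if (with_covariates) {
    feats$._sex <- as.integer(metadata$sex[match(rownames(feats),
                                                 metadata$sample_id)])
    feats$._age <- metadata$age[match(rownames(feats), metadata$sample_id)]
    feats$._bmi <- metadata$bmi[match(rownames(feats), metadata$sample_id)]
  }
  labels <- stats::setNames(factor(as.character(metadata$diet),
                                   levels = diet_pair),
                            metadata$sample_id)
  counts <- table(metadata$cohort[metadata$diet %in% diet_pair],
                  droplevels(metadata$diet[metadata$diet %in% diet_pair]))
  targets <- rownames(counts)[apply(counts >= 2L, 1L, all)]
  if (length(targets) == 0L) stop("no cohort contains both diet classes")

  per_test <- list(); rocs <- list()
  for (ti in seq_along(targets)) {
    tc <- targets[ti]
    splits <- make_splits(metadata, diet_pair, scheme, tc,
                          n_repeats = rf$n_repeats, n_folds = rf$n_folds,
                          seed = child_seed(seed, ti))
    for (si in seq_along(splits)) {
      sp <- splits[[si]]
      res <- fit_predict_auc(feats, labels, sp$train, sp$test, rf,
                             seed = child_seed(seed, 1000L * ti + si))
      if (is.null(res)) next
      per_test[[length(per_test) + 1L]] <-
        data.frame(target_cohort = tc, repetition = sp$repetition,
                   fold = sp$fold, auc = res$auc, stringsAsFactors = FALSE)
      rocs[[length(rocs) + 1L]] <- res$roc
    }
  }
  per_test <- do.call(rbind, per_test)
  if (is.null(per_test)) stop("no evaluable split produced an AUC")
  per_cohort <- do.call(rbind, lapply(split(per_test, per_test$target_cohort),
    function(sub) data.frame(cohort = sub$target_cohort[1L],
                             mean_auc = mean(sub$auc), n_tests = nrow(sub),
                             stringsAsFactors = FALSE)))
  rownames(per_cohort) <- NULL
  structure(list(scheme = scheme, diet_pair = diet_pair,
                 per_test = per_test, mean_auc = mean(per_test$auc),
                 per_cohort = per_cohort,
                 roc = average_roc(rocs, seed = child_seed(seed, 777779L))),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> %s, %s vs %s: mean AUC %.3f over %d tests\n",
              x$scheme, x$diet_pair[1L], x$diet_pair[2L], x$mean_auc,
              nrow(x$per_test)))
  invisible(x)
}

#' Predict per-feature presence from FFQ items
#'
#' For every feature whose presence (abundance > 0) prevalence lies inside
#' the prevalence window within a cohort, runs a repeated stratified
#' cross-validation predicting presence from the FFQ item intakes with a
#' probability random forest; the cohort AUC is the mean per-fold AUC with
#' standard error sd/sqrt(number of tests). Cohort AUCs are pooled across
#' cohorts by DerSimonian-Laird random-effects meta-analysis. Features
#' outside the window in every cohort are excluded.
#'
#' @param table an [abundance_table()].
#' @param ffq an [ffq_table()] over the same samples.
#' @param metadata a [sample_metadata()].
#' @param features feature ids to model (default: all).
#' @param prevalence_window inclusive per-cohort prevalence bounds.
#' @param rf an [rf_spec()].
#' @param seed master seed.
#' @return list with `meta` (per feature: pooled_auc, se, ci, k, i2) and
#'   `cohort` (per-cohort mean AUC and se).
#' @export
predict_presence_from_ffq <- function(table, ffq, metadata, features = NULL,
                                      prevalence_window = c(0.10, 0.90),
                                      rf = rf_spec("scaled"), seed = 1L) {
  al <- align_samples(table, metadata)
  table <- al$table; metadata <- al$metadata
  common <- intersect(rownames(table), rownames(ffq$intakes))
  table <- table[common, , drop = FALSE]
  metadata <- metadata[match(common, metadata$sample_id), , drop = FALSE]
  items <- as.data.frame(ffq$intakes[common, , drop = FALSE])
  if (is.null(features)) features <- colnames(table)

  cohort_rows <- list()
  for (f in features) {
    pres <- stats::setNames(factor(ifelse(table[, f] > 0, "present", "absent"),
                                   levels = c("absent", "present")), common)
    for (co in unique(metadata$cohort)) {
      idx <- metadata$cohort == co
      prev <- mean(pres[idx] == "present")
      if (prev < prevalence_window[1L] || prev > prevalence_window[2L]) next
      ids <- metadata$sample_id[idx]
      lab <- as.character(pres[ids])
      n_folds <- min(rf$n_folds, min(table(lab)))
      if (n_folds < 2L) next
      aucs <- with_seed(child_seed(seed, match(f, features) * 131L +
                                     match(co, unique(metadata$cohort))), {
        out <- c()
        for (r in seq_len(rf$n_repeats)) {
          fold <- stratified_folds(lab, n_folds)
          for (fi in seq_len(n_folds)) {
            res <- fit_predict_auc(items, pres, ids[fold != fi],
                                   ids[fold == fi], rf,
                                   seed = child_seed(seed, 31L * r + fi))
            if (!is.null(res)) out <- c(out, res$auc)
          }
        }
        out
      })
      if (length(aucs) < 2L) next
      cohort_rows[[length(cohort_rows) + 1L]] <-
        data.frame(feature_id = f, cohort = co, auc = mean(aucs),
                   se = stats::sd(aucs) / sqrt(length(aucs)),
                   n_tests = length(aucs), prevalence = prev,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(cohort_rows) == 0L) {
    stop("no feature lies inside the prevalence window in any cohort")
  }
  cohort_df <- do.call(rbind, cohort_rows)
  meta <- do.call(rbind, lapply(split(cohort_df, cohort_df$feature_id),
    function(sub) {
      dl <- dersimonian_laird(sub$auc, pmax(sub$se, 1e-6)^2)
      data.frame(feature_id = sub$feature_id[1L], pooled_auc = dl$pooled,
                 se = dl$se, ci_low = dl$ci_low, ci_high = dl$ci_high,
                 i2 = dl$i2, k = dl$k, stringsAsFactors = FALSE)
    }))
  rownames(meta) <- NULL
  list(meta = meta, cohort = cohort_df)
}
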