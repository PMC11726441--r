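#' Partial Spearman correlation
#'
#' Rank-transforms every variable (average ranks for ties; numeric
#' covariates are ranked as well, in the usual Spearman-partial
#' convention), residualizes the two target rank vectors on the covariate
#' design by least squares, and returns the Pearson correlation of the
#' residual vectors. With no covariates this equals the classical Spearman
#' rho.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data frame of adjustment covariates; rows
#'   with missing values are dropped listwise.
#' @return `rho_partial`, or `NA` when either variable is constant.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  dat <- data.frame(.x = x, .y = y)
  has_cov <- !is.null(covariates) && ncol(as.data.frame(covariates)) > 0L
  if (has_cov) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  k <- if (has_cov) ncol(dat) - 2L else 0L
  if (n <= k + 3L) stop("too few complete observations for the covariate set")
  if (stats::sd(dat$.x) == 0 || stats::sd(dat$.y) == 0) return(NA_real_)
  rx <- rank(dat$.x); ry <- rank(dat$.y)
  if (!has_cov) return(stats::cor(rx, ry))
  covs <- dat[, -(1:2), drop = FALSE]
  for (j in seq_along(covs)) {
    if (is.numeric(covs[[j]])) covs[[j]] <- rank(covs[[j]])
  }
  qr_x <- qr(stats::model.matrix(~ ., data = covs))
  ex <- qr.resid(qr_x, rx)
  ey <- qr.resid(qr_x, ry)
  if (stats::sd(ex) == 0 || stats::sd(ey) == 0) return(NA_real_)
  stats::cor(ex, ey)
}

#' Fisher-Z random-effects pooling of correlations
#'
#' Transforms per-cohort correlations to the Fisher z scale
#' (`atanh(rho)`), pools them by DerSimonian-Laird inverse-variance
#' random-effects meta-analysis and back-transforms the pooled estimate and
#' its CI with `tanh`. The z-scale standard error is
#' `1/sqrt(n - 3 - k_covariates)` by default (partial-correlation degrees of
#' freedom); `df = "classic"` uses `1/sqrt(n - 3)`.
#'
#' @param rho per-cohort correlations (strictly inside (-1, 1)).
#' @param n per-cohort effective sample sizes.
#' @param k_covariates number of adjustment covariates.
#' @param df `"partial"` (default) or `"classic"`.
#' @return list with `pooled_rho`, `ci_low`, `ci_high`, `p`, `tau2`, `i2`,
#'   `k` and the z-scale fields `pooled_z`, `se_z`.
#' @export
fisher_pool <- function(rho, n, k_covariates = 0L, df = c("partial", "classic")) {
  df <- match.arg(df)
  if (any(abs(rho) >= 1)) stop("rho = +/-1 has infinite Fisher z")
  adj <- if (df == "partial") 3 + k_covariates else 3
  if (any(n - adj < 1)) stop("effective n too small for the Fisher-z variance")
  z <- atanh(rho)
  v <- 1 / (n - adj)
  dl <- dersimonian_laird(z, v)
  list(pooled_rho = tanh(dl$pooled), ci_low = tanh(dl$ci_low),
       ci_high = tanh(dl$ci_high), p = dl$p, tau2 = dl$tau2, i2 = dl$i2,
       k = dl$k, pooled_z = dl$pooled, se_z = dl$se)
}

#' Total intake of a food group
#'
#' @param ffq an [ffq_table()].
#' @param group food-group name present in the group map.
#' @return named per-sample totals; samples with a missing item intake get
#'   `NA` (flagged out of that group's correlations).
#' @export
food_group_intake <- function(ffq, group) {
  items <- ffq$group_map$item[ffq$group_map$group == group]
  if (length(items) == 0L) stop("no items mapped to group: ", group)
  rowSums(ffq$intakes[, items, drop = FALSE])
}

# which diet patterns are eligible consumers of an exposure
consumer_diets <- function(exposure) {
  switch(exposure,
         red_meat = , white_meat = , meat = , fish = "omnivore",
         dairy = , eggs = , animal_fat = c("omnivore", "vegetarian"),
         DIET_LEVELS)
}

#' Cross-cohort correlation meta-analysis
#'
#' For one exposure — a food-group intake or the hPDI — computes within
#' every cohort the partial Spearman correlation (adjusted for sex, age and
#' BMI) between each feature's arcsine-square-root transformed relative
#' abundance and the exposure, over the eligible consumer population only
#' (meat: omnivores; dairy: omnivores and vegetarians; fruits/vegetables:
#' all diets; hPDI: within the diet pattern given by `hpdi_within`). The
#' per-cohort correlations are pooled by Fisher-Z random-effects
#' meta-analysis ([fisher_pool()]) and q-values are BH-adjusted across
#' features.
#'
#' @param table an [abundance_table()].
#' @param metadata a [sample_metadata()].
#' @param exposure food-group name, or `"hpdi"`.
#' @param ffq an [ffq_table()] (food-group exposures).
#' @param hpdi_scores output of [compute_hpdi()] (hPDI exposure).
#' @param hpdi_within diet pattern the hPDI correlations are computed in.
#' @param eligible_diets override of the consumer-population rule.
#' @param covariates metadata columns to adjust for.
#' @param min_n smallest per-cohort eligible population used.
#' @param q_threshold significance threshold.
#' @param fisher_df passed to [fisher_pool()] (`"partial"` or `"classic"`).
#' @return list of class `meta_correlation_result` with `meta` (per feature:
#'   pooled rho, CI, p, q, tau2, i2, k) and `cohort` (per-cohort rho and n).
#' @export
run_correlation_meta <- function(table, metadata, exposure, ffq = NULL,
                                 hpdi_scores = NULL, hpdi_within = "omnivore",
                                 eligible_diets = NULL,
                                 covariates = c("sex", "age", "bmi"),
                                 min_n = 10L, q_threshold = 0.1,
                                 fisher_df = "partial") {
  al <- align_samples(table, metadata)
  table <- al$table; metadata <- al$metadata
  if (identical(exposure, "hpdi")) {
    if (is.null(hpdi_scores)) stop("hpdi exposure needs hpdi_scores")
    expo <- hpdi_scores$hpdi[match(metadata$sample_id, hpdi_scores$sample_id)]
    eligible <- hpdi_within
  } else {
    if (is.null(ffq)) stop("food-group exposure needs an ffq table")
    gi <- food_group_intake(ffq, exposure)
    expo <- unname(gi[match(metadata$sample_id, names(gi))])
    eligible <- if (is.null(eligible_diets)) consumer_diets(exposure)
                else eligible_diets
  }
  keep <- metadata$diet %in% eligible & !is.na(expo)
  if (!any(keep)) stop("eligible consumer population is empty")
  table <- table[keep, , drop = FALSE]
  metadata <- metadata[keep, , drop = FALSE]
  expo <- expo[keep]
  y_all <- arcsin_sqrt(unclass(table))
  k_cov <- length(covariates)

  cohort_rows <- list()
  for (co in unique(metadata$cohort)) {
    idx <- which(metadata$cohort == co)
    covs <- metadata[idx, covariates, drop = FALSE]
    cc <- stats::complete.cases(covs)
    idx <- idx[cc]; covs <- covs[cc, , drop = FALSE]
    if (length(idx) < max(min_n, k_cov + 5L)) next
    # batch partial Spearman: rank everything (covariates included),
    # residualize on the shared design once (equals partial_spearman)
    R <- apply(y_all[idx, , drop = FALSE], 2L, rank)
    re <- rank(expo[idx])
    if (k_cov > 0L) {
      for (j in seq_along(covs)) {
        if (is.numeric(covs[[j]])) covs[[j]] <- rank(covs[[j]])
      }
      qr_x <- qr(stats::model.matrix(~ ., data = covs))
      R <- qr.resid(qr_x, R)
      re <- qr.resid(qr_x, re)
    } else {
      R <- sweep(R, 2L, colMeans(R)); re <- re - mean(re)
    }
    den <- sqrt(colSums(R^2)) * sqrt(sum(re^2))
    rho <- ifelse(den > 0, colSums(R * re) / den, NA_real_)
    keep_f <- !is.na(rho) & abs(rho) < 1
    if (!any(keep_f)) next
    cohort_rows[[co]] <- data.frame(
      cohort = co, feature_id = colnames(table)[keep_f], exposure = exposure,
      rho_partial = unname(rho[keep_f]), n_effective = length(idx),
      stringsAsFactors = FALSE)
  }
  if (length(cohort_rows) == 0L) stop("no cohort has a usable population")
  cohort_df <- do.call(rbind, cohort_rows)
  rownames(cohort_df) <- NULL

  meta <- lapply(split(cohort_df, cohort_df$feature_id), function(sub) {
    fp <- fisher_pool(sub$rho_partial, sub$n_effective, k_cov, df = fisher_df)
    data.frame(feature_id = sub$feature_id[1L], exposure = exposure,
               pooled_rho = fp$pooled_rho, ci_low = fp$ci_low,
               ci_high = fp$ci_high, p = fp$p, tau2 = fp$tau2, i2 = fp$i2,
               k = fp$k, stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, meta)
  meta$q <- bh_adjust(meta$p)
  meta$significant <- meta$q < q_threshold
  rownames(meta) <- NULL
  structure(list(meta = meta, cohort = cohort_df, exposure = exposure,
                 eligible_diets = eligible),
            class = "meta_correlation_result")
}

#' @export
print.meta_correlation_result <- function(x, ...) {
  cat(sprintf("<meta_correlation_result> exposure %s (%s): %d features, %d significant\n",
              x$exposure, paste(x$eligible_diets, collapse = "+"),
              nrow(x$meta), sum(x$meta$significant)))
  invisible(x)
}
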