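#' Arcsine-square-root transform of percent relative abundances
#'
#' The variance-stabilizing transform for proportions: `asin(sqrt(x/100))`,
#' mapping the percent scale \[0, 100\] onto \[0, pi/2\]. All standardized
#' mean differences and correlations in the differential-abundance machinery
#' operate on this scale.
#'
#' @param abundance_percent numeric vector or matrix on the percent scale.
#' @return transformed values in \[0, pi/2\].
#' @examples
#' arcsin_sqrt(c(0, 25, 100))  # 0, pi/6, pi/2
#' @export
arcsin_sqrt <- function(abundance_percent) {
  if (any(abundance_percent < 0 | abundance_percent > 100, na.rm = TRUE)) {
    stop("abundance must lie in [0, 100] percent")
  }
  asin(sqrt(abundance_percent / 100))
}

#' Covariate-adjusted Cohen's d
#'
#' Fits an ordinary least-squares model of the (transformed) abundance on a
#' two-level group indicator plus covariates, and standardizes the group
#' coefficient by the residual standard deviation. The sign convention is
#' positive when the second factor level (the comparison group) has the
#' larger adjusted mean. The sampling variance uses the standard
#' approximation `(n1+n2)/(n1*n2) + d^2/(2*(n1+n2))` and the Wald p-value
#' comes from the coefficient's t statistic on the residual degrees of
#' freedom.
#'
#' @param y numeric response (typically [arcsin_sqrt()] abundances).
#' @param group factor with exactly two levels (reference first).
#' @param covariates optional data frame of adjustment covariates
#'   (e.g. sex, age, bmi). Rows with missing values are dropped listwise.
#' @param min_group_size smallest group size accepted (default 3).
#' @return list with `d`, `var_d`, `se_d`, `wald_p`, `n_ref`, `n_cmp`.
#' @export
adjusted_cohens_d <- function(y, group, covariates = NULL, min_group_size = 3L) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  dat <- data.frame(.y = y, .g = group)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    dat <- cbind(dat, as.data.frame(covariates))
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n1 <- sum(dat$.g == levels(group)[1L])
  n2 <- sum(dat$.g == levels(group)[2L])
  if (min(n1, n2) < min_group_size) {
    stop(sprintf("group below minimum size (%d vs %d, need >= %d)",
                 n1, n2, min_group_size))
  }
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) stop("rank-deficient model matrix")
  beta <- stats::coef(fit)[2L]
  sigma <- sqrt(sum(stats::residuals(fit)^2) / fit$df.residual)
  if (sigma <= 0) stop("zero residual variance; d undefined")
  d <- unname(beta / sigma)
  var_d <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  tstat <- summary(fit)$coefficients[2L, "t value"]
  wald_p <- 2 * stats::pt(-abs(tstat), df = fit$df.residual)
  list(d = d, var_d = var_d, se_d = sqrt(var_d), wald_p = unname(wald_p),
       n_ref = n1, n_cmp = n2)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment-based random-effects meta-analysis. Given per-cohort effects `y`
#' with sampling variances `v`, computes the fixed-effect weights
#' `w = 1/v`, Cochran's Q, the between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, the
#' random-effects weights `1/(v + tau2)`, the pooled estimate, its standard
#' error, a Wald z and two-sided normal p, the 95 percent CI and
#' `I2 = max(0, (Q-(k-1))/Q) * 100`. A single study degenerates to the study
#' itself with `tau2 = 0` and `I2` reported as 0.
#'
#' @param y numeric vector of per-cohort effect estimates.
#' @param v numeric vector of their sampling variances (all > 0).
#' @param conf_level confidence level for the normal-approximation CI.
#' @return list with `pooled`, `se`, `ci_low`, `ci_high`, `z`, `p`, `tau2`,
#'   `i2`, `q_het`, `k`.
#' @export
dersimonian_laird <- function(y, v, conf_level = 0.95) {
  if (length(y) != length(v)) stop("y and v lengths differ")
  if (length(y) < 1L) stop("at least one study required")
  if (any(!is.finite(y)) || any(!is.finite(v))) stop("non-finite input")
  if (any(v <= 0)) stop("all variances must be positive")
  k <- length(y)
  w <- 1 / v
  y_fe <- sum(w * y) / sum(w)
  q <- sum(w * (y - y_fe)^2)
  if (k == 1L) {
    tau2 <- 0
    i2 <- 0
  } else {
    denom <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - (k - 1)) / denom)
    i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  }
  ws <- 1 / (v + tau2)
  pooled <- sum(ws * y) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  z <- pooled / se
  p <- 2 * stats::pnorm(-abs(z))
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(pooled = pooled, se = se,
       ci_low = pooled - zcrit * se, ci_high = pooled + zcrit * se,
       z = z, p = p, tau2 = tau2, i2 = i2, q_het = q, k = k)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q-values via [stats::p.adjust()], with input validation.
#' Adjustment families follow the analysis design: per-cohort Wald p-values
#' and meta-analysis p-values are adjusted separately.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Batch version of adjusted_cohens_d over all features of one cohort:
# one QR decomposition of the shared design matrix, identical results to
# the per-feature OLS path (asserted in the test suite).
batch_adjusted_d <- function(Y, group, covariates = NULL, min_group_size = 3L) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  df <- data.frame(.g = group)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    df <- cbind(df, as.data.frame(covariates))
  }
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]; Y <- Y[cc, , drop = FALSE]
  n1 <- sum(df$.g == levels(group)[1L]); n2 <- sum(df$.g == levels(group)[2L])
  if (min(n1, n2) < min_group_size) return(NULL)
  X <- stats::model.matrix(~ ., data = df)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient model matrix")
  p <- ncol(X); n <- nrow(X); dfres <- n - p
  beta <- qr.coef(qr_x, Y)[2L, ]
  res <- qr.resid(qr_x, Y)
  sigma2 <- colSums(res^2) / dfres
  xtx_inv_gg <- chol2inv(qr.R(qr_x))[2L, 2L]
  ok <- sigma2 > 0
  d <- beta / sqrt(sigma2)
  var_d <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  tstat <- beta / sqrt(sigma2 * xtx_inv_gg)
  data.frame(feature_id = colnames(Y), d = d, var_d = var_d,
             n_ref = n1, n_cmp = n2,
             wald_p = 2 * stats::pt(-abs(tstat), df = dfres),
             ok = ok, stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-cohort differential-abundance meta-analysis
#'
#' The pipeline's core: for one diet pair, fits within every cohort an OLS
#' model of the arcsine-square-root transformed relative abundance of each
#' feature on the diet indicator adjusted for sex, age and BMI, converts the
#' coefficient to an adjusted Cohen's d ([adjusted_cohens_d()]), pools the
#' per-cohort d values by DerSimonian-Laird random-effects meta-analysis
#' ([dersimonian_laird()]) and adjusts the pooled Wald p-values across
#' features by Benjamini-Hochberg. Per-cohort Wald p-values are BH-adjusted
#' within each cohort as a separate family. Features whose two diet groups
#' are below the minimum size or degenerate (zero residual variance) in a
#' cohort are skipped for that cohort; `k` records how many cohorts
#' contributed to each pooled estimate.
#'
#' @param table an [abundance_table()] (percent scale).
#' @param metadata a [sample_metadata()] frame covering the table's samples.
#' @param diet_pair character vector `c(reference, comparison)`; positive
#'   pooled d means enrichment in the comparison diet.
#' @param covariates character vector of metadata columns to adjust for.
#' @param min_group_size per-cohort minimum diet-group size.
#' @param q_threshold significance threshold on the meta-analysis q-value.
#' @param transform set `FALSE` if `table` is already on the analysis scale.
#' @return list of class `meta_diffabund_result` with elements `meta` (one
#'   row per feature: pooled_d, se, ci, z, p, q, tau2, i2, q_het, k,
#'   significant, rank by absolute pooled d), `cohort` (per-cohort effects
#'   with per-cohort q) and `diet_pair`.
#' @export
run_diffabund_meta <- function(table, metadata,
                               diet_pair = c("omnivore", "vegan"),
                               covariates = c("sex", "age", "bmi"),
                               min_group_size = 3L, q_threshold = 0.1,
                               transform = TRUE) {
  stopifnot(length(diet_pair) == 2L)
  al <- align_samples(table, metadata)
  table <- al$table; metadata <- al$metadata
  keep <- metadata$diet %in% diet_pair
  table <- table[keep, , drop = FALSE]
  metadata <- metadata[keep, , drop = FALSE]
  y_all <- if (transform) arcsin_sqrt(unclass(table)) else unclass(table)
  grp <- factor(as.character(metadata$diet), levels = diet_pair)

  cohorts <- unique(metadata$cohort)
  cohort_rows <- list()
  effects <- list()  # feature -> list of (cohort, d, var)
  for (co in cohorts) {
    idx <- metadata$cohort == co
    if (length(unique(grp[idx])) < 2L) next
    covs <- metadata[idx, covariates, drop = FALSE]
    rows <- tryCatch(
      batch_adjusted_d(y_all[idx, , drop = FALSE], grp[idx], covs,
                       min_group_size),
      error = function(e) NULL)
    if (is.null(rows)) next
    rows <- rows[rows$ok & is.finite(rows$d), setdiff(names(rows), "ok")]
    if (nrow(rows) == 0L) next
    rows <- cbind(cohort = co, rows)
    rows$q <- bh_adjust(rows$wald_p)  # per-cohort family
    cohort_rows[[co]] <- rows
  }
  if (length(cohort_rows) == 0L) {
    stop("no cohort contains both diet groups at the minimum size")
  }
  cohort_df <- do.call(rbind, cohort_rows)
  rownames(cohort_df) <- NULL

  meta <- lapply(split(cohort_df, cohort_df$feature_id), function(sub) {
    dl <- dersimonian_laird(sub$d, sub$var_d)
    data.frame(feature_id = sub$feature_id[1L], pooled_d = dl$pooled,
               se = dl$se, ci_low = dl$ci_low, ci_high = dl$ci_high,
               z = dl$z, wald_p = dl$p, tau2 = dl$tau2, i2 = dl$i2,
               q_het = dl$q_het, k = dl$k, stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, meta)
  meta$q <- bh_adjust(meta$wald_p)  # meta-analysis family
  meta$significant <- meta$q < q_threshold
  meta <- meta[order(-abs(meta$pooled_d)), , drop = FALSE]
  meta$rank_abs_d <- seq_len(nrow(meta))
  rownames(meta) <- NULL
  structure(list(meta = meta, cohort = cohort_df, diet_pair = diet_pair,
                 q_threshold = q_threshold),
            class = "meta_diffabund_result")
}

#' @export
print.meta_diffabund_result <- function(x, ...) {
  cat(sprintf("<meta_diffabund_result> %s vs %s: %d features, %d significant (q < %g)\n",
              x$diet_pair[1L], x$diet_pair[2L], nrow(x$meta),
              sum(x$meta$significant), x$q_threshold))
  invisible(x)
}

#' Filter a pathway-abundance table by prevalence
#'
#' Mirrors the functional-potential screen applied before the SMD
#' meta-analysis of pathway abundances: a pathway is kept when its
#' prevalence (fraction of samples with nonzero abundance) reaches
#' `min_prevalence` within every diet pattern, after removing unmapped /
#' unintegrated rows.
#'
#' @param table an [abundance_table()] of pathway abundances.
#' @param metadata a [sample_metadata()] frame.
#' @param min_prevalence minimum within-diet prevalence (default 0.05).
#' @param drop_patterns regular expression of feature ids to discard first.
#' @return the filtered [abundance_table()].
#' @export
filter_pathway_table <- function(table, metadata, min_prevalence = 0.05,
                                 drop_patterns = "(?i)^(UNMAPPED|UNINTEGRATED)") {
  al <- align_samples(table, metadata)
  table <- al$table; metadata <- al$metadata
  keep_feat <- !grepl(drop_patterns, colnames(table), perl = TRUE)
  table <- table[, keep_feat, drop = FALSE]
  prev_ok <- rep(TRUE, ncol(table))
  for (dt in levels(droplevels(metadata$diet))) {
    idx <- metadata$diet == dt
    prev <- colMeans(table[idx, , drop = FALSE] > 0)
    prev_ok <- prev_ok & prev >= min_prevalence
  }
  abundance_table(table[, prev_ok, drop = FALSE])
}
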