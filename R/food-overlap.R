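#' Call food SGBs from a food-metagenome catalog
#'
#' A feature is a food SGB when it was detected at a relative abundance at
#' or above `abundance_threshold` (percent) in at least `min_samples` food
#' samples — the catalog's `n_food_samples_detected` column already counts
#' detections at that threshold. A called food SGB is additionally labelled
#' a signature of a food category (meat, dairy, fruits/vegetables) when its
#' prevalence across that category's food samples is strictly greater than
#' `signature_prevalence` (a fraction; the default 0.001 encodes the
#' ">0.1%" rule). Raising either calling threshold can only shrink the
#' called set.
#'
#' @param catalog a food catalog data frame (e.g.
#'   [simulate_food_catalog()]): `feature_id`, `n_food_samples_detected`
#'   and one `prev_<category>` column per food category with prevalences in
#'   \[0, 1\].
#' @param abundance_threshold detection threshold in percent (documentation
#'   of the catalog's detection rule; the catalog counts are assumed to be
#'   computed at this threshold).
#' @param min_samples minimum number of detected food samples (inclusive).
#' @param signature_prevalence strict lower bound on category prevalence.
#' @return data frame of class `food_sgb_catalog`: `feature_id`,
#'   `is_food_sgb`, and logical `signature_<category>` columns (TRUE only
#'   for called food SGBs).
#' @export
call_food_sgbs <- function(catalog, abundance_threshold = 0.1,
                           min_samples = 4L, signature_prevalence = 0.001) {
  prev_cols <- grep("^prev_", names(catalog), value = TRUE)
  if (!"n_food_samples_detected" %in% names(catalog) || !length(prev_cols)) {
    stop("catalog needs n_food_samples_detected and prev_<category> columns")
  }
  prev <- as.matrix(catalog[prev_cols])
  if (any(prev < 0 | prev > 1, na.rm = TRUE)) {
    stop("category prevalences must lie in [0, 1]")
  }
  is_food <- catalog$n_food_samples_detected >= min_samples
  sig <- prev > signature_prevalence & is_food  # signatures only on called SGBs
  colnames(sig) <- sub("^prev_", "signature_", prev_cols)
  out <- data.frame(feature_id = catalog$feature_id, is_food_sgb = is_food,
                    sig, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "abundance_threshold") <- abundance_threshold
  class(out) <- c("food_sgb_catalog", "data.frame")
  out
}

#' Per-sample food-SGB count and cumulative abundance
#'
#' For each sample, the number of distinct food SGBs present (abundance
#' strictly positive) and their cumulative relative abundance (percent).
#' When `by_category = TRUE` the statistics are additionally computed per
#' signature category, one row per sample x category.
#'
#' @param table an [abundance_table()].
#' @param metadata a [sample_metadata()].
#' @param food_catalog a [call_food_sgbs()] result.
#' @param by_category also stratify by signature category.
#' @return data frame with `sample_id`, `cohort`, `diet`, `category`
#'   (`"all"` or the signature category), `n_food_sgbs`,
#'   `cumulative_abundance`.
#' @export
per_sample_food_stats <- function(table, metadata, food_catalog,
                                  by_category = FALSE) {
  al <- align_samples(table, metadata)
  table <- al$table; metadata <- al$metadata
  food_ids <- food_catalog$feature_id[food_catalog$is_food_sgb]
  if (length(food_ids) == 0L) stop("food catalog calls no food SGBs")
  sets <- list(all = intersect(food_ids, colnames(table)))
  if (by_category) {
    for (sc in grep("^signature_", names(food_catalog), value = TRUE)) {
      ids <- food_catalog$feature_id[food_catalog[[sc]]]
      sets[[sub("^signature_", "", sc)]] <- intersect(ids, colnames(table))
    }
  }
  out <- lapply(names(sets), function(cat) {
    ids <- sets[[cat]]
    sub <- table[, ids, drop = FALSE]
    data.frame(sample_id = rownames(table), cohort = metadata$cohort,
               diet = as.character(metadata$diet), category = cat,
               n_food_sgbs = as.integer(rowSums(sub > 0)),
               cumulative_abundance = rowSums(sub),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Monte-Carlo chi-squared test of prevalence across diets
#'
#' Pearson chi-squared statistic on a diets x present/absent contingency
#' table, with the p-value computed by Monte-Carlo simulation under fixed
#' margins: `p = (1 + #{replicate chi2 >= observed}) / (n_mc + 1)` (via
#' [stats::chisq.test()] with `simulate.p.value = TRUE`).
#'
#' @param counts matrix of nonnegative integers, diets in rows, columns
#'   present/absent.
#' @param n_mc number of Monte-Carlo replicates (default 99,999).
#' @param seed RNG seed for the replicate draws.
#' @return list with `chisq`, `p`, `n_mc`.
#' @export
prevalence_chisq <- function(counts, n_mc = 99999L, seed = 1L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero margin in the contingency table")
  }
  res <- with_seed(seed, {
    stats::chisq.test(counts, simulate.p.value = TRUE, B = n_mc)
  })
  list(chisq = unname(res$statistic), p = res$p.value, n_mc = n_mc)
}

#' Compare health-rank distributions of two signature sets
#'
#' Equal-variance two-sample t-test on the health ranks of two feature
#' sets (e.g. the significant signatures of two diet patterns), preceded by
#' a Levene check of the equal-variance assumption (via
#' [car::leveneTest()]). Features without a rank are dropped with a
#' message. Ranks live in \[0, 1\], values near 0 marking favourable
#' cardiometabolic associations.
#'
#' @param features_a,features_b feature-id vectors of the two sets.
#' @param ranks data frame with columns `feature_id` and `rank`.
#' @return list with `mean_a`, `mean_b`, `n_a`, `n_b`, `levene_p`, `t`,
#'   `df`, `p`.
#' @export
compare_health_ranks <- function(features_a, features_b, ranks) {
  if (any(ranks$rank < 0 | ranks$rank > 1, na.rm = TRUE)) {
    stop("health ranks must lie in [0, 1]")
  }
  ra <- ranks$rank[match(features_a, ranks$feature_id)]
  rb <- ranks$rank[match(features_b, ranks$feature_id)]
  dropped <- sum(is.na(ra)) + sum(is.na(rb))
  if (dropped > 0L) message(sprintf("%d unranked feature(s) dropped", dropped))
  ra <- ra[!is.na(ra)]; rb <- rb[!is.na(rb)]
  if (length(ra) < 2L || length(rb) < 2L) {
    stop("both sets need at least two ranked features")
  }
  vals <- c(ra, rb)
  grp <- factor(rep(c("a", "b"), c(length(ra), length(rb))))
  lev <- car::leveneTest(vals ~ grp)
  tt <- stats::t.test(ra, rb, var.equal = TRUE)
  list(mean_a = mean(ra), mean_b = mean(rb),
       n_a = length(ra), n_b = length(rb),
       levene_p = lev$`Pr(>F)`[1L],
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Dunn contrasts of food statistics across diets
#'
#' Runs [kruskal_dunn()] on a per-sample food statistic (count or
#' cumulative abundance) between diet patterns, within each cohort and
#' signature-category stratum. Strata with fewer than two diet groups are
#' skipped with a warning.
#'
#' @param stats_df output of [per_sample_food_stats()].
#' @param value_col `"n_food_sgbs"` or `"cumulative_abundance"`.
#' @return data frame of pairwise contrasts: cohort, category, group pair,
#'   Dunn z, p and BH q (adjusted within each stratum's family).
#' @export
dunn_contrasts_food <- function(stats_df, value_col = c("n_food_sgbs",
                                                        "cumulative_abundance")) {
  value_col <- match.arg(value_col)
  out <- list()
  for (co in unique(stats_df$cohort)) {
    for (cat in unique(stats_df$category)) {
      sub <- stats_df[stats_df$cohort == co & stats_df$category == cat, ]
      if (length(unique(sub$diet[table(sub$diet)[sub$diet] >= 2])) < 2L) {
        warning(sprintf("stratum %s/%s has fewer than two diet groups; skipped",
                        co, cat))
        next
      }
      kd <- tryCatch(kruskal_dunn(sub[[value_col]], sub$diet),
                     error = function(e) NULL)
      if (is.null(kd)) next
      res <- kd$pairs
      res$cohort <- co; res$category <- cat
      res$kw_p <- kd$p
      out[[length(out) + 1L]] <- res
    }
  }
  if (length(out) == 0L) stop("no stratum was testable")
  out <- do.call(rbind, out)
  out[, c("cohort", "category", "group1", "group2", "z", "p", "q", "kw_p")]
}
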