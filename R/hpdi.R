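#' Quintile score of a single food-group intake
#'
#' The hPDI component score. Intakes are binned by the four quintile
#' cutpoints of the scored population's group-intake distribution. With
#' `direction = "positive"` an intake above the largest cutpoint scores 5
#' and one at or below the smallest scores 1, interior bins scoring 2 to 4
#' in order; with `direction = "reverse"` the mapping is flipped so the
#' smallest bin scores 5. Ties at a boundary fall into the lower bin.
#'
#' @param intake numeric vector of intakes.
#' @param boundaries four nondecreasing quintile cutpoints.
#' @param direction `"positive"` or `"reverse"`.
#' @return integer scores in 1..5.
#' @examples
#' quintile_score(c(0.1, 10), boundaries = c(1, 2, 3, 4), "positive") # 1, 5
#' @export
quintile_score <- function(intake, boundaries, direction = c("positive", "reverse")) {
  direction <- match.arg(direction)
  if (length(boundaries) != 4L) stop("exactly four quintile cutpoints required")
  if (is.unsorted(boundaries)) stop("quintile cutpoints must be nondecreasing")
  bin <- 1L + rowSums(outer(intake, boundaries, `>`))
  if (direction == "reverse") bin <- 6L - bin
  as.integer(bin)
}

#' Healthful plant-based diet index
#'
#' Sums quintile component scores over the 18 hPDI food groups: healthy
#' plant groups are scored positively (higher intake, higher score) and
#' less healthy plant / animal groups reverse. Group intakes are the sums
#' of mapped item intakes; quintile boundaries are computed from the scored
#' population's own group-intake distribution, by default within each
#' cohort separately.
#'
#' @param ffq an [ffq_table()] whose group map flags the 18 hPDI groups via
#'   `hpdi_direction`.
#' @param metadata optional [sample_metadata()]; required when
#'   `stratify_by_cohort = TRUE`.
#' @param stratify_by_cohort compute quintile boundaries per cohort
#'   (default) or pooled.
#' @param n_groups_required number of hPDI groups expected (default 18;
#'   lower it explicitly to score a reduced-group variant).
#' @return data frame with `sample_id`, `hpdi` (in
#'   \[`n_groups`, `5 * n_groups`\]) and one `score_<group>` column per group.
#' @export
compute_hpdi <- function(ffq, metadata = NULL, stratify_by_cohort = TRUE,
                         n_groups_required = 18L) {
  gm <- ffq$group_map[!is.na(ffq$group_map$hpdi_direction), , drop = FALSE]
  hgroups <- unique(gm[, c("group", "hpdi_direction")])
  if (nrow(hgroups) < n_groups_required) {
    stop(sprintf("only %d hPDI groups mapped; %d required (set n_groups_required to override)",
                 nrow(hgroups), n_groups_required))
  }
  samples <- rownames(ffq$intakes)
  # per-sample group intakes
  gint <- vapply(hgroups$group, function(g) {
    items <- gm$item[gm$group == g]
    rowSums(ffq$intakes[, items, drop = FALSE])
  }, numeric(length(samples)))
  if (stratify_by_cohort) {
    if (is.null(metadata)) stop("metadata required for per-cohort quintiles")
    stratum <- metadata$cohort[match(samples, metadata$sample_id)]
    if (anyNA(stratum)) stop("every FFQ sample needs a cohort in metadata")
  } else {
    stratum <- rep("all", length(samples))
  }
  scores <- matrix(NA_integer_, length(samples), nrow(hgroups),
                   dimnames = list(samples, paste0("score_", hgroups$group)))
  for (s in unique(stratum)) {
    idx <- stratum == s
    for (j in seq_len(nrow(hgroups))) {
      bnd <- unname(stats::quantile(gint[idx, j], c(0.2, 0.4, 0.6, 0.8),
                                    type = 7))
      scores[idx, j] <- quintile_score(gint[idx, j], bnd,
                                       hgroups$hpdi_direction[j])
    }
  }
  data.frame(sample_id = samples, hpdi = as.integer(rowSums(scores)),
             scores, stringsAsFactors = FALSE, row.names = NULL)
}
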