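#' @keywords internal
"_PACKAGE"

DIET_LEVELS <- c("omnivore", "vegetarian", "vegan")

#' Construct a validated abundance table
#'
#' An `abundance_table` holds species-level (SGB) or pathway relative
#' abundances on the percent scale, samples in rows and features in columns.
#' Per-sample totals may be below 100 when an unclassified fraction was
#' dropped upstream, but never above.
#'
#' @param values numeric matrix, samples x features, percent scale.
#' @param sample_ids,feature_ids unique identifiers; defaults taken from
#'   `dimnames(values)`.
#' @return an object of class `abundance_table` (a numeric matrix with
#'   validated dimnames).
#' @examples
#' m <- matrix(c(60, 40, 25, 75), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2")))
#' abundance_table(m)
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            feature_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids) || is.null(feature_ids)) {
    stop("abundance_table requires sample and feature identifiers")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  if (length(values) == 0L) stop("empty abundance table")
  if (!is.numeric(values)) stop("abundances must be numeric")
  if (anyNA(values)) stop("abundances must not contain NA")
  if (any(values < 0)) stop("negative abundance encountered")
  if (any(rowSums(values) > 100 + 1e-6)) {
    stop("per-sample abundance sums exceed 100")
  }
  dimnames(values) <- list(as.character(sample_ids), as.character(feature_ids))
  class(values) <- c("abundance_table", class(values))
  values
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d features (percent scale)\n",
              nrow(x), ncol(x)))
  cat(sprintf("  per-sample totals: %.4g-%.4g\n",
              min(rowSums(x)), max(rowSums(x))))
  invisible(x)
}

#' Construct validated sample metadata
#'
#' Per-sample covariates used by every adjusted model: cohort, diet pattern
#' (one of omnivore/vegetarian/vegan), sex, age in years, BMI in kg/m2.
#' Diet labels are matched case-insensitively against the closed three-level
#' set; unknown labels are rejected.
#'
#' @param df data frame with columns `sample_id`, `cohort`, `diet`, `sex`,
#'   `age`, `bmi`.
#' @return a validated data frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "cohort", "diet", "sex", "age", "bmi")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("metadata missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[req]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  diet <- tolower(trimws(as.character(df$diet)))
  bad <- !is.na(diet) & !(diet %in% DIET_LEVELS)
  if (any(bad)) {
    stop("unknown diet label(s): ",
         paste(unique(df$diet[bad]), collapse = ", "))
  }
  df$diet <- factor(diet, levels = DIET_LEVELS)
  df$cohort <- as.character(df$cohort)
  df$sex <- factor(as.character(df$sex))
  if (nlevels(df$sex) > 2L) stop("sex must be a binary categorical")
  df$age <- as.numeric(df$age)
  df$bmi <- as.numeric(df$bmi)
  if (any(df$age <= 0, na.rm = TRUE)) stop("age must be positive")
  if (any(df$bmi <= 0, na.rm = TRUE)) stop("bmi must be positive")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Construct a validated FFQ table
#'
#' Food-frequency questionnaire intakes (samples x items, nonnegative
#' habitual intakes) together with the item-to-food-group mapping. Groups
#' flagged as hPDI groups carry a scoring direction, `positive` for healthy
#' plant foods and `reverse` for less healthy plant and animal foods.
#'
#' @param intakes numeric matrix, samples x items, nonnegative.
#' @param group_map data frame with columns `item`, `group` and
#'   `hpdi_direction` (one of "positive", "reverse", or NA for groups that
#'   do not enter the hPDI).
#' @return an object of class `ffq_table`: a list with elements `intakes`
#'   and `group_map`.
#' @export
ffq_table <- function(intakes, group_map) {
  intakes <- as.matrix(intakes)
  if (is.null(rownames(intakes)) || is.null(colnames(intakes))) {
    stop("ffq intakes need sample and item identifiers")
  }
  if (anyDuplicated(rownames(intakes))) stop("duplicate sample ids in FFQ")
  if (anyDuplicated(colnames(intakes))) stop("duplicate item ids in FFQ")
  if (any(intakes < 0, na.rm = TRUE)) stop("negative intake encountered")
  req <- c("item", "group")
  if (!all(req %in% names(group_map))) {
    stop("group map needs columns 'item' and 'group'")
  }
  group_map <- as.data.frame(group_map)
  if (!"hpdi_direction" %in% names(group_map)) group_map$hpdi_direction <- NA
  group_map$item <- as.character(group_map$item)
  group_map$group <- as.character(group_map$group)
  dir <- as.character(group_map$hpdi_direction)
  ok <- is.na(dir) | dir %in% c("positive", "reverse")
  if (!all(ok)) stop("hpdi_direction must be 'positive', 'reverse' or NA")
  unknown <- setdiff(group_map$item, colnames(intakes))
  if (length(unknown)) {
    stop("group map item(s) absent from intake table: ",
         paste(unknown, collapse = ", "))
  }
  # one direction per hPDI group
  hg <- unique(group_map[!is.na(group_map$hpdi_direction),
                         c("group", "hpdi_direction")])
  if (anyDuplicated(hg$group)) {
    stop("an hPDI group is flagged with more than one direction")
  }
  unmapped <- setdiff(colnames(intakes), group_map$item)
  if (length(unmapped)) {
    warning(sprintf("%d FFQ item(s) not in group map; kept as raw features, excluded from group sums: %s",
                    length(unmapped), paste(unmapped, collapse = ", ")))
  }
  out <- list(intakes = intakes, group_map = group_map)
  class(out) <- "ffq_table"
  out
}

#' @export
print.ffq_table <- function(x, ...) {
  cat(sprintf("<ffq_table> %d samples x %d items, %d groups (%d hPDI)\n",
              nrow(x$intakes), ncol(x$intakes),
              length(unique(x$group_map$group)),
              length(unique(x$group_map$group[!is.na(x$group_map$hpdi_direction)]))))
  invisible(x)
}

# Align an abundance table with metadata: drop (with a warning) samples
# lacking metadata, and metadata rows without abundances.
align_samples <- function(table, metadata) {
  common <- intersect(rownames(table), metadata$sample_id)
  orphans <- setdiff(rownames(table), common)
  if (length(orphans)) {
    warning(sprintf("dropping %d sample(s) absent from metadata", length(orphans)))
  }
  metadata <- metadata[match(common, metadata$sample_id), , drop = FALSE]
  list(table = table[common, , drop = FALSE], metadata = metadata)
}
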