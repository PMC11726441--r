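#' Read a relative-abundance table
#'
#' Two dialects are supported. `plain_tsv` expects a samples-in-columns
#' matrix with feature ids in the first column. `metaphlan_merged` expects
#' the merged-profile layout written by MetaPhlAn: '#'-prefixed comment
#' lines, a first column of '|'-delimited clade lineages and one column per
#' sample, values on the percent scale. In the merged dialect only the rows
#' at the deepest taxonomic rank present in the file (usually the
#' species/SGB level) are retained, and the feature id is the terminal
#' lineage segment.
#'
#' @param path path to the TSV file.
#' @param dialect `"metaphlan_merged"` or `"plain_tsv"`.
#' @return an [abundance_table()] (samples x features, percent scale).
#' @export
read_abundance_table <- function(path, dialect = c("metaphlan_merged", "plain_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty abundance table: ", path)
  clade <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  if (dialect == "metaphlan_merged") {
    depth <- lengths(strsplit(clade, "|", fixed = TRUE))
    keep <- depth == max(depth)
    clade <- vapply(strsplit(clade[keep], "|", fixed = TRUE),
                    function(p) p[length(p)], character(1))
    vals <- vals[keep, , drop = FALSE]
  }
  if (anyDuplicated(clade)) stop("duplicate feature ids in ", path)
  if (anyDuplicated(colnames(vals))) stop("duplicate sample ids in ", path)
  rownames(vals) <- clade
  abundance_table(t(vals))
}

#' Write an abundance table
#'
#' @param table an [abundance_table()].
#' @param path output path; written as a plain TSV with features in rows and
#'   samples in columns (the `plain_tsv` dialect of [read_abundance_table()]).
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(feature_id = colnames(table), t(unclass(table)),
                   check.names = FALSE)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a TSV with columns `sample_id`, `cohort`, `diet`, `sex`, `age`,
#' `bmi`. Diet labels are normalized case-insensitively to
#' omnivore/vegetarian/vegan; anything else is an error.
#'
#' @param path path to the metadata TSV.
#' @return a [sample_metadata()] data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  sample_metadata(df)
}

#' Write per-sample metadata
#' @param metadata a [sample_metadata()] frame.
#' @param path output TSV path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(as.data.frame(metadata), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an FFQ intake table and its food-group map
#'
#' @param path intake table (TSV/CSV, first column sample ids, remaining
#'   columns item intakes). Delimiter inferred from the extension
#'   (.csv = comma, otherwise tab).
#' @param group_map_path TSV with columns `item`, `group`, `hpdi_direction`.
#' @return an [ffq_table()].
#' @export
read_ffq <- function(path, group_map_path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(group_map_path)) stop("file not found: ", group_map_path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  intakes <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(intakes) <- "double"
  rownames(intakes) <- as.character(df[[1L]])
  gm <- utils::read.delim(group_map_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if ("hpdi_direction" %in% names(gm)) {
    gm$hpdi_direction[gm$hpdi_direction %in% c("", "NA")] <- NA
  }
  # items present in the map but absent from the intake file are dropped
  # from the map with a warning; unmapped intake items warn in ffq_table()
  gone <- setdiff(gm$item, colnames(intakes))
  if (length(gone)) {
    warning(sprintf("%d mapped item(s) absent from intake table, dropped: %s",
                    length(gone), paste(gone, collapse = ", ")))
    gm <- gm[gm$item %in% colnames(intakes), , drop = FALSE]
  }
  ffq_table(intakes, gm)
}

#' Write the FFQ intakes and group map
#' @param ffq an [ffq_table()].
#' @param path intake TSV path.
#' @param group_map_path group-map TSV path.
#' @export
write_ffq <- function(ffq, path, group_map_path) {
  df <- data.frame(sample_id = rownames(ffq$intakes), ffq$intakes,
                   check.names = FALSE)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ffq$group_map, group_map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a result record set
#'
#' Serializes any result data frame (meta-analysis output, validation
#' summaries, per-sample statistics) with a deterministic column order and
#' floats at 10 significant digits, so that a read-back agrees with the
#' in-memory values to 1e-9.
#'
#' @param results a data frame.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  if (format == "tsv") {
    out <- results
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) out[[j]] <- sprintf("%.10g", out[[j]])
    }
    ok <- tryCatch({
      utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write results to ", path)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a result record set written by [write_results()]
#' @param path file path.
#' @param format `"tsv"` or `"json"`.
#' @return a data frame.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
}
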