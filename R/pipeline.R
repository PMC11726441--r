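# End-to-end orchestration: simulate -> hPDI -> diversity -> meta-analyses
# -> ML validation -> food overlap, with a machine-readable run manifest.
# The package functions and this orchestrator are the interface; each stage
# writes plain TSV/JSON artifacts into the output directory.

pipeline_stage_order <- c("simulate", "hpdi", "diversity", "diffabund",
                          "correlation", "ml", "food_overlap")

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order against a simulated
#' multi-cohort dataset, writing every stage's artifacts under `out_dir`
#' and a JSON run manifest (configuration snapshot, seeds, per-file md5
#' digests) that makes deterministic stages reproducible: rerunning with
#' the same config and seed yields identical digests.
#'
#' @param config a [sim_config()]; its `seed` drives the simulation while
#'   `seed` below drives the stochastic analysis stages.
#' @param out_dir output directory (created if needed).
#' @param stages subset of
#'   `c("simulate","hpdi","diversity","diffabund","correlation","ml","food_overlap")`.
#'   `"simulate"` is implied by every other stage.
#' @param diet_pair diet pair for the differential-abundance and ML stages.
#' @param rf an [rf_spec()] for the ML stage.
#' @param permanova_metric distance metric for the PERMANOVA stage.
#' @param seed analysis seed (permutations, forests).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, stages = pipeline_stage_order,
                         diet_pair = c("omnivore", "vegan"),
                         rf = rf_spec("scaled"),
                         permanova_metric = "bray_curtis", seed = 1L) {
  stages <- match.arg(stages, pipeline_stage_order, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }

  sim <- simulate_cohorts(config)
  if ("simulate" %in% stages) {
    emit("abundance.tsv", function(p) write_abundance_table(sim$abundance, p))
    emit("metadata.tsv", function(p) write_metadata(sim$metadata, p))
    emit("ffq.tsv", function(p) write_ffq(sim$ffq, p,
                                          file.path(out_dir, "group_map.tsv")))
    outputs <- c(outputs, file.path(out_dir, "group_map.tsv"))
    emit("truth.json", function(p)
      jsonlite::write_json(sim$truth, p, digits = NA, auto_unbox = TRUE,
                           pretty = TRUE))
  }

  hpdi_scores <- NULL
  if (any(c("hpdi", "correlation") %in% stages)) {
    hpdi_scores <- compute_hpdi(sim$ffq, sim$metadata)
    if ("hpdi" %in% stages) {
      emit("hpdi.tsv", function(p) write_results(hpdi_scores, p))
    }
  }

  if ("diversity" %in% stages) {
    rich <- observed_richness(sim$abundance)
    filt <- richness_outlier_filter(rich)
    keep <- filt$retained
    md <- sim$metadata[match(keep, sim$metadata$sample_id), ]
    kd_rows <- lapply(unique(md$cohort), function(co) {
      idx <- md$cohort == co
      kd <- tryCatch(kruskal_dunn(rich[keep][idx], md$diet[idx]),
                     error = function(e) NULL)
      if (is.null(kd)) return(NULL)
      cbind(cohort = co, kd$pairs, kw_p = kd$p)
    })
    emit("richness_dunn.tsv",
         function(p) write_results(do.call(rbind, kd_rows), p))
    # PERMANOVA per cohort on a manageable subsample per cohort
    pmv <- lapply(unique(md$cohort), function(co) {
      ids <- md$sample_id[md$cohort == co]
      if (length(ids) > 400L) {
        ids <- with_seed(child_seed(seed, 17L), sample(ids, 400L))
      }
      d <- beta_distance(sim$abundance[ids, , drop = FALSE], permanova_metric)
      res <- permanova_sequential(d, sim$metadata, seed = child_seed(seed, 19L))
      cbind(cohort = co, res)
    })
    emit("permanova.tsv", function(p) write_results(do.call(rbind, pmv), p))
  }

  if ("diffabund" %in% stages) {
    da <- run_diffabund_meta(sim$abundance, sim$metadata, diet_pair)
    emit("diffabund_meta.tsv", function(p) write_results(da$meta, p))
    emit("diffabund_cohort.tsv", function(p) write_results(da$cohort, p))
  }

  if ("correlation" %in% stages) {
    cm <- run_correlation_meta(sim$abundance, sim$metadata, "dairy",
                               ffq = sim$ffq)
    emit("correlation_dairy.tsv", function(p) write_results(cm$meta, p))
    ch <- run_correlation_meta(sim$abundance, sim$metadata, "hpdi",
                               hpdi_scores = hpdi_scores)
    emit("correlation_hpdi.tsv", function(p) write_results(ch$meta, p))
  }

  if ("ml" %in% stages) {
    vr <- run_diet_classification(sim$abundance, sim$metadata, diet_pair,
                                  scheme = "cross_lodo", rf = rf, seed = seed)
    emit("ml_per_test.tsv", function(p) write_results(vr$per_test, p))
    emit("ml_roc.tsv", function(p) write_results(vr$roc, p))
    emit("ml_summary.json", function(p)
      jsonlite::write_json(list(scheme = vr$scheme, diet_pair = vr$diet_pair,
                                mean_auc = vr$mean_auc,
                                per_cohort = vr$per_cohort),
                           p, digits = NA, auto_unbox = TRUE, pretty = TRUE))
  }

  if ("food_overlap" %in% stages) {
    catalog <- simulate_food_catalog(config, truth = sim$truth)
    called <- call_food_sgbs(catalog)
    stats_df <- per_sample_food_stats(sim$abundance, sim$metadata, called,
                                      by_category = TRUE)
    emit("food_stats.tsv", function(p) write_results(stats_df, p))
    dn <- dunn_contrasts_food(stats_df, "n_food_sgbs")
    emit("food_dunn.tsv", function(p) write_results(dn, p))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("microdiet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config), seeds = list(simulation = config$seed,
                                           analysis = seed),
    stages = stages,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = basename(p),
                                      md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
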