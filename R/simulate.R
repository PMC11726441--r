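# Multi-cohort synthetic data with planted, calibrated diet effects.
#
# The generator emulates the study design every downstream stage expects:
# a handful of cohorts of unequal size, heavily unbalanced diet labels,
# sparse compositional species profiles closing to 100 percent, sex/age/BMI
# covariates, FFQ intakes coupled to the diet label, and designated
# food-derived features whose presence is coupled to the matching FFQ group.

# run expr with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# fixed seed-splitting rule: adding a cohort never perturbs earlier ones
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults mirror the study conditions: five cohorts of strongly unequal
#' size, diet labels split roughly 92/5/3 percent between omnivores,
#' vegetarians and vegans, several hundred sparse compositional features,
#' and a small set of signature features carrying a planted standardized
#' mean difference between one diet pair on the arcsine-square-root scale.
#'
#' @param n_cohorts number of cohorts.
#' @param n_samples per-cohort sample sizes (recycled to `n_cohorts`).
#' @param diet_props named or positional proportions for
#'   omnivore/vegetarian/vegan; must sum to 1.
#' @param n_features number of compositional features (SGBs).
#' @param n_signature_features how many features carry a planted effect.
#' @param planted_smd target adjusted Cohen's d on the arcsin-sqrt scale for
#'   each signature feature (scalar or vector, sign = direction: positive
#'   means enriched in the comparison diet of `signature_pair`).
#' @param signature_pair the diet pair `c(reference, comparison)` carrying
#'   the planted effects.
#' @param zero_inflation per-feature detection prevalence in (0, 1]; scalar,
#'   vector of length `n_features`, or `NULL` to draw Uniform(0.2, 0.95).
#'   Signature and food features are kept at 0.9 so abundance effects remain
#'   identifiable.
#' @param cohort_shift_sd sd of the per-cohort, per-feature random shift on
#'   the log-abundance scale (between-cohort heterogeneity).
#' @param feature_log_mean_sd spread of baseline feature log-means.
#' @param feature_log_sd within-cohort log-abundance sd.
#' @param age_mean,age_sd,bmi_mean,bmi_sd,sex_prob covariate distributions.
#' @param ffq_coupling log-scale increase of healthy-plant food-group
#'   intakes per step omnivore -> vegetarian -> vegan.
#' @param ffq_presence_coupling logistic slope linking a food feature's
#'   detection odds to the standardized intake of its food group.
#' @param n_food_features number of designated food-derived features
#'   (split across dairy, meat and fruits/vegetables categories).
#' @param seed integer master seed; all randomness derives from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 5,
                       n_samples = c(1062, 12353, 7931, 118, 97),
                       diet_props = c(omnivore = 0.92, vegetarian = 0.05,
                                      vegan = 0.03),
                       n_features = 200,
                       n_signature_features = 10,
                       planted_smd = 0.5,
                       signature_pair = c("omnivore", "vegan"),
                       zero_inflation = NULL,
                       cohort_shift_sd = 0.3,
                       feature_log_mean_sd = 1.5,
                       feature_log_sd = 1.0,
                       age_mean = 45, age_sd = 12,
                       bmi_mean = 25, bmi_sd = 4,
                       sex_prob = 0.5,
                       ffq_coupling = 0.6,
                       ffq_presence_coupling = 2.0,
                       n_food_features = 12,
                       seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              n_samples = as.integer(rep_len(n_samples, n_cohorts)),
              diet_props = diet_props, n_features = as.integer(n_features),
              n_signature_features = as.integer(n_signature_features),
              planted_smd = planted_smd, signature_pair = signature_pair,
              zero_inflation = zero_inflation,
              cohort_shift_sd = cohort_shift_sd,
              feature_log_mean_sd = feature_log_mean_sd,
              feature_log_sd = feature_log_sd,
              age_mean = age_mean, age_sd = age_sd,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd, sex_prob = sex_prob,
              ffq_coupling = ffq_coupling,
              ffq_presence_coupling = ffq_presence_coupling,
              n_food_features = as.integer(n_food_features),
              seed = as.integer(seed))
  if (length(cfg$diet_props) != 3L ||
      abs(sum(cfg$diet_props) - 1) > 1e-8) {
    stop("diet_props must be three proportions summing to 1")
  }
  names(cfg$diet_props) <- DIET_LEVELS
  if (!all(is.finite(cfg$planted_smd))) stop("planted_smd must be finite")
  if (cfg$n_signature_features > cfg$n_features) {
    stop("n_signature_features exceeds n_features")
  }
  if (!all(cfg$signature_pair %in% DIET_LEVELS)) {
    stop("signature_pair must name two diet patterns")
  }
  if (!is.null(cfg$zero_inflation) &&
      any(cfg$zero_inflation <= 0 | cfg$zero_inflation > 1)) {
    stop("zero_inflation prevalences must lie in (0, 1]")
  }
  cfg$planted_smd <- rep_len(cfg$planted_smd, cfg$n_signature_features)
  class(cfg) <- "sim_config"
  cfg
}

# default FFQ design: 18 hPDI food groups (7 healthy-plant scored positive;
# 5 less-healthy-plant and 6 animal groups reverse-scored), two items each
default_ffq_groups <- function() {
  positive <- c("whole_grains", "fruits", "vegetables", "nuts", "legumes",
                "vegetable_oils", "tea_coffee")
  reverse_plant <- c("fruit_juices", "refined_grains", "potatoes",
                     "sugary_drinks", "sweets")
  animal <- c("animal_fat", "dairy", "eggs", "fish", "red_meat", "white_meat")
  data.frame(
    group = c(positive, reverse_plant, animal),
    hpdi_direction = c(rep("positive", length(positive)),
                       rep("reverse", length(reverse_plant) + length(animal))),
    kind = c(rep("healthy_plant", length(positive)),
             rep("unhealthy_plant", length(reverse_plant)),
             rep("animal", length(animal))),
    stringsAsFactors = FALSE)
}

# groups a diet pattern does not consume at all
excluded_groups <- function(diet) {
  switch(as.character(diet),
         vegan = c("red_meat", "white_meat", "fish", "eggs", "dairy",
                   "animal_fat"),
         vegetarian = c("red_meat", "white_meat", "fish"),
         character(0))
}

# Calibrate the log-scale multiplier delta so the expected Cohen's d of
# asin(sqrt(p)) between comparison and reference samples equals the target.
# Monte-Carlo with common random numbers against a simulated background
# total, so d(delta) is smooth and monotone in delta. Because compositional
# closure couples the signature features (every elevated feature deflates
# the others' proportions in the comparison group), the solve is iterated:
# each pass recalibrates every feature against totals that include the
# other features' current deltas.
calibrate_deltas <- function(targets, mu, sigma, prevalence, sig_idx,
                             seed, m = 10000L, w_cmp = 0.5, n_iter = 3L) {
  if (length(sig_idx) == 0L) return(numeric(0))
  with_seed(seed, {
    nf <- length(mu)
    eps <- matrix(stats::rnorm(m * nf, 0, sigma), m, nf)
    base <- sweep(exp(eps), 2L, exp(mu), `*`)
    keep <- matrix(stats::runif(m * nf), m, nf) <=
      matrix(prevalence, m, nf, byrow = TRUE)
    base <- base * keep
    totals <- rowSums(base)
    sig_base <- base[, sig_idx, drop = FALSE]
    d_of <- function(delta, j, extra2) {
      v <- sig_base[, j]
      v2 <- v * exp(delta)
      p1 <- v / totals
      p2 <- v2 / (totals + extra2 - v + v2)
      y1 <- asin(sqrt(pmin(p1, 1)))
      y2 <- asin(sqrt(pmin(p2, 1)))
      # residual sd of the standardizing OLS is the group-size-weighted
      # pooled sd, so weight the variances by the design's group balance
      (mean(y2) - mean(y1)) /
        sqrt((1 - w_cmp) * stats::var(y1) + w_cmp * stats::var(y2))
    }
    deltas <- numeric(length(sig_idx))
    for (it in seq_len(n_iter)) {
      for (j in seq_along(sig_idx)) {
        tgt <- targets[j]
        if (tgt == 0) next
        # comparison-group totals carry the other features' planted
        # effects (signed: negative deltas deflate the comparison group)
        extra2 <- as.vector(sig_base[, -j, drop = FALSE] %*%
                              (exp(deltas[-j]) - 1))
        f <- function(delta) d_of(delta, j, extra2) - tgt
        hi <- 8
        deltas[j] <- if (tgt > 0 && f(hi) < 0) hi       # cap, recorded
                     else if (tgt < 0 && f(-hi) > 0) -hi
                     else stats::uniroot(f, c(-hi, hi), tol = 1e-5)$root
      }
    }
    deltas
  })
}

#' Simulate a multi-cohort diet-microbiome dataset
#'
#' Draws, per cohort: diet labels from the configured proportions,
#' covariates, FFQ intakes with diet-dependent group means (diet-excluded
#' groups at zero, healthy-plant groups shifted up along
#' omnivore -> vegetarian -> vegan), and log-normal feature abundances with
#' an additive per-cohort random effect and a multiplicative diet effect on
#' the signature features sized so that the expected adjusted Cohen's d on
#' the arcsine-square-root scale equals `planted_smd` (generator-side
#' Monte-Carlo calibration; the calibrated constants are part of the truth
#' record). Bernoulli zero-inflation is applied after effect planting —
#' for designated food features the detection odds depend on the sample's
#' matching FFQ group intake — and every sample is closed to 100 percent.
#' The same seed yields byte-identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `abundance` ([abundance_table()]), `metadata`
#'   ([sample_metadata()]), `ffq` ([ffq_table()]) and `truth` (planted
#'   effects with calibrated constants, food-feature assignments, FFQ
#'   couplings).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nf <- config$n_features
  feature_ids <- sprintf("SGB%04d", seq_len(nf))
  groups <- default_ffq_groups()
  items <- data.frame(
    item = paste0(rep(groups$group, each = 2L), c("_item1", "_item2")),
    group = rep(groups$group, each = 2L),
    hpdi_direction = rep(groups$hpdi_direction, each = 2L),
    stringsAsFactors = FALSE)

  # global feature-level draws
  glob <- with_seed(child_seed(config$seed, 0L), {
    mu <- stats::rnorm(nf, 0, config$feature_log_mean_sd)
    prevalence <- if (is.null(config$zero_inflation)) {
      stats::runif(nf, 0.2, 0.95)
    } else rep_len(config$zero_inflation, nf)
    sig_idx <- if (config$n_signature_features > 0L) {
      sort(sample.int(nf, config$n_signature_features))
    } else integer(0)
    food_cats <- c("dairy", "meat", "fruits_vegetables")
    food_idx <- if (config$n_food_features > 0L) {
      pool <- setdiff(seq_len(nf), sig_idx)
      sort(sample(pool, min(config$n_food_features, length(pool))))
    } else integer(0)
    food_cat <- rep_len(food_cats, length(food_idx))
    prevalence[c(sig_idx, food_idx)] <- 0.9
    list(mu = mu, prevalence = prevalence, sig_idx = sig_idx,
         food_idx = food_idx, food_cat = food_cat)
  })
  pr <- config$diet_props[config$signature_pair]
  deltas <- calibrate_deltas(config$planted_smd, glob$mu,
                             config$feature_log_sd, glob$prevalence,
                             glob$sig_idx, child_seed(config$seed, 999983L),
                             w_cmp = unname(pr[2L] / sum(pr)))

  ref_diet <- config$signature_pair[1L]
  cmp_diet <- config$signature_pair[2L]
  # which FFQ group feeds each food-feature category
  cat_group <- c(dairy = "dairy", meat = "red_meat",
                 fruits_vegetables = "vegetables")

  meta_list <- list(); abund_list <- list(); ffq_list <- list()
  for (k in seq_len(config$n_cohorts)) {
    co <- sprintf("cohort%d", k)
    n <- config$n_samples[k]
    out <- with_seed(child_seed(config$seed, k), {
      counts <- as.vector(stats::rmultinom(1L, n, config$diet_props))
      if (config$n_signature_features > 0L) {
        need <- DIET_LEVELS %in% config$signature_pair
        if (any(counts[need] == 0L)) {
          stop(sprintf("infeasible config: cohort %d drew zero '%s' samples",
                       k, DIET_LEVELS[need & counts == 0L][1L]))
        }
      }
      diet <- sample(rep(DIET_LEVELS, counts))
      sex <- ifelse(stats::runif(n) < config$sex_prob, "female", "male")
      age <- pmax(18, stats::rnorm(n, config$age_mean, config$age_sd))
      bmi <- pmax(15, stats::rnorm(n, config$bmi_mean, config$bmi_sd))
      ids <- sprintf("%s_S%05d", co, seq_len(n))
      md <- data.frame(sample_id = ids, cohort = co, diet = diet,
                       sex = sex, age = age, bmi = bmi,
                       stringsAsFactors = FALSE)

      # FFQ: item intake = exp(N(0, 0.5)) * group multiplier(diet)
      step <- c(omnivore = 0, vegetarian = 0.5, vegan = 1)[diet]
      intakes <- matrix(0, n, nrow(items),
                        dimnames = list(ids, items$item))
      healthy <- groups$kind[match(items$group, groups$group)] == "healthy_plant"
      for (j in seq_len(nrow(items))) {
        base <- exp(stats::rnorm(n, 0, 0.5))
        mult <- rep(1, n)
        if (healthy[j]) mult <- exp(config$ffq_coupling * step)
        excl <- vapply(diet, function(d) items$group[j] %in% excluded_groups(d),
                       logical(1))
        intakes[, j] <- base * mult * !excl
      }

      # abundances: log-normal latents + cohort shift + planted diet effect
      shift <- stats::rnorm(nf, 0, config$cohort_shift_sd)
      lv <- matrix(stats::rnorm(n * nf, 0, config$feature_log_sd), n, nf)
      lv <- sweep(lv, 2L, glob$mu + shift, `+`)
      vals <- exp(lv)
      if (length(glob$sig_idx)) {
        in_cmp <- diet == cmp_diet
        for (j in seq_along(glob$sig_idx)) {
          i <- glob$sig_idx[j]
          vals[in_cmp, i] <- vals[in_cmp, i] * exp(deltas[j])
        }
      }
      # zero-inflation; food features' detection odds follow group intake
      u <- matrix(stats::runif(n * nf), n, nf)
      keep_prob <- matrix(glob$prevalence, n, nf, byrow = TRUE)
      if (length(glob$food_idx)) {
        for (j in seq_along(glob$food_idx)) {
          i <- glob$food_idx[j]
          g <- cat_group[[glob$food_cat[j]]]
          gi <- rowSums(intakes[, items$item[items$group == g], drop = FALSE])
          z <- (gi - mean(gi)) / max(stats::sd(gi), 1e-9)
          keep_prob[, i] <- stats::plogis(
            stats::qlogis(glob$prevalence[i]) +
              config$ffq_presence_coupling * z)
        }
      }
      vals <- vals * (u <= keep_prob)
      tot <- rowSums(vals)
      if (any(tot == 0)) stop("degenerate sample with no detected features")
      vals <- 100 * vals / tot
      dimnames(vals) <- list(ids, feature_ids)
      list(md = md, vals = vals, intakes = intakes)
    })
    meta_list[[k]] <- out$md
    abund_list[[k]] <- out$vals
    ffq_list[[k]] <- out$intakes
  }

  metadata <- sample_metadata(do.call(rbind, meta_list))
  abundance <- abundance_table(do.call(rbind, abund_list))
  ffq <- ffq_table(do.call(rbind, ffq_list),
                   items[, c("item", "group", "hpdi_direction")])
  truth <- list(
    effects = data.frame(
      feature_id = feature_ids[glob$sig_idx],
      reference = rep_len(ref_diet, length(glob$sig_idx)),
      comparison = rep_len(cmp_diet, length(glob$sig_idx)),
      target_smd = config$planted_smd,
      delta_log = deltas, stringsAsFactors = FALSE),
    food_features = data.frame(
      feature_id = feature_ids[glob$food_idx],
      category = glob$food_cat, stringsAsFactors = FALSE),
    ffq_coupling = config$ffq_coupling,
    ffq_presence_coupling = config$ffq_presence_coupling,
    prevalence = stats::setNames(glob$prevalence, feature_ids),
    seed = config$seed)
  list(abundance = abundance, metadata = metadata, ffq = ffq, truth = truth)
}

#' Simulate a food-SGB catalog
#'
#' Emulates the catalog summaries derived from food metagenomes: designated
#' food features are detected (relative abundance at or above the 0.1
#' percent threshold) in at least four food samples and show a prevalence
#' above 0.1 percent in their assigned food category; all other features
#' fall below one or both thresholds.
#'
#' @param config a [sim_config()].
#' @param truth optionally, the `truth` record of [simulate_cohorts()] run
#'   with the same config (avoids regenerating the food-feature draw).
#' @return data frame of class `food_catalog` with columns `feature_id`,
#'   `n_food_samples_detected` and `prev_<category>` prevalence columns.
#' @export
simulate_food_catalog <- function(config, truth = NULL) {
  if (is.null(truth)) truth <- simulate_cohorts(config)$truth
  feature_ids <- names(truth$prevalence)
  cats <- c("dairy", "meat", "fruits_vegetables")
  with_seed(child_seed(config$seed, 424243L), {
    nfeat <- length(feature_ids)
    n_det <- sample(0:3, nfeat, replace = TRUE)
    prev <- matrix(stats::runif(nfeat * length(cats), 0, 0.0008),
                   nfeat, length(cats),
                   dimnames = list(feature_ids, paste0("prev_", cats)))
    ff <- truth$food_features
    for (r in seq_len(nrow(ff))) {
      i <- match(ff$feature_id[r], feature_ids)
      n_det[i] <- sample(4:30, 1L)
      prev[i, paste0("prev_", ff$category[r])] <- stats::runif(1, 0.02, 0.6)
    }
    out <- data.frame(feature_id = feature_ids,
                      n_food_samples_detected = n_det, prev,
                      stringsAsFactors = FALSE, row.names = NULL)
    class(out) <- c("food_catalog", "data.frame")
    out
  })
}
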