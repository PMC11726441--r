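test_that("arcsine-square-root transform hits its closed-form fixed points", {
  expect_equal(arcsin_sqrt(0), 0)
  expect_equal(arcsin_sqrt(100), pi / 2)
  expect_equal(arcsin_sqrt(25), pi / 6)
  expect_error(arcsin_sqrt(101), "0, 100")
  expect_error(arcsin_sqrt(-1), "0, 100")
})

test_that("adjusted Cohen's d reduces to the classical formula", {
  # groups {1,2,3} vs {4,5,6}: pooled sd 1, mean difference 3
  y <- c(1, 2, 3, 4, 5, 6)
  g <- factor(rep(c("ref", "cmp"), each = 3), levels = c("ref", "cmp"))
  res <- adjusted_cohens_d(y, g)
  expect_equal(res$d, 3.0, tolerance = 1e-12)
  # reversing the factor order flips the sign
  g2 <- factor(as.character(g), levels = c("cmp", "ref"))
  expect_equal(adjusted_cohens_d(y, g2)$d, -3.0, tolerance = 1e-12)
  # variance formula evaluated independently: 6/9 + 9/12
  expect_equal(res$var_d, 6 / 9 + 9 / 12, tolerance = 1e-12)
  expect_equal(res$se_d, sqrt(1.4166666667), tolerance = 1e-9)
  # no-covariate path equals the direct pooled-sd oracle on random data
  set.seed(8)
  for (i in 1:5) {
    y <- c(rnorm(15, 0, 1.3), rnorm(9, 0.7, 1.3))
    g <- factor(rep(c("a", "b"), c(15, 9)), levels = c("a", "b"))
    sp <- sqrt(((15 - 1) * var(y[1:15]) + (9 - 1) * var(y[16:24])) / (24 - 2))
    expect_equal(adjusted_cohens_d(y, g)$d,
                 (mean(y[16:24]) - mean(y[1:15])) / sp, tolerance = 1e-12)
  }
})

test_that("adjusted Cohen's d enforces its contract", {
  y <- rnorm(20)
  g <- factor(rep(c("a", "b"), each = 10))
  # covariate exactly collinear with the group indicator
  expect_error(adjusted_cohens_d(y, g, data.frame(x = as.integer(g))),
               "rank")
  expect_error(adjusted_cohens_d(y[1:12], factor(rep(c("a", "b"), c(10, 2)))),
               "minimum size")
})

test_that("DerSimonian-Laird reproduces the hand-worked cases", {
  # single study: identity
  one <- dersimonian_laird(0.3, 0.01)
  expect_equal(one$pooled, 0.3, tolerance = 1e-12)
  expect_equal(one$se, 0.1, tolerance = 1e-12)
  expect_equal(one$tau2, 0)
  expect_equal(one$i2, 0)
  # three identical studies: homogeneous closed form
  hom <- dersimonian_laird(c(0.5, 0.5, 0.5), c(0.04, 0.04, 0.04))
  expect_equal(hom$q_het, 0, tolerance = 1e-12)
  expect_equal(hom$tau2, 0, tolerance = 1e-12)
  expect_equal(hom$pooled, 0.5, tolerance = 1e-12)
  expect_equal(hom$se, sqrt(0.04 / 3), tolerance = 1e-12)
  # two heterogeneous studies: every DL step hand-evaluated
  het <- dersimonian_laird(c(0.2, 0.6), c(0.04, 0.04))
  expect_equal(het$q_het, 2, tolerance = 1e-12)
  expect_equal(het$tau2, 0.04, tolerance = 1e-12)
  expect_equal(het$pooled, 0.4, tolerance = 1e-12)
  expect_equal(het$se, 0.2, tolerance = 1e-12)
  expect_equal(het$i2, 50, tolerance = 1e-12)
  expect_error(dersimonian_laird(c(0.1, 0.2), c(0.01, 0)), "positive")
})

test_that("DL pooling matches an independent reference implementation", {
  skip_if_not_installed("metafor")
  set.seed(123)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    y <- rnorm(k, 0, 0.8)
    v <- runif(k, 0.005, 0.3)
    mine <- dersimonian_laird(y, v)
    ref <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(mine$pooled, unname(as.numeric(ref$b)), tolerance = 1e-9)
    expect_equal(mine$se, unname(ref$se), tolerance = 1e-9)
    expect_equal(mine$tau2, unname(ref$tau2), tolerance = 1e-9)
    expect_equal(mine$q_het, unname(ref$QE), tolerance = 1e-9)
    expect_equal(mine$i2, unname(ref$I2), tolerance = 1e-7)
  }
})

test_that("DL with zero heterogeneity equals fixed-effect pooling", {
  y <- c(0.1, 0.12, 0.11, 0.09)
  v <- c(0.5, 0.4, 0.6, 0.5)  # tiny spread relative to v: Q < k-1
  res <- dersimonian_laird(y, v)
  expect_equal(res$tau2, 0)
  w <- 1 / v
  expect_equal(res$pooled, sum(w * y) / sum(w), tolerance = 1e-12)
  expect_equal(res$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
})

test_that("BH adjustment matches the brute-force step-up evaluation", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), rep(0.04, 4), tolerance = 1e-12)
  expect_equal(bh_adjust(0.123), 0.123)
  # monotone after sorting, for random inputs
  set.seed(2)
  pr <- runif(50)
  q <- bh_adjust(pr)
  expect_true(all(diff(q[order(pr)]) >= -1e-12))
  # brute-force oracle: q_(i) = min_{j>=i} p_(j) * m / j
  ps <- sort(pr); m <- length(ps)
  brute <- sapply(seq_len(m), function(i) min(pmin(1, ps[i:m] * m / (i:m))))
  expect_equal(sort(q), brute, tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the batch per-cohort OLS path equals the scalar operation", {
  sim <- small_sim()
  da <- run_diffabund_meta(sim$abundance, sim$metadata, c("omnivore", "vegan"))
  md <- sim$metadata
  y_all <- arcsin_sqrt(unclass(sim$abundance))
  for (f in c("SGB0005", "SGB0037")) {
    idx <- md$cohort == "cohort1" & md$diet %in% c("omnivore", "vegan")
    sc <- adjusted_cohens_d(
      y_all[idx, f],
      factor(as.character(md$diet[idx]), c("omnivore", "vegan")),
      md[idx, c("sex", "age", "bmi")])
    row <- da$cohort[da$cohort$cohort == "cohort1" & da$cohort$feature_id == f, ]
    expect_equal(row$d, sc$d, tolerance = 1e-10)
    expect_equal(row$var_d, sc$var_d, tolerance = 1e-10)
    expect_equal(row$wald_p, sc$wald_p, tolerance = 1e-10)
  }
})

test_that("planted effects are recovered with the documented sign", {
  sim <- small_sim()  # 5 features planted at d = +1 (enriched in vegans)
  da <- run_diffabund_meta(sim$abundance, sim$metadata, c("omnivore", "vegan"))
  planted <- sim$truth$effects$feature_id
  hits <- da$meta[da$meta$feature_id %in% planted, ]
  expect_true(all(hits$pooled_d > 0))  # positive = enriched in comparison
  expect_true(all(planted %in% da$meta$feature_id[da$meta$rank_abs_d <= 20]))
  expect_true(all(hits$k >= 2))
  # pooled estimate is invariant to cohort ordering
  md_rev <- sim$metadata[rev(seq_len(nrow(sim$metadata))), ]
  da2 <- run_diffabund_meta(sim$abundance, md_rev, c("omnivore", "vegan"))
  m1 <- da$meta[order(da$meta$feature_id), ]
  m2 <- da2$meta[order(da2$meta$feature_id), ]
  expect_equal(m1$pooled_d, m2$pooled_d, tolerance = 1e-9)
})

test_that("pathway prevalence filtering keeps within-diet-prevalent features", {
  sim <- small_sim()
  tab <- unclass(sim$abundance)
  colnames(tab)[1:2] <- c("UNMAPPED", "UNINTEGRATED")
  filt <- filter_pathway_table(abundance_table(tab), sim$metadata,
                               min_prevalence = 0.05)
  expect_false(any(c("UNMAPPED", "UNINTEGRATED") %in% colnames(filt)))
  md <- sim$metadata
  for (dt in levels(md$diet)) {
    prev <- colMeans(filt[md$diet[match(rownames(filt), md$sample_id)] == dt,
                          , drop = FALSE] > 0)
    expect_true(all(prev >= 0.05))
  }
})
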