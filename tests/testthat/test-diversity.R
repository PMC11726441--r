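test_that("observed richness counts strictly positive features", {
  tab <- tiny_table()
  expect_equal(unname(observed_richness(tab)), c(2L, 3L))
  m <- matrix(c(50, 50, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(unname(observed_richness(m)), c(2L, 0L))
  # invariant to positive rescaling
  expect_equal(observed_richness(m), observed_richness(m * 0.42))
})

test_that("the central-interval outlier rule matches a percentile oracle", {
  set.seed(11)
  r <- stats::setNames(rnorm(1000, 250, 40), paste0("s", 1:1000))
  filt <- richness_outlier_filter(r)
  q <- quantile(r, c(0.025, 0.975), type = 7)
  expect_setequal(filt$removed, names(r)[r < q[1] | r > q[2]])
  expect_true(length(filt$removed) > 30 && length(filt$removed) < 70)
  # constant richness: nothing removed
  expect_length(richness_outlier_filter(setNames(rep(5, 50), 1:50))$removed, 0)
  # one extreme value among 100 is removed
  r2 <- setNames(c(rep(100, 99) + rnorm(99), 1e4), paste0("x", 1:100))
  expect_true("x100" %in% richness_outlier_filter(r2)$removed)
  expect_warning(richness_outlier_filter(rnorm(10)), "fewer than 20")
})

test_that("Kruskal-Wallis/Dunn agrees with a brute-force rank oracle", {
  vals <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  grp <- rep(c("a", "b", "c"), each = 3)
  kd <- kruskal_dunn(vals, grp)
  # oracle: H computed from first principles (no ties)
  r <- rank(vals); n <- length(vals)
  H <- 12 / (n * (n + 1)) * sum(tapply(r, grp, function(x) length(x) * mean(x)^2)) -
    3 * (n + 1)
  expect_equal(kd$h, H, tolerance = 1e-12)
  expect_equal(kd$p, kruskal.test(vals, factor(grp))$p.value)
  # oracle: two-group Dunn z from the rank-mean formula, tie-free data
  sub <- kruskal_dunn(vals[1:6], grp[1:6])
  rr <- rank(vals[1:6])
  z_hand <- (mean(rr[1:3]) - mean(rr[4:6])) /
    sqrt((6 * 7 / 12) * (1 / 3 + 1 / 3))
  expect_equal(sub$pairs$z, z_hand, tolerance = 1e-12)
  # identical groups give z = 0
  same <- kruskal_dunn(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$pairs$z, 0, tolerance = 1e-12)
  expect_warning(kruskal_dunn(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "excluding")
})

test_that("Dunn rejects at close to nominal rate under the null", {
  set.seed(42)
  rej <- replicate(400, {
    kd <- kruskal_dunn(rnorm(60), rep(c("a", "b", "c"), 20))
    kd$p < 0.05
  })
  expect_lte(mean(rej), 0.08)
  expect_gte(mean(rej), 0.02)
})

test_that("unweighted UniFrac reproduces hand-enumerated toy cases", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  m <- matrix(c(1, 0, 0,
                0, 0, 1),
              2, 3, byrow = TRUE, dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  tab <- abundance_table(m)
  d <- beta_distance(tab, "unifrac_unweighted", tree = tree)
  expect_equal(d["s1", "s2"], 1.0)  # disjoint single leaves span all branches
  m2 <- matrix(c(1, 1, 0,
                 1, 0, 1),
               2, 3, byrow = TRUE, dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  d2 <- beta_distance(abundance_table(m2), "unifrac_unweighted", tree = tree)
  # unique branches B(1) + C(2); union A(1) + B(1) + internal(1) + C(2)
  expect_equal(d2["s1", "s2"], 3 / 5)
  expect_equal(d2["s1", "s1"], 0)
  expect_error(beta_distance(tab, "unifrac_unweighted"), "tree")
  tree2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_error(beta_distance(tab, "unifrac_unweighted", tree = tree2),
               "missing from tree")
})

test_that("UniFrac agrees with an independent implementation", {
  skip_if_not_installed("picante")
  set.seed(7)
  n_feat <- 12
  tree <- ape::rtree(n_feat, tip.label = paste0("t", 1:n_feat))
  m <- matrix(rexp(8 * n_feat) * rbinom(8 * n_feat, 1, 0.6), 8, n_feat,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:n_feat)))
  m <- 100 * m / rowSums(m)
  d <- beta_distance(abundance_table(m), "unifrac_unweighted", tree = tree)
  ref <- as.matrix(picante::unifrac(1 * (m > 0), tree))
  expect_equal(unclass(d)[rownames(ref), colnames(ref)], ref,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("distance matrices satisfy the metric-space invariants", {
  sim <- small_sim()
  tab <- abundance_table(unclass(sim$abundance)[1:25, , drop = FALSE])
  tree <- ape::rtree(ncol(tab), tip.label = colnames(tab))
  for (metric in c("bray_curtis", "aitchison", "unifrac_unweighted",
                   "unifrac_weighted")) {
    d <- beta_distance(tab, metric, tree = tree)
    expect_equal(unclass(d), t(unclass(d)), tolerance = 1e-12)
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0))
    if (metric %in% c("bray_curtis", "unifrac_unweighted")) {
      expect_true(all(d <= 1 + 1e-12))
    }
  }
  # identical samples are at distance zero under every metric
  two <- abundance_table(unclass(tab)[c(1, 1), , drop = FALSE],
                         sample_ids = c("a", "b"))
  for (metric in c("bray_curtis", "aitchison", "unifrac_unweighted")) {
    expect_equal(beta_distance(two, metric, tree = tree)["a", "b"], 0,
                 tolerance = 1e-12)
  }
})

test_that("sequential PERMANOVA partitions variance and hits the p floor", {
  set.seed(3)
  # two fully separated clusters of 20 as the diet term
  n <- 40
  m <- matrix(abs(rnorm(n * 10)), n, 10)
  m[1:20, 1:5] <- m[1:20, 1:5] + 50
  m[21:40, 6:10] <- m[21:40, 6:10] + 50
  rownames(m) <- paste0("s", 1:n); colnames(m) <- paste0("f", 1:10)
  tab <- abundance_table(100 * m / rowSums(m))
  md <- sample_metadata(data.frame(
    sample_id = rownames(m), cohort = "c1",
    diet = rep(c("omnivore", "vegan"), each = 20),
    sex = rep_len(c("female", "male"), n),
    age = rnorm(n, 45, 8), bmi = rnorm(n, 25, 3)))
  d <- beta_distance(tab, "bray_curtis")
  res <- permanova_sequential(d, md, n_perm = 999, seed = 5)
  expect_equal(sum(res$r2[!res$term %in% "Total"]), 1, tolerance = 1e-9)
  expect_equal(res$p[res$term == "diet"], 1 / 1000)  # minimum attainable
  expect_gt(res$r2[res$term == "diet"], 0.5)
  # deterministic under a fixed seed
  res2 <- permanova_sequential(d, md, n_perm = 999, seed = 5)
  expect_identical(res$p, res2$p)
})

test_that("PERMANOVA p-values are calibrated under the null", {
  set.seed(21)
  rej <- replicate(120, {
    n <- 24
    m <- matrix(abs(rnorm(n * 8)) + 0.1, n, 8,
                dimnames = list(paste0("s", 1:n), paste0("f", 1:8)))
    tab <- abundance_table(100 * m / rowSums(m))
    md <- sample_metadata(data.frame(
      sample_id = rownames(m), cohort = "c1",
      diet = sample(rep(c("omnivore", "vegan"), each = n / 2)),
      sex = sample(rep_len(c("female", "male"), n)),
      age = rnorm(n, 45, 8), bmi = rnorm(n, 25, 3)))
    d <- beta_distance(tab, "bray_curtis")
    res <- permanova_sequential(d, md, n_perm = 99,
                                seed = sample.int(1e6, 1))
    res$p[res$term == "diet"] < 0.05
  })
  expect_lte(mean(rej), 0.10)
})
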