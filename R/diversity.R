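#' Observed richness
#'
#' Number of features with strictly positive abundance per sample.
#'
#' @param table an [abundance_table()] or numeric matrix (samples x features).
#' @return named integer vector of per-sample richness.
#' @export
observed_richness <- function(table) {
  rowSums(unclass(as.matrix(table)) > 0)
}

#' Central-interval richness outlier filter
#'
#' Flags as outliers all samples whose richness falls outside the central
#' 95 percent percentile interval (2.5th to 97.5th percentiles, inclusive)
#' of the richness distribution. With fewer than 20 samples no filtering is
#' applied (warning).
#'
#' @param richness named numeric vector (names = sample ids).
#' @param level width of the central interval retained (default 0.95).
#' @return list with `retained` and `removed` sample-id vectors and the
#'   interval `bounds`.
#' @export
richness_outlier_filter <- function(richness, level = 0.95) {
  ids <- names(richness)
  if (is.null(ids)) ids <- as.character(seq_along(richness))
  if (length(richness) < 20L) {
    warning("fewer than 20 samples; outlier filter skipped")
    return(list(retained = ids, removed = character(0),
                bounds = c(NA_real_, NA_real_)))
  }
  a <- (1 - level) / 2
  bounds <- unname(stats::quantile(richness, c(a, 1 - a), type = 7))
  keep <- richness >= bounds[1L] & richness <= bounds[2L]
  list(retained = ids[keep], removed = ids[!keep], bounds = bounds)
}

#' Kruskal-Wallis omnibus test with Dunn's pairwise contrasts
#'
#' Omnibus Kruskal-Wallis rank-sum test (tie-corrected, via
#' [stats::kruskal.test()]) followed by Dunn's z tests on rank-mean
#' differences with the tie-corrected variance, adjusted across the
#' pairwise family by Benjamini-Hochberg. Groups with fewer than two
#' observations are excluded with a warning.
#'
#' @param values numeric vector.
#' @param groups grouping factor.
#' @param p_adjust adjustment method for the pairwise family.
#' @return list with `h`, `df`, `p` (omnibus) and `pairs` (data frame:
#'   group1, group2, z, p, q).
#' @export
kruskal_dunn <- function(values, groups, p_adjust = "BH") {
  groups <- as.factor(groups)
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  small <- names(which(table(groups) < 2L))
  if (length(small)) {
    warning("excluding group(s) with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2L) stop("need at least two groups with >= 2 samples")
  kw <- stats::kruskal.test(values, groups)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  cmb <- utils::combn(lev, 2L)
  pairs <- data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ],
                      stringsAsFactors = FALSE)
  pairs$z <- vapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1L, i]; b <- cmb[2L, i]
    sigma <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ng[[a]] + 1 / ng[[b]]))
    (rbar[[a]] - rbar[[b]]) / sigma
  }, numeric(1))
  pairs$p <- 2 * stats::pnorm(-abs(pairs$z))
  pairs$q <- stats::p.adjust(pairs$p, method = p_adjust)
  list(h = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairs = pairs)
}

# branch (edge) incidence: for each edge of the tree, which features
# (tips) descend from it; returns edge lengths and a tips x edges logical
edge_incidence <- function(tree, feature_ids) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  miss <- setdiff(feature_ids, tree$tip.label)
  if (length(miss)) {
    stop("feature(s) missing from tree: ", paste(miss, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # postorder guarantees children are resolved before their parent edge
  for (e in ape::postorder(tree)) {
    par <- tree$edge[e, 1L]; chl <- tree$edge[e, 2L]
    desc[[par]] <- c(desc[[par]], desc[[chl]])
  }
  inc <- matrix(FALSE, ntip, nedge)
  for (e in seq_len(nedge)) inc[desc[[tree$edge[e, 2L]]], e] <- TRUE
  rownames(inc) <- tree$tip.label
  list(incidence = inc[feature_ids, , drop = FALSE],
       lengths = tree$edge.length)
}

#' Beta-diversity distance matrix
#'
#' Computes one of four sample-by-sample dissimilarities on a percent-scale
#' abundance table: Bray-Curtis (via [vegan::vegdist()]), Aitchison
#' (Euclidean distance of centered log-ratio transformed proportions after
#' multiplicative pseudocount replacement of zeros), or unweighted /
#' weighted (normalized) UniFrac from a phylogenetic tree covering the
#' features. Unweighted UniFrac is the branch length unique to either
#' sample's feature set divided by the branch length of the union.
#'
#' @param table an [abundance_table()].
#' @param metric one of `"bray_curtis"`, `"aitchison"`,
#'   `"unifrac_unweighted"`, `"unifrac_weighted"`.
#' @param tree an [ape::read.tree()] phylo object (UniFrac metrics only);
#'   its tip set must cover the table's features.
#' @param pseudocount zero replacement for the Aitchison clr; default half
#'   the smallest nonzero proportion in the table.
#' @return a `dist`-like symmetric matrix of class `distance_matrix` with
#'   zero diagonal.
#' @export
beta_distance <- function(table,
                          metric = c("bray_curtis", "aitchison",
                                     "unifrac_unweighted", "unifrac_weighted"),
                          tree = NULL, pseudocount = NULL) {
  metric <- match.arg(metric)
  x <- unclass(as.matrix(table))
  if (any(rowSums(x) == 0)) stop("zero-sum sample; distances undefined")
  n <- nrow(x)
  if (metric == "bray_curtis") {
    d <- as.matrix(vegan::vegdist(x, method = "bray"))
  } else if (metric == "aitchison") {
    p <- x / rowSums(x)
    if (is.null(pseudocount)) pseudocount <- min(p[p > 0]) / 2
    p[p == 0] <- pseudocount
    lp <- log(p)
    clr <- lp - rowMeans(lp)
    d <- as.matrix(stats::dist(clr))
  } else {
    if (is.null(tree)) stop("UniFrac requires a phylogenetic tree")
    ei <- edge_incidence(tree, colnames(x))
    len <- ei$lengths
    if (metric == "unifrac_unweighted") {
      # sample x edge presence: any descendant tip present in the sample
      pres <- (x > 0) %*% ei$incidence > 0
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        a <- pres[i, ]; b <- pres[j, ]
        union_len <- sum(len[a | b])
        d[i, j] <- d[j, i] <-
          if (union_len == 0) 0 else sum(len[xor(a, b)]) / union_len
      }
    } else {
      p <- x / rowSums(x)
      pe <- p %*% ei$incidence  # fraction of abundance under each edge
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        denom <- sum(len * (pe[i, ] + pe[j, ]))
        d[i, j] <- d[j, i] <-
          if (denom == 0) 0 else sum(len * abs(pe[i, ] - pe[j, ])) / denom
      }
    }
  }
  dimnames(d) <- list(rownames(x), rownames(x))
  diag(d) <- 0
  class(d) <- c("distance_matrix", class(d))
  d
}

#' Sequential-term PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' with terms assessed sequentially (Type I), via [vegan::adonis2()] with
#' 999 permutations by default — the convention throughout this pipeline is
#' sex, scaled age, scaled BMI and diet pattern, in that order, so the diet
#' term is tested after the covariates. Sample rows are permuted freely.
#'
#' @param dist a [beta_distance()] matrix (or any square symmetric matrix).
#' @param metadata a [sample_metadata()] covering the matrix's samples.
#' @param terms model terms in the order they should be assessed; `age` and
#'   `bmi` are scaled internally when given as `age_scaled` / `bmi_scaled`.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return data frame (class `permanova_result`): one row per term plus
#'   Residual and Total, with df, sums of squares, R2, F and permutation p.
#' @export
permanova_sequential <- function(dist, metadata,
                                 terms = c("sex", "age_scaled", "bmi_scaled", "diet"),
                                 n_perm = 999, seed = 1L) {
  d <- as.matrix(dist)
  md <- metadata[match(rownames(d), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata missing for some samples")
  frame <- data.frame(row.names = rownames(d))
  for (tm in terms) {
    base <- sub("_scaled$", "", tm)
    if (!base %in% names(md)) stop("unknown model term: ", tm)
    v <- md[[base]]
    if (grepl("_scaled$", tm)) v <- as.numeric(scale(v))
    if (is.factor(v)) v <- droplevels(v)
    frame[[tm]] <- v
  }
  if (anyNA(frame)) stop("missing covariate values among included samples")
  fml <- stats::as.formula(paste("as.dist(d) ~", paste(terms, collapse = " + ")))
  res <- with_seed(seed, {
    vegan::adonis2(fml, data = frame, permutations = n_perm, by = "terms")
  })
  out <- data.frame(term = rownames(res), df = res$Df,
                    sum_of_squares = res$SumOfSqs, r2 = res$R2,
                    f = res$F, p = res$`Pr(>F)`,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' Principal coordinates of a distance matrix
#'
#' Classical metric MDS (PCoA) for ordination plots, via
#' [stats::cmdscale()].
#'
#' @param dist a [beta_distance()] matrix.
#' @param k number of coordinate axes.
#' @return data frame with `sample_id` and `PCo1..PCok`.
#' @export
pcoa_coordinates <- function(dist, k = 2L) {
  co <- stats::cmdscale(as.dist(as.matrix(dist)), k = k)
  colnames(co) <- paste0("PCo", seq_len(ncol(co)))
  data.frame(sample_id = rownames(co), co, stringsAsFactors = FALSE,
             row.names = NULL)
}
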