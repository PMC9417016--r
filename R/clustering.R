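#' Principal component analysis of the nine map metrics
#'
#' Correlation (standardized) PCA of the active metrics: the nine variables
#' mix counts and proportions on different scales, so each is centered and
#' scaled to unit variance before decomposition (an unstandardized PCA would
#' be dominated by link counts). The respondent stakeholder group is
#' projected as a supplementary variable: category centroids are computed in
#' score space without influencing the axes. Axis signs are fixed so that
#' each axis's largest-|loading| variable loads positively, making results
#' reproducible across platforms.
#'
#' @param table Metrics table from [metrics_table()] (columns
#'   `respondent_id`, `group`, nine metrics), or a plain numeric matrix/data
#'   frame of active variables.
#' @param supplementary Optional named vector (names = respondent ids) of
#'   supplementary categories; defaults to the table's `group` column.
#' @return Object of class `pca_result` with fields `eigenvalues`,
#'   `percent_variance`, `cumulative_percent`, `scores`, `loadings`
#'   (variable-axis correlations), `rotation`, `supp_centroids`, `n`,
#'   `variables`.
#' @export
run_pca <- function(table, supplementary = NULL) {
  if (is.data.frame(table) && all(c("respondent_id", "group") %in%
                                  names(table))) {
    ids <- table$respondent_id
    if (is.null(supplementary)) {
      supplementary <- stats::setNames(table$group, ids)
    }
    x <- as.matrix(table[setdiff(names(table), c("respondent_id", "group"))])
    rownames(x) <- ids
  } else {
    x <- as.matrix(table)
    if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  }
  if (nrow(x) < 3) stop_repmap("PCA requires at least 3 rows")
  if (anyNA(x)) stop_repmap("missing values in metrics table")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop_repmap("constant (zero-variance) column(s): ",
                paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  rot <- pc$rotation
  scores <- pc$x
  # sign convention: dominant variable of each axis loads positively
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  loadings <- sweep(rot, 2, pc$sdev, `*`)  # correlations with axes
  pct <- 100 * eig / sum(eig)
  supp_centroids <- NULL
  if (!is.null(supplementary)) {
    supp <- as.character(supplementary[rownames(scores)])
    supp_centroids <- do.call(rbind, lapply(split(seq_len(nrow(scores)),
                                                  supp), function(idx) {
      colMeans(scores[idx, , drop = FALSE])
    }))
  }
  structure(
    list(eigenvalues = eig, percent_variance = pct,
         cumulative_percent = cumsum(pct), scores = scores,
         loadings = loadings, rotation = rot,
         supp_centroids = supp_centroids, n = nrow(x),
         variables = colnames(x)),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", x$n, " rows x ", length(x$variables),
      " active variables; axis variance (%): ",
      paste(sprintf("%.1f", x$percent_variance[seq_len(min(3,
        length(x$percent_variance)))]), collapse = ", "), ", ...\n", sep = "")
  invisible(x)
}

#' Hierarchical clustering on principal components
#'
#' Ward-linkage hierarchical clustering of respondents in the reduced space
#' of retained principal-component scores (Euclidean distances,
#' `stats::hclust(method = "ward.D2")`). The number of retained axes is the
#' smallest set reaching a cumulative-variance target (default 80%), or an
#' explicit count. With `k = "auto"` the cut is chosen in `[2, kmax]` to
#' maximize the ratio of successive between-inertia gains — the cut after
#' which further splitting buys comparatively little. Optional k-means
#' consolidation reassigns respondents starting from the hierarchical
#' cluster centroids (off by default so results are linkage-reproducible).
#'
#' @param pca A `pca_result`.
#' @param retained Number of axes (integer >= 1) or cumulative-variance
#'   proportion in (0, 1) (default 0.8).
#' @param k Number of clusters, or `"auto"`.
#' @param kmax Largest k considered by `"auto"`
#'   (default `min(10, n - 1)`).
#' @param consolidate Run k-means consolidation from hierarchical centroids.
#' @param seed Seed used for the (deterministic-start) consolidation step.
#' @return Object of class `cluster_result` with fields `labels` (named
#'   integer vector), `k`, `retained_axes`, `tree` (the `hclust` object),
#'   `within_inertia`, `between_inertia`, `total_inertia`, `consolidated`.
#' @export
hcpc <- function(pca, retained = 0.8, k = "auto", kmax = NULL,
                 consolidate = FALSE, seed = 1) {
  if (retained < 1) {
    m <- which(pca$cumulative_percent >= 100 * retained)[1]
    if (is.na(m)) m <- length(pca$eigenvalues)
  } else {
    m <- min(as.integer(retained), ncol(pca$scores))
  }
  if (m < 1) stop_repmap("at least one retained axis is required")
  s <- pca$scores[, seq_len(m), drop = FALSE]
  n <- nrow(s)
  hc <- stats::hclust(stats::dist(s), method = "ward.D2")
  total <- sum(sweep(s, 2, colMeans(s))^2)
  within_at <- function(kk) {
    labs <- stats::cutree(hc, k = kk)
    sum(vapply(split(seq_len(n), labs), function(idx) {
      sub <- s[idx, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
  }
  if (identical(k, "auto")) {
    kmax <- kmax %||% min(10L, n - 1L)
    if (kmax < 2L) stop_repmap("too few respondents for automatic k")
    W <- vapply(seq_len(min(kmax + 1L, n)), within_at, numeric(1))
    ks <- 2:kmax
    gain <- function(kk) if (kk + 1L <= length(W)) W[kk - 1L] - W[kk] else NA
    ratio <- vapply(ks, function(kk) {
      g1 <- W[kk - 1L] - W[kk]
      g2 <- if (kk + 1L <= length(W)) W[kk] - W[kk + 1L] else NA_real_
      if (is.na(g2)) return(NA_real_)
      g1 / max(g2, .Machine$double.eps)
    }, numeric(1))
    k <- if (all(is.na(ratio))) 2L else ks[which.max(ratio)]
  } else {
    k <- as.integer(k)
    if (k > n) stop_repmap("k exceeds the number of respondents")
  }
  labels <- stats::cutree(hc, k = k)
  consolidated <- FALSE
  if (consolidate && k > 1L) {
    centroids <- do.call(rbind, lapply(split(seq_len(n), labels),
      function(idx) colMeans(s[idx, , drop = FALSE])))
    km <- with_local_seed(seed,
      stats::kmeans(s, centers = centroids, iter.max = 100))
    labels <- stats::setNames(km$cluster, rownames(s))
    consolidated <- TRUE
  }
  within <- sum(vapply(split(seq_len(n), labels), function(idx) {
    sub <- s[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
  structure(
    list(labels = stats::setNames(as.integer(labels), rownames(s)),
         k = k, retained_axes = m, tree = hc,
         within_inertia = within, between_inertia = total - within,
         total_inertia = total, consolidated = consolidated),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> k = ", x$k, " on ", x$retained_axes,
      " retained axes; between/total inertia = ",
      sprintf("%.3f", x$between_inertia / x$total_inertia), "\n", sep = "")
  invisible(x)
}

#' Compare two respondent clusters metric by metric
#'
#' Per metric: per-cluster mean and standard deviation (n-1 denominator) and
#' a two-sample t test (pooled-variance Student by default, Welch as an
#' option), two-sided. Per cluster: composition by stakeholder group. No
#' multiple-testing correction is applied by default; set `p_adjust =
#' "holm"` to add adjusted p-values.
#'
#' @param table Metrics table from [metrics_table()].
#' @param clusters A `cluster_result` (or named label vector) with exactly
#'   two clusters for testing; means/SDs are reported for any k, with tests
#'   set to `NA`.
#' @param test `"student"` (pooled variance) or `"welch"`.
#' @param p_adjust Optional p-value adjustment method (see
#'   [stats::p.adjust()]); `"none"` by default.
#' @return List with `metrics` (data frame: `metric`, `mean_<k>`, `sd_<k>`
#'   per cluster, `t`, `p`) and `composition` (group x cluster count table).
#' @export
compare_clusters <- function(table, clusters, test = c("student", "welch"),
                             p_adjust = "none") {
  test <- match.arg(test)
  labels <- if (inherits(clusters, "cluster_result")) clusters$labels else
    clusters
  labs <- labels[table$respondent_id]
  if (anyNA(labs)) stop_repmap("cluster label missing for some respondents")
  ks <- sort(unique(labs))
  do_test <- length(ks) == 2L
  if (do_test && any(table(labs) < 2L)) {
    stop_repmap("clusters of size < 2 cannot be tested")
  }
  rows <- lapply(METRIC_COLUMNS, function(v) {
    vals <- split(table[[v]], labs)
    row <- data.frame(metric = v, stringsAsFactors = FALSE)
    for (kk in ks) {
      row[[paste0("mean_", kk)]] <- mean(vals[[as.character(kk)]])
      row[[paste0("sd_", kk)]] <- stats::sd(vals[[as.character(kk)]])
    }
    if (do_test) {
      a <- vals[[1]]; b <- vals[[2]]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        d <- mean(a) - mean(b)
        row$t <- if (d == 0) 0 else sign(d) * Inf
        row$p <- if (d == 0) 1 else 0
      } else {
        tt <- stats::t.test(a, b, var.equal = (test == "student"))
        row$t <- unname(tt$statistic)
        row$p <- tt$p.value
      }
    } else {
      row$t <- NA_real_; row$p <- NA_real_
    }
    row
  })
  metrics <- do.call(rbind, rows)
  if (!identical(p_adjust, "none")) {
    metrics$p_adjusted <- stats::p.adjust(metrics$p, method = p_adjust)
  }
  composition <- table(group = table$group, cluster = labs)
  list(metrics = metrics, composition = composition)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_repmap("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
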