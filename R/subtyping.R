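#' Filter methylation sites by detection p-value
#'
#' Keeps exactly the sites whose detection p-value is strictly below the
#' threshold in every sample, the standard reliability filter for Illumina
#' methylation arrays.
#'
#' @param m A [beta_matrix()] with detection p-values.
#' @param p_threshold Detection p-value threshold (strict `<`).
#' @return A filtered `beta_matrix`.
#' @export
filter_by_detection <- function(m, p_threshold = 0.05) {
  stopifnot(inherits(m, "beta_matrix"))
  if (is.null(m$detection_p)) {
    stop("filter_by_detection: matrix carries no detection p-values",
         call. = FALSE)
  }
  keep <- rownames(m$values)[apply(m$detection_p < p_threshold, 1, all)]
  restrict(m, features = keep)
}

#' Filter features by sample standard deviation
#'
#' Retains features whose sample standard deviation (n - 1 denominator)
#' satisfies the comparator against the threshold: `"ge"` (>=) for the
#' methylation variance filter, `"gt"` (>) for the expression one.
#'
#' @param m A `beta_matrix` or `expr_matrix` with at least two samples.
#' @param sd_threshold Positive threshold.
#' @param comparator `"ge"` or `"gt"`.
#' @return A filtered matrix of the same class; feature order preserved.
#' @export
filter_by_sd <- function(m, sd_threshold, comparator = c("ge", "gt")) {
  stopifnot(inherits(m, "omics_matrix"))
  comparator <- match.arg(comparator)
  if (ncol(m$values) < 2) {
    stop("filter_by_sd: standard deviation undefined with fewer than 2 samples",
         call. = FALSE)
  }
  sds <- row_sds(m$values)
  keep <- if (comparator == "ge") sds >= sd_threshold else sds > sd_threshold
  restrict(m, features = rownames(m$values)[keep])
}

row_sds <- function(v) {
  n <- ncol(v)
  mu <- rowMeans(v)
  sqrt(pmax(rowSums((v - mu)^2), 0) / (n - 1))
}

#' Partition (k-means) clustering of samples
#'
#' Clusters samples as points in feature space with Euclidean k-means,
#' keeping the best of `restarts` random initializations by within-cluster
#' sum of squares. Deterministic for a fixed seed. Methylation samples are
#' clustered unstandardized.
#'
#' @param m A `beta_matrix` or `expr_matrix`.
#' @param k Number of clusters (>= 2, < number of samples).
#' @param seed Integer RNG seed.
#' @param restarts Number of random restarts.
#' @return A list with `assignment` (named integer vector per sample),
#'   `centers` (k x features matrix) and `inertia` (total within-cluster sum
#'   of squares).
#' @export
partition_cluster <- function(m, k, seed = 1L, restarts = 50L) {
  stopifnot(inherits(m, "omics_matrix"))
  n <- ncol(m$values)
  if (k < 2) stop("partition_cluster: k must be >= 2", call. = FALSE)
  if (k >= n) {
    stop("partition_cluster: k must be smaller than the number of samples",
         call. = FALSE)
  }
  x <- t(m$values)
  set.seed(seed)
  fit <- NULL
  for (attempt in 1:5) {
    fit <- tryCatch(
      stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100),
      error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    stop("partition_cluster: degenerate clustering (", conditionMessage(fit),
         ")", call. = FALSE)
  }
  assignment <- fit$cluster
  names(assignment) <- colnames(m$values)
  list(assignment = assignment, centers = fit$centers,
       inertia = fit$tot.withinss)
}

#' Davies-Bouldin cluster-separation index
#'
#' DB = (1/k) * sum_i max_{j != i} (s_i + s_j) / d(c_i, c_j), where s_i is
#' the mean Euclidean distance of cluster i's members to their centroid and
#' d(c_i, c_j) the Euclidean centroid distance. Lower is better.
#'
#' @param assignment Integer cluster label per sample (>= 2 distinct values).
#' @param points Samples-by-features numeric matrix, rows aligned with
#'   `assignment`.
#' @return The (nonnegative) Davies-Bouldin score.
#' @export
davies_bouldin <- function(assignment, points) {
  points <- as.matrix(points)
  stopifnot(length(assignment) == nrow(points))
  labels <- sort(unique(assignment))
  k <- length(labels)
  if (k < 2) stop("davies_bouldin: need at least 2 clusters", call. = FALSE)
  centroids <- t(vapply(labels, function(l) {
    colMeans(points[assignment == l, , drop = FALSE])
  }, numeric(ncol(points))))
  scatter <- vapply(seq_along(labels), function(i) {
    mem <- points[assignment == labels[i], , drop = FALSE]
    mean(sqrt(rowSums((mem - rep(centroids[i, ], each = nrow(mem)))^2)))
  }, numeric(1))
  dmat <- as.matrix(stats::dist(centroids))
  if (any(dmat[upper.tri(dmat)] == 0)) {
    stop("davies_bouldin: degenerate clustering (coincident centroids)",
         call. = FALSE)
  }
  ratios <- outer(scatter, scatter, "+") / dmat
  diag(ratios) <- -Inf
  mean(apply(ratios, 1, max))
}

#' Discover G-CIMP subtypes from a methylation matrix
#'
#' Runs partition clustering for each k in the configured range, selects the
#' k minimizing the Davies-Bouldin score, and when k = 2 labels the larger
#' cluster G-CIMP negative and the smaller one G-CIMP positive. A size tie is
#' resolved by mean beta value (the hypermethylated cluster is POS). When the
#' selected k is not 2, cluster indices are returned without POS/NEG labels
#' and the report status says so.
#'
#' @param m A `beta_matrix`, typically already variance-filtered.
#' @param config A [pipeline_config()].
#' @param sd_filter Apply `filter_by_sd(m, config$meth_sd_threshold, "ge")`
#'   first. Default `FALSE` (filtering is usually an explicit upstream step).
#' @return A list with `calls` (data frame `sample_id`, `cluster`, `label`)
#'   and `report` (`k_tried`, `db_score_per_k`, `chosen_k`, `cluster_sizes`,
#'   `inertia`, `status`).
#' @export
discover_subtypes <- function(m, config = pipeline_config(),
                              sd_filter = FALSE) {
  stopifnot(inherits(m, "beta_matrix"))
  if (sd_filter) m <- filter_by_sd(m, config$meth_sd_threshold, "ge")
  k_range <- config$k_range
  n <- ncol(m$values)
  k_range <- k_range[k_range < n]
  if (length(k_range) == 0) {
    stop("discover_subtypes: no feasible k below the sample count",
         call. = FALSE)
  }
  fits <- lapply(k_range, function(k) {
    partition_cluster(m, k, seed = config$rng_seed,
                      restarts = config$kmeans_restarts)
  })
  pts <- t(m$values)
  db <- vapply(fits, function(f) davies_bouldin(f$assignment, pts), numeric(1))
  best <- which.min(db)
  chosen_k <- k_range[best]
  fit <- fits[[best]]
  sizes <- as.integer(table(fit$assignment))

  calls <- data.frame(sample_id = names(fit$assignment),
                      cluster = as.integer(fit$assignment),
                      label = NA_character_, stringsAsFactors = FALSE)
  status <- "ok"
  if (chosen_k == 2) {
    s1 <- sum(fit$assignment == 1); s2 <- sum(fit$assignment == 2)
    if (s1 == s2) {
      mb <- vapply(1:2, function(l) mean(m$values[, fit$assignment == l]),
                   numeric(1))
      pos_cluster <- which.max(mb)
      warning("discover_subtypes: size tie at k = 2 resolved by mean beta",
              call. = FALSE)
    } else {
      pos_cluster <- if (s1 < s2) 1L else 2L
    }
    calls$label <- ifelse(calls$cluster == pos_cluster, "POS", "NEG")
  } else {
    status <- "no-two-cluster-labeling"
    warning("discover_subtypes: selected k = ", chosen_k,
            "; POS/NEG labels are only defined for k = 2", call. = FALSE)
  }
  list(calls = calls,
       report = list(k_tried = k_range, db_score_per_k = db,
                     chosen_k = chosen_k, cluster_sizes = sizes,
                     inertia = fit$inertia, status = status))
}

#' Principal-component scores on the correlation matrix
#'
#' PCA of the feature-standardized data (i.e. on the correlation dispersion
#' matrix) with unit-normalized eigenvectors; used for QC plots of cluster
#' structure. Zero-variance features are dropped with a warning.
#'
#' @param m A `beta_matrix` or `expr_matrix`.
#' @param n_components Number of components to return.
#' @return A list with `scores` (samples x components), `var_explained`
#'   (proportion per returned component) and `dropped` (zero-variance
#'   feature ids).
#' @export
pca_scores <- function(m, n_components = 2L) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  sds <- row_sds(v)
  dropped <- rownames(v)[sds == 0]
  if (length(dropped)) {
    warning("pca_scores: dropping ", length(dropped),
            " zero-variance feature(s)", call. = FALSE)
    v <- v[sds > 0, , drop = FALSE]
  }
  if (nrow(v) < 2) {
    stop("pca_scores: need at least 2 features with nonzero variance",
         call. = FALSE)
  }
  p <- stats::prcomp(t(v), center = TRUE, scale. = TRUE)
  nc <- min(n_components, ncol(p$x))
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(nc), drop = FALSE],
       var_explained = ve[seq_len(nc)], dropped = dropped)
}
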