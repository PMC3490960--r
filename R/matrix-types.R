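#' Methylation beta-value matrix
#'
#' Container for a sites-by-samples matrix of Illumina-style beta values
#' (methylated / (methylated + unmethylated) probe intensity, in \[0, 1\]),
#' optionally carrying a detection p-value matrix of identical shape.
#'
#' @param values Numeric matrix, sites in rows, samples in columns. Row and
#'   column names are required, must be unique, and all values must lie in
#'   \[0, 1\] with no missing entries.
#' @param detection_p Optional numeric matrix of per-site, per-sample detection
#'   p-values in \[0, 1\], aligned index-for-index with `values`.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, detection_p = NULL) {
  check_feature_matrix(values, "methylation")
  if (anyNA(values)) {
    stop("beta_matrix: missing values are not allowed; ",
         "drop incomplete sites before construction", call. = FALSE)
  }
  if (any(values < 0 | values > 1)) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("beta_matrix: value out of [0,1] at site '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]),
         call. = FALSE)
  }
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(values))) {
      stop("beta_matrix: detection_p must have the same shape as values",
           call. = FALSE)
    }
    dimnames(detection_p) <- dimnames(values)
    if (anyNA(detection_p) || any(detection_p < 0 | detection_p > 1)) {
      stop("beta_matrix: detection p-values must lie in [0,1]", call. = FALSE)
    }
  }
  structure(list(values = values, detection_p = detection_p),
            class = c("beta_matrix", "omics_matrix"))
}

#' Log-scale expression matrix
#'
#' Container for a probe-sets-by-samples matrix of log-scale expression
#' intensities (e.g. RMA-normalized microarray data).
#'
#' @param values Numeric matrix, probe sets in rows, samples in columns, with
#'   unique row and column names and finite values.
#' @param platform Free-text platform/batch tag (e.g. `"U133A"`).
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, platform = "unknown") {
  check_feature_matrix(values, "expression")
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "expr_matrix: non-finite value at probe '%s', sample '%s'",
      rownames(values)[bad[1]], colnames(values)[bad[2]]), call. = FALSE)
  }
  structure(list(values = values, platform = as.character(platform)[1]),
            class = c("expr_matrix", "omics_matrix"))
}

check_feature_matrix <- function(values, what) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop(sprintf("%s matrix: 'values' must be a numeric matrix", what),
         call. = FALSE)
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (nrow(values) > 0 && is.null(fid)) {
    stop(sprintf("%s matrix: feature ids (rownames) are required", what),
         call. = FALSE)
  }
  if (ncol(values) > 0 && is.null(sid)) {
    stop(sprintf("%s matrix: sample ids (colnames) are required", what),
         call. = FALSE)
  }
  if (anyDuplicated(fid)) {
    stop(sprintf("%s matrix: duplicate feature id '%s'", what,
                 fid[duplicated(fid)][1]), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop(sprintf("%s matrix: duplicate sample id '%s'", what,
                 sid[duplicated(sid)][1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.omics_matrix <- function(x, ...) {
  kind <- if (inherits(x, "beta_matrix")) "beta_matrix" else "expr_matrix"
  cat(sprintf("<%s> %d features x %d samples\n", kind,
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$detection_p)) cat("  with detection p-values\n")
  if (!is.null(x$platform)) cat("  platform:", x$platform, "\n")
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Feature and sample identifiers of an omics matrix
#' @param x A `beta_matrix` or `expr_matrix`.
#' @return Character vector of ids.
#' @export
features <- function(x) rownames(x$values) %||% character(0)

#' @rdname features
#' @export
samples <- function(x) colnames(x$values) %||% character(0)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restrict an omics matrix to a subset of features or samples
#'
#' @param x A `beta_matrix` or `expr_matrix`.
#' @param features,samples Character vectors of ids to keep (in the given
#'   order); `NULL` keeps everything.
#' @return An object of the same class as `x`.
#' @export
restrict <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  v <- x$values
  dp <- x$detection_p
  if (!is.null(features)) {
    missing_f <- setdiff(features, rownames(v))
    if (length(missing_f)) {
      stop("restrict: unknown feature id(s): ",
           paste(utils::head(missing_f, 5), collapse = ", "), call. = FALSE)
    }
    v <- v[features, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(v))
    if (length(missing_s)) {
      stop("restrict: unknown sample id(s): ",
           paste(utils::head(missing_s, 5), collapse = ", "), call. = FALSE)
    }
    v <- v[, samples, drop = FALSE]
    if (!is.null(dp)) dp <- dp[, samples, drop = FALSE]
  }
  if (inherits(x, "beta_matrix")) beta_matrix(v, dp)
  else expr_matrix(v, x$platform)
}

#' Pipeline configuration
#'
#' Bundles the numeric constants used across the pipeline: variance and
#' detection filters, the clustering k range, the five classifier model sizes,
#' the FDR level for survival screens, and clustering seeds/restarts.
#'
#' @param meth_sd_threshold Methylation SD filter threshold (kept when
#'   SD >= threshold). Default 0.2.
#' @param expr_sd_threshold Expression SD filter threshold (kept when
#'   SD > threshold). Default 1.0.
#' @param k_range Integer vector of cluster counts tried. Default 2:5.
#' @param model_sizes Ascending integer vector of top-N model sizes.
#'   Default c(10, 25, 50, 100, 200).
#' @param detection_p_threshold Detection p-value cut (strict `<`). Default 0.05.
#' @param fdr_level Benjamini-Hochberg FDR level. Default 0.05.
#' @param rng_seed Seed used by clustering and cross-validation. Default 1.
#' @param kmeans_restarts Number of random k-means restarts. Default 50.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(meth_sd_threshold = 0.2,
                            expr_sd_threshold = 1.0,
                            k_range = 2:5,
                            model_sizes = c(10L, 25L, 50L, 100L, 200L),
                            detection_p_threshold = 0.05,
                            fdr_level = 0.05,
                            rng_seed = 1L,
                            kmeans_restarts = 50L) {
  stopifnot(meth_sd_threshold > 0, expr_sd_threshold > 0,
            detection_p_threshold > 0, fdr_level > 0, fdr_level < 1,
            all(k_range >= 2), length(model_sizes) >= 1,
            !is.unsorted(model_sizes, strictly = TRUE),
            all(model_sizes >= 1), kmeans_restarts >= 1)
  structure(list(
    meth_sd_threshold = meth_sd_threshold,
    expr_sd_threshold = expr_sd_threshold,
    k_range = as.integer(k_range),
    model_sizes = as.integer(model_sizes),
    detection_p_threshold = detection_p_threshold,
    fdr_level = fdr_level,
    rng_seed = as.integer(rng_seed),
    kmeans_restarts = as.integer(kmeans_restarts)
  ), class = "pipeline_config")
}
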