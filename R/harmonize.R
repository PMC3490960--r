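#' Average-linkage hierarchical clustering of samples
#'
#' Samples are clustered on Euclidean distances after per-sample column
#' standardization (each sample z-scored across features), the standard QC
#' configuration for expression data; methylation is clustered
#' unstandardized by passing `standardize = FALSE`.
#'
#' @param m A `beta_matrix` or `expr_matrix`.
#' @param n_groups Number of groups to cut the tree into.
#' @param standardize Z-score each sample column first. Default `TRUE`.
#' @return Named integer vector of group memberships per sample.
#' @export
hierarchical_cluster <- function(m, n_groups, standardize = TRUE) {
  stopifnot(inherits(m, "omics_matrix"))
  n <- ncol(m$values)
  if (n_groups > n) {
    stop("hierarchical_cluster: more groups than samples", call. = FALSE)
  }
  v <- m$values
  if (standardize) v <- standardize_samples(v)
  hc <- stats::hclust(stats::dist(t(v)), method = "average")
  stats::cutree(hc, k = n_groups)
}

standardize_samples <- function(v) {
  mu <- colMeans(v)
  s <- apply(v, 2, stats::sd)
  s[s == 0] <- 1
  sweep(sweep(v, 2, mu), 2, s, "/")
}

#' Flag tumors that co-cluster with normal brain samples
#'
#' Restricts to high-variance features (SD > the configured expression
#' threshold), cuts an average-linkage tree into two groups, and flags every
#' tumor falling in the group that holds the majority of normals — the
#' operational rule for likely normal-tissue contamination.
#'
#' @param m An `expr_matrix` containing tumors and at least two normals.
#' @param annotations Annotation data frame covering `samples(m)`.
#' @param config A [pipeline_config()].
#' @return A list with `flagged` (tumor sample ids), `membership`
#'   (data frame of sample, group, tissue) and `n_features_used`.
#' @export
flag_contaminated <- function(m, annotations, config = pipeline_config()) {
  stopifnot(inherits(m, "expr_matrix"))
  validate_annotation(annotations)
  ann <- annotations[match(samples(m), annotations$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id)) {
    stop("flag_contaminated: annotation missing for some samples", call. = FALSE)
  }
  normals <- ann$sample_id[ann$tissue == "normal"]
  if (length(normals) < 2) {
    stop("flag_contaminated: need at least 2 normal samples", call. = FALSE)
  }
  mf <- filter_by_sd(m, config$expr_sd_threshold, "gt")
  if (nrow(mf$values) < 2) {
    stop("flag_contaminated: fewer than 2 features pass the variance filter",
         call. = FALSE)
  }
  grp <- hierarchical_cluster(mf, 2, standardize = TRUE)
  n_in <- c(sum(grp[normals] == 1), sum(grp[normals] == 2))
  if (n_in[1] == n_in[2]) {
    stop("flag_contaminated: normals split evenly between groups; ",
         "manual review required", call. = FALSE)
  }
  normal_grp <- which.max(n_in)
  tumors <- ann$sample_id[ann$tissue == "tumor"]
  flagged <- tumors[grp[tumors] == normal_grp]
  list(flagged = flagged,
       membership = data.frame(sample_id = names(grp),
                               group = as.integer(grp),
                               tissue = ann$tissue[match(names(grp),
                                                         ann$sample_id)],
                               stringsAsFactors = FALSE),
       n_features_used = nrow(mf$values))
}

#' Fit a per-feature additive batch/tissue ANOVA model
#'
#' For every feature, fits value = grand mean + batch effect (+ tissue
#' effect) + residual by least squares with sum-to-zero effect coding and no
#' interaction. This is the additive fixed-effects form of ANOVA-style batch
#' correction for a two-batch, two-tissue design.
#'
#' @param m An `expr_matrix` over the combined cohort.
#' @param annotations Annotation data frame covering `samples(m)`.
#' @param factors Model terms, a subset of `c("batch", "tissue")`.
#' @return A list of class `batch_model_fit` with per-feature `grand_mean`,
#'   `batch_effects` (features x batch levels, rows summing to zero),
#'   optional `tissue_effects`, and the sample-to-batch map used.
#' @export
fit_batch_model <- function(m, annotations, factors = c("batch", "tissue")) {
  stopifnot(inherits(m, "expr_matrix"))
  factors <- match.arg(factors, c("batch", "tissue"), several.ok = TRUE)
  if (!"batch" %in% factors) {
    stop("fit_batch_model: 'batch' must be among the model factors",
         call. = FALSE)
  }
  validate_annotation(annotations)
  ann <- annotations[match(samples(m), annotations$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id)) {
    stop("fit_batch_model: annotation missing for some samples", call. = FALSE)
  }
  batch <- factor(ann$batch)
  if (nlevels(batch) < 2) {
    stop("fit_batch_model: need at least 2 batches", call. = FALSE)
  }
  if (any(table(batch) == 1)) {
    warning("fit_batch_model: a batch has a single sample; ",
            "estimates will be unstable", call. = FALSE)
  }
  terms <- list(batch = batch)
  if ("tissue" %in% factors) {
    tissue <- factor(ann$tissue, levels = c("tumor", "normal"))
    if (nlevels(droplevels(tissue)) < 2) {
      stop("fit_batch_model: tissue factor requested but only one tissue present",
           call. = FALSE)
    }
    if (any(table(batch, tissue) == 0)) {
      stop("fit_batch_model: empty batch x tissue cell", call. = FALSE)
    }
    terms$tissue <- tissue
  }
  mk_sum <- function(f) {
    cm <- stats::contr.sum(nlevels(f))
    cm[as.integer(f), , drop = FALSE]
  }
  X <- cbind(`(Intercept)` = 1, do.call(cbind, lapply(terms, mk_sum)))
  fit <- stats::lm.fit(X, t(m$values))
  B <- t(fit$coefficients)  # features x coefficients

  decode <- function(f, cols) {
    eff <- cbind(B[, cols, drop = FALSE], -rowSums(B[, cols, drop = FALSE]))
    colnames(eff) <- levels(f)
    rownames(eff) <- features(m)
    eff
  }
  nb <- nlevels(batch)
  batch_cols <- 1 + seq_len(nb - 1)
  out <- list(grand_mean = stats::setNames(B[, 1], features(m)),
              batch_effects = decode(batch, batch_cols),
              tissue_effects = NULL,
              factors = factors,
              sample_batch = stats::setNames(as.character(batch),
                                             samples(m)))
  if ("tissue" %in% factors) {
    nt <- nlevels(terms$tissue)
    out$tissue_effects <- decode(terms$tissue,
                                 1 + (nb - 1) + seq_len(nt - 1))
  }
  structure(out, class = "batch_model_fit")
}

#' Subtract estimated batch effects from an expression matrix
#'
#' Each sample's per-feature batch effect is subtracted; tissue effects (when
#' fitted) are deliberately retained. Refitting the batch model on corrected
#' data yields effects of (numerically) zero.
#'
#' @param m An `expr_matrix`; its features must all be covered by the fit.
#' @param fit A `batch_model_fit`.
#' @param annotations Optional annotation supplying each sample's batch;
#'   defaults to the sample-to-batch map stored in the fit.
#' @return The corrected `expr_matrix`.
#' @export
remove_batch <- function(m, fit, annotations = NULL) {
  stopifnot(inherits(m, "expr_matrix"), inherits(fit, "batch_model_fit"))
  if (!all(features(m) %in% rownames(fit$batch_effects))) {
    stop("remove_batch: fit does not cover all features of the matrix",
         call. = FALSE)
  }
  if (is.null(annotations)) {
    batch <- fit$sample_batch[samples(m)]
    if (anyNA(batch)) {
      stop("remove_batch: no batch known for sample '",
           samples(m)[which(is.na(batch))[1]], "'", call. = FALSE)
    }
  } else {
    validate_annotation(annotations)
    batch <- annotations$batch[match(samples(m), annotations$sample_id)]
    if (anyNA(batch)) {
      stop("remove_batch: annotation missing for some samples", call. = FALSE)
    }
  }
  unknown <- setdiff(unique(batch), colnames(fit$batch_effects))
  if (length(unknown)) {
    stop("remove_batch: unknown batch label '", unknown[1], "'", call. = FALSE)
  }
  eff <- fit$batch_effects[features(m), batch, drop = FALSE]
  expr_matrix(m$values - eff, platform = m$platform)
}

#' Harmonize two expression cohorts for cross-platform classification
#'
#' Executes the two-pass integration protocol: contamination-filter each
#' cohort against its normals, intersect features, combine, fit
#' batch + tissue effects on the full combined set and validate that normals
#' from both cohorts co-cluster after correction, then drop normals, refit on
#' batch alone over tumors, and remove that batch effect. Returns the
#' corrected tumor-only matrix plus the validation and contamination reports.
#'
#' @param a,b `expr_matrix` cohorts (e.g. reference and external). If `b` is
#'   `NULL` the contamination-filtered `a` is returned unchanged.
#' @param annotations Annotation covering all samples of both matrices.
#' @param config A [pipeline_config()].
#' @return A list with `matrix` (tumor-only corrected `expr_matrix`),
#'   `contamination` (per-batch reports), `validation`
#'   (`normal_purity` in \[0.5, 1\]: fraction of normals in their majority
#'   group after pass-1 correction) and `fits` (pass-1 and pass-2 models).
#' @export
harmonize <- function(a, b = NULL, annotations, config = pipeline_config()) {
  validate_annotation(annotations)
  screen1 <- flag_contaminated(a, annotations, config)
  a <- drop_samples(a, screen1$flagged)
  if (is.null(b)) {
    tumors <- tumor_samples(annotations, samples(a))
    return(list(matrix = restrict(a, samples = tumors),
                contamination = list(screen1), validation = NULL,
                fits = NULL))
  }
  screen2 <- flag_contaminated(b, annotations, config)
  b <- drop_samples(b, screen2$flagged)

  both <- intersect_features(a, b)
  combined <- expr_matrix(cbind(both$a$values, both$b$values),
                          platform = "combined")

  fit1 <- fit_batch_model(combined, annotations, c("batch", "tissue"))
  corrected1 <- remove_batch(combined, fit1)
  normal_purity <- normal_cocluster_purity(corrected1, annotations, config)

  tumors <- tumor_samples(annotations, samples(combined))
  tumor_m <- restrict(combined, samples = tumors)
  fit2 <- fit_batch_model(tumor_m, annotations, "batch")
  corrected <- remove_batch(tumor_m, fit2)

  list(matrix = corrected,
       contamination = list(screen1, screen2),
       validation = list(normal_purity = normal_purity),
       fits = list(pass1 = fit1, pass2 = fit2))
}

tumor_samples <- function(annotations, ids) {
  ann <- annotations[match(ids, annotations$sample_id), , drop = FALSE]
  ids[ann$tissue == "tumor"]
}

drop_samples <- function(m, ids) {
  keep <- setdiff(samples(m), ids)
  restrict(m, samples = keep)
}

normal_cocluster_purity <- function(m, annotations, config) {
  ann <- annotations[match(samples(m), annotations$sample_id), , drop = FALSE]
  normals <- ann$sample_id[ann$tissue == "normal"]
  if (length(normals) < 2) return(NA_real_)
  mf <- tryCatch(filter_by_sd(m, config$expr_sd_threshold, "gt"),
                 error = function(e) m)
  if (nrow(mf$values) < 2) mf <- m
  grp <- hierarchical_cluster(mf, 2, standardize = TRUE)
  max(table(grp[normals])) / length(normals)
}
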