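#' Rank features by differential expression between subtypes
#'
#' Computes a pooled-variance two-sample t statistic per feature and ranks by
#' absolute value, descending; ties are broken lexicographically by feature
#' id so rankings are reproducible. A feature with zero pooled variance and
#' equal class means gets t = 0; zero variance with unequal means is ranked
#' first (infinite separation).
#'
#' @param m An `expr_matrix`.
#' @param labels Named `"POS"`/`"NEG"` vector covering `samples(m)` (at least
#'   two samples per class).
#' @return Data frame `feature_id`, `t`, `p` ordered by rank.
#' @export
rank_differential_features <- function(m, labels) {
  stopifnot(inherits(m, "expr_matrix"))
  labels <- labels[samples(m)]
  if (anyNA(labels) || !all(labels %in% c("POS", "NEG"))) {
    stop("rank_differential_features: labels must cover all samples with POS/NEG",
         call. = FALSE)
  }
  n1 <- sum(labels == "POS"); n2 <- sum(labels == "NEG")
  if (n1 < 2 || n2 < 2) {
    stop("rank_differential_features: need at least 2 samples per class",
         call. = FALSE)
  }
  v <- m$values
  v1 <- v[, labels == "POS", drop = FALSE]
  v2 <- v[, labels == "NEG", drop = FALSE]
  m1 <- rowMeans(v1); m2 <- rowMeans(v2)
  s1 <- rowSums((v1 - m1)^2); s2 <- rowSums((v2 - m2)^2)
  sp2 <- (s1 + s2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, (m1 - m2) / se,
               ifelse(m1 == m2, 0, sign(m1 - m2) * Inf))
  df <- n1 + n2 - 2
  p <- ifelse(is.infinite(tt), 0, 2 * stats::pt(-abs(tt), df))
  ord <- order(-abs(tt), rownames(v))
  data.frame(feature_id = rownames(v)[ord], t = tt[ord], p = p[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the nested top-N 1-NN prediction models
#'
#' One shared differential-expression ranking is computed on the training
#' data; model k keeps the top `model_sizes[k]` features, so smaller models'
#' feature lists are prefixes of larger ones.
#'
#' @param m Training `expr_matrix`.
#' @param labels Named POS/NEG training labels.
#' @param config A [pipeline_config()] (supplies `model_sizes`).
#' @return List of `prediction_model` objects, one per model size.
#' @export
build_models <- function(m, labels, config = pipeline_config()) {
  ranking <- rank_differential_features(m, labels)
  sizes <- config$model_sizes
  if (max(sizes) > nrow(m$values)) {
    stop("build_models: model size ", max(sizes), " exceeds the ",
         nrow(m$values), " available features", call. = FALSE)
  }
  labels <- labels[samples(m)]
  lapply(sizes, function(sz) {
    fids <- ranking$feature_id[seq_len(sz)]
    structure(list(model_size = as.integer(sz),
                   feature_ids = fids,
                   training_values = m$values[fids, , drop = FALSE],
                   training_labels = labels),
              class = "prediction_model")
  })
}

#' Classify samples with a single nearest-neighbor model
#'
#' Each query sample receives the label of the Euclidean-nearest training
#' sample over the model's features. Exact distance ties are broken by the
#' lexicographically smallest training sample id.
#'
#' @param model A `prediction_model`.
#' @param query An `expr_matrix` (or feature-by-sample matrix) containing all
#'   model features.
#' @return Named character vector of POS/NEG calls per query sample.
#' @export
predict_1nn <- function(model, query) {
  stopifnot(inherits(model, "prediction_model"))
  qv <- if (inherits(query, "omics_matrix")) query$values else as.matrix(query)
  missing_f <- setdiff(model$feature_ids, rownames(qv))
  if (length(missing_f)) {
    stop("predict_1nn: query lacks model feature '", missing_f[1], "'",
         call. = FALSE)
  }
  tv <- model$training_values[model$feature_ids, , drop = FALSE]
  qv <- qv[model$feature_ids, , drop = FALSE]
  # squared distances: |q|^2 + |t|^2 - 2 q.t  (queries x training)
  d2 <- outer(colSums(qv^2), colSums(tv^2), "+") - 2 * crossprod(qv, tv)
  train_ids <- colnames(tv)
  calls <- apply(d2, 1, function(row) {
    cand <- train_ids[row == min(row)]
    model$training_labels[[sort(cand)[1]]]
  })
  stats::setNames(as.character(calls), colnames(qv))
}

#' Combine five model calls into a consensus G-CIMP call
#'
#' A sample is called POS or NEG only when all five models agree; any
#' disagreement yields the abstention call `"NC"` (Non-Consistent).
#'
#' @param calls Samples-by-five character matrix (or data frame) of POS/NEG
#'   calls, columns in model-size order.
#' @return Data frame with one call column per model plus `final`.
#' @export
consensus_call <- function(calls) {
  calls <- as.matrix(calls)
  if (ncol(calls) != 5) {
    stop("consensus_call: expected exactly five calls per sample, got ",
         ncol(calls), call. = FALSE)
  }
  if (!all(calls %in% c("POS", "NEG"))) {
    stop("consensus_call: calls must be POS or NEG", call. = FALSE)
  }
  final <- if (nrow(calls)) {
    apply(calls, 1, function(x) if (length(unique(x)) == 1) x[1] else "NC")
  } else character(0)
  ids <- rownames(calls) %||% character(nrow(calls))
  out <- cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE),
               as.data.frame(calls, stringsAsFactors = FALSE),
               data.frame(final = final, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Predict consensus G-CIMP calls with a model ensemble
#'
#' @param models List of `prediction_model`s from [build_models()].
#' @param query Query `expr_matrix`.
#' @return Consensus data frame (see [consensus_call()]).
#' @export
predict_consensus <- function(models, query) {
  per_model <- vapply(models, predict_1nn, character(ncol(query$values)),
                      query = query)
  if (is.null(dim(per_model))) {
    per_model <- matrix(per_model, nrow = ncol(query$values),
                        dimnames = list(samples(query), NULL))
  }
  colnames(per_model) <- paste0("call_", vapply(models, `[[`, 1L, "model_size"))
  rownames(per_model) <- samples(query)
  consensus_call(per_model)
}

#' Two-fold cross-validation of the consensus classifier
#'
#' Samples are split into stratified random halves; within each orientation
#' the feature ranking and all five models are rebuilt on the training half
#' only (no selection leakage) and the held-out half is consensus-called.
#' Accuracy counts NC as an error; `accuracy_called` restricts to samples
#' where a call was made.
#'
#' @param m Tumor `expr_matrix`.
#' @param labels Named POS/NEG truth covering `samples(m)`.
#' @param config A [pipeline_config()].
#' @param seed RNG seed for the split.
#' @return A list with `accuracy`, `accuracy_called`, `nc_rate`, per-fold
#'   summaries and the full call table.
#' @export
two_fold_cv <- function(m, labels, config = pipeline_config(), seed = 1L) {
  labels <- labels[samples(m)]
  if (anyNA(labels)) {
    stop("two_fold_cv: labels must cover all samples", call. = FALSE)
  }
  set.seed(seed)
  fold <- stats::setNames(integer(length(labels)), samples(m))
  for (cl in c("POS", "NEG")) {
    ids <- samples(m)[labels == cl]
    if (length(ids) < 4) {
      stop("two_fold_cv: class ", cl,
           " too small to stratify into two folds", call. = FALSE)
    }
    ids <- sample(ids)
    fold[ids] <- rep(1:2, length.out = length(ids))
  }
  folds <- list(`1` = names(fold)[fold == 1], `2` = names(fold)[fold == 2])

  all_calls <- list()
  per_fold <- list()
  for (o in 1:2) {
    train_ids <- folds[[o]]
    test_ids <- folds[[3 - o]]
    models <- build_models(restrict(m, samples = train_ids),
                           labels[train_ids], config)
    res <- predict_consensus(models, restrict(m, samples = test_ids))
    res$truth <- unname(labels[res$sample_id])
    res$fold <- o
    all_calls[[o]] <- res
    per_fold[[o]] <- list(
      n_test = nrow(res),
      accuracy = mean(res$final == res$truth),
      nc = sum(res$final == "NC"))
  }
  calls <- do.call(rbind, all_calls)
  called <- calls$final != "NC"
  list(accuracy = mean(calls$final == calls$truth),
       accuracy_called = if (any(called))
         mean(calls$final[called] == calls$truth[called]) else NA_real_,
       nc_rate = mean(!called),
       per_fold = per_fold,
       calls = calls)
}

#' Abstention rate on ambiguous samples
#'
#' Applies the model ensemble to queries and reports the fraction receiving
#' the Non-Consistent consensus call; used to verify that samples lying
#' between the two methylation archetypes are flagged rather than forced
#' into a subtype.
#'
#' @param models List of `prediction_model`s.
#' @param query Query `expr_matrix` (may be empty).
#' @return A list with `nc_rate` (`NA` for an empty query) and the call
#'   table.
#' @export
ambiguity_behavior <- function(models, query) {
  if (ncol(query$values) == 0) {
    return(list(nc_rate = NA_real_,
                calls = data.frame(sample_id = character(0),
                                   final = character(0))))
  }
  res <- predict_consensus(models, query)
  list(nc_rate = mean(res$final == "NC"), calls = res)
}

#' Serialize or restore a prediction model as JSON
#'
#' @param model A `prediction_model`.
#' @param path File path.
#' @return `read_model` returns the restored `prediction_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "prediction_model"))
  obj <- list(model_size = model$model_size,
              feature_ids = model$feature_ids,
              training = list(sample_ids = colnames(model$training_values),
                              labels = unname(model$training_labels),
                              matrix = unname(model$training_values)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tv <- matrix(obj$training$matrix,
               nrow = length(obj$feature_ids),
               dimnames = list(obj$feature_ids, obj$training$sample_ids))
  structure(list(model_size = as.integer(obj$model_size),
                 feature_ids = obj$feature_ids,
                 training_values = tv,
                 training_labels = stats::setNames(obj$training$labels,
                                                   obj$training$sample_ids)),
            class = "prediction_model")
}
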