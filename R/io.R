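#' Read a feature-by-sample matrix from a TSV file
#'
#' The supported dialect is tab-separated text: the first header cell is the
#' literal token `feature_id`, the remaining header cells are sample ids, and
#' each subsequent row is a feature id followed by numeric values. This is the
#' exact dialect [write_matrix()] produces.
#'
#' @param path Path to a TSV file.
#' @param kind Either `"methylation"` (values validated to \[0, 1\]) or
#'   `"expression"`.
#' @param drop_incomplete Drop features with any missing value instead of
#'   erroring. Defaults to `TRUE` for methylation (mirroring the use of
#'   complete sites only) and is ignored for expression, where any
#'   non-numeric cell is an error.
#' @return A [beta_matrix()] or [expr_matrix()].
#' @export
read_matrix <- function(path, kind = c("methylation", "expression"),
                        drop_incomplete = (kind == "methylation")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("read_matrix: no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 1 || names(raw)[1] != "feature_id") {
    stop("read_matrix: first header cell must be 'feature_id' (got '",
         names(raw)[1], "')", call. = FALSE)
  }
  fid <- raw[[1]]
  sid <- names(raw)[-1]
  if (anyDuplicated(fid)) {
    stop("read_matrix: duplicate feature id '", fid[duplicated(fid)][1], "'",
         call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("read_matrix: duplicate sample id '", sid[duplicated(sid)][1], "'",
         call. = FALSE)
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  dimnames(vals) <- list(fid, sid)
  bad <- is.na(vals)
  if (any(bad)) {
    if (kind == "methylation" && isTRUE(drop_incomplete)) {
      keep <- rowSums(bad) == 0
      vals <- vals[keep, , drop = FALSE]
    } else {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "read_matrix: non-numeric cell '%s' at feature '%s', sample '%s'",
        body[idx[1], idx[2]], fid[idx[1]], sid[idx[2]]), call. = FALSE)
    }
  }
  if (kind == "methylation") beta_matrix(vals) else expr_matrix(vals)
}

#' Write a feature-by-sample matrix to a TSV file
#'
#' Writes the dialect [read_matrix()] expects; values are serialized with 17
#' significant digits so a read/write round trip reproduces them to well
#' within 1e-12.
#'
#' @param m A `beta_matrix` or `expr_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("write_matrix: cannot open '", path, "' for writing", call. = FALSE)
  })
  on.exit(close(con))
  v <- m$values
  writeLines(paste(c("feature_id", colnames(v)), collapse = "\t"), con)
  if (nrow(v) > 0) {
    body <- apply(v, 2, function(col) sprintf("%.17g", col))
    if (nrow(v) == 1) body <- matrix(body, nrow = 1)
    writeLines(paste(rownames(v),
                     apply(body, 1, paste, collapse = "\t"),
                     sep = if (ncol(v) > 0) "\t" else ""), con)
  }
  invisible(path)
}

#' Restrict two matrices to their shared features
#'
#' Both matrices are reduced to the intersection of their feature ids, in
#' lexicographic order, so that downstream models built on one can be applied
#' to the other. Mirrors cross-platform integration on common probe sets or
#' common methylation sites.
#'
#' @param a,b Two matrices of the same kind.
#' @return A list with elements `a` and `b`, each restricted to the shared
#'   features in identical order.
#' @export
intersect_features <- function(a, b) {
  stopifnot(inherits(a, "omics_matrix"), inherits(b, "omics_matrix"))
  if (!identical(class(a)[1], class(b)[1])) {
    stop("intersect_features: matrices must be of the same kind", call. = FALSE)
  }
  common <- sort(intersect(features(a), features(b)))
  if (length(common) == 0) {
    stop("intersect_features: no shared features", call. = FALSE)
  }
  list(a = restrict(a, features = common), b = restrict(b, features = common))
}

ANNOTATION_COLS <- c("sample_id", "batch", "tissue", "age_years",
                     "survival_days", "event", "true_subtype")

#' Validate a sample annotation table
#'
#' @param ann Data frame with columns `sample_id`, `batch`,
#'   `tissue` (`tumor`/`normal`), `age_years`, `survival_days`, `event`
#'   (1 = death observed, 0 = censored) and `true_subtype`
#'   (`POS`/`NEG`/`AMBIGUOUS`, synthetic ground truth only). Missing optional
#'   values are `NA`.
#' @return `ann`, invisibly, after validation.
#' @export
validate_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  missing_cols <- setdiff(c("sample_id", "batch", "tissue"), names(ann))
  if (length(missing_cols)) {
    stop("annotation: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ann$sample_id)) {
    stop("annotation: duplicate sample_id '",
         ann$sample_id[duplicated(ann$sample_id)][1], "'", call. = FALSE)
  }
  if (any(is.na(ann$batch) | !nzchar(ann$batch))) {
    stop("annotation: batch must be non-empty", call. = FALSE)
  }
  if (!all(ann$tissue %in% c("tumor", "normal"))) {
    stop("annotation: tissue must be 'tumor' or 'normal'", call. = FALSE)
  }
  if ("survival_days" %in% names(ann) && "event" %in% names(ann)) {
    if (any(is.na(ann$survival_days) != is.na(ann$event))) {
      stop("annotation: survival_days must be present iff event is present",
           call. = FALSE)
    }
    ev <- ann$event[!is.na(ann$event)]
    if (length(ev) && !all(ev %in% c(0, 1))) {
      stop("annotation: event must be 0 or 1", call. = FALSE)
    }
    sv <- ann$survival_days[!is.na(ann$survival_days)]
    if (length(sv) && any(sv < 0)) {
      stop("annotation: survival_days must be nonnegative", call. = FALSE)
    }
  }
  if ("true_subtype" %in% names(ann)) {
    ts <- ann$true_subtype[!is.na(ann$true_subtype)]
    if (length(ts) && !all(ts %in% c("POS", "NEG", "AMBIGUOUS"))) {
      stop("annotation: true_subtype must be POS, NEG or AMBIGUOUS",
           call. = FALSE)
    }
  }
  invisible(ann)
}

#' Read or write a sample annotation TSV
#'
#' The annotation file is tab-separated with columns `sample_id`, `batch`,
#' `tissue`, `age_years`, `survival_days`, `event`, `true_subtype`; empty
#' strings encode missing values.
#'
#' @param path File path.
#' @return `read_annotation` returns a validated data frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, na.strings = c("", "NA"),
                           stringsAsFactors = FALSE)
  for (col in c("age_years", "survival_days", "event")) {
    if (col %in% names(ann)) ann[[col]] <- as.numeric(ann[[col]])
  }
  validate_annotation(ann)
  ann
}

#' @rdname read_annotation
#' @param ann Annotation data frame.
#' @export
write_annotation <- function(ann, path) {
  validate_annotation(ann)
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
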