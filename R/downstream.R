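#' Benjamini-Hochberg step-up multiple-testing correction
#'
#' Returns step-up rejection flags at level `alpha` together with BH
#' q-values (monotone, capped at 1). Rejections are exactly the hypotheses
#' with q <= alpha.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return A list with `reject` (logical) and `q` (numeric), aligned with
#'   the input; empty input yields empty output.
#' @export
bh_stepup <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    return(list(reject = logical(0), q = numeric(0)))
  }
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("bh_stepup: p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p_values, method = "BH")
  list(reject = q <= alpha, q = q)
}

#' Per-feature univariate Cox proportional-hazards screen
#'
#' Fits, for every feature, a proportional-hazards model with the feature as
#' the sole continuous covariate (partial likelihood, Breslow tie handling),
#' collects Wald p-values and applies Benjamini-Hochberg correction across
#' all converged features. Zero-variance covariates get p = 1 by convention;
#' non-converged features are flagged and excluded from the q computation.
#'
#' @param m An `expr_matrix`.
#' @param annotations Annotation with `survival_days` and `event`.
#' @param subset Optional character vector of sample ids to screen
#'   (intersected with samples that have survival data).
#' @param fdr_level FDR level for the `significant` flag.
#' @return A list of class `screen_result`: `table` (data frame
#'   `feature_id`, `coef`, `z`, `p`, `q`, `significant`, `converged`),
#'   `n`, `n_events`, `fdr_level`.
#' @export
cox_screen <- function(m, annotations, subset = NULL, fdr_level = 0.05) {
  stopifnot(inherits(m, "expr_matrix"))
  validate_annotation(annotations)
  ids <- samples(m)
  if (!is.null(subset)) ids <- intersect(ids, subset)
  ann <- annotations[match(ids, annotations$sample_id), , drop = FALSE]
  ok <- !is.na(ann$survival_days) & !is.na(ann$event)
  ids <- ids[ok]; ann <- ann[ok, , drop = FALSE]
  if (sum(ann$event) < 2) {
    stop("cox_screen: need at least 2 observed events", call. = FALSE)
  }
  surv <- survival::Surv(ann$survival_days, ann$event)
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 50)
  v <- m$values[, ids, drop = FALSE]

  fit_one <- function(x) {
    if (stats::sd(x) == 0) {
      return(c(coef = 0, z = 0, p = 1, converged = 1))
    }
    fit <- tryCatch(
      suppressWarnings(survival::coxph(surv ~ x, ties = "breslow",
                                       control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit) || is.na(stats::coef(fit)) ||
        !is.finite(sqrt(fit$var[1, 1]))) {
      return(c(coef = NA_real_, z = NA_real_, p = NA_real_, converged = 0))
    }
    b <- unname(stats::coef(fit))
    z <- b / sqrt(fit$var[1, 1])
    conv <- as.numeric(fit$iter < ctrl$iter.max && is.finite(z))
    c(coef = b, z = z, p = 2 * stats::pnorm(-abs(z)), converged = conv)
  }
  res <- t(apply(v, 1, fit_one))
  tab <- data.frame(feature_id = rownames(v), coef = res[, "coef"],
                    z = res[, "z"], p = res[, "p"],
                    converged = res[, "converged"] == 1,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(!tab$converged)) {
    warning("cox_screen: ", sum(!tab$converged),
            " feature(s) failed to converge; excluded from FDR correction",
            call. = FALSE)
  }
  tab$q <- NA_real_
  bh <- bh_stepup(tab$p[tab$converged], fdr_level)
  tab$q[tab$converged] <- bh$q
  tab$significant <- !is.na(tab$q) & tab$q <= fdr_level
  structure(list(table = tab, n = length(ids), n_events = sum(ann$event),
                 fdr_level = fdr_level),
            class = "screen_result")
}

#' Subtype-confounding contrast of survival screens
#'
#' Runs the Cox screen on all tumors and on the majority (NEG) subtype
#' alone, plus an equal-size random-deletion control (removing as many NEG
#' samples as there are POS samples), and summarizes how the sets of
#' survival-associated features change. A collapse of the NEG-only hit count
#' with a stable deletion control indicates that the original associations
#' were driven by subtype membership rather than within-subtype hazard.
#'
#' @param m Tumor `expr_matrix`.
#' @param annotations Annotation with survival columns.
#' @param calls Named POS/NEG subtype call per tumor sample.
#' @param config A [pipeline_config()] (supplies `fdr_level`).
#' @param seed Seed for the random deletion control.
#' @return A list with the three `screen_result`s (`full`, `neg_only`,
#'   `deletion_control`) and a `summary` of hit counts, overlaps and
#'   percent-changed at FDR and at raw p < 0.05.
#' @export
confounding_contrast <- function(m, annotations, calls,
                                 config = pipeline_config(), seed = 1L) {
  ids <- intersect(samples(m), names(calls))
  if (length(ids) < length(samples(m))) {
    stop("confounding_contrast: subtype calls must cover the cohort",
         call. = FALSE)
  }
  pos_ids <- ids[calls[ids] == "POS"]
  neg_ids <- ids[calls[ids] == "NEG"]
  n_del <- length(pos_ids)
  if (n_del > length(neg_ids)) {
    stop("confounding_contrast: deletion count exceeds the NEG group size",
         call. = FALSE)
  }
  full <- cox_screen(m, annotations, subset = ids,
                     fdr_level = config$fdr_level)
  neg_only <- cox_screen(m, annotations, subset = neg_ids,
                         fdr_level = config$fdr_level)
  set.seed(seed)
  kept <- setdiff(ids, sample(neg_ids, n_del))
  control <- cox_screen(m, annotations, subset = kept,
                        fdr_level = config$fdr_level)

  hits <- function(s, raw = FALSE) {
    t <- s$table
    if (raw) t$feature_id[!is.na(t$p) & t$p < 0.05]
    else t$feature_id[t$significant]
  }
  summarize <- function(raw) {
    h_full <- hits(full, raw); h_neg <- hits(neg_only, raw)
    h_ctl <- hits(control, raw)
    list(n_full = length(h_full), n_neg_only = length(h_neg),
         n_control = length(h_ctl),
         shared_full_neg = length(intersect(h_full, h_neg)),
         shared_full_control = length(intersect(h_full, h_ctl)),
         control_retention = if (length(h_full))
           length(intersect(h_full, h_ctl)) / length(h_full) else NA_real_,
         pct_changed_neg = if (length(h_full))
           1 - length(intersect(h_full, h_neg)) / length(h_full) else NA_real_)
  }
  list(full = full, neg_only = neg_only, deletion_control = control,
       summary = list(fdr = summarize(FALSE), raw_p = summarize(TRUE),
                      n_deleted = n_del))
}

#' Welch two-sample t-test on patient age
#'
#' @param age Numeric ages (years); missing values are dropped and counted.
#' @param group Two-level grouping aligned with `age`.
#' @return A list with `t`, `df`, `p`, per-group `n` and medians, and
#'   `n_dropped`.
#' @export
compare_age <- function(age, group) {
  stopifnot(length(age) == length(group))
  keep <- !is.na(age) & !is.na(group)
  n_dropped <- sum(!keep)
  age <- age[keep]
  group <- factor(group, levels = unique(group))[keep]  # first-seen order
  if (nlevels(group) != 2) {
    stop("compare_age: exactly two groups required", call. = FALSE)
  }
  a <- age[group == levels(group)[1]]
  b <- age[group == levels(group)[2]]
  if (length(a) < 2 || length(b) < 2) {
    stop("compare_age: need at least 2 ages per group", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    return(list(t = 0, df = NA_real_, p = 1,
                n = c(length(a), length(b)),
                medians = c(stats::median(a), stats::median(b)),
                n_dropped = n_dropped))
  }
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = c(length(a), length(b)),
       medians = c(stats::median(a), stats::median(b)),
       n_dropped = n_dropped)
}

#' Gehan's generalized Wilcoxon test for censored survival
#'
#' Scores every pooled pair +1/-1/0 according to whether one survival time
#' is definitely longer, definitely shorter, or indeterminate under
#' censoring; the test statistic is the sum of scores of the first group,
#' with Gehan's permutation variance and a normal approximation for the
#' p-value. Without censoring it reduces exactly to the Mann-Whitney
#' statistic via U = 2 U_MW - n1 n2.
#'
#' @param time Survival times.
#' @param event Event indicator (1 = death observed, 0 = censored).
#' @param group Two-level grouping.
#' @return A list with `U` (Gehan statistic for the first factor level),
#'   `z`, `p` and per-group sizes.
#' @export
gehan_wilcoxon <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- factor(group)
  if (nlevels(group) != 2) {
    stop("gehan_wilcoxon: exactly two groups required", call. = FALSE)
  }
  if (all(event == 0)) {
    stop("gehan_wilcoxon: all observations censored", call. = FALSE)
  }
  n <- length(time)
  # U_i = #(definitely longer than j) - #(definitely shorter than j)
  gt <- outer(time, time, ">") & matrix(event == 1, n, n, byrow = TRUE)
  U_i <- rowSums(gt) - colSums(gt)
  in1 <- group == levels(group)[1]
  n1 <- sum(in1); n2 <- n - n1
  U <- sum(U_i[in1])
  V <- n1 * n2 * sum(U_i^2) / (n * (n - 1))
  z <- if (V > 0) U / sqrt(V) else 0
  list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)), n = c(n1, n2))
}

#' Assign genes to top-N model categories
#'
#' A gene's category is the band of its best-ranked probe set within the
#' largest model's shared ranking: `top10`, `top11-25`, `top26-50`,
#' `top51-100`, `top101-200`, or `not-in-lists` for genes absent from every
#' model. Probes without a gene mapping are bucketed under their own probe
#' id with a warning.
#'
#' @param models Nested `prediction_model` list from [build_models()].
#' @param probe_to_gene Data frame with columns `probe_id` and `gene`.
#' @param gene_universe Optional character vector of genes to report;
#'   defaults to all mapped genes plus any unmapped model probes.
#' @return Data frame `gene`, `category`, `best_rank` (NA outside the
#'   models).
#' @export
assign_categories <- function(models, probe_to_gene, gene_universe = NULL) {
  sizes <- vapply(models, `[[`, integer(1), "model_size")
  ord <- order(sizes)
  models <- models[ord]; sizes <- sizes[ord]
  ranked <- models[[length(models)]]$feature_ids  # shared ranking prefix
  band_labels <- band_names(sizes)

  map <- stats::setNames(probe_to_gene$gene, probe_to_gene$probe_id)
  unmapped <- setdiff(ranked, names(map))
  if (length(unmapped)) {
    warning("assign_categories: ", length(unmapped),
            " probe(s) without gene mapping kept under their probe id",
            call. = FALSE)
    map[unmapped] <- unmapped
  }
  gene_of <- unname(map[ranked])
  best_rank <- tapply(seq_along(ranked), gene_of, min)

  if (is.null(gene_universe)) {
    gene_universe <- unique(c(probe_to_gene$gene, names(best_rank)))
  }
  rank_vec <- best_rank[gene_universe]
  category <- vapply(rank_vec, function(r) {
    if (is.na(r)) return("not-in-lists")
    band_labels[findInterval(r, c(0, sizes), left.open = TRUE)]
  }, character(1))
  data.frame(gene = gene_universe, category = unname(category),
             best_rank = as.integer(unname(rank_vec)),
             row.names = NULL, stringsAsFactors = FALSE)
}

band_names <- function(sizes) {
  lo <- c(1, utils::head(sizes, -1) + 1)
  ifelse(lo == 1, paste0("top", sizes), paste0("top", lo, "-", sizes))
}

#' Methylation difference and methylation-expression correlation by category
#'
#' For every methylation site with a mapped gene: the absolute difference of
#' median beta between subtype groups and the Pearson correlation between
#' the site's beta values and its gene's expression (mean across the gene's
#' probes) over the shared samples. Summaries (median and quartiles) are
#' reported per model category.
#'
#' @param meth A `beta_matrix`.
#' @param expr An `expr_matrix` sharing samples with `meth`.
#' @param calls Named POS/NEG subtype call per sample.
#' @param categories Category table from [assign_categories()].
#' @param site_to_gene Data frame with columns `site_id` and `gene`.
#' @param probe_to_gene Data frame with columns `probe_id` and `gene`.
#' @return A list with `per_site` and `per_category` data frames and
#'   `n_excluded` (sites with fewer than 3 shared samples).
#' @export
methylation_contrast_by_category <- function(meth, expr, calls, categories,
                                             site_to_gene, probe_to_gene) {
  stopifnot(inherits(meth, "beta_matrix"), inherits(expr, "expr_matrix"))
  shared <- intersect(samples(meth), samples(expr))
  shared <- shared[shared %in% names(calls)]
  cat_of <- stats::setNames(categories$category, categories$gene)
  gene_of_site <- stats::setNames(site_to_gene$gene, site_to_gene$site_id)
  probes_of_gene <- split(probe_to_gene$probe_id, probe_to_gene$gene)

  sites <- intersect(features(meth), names(gene_of_site))
  n_excluded <- 0L
  rows <- lapply(sites, function(s) {
    g <- gene_of_site[[s]]
    probes <- intersect(probes_of_gene[[g]], features(expr))
    if (length(probes) == 0) return(NULL)
    if (length(shared) < 3) { n_excluded <<- n_excluded + 1L; return(NULL) }
    beta <- meth$values[s, shared]
    ev <- expr$values[probes, shared, drop = FALSE]
    e <- if (nrow(ev) > 1) colMeans(ev) else ev[1, ]
    grp <- calls[shared]
    pos <- beta[grp == "POS"]; neg <- beta[grp == "NEG"]
    abs_diff <- if (length(pos) && length(neg))
      abs(stats::median(pos) - stats::median(neg)) else NA_real_
    r <- if (stats::sd(beta) > 0 && stats::sd(e) > 0)
      stats::cor(beta, e) else NA_real_
    data.frame(site_id = s, gene = g,
               category = if (g %in% names(cat_of)) cat_of[[g]]
                          else "not-in-lists",
               abs_median_diff = abs_diff, pearson_r = r,
               stringsAsFactors = FALSE)
  })
  per_site <- do.call(rbind, rows)
  if (is.null(per_site)) {
    return(list(per_site = NULL, per_category = NULL,
                n_excluded = n_excluded))
  }
  per_category <- do.call(rbind, lapply(split(per_site, per_site$category),
    function(d) {
      qd <- stats::quantile(d$abs_median_diff, c(0.25, 0.5, 0.75), na.rm = TRUE)
      qr <- stats::quantile(d$pearson_r, c(0.25, 0.5, 0.75), na.rm = TRUE)
      data.frame(category = d$category[1], n_sites = nrow(d),
                 diff_q25 = qd[1], diff_median = qd[2], diff_q75 = qd[3],
                 r_q25 = qr[1], r_median = qr[2], r_q75 = qr[3],
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  rownames(per_category) <- NULL
  list(per_site = per_site, per_category = per_category,
       n_excluded = n_excluded)
}
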