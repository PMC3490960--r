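#' Specification of a synthetic two-batch GBM cohort
#'
#' Describes a paired methylation/expression/clinical cohort with the
#' structure the pipeline assumes: a hypermethylated minority subtype (POS)
#' against a majority subtype (NEG), anti-correlated expression at
#' subtype-marker genes, additive per-probe batch offsets between cohorts,
#' normal-brain samples in each batch, optional normal-contaminated tumors,
#' optional intermediate ("ambiguous") tumors placed halfway between the two
#' subtype archetypes, and subtype-linked age and survival distributions.
#'
#' Per-batch counts (`n_pos`, `n_neg`, `n_normal`, `n_ambiguous`,
#' `n_contaminated`) are recycled along `batches`. The defaults reproduce the
#' cohort sizes of the motivating study: a 30/338 POS/NEG split with 10
#' normals in the first batch and 10/159 with 31 normals in the second.
#'
#' @param batches Character vector of batch names.
#' @param n_pos,n_neg,n_normal Per-batch counts of POS tumors, NEG tumors and
#'   normal-brain samples.
#' @param n_ambiguous Per-batch count of tumors generated at the 50/50 convex
#'   combination of the POS and NEG archetypes (`true_subtype = "AMBIGUOUS"`).
#' @param n_contaminated Per-batch count of additional NEG tumors whose
#'   expression is a 50/50 mixture with the normal-brain archetype
#'   (flagged in the annotation column `contaminated`).
#' @param n_sites,n_probes Number of methylation sites / expression probe sets.
#' @param n_marker_genes Number of paired marker site/probe/gene triples that
#'   carry the subtype signal.
#' @param beta_shift Mean beta elevation of marker sites in POS tumors.
#' @param expr_effect Log2 expression decrease at marker probes in POS tumors.
#' @param meth_expr_coupling Target within-subtype Pearson correlation between
#'   marker beta and marker expression, in \[-1, 0\].
#' @param batch_offset_sd SD of the per-probe additive log2 offset applied to
#'   every batch after the first (methylation carries no batch effect).
#' @param noise_sd_expr SD of i.i.d. Gaussian expression noise.
#' @param beta_concentration Concentration of the Beta distributions that
#'   generate beta values (larger = tighter around the archetype mean).
#' @param normal_effect Log2 offset of the normal-brain archetype on its
#'   signature probes; the default 3 keeps normals separable from both tumor
#'   archetypes by at least 3 noise SDs.
#' @param n_normal_probes Number of normal-signature probes.
#' @param tumor_het_sd SD of per-tumor biological heterogeneity on the
#'   normal-signature probes (tissue-differentiation genes vary most between
#'   tumors); together with `normal_effect` this puts those probes above the
#'   SD > 1 variance filter used for contamination screening, as in real
#'   arrays.
#' @param age_pos_median,age_neg_median,age_sd Age model (years): Gaussian per
#'   subtype with the stated medians.
#' @param surv_pos_median,surv_neg_median Median survival (days) of the
#'   exponential survival model per subtype.
#' @param censor_rate Target fraction of independently censored tumors.
#' @param detect_fail_rate Fraction of sites given a failing detection
#'   p-value in one random sample.
#' @param seed Integer RNG seed; generation is fully deterministic given it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(batches = c("TCGA", "NOB"),
                        n_pos = c(30L, 10L),
                        n_neg = c(338L, 159L),
                        n_normal = c(10L, 31L),
                        n_ambiguous = 0L,
                        n_contaminated = 0L,
                        n_sites = 1000L,
                        n_probes = 2000L,
                        n_marker_genes = 100L,
                        beta_shift = 0.4,
                        expr_effect = 2.0,
                        meth_expr_coupling = -0.7,
                        batch_offset_sd = 0.8,
                        noise_sd_expr = 0.5,
                        beta_concentration = 30,
                        normal_effect = 3.0,
                        n_normal_probes = 200L,
                        tumor_het_sd = 1.0,
                        age_pos_median = 36,
                        age_neg_median = 59,
                        age_sd = 12,
                        surv_pos_median = 840.5,
                        surv_neg_median = 327,
                        censor_rate = 0.2,
                        detect_fail_rate = 0.01,
                        seed = 1L) {
  nb <- length(batches)
  stopifnot(nb >= 1, !anyDuplicated(batches))
  rec <- function(x) as.integer(rep_len(x, nb))
  spec <- list(batches = as.character(batches),
               n_pos = rec(n_pos), n_neg = rec(n_neg),
               n_normal = rec(n_normal), n_ambiguous = rec(n_ambiguous),
               n_contaminated = rec(n_contaminated),
               n_sites = as.integer(n_sites), n_probes = as.integer(n_probes),
               n_marker_genes = as.integer(n_marker_genes),
               beta_shift = beta_shift, expr_effect = expr_effect,
               meth_expr_coupling = meth_expr_coupling,
               batch_offset_sd = batch_offset_sd,
               noise_sd_expr = noise_sd_expr,
               beta_concentration = beta_concentration,
               normal_effect = normal_effect,
               n_normal_probes = as.integer(n_normal_probes),
               tumor_het_sd = tumor_het_sd,
               age_pos_median = age_pos_median,
               age_neg_median = age_neg_median, age_sd = age_sd,
               surv_pos_median = surv_pos_median,
               surv_neg_median = surv_neg_median,
               censor_rate = censor_rate,
               detect_fail_rate = detect_fail_rate,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  counts <- c(spec$n_pos, spec$n_neg, spec$n_normal, spec$n_ambiguous,
              spec$n_contaminated)
  if (any(counts < 0)) stop("cohort_spec: counts must be nonnegative", call. = FALSE)
  if (spec$n_marker_genes > min(spec$n_sites, spec$n_probes)) {
    stop("cohort_spec: n_marker_genes must not exceed min(n_sites, n_probes)",
         call. = FALSE)
  }
  if (spec$beta_shift <= 0 || spec$beta_shift >= 1) {
    stop("cohort_spec: beta_shift must lie in (0, 1)", call. = FALSE)
  }
  if (spec$meth_expr_coupling < -1 || spec$meth_expr_coupling > 0) {
    stop("cohort_spec: meth_expr_coupling must lie in [-1, 0]", call. = FALSE)
  }
  if (spec$surv_pos_median <= 0 || spec$surv_neg_median <= 0) {
    stop("cohort_spec: survival medians must be positive", call. = FALSE)
  }
  if (spec$censor_rate < 0 || spec$censor_rate >= 1) {
    stop("cohort_spec: censor_rate must lie in [0, 1)", call. = FALSE)
  }
  if (spec$n_normal_probes + spec$n_marker_genes > spec$n_probes) {
    stop("cohort_spec: marker and normal-signature probes exceed n_probes",
         call. = FALSE)
  }
  invisible(spec)
}

rbeta_mean <- function(n, mean, conc) {
  # Beta draw parameterized by mean and concentration; clamp away from 0/1
  m <- pmin(pmax(mean, 1e-3), 1 - 1e-3)
  stats::rbeta(n, m * conc, (1 - m) * conc)
}

#' Generate a synthetic methylation/expression/clinical cohort
#'
#' Draws a cohort under [cohort_spec()]: beta values come from Beta
#' distributions around subtype archetype means (marker sites are elevated by
#' `beta_shift` in POS tumors), log2 expression is
#' `baseline - expr_effect * POS` at marker probes plus a within-subtype
#' coupling term that tracks the sample's methylation deviation, an additive
#' per-probe batch offset for batches after the first, and Gaussian noise.
#' Survival is exponential with subtype-specific medians under independent
#' exponential censoring; ages are Gaussian per subtype.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{methylation}{[beta_matrix()] over all tumor samples (all
#'       batches), with detection p-values.}
#'     \item{expression}{Named list of per-batch [expr_matrix()] objects
#'       covering that batch's tumors and normals.}
#'     \item{annotation}{Sample annotation data frame with synthetic-truth
#'       columns `true_subtype` and `contaminated`.}
#'     \item{site_to_gene, probe_to_gene}{Two-column feature/gene maps.}
#'     \item{marker_sites, marker_probes, spec}{Bookkeeping.}
#'   }
#' @export
simulate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  ns <- spec$n_sites; np <- spec$n_probes; m <- spec$n_marker_genes

  site_ids <- sprintf("cg%06d", seq_len(ns))
  probe_ids <- sprintf("ps%05d_at", seq_len(np))
  genes <- sprintf("GENE%04d", seq_len(np))
  marker_idx <- seq_len(m)
  normalsig_idx <- m + seq_len(spec$n_normal_probes)

  # archetype means: marker sites are hypomethylated in NEG, shifted up in POS
  mu_neg <- stats::runif(ns, 0.05, 0.95)
  mu_neg[marker_idx] <- stats::runif(m, 0.10, 0.95 - spec$beta_shift - 0.05)
  mu_pos <- mu_neg
  mu_pos[marker_idx] <- mu_neg[marker_idx] + spec$beta_shift
  baseline <- stats::runif(np, 4, 10)

  # per-sample table -----------------------------------------------------
  rows <- list()
  for (b in seq_along(spec$batches)) {
    bn <- spec$batches[b]
    kinds <- c(rep("POS", spec$n_pos[b]), rep("NEG", spec$n_neg[b]),
               rep("AMBIGUOUS", spec$n_ambiguous[b]),
               rep("CONTAM", spec$n_contaminated[b]),
               rep("NORMAL", spec$n_normal[b]))
    if (length(kinds) == 0) next
    rows[[b]] <- data.frame(
      sample_id = sprintf("%s.S%04d", bn, seq_along(kinds)),
      batch = bn,
      tissue = ifelse(kinds == "NORMAL", "normal", "tumor"),
      kind = kinds, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$true_subtype <- ifelse(tab$kind == "NORMAL", NA_character_,
                        ifelse(tab$kind == "CONTAM", "NEG", tab$kind))
  tab$contaminated <- tab$kind == "CONTAM"

  tumor <- tab$tissue == "tumor"
  tumor_ids <- tab$sample_id[tumor]

  # methylation (tumors only; no batch effect by design) ------------------
  n_t <- sum(tumor)
  beta <- matrix(0, ns, n_t, dimnames = list(site_ids, tumor_ids))
  tkind <- tab$kind[tumor]
  arch <- function(kind) {
    switch(kind,
           POS = mu_pos,
           NEG = mu_neg,
           CONTAM = mu_neg,
           AMBIGUOUS = (mu_pos + mu_neg) / 2)
  }
  for (j in seq_len(n_t)) {
    beta[, j] <- rbeta_mean(ns, arch(tkind[j]), spec$beta_concentration)
  }
  detp <- matrix(stats::runif(ns * n_t, 0, 0.04), ns, n_t,
                 dimnames = list(site_ids, tumor_ids))
  n_fail <- ceiling(spec$detect_fail_rate * ns)
  if (n_fail > 0 && n_t > 0) {
    fail_sites <- sample.int(ns, n_fail)
    fail_samp <- sample.int(n_t, n_fail, replace = TRUE)
    detp[cbind(fail_sites, fail_samp)] <- stats::runif(n_fail, 0.06, 0.5)
  }

  # expression ------------------------------------------------------------
  # coupling gain g per marker, solved so that the cohort-level Pearson
  # correlation between marker beta and marker expression hits the target:
  # the subtype mixture (beta up / expression down in POS) contributes most
  # of it; g adds the within-subtype component via
  #   r = (cov_B + g W) / sqrt((vbB + W)(veB + noise^2 + g^2 W)),
  # a quadratic in g (negative root of smallest magnitude).
  cc <- spec$meth_expr_coupling
  p_pos <- {
    n_p <- sum(spec$n_pos); n_n <- sum(spec$n_neg) + sum(spec$n_contaminated)
    if (n_p + n_n > 0) n_p / (n_p + n_n) else 0.5
  }
  W <- (mu_neg[marker_idx] + spec$beta_shift / 2) *
       (1 - mu_neg[marker_idx] - spec$beta_shift / 2) /
       (spec$beta_concentration + 1)
  vbB <- p_pos * (1 - p_pos) * spec$beta_shift^2
  veB <- p_pos * (1 - p_pos) * spec$expr_effect^2
  covB <- -p_pos * (1 - p_pos) * spec$beta_shift * spec$expr_effect
  Nv <- veB + spec$noise_sd_expr^2
  gain <- vapply(W, function(w) {
    if (cc == 0) return(0)
    a2 <- w^2 - cc^2 * (vbB + w) * w
    a1 <- 2 * covB * w
    a0 <- covB^2 - cc^2 * (vbB + w) * Nv
    disc <- a1^2 - 4 * a2 * a0
    if (abs(a2) < 1e-12) {
      roots <- -a0 / a1
    } else if (disc >= 0) {
      roots <- (-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2)
    } else {
      # target unreachable for this marker; saturate the within coupling
      return(-10 * spec$noise_sd_expr / sqrt(w))
    }
    neg <- roots[roots < 0]
    if (length(neg) == 0) 0 else neg[which.min(abs(neg))]
  }, numeric(1))
  batch_offsets <- lapply(seq_along(spec$batches), function(b) {
    if (b == 1) rep(0, np) else stats::rnorm(np, 0, spec$batch_offset_sd)
  })

  # tissue signature with mixed signs: up- and down-regulated genes in
  # normal brain, so per-sample standardization cannot cancel it
  normal_sign <- sample(c(-1, 1), spec$n_normal_probes, replace = TRUE)
  normal_arch <- baseline
  normal_arch[normalsig_idx] <- normal_arch[normalsig_idx] +
    normal_sign * spec$normal_effect

  expression <- list()
  for (b in seq_along(spec$batches)) {
    bn <- spec$batches[b]
    sel <- tab$batch == bn
    if (!any(sel)) next
    ids <- tab$sample_id[sel]
    kind_b <- tab$kind[sel]
    ev <- matrix(0, np, length(ids), dimnames = list(probe_ids, ids))
    for (j in seq_along(ids)) {
      mu_e <- switch(kind_b[j],
        POS = { x <- baseline; x[marker_idx] <- x[marker_idx] - spec$expr_effect; x },
        NEG = baseline,
        AMBIGUOUS = { x <- baseline
                      x[marker_idx] <- x[marker_idx] - spec$expr_effect / 2; x },
        CONTAM = (baseline + normal_arch) / 2,
        NORMAL = normal_arch)
      if (kind_b[j] %in% c("POS", "NEG", "AMBIGUOUS")) {
        dev <- beta[marker_idx, ids[j]] - arch(kind_b[j])[marker_idx]
        mu_e[marker_idx] <- mu_e[marker_idx] + gain * dev
      }
      if (kind_b[j] != "NORMAL") {
        het_w <- if (kind_b[j] == "CONTAM") 0.5 else 1
        mu_e[normalsig_idx] <- mu_e[normalsig_idx] +
          het_w * stats::rnorm(spec$n_normal_probes, 0, spec$tumor_het_sd)
      }
      ev[, j] <- mu_e + batch_offsets[[b]] +
        stats::rnorm(np, 0, spec$noise_sd_expr)
    }
    expression[[bn]] <- expr_matrix(ev, platform = bn)
  }

  # clinical --------------------------------------------------------------
  n_all <- nrow(tab)
  age <- rep(NA_real_, n_all)
  surv <- rep(NA_real_, n_all)
  event <- rep(NA_real_, n_all)
  for (i in seq_len(n_all)) {
    if (tab$tissue[i] != "tumor") next
    sub <- tab$true_subtype[i]
    med_age <- switch(sub, POS = spec$age_pos_median,
                      NEG = spec$age_neg_median,
                      AMBIGUOUS = (spec$age_pos_median + spec$age_neg_median) / 2)
    med_surv <- switch(sub, POS = spec$surv_pos_median,
                       NEG = spec$surv_neg_median,
                       AMBIGUOUS = (spec$surv_pos_median + spec$surv_neg_median) / 2)
    age[i] <- max(1, stats::rnorm(1, med_age, spec$age_sd))
    lambda <- log(2) / med_surv
    t_true <- stats::rexp(1, lambda)
    if (spec$censor_rate > 0) {
      mu_c <- lambda * spec$censor_rate / (1 - spec$censor_rate)
      t_cens <- stats::rexp(1, mu_c)
    } else {
      t_cens <- Inf
    }
    surv[i] <- max(min(t_true, t_cens), 0.5)
    event[i] <- as.numeric(t_true <= t_cens)
  }

  ann <- data.frame(sample_id = tab$sample_id, batch = tab$batch,
                    tissue = tab$tissue, age_years = age,
                    survival_days = surv, event = event,
                    true_subtype = tab$true_subtype,
                    contaminated = tab$contaminated,
                    stringsAsFactors = FALSE)
  validate_annotation(ann)

  list(methylation = beta_matrix(beta, detp),
       expression = expression,
       annotation = ann,
       site_to_gene = data.frame(site_id = site_ids[marker_idx],
                                 gene = genes[marker_idx],
                                 stringsAsFactors = FALSE),
       probe_to_gene = data.frame(probe_id = probe_ids, gene = genes,
                                  stringsAsFactors = FALSE),
       marker_sites = site_ids[marker_idx],
       marker_probes = probe_ids[marker_idx],
       spec = spec)
}

#' Extract the planted subtype ground truth from an annotation table
#'
#' @param annotations Annotation data frame carrying `true_subtype`.
#' @return A list with `map` (named POS/NEG vector over non-ambiguous tumors)
#'   and `ambiguous` (ids of AMBIGUOUS tumors, excluded from accuracy
#'   denominators).
#' @export
planted_truth <- function(annotations) {
  if (!is.data.frame(annotations) || !"true_subtype" %in% names(annotations)) {
    stop("planted_truth: annotations lack a true_subtype column", call. = FALSE)
  }
  tum <- annotations[annotations$tissue == "tumor", , drop = FALSE]
  amb <- tum$sample_id[!is.na(tum$true_subtype) & tum$true_subtype == "AMBIGUOUS"]
  keep <- !is.na(tum$true_subtype) & tum$true_subtype %in% c("POS", "NEG")
  map <- tum$true_subtype[keep]
  names(map) <- tum$sample_id[keep]
  list(map = map, ambiguous = amb)
}
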