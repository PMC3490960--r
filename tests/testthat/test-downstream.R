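test_that("BH step-up matches the definitional scan and dominates Bonferroni", {
  res <- bh_stepup(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(res$reject))

  res1 <- bh_stepup(rep(1, 5), 0.05)
  expect_false(any(res1$reject))
  expect_true(all(res1$q == 1))

  expect_length(bh_stepup(numeric(0))$q, 0)
  expect_error(bh_stepup(c(0.5, 1.2)), "\\[0, 1\\]")

  stepup_oracle <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= (seq_len(m) / m) * alpha)
    rej <- logical(m)
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  set.seed(301)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- round(runif(m)^sample(1:3, 1), 4)
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    res <- bh_stepup(p, alpha)
    expect_identical(res$reject, stepup_oracle(p, alpha))
    # BH rejects at least what Bonferroni rejects
    expect_true(all(res$reject[p <= alpha / m]))
  }
})

test_that("Cox screen agrees with a grid-search partial-likelihood oracle", {
  # 4 subjects, all events, interleaved binary covariate (a covariate that
  # perfectly orders the deaths has a monotone partial likelihood and no
  # finite maximizer, so the groups must alternate); Breslow log partial
  # likelihood maximized by grid search
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  breslow_lpl <- function(b) {
    risk <- exp(b * x)
    ord <- order(time)
    lpl <- 0
    for (i in ord) {
      at_risk <- time >= time[i]
      lpl <- lpl + b * x[i] - log(sum(risk[at_risk]))
    }
    lpl
  }
  grid <- seq(-5, 5, by = 1e-4)
  b_star <- grid[which.max(vapply(grid, breslow_lpl, numeric(1)))]

  v <- matrix(x, 1, 4, dimnames = list("f1", paste0("s", 1:4)))
  ann <- data.frame(sample_id = paste0("s", 1:4), batch = "A",
                    tissue = "tumor", survival_days = time, event = event,
                    stringsAsFactors = FALSE)
  sr <- cox_screen(expr_matrix(v), ann)
  expect_lt(abs(sr$table$coef[1] - b_star), 1e-4)
})

test_that("Cox screen conventions: constant covariate and planted effects", {
  set.seed(311)
  n <- 120
  x <- rnorm(n)
  haz <- exp(1.0 * x)
  time <- rexp(n, rate = haz / 500)
  ann <- data.frame(sample_id = sprintf("s%03d", 1:n), batch = "A",
                    tissue = "tumor", survival_days = time, event = 1,
                    stringsAsFactors = FALSE)
  v <- rbind(effect = x, flat = rep(2, n), noise = rnorm(n))
  colnames(v) <- ann$sample_id
  sr <- cox_screen(expr_matrix(v), ann)
  tab <- sr$table
  expect_equal(tab$p[tab$feature_id == "flat"], 1)
  expect_gt(tab$coef[tab$feature_id == "effect"], 0)
  expect_lt(tab$p[tab$feature_id == "effect"], 1e-6)
  expect_gt(tab$p[tab$feature_id == "noise"], 0.001)
  expect_true(all(sr$table$significant == (!is.na(sr$table$q) &
                                           sr$table$q <= 0.05)))
  expect_error(cox_screen(expr_matrix(v), transform(ann, event = 0)),
               "events")
})

test_that("Cox coefficient signs track planted log-hazard effects", {
  set.seed(321)
  n <- 200
  hits <- 0
  for (rep in 1:10) {
    x <- rnorm(n)
    sgn <- sample(c(-1, 1), 1)
    time <- rexp(n, rate = exp(sgn * 1.0 * x) / 300)
    ann <- data.frame(sample_id = sprintf("s%03d", 1:n), batch = "A",
                      tissue = "tumor", survival_days = time, event = 1,
                      stringsAsFactors = FALSE)
    v <- matrix(x, 1, n, dimnames = list("f", ann$sample_id))
    tab <- cox_screen(expr_matrix(v), ann)$table
    if (sign(tab$coef) == sgn && tab$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("Welch age comparison matches the textbook formula", {
  a <- c(30, 35, 40); b <- c(50, 60, 70)
  res <- compare_age(c(a, b), rep(c("POS", "NEG"), each = 3))
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  same <- compare_age(c(a, a), rep(c("POS", "NEG"), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # missing ages dropped and counted
  res2 <- compare_age(c(a, NA, b), c("POS", "POS", "POS", "POS",
                                     "NEG", "NEG", "NEG"))
  expect_identical(res2$n_dropped, 1L)
})

test_that("age separation at study scale is decisive", {
  pvals <- vapply(1:20, function(s) {
    co <- simulate_cohort(cohort_spec(batches = "TCGA", n_pos = 30L,
                                      n_neg = 338L, n_normal = 0L,
                                      n_sites = 10L, n_probes = 10L,
                                      n_marker_genes = 5L,
                                      n_normal_probes = 0L,
                                      seed = 600 + s))
    ann <- co$annotation
    tr <- planted_truth(ann)
    idx <- match(names(tr$map), ann$sample_id)
    compare_age(ann$age_years[idx], unname(tr$map))$p
  }, numeric(1))
  expect_true(all(pvals < 1e-6))
})

test_that("Gehan-Wilcoxon scores pairs correctly under censoring", {
  # all four cross-pairs decided: A strictly longer
  res <- gehan_wilcoxon(c(5, 6, 1, 2), c(1, 1, 1, 1),
                        rep(c("A", "B"), each = 2))
  expect_equal(res$U, 4)
  expect_lt(res$p, 0.2)

  # identical groups: statistic 0
  res0 <- gehan_wilcoxon(c(3, 7, 3, 7), c(1, 1, 1, 1),
                         rep(c("A", "B"), each = 2))
  expect_equal(res0$U, 0)
  expect_equal(res0$p, 1)

  # censored-at-5 vs event-at-3: decided; censored-at-3 vs event-at-5: not
  res1 <- gehan_wilcoxon(c(5, 3), c(0, 1), c("A", "B"))
  expect_equal(res1$U, 1)
  res2 <- gehan_wilcoxon(c(3, 5), c(0, 1), c("A", "B"))
  expect_equal(res2$U, 0)

  expect_error(gehan_wilcoxon(c(1, 2), c(0, 0), c("A", "B")), "censored")
})

test_that("without censoring Gehan reduces to the Mann-Whitney relation", {
  set.seed(331)
  for (i in 1:50) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    a <- runif(n1); b <- runif(n2)          # continuous: no ties
    res <- gehan_wilcoxon(c(a, b), rep(1, n1 + n2),
                          rep(c("A", "B"), c(n1, n2)))
    u_mw <- unname(wilcox.test(a, b, exact = TRUE)$statistic)
    expect_equal(res$U, 2 * u_mw - n1 * n2)
  }
})

test_that("gene categories follow the best-probe-rank banding rule", {
  co <- simulate_cohort(small_spec(seed = 341))
  m <- co$expression$TCGA
  labels <- truth_for(co, m)
  models <- build_models(restrict(m, samples = names(labels)), labels,
                         pipeline_config())
  p2g <- co$probe_to_gene
  cats <- assign_categories(models, p2g)
  expect_setequal(setdiff(unique(cats$category), "not-in-lists"),
                  intersect(c("top10", "top11-25", "top26-50", "top51-100",
                              "top101-200"), unique(cats$category)))
  # banding oracle from the shared ranking
  ranking <- models[[5]]$feature_ids
  gene_of <- setNames(p2g$gene, p2g$probe_id)
  for (g in sample(cats$gene, 50)) {
    ranks <- which(gene_of[ranking] == g)
    expected <- if (length(ranks) == 0) "not-in-lists"
      else c("top10", "top11-25", "top26-50", "top51-100",
             "top101-200")[findInterval(min(ranks),
                                        c(0, 10, 25, 50, 100), left.open = TRUE)]
    expect_identical(cats$category[cats$gene == g], expected)
  }
  # probes with ranks 8 and 120 for one gene: best rank wins
  fake <- data.frame(probe_id = ranking, gene = "G1",
                     stringsAsFactors = FALSE)
  fake$gene <- paste0("G", seq_along(ranking))
  fake$gene[c(8, 120)] <- "SHARED"
  cats2 <- assign_categories(models, fake)
  expect_identical(cats2$category[cats2$gene == "SHARED"], "top10")

  # unmapped probe bucketed under its own id with warning
  expect_warning(c3 <- assign_categories(models, fake[-1, ]), "without gene")
  expect_identical(c3$category[c3$gene == ranking[1]], "top10")
})

test_that("methylation contrast summaries match hand computation", {
  v <- rbind(cg1 = c(0.8, 0.9, 0.1, 0.2))
  colnames(v) <- paste0("s", 1:4)
  meth <- beta_matrix(v)
  ev <- rbind(p1 = c(1, 2, 8, 9))
  colnames(ev) <- paste0("s", 1:4)
  expr <- expr_matrix(ev)
  calls <- setNames(c("POS", "POS", "NEG", "NEG"), paste0("s", 1:4))
  cats <- data.frame(gene = "G1", category = "top10", best_rank = 1L,
                     stringsAsFactors = FALSE)
  res <- methylation_contrast_by_category(
    meth, expr, calls, cats,
    site_to_gene = data.frame(site_id = "cg1", gene = "G1"),
    probe_to_gene = data.frame(probe_id = "p1", gene = "G1"))
  expect_equal(res$per_site$abs_median_diff, 0.70)
  expect_equal(res$per_site$pearson_r, cor(v[1, ], ev[1, ]))

  # correlation bounds: beta equal to expression gives r = 1, negated -1
  expr2 <- expr_matrix(rbind(p1 = v[1, ]))
  res2 <- methylation_contrast_by_category(
    meth, expr2, calls, cats,
    data.frame(site_id = "cg1", gene = "G1"),
    data.frame(probe_id = "p1", gene = "G1"))
  expect_equal(res2$per_site$pearson_r, 1)
  expr3 <- expr_matrix(rbind(p1 = -v[1, ]))
  res3 <- methylation_contrast_by_category(
    meth, expr3, calls, cats,
    data.frame(site_id = "cg1", gene = "G1"),
    data.frame(probe_id = "p1", gene = "G1"))
  expect_equal(res3$per_site$pearson_r, -1)

  # label swap leaves the absolute difference unchanged
  swapped <- setNames(c("NEG", "NEG", "POS", "POS"), paste0("s", 1:4))
  res4 <- methylation_contrast_by_category(
    meth, expr, swapped, cats,
    data.frame(site_id = "cg1", gene = "G1"),
    data.frame(probe_id = "p1", gene = "G1"))
  expect_equal(res4$per_site$abs_median_diff, res$per_site$abs_median_diff)
})

test_that("marker categories show strong contrast, background none", {
  co <- simulate_cohort(small_spec(seed = 351, n_pos = c(20, 10),
                                   n_neg = c(120, 80)))
  m <- co$expression$TCGA
  labels <- truth_for(co, m)
  models <- build_models(restrict(m, samples = names(labels)), labels,
                         pipeline_config())
  # map every site to a gene: markers to their paired gene, the rest 1:1
  all_sites <- rownames(co$methylation$values)
  extra <- setdiff(all_sites, co$site_to_gene$site_id)
  s2g <- rbind(co$site_to_gene,
               data.frame(site_id = extra,
                          gene = paste0("BG_", extra),
                          stringsAsFactors = FALSE))
  p2g <- co$probe_to_gene
  extra_p <- setdiff(rownames(m$values), p2g$probe_id)
  cats <- assign_categories(models, p2g)
  res <- methylation_contrast_by_category(co$methylation, m, labels, cats,
                                          s2g, p2g)
  pc <- res$per_category
  expect_lt(pc$r_median[pc$category == "top10"], -0.3)
  nil <- pc[pc$category == "not-in-lists", ]
  if (nrow(nil) == 1) {
    expect_lt(abs(nil$r_median), 0.15)
    expect_gte(pc$diff_median[pc$category == "top10"], nil$diff_median)
  }
})

test_that("confounding contrast errors when deletion exceeds the NEG pool", {
  co <- simulate_cohort(small_spec(seed = 361, n_pos = c(30, 0),
                                   n_neg = c(10, 0), n_normal = c(2, 0)))
  m <- co$expression$TCGA
  labels <- truth_for(co, m)
  m <- restrict(m, samples = names(labels))
  expect_error(confounding_contrast(m, co$annotation, labels,
                                    pipeline_config(), 1),
               "exceeds")
})
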