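# Shared fixture builders. All fixtures are generated in code; the scaled
# cohort keeps unit tests fast while preserving the default cohort's
# statistical structure (minority hypermethylated subtype, two batches,
# normals, batch offsets).

small_spec <- function(seed = 1, ...) {
  args <- list(batches = c("TCGA", "NOB"),
               n_pos = c(10L, 6L), n_neg = c(60L, 40L),
               n_normal = c(5L, 8L),
               n_sites = 150L, n_probes = 400L, n_marker_genes = 40L,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_spec, args)
}

random_expr <- function(n_feat, n_samp, seed = 1, prefix = "f") {
  set.seed(seed)
  v <- matrix(rnorm(n_feat * n_samp), n_feat, n_samp,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_feat)),
                              sprintf("s%03d", seq_len(n_samp))))
  expr_matrix(v)
}

random_beta <- function(n_feat, n_samp, seed = 1) {
  set.seed(seed)
  v <- matrix(runif(n_feat * n_samp), n_feat, n_samp,
              dimnames = list(sprintf("cg%03d", seq_len(n_feat)),
                              sprintf("s%03d", seq_len(n_samp))))
  beta_matrix(v)
}

# truth labels restricted to samples present in a matrix
truth_for <- function(cohort, m) {
  tr <- planted_truth(cohort$annotation)
  ids <- intersect(samples(m), names(tr$map))
  tr$map[ids]
}
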