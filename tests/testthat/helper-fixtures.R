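# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except the packaged panel/score files.

# A small independent SNP panel in HWE, no LD, no effects unless asked.
toy_panel <- function(p = c(0.2, 0.35, 0.5), ids = NULL) {
  if (is.null(ids)) {
    ids <- paste0("snp", seq_along(p))
  }
  data.frame(snp = ids, gene = rep("G1", length(p)), alt_freq = p,
             stringsAsFactors = FALSE)
}

toy_config <- function(..., seed = 42L) {
  cohort_config(panel = toy_panel(), effects = NULL, residual_sd = 10,
                technical_sd = 2, seed = seed, ...)
}

# Deterministic genotype matrix with named columns.
toy_genotypes <- function(n = 12, seed = 1L, p = c(0.2, 0.35, 0.5)) {
  cfg <- cohort_config(n_participants = n, panel = toy_panel(p),
                       effects = NULL, residual_sd = 10, seed = seed)
  simulate_genotypes(cfg)
}

# A cohort drawn from the published 10-SNP architecture at study defaults.
study_cohort <- function(seed, ...) {
  simulate_cohort(cohort_config(seed = seed, ...))
}

# Aggregated phenotype vector aligned with the genotype rows.
cohort_phenotype <- function(cohort) {
  ph <- aggregate_phenotype(cohort$measurements)
  ph$adipose_atoc[match(rownames(cohort$genotypes), ph$participant_id)]
}

# Design of the true causal predictors (the published codings).
true_design <- function(cohort) {
  eff <- atoc_effects()
  build_design(cohort$genotypes,
               data.frame(snp = eff$snp, model = eff$coding,
                          stringsAsFactors = FALSE))
}

# Random regression instance for PLS/OLS oracle comparisons.
random_instance <- function(n, p, seed, noise = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, sd = noise)
  list(X = X, y = y, beta = beta)
}
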