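test_that("genotypes follow Hardy-Weinberg class frequencies", {
  cfg <- cohort_config(n_participants = 100000,
                       panel = toy_panel(p = 0.5, ids = "s"),
                       effects = NULL, residual_sd = 1, seed = 1)
  g <- simulate_genotypes(cfg)
  freq <- as.vector(table(factor(g, levels = 0:2))) / length(g)
  expect_lt(max(abs(freq - c(0.25, 0.5, 0.25))), 0.01)

  # the CD36 SNP frequency: mean dosage 2p = 0.90
  cfg2 <- cohort_config(n_participants = 50000,
                        panel = toy_panel(p = 0.45, ids = "rs3211958"),
                        effects = NULL, residual_sd = 1, seed = 2)
  expect_equal(mean(simulate_genotypes(cfg2)), 0.90, tolerance = 0.01)
})

test_that("LD partners reach their target dosage correlation", {
  panel <- data.frame(snp = c("src", "copy", "half"),
                      gene = "G", alt_freq = c(0.4, 0.4, 0.4),
                      ld_partner = c("", "src", "src"),
                      ld_r2 = c(NA, 1.0, 0.5),
                      stringsAsFactors = FALSE)
  cfg <- cohort_config(n_participants = 20000, panel = panel,
                       effects = NULL, residual_sd = 1, seed = 3)
  g <- simulate_genotypes(cfg)
  expect_equal(dosage_r2(g[, "src"], g[, "copy"]), 1.0)
  expect_equal(dosage_r2(g[, "src"], g[, "half"]), 0.5, tolerance = 0.05)
  bad <- panel
  bad$ld_r2[2] <- 1.5
  expect_error(cohort_config(panel = bad, effects = NULL, residual_sd = 1),
               "r2")
  bad2 <- panel
  bad2$ld_partner[2] <- "nope"
  expect_error(cohort_config(panel = bad2, effects = NULL, residual_sd = 1),
               "partner")
})

test_that("degenerate noise collapses every replicate onto the intercept", {
  cfg <- cohort_config(n_participants = 8, panel = toy_panel(),
                       effects = NULL, intercept = 35.7, residual_sd = 0,
                       technical_sd = 0, seed = 4)
  co <- simulate_cohort(cfg)
  expect_true(all(co$measurements$adipose_atoc == 35.7))
})

test_that("a carrier of one minor allele at every effect SNP scores 281.2", {
  eff <- atoc_effects()
  g <- matrix(1, 1, nrow(eff), dimnames = list("P01", eff$snp))
  cfg <- cohort_config(n_participants = 1, seed = 5, residual_sd = 0,
                       technical_sd = 0)
  ph <- simulate_phenotypes(g, cfg)
  expect_equal(unname(ph$latent), 281.2, tolerance = 1e-10)
  expect_error(simulate_phenotypes(g[, -1, drop = FALSE], cfg), "rs709158")
})

test_that("residual noise at 61% of the mean yields a ~61% phenotype CV", {
  cvs <- vapply(1:200, function(s) {
    cfg <- cohort_config(n_participants = 42, panel = toy_panel(),
                         effects = NULL, intercept = 35.7,
                         residual_sd = 0.61 * 35.7, technical_sd = 0,
                         n_replicates = 2, seed = s)
    co <- simulate_cohort(cfg)
    percent_cv(aggregate_phenotype(co$measurements)$adipose_atoc) / 100
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 0.61), 0.05)
})

test_that("the default configuration implements the study conditions", {
  cfg <- cohort_config()
  expect_equal(cfg$n_participants, 42)
  expect_equal(cfg$intercept, 35.7)
  expect_equal(nrow(cfg$panel), 77)
  expect_equal(nrow(cfg$effects), 10)
  # residual SD solves the 61% CV target given the genetic variance
  expect_equal(cfg$residual_sd,
               implied_residual_sd(cfg$effects, 35.7, 0.61, 15, 6))
  co <- simulate_cohort(cfg)
  expect_equal(dim(co$genotypes), c(42, 77))
  expect_equal(nrow(co$measurements), 42 * 6)
  # cholesterol tracks the phenotype
  expect_gt(cor(co$covariates$total_cholesterol, co$latent), 0)
})

test_that("seeded simulation is bit-reproducible and replicate counts vary", {
  a <- simulate_cohort(cohort_config(seed = 7))
  b <- simulate_cohort(cohort_config(seed = 7))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$covariates, b$covariates)

  v <- simulate_cohort(cohort_config(seed = 8, vary_replicates = TRUE))
  counts <- table(v$measurements$participant_id)
  expect_true(all(counts >= 2 & counts <= 6))
  expect_gt(length(unique(counts)), 1)
})

test_that("missingness is injected at the requested rate", {
  cfg <- cohort_config(n_participants = 2000, panel = toy_panel(),
                       effects = NULL, residual_sd = 1,
                       missing_rate = 0.03, seed = 9)
  g <- simulate_genotypes(cfg)
  expect_lt(abs(mean(is.na(g)) - 0.03), 0.01)
})

test_that("simulated SNPs fail the HWE screen at about the nominal rate", {
  rejections <- vapply(1:30, function(s) {
    g <- toy_genotypes(n = 100, seed = 200 + s,
                       p = rep(c(0.2, 0.3, 0.4, 0.5), 5))
    mean(vapply(seq_len(ncol(g)), function(j) {
      d <- g[, j]
      hwe_test(sum(d == 0), sum(d == 1), sum(d == 2))$p.value < 0.05
    }, logical(1)))
  }, numeric(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})
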