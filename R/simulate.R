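#' Packaged candidate-SNP panel annotation
#'
#' The 77-SNP candidate panel that survives univariate screening in the
#' source cohort: SNP id, gene, allele pair (major > minor), alternate-allele
#' frequency in Europeans, gene region, the coding model under which the SNP
#' was significant, its unstandardized univariate coefficient with standard
#' error and p-value, and the RegulomeDB-style regulatory score.
#'
#' @return data frame with one row per SNP.
#' @export
atoc_panel <- function() {
  path <- system.file("extdata", "snp_panel.tsv", package = "tocopls",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Packaged 10-SNP generating architecture
#'
#' The linear genetic architecture of the final published model: per-SNP
#' coding and effect size (nmol/g protein per allele or carrier status), used
#' as the default truth of the cohort generator.
#'
#' @return data frame with columns `snp`, `gene`, `coding`, `coefficient`,
#'   `vip`, `alt_freq`.
#' @export
atoc_effects <- function() {
  gs <- atoc_score()
  panel <- atoc_panel()
  e <- gs$entries
  e$alt_freq <- panel$alt_freq[match(e$snp, panel$snp)]
  e
}

# Expected value and variance of the coded genotype under HWE.
coded_moments <- function(p, coding) {
  if (coding == "additive") {
    list(mean = 2 * p, var = 2 * p * (1 - p))
  } else {
    carrier <- 1 - (1 - p)^2
    list(mean = carrier, var = carrier * (1 - carrier))
  }
}

#' Residual standard deviation implied by a target phenotype CV
#'
#' Solves for the between-participant residual SD such that the aggregated
#' phenotype (genetic value + residual + technical noise averaged over
#' replicates) has the target coefficient of variation under
#' Hardy-Weinberg genotype frequencies. Returns 0 when the genetic variance
#' alone already exceeds the target.
#'
#' @param effects effect table (`snp`, `coding`, `coefficient`, `alt_freq`).
#' @param intercept phenotype intercept.
#' @param cv_target target between-participant CV (default 0.61).
#' @param technical_sd within-participant replicate SD.
#' @param n_replicates replicates averaged per participant.
#' @return residual SD in phenotype units.
#' @export
implied_residual_sd <- function(effects, intercept, cv_target = 0.61,
                                technical_sd = 0, n_replicates = 6) {
  mom <- Map(coded_moments, effects$alt_freq, effects$coding)
  mu <- intercept + sum(effects$coefficient *
                          vapply(mom, `[[`, numeric(1), "mean"))
  gvar <- sum(effects$coefficient^2 * vapply(mom, `[[`, numeric(1), "var"))
  total <- (cv_target * mu)^2
  sqrt(max(total - gvar - technical_sd^2 / n_replicates, 0))
}

#' Configure a synthetic cohort
#'
#' Defaults reproduce the structure of the study cohort: 42 healthy adult
#' males genotyped at the packaged 77-SNP candidate panel (Hardy-Weinberg
#' genotype frequencies at the published European alternate-allele
#' frequencies), a linear genetic architecture given by the published 10-SNP
#' model (intercept 35.7 nmol/g protein), between-participant residual noise
#' solved so the aggregated phenotype CV is ~61%, six adipose replicate
#' measurements per participant (3 meals x fasting/8 h), and a total
#' cholesterol covariate correlated ~0.36 with the phenotype.
#'
#' @param n_participants cohort size (default 42).
#' @param panel SNP annotation data frame with at least `snp` and `alt_freq`
#'   (optional `gene`, `ld_partner`, `ld_r2` for linked pairs).
#' @param effects effect table (`snp`, `coding`, `coefficient`); SNPs must
#'   exist in `panel`. `NULL` means no genetic effects.
#' @param intercept phenotype intercept (nmol/g protein).
#' @param residual_sd between-participant residual SD; `NULL` solves it from
#'   `cv_target` via [implied_residual_sd()].
#' @param cv_target target between-participant CV used when `residual_sd` is
#'   `NULL`.
#' @param technical_sd within-participant replicate SD (assay noise).
#' @param n_replicates replicates per participant (1-6 draws from the
#'   meal x time grid).
#' @param vary_replicates when `TRUE`, each participant gets a uniform
#'   2-6 replicates instead of a fixed count.
#' @param covariate_spec named list of covariates; each element is
#'   `list(r = target correlation with the latent phenotype, mean, sd)`.
#' @param missing_rate fraction of dosages set missing uniformly at random.
#' @param seed integer seed; every draw derives from it.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_participants = 42,
                          panel = atoc_panel(),
                          effects = atoc_effects(),
                          intercept = 35.7,
                          residual_sd = NULL,
                          cv_target = 0.61,
                          technical_sd = 15,
                          n_replicates = 6,
                          vary_replicates = FALSE,
                          covariate_spec = list(
                            total_cholesterol = list(r = 0.36, mean = 1.6,
                                                     sd = 0.65),
                            plasma_atoc = list(r = 0.24, mean = 25.5,
                                               sd = 5.8)),
                          missing_rate = 0,
                          seed = 1L) {
  stopifnot(n_participants >= 1,
            all(c("snp", "alt_freq") %in% names(panel)),
            all(panel$alt_freq > 0 & panel$alt_freq < 1),
            !anyDuplicated(panel$snp),
            technical_sd >= 0,
            n_replicates >= 1, n_replicates <= 6,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(effects)) {
    stopifnot(all(c("snp", "coding", "coefficient") %in% names(effects)),
              all(effects$coding %in% c("additive", "dominant")))
    if (!all(effects$snp %in% panel$snp)) {
      stop("effect SNP(s) absent from panel: ",
           paste(setdiff(effects$snp, panel$snp), collapse = ", "))
    }
    if (is.null(effects$alt_freq)) {
      effects$alt_freq <- panel$alt_freq[match(effects$snp, panel$snp)]
    }
  }
  if ("ld_partner" %in% names(panel)) {
    has <- !is.na(panel$ld_partner) & panel$ld_partner != ""
    if (any(has & !(panel$ld_partner %in% panel$snp))) {
      stop("LD partner not in panel")
    }
    if (any(has & (panel$ld_r2 > 1 | panel$ld_r2 <= 0))) {
      stop("LD target r2 must be in (0, 1]")
    }
  }
  if (is.null(residual_sd)) {
    residual_sd <- if (is.null(effects)) cv_target * intercept else
      implied_residual_sd(effects, intercept, cv_target, technical_sd,
                          n_replicates)
  }
  stopifnot(residual_sd >= 0)
  structure(
    list(n_participants = n_participants, panel = panel, effects = effects,
         intercept = intercept, residual_sd = residual_sd,
         technical_sd = technical_sd, n_replicates = n_replicates,
         vary_replicates = vary_replicates, covariate_spec = covariate_spec,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Flip probability such that per-allele copying with flips attains the
# target allele correlation sqrt(r2) at source frequency p.
ld_flip_prob <- function(p, r2_target) {
  r_target <- sqrt(r2_target)
  allele_cor <- function(f) {
    pb <- p * (1 - f) + (1 - p) * f
    if (pb <= 0 || pb >= 1) {
      return(0)
    }
    (p * (1 - f) - p * pb) / sqrt(p * (1 - p) * pb * (1 - pb))
  }
  if (r_target >= 1) {
    return(0)
  }
  uniroot(function(f) allele_cor(f) - r_target, c(1e-9, 0.5 - 1e-9))$root
}

#' Simulate genotypes for a configured cohort
#'
#' Independent SNPs are drawn per allele as Bernoulli(`alt_freq`) pairs, so
#' genotype classes follow the Hardy-Weinberg probabilities `(1-p)^2`,
#' `2 p (1-p)`, `p^2`. LD-partnered SNPs copy the partner's alleles with a
#' flip probability calibrated so the squared dosage correlation approaches
#' the target r-squared. Missing entries are injected uniformly at random at
#' `missing_rate`. Fully reproducible under the config seed.
#'
#' @param config a [cohort_config()].
#' @return dosage matrix (participants x SNPs) with participant row names.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  panel <- config$panel
  n <- config$n_participants
  with_seed(config$seed, {
    alleles <- list() # per SNP: n x 2 matrix of allele indicators
    g <- matrix(NA_real_, n, nrow(panel),
                dimnames = list(sprintf("P%02d", seq_len(n)), panel$snp))
    for (i in seq_len(nrow(panel))) {
      partner <- if ("ld_partner" %in% names(panel)) panel$ld_partner[i]
        else NA
      if (!is.na(partner) && nzchar(partner)) {
        src <- alleles[[partner]]
        if (is.null(src)) {
          stop("LD partner must precede the dependent SNP in the panel")
        }
        f <- ld_flip_prob(panel$alt_freq[match(partner, panel$snp)],
                          panel$ld_r2[i])
        flip <- matrix(rbinom(2 * n, 1, f), n, 2)
        a <- abs(src - flip)
      } else {
        a <- matrix(rbinom(2 * n, 1, panel$alt_freq[i]), n, 2)
      }
      alleles[[panel$snp[i]]] <- a
      g[, i] <- rowSums(a)
    }
    if (config$missing_rate > 0) {
      drop <- runif(length(g)) < config$missing_rate
      g[drop] <- NA_real_
    }
    g
  })
}

#' Simulate phenotypes and covariates for simulated genotypes
#'
#' The latent phenotype is `intercept + sum effects (dominant coding
#' collapses dosage 2 to 1) + N(0, residual_sd^2)` per participant; replicate
#' adipose measurements add independent `N(0, technical_sd^2)` assay noise on
#' the meal x time grid. Covariates are drawn by a Gaussian-copula
#' construction against the latent phenotype so their realized Pearson
#' correlations approach the configured targets. Missing effect-SNP dosages
#' are mean-imputed before computing the genetic value.
#'
#' @param genotypes dosage matrix from [simulate_genotypes()].
#' @param config the same [cohort_config()].
#' @return list with `measurements` (long data frame: `participant_id`,
#'   `meal`, `time`, `adipose_atoc`), `covariates` (one row per participant)
#'   and `latent` (the noiseless-replicate participant values).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(genotypes)
  ids <- rownames(genotypes)
  genetic <- rep(config$intercept, n)
  if (!is.null(config$effects)) {
    for (i in seq_len(nrow(config$effects))) {
      snp <- config$effects$snp[i]
      if (!snp %in% colnames(genotypes)) {
        stop("effect SNP missing from genotype matrix: ", snp)
      }
      d <- genotypes[, snp]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      x <- if (config$effects$coding[i] == "dominant") pmin(d, 1) else d
      genetic <- genetic + config$effects$coefficient[i] * x
    }
  }
  with_seed(config$seed + 1L, {
    latent <- genetic + rnorm(n, sd = config$residual_sd)
    grid <- expand.grid(meal = c("control", "alpha-toc", "tomato"),
                        time = c("fasting", "8h"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meas <- lapply(seq_len(n), function(i) {
      k <- if (config$vary_replicates) sample(2:6, 1) else config$n_replicates
      take <- sort(sample.int(nrow(grid), k))
      data.frame(participant_id = ids[i],
                 meal = grid$meal[take], time = grid$time[take],
                 adipose_atoc = latent[i] +
                   rnorm(k, sd = config$technical_sd),
                 stringsAsFactors = FALSE)
    })
    z <- (latent - mean(latent)) / sd(latent)
    covs <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
    for (nm in names(config$covariate_spec)) {
      spec <- config$covariate_spec[[nm]]
      zc <- spec$r * z + sqrt(1 - spec$r^2) * rnorm(n)
      covs[[nm]] <- spec$mean + spec$sd * zc
    }
    list(measurements = do.call(rbind, meas), covariates = covs,
         latent = stats::setNames(latent, ids))
  })
}

#' Simulate a complete cohort
#'
#' Genotypes, replicate adipose measurements and covariates in one call.
#'
#' @param config a [cohort_config()]; default is the study-structure cohort.
#' @return object of class `atoc_cohort`: list with `genotypes`,
#'   `annotation`, `measurements`, `covariates`, `latent` and the `config`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 7))
#' str(cohort$genotypes)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  g <- simulate_genotypes(config)
  ph <- simulate_phenotypes(g, config)
  structure(
    list(genotypes = g, annotation = config$panel,
         measurements = ph$measurements, covariates = ph$covariates,
         latent = ph$latent, config = config),
    class = "atoc_cohort"
  )
}

#' @export
print.atoc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d SNPs, %d measurements\n",
              nrow(x$genotypes), ncol(x$genotypes), nrow(x$measurements)))
  invisible(x)
}
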