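# Interchange formats. Dosage TSV is the primary format: header row
# `participant_id` then SNP ids, cells 0/1/2/NA, tab-delimited, UTF-8, no
# quoting. PLINK text ped/map is supported for genotype import.

#' Read a dosage TSV
#'
#' @param path file with header `participant_id` followed by SNP ids; cells
#'   are minor-allele counts 0/1/2 or `NA`.
#' @return dosage matrix with participant row names.
#' @export
read_dosage_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  if (names(df)[1] != "participant_id") {
    stop("first column must be 'participant_id'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(df$participant_id)
  bad <- which(!(is.na(m) | m %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid dosage at line %d (participant %s, SNP %s)",
                 bad[1, 1] + 1L, rownames(m)[bad[1, 1]],
                 colnames(m)[bad[1, 2]]))
  }
  check_genotype_matrix(m)
}

#' Write a dosage TSV
#'
#' @param g dosage matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(g, path) {
  check_genotype_matrix(g)
  df <- data.frame(participant_id = rownames(g), g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read PLINK text ped/map genotypes as dosages
#'
#' Parses a whitespace-delimited `.ped` (6 leading columns, then two allele
#' calls per SNP; `0` codes a missing call) with its `.map` (chromosome, SNP
#' id, genetic distance, position). The minor allele of each SNP is inferred
#' from the observed allele frequency (ties broken alphabetically) and
#' dosages count its copies; a genotype with any missing call is `NA`.
#'
#' @param ped,map file paths.
#' @return dosage matrix (participants x SNPs).
#' @export
read_plink_text <- function(ped, map) {
  mp <- utils::read.table(map, stringsAsFactors = FALSE)
  if (ncol(mp) < 4) {
    stop("map file needs 4 columns (chr, snp, cM, bp)")
  }
  snps <- as.character(mp[[2]])
  pd <- utils::read.table(ped, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(pd) != 6 + 2 * length(snps)) {
    stop(sprintf("ped/map inconsistency: ped has %d genotype columns, map %d SNPs",
                 ncol(pd) - 6, length(snps)))
  }
  n <- nrow(pd)
  g <- matrix(NA_real_, n, length(snps),
              dimnames = list(pd[[2]], snps))
  for (j in seq_along(snps)) {
    a1 <- pd[[6 + 2 * j - 1]]
    a2 <- pd[[6 + 2 * j]]
    calls <- c(a1, a2)
    obs <- calls[calls != "0"]
    if (!length(obs)) {
      next
    }
    tab <- sort(table(obs))
    minor <- if (length(tab) == 1) names(tab) else {
      cand <- names(tab)[tab == min(tab)]
      sort(cand)[1]
    }
    miss <- a1 == "0" | a2 == "0"
    g[, j] <- (a1 == minor) + (a2 == minor)
    g[miss, j] <- NA_real_
  }
  g
}

#' Read a long phenotype measurement TSV
#'
#' @param path file with columns `participant_id`, `meal`, `time`,
#'   `adipose_atoc`.
#' @return data frame.
#' @export
read_phenotype_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "meal", "time", "adipose_atoc")
  if (!all(need %in% names(df))) {
    stop("phenotype TSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Read a covariate TSV keyed by participant id
#'
#' @param path file with a `participant_id` column plus numeric covariates.
#' @return data frame.
#' @export
read_covariates_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(df)) {
    stop("covariate TSV needs a participant_id column")
  }
  df
}

#' Pipeline configuration
#'
#' All thresholds of the analysis in one place, with the published defaults:
#' 95% call rate, Hardy-Weinberg alpha 0.05, LD r-squared 0.80, at least 5
#' observations per genotype group, univariate alpha 0.05, 95% covariate
#' CI, VIP grid 0.8-1.5 by 0.05, 7 cross-validation folds, 100 permutations,
#' Grubbs alpha 0.05.
#'
#' @param call_rate_min,hwe_alpha,ld_r2,min_group,screen_alpha,ci_level
#'   QC and screening thresholds.
#' @param vip_grid numeric vector of increasing VIP thresholds.
#' @param cv_folds,n_perm,grubbs_alpha,select_alpha remaining tunables.
#' @param seed integer seed used for every stochastic step.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(call_rate_min = 0.95, hwe_alpha = 0.05,
                            ld_r2 = 0.80, min_group = 5,
                            screen_alpha = 0.05, ci_level = 0.95,
                            vip_grid = seq(0.8, 1.5, by = 0.05),
                            cv_folds = 7, n_perm = 100,
                            grubbs_alpha = 0.05, select_alpha = 0.05,
                            seed = 1L) {
  stopifnot(call_rate_min > 0, call_rate_min <= 1,
            hwe_alpha > 0, hwe_alpha < 1,
            ld_r2 > 0, ld_r2 <= 1,
            min_group >= 1,
            screen_alpha > 0, screen_alpha < 1,
            ci_level > 0, ci_level < 1,
            length(vip_grid) >= 1, !is.unsorted(vip_grid),
            cv_folds >= 2, n_perm >= 1,
            grubbs_alpha > 0, grubbs_alpha < 1,
            select_alpha > 0, select_alpha < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the complete association pipeline
#'
#' Genotype QC, phenotype aggregation, covariate screening, univariate SNP
#' screening, PLS fitting with the VIP-threshold sweep, CV-ANOVA-gated model
#' selection, post-selection LD pruning, the validation battery, and export
#' of the genetic score. When no sweep entry is significant the pipeline
#' returns gracefully with `status = "no_model"`.
#'
#' @param genotypes dosage matrix (participants x SNPs).
#' @param measurements long replicate table (`participant_id`, `meal`,
#'   `time`, `adipose_atoc`).
#' @param covariates optional covariate data frame keyed by
#'   `participant_id`.
#' @param annotation optional SNP annotation (`snp`, `gene`) for
#'   within-gene tag-SNP binning.
#' @param config a [pipeline_config()].
#' @return object of class `atoc_pipeline`: list with `qc`, `phenotype`,
#'   `covariates_kept`, `screen`, `selection`, `validation`, `score`,
#'   `status` (`"ok"` or `"no_model"`), and a `manifest` of all thresholds
#'   and seeds used.
#' @export
run_pipeline <- function(genotypes, measurements, covariates = NULL,
                         annotation = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))

  qc <- run_qc(genotypes, annotation, config$call_rate_min,
               config$hwe_alpha, config$ld_r2, config$seed)

  pheno <- aggregate_phenotype(measurements, config$grubbs_alpha)
  ids <- rownames(qc$genotypes)
  if (is.null(ids)) {
    ids <- pheno$participant_id
  }
  pheno <- pheno[match(ids, pheno$participant_id), ]
  if (anyNA(pheno$adipose_atoc)) {
    stop("phenotype missing for participant(s): ",
         paste(ids[is.na(pheno$adipose_atoc)], collapse = ", "))
  }
  y <- pheno$adipose_atoc

  kept_cov <- character(0)
  cov_df <- NULL
  if (!is.null(covariates)) {
    cov_num <- covariates[match(ids, covariates$participant_id),
                          setdiff(names(covariates), "participant_id"),
                          drop = FALSE]
    kept_cov <- covariate_screen(y, cov_num, config$ci_level)
    if (length(kept_cov)) {
      cov_df <- cov_num[, kept_cov, drop = FALSE]
    }
  }

  screen <- screen_snps(qc$genotypes, y, config$screen_alpha,
                        config$min_group)
  candidates <- attr(screen, "candidates")

  manifest <- c(unclass(config),
                list(n_participants = length(y),
                     n_snps_in = ncol(genotypes),
                     n_snps_qc = ncol(qc$genotypes),
                     n_candidates = nrow(candidates),
                     covariates_kept = kept_cov))

  base <- list(qc = qc, phenotype = pheno, covariates_kept = kept_cov,
               screen = screen, manifest = manifest, config = config)
  if (nrow(candidates) == 0) {
    base$status <- "no_model"
    class(base) <- "atoc_pipeline"
    return(base)
  }

  X <- build_design(qc$genotypes, candidates, cov_df)
  selection <- vip_select(X, y, genotypes = qc$genotypes,
                          thresholds = config$vip_grid,
                          folds = config$cv_folds,
                          alpha = config$select_alpha,
                          r2_threshold = config$ld_r2)
  base$design <- X
  base$selection <- selection
  if (!selection$selected) {
    base$status <- "no_model"
    class(base) <- "atoc_pipeline"
    return(base)
  }

  Xf <- X[, selection$final_variables, drop = FALSE]
  base$validation <- validate_model(Xf, y, selection$final_model$ncomp,
                                    folds = config$cv_folds,
                                    n_perm = config$n_perm,
                                    seed = config$seed)
  base$score <- withCallingHandlers(
    score_from_fit(selection),
    warning = function(w) invokeRestart("muffleWarning"))
  base$status <- "ok"
  class(base) <- "atoc_pipeline"
  base
}

#' @export
print.atoc_pipeline <- function(x, ...) {
  cat("Adipose alpha-tocopherol association pipeline\n")
  print(x$qc$report, row.names = FALSE)
  cat(sprintf("Candidates after univariate screen: %d (covariates kept: %s)\n",
              nrow(attr(x$screen, "candidates")),
              if (length(x$covariates_kept))
                paste(x$covariates_kept, collapse = ", ") else "none"))
  if (x$status == "no_model") {
    cat("No significant model selected.\n")
  } else {
    print(x$selection)
  }
  invisible(x)
}
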