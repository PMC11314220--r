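#' Encode dosages under an inheritance model
#'
#' Additive coding is the identity on minor-allele counts; dominant coding
#' collapses homozygous-minor (dosage 2) with heterozygous carriers, so 0
#' stays 0 and both 1 and 2 map to 1. Missing values propagate.
#'
#' @param dosages vector of 0/1/2/NA minor-allele counts.
#' @param model `"additive"` or `"dominant"`.
#' @return numeric regressor vector.
#' @export
encode_genotype <- function(dosages, model = c("additive", "dominant")) {
  model <- match.arg(model)
  if (!is_dosage(dosages)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (model == "additive") {
    as.numeric(dosages)
  } else {
    ifelse(is.na(dosages), NA_real_, as.numeric(dosages > 0))
  }
}

#' Minimum observations-per-genotype-group rule
#'
#' Under the additive model all three genotype classes must contain at least
#' `min_obs` observations; under the dominant model the two collapsed classes
#' (non-carriers vs carriers) must. SNPs failing the rule are excluded from
#' association testing. The additive rule is the more restrictive one, which
#' is why fewer SNPs survive it.
#'
#' @param dosages 0/1/2/NA vector.
#' @param model coding model.
#' @param min_obs minimum class size (default 5).
#' @return logical: keep the SNP under this model?
#' @export
group_count_filter <- function(dosages, model = c("additive", "dominant"),
                               min_obs = 5) {
  model <- match.arg(model)
  d <- dosages[!is.na(dosages)]
  counts <- c(sum(d == 0), sum(d == 1), sum(d == 2))
  if (model == "additive") {
    all(counts >= min_obs)
  } else {
    counts[1] >= min_obs && (counts[2] + counts[3]) >= min_obs
  }
}

#' Simple least-squares association with Wald test
#'
#' Fits `y = b0 + B g` by ordinary least squares on pairwise-complete
#' observations and refers the Wald statistic `B / SE` to a t distribution on
#' `n - 2` degrees of freedom (two-sided).
#'
#' @param y phenotype vector.
#' @param g regressor vector (already coded).
#' @return list with `B`, `SE`, `t`, `p`, `n`; errors if fewer than 3 complete
#'   pairs remain or the regressor is constant.
#' @export
ols_assoc <- function(y, g) {
  ok <- complete.cases(y, g)
  y <- y[ok]
  g <- g[ok]
  n <- length(y)
  if (n < 3) {
    stop("ols_assoc needs at least 3 complete pairs")
  }
  sxx <- sum((g - mean(g))^2)
  if (sxx == 0) {
    stop("constant regressor")
  }
  b <- sum((g - mean(g)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - b * (g - mean(g))
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tstat <- b / se
  list(B = b, SE = se, t = tstat,
       p = 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE), n = n)
}

#' Univariate SNP screen under additive and dominant codings
#'
#' Every SNP is tested under both codings after the observations-per-group
#' rule; results with Wald p < `alpha` are retained as candidate predictors.
#' A SNP whose additive and dominant regressors are identical vectors (no
#' homozygous-minor genotypes present) contributes a single additive
#' candidate, so candidates are never double counted. Results are ranked by
#' increasing p within each model.
#'
#' @param g QC-passed dosage matrix.
#' @param y aggregated phenotype vector, one value per row of `g`.
#' @param alpha retention threshold (default 0.05).
#' @param min_obs observations-per-group minimum (default 5).
#' @return object of class `snp_screen`: data frame with one row per tested
#'   (snp, model) pair (`snp`, `model`, `B`, `SE`, `p`, `n`, `n0`, `n1`,
#'   `n2`, `tested`, `retained`); retained candidates in attribute
#'   `"candidates"`.
#' @export
screen_snps <- function(g, y, alpha = 0.05, min_obs = 5) {
  check_genotype_matrix(g)
  stopifnot(length(y) == nrow(g))
  rows <- list()
  for (snp in colnames(g)) {
    d <- g[, snp]
    cnt <- c(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
             sum(d == 2, na.rm = TRUE))
    dom_equals_add <- cnt[3] == 0
    retained_add <- FALSE
    for (model in c("additive", "dominant")) {
      x <- encode_genotype(d, model)
      tested <- group_count_filter(d, model, min_obs) &&
        length(unique(x[!is.na(x)])) > 1
      res <- if (tested) ols_assoc(y, x) else
        list(B = NA_real_, SE = NA_real_, t = NA_real_, p = NA_real_,
             n = sum(!is.na(x)))
      # a dominant regressor identical to the additive one (no dosage-2
      # genotypes) must not add a second copy of an already-retained SNP
      retained <- tested && !is.na(res$p) && res$p < alpha &&
        !(model == "dominant" && dom_equals_add && retained_add)
      if (model == "additive") {
        retained_add <- retained
      }
      rows[[paste(snp, model)]] <- data.frame(
        snp = snp, model = model, B = res$B, SE = res$SE, p = res$p,
        n = res$n, n0 = cnt[1], n1 = cnt[2], n2 = cnt[3],
        tested = tested, retained = retained, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ord <- order(match(tab$model, c("additive", "dominant")), tab$p)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  candidates <- tab[tab$retained, c("snp", "model", "B", "SE", "p")]
  rownames(candidates) <- NULL
  structure(tab, candidates = candidates, class = c("snp_screen",
                                                    "data.frame"))
}

#' Build the predictor matrix for PLS from screened candidates
#'
#' One column per retained (snp, coding) candidate, named
#' `<snp>_<add|dom>`, plus any screened covariates. Missing coded genotypes
#' are mean-imputed (PLS needs complete columns).
#'
#' @param g dosage matrix.
#' @param candidates data frame with columns `snp` and `model` (as produced
#'   by [screen_snps()] in attribute `"candidates"`).
#' @param covariates optional data frame of covariate columns to append.
#' @return numeric design matrix with rows aligned to `g`; the candidate
#'   table (including covariates, coded `"covariate"`) is attached as
#'   attribute `"variables"`.
#' @export
build_design <- function(g, candidates, covariates = NULL) {
  check_genotype_matrix(g)
  cols <- list()
  meta <- list()
  for (i in seq_len(nrow(candidates))) {
    snp <- candidates$snp[i]
    model <- candidates$model[i]
    x <- encode_genotype(g[, snp], model)
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    nm <- paste0(snp, "_", substr(model, 1, 3))
    cols[[nm]] <- x
    meta[[nm]] <- data.frame(variable = nm, snp = snp, model = model,
                             stringsAsFactors = FALSE)
  }
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      x <- as.numeric(covariates[[nm]])
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      cols[[nm]] <- x
      meta[[nm]] <- data.frame(variable = nm, snp = NA_character_,
                               model = "covariate", stringsAsFactors = FALSE)
    }
  }
  if (!length(cols)) {
    stop("no candidate predictors to assemble")
  }
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(g)
  structure(X, variables = do.call(rbind, c(meta, list(make.row.names = FALSE))))
}
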