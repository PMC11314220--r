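#' SNP call-rate filter
#'
#' Drops SNPs whose genotype call rate (fraction of non-missing dosages) falls
#' below `min_rate`. A SNP is kept iff non-missing / n >= `min_rate`, so with
#' n = 42 a SNP with 2 missing genotypes (rate 40/42 ~ 0.952) survives a 95%
#' threshold while 3 missing (~ 0.929) does not.
#'
#' @param g numeric participants x SNPs dosage matrix (0/1/2/NA).
#' @param min_rate minimum call rate in \[0, 1\]; default 0.95.
#' @return list with `genotypes` (column-subset matrix) and `excluded`
#'   (character vector of dropped SNP ids).
#' @export
call_rate_filter <- function(g, min_rate = 0.95) {
  check_genotype_matrix(g)
  rate <- colMeans(!is.na(g))
  drop <- rate < min_rate
  list(genotypes = g[, !drop, drop = FALSE], excluded = colnames(g)[drop])
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit test of the observed genotype counts against the
#' Hardy-Weinberg expectation computed from the estimated allele frequency
#' `p = (n1 + 2 n2) / (2 n)`: expected counts `n (1-p)^2`, `2 n p (1-p)`,
#' `n p^2`, 1 degree of freedom, no continuity correction. Monomorphic SNPs
#' (estimated frequency 0 or 1) are defined to have statistic 0 and are
#' flagged.
#'
#' @param n0,n1,n2 genotype class counts (0, 1 and 2 copies of the minor
#'   allele).
#' @return an object of class `htest` with fields `statistic`, `parameter`
#'   (df), `p.value` and a logical `monomorphic` element.
#' @export
hwe_test <- function(n0, n1, n2) {
  stopifnot(length(n0) == 1, length(n1) == 1, length(n2) == 1)
  if (any(c(n0, n1, n2) < 0) || n0 + n1 + n2 < 1) {
    stop("genotype counts must be non-negative with at least one observation")
  }
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  mono <- p <= 0 || p >= 1
  if (mono) {
    stat <- 0
  } else {
    expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((c(n0, n1, n2) - expected)^2 / expected)
  }
  structure(
    list(
      statistic = c(`X-squared` = stat),
      parameter = c(df = 1),
      p.value = pchisq(stat, df = 1, lower.tail = FALSE),
      estimate = c(`minor allele frequency` = p),
      method = "Hardy-Weinberg equilibrium chi-squared test",
      data.name = sprintf("counts (%d, %d, %d)", n0, n1, n2),
      monomorphic = mono
    ),
    class = "htest"
  )
}

#' Squared dosage correlation between two SNPs
#'
#' Composite linkage-disequilibrium measure: the squared Pearson correlation
#' of minor-allele dosages over pairwise-complete participants. Invariant to
#' allele flips (`g2 = 2 - g1` gives 1). Returns `NA` when fewer than 3
#' complete pairs remain or either vector is constant.
#'
#' @param g1,g2 dosage vectors of equal length.
#' @return squared correlation in \[0, 1\], or `NA`.
#' @export
dosage_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3) {
    return(NA_real_)
  }
  x <- g1[ok]
  y <- g2[ok]
  if (var(x) == 0 || var(y) == 0) {
    return(NA_real_)
  }
  min(cor(x, y)^2, 1)
}

# Pairwise dosage r^2 matrix for a set of SNP columns.
dosage_r2_matrix <- function(g) {
  p <- ncol(g)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(g), colnames(g)))
  diag(out) <- 1
  if (p < 2) {
    return(out)
  }
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      out[i, j] <- out[j, i] <- dosage_r2(g[, i], g[, j])
    }
  }
  out
}

#' Greedy tag-SNP selection
#'
#' Bins SNPs by pairwise dosage r-squared within each gene group and keeps one
#' tag per bin, Carlson-style: repeatedly pick the unassigned SNP linked
#' (r^2 > `r2_threshold`) to the most unassigned SNPs, make it the tag of a
#' bin containing itself and its linked SNPs, and iterate until every SNP is
#' assigned. Singletons tag themselves. Ties are broken by input column order,
#' so the procedure is deterministic.
#'
#' @param g dosage matrix.
#' @param r2_threshold LD threshold; SNPs with pairwise r^2 strictly above it
#'   are binned together. Default 0.80.
#' @param groups optional character vector (one per SNP) restricting binning
#'   to within-group pairs, e.g. the annotated gene; `NULL` treats the panel
#'   as one group.
#' @return list with `tags` (kept SNP ids, input order) and `bins` (named list
#'   of bin members per tag).
#' @export
tag_snp_selection <- function(g, r2_threshold = 0.80, groups = NULL) {
  check_genotype_matrix(g)
  snps <- colnames(g)
  if (is.null(groups)) {
    groups <- rep("all", length(snps))
  }
  stopifnot(length(groups) == length(snps))
  r2 <- dosage_r2_matrix(g)
  linked <- !is.na(r2) & r2 > r2_threshold &
    outer(groups, groups, `==`)
  diag(linked) <- FALSE

  assigned <- rep(FALSE, length(snps))
  bins <- list()
  while (!all(assigned)) {
    # number of *unassigned* neighbours of each unassigned SNP
    deg <- vapply(seq_along(snps), function(j) {
      if (assigned[j]) -1L else sum(linked[, j] & !assigned)
    }, integer(1))
    tag <- which.max(deg) # ties: first in input order
    members <- c(tag, which(linked[tag, ] & !assigned))
    members <- unique(members)
    assigned[members] <- TRUE
    bins[[snps[tag]]] <- snps[members]
  }
  tags <- snps[snps %in% names(bins)] # preserve input order
  list(tags = tags, bins = bins[tags])
}

#' Drop perfectly correlated SNPs
#'
#' Within each connected component of SNP pairs with dosage r^2 = 1 exactly
#' (to numerical tolerance), one SNP is kept at random and the rest are
#' excluded. The random choice is seeded so reruns are identical.
#'
#' @param g dosage matrix.
#' @param seed integer seed controlling which member of each perfect clique
#'   survives.
#' @return list with `genotypes` and `excluded`.
#' @export
dedup_perfect_pairs <- function(g, seed = 1L) {
  check_genotype_matrix(g)
  if (ncol(g) < 2) {
    return(list(genotypes = g, excluded = character(0)))
  }
  r2 <- dosage_r2_matrix(g)
  perfect <- !is.na(r2) & r2 >= 1 - 1e-9
  diag(perfect) <- FALSE
  if (!any(perfect)) {
    return(list(genotypes = g, excluded = character(0)))
  }
  comp <- graph_components(perfect | t(perfect) | diag(TRUE, ncol(g)))
  keep <- rep(TRUE, ncol(g))
  with_seed(seed, {
    for (cid in unique(comp)) {
      members <- which(comp == cid)
      if (length(members) > 1) {
        survivor <- members[sample.int(length(members), 1)]
        keep[setdiff(members, survivor)] <- FALSE
      }
    }
  })
  list(genotypes = g[, keep, drop = FALSE], excluded = colnames(g)[!keep])
}

#' Run the full genotype QC cascade
#'
#' Applies, in order: call-rate filtering, Hardy-Weinberg exclusion at
#' `hwe_alpha`, greedy tag-SNP selection at `ld_r2`, and seeded
#' perfect-correlation de-duplication. The returned report chains exactly:
#' each stage's SNPs out equals its SNPs in minus exclusions, and feeds the
#' next stage.
#'
#' @param g dosage matrix.
#' @param annotation optional data frame with columns `snp` and `gene`; when
#'   supplied, tag-SNP binning is restricted to within-gene pairs.
#' @param call_rate_min,hwe_alpha,ld_r2 stage thresholds (defaults 0.95, 0.05,
#'   0.80).
#' @param seed seed for the perfect-pair survivor choice.
#' @return object of class `qc_result`: list with `genotypes` (filtered
#'   matrix), `report` (stage table), and `exclusions` (SNP, stage, reason).
#' @export
run_qc <- function(g, annotation = NULL, call_rate_min = 0.95,
                   hwe_alpha = 0.05, ld_r2 = 0.80, seed = 1L) {
  check_genotype_matrix(g)
  exclusions <- data.frame(snp = character(0), stage = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  stage_rows <- list()
  note <- function(snps, stage, reason) {
    if (length(snps)) {
      exclusions <<- rbind(exclusions, data.frame(
        snp = snps, stage = stage, reason = reason, stringsAsFactors = FALSE))
    }
  }
  log_stage <- function(stage, n_in, n_out) {
    stage_rows[[length(stage_rows) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_excluded = n_in - n_out, n_out = n_out,
      stringsAsFactors = FALSE)
  }

  # 1. call rate
  n_in <- ncol(g)
  cr <- call_rate_filter(g, call_rate_min)
  note(cr$excluded, "call_rate", sprintf("call rate < %.3g", call_rate_min))
  g <- cr$genotypes
  log_stage("call_rate", n_in, ncol(g))

  # 2. Hardy-Weinberg
  n_in <- ncol(g)
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    d <- g[, j]
    hwe_test(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
             sum(d == 2, na.rm = TRUE))$p.value
  }, numeric(1))
  drop <- hwe_p < hwe_alpha
  note(colnames(g)[drop], "hwe", sprintf("HWE p < %.3g", hwe_alpha))
  g <- g[, !drop, drop = FALSE]
  log_stage("hwe", n_in, ncol(g))

  # 3. tag-SNP selection
  n_in <- ncol(g)
  groups <- NULL
  if (!is.null(annotation)) {
    stopifnot(all(c("snp", "gene") %in% names(annotation)))
    groups <- annotation$gene[match(colnames(g), annotation$snp)]
    groups[is.na(groups)] <- "unannotated"
  }
  tg <- tag_snp_selection(g, ld_r2, groups)
  dropped <- setdiff(colnames(g), tg$tags)
  note(dropped, "tag_snp", sprintf("binned with a tag SNP at r2 > %.3g", ld_r2))
  g <- g[, tg$tags, drop = FALSE]
  log_stage("tag_snp", n_in, ncol(g))

  # 4. perfect-correlation dedup
  n_in <- ncol(g)
  dd <- dedup_perfect_pairs(g, seed)
  note(dd$excluded, "perfect_dedup", "perfectly correlated (r2 = 1)")
  g <- dd$genotypes
  log_stage("perfect_dedup", n_in, ncol(g))

  structure(
    list(genotypes = g, report = do.call(rbind, stage_rows),
         exclusions = exclusions, bins = tg$bins),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Genotype QC cascade\n")
  print(x$report, row.names = FALSE)
  cat(sprintf("%d SNPs retained\n", ncol(x$genotypes)))
  invisible(x)
}
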