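#' VIP-threshold sweep
#'
#' Starting from the full model, refits the PLS regression at each increasing
#' VIP threshold, keeping only variables whose VIP in the *current* model
#' meets the threshold, and re-ranking VIPs after every refit. Retained sets
#' are therefore nested along the sweep. Each entry records the threshold,
#' retained variables, k, number of components, R2, adjusted R2, Q2 and the
#' CV-ANOVA p-value.
#'
#' @param X predictor matrix (original units), as from [build_design()].
#' @param y phenotype vector.
#' @param thresholds increasing VIP thresholds; default `seq(0.8, 1.5, 0.05)`.
#'   A leading 0 entry records the full model.
#' @param folds cross-validation folds.
#' @return object of class `selection_trace`: a data frame with one row per
#'   sweep entry plus a `variables` list-column; per-entry VIP vectors in
#'   attribute `"vips"`.
#' @export
vip_sweep <- function(X, y, thresholds = seq(0.8, 1.5, by = 0.05),
                      folds = 7) {
  X <- as.matrix(X)
  stopifnot(!is.unsorted(thresholds))
  thresholds <- c(0, thresholds[thresholds > 0])
  n <- nrow(X)
  current <- colnames(X)
  entries <- list()
  vips <- list()
  last_fit_vars <- NULL
  fit <- NULL
  for (th in thresholds) {
    if (th > 0 && length(current)) {
      current <- current[fit$vip[current] >= th]
    }
    if (!length(current)) {
      entries[[length(entries) + 1L]] <- data.frame(
        threshold = th, k = 0L, ncomp = NA_integer_, r2 = NA_real_,
        adj_r2 = NA_real_, q2 = NA_real_, cv_anova_p = NA_real_,
        stringsAsFactors = FALSE)
      vips[[length(entries)]] <- numeric(0)
      entries[[length(entries)]]$variables <- I(list(character(0)))
      next
    }
    if (!identical(current, last_fit_vars)) {
      fit <- pls1(X[, current, drop = FALSE], y, folds = folds)
      last_fit_vars <- current
    }
    k <- length(current)
    ca <- cv_anova(X[, current, drop = FALSE], y, fit$ncomp, folds = folds)
    entry <- data.frame(
      threshold = th, k = k, ncomp = fit$ncomp, r2 = fit$r2,
      adj_r2 = if (n - k - 1 >= 1) adjusted_r2(fit$r2, n, k) else NA_real_,
      q2 = fit$q2[length(fit$q2)], cv_anova_p = ca$p.value,
      stringsAsFactors = FALSE)
    entry$variables <- I(list(current))
    entries[[length(entries) + 1L]] <- entry
    vips[[length(entries)]] <- fit$vip
  }
  trace <- do.call(rbind, entries)
  rownames(trace) <- NULL
  structure(trace, vips = vips, class = c("selection_trace", "data.frame"))
}

#' Select the best sweep entry
#'
#' Among sweep entries with CV-ANOVA p < `alpha` (and a defined adjusted R2),
#' picks the entry maximizing the adjusted R2; ties are broken toward the
#' smaller model. When no entry is significant an explicit no-model result is
#' returned.
#'
#' @param trace a [vip_sweep()] trace.
#' @param alpha CV-ANOVA significance level (default 0.05).
#' @return list with `selected` (`TRUE`/`FALSE`), and when selected the
#'   entry `index`, `threshold`, `variables`, `vips`, and the entry's fit
#'   statistics.
#' @export
select_model <- function(trace, alpha = 0.05) {
  stopifnot(inherits(trace, "selection_trace"))
  ok <- which(!is.na(trace$cv_anova_p) & trace$cv_anova_p < alpha &
                !is.na(trace$adj_r2) & trace$k >= 1)
  if (!length(ok)) {
    return(list(selected = FALSE))
  }
  best <- ok[order(-trace$adj_r2[ok], trace$k[ok])][1]
  list(selected = TRUE, index = best, threshold = trace$threshold[best],
       variables = trace$variables[[best]],
       vips = attr(trace, "vips")[[best]],
       k = trace$k[best], ncomp = trace$ncomp[best], r2 = trace$r2[best],
       adj_r2 = trace$adj_r2[best], q2 = trace$q2[best],
       cv_anova_p = trace$cv_anova_p[best])
}

#' De-duplicate a selected variable set by linkage disequilibrium
#'
#' Among the selected SNP variables, groups SNPs whose pairwise dosage
#' r-squared exceeds `r2_threshold` (connected components) and keeps only the
#' member with the highest VIP in each group; VIP ties break by input order.
#' Covariate variables (no underlying SNP) always survive.
#'
#' @param variables selected variable names (`<snp>_add` / `<snp>_dom` or
#'   covariate names).
#' @param vips named VIP vector covering `variables`.
#' @param genotypes dosage matrix holding the SNP columns.
#' @param variable_meta data frame mapping `variable` to `snp` (as attached
#'   by [build_design()]); variables absent from it are treated as
#'   covariates.
#' @param r2_threshold LD threshold (default 0.80).
#' @return character vector: the surviving variables, in input order.
#' @export
ld_dedup_selected <- function(variables, vips, genotypes, variable_meta,
                              r2_threshold = 0.80) {
  snp_of <- variable_meta$snp[match(variables, variable_meta$variable)]
  is_snp <- !is.na(snp_of)
  snp_vars <- variables[is_snp]
  if (length(snp_vars) < 2) {
    return(variables)
  }
  g <- genotypes[, snp_of[is_snp], drop = FALSE]
  r2 <- dosage_r2_matrix(g)
  linked <- !is.na(r2) & r2 > r2_threshold
  diag(linked) <- TRUE
  comp <- graph_components(linked)
  keep <- rep(TRUE, length(snp_vars))
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) > 1) {
      v <- vips[snp_vars[members]]
      winner <- members[which.max(v)] # which.max breaks ties by order
      keep[setdiff(members, winner)] <- FALSE
    }
  }
  survivors <- c(snp_vars[keep], variables[!is_snp])
  variables[variables %in% survivors]
}

#' Fit, sweep, select and de-duplicate in one call
#'
#' The model-building half of the pipeline: fit the full PLS model on all
#' candidate predictors, sweep increasing VIP thresholds, select the entry
#' maximizing adjusted R2 subject to CV-ANOVA significance, prune selected
#' SNPs in mutual LD (keeping the highest VIP per group), refit, and
#' re-verify CV-ANOVA significance of the final model.
#'
#' @param X candidate predictor matrix from [build_design()].
#' @param y phenotype vector.
#' @param genotypes dosage matrix (for the LD pruning step); `NULL` skips
#'   de-duplication.
#' @param thresholds,folds,alpha,r2_threshold tuning parameters; see
#'   [vip_sweep()], [select_model()] and [ld_dedup_selected()].
#' @return object of class `vip_selection`: list with the sweep `trace`, the
#'   `chosen` entry, `final_variables`, the refit `final_model` ([pls1()]),
#'   `final_cv_anova`, and `selected` flag.
#' @export
vip_select <- function(X, y, genotypes = NULL,
                       thresholds = seq(0.8, 1.5, by = 0.05), folds = 7,
                       alpha = 0.05, r2_threshold = 0.80) {
  X <- as.matrix(X)
  trace <- vip_sweep(X, y, thresholds, folds)
  chosen <- select_model(trace, alpha)
  out <- list(trace = trace, chosen = chosen, selected = chosen$selected,
              alpha = alpha)
  if (!chosen$selected) {
    class(out) <- "vip_selection"
    return(out)
  }
  vars <- chosen$variables
  meta <- attr(X, "variables")
  if (is.null(meta)) {
    meta <- data.frame(variable = colnames(X),
                       snp = sub("_(add|dom)$", "", colnames(X)),
                       stringsAsFactors = FALSE)
    meta$snp[!grepl("_(add|dom)$", meta$variable)] <- NA_character_
  }
  if (!is.null(genotypes)) {
    vars <- ld_dedup_selected(chosen$variables, chosen$vips, genotypes, meta,
                              r2_threshold)
  }
  final <- pls1(X[, vars, drop = FALSE], y, folds = folds)
  ca <- cv_anova(X[, vars, drop = FALSE], y, final$ncomp, folds = folds)
  out$dedup_removed <- setdiff(chosen$variables, vars)
  out$final_variables <- vars
  out$final_model <- final
  out$final_cv_anova <- ca
  out$final_adj_r2 <- if (nrow(X) - length(vars) - 1 >= 1)
    adjusted_r2(final$r2, nrow(X), length(vars)) else NA_real_
  out$final_significant <- ca$p.value < alpha
  out$variable_meta <- meta
  class(out) <- "vip_selection"
  out
}

#' @export
print.vip_selection <- function(x, digits = 4, ...) {
  cat("VIP-threshold model selection\n")
  if (!x$selected) {
    cat(sprintf("No sweep entry reached CV-ANOVA p < %.3g: no model selected.\n",
                x$alpha))
    return(invisible(x))
  }
  cat(sprintf("  chosen threshold %.2f: k = %d, A = %d, adj R2 = %.*f\n",
              x$chosen$threshold, x$chosen$k, x$chosen$ncomp, digits,
              x$chosen$adj_r2))
  if (length(x$dedup_removed)) {
    cat(sprintf("  LD pruning removed: %s\n",
                paste(x$dedup_removed, collapse = ", ")))
  }
  cat(sprintf("  final model: k = %d, R2 = %.*f, adj R2 = %s, CV-ANOVA p = %.3g%s\n",
              length(x$final_variables), digits, x$final_model$r2,
              if (is.na(x$final_adj_r2)) "NA" else
                formatC(x$final_adj_r2, digits = digits, format = "f"),
              x$final_cv_anova$p.value,
              if (x$final_significant) "" else " (not significant)"))
  invisible(x)
}

#' @export
summary.vip_selection <- function(object, ...) {
  print(object, ...)
  cat("\nSweep trace:\n")
  print(as.data.frame(object$trace)[, c("threshold", "k", "ncomp", "r2",
                                        "adj_r2", "q2", "cv_anova_p")],
        row.names = FALSE, digits = 4)
  invisible(object)
}
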