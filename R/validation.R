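#' Cross-validation ANOVA for a PLS model
#'
#' F-test comparing the variation explained by the cross-validated model with
#' the cross-validated residual variation:
#' `F = [(SS_y - PRESS) / A] / [PRESS / (n - A - 1)]` referred to
#' `F(A, n - A - 1)`, where `SS_y` is the centered response sum of squares
#' and PRESS comes from the same fold scheme as [q_squared()] (the two share
#' one PRESS computation). PRESS >= SS_y yields p near 1 rather than an
#' error.
#'
#' @param X predictor matrix of the model being judged.
#' @param y response vector.
#' @param ncomp number of PLS components of the model.
#' @param folds,fold_id fold scheme (venetian blinds by default).
#' @return an `htest` with the F statistic, df pair, p-value, and `press`,
#'   `ss` elements.
#' @export
cv_anova <- function(X, y, ncomp, folds = 7, fold_id = NULL) {
  n <- length(y)
  pr <- press_pls(X, y, ncomp, folds, fold_id)
  df2 <- n - ncomp - 1
  stopifnot(df2 >= 1)
  f <- max(0, (pr$ss - pr$press) / ncomp) / (pr$press / df2)
  structure(
    list(statistic = c(F = f), parameter = c(df1 = ncomp, df2 = df2),
         p.value = pf(f, ncomp, df2, lower.tail = FALSE),
         method = "Cross-validation ANOVA for PLS regression",
         data.name = sprintf("%d-component PLS model", ncomp),
         press = pr$press, ss = pr$ss),
    class = "htest"
  )
}

#' Response-permutation validation of a PLS model
#'
#' Refits the model (fixed variable set, number of components re-chosen each
#' time) on `n_perm` random permutations of the response and records, per
#' permutation, the absolute correlation between permuted and original
#' response, R2, and Q2. Least-squares lines of R2 and Q2 against the
#' absolute correlation (including the unpermuted model as the
#' correlation-1 anchor) give the reported intercepts; following standard
#' chemometrics practice the model passes when the Q2 intercept is below
#' 0.05 and the R2 intercept below 0.4.
#'
#' @param X predictor matrix of the final model.
#' @param y response vector.
#' @param n_perm number of permutations (default 100; fewer than 20 warns).
#' @param folds folds used for Q2 and component choice.
#' @param seed integer seed for the permutations.
#' @param max_comp optional cap on components per refit.
#' @return object of class `perm_validation`: list with `records` (data
#'   frame: `perm`, `abs_cor`, `r2`, `q2`; row `perm = 0` is the real
#'   model), `r2_intercept`, `q2_intercept`, `pass`, and `rank_p` (fraction
#'   of permutations with R2 >= the real R2, a permutation p-value-like
#'   rank).
#' @export
permutation_validation <- function(X, y, n_perm = 100, folds = 7, seed = 1L,
                                   max_comp = NULL) {
  X <- as.matrix(X)
  if (n_perm < 20) {
    warning("fewer than 20 permutations: intercept estimates are unstable")
  }
  fit_one <- function(yy) {
    sel <- select_components(X, yy, folds = folds, max_comp = max_comp)
    m <- pls1(X, yy, ncomp = sel$ncomp, folds = folds)
    c(r2 = m$r2, q2 = m$q2[length(m$q2)])
  }
  real <- fit_one(y)
  perms <- with_seed(seed, {
    lapply(seq_len(n_perm), function(i) {
      yp <- sample(y)
      c(abs_cor = abs(cor(y, yp)), fit_one(yp))
    })
  })
  records <- rbind(
    data.frame(perm = 0L, abs_cor = 1, r2 = real["r2"], q2 = real["q2"]),
    do.call(rbind, lapply(seq_along(perms), function(i) {
      data.frame(perm = i, abs_cor = perms[[i]]["abs_cor"],
                 r2 = perms[[i]]["r2"], q2 = perms[[i]]["q2"])
    }))
  )
  rownames(records) <- NULL
  r2_line <- lm(r2 ~ abs_cor, data = records)
  q2_line <- lm(q2 ~ abs_cor, data = records)
  r2_int <- unname(coef(r2_line)[1])
  q2_int <- unname(coef(q2_line)[1])
  structure(
    list(records = records, r2_intercept = r2_int, q2_intercept = q2_int,
         pass = q2_int < 0.05 && r2_int < 0.4,
         rank_p = mean(records$r2[records$perm > 0] >= real["r2"]),
         n_perm = n_perm, seed = seed),
    class = "perm_validation"
  )
}

#' @export
print.perm_validation <- function(x, ...) {
  cat(sprintf("Permutation validation (%d permutations)\n", x$n_perm))
  cat(sprintf("  R2 intercept = %.3f (pass < 0.4), Q2 intercept = %.3f (pass < 0.05)\n",
              x$r2_intercept, x$q2_intercept))
  cat(sprintf("  fraction of permuted R2 >= real R2: %.3f\n", x$rank_p))
  cat(if (x$pass) "  PASS\n" else "  FAIL\n")
  invisible(x)
}

#' Leave-k-out cross-validation profile
#'
#' For each requested `k`, partitions the participants at random (seeded)
#' into folds of size `k` and computes Q2 with models refit on each fold
#' complement. Stability is summarized as the maximum drop of Q2 across the
#' profile.
#'
#' @param X,y model data.
#' @param ncomp number of components.
#' @param ks fold sizes to leave out (default `c(1, 3, 7)`).
#' @param seed partition seed.
#' @return data frame (`k`, `folds`, `q2`) with attribute `"max_drop"`.
#' @export
leave_k_out <- function(X, y, ncomp, ks = c(1, 3, 7), seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(all(ks >= 1), all(ks < n))
  rows <- lapply(seq_along(ks), function(i) {
    k <- ks[i]
    nfold <- ceiling(n / k)
    # random but seeded partition into folds of size <= k
    fold_id <- with_seed(seed + i, {
      sample(rep(seq_len(nfold), length.out = n))
    })
    data.frame(k = k, folds = nfold,
               q2 = q_squared(X, y, ncomp, fold_id = fold_id))
  })
  out <- do.call(rbind, rows)
  attr(out, "max_drop") <- max(out$q2) - min(out$q2)
  out
}

#' Regression-coefficient stability across cross-validation refits
#'
#' Refits the model on each fold complement and summarizes, per variable,
#' the spread of the unstandardized coefficients: mean, delete-group
#' jackknife interval around the full-data coefficient, and the fraction of
#' refits agreeing in sign with the full-data fit.
#'
#' @param X,y model data.
#' @param ncomp number of components.
#' @param folds number of refits (fold complements).
#' @param seed optional seed shuffling fold membership.
#' @param level confidence level of the jackknife interval.
#' @return data frame: `variable`, `full`, `mean`, `sd`, `lower`, `upper`,
#'   `sign_consistency`.
#' @export
coefficient_stability <- function(X, y, ncomp, folds = 7, seed = NULL,
                                  level = 0.95) {
  X <- as.matrix(X)
  n <- nrow(X)
  fold_id <- fold_assignment(n, min(folds, n), seed)
  full <- pls1(X, y, ncomp = ncomp, folds = folds)
  coefs <- sapply(sort(unique(fold_id)), function(f) {
    keep <- fold_id != f
    m <- pls1(X[keep, , drop = FALSE], y[keep],
              ncomp = min(ncomp, sum(keep) - 1), folds = folds)
    m$coefficients
  })
  coefs <- matrix(coefs, nrow = ncol(X),
                  dimnames = list(colnames(X), NULL))
  g <- ncol(coefs)
  jack_se <- sqrt((g - 1) / g * rowSums((coefs - rowMeans(coefs))^2))
  tq <- qt(1 - (1 - level) / 2, df = g - 1)
  full_b <- full$coefficients
  data.frame(
    variable = colnames(X),
    full = unname(full_b),
    mean = unname(rowMeans(coefs)),
    sd = unname(apply(coefs, 1, sd)),
    lower = unname(full_b - tq * jack_se),
    upper = unname(full_b + tq * jack_se),
    sign_consistency = unname(rowMeans(sign(coefs) == sign(full_b))),
    stringsAsFactors = FALSE
  )
}

#' Run the full validation battery on a final model
#'
#' Bundles CV-ANOVA, permutation validation, the leave-k-out profile and
#' coefficient stability into one report.
#'
#' @param X,y final model data.
#' @param ncomp number of components.
#' @param folds CV folds.
#' @param n_perm permutations.
#' @param ks leave-k-out sizes.
#' @param seed seed for permutations and partitions.
#' @return object of class `pls_validation`.
#' @export
validate_model <- function(X, y, ncomp, folds = 7, n_perm = 100,
                           ks = c(1, 3, 7), seed = 1L) {
  structure(
    list(cv_anova = cv_anova(X, y, ncomp, folds),
         permutation = permutation_validation(X, y, n_perm, folds, seed),
         leave_k_out = leave_k_out(X, y, ncomp, ks, seed),
         stability = coefficient_stability(X, y, ncomp, folds)),
    class = "pls_validation"
  )
}

#' @export
print.pls_validation <- function(x, ...) {
  cat("PLS model validation battery\n\n")
  cat(sprintf("CV-ANOVA: F = %.3f on (%d, %d) df, p = %.3g\n",
              unname(x$cv_anova$statistic), x$cv_anova$parameter[1],
              x$cv_anova$parameter[2], x$cv_anova$p.value))
  print(x$permutation)
  cat("\nLeave-k-out Q2:\n")
  print(x$leave_k_out, row.names = FALSE)
  cat(sprintf("  max drop: %.3f\n", attr(x$leave_k_out, "max_drop")))
  cat("\nCoefficient stability:\n")
  print(x$stability, row.names = FALSE, digits = 3)
  invisible(x)
}
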