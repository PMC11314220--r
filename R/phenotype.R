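#' Two-tailed Grubbs test for a single outlier
#'
#' Computes `G = max |x_i - mean(x)| / sd(x)` and compares it with the
#' closed-form critical value
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))`, where `t` is the
#' upper `alpha/(2n)` quantile of the t distribution on `n - 2` degrees of
#' freedom. Single-pass: at most one observation is flagged.
#'
#' @param x numeric vector, length >= 3.
#' @param alpha two-sided significance level (default 0.05).
#' @return list with `outlier` (index of the flagged value, or `NA`),
#'   `statistic` (G), `critical` (G_crit), `p.value` (approximate, clipped to
#'   \[0, 1\]) and `degenerate` (`TRUE` when the sample has zero spread).
#' @export
grubbs_test <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) {
    stop("Grubbs test needs at least 3 values")
  }
  s <- sd(x)
  if (s == 0) {
    return(list(outlier = NA_integer_, statistic = 0, critical = NA_real_,
                p.value = 1, degenerate = TRUE))
  }
  dev <- abs(x - mean(x))
  idx <- which.max(dev)
  g <- dev[idx] / s
  tq <- qt(1 - alpha / (2 * n), df = n - 2)
  gcrit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  # invert the critical-value relation to get an approximate p-value
  denom <- (n - 1)^2 - n * g^2
  p <- if (denom <= 0) 0 else {
    tstat <- sqrt(n * (n - 2) * g^2 / denom)
    min(1, 2 * n * pt(tstat, df = n - 2, lower.tail = FALSE))
  }
  list(outlier = if (g > gcrit) idx else NA_integer_,
       statistic = g, critical = gcrit, p.value = p, degenerate = FALSE)
}

#' Average technical replicates after Grubbs screening
#'
#' Runs a single-pass two-tailed Grubbs test on a participant's replicate
#' measurements (when at least 3 are present), removes the flagged value if
#' any, and returns the arithmetic mean of the survivors.
#'
#' @param values replicate measurements for one participant.
#' @param alpha Grubbs significance level.
#' @return list with `mean`, `n_used`, `outlier` (removed value or `NA`) and
#'   `low_confidence` (`TRUE` when fewer than 2 replicates survive).
#' @export
aggregate_replicates <- function(values, alpha = 0.05) {
  values <- as.numeric(values[!is.na(values)])
  if (length(values) == 0) {
    stop("no replicate values supplied")
  }
  removed <- NA_real_
  if (length(values) >= 3) {
    gt <- grubbs_test(values, alpha)
    if (!is.na(gt$outlier)) {
      removed <- values[gt$outlier]
      values <- values[-gt$outlier]
    }
  }
  list(mean = mean(values), n_used = length(values), outlier = removed,
       low_confidence = length(values) < 2)
}

#' Aggregate a long measurement table into one phenotype per participant
#'
#' @param measurements data frame with columns `participant_id`, `meal`,
#'   `time` and `adipose_atoc` (nmol/g protein), one row per replicate.
#' @param alpha Grubbs significance level used per participant.
#' @return data frame with one row per participant: `participant_id`,
#'   `adipose_atoc` (mean of screened replicates), `n_replicates`,
#'   `outlier_removed`.
#' @export
aggregate_phenotype <- function(measurements, alpha = 0.05) {
  stopifnot(all(c("participant_id", "adipose_atoc") %in% names(measurements)))
  ids <- unique(measurements$participant_id)
  rows <- lapply(ids, function(id) {
    v <- measurements$adipose_atoc[measurements$participant_id == id]
    a <- aggregate_replicates(v, alpha)
    data.frame(participant_id = id, adipose_atoc = a$mean,
               n_replicates = a$n_used,
               outlier_removed = !is.na(a$outlier),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired t-tests for meal and sampling-time effects
#'
#' For each meal, compares fasting vs 8 h post-meal adipose concentrations by
#' a two-sided paired t-test, and compares meals pairwise at matched sampling
#' time. A contrast whose paired differences have zero variance is reported
#' with p = 1 and flagged degenerate. A non-significant battery justifies
#' treating all measurements within a participant as technical replicates.
#'
#' @param measurements long data frame (`participant_id`, `meal`, `time`,
#'   `adipose_atoc`).
#' @return data frame with one row per contrast: `contrast`, `n`, `t`, `df`,
#'   `p`, `degenerate`.
#' @export
paired_meal_tests <- function(measurements) {
  stopifnot(all(c("participant_id", "meal", "time", "adipose_atoc") %in%
                  names(measurements)))
  key <- function(meal, time) {
    sub <- measurements[measurements$meal == meal & measurements$time == time, ]
    v <- sub$adipose_atoc[match(ids, sub$participant_id)]
    v
  }
  ids <- unique(measurements$participant_id)
  meals <- unique(measurements$meal)
  times <- unique(measurements$time)
  contrasts <- list()
  add <- function(label, a, b) {
    ok <- complete.cases(a, b)
    if (sum(ok) < 3) {
      return()
    }
    d <- a[ok] - b[ok]
    if (sd(d) == 0) {
      contrasts[[label]] <<- data.frame(
        contrast = label, n = sum(ok), t = 0, df = sum(ok) - 1, p = 1,
        degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      tt <- t.test(a[ok], b[ok], paired = TRUE)
      contrasts[[label]] <<- data.frame(
        contrast = label, n = sum(ok), t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (length(times) == 2) {
    for (m in meals) {
      add(sprintf("%s: %s vs %s", m, times[1], times[2]),
          key(m, times[1]), key(m, times[2]))
    }
  }
  if (length(meals) >= 2) {
    for (tm in times) {
      pairs <- utils::combn(meals, 2, simplify = FALSE)
      for (pr in pairs) {
        add(sprintf("%s vs %s at %s", pr[1], pr[2], tm),
            key(pr[1], tm), key(pr[2], tm))
      }
    }
  }
  do.call(rbind, c(contrasts, list(make.row.names = FALSE)))
}

#' Percent coefficient of variation
#'
#' `100 * sd / mean`, either from a vector of values or directly from a
#' reported mean and SD (as when recomputing a summary table).
#'
#' @param x numeric vector (ignored when `mean` and `sd` are given).
#' @param mean,sd optional summary statistics.
#' @return percent CV.
#' @export
percent_cv <- function(x = NULL, mean = NULL, sd = NULL) {
  if (is.null(mean) || is.null(sd)) {
    x <- as.numeric(x[!is.na(x)])
    if (length(x) < 2) {
      stop("percent_cv needs at least 2 values")
    }
    mean <- base::mean(x)
    sd <- stats::sd(x)
  }
  if (mean <= 0) {
    stop("percent CV is only defined for a positive mean")
  }
  100 * sd / mean
}

#' Forkman's F-test for equality of two coefficients of variation
#'
#' With sample CVs `c1`, `c2` from independent normal samples, the statistic
#' `F = [c1^2 / (1 + c1^2 (n1-1)/n1)] / [c2^2 / (1 + c2^2 (n2-1)/n2)]`
#' is referred to an F distribution with (n1 - 1, n2 - 1) degrees of freedom
#' (McKay's approximation); the returned p-value is two-sided.
#'
#' @param x,y numeric samples with positive means, each n >= 3.
#' @return an `htest` object with the F statistic, df pair, two-sided p and
#'   the two sample CVs as `estimate`.
#' @export
forkman_cv_test <- function(x, y) {
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 3 || n2 < 3) {
    stop("both samples need at least 3 observations")
  }
  if (mean(x) <= 0 || mean(y) <= 0) {
    stop("coefficients of variation require positive means")
  }
  c1 <- sd(x) / mean(x)
  c2 <- sd(y) / mean(y)
  num <- c1^2 / (1 + c1^2 * (n1 - 1) / n1)
  den <- c2^2 / (1 + c2^2 * (n2 - 1) / n2)
  f <- num / den
  p_low <- pf(f, n1 - 1, n2 - 1)
  p <- 2 * min(p_low, 1 - p_low)
  structure(
    list(statistic = c(F = f), parameter = c(df1 = n1 - 1, df2 = n2 - 1),
         p.value = min(1, p),
         estimate = c(cv1 = c1, cv2 = c2),
         method = "Forkman's test for equality of coefficients of variation",
         data.name = "x and y"),
    class = "htest"
  )
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' @param r Pearson correlation.
#' @param n sample size (n >= 4).
#' @param level confidence level, default 0.95.
#' @return numeric vector `c(lower, upper)` from `tanh(atanh(r) +/-
#'   z_(alpha/2)/sqrt(n-3))`.
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  stopifnot(n >= 4, abs(r) <= 1)
  if (abs(r) == 1) {
    return(c(lower = r, upper = r))
  }
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  c(lower = tanh(z - half), upper = tanh(z + half))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation on pairwise-complete observations, a
#' `level` confidence interval by the Fisher z-transform, and a two-sided
#' p-value from `t = r sqrt(n-2) / sqrt(1-r^2)` on `n - 2` df.
#'
#' @param x,y numeric vectors.
#' @param level confidence level.
#' @return list with `r`, `lower`, `upper`, `p.value`, `n` and `degenerate`
#'   (`TRUE` when |r| = 1, in which case the interval collapses).
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4) {
    stop("pearson_ci needs at least 4 complete pairs")
  }
  r <- cor(x, y)
  degenerate <- abs(r) >= 1 - 1e-12
  ci <- fisher_ci(if (degenerate) sign(r) else r, n, level)
  p <- if (degenerate) 0 else {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, lower = unname(ci[1]), upper = unname(ci[2]), p.value = p,
       n = n, degenerate = degenerate)
}

#' Screen covariates by correlation confidence interval
#'
#' A covariate is retained when the `level` Fisher-z confidence interval of
#' its Pearson correlation with the aggregated phenotype excludes zero.
#'
#' @param phenotype numeric vector (one value per participant).
#' @param covariates data frame of candidate covariates, rows aligned with
#'   `phenotype`.
#' @param level confidence level.
#' @return character vector of retained covariate names; the full per-
#'   covariate table is attached as attribute `"table"`.
#' @export
covariate_screen <- function(phenotype, covariates, level = 0.95) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(phenotype))
  rows <- lapply(names(covariates), function(nm) {
    ci <- pearson_ci(phenotype, covariates[[nm]], level)
    data.frame(covariate = nm, r = ci$r, lower = ci$lower, upper = ci$upper,
               p = ci$p.value, kept = ci$lower > 0 | ci$upper < 0,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(tab$covariate[tab$kept], table = tab)
}
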