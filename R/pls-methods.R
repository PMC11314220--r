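#' @export
print.pls1 <- function(x, digits = 4, ...) {
  cat("PLS1 regression (NIPALS)\n")
  cat(sprintf("  %d observations, %d predictors, %d component(s)\n",
              nrow(x$X), ncol(x$X), x$ncomp))
  cat(sprintf("  R2 = %.*f, Q2 = %.*f (%d-fold CV)\n", digits, x$r2,
              digits, x$q2[length(x$q2)], x$folds))
  invisible(x)
}

#' @export
summary.pls1 <- function(object, ...) {
  tab <- data.frame(
    coefficient = object$coefficients,
    standardized = object$coef_std,
    VIP = object$vip
  )
  out <- list(ncomp = object$ncomp, r2 = object$r2,
              adj_r2 = tryCatch(
                adjusted_r2(object$r2, nrow(object$X), ncol(object$X)),
                error = function(e) NA_real_),
              q2 = object$q2, intercept = object$intercept,
              n = nrow(object$X), k = ncol(object$X),
              coefficients = tab[order(-tab$VIP), ])
  class(out) <- "summary.pls1"
  out
}

#' @export
print.summary.pls1 <- function(x, digits = 4, ...) {
  cat("PLS1 regression (NIPALS)\n")
  cat(sprintf("n = %d, k = %d predictors, A = %d component(s)\n",
              x$n, x$k, x$ncomp))
  cat(sprintf("R2 = %.*f, adjusted R2 = %s, cumulative Q2 = %.*f\n",
              digits, x$r2,
              if (is.na(x$adj_r2)) "undefined (n - k - 1 < 1)" else
                formatC(x$adj_r2, digits = digits, format = "f"),
              digits, x$q2[length(x$q2)]))
  cat(sprintf("Intercept: %.*f\n\n", digits, x$intercept))
  cat("Coefficients (original units), ranked by VIP:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Extract PLS1 coefficients
#'
#' @param object a fitted [pls1()] model.
#' @param standardized return coefficients on the autoscaled scale
#'   (no intercept) instead of original units.
#' @param ... unused.
#' @return named vector; the unstandardized form includes `(Intercept)`.
#' @export
coef.pls1 <- function(object, standardized = FALSE, ...) {
  if (standardized) {
    object$coef_std
  } else {
    c("(Intercept)" = object$intercept, object$coefficients)
  }
}

#' Predict from a PLS1 model
#'
#' @param object a fitted [pls1()] model.
#' @param newdata matrix or data frame with the model's predictor columns;
#'   omitted returns fitted values.
#' @param ... unused.
#' @return numeric predictions in original response units.
#' @export
predict.pls1 <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(object$fitted.values)
  }
  newdata <- as.matrix(newdata)
  missing_cols <- setdiff(names(object$coefficients), colnames(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  X <- newdata[, names(object$coefficients), drop = FALSE]
  object$intercept + drop(X %*% object$coefficients)
}

#' @export
residuals.pls1 <- function(object, ...) {
  object$residuals
}

#' @export
fitted.pls1 <- function(object, ...) {
  object$fitted.values
}

#' Diagnostic plots for a PLS1 model
#'
#' Observed vs predicted response and a VIP bar chart with the conventional
#' VIP = 1 reference line.
#'
#' @param x fitted [pls1()] model.
#' @param which `"fit"`, `"vip"` or both.
#' @param ... passed to the base plotting functions.
#' @export
plot.pls1 <- function(x, which = c("fit", "vip"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (length(which) > 1) {
    old <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(old))
  }
  if ("fit" %in% which) {
    graphics::plot(x$fitted.values, x$y,
                   xlab = "Predicted", ylab = "Observed",
                   main = sprintf("R2 = %.2f", x$r2), ...)
    graphics::abline(0, 1, lty = 2)
  }
  if ("vip" %in% which) {
    v <- sort(x$vip, decreasing = TRUE)
    graphics::barplot(v, las = 2, ylab = "VIP",
                      main = "Variable importance", ...)
    graphics::abline(h = 1, lty = 2)
  }
  invisible(x)
}

#' Simulate responses from a fitted PLS1 model
#'
#' Draws `nsim` response vectors as fitted values plus Gaussian noise with
#' the residual standard deviation of the fit.
#'
#' @param object fitted [pls1()] model.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame with `nsim` columns.
#' @export
simulate.pls1 <- function(object, nsim = 1, seed = NULL, ...) {
  n <- length(object$y)
  df <- max(n - object$ncomp - 1, 1)
  sigma <- sqrt(sum(object$residuals^2) / df)
  draw <- function() object$fitted.values + rnorm(n, sd = sigma)
  sims <- if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    with_seed(seed, replicate(nsim, draw()))
  }
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}
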