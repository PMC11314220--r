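#' Autoscale a predictor matrix and response
#'
#' Centers every predictor column and the response to mean 0 and scales to
#' unit standard deviation (denominator n - 1), i.e. codes all variables "in
#' units of variance". The scaling parameters are returned so fits can be
#' back-transformed to the original units.
#'
#' @param X numeric predictor matrix without missing values.
#' @param y numeric response vector.
#' @return list with `Xs`, `ys`, `x_center`, `x_scale`, `y_center`,
#'   `y_scale`. Errors on a zero-variance column, naming it.
#' @export
autoscale <- function(X, y) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) {
    stop("autoscale requires complete data; impute missing values upstream")
  }
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, sd)
  if (any(x_scale == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(X)[x_scale == 0], collapse = ", "))
  }
  y_center <- mean(y)
  y_scale <- sd(y)
  if (y_scale == 0) {
    stop("response has zero variance")
  }
  list(Xs = sweep(sweep(X, 2, x_center), 2, x_scale, "/"),
       ys = (y - y_center) / y_scale,
       x_center = x_center, x_scale = x_scale,
       y_center = y_center, y_scale = y_scale)
}

# Like autoscale() but tolerant of zero-variance columns (scale set to 1 so
# the centered column is identically zero); used inside cross-validation
# folds, where a rare-genotype column can be constant on the training rows.
autoscale_tolerant <- function(X, y) {
  X <- as.matrix(X)
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, sd)
  x_scale[x_scale == 0] <- 1
  y_center <- mean(y)
  y_scale <- sd(y)
  if (y_scale == 0) {
    y_scale <- 1
  }
  list(Xs = sweep(sweep(X, 2, x_center), 2, x_scale, "/"),
       ys = (y - y_center) / y_scale,
       x_center = x_center, x_scale = x_scale,
       y_center = y_center, y_scale = y_scale)
}

# Core NIPALS PLS1 component extraction on scaled data. Returns weights W,
# X-loadings P, y-loadings q, scores T and the standardized coefficient
# vector b = W (P'W)^-1 q. Components whose weight vector vanishes (response
# residual orthogonal to X residual) truncate the extraction.
nipals_pls1 <- function(Xs, ys, ncomp) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  W <- matrix(0, p, 0)
  P <- matrix(0, p, 0)
  q <- numeric(0)
  Tm <- matrix(0, n, 0)
  Xd <- Xs
  yd <- ys
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      break
    }
    w <- w / nw
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) {
      break
    }
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - t_a * q_a
    W <- cbind(W, w)
    P <- cbind(P, p_a)
    q <- c(q, q_a)
    Tm <- cbind(Tm, t_a)
  }
  A <- length(q)
  coef_std <- if (A == 0) rep(0, p) else
    drop(W %*% solve(crossprod(P, W), q))
  dimnames(W) <- dimnames(P) <- list(colnames(Xs), NULL)
  list(W = W, P = P, q = q, scores = Tm, ncomp = A,
       coef_std = coef_std, X_residual = Xd)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a )` with
#' `SS_a = q_a^2 t_a' t_a` the response variance explained by component `a`.
#' VIPs are normalized so that the mean squared VIP over the `p` predictors
#' is exactly 1; with a single predictor the VIP is 1.
#'
#' @param object a fitted [pls1()] model (or the internal component list).
#' @return named numeric vector of VIPs.
#' @export
vip <- function(object) {
  if (inherits(object, "pls1")) {
    return(object$vip)
  }
  W <- object$W
  q <- object$q
  Tm <- object$scores
  p <- nrow(W)
  A <- length(q)
  if (A == 0) {
    return(stats::setNames(rep(1, p), rownames(W)))
  }
  ss <- q^2 * colSums(Tm^2)
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  v <- sqrt(p * drop(wn^2 %*% ss) / sum(ss))
  stats::setNames(v, rownames(W))
}

#' Adjusted R-squared
#'
#' `1 - (1 - R2) (n - 1) / (n - k - 1)` with `n` the sample size and `k` the
#' number of predictors excluding the constant. Undefined (an error) when
#' `n - k - 1 < 1`, the regime in which the unadjusted R2 of a heavily
#' parameterized model is positively biased.
#'
#' @param r2 unadjusted R-squared.
#' @param n sample size.
#' @param k number of predictors.
#' @return adjusted R-squared (always <= `r2`).
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (n - k - 1 < 1) {
    stop("adjusted R2 undefined: n - k - 1 < 1")
  }
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

# PRESS over cross-validation folds, in original response units. Each fold's
# model is refit from scratch on the remaining rows (including re-estimation
# of the scaling parameters), and held-out rows are predicted with the
# training-fold scaling. Returns PRESS together with the total centered sum
# of squares of y so Q2 and CV-ANOVA share one computation bit for bit.
press_pls <- function(X, y, ncomp, folds = 7, fold_id = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(fold_id)) {
    fold_id <- fold_assignment(n, min(folds, n))
  }
  press <- 0
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    # tolerant scaling: a column constant within the training fold carries no
    # information there; it is centered and left unscaled so its weight is 0
    sc <- autoscale_tolerant(X[!test, , drop = FALSE], y[!test])
    fit <- nipals_pls1(sc$Xs, sc$ys, min(ncomp, sum(!test) - 1, ncol(X)))
    Xt <- sweep(sweep(X[test, , drop = FALSE], 2, sc$x_center), 2,
                sc$x_scale, "/")
    pred <- sc$y_center + sc$y_scale * drop(Xt %*% fit$coef_std)
    press <- press + sum((y[test] - pred)^2)
  }
  list(press = press, ss = sum((y - mean(y))^2), fold_id = fold_id)
}

#' Cross-validated Q-squared
#'
#' `Q2 = 1 - PRESS / SS_y`, where PRESS accumulates squared prediction errors
#' over held-out venetian-blind folds using models (and scaling parameters)
#' refit on the remaining data, and `SS_y` is the centered response sum of
#' squares.
#'
#' @param X predictor matrix (original units).
#' @param y response vector.
#' @param ncomp number of PLS components.
#' @param folds number of cross-validation folds (default 7).
#' @param fold_id optional explicit fold assignment (overrides `folds`).
#' @return Q-squared (can be negative for models worse than the mean).
#' @export
q_squared <- function(X, y, ncomp, folds = 7, fold_id = NULL) {
  pr <- press_pls(X, y, ncomp, folds, fold_id)
  1 - pr$press / pr$ss
}

#' Choose the number of PLS components by cross-validation
#'
#' Components are adopted sequentially while the incremental Q2 of the new
#' component exceeds `threshold` and the cumulative Q2 does not decrease; at
#' least one component is always kept.
#'
#' @param X,y data in original units.
#' @param folds number of venetian-blind folds.
#' @param max_comp upper bound on components (default `min(n - 1, p)`).
#' @param threshold minimum incremental Q2 (default 0.01).
#' @param fold_id optional explicit fold assignment.
#' @return list with `ncomp` and the vector of cumulative `q2` values
#'   evaluated (one per candidate component).
#' @export
select_components <- function(X, y, folds = 7, max_comp = NULL,
                              threshold = 0.01, fold_id = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(max_comp)) {
    max_comp <- min(n - 1, ncol(X))
  }
  max_comp <- max(1, min(max_comp, n - 1, ncol(X)))
  if (is.null(fold_id)) {
    fold_id <- fold_assignment(n, min(folds, n))
  }
  q2 <- numeric(0)
  ncomp <- 1
  for (a in seq_len(max_comp)) {
    q2[a] <- q_squared(X, y, a, fold_id = fold_id)
    if (a == 1) {
      next
    }
    if (q2[a] - q2[a - 1] > threshold && q2[a] >= q2[a - 1]) {
      ncomp <- a
    } else {
      break
    }
  }
  list(ncomp = ncomp, q2 = q2)
}

#' Fit a PLS1 regression model (NIPALS)
#'
#' Partial least squares regression with a single response, fitted by NIPALS
#' component extraction on autoscaled data (all variables coded in units of
#' variance). When `ncomp` is `NULL` the number of components is chosen by
#' venetian-blind cross-validation via [select_components()]. Coefficients
#' are reported both standardized and back-transformed to the original
#' phenotype units (`b_j = b_j_std * sd_y / sd_xj`, intercept
#' `mean_y - sum b_j mean_xj`); the two prediction pathways agree to
#' numerical tolerance.
#'
#' @param X numeric predictor matrix (participants x variables), no missing
#'   values.
#' @param y numeric response vector (phenotype, original units).
#' @param ncomp number of components, or `NULL` to cross-validate.
#' @param folds folds for component selection and the reported Q2.
#' @return an object of class `pls1` with components `ncomp`, `weights`,
#'   `loadings`, `yloadings`, `scores`, `coef_std`, `coefficients`,
#'   `intercept`, `vip`, `r2`, `q2` (cumulative, per component),
#'   `fitted.values`, `residuals`, scaling parameters and the `call`.
#' @seealso [vip()], [q_squared()], [predict.pls1()], [vip_select()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("x", 1:5)))
#' y <- 2 * X[, 1] - X[, 2] + rnorm(40, sd = 0.5)
#' fit <- pls1(X, y)
#' summary(fit)
#' @export
pls1 <- function(X, y, ncomp = NULL, folds = 7) {
  cl <- match.call()
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("X", seq_len(ncol(X)))
  }
  stopifnot(nrow(X) == length(y))
  n <- nrow(X)
  sc <- autoscale(X, y)
  max_comp <- min(n - 1, ncol(X))
  q2 <- NULL
  if (is.null(ncomp)) {
    sel <- select_components(X, y, folds = folds)
    ncomp <- sel$ncomp
    q2 <- sel$q2[seq_len(ncomp)]
  } else {
    if (ncomp > max_comp) {
      warning(sprintf("ncomp reduced from %d to rank bound %d", ncomp,
                      max_comp))
      ncomp <- max_comp
    }
    q2 <- vapply(seq_len(ncomp), function(a)
      q_squared(X, y, a, folds = folds), numeric(1))
  }
  core <- nipals_pls1(sc$Xs, sc$ys, ncomp)
  if (core$ncomp < ncomp) {
    warning(sprintf("extraction stopped at %d component(s) (rank deficiency)",
                    core$ncomp))
    ncomp <- core$ncomp
    q2 <- q2[seq_len(max(ncomp, 1))]
  }
  coef_std <- stats::setNames(core$coef_std, colnames(X))
  b <- coef_std * sc$y_scale / sc$x_scale
  intercept <- sc$y_center - sum(b * sc$x_center)
  fitted <- intercept + drop(X %*% b)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  structure(
    list(ncomp = ncomp, weights = core$W, loadings = core$P,
         yloadings = core$q, scores = core$scores,
         coef_std = coef_std, coefficients = b, intercept = intercept,
         vip = vip(core), r2 = r2, q2 = q2,
         x_center = sc$x_center, x_scale = sc$x_scale,
         y_center = sc$y_center, y_scale = sc$y_scale,
         fitted.values = fitted, residuals = y - fitted,
         y = y, X = X, folds = folds, call = cl),
    class = "pls1"
  )
}
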