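test_that("autoscaling centers, scales and round-trips", {
  inst <- random_instance(30, 4, seed = 1)
  sc <- autoscale(inst$X, inst$y)
  expect_equal(unname(colMeans(sc$Xs)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(sc$Xs, 2, sd)), rep(1, 4), tolerance = 1e-12)
  back <- sweep(sweep(sc$Xs, 2, sc$x_scale, "*"), 2, sc$x_center, "+")
  expect_equal(back, inst$X, tolerance = 1e-10)
  Xc <- inst$X
  Xc[, 2] <- 3
  expect_error(autoscale(Xc, inst$y), "x2")
})

test_that("single-predictor PLS equals simple least squares", {
  inst <- random_instance(25, 1, seed = 2)
  fit <- pls1(inst$X, inst$y, ncomp = 1)
  ref <- lm(inst$y ~ inst$X)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-10)
})

test_that("full-component PLS reproduces ordinary least squares", {
  for (s in 1:10) {
    n <- sample(15:40, 1)
    p <- sample(2:6, 1)
    inst <- random_instance(n, p, seed = 100 + s)
    fit <- pls1(inst$X, inst$y, ncomp = p)
    ref <- unname(coef(lm(inst$y ~ inst$X)))
    expect_equal(unname(coef(fit)), ref, tolerance = 1e-8)
    expect_equal(unname(predict(fit, inst$X)), unname(fitted(lm(inst$y ~ inst$X))),
                 tolerance = 1e-8)
  }
})

test_that("NIPALS deflation conserves the scaled X variance", {
  inst <- random_instance(20, 5, seed = 3)
  sc <- autoscale(inst$X, inst$y)
  core <- tocopls:::nipals_pls1(sc$Xs, sc$ys, 5)
  recon <- sum(vapply(seq_len(core$ncomp), function(a)
    sum((tcrossprod(core$scores[, a], core$P[, a]))^2), numeric(1)))
  expect_equal(recon + sum(core$X_residual^2), sum(sc$Xs^2),
               tolerance = 1e-8)
  # scores of different components are mutually orthogonal
  gram <- crossprod(core$scores)
  expect_equal(gram[upper.tri(gram)], rep(0, sum(upper.tri(gram))),
               tolerance = 1e-8)
})

test_that("VIP is normalized and ranks the generating predictor first", {
  inst <- random_instance(30, 1, seed = 4)
  expect_equal(unname(vip(pls1(inst$X, inst$y, ncomp = 1))), 1,
               tolerance = 1e-10)
  set.seed(5)
  X <- cbind(signal = rnorm(40), noise = rnorm(40))
  y <- 3 * X[, "signal"] + rnorm(40, sd = 0.3)
  fit <- pls1(X, y, ncomp = 2)
  v <- vip(fit)
  expect_true(v["signal"] > 1 && v["noise"] < 1)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)
})

test_that("adjusted R2 follows the penalized formula exactly", {
  expect_equal(adjusted_r2(0.6976, 42, 10), 0.60, tolerance = 5e-4)
  expect_equal(adjusted_r2(0.5, 30, 0), 0.5)
  expect_lte(adjusted_r2(0, 42, 10), 0)
  expect_error(adjusted_r2(0.8, 12, 11), "undefined")
  for (s in 1:20) {
    set.seed(s)
    r2 <- runif(1)
    n <- sample(10:100, 1)
    k <- sample(1:5, 1)
    expect_equal(adjusted_r2(r2, n, k), 1 - (1 - r2) * (n - 1) / (n - k - 1))
    expect_lte(adjusted_r2(r2, n, k), r2)
  }
})

test_that("Q2 matches a brute-force fold-by-fold recomputation", {
  inst <- random_instance(10, 3, seed = 6)
  fold_id <- rep(1:5, 2)
  mine <- q_squared(inst$X, inst$y, ncomp = 2, fold_id = fold_id)
  press <- 0
  for (f in 1:5) {
    test <- fold_id == f
    Xtr <- inst$X[!test, , drop = FALSE]
    ytr <- inst$y[!test]
    ctr <- colMeans(Xtr)
    sctr <- apply(Xtr, 2, sd)
    Xs <- sweep(sweep(Xtr, 2, ctr), 2, sctr, "/")
    ys <- (ytr - mean(ytr)) / sd(ytr)
    core <- tocopls:::nipals_pls1(Xs, ys, 2)
    Xte <- sweep(sweep(inst$X[test, , drop = FALSE], 2, ctr), 2, sctr, "/")
    pred <- mean(ytr) + sd(ytr) * drop(Xte %*% core$coef_std)
    press <- press + sum((inst$y[test] - pred)^2)
  }
  oracle <- 1 - press / sum((inst$y - mean(inst$y))^2)
  expect_equal(mine, oracle, tolerance = 1e-12)
})

test_that("Q2 approaches 1 without noise and stays <= 0 under permutation", {
  inst <- random_instance(40, 3, seed = 7, noise = 1e-8)
  expect_gt(q_squared(inst$X, inst$y, ncomp = 3), 0.999)
  set.seed(8)
  q2_perm <- replicate(30, {
    inst <- random_instance(30, 3, seed = sample.int(1e6, 1))
    q_squared(inst$X, sample(inst$y), ncomp = 2)
  })
  expect_lt(mean(q2_perm), 0)
})

test_that("component selection finds latent dimension and handles noise", {
  # two latent factors, unequal representation in X: the first component
  # captures the dominant factor, a second one is needed for the other
  set.seed(9)
  hits <- sum(replicate(10, {
    n <- 150
    t1 <- rnorm(n)
    t2 <- rnorm(n)
    X <- cbind(sapply(1:5, function(i) t1 + rnorm(n, sd = 0.3)),
               t2 + rnorm(n, sd = 0.3))
    colnames(X) <- paste0("x", 1:6)
    y <- t1 + t2 + rnorm(n, sd = 0.3)
    select_components(X, y)$ncomp == 2
  }))
  expect_gte(hits, 9)

  set.seed(123)
  ynull <- rnorm(30)
  noise <- random_instance(30, 5, seed = 10)
  sel <- select_components(noise$X, ynull)
  expect_equal(sel$ncomp, 1)
  expect_lte(sel$q2[1], 0.05)
  # deterministic rerun on identical input
  expect_identical(sel, select_components(noise$X, ynull))
})

test_that("back-transformed coefficients reproduce standardized predictions", {
  inst <- random_instance(35, 4, seed = 11)
  fit <- pls1(inst$X, inst$y, ncomp = 2)
  sc_pred <- fit$y_center + fit$y_scale *
    drop(sweep(sweep(inst$X, 2, fit$x_center), 2, fit$x_scale, "/") %*%
           fit$coef_std)
  expect_equal(unname(predict(fit, inst$X)), unname(sc_pred),
               tolerance = 1e-10)
  # doubling one predictor's units halves its unstandardized coefficient
  X2 <- inst$X
  X2[, 1] <- 2 * X2[, 1]
  fit2 <- pls1(X2, inst$y, ncomp = 2)
  expect_equal(fit2$coefficients[1], fit$coefficients[1] / 2,
               tolerance = 1e-10)
  expect_equal(unname(fit2$coefficients[-1]), unname(fit$coefficients[-1]),
               tolerance = 1e-10)
})

test_that("NIPALS agrees with the mixOmics reference implementation", {
  skip_if_not_installed("mixOmics")
  inst <- random_instance(30, 5, seed = 12)
  fit <- pls1(inst$X, inst$y, ncomp = 2)
  ref <- mixOmics::pls(inst$X, inst$y, ncomp = 2, mode = "regression",
                       scale = TRUE)
  ref_pred <- predict(ref, inst$X)$predict[, 1, 2]
  expect_equal(unname(predict(fit, inst$X)), unname(ref_pred),
               tolerance = 1e-6)
})
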