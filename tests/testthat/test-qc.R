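test_that("call-rate filter applies the 95% threshold at n = 42", {
  g <- matrix(1, 42, 3, dimnames = list(NULL, c("a", "b", "c")))
  g[, 1] <- rep(c(0, 1, 2), 14)
  g[, 2] <- rep(c(0, 1, 2), 14)
  g[, 3] <- rep(c(0, 1, 2), 14)
  g[1:2, 2] <- NA # rate 40/42 = 0.952 -> kept
  g[1:3, 3] <- NA # rate 39/42 = 0.929 -> excluded
  res <- call_rate_filter(g, 0.95)
  expect_identical(colnames(res$genotypes), c("a", "b"))
  expect_identical(res$excluded, "c")
  expect_error(call_rate_filter(g[, 0, drop = FALSE]), "empty")
})

test_that("HWE chi-square matches hand-computed worked examples", {
  perfect <- hwe_test(25, 50, 25)
  expect_equal(unname(perfect$statistic), 0)
  expect_equal(perfect$p.value, 1)

  kept <- hwe_test(30, 10, 2) # expected counts 29.17, 11.67, 1.17
  expect_equal(unname(kept$statistic), 0.857, tolerance = 1e-3)
  expect_equal(kept$p.value, 0.3545, tolerance = 1e-3)

  excluded <- hwe_test(20, 2, 20) # p-hat = 0.5
  expect_equal(unname(excluded$statistic), 34.38, tolerance = 1e-2)
  expect_lt(excluded$p.value, 1e-8)

  mono <- hwe_test(10, 0, 0)
  expect_true(mono$monomorphic)
  expect_equal(unname(mono$statistic), 0)
})

test_that("HWE chi-square equals a first-principles computation", {
  oracle <- function(n0, n1, n2) {
    n <- n0 + n1 + n2
    p <- (n1 + 2 * n2) / (2 * n)
    if (p <= 0 || p >= 1) {
      return(0)
    }
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    sum((c(n0, n1, n2) - e)^2 / e)
  }
  set.seed(7)
  for (i in 1:50) {
    cnt <- as.vector(stats::rmultinom(1, sample(3:50, 1), c(0.3, 0.5, 0.2)))
    expect_equal(unname(hwe_test(cnt[1], cnt[2], cnt[3])$statistic),
                 oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

test_that("dosage r-squared is flip-invariant and matches direct Pearson", {
  g1 <- c(0, 0, 1, 1, 2, 2)
  expect_equal(dosage_r2(g1, g1), 1)
  expect_equal(dosage_r2(g1, 2 - g1), 1)
  # direct product-moment computation on the six pairs: r^2 = 27/40
  g2 <- c(0, 1, 1, 2, 2, 2)
  expect_equal(dosage_r2(g1, g2), 27 / 40, tolerance = 1e-12)
  expect_true(is.na(dosage_r2(g1, rep(1, 6))))
  expect_true(is.na(dosage_r2(c(0, NA, NA, NA, NA, 2), g2)))
})

test_that("greedy tag-SNP selection follows the most-connected-first rule", {
  # base dosage patterns engineered for exact correlations
  a <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1, 0, 2)
  b <- a
  b[1] <- 1 # r^2 > 0.8 with a
  cc <- a
  cc[7] <- 1
  d <- c(2, 0, 0, 2, 1, 0, 1, 2, 0, 1, 2, 0)
  e <- c(1, 1, 0, 2, 0, 2, 2, 0, 1, 0, 1, 2)
  g <- cbind(A = a, B = b, C = cc, D = d, E = e)
  stopifnot(dosage_r2(a, b) > 0.8, dosage_r2(a, cc) > 0.8)
  res <- tag_snp_selection(g, 0.80)
  expect_identical(res$tags, c("A", "D", "E"))
  expect_setequal(res$bins$A, c("A", "B", "C"))

  # all pairwise r^2 below threshold: every SNP its own tag
  res2 <- tag_snp_selection(g[, c("A", "D", "E")], 0.80)
  expect_identical(res2$tags, c("A", "D", "E"))

  # three mutually perfect copies: a single tag
  res3 <- tag_snp_selection(cbind(X = a, Y = a, Z = a), 0.80)
  expect_length(res3$tags, 1)
})

test_that("perfect-pair dedup keeps exactly one survivor, reproducibly", {
  a <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1)
  d <- c(2, 0, 0, 2, 1, 0, 1, 2, 0, 1)
  g <- cbind(A = a, B = a, C = d)
  r1 <- dedup_perfect_pairs(g, seed = 5)
  expect_length(r1$excluded, 1)
  expect_true(r1$excluded %in% c("A", "B"))
  expect_true("C" %in% colnames(r1$genotypes))
  r2 <- dedup_perfect_pairs(g, seed = 5)
  expect_identical(colnames(r1$genotypes), colnames(r2$genotypes))

  clean <- dedup_perfect_pairs(cbind(A = a, C = d), seed = 1)
  expect_length(clean$excluded, 0)
})

test_that("QC cascade chains, flags planted violations, and is idempotent", {
  g <- toy_genotypes(n = 60, seed = 3)
  # plant: low call rate column, HWE-violating column, duplicate column
  low_cr <- g[, 1]
  low_cr[1:6] <- NA
  hwe_bad <- c(rep(0, 30), rep(2, 30)) # no heterozygotes
  g2 <- cbind(g, bad_cr = low_cr, bad_hwe = hwe_bad, dup = g[, 2])
  res <- run_qc(g2, seed = 9)
  expect_equal(sum(res$report$n_excluded), 3)
  expect_setequal(
    res$exclusions$stage[match(c("bad_cr", "bad_hwe"), res$exclusions$snp)],
    c("call_rate", "hwe"))
  # the duplicate pair is resolved at tag selection or perfect dedup
  expect_true(xor("dup" %in% colnames(res$genotypes),
                  "snp2" %in% colnames(res$genotypes)))
  # report chains stage by stage
  expect_true(all(res$report$n_out == res$report$n_in - res$report$n_excluded))
  expect_equal(res$report$n_in[-1], res$report$n_out[-nrow(res$report)])
  # column order of survivors preserves input order
  expect_identical(colnames(res$genotypes),
                   intersect(colnames(g2), colnames(res$genotypes)))
  # idempotence
  res2 <- run_qc(res$genotypes, seed = 9)
  expect_identical(colnames(res2$genotypes), colnames(res$genotypes))
  expect_equal(sum(res2$report$n_excluded), 0)
})

test_that("clean simulated panel passes QC without exclusions", {
  g <- toy_genotypes(n = 80, seed = 17)
  res <- run_qc(g)
  expect_equal(sum(res$report$n_excluded), 0)
  expect_identical(colnames(res$genotypes), colnames(g))
})
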