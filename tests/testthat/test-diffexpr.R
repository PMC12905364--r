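test_that("size factors follow median-of-ratios", {
  k <- matrix(rpois(200, 50), 50)
  same <- cbind(k[, 1], k[, 1], k[, 1])
  expect_equal(size_factors(same), rep(1, 3))
  doubled <- cbind(k, 2 * k[, 1])
  s <- size_factors(doubled)
  expect_equal(s[5] / s[1] /
                 (size_factors(doubled)[5] / size_factors(doubled)[1]), 1)
  # brute-force median-of-ratios on a random NB matrix
  set.seed(12)
  m <- matrix(rnbinom(600, mu = 80, size = 5), 100)
  pos <- rowSums(m > 0) == ncol(m)
  logg <- rowMeans(log(m[pos, ]))
  raw <- apply(m[pos, ], 2, function(col) median(col / exp(logg)))
  expect_equal(size_factors(m), raw / exp(mean(log(raw))))
  # doubled column gets a doubled factor
  m2 <- cbind(m, m[, 1] * 2)
  s2 <- size_factors(m2)
  expect_equal(unname(s2[7] / s2[1]), 2, tolerance = 1e-9)
  # all-zero features only -> total-count fallback with warning
  z <- rbind(c(5, 0, 5), c(0, 5, 5))
  expect_warning(size_factors(z), "fall")
})

test_that("dispersion estimation recovers the simulated value", {
  d <- cohort_design(seed = 1)
  cm <- simulate_feature_counts(2000, d, beta = 0, alpha = 0.2, seed = 2)
  a <- estimate_dispersions(cm$counts)
  expect_gt(median(a), 0.15)
  expect_lt(median(a), 0.25)
  # Poisson data pushed toward the floor as n grows
  pois <- matrix(rpois(500 * 33, 200), 500)
  ap <- estimate_dispersions(pois, rep(1, 33))
  expect_lt(median(ap), 0.01)
})

test_that("nb_wald matches an independent single-feature MLE", {
  set.seed(3)
  n <- 23
  X <- cbind(1, rep(c(1, 0), c(10, 13)))
  s <- runif(n, 0.8, 1.2)
  mu <- s * 100 * 2^(X[, 2] * 1.3)
  y <- rnbinom(n, size = 1 / 0.1, mu = mu)
  fit <- nb_wald(matrix(y, 1), s, 0.1, X, coef = 2)
  bhat <- oracle_nb_mle(y, X, log(s), 0.1)
  expect_equal(fit$log2FoldChange * log(2), bhat[2], tolerance = 1e-4)
})

test_that("large-n low-dispersion fold changes approach the truth", {
  d <- cohort_design(40, 40, 2, seed = 4)
  cm <- simulate_feature_counts(300, d, beta = 2, alpha = 1e-3,
                                libsize_range = c(2e6, 2e6), seed = 5)
  des <- condition_design(cm$samples, c("DCM", "CTRL"))
  r <- nb_wald(cm$counts[, des$keep], rep(1, sum(des$keep)), 1e-3, des$X,
               "cond")
  expect_lt(abs(median(r$log2FoldChange, na.rm = TRUE) - 2), 0.1)
})

test_that("BH adjustment equals the brute-force step-up", {
  set.seed(6)
  d <- cohort_design(seed = 1)
  cm <- simulate_feature_counts(300, d, alpha = 0.2, seed = 7)
  des <- condition_design(cm$samples, c("DCM", "CTRL"))
  k <- cm$counts[, des$keep]
  r <- nb_wald(k, size_factors(k), 0.2, des$X, "cond")
  ok <- !is.na(r$pvalue)
  expect_equal(r$padj[ok], oracle_bh(r$pvalue[ok]))
  # invariant: padj >= p, monotone in p
  expect_true(all(r$padj[ok] >= r$pvalue[ok] - 1e-12))
})

test_that("scaling one sample moves its size factor, not the estimates", {
  d <- cohort_design(seed = 8)
  cm <- simulate_feature_counts(200, d, alpha = 1e-8, seed = 9)
  des <- condition_design(cm$samples, c("DCM", "CTRL"))
  k <- cm$counts[, des$keep]
  k2 <- k; k2[, 3] <- k2[, 3] * 3
  s1 <- size_factors(k); s2 <- size_factors(k2)
  expect_equal(unname((s2[3] / s2[1]) / (s1[3] / s1[1])), 3,
               tolerance = 0.05)
  # with the scaled sample's factor corrected exactly, the scaled sample
  # keeps its normalized contribution and the fold-change estimates stay
  # essentially unchanged (exact equality holds only asymptotically: the
  # GLM score weights a deeper sample more)
  s2e <- s1; s2e[3] <- s1[3] * 3
  r1 <- nb_wald(k, s1, 1e-8, des$X, "cond")
  r2e <- nb_wald(k2, s2e, 1e-8, des$X, "cond")
  expect_lt(max(abs(r1$log2FoldChange - r2e$log2FoldChange), na.rm = TRUE),
            0.05)
})

test_that("all-zero features are excluded from testing and BH", {
  d <- cohort_design(seed = 1)
  cm <- simulate_feature_counts(50, d, alpha = 0.2, seed = 10)
  des <- condition_design(cm$samples, c("DCM", "CTRL"))
  k <- cm$counts[, des$keep]
  k[1, ] <- 0
  r <- nb_wald(k, size_factors(k), 0.2, des$X, "cond")
  expect_true(is.na(r$pvalue[1]))
  expect_true(is.na(r$padj[1]))
})

test_that("permutation cutoff is reproducible and guards small B", {
  d <- cohort_design(5, 5, 2, seed = 11)
  cm <- simulate_feature_counts(150, d, alpha = 0.2, seed = 12)
  des <- condition_design(cm$samples, c("DCM", "CTRL"))
  keep_meta <- cm$samples[des$keep, ]
  k <- cm$counts[, des$keep]
  c1 <- permutation_cutoff(k, keep_meta, c("DCM", "CTRL"), B = 25, seed = 5)
  c2 <- permutation_cutoff(k, keep_meta, c("DCM", "CTRL"), B = 25, seed = 5)
  expect_identical(c1$min_p, c2$min_p)
  expect_identical(c1$alpha_star, c2$alpha_star)
  expect_gt(c1$alpha_star, 0)
  expect_lt(c1$alpha_star, 1)
  expect_error(permutation_cutoff(k, keep_meta, c("DCM", "CTRL"), B = 10),
               "B")
  # relabeling within a group leaves the Wald fit unchanged
  perm <- c(2, 1, seq_len(ncol(k))[-(1:2)])
  r1 <- nb_wald(k, size_factors(k), 0.2, des$X, "cond")
  r2 <- nb_wald(k[, perm], size_factors(k)[perm], 0.2,
                des$X[perm, ], "cond")
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-10)
})

test_that("TPM columns sum to one million with the length weighting", {
  expect_equal(unname(tpm(matrix(5, 1, 3), 100)[1, ]), rep(1e6, 3))
  two <- tpm(matrix(c(10, 10), 2, 1), c(1000, 2000))
  expect_equal(unname(two[1, 1] / two[2, 1]), 2)
  set.seed(13)
  m <- matrix(rpois(300, 40), 50)
  expect_equal(unname(colSums(tpm(m, sample(500:2000, 50)))),
               rep(1e6, 6), tolerance = 1e-9)
})

test_that("Mann-Whitney comparison matches exact enumeration", {
  x <- rbind(a = c(1, 2, 3, 4, 5, 6))
  g <- rep(c("A", "B"), each = 3)
  r <- group_compare_tpm(x, g)
  expect_equal(r$pvalue, 0.1)          # 2/20 orderings as extreme
  same <- rbind(a = rep(2, 6))
  expect_equal(group_compare_tpm(same, g)$pvalue, 1)
  # power is monotone in the shift
  set.seed(14)
  shift_p <- vapply(c(0, 2, 6), function(s) {
    m <- matrix(rnbinom(50 * 20, mu = 50, size = 5), 50)
    m[, 11:20] <- m[, 11:20] + s * 5
    median(group_compare_tpm(m, rep(c("A", "B"), each = 10))$pvalue)
  }, numeric(1))
  expect_true(all(diff(shift_p) <= 0))
})
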