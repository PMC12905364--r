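test_that("protein groups aggregate on the linear scale", {
  x <- rbind(pg1 = c(10, 20), pg2 = c(30, 40))
  map <- c(pg1 = "geneA", pg2 = "geneA")
  agg <- aggregate_protein_groups(x, map)
  expect_equal(unname(agg["geneA", 1]), log2(40))   # 10 + 30 -> 5.3219
  expect_equal(unname(agg["geneA", ]), log2(c(40, 60)))
  # single group is the identity (up to log2)
  one <- aggregate_protein_groups(rbind(p = c(8, 16)), c(p = "g"))
  expect_equal(unname(one["g", ]), c(3, 4))
  # log2 input is linearized first
  l2 <- aggregate_protein_groups(log2(x), map, input_scale = "log2")
  expect_equal(l2, agg)
  # randomized map equals brute-force group sums
  set.seed(31)
  m <- matrix(runif(60, 1, 100), 20)
  rownames(m) <- paste0("p", 1:20)
  genes <- sample(paste0("g", 1:5), 20, replace = TRUE)
  agg2 <- aggregate_protein_groups(m, stats::setNames(genes, rownames(m)))
  for (g in unique(genes))
    expect_equal(unname(agg2[g, ]), log2(colSums(m[genes == g, ,
                                                   drop = FALSE])))
})

test_that("study effects equal the normal-equations oracle", {
  # noise-free: recovered effect is exactly the injected one
  cov6 <- data.frame(hf = c(1, 1, 1, 0, 0, 0), age = c(50, 60, 70, 55, 65,
                                                       45),
                     sex = c(1, 0, 1, 0, 1, 0))
  y <- 5 + 1 * cov6$hf + 0.02 * cov6$age + 0.3 * cov6$sex
  eff <- study_effect(matrix(y, 1, dimnames = list("g1", NULL)), cov6)
  expect_equal(eff$effect, 1, tolerance = 1e-10)
  expect_equal(eff$n_hf, 3)

  # noisy 6-sample fixture vs explicit normal equations
  set.seed(32)
  y2 <- y + rnorm(6, 0, 0.4)
  eff2 <- study_effect(matrix(y2, 1, dimnames = list("g1", NULL)), cov6)
  X <- cbind(1, cov6$hf, cov6$age, cov6$sex)
  bh <- solve(t(X) %*% X, t(X) %*% y2)
  res <- y2 - X %*% bh
  s2 <- sum(res^2) / (6 - 4)
  expect_equal(eff2$effect, bh[2], tolerance = 1e-10)
  expect_equal(eff2$se, sqrt(s2 * solve(t(X) %*% X)[2, 2]),
               tolerance = 1e-10)

  # constant covariate dropped with a warning
  cov_c <- transform(cov6, sex = 1)
  expect_warning(study_effect(matrix(y2, 1), cov_c), "sex")
})

test_that("DerSimonian-Laird equals its closed forms", {
  two <- data.frame(effect = c(1, 1), se = c(1, 1))
  m <- meta_re(two)
  expect_equal(m$mu, 1)
  expect_equal(m$Q, 0)
  expect_equal(m$tau2, 0)
  expect_equal(m$I2, 0)
  expect_equal(m$ci_lo, 1 - 1.96 * m$se)

  # equal se, tau2 = 0 -> arithmetic mean
  eq <- data.frame(effect = c(0.2, 0.4, 0.6), se = rep(0.5, 3))
  m2 <- meta_re(eq)
  expect_equal(m2$mu, 0.4)
  # duplicated study at equal se: mu = y, I2 = 0
  dup <- data.frame(effect = rep(0.7, 4), se = rep(0.3, 4))
  m3 <- meta_re(dup)
  expect_equal(m3$mu, 0.7)
  expect_equal(m3$I2, 0)
  expect_error(meta_re(data.frame(effect = 1, se = 1)), "two studies")
  # hand-computed heterogeneous fixture
  het <- data.frame(effect = c(0, 1), se = c(0.1, 0.1))
  w <- 1 / 0.01
  Q <- w * (0 - 0.5)^2 + w * (1 - 0.5)^2
  tau2 <- (Q - 1) / (2 * w - (2 * w^2) / (2 * w))
  m4 <- meta_re(het)
  expect_equal(m4$Q, Q)
  expect_equal(m4$tau2, tau2)
  expect_equal(m4$I2, (Q - 1) / Q * 100)
  # REML option returns a valid pooled result too
  m5 <- meta_re(het, method = "REML")
  expect_equal(m5$mu, 0.5, tolerance = 1e-6)
})

test_that("percent_change inverts the log2 ratio", {
  expect_equal(round(percent_change(0.33)), 26)
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(1), 100)
  ratios <- c(1.3, 0.5, 2.7)
  expect_equal(percent_change(log2(ratios)), (ratios - 1) * 100)
})

test_that("forest table carries study rows plus the pooled row", {
  eff <- data.frame(study_id = paste0("s", 1:3),
                    effect = c(0.2, 0.4, 0.3), se = c(0.1, 0.15, 0.2))
  m <- meta_re(eff)
  ft <- forest_table(m, eff)
  expect_equal(nrow(ft), 4)
  expect_equal(ft$ci_lo[1:3], eff$effect - 1.96 * eff$se)
  expect_equal(ft$effect[4], m$mu)
  expect_equal(sum(ft$weight[1:3]), 100)
})

test_that("nine-sector classification partitions the joined genes", {
  rna <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1, -1, 0.2, 1),
                    significant = c(TRUE, TRUE, FALSE, TRUE))
  prot <- data.frame(gene = c("a", "b", "c", "d"),
                     log2fc = c(0.5, -0.5, 0.1, -0.4),
                     significant = c(TRUE, TRUE, FALSE, TRUE))
  ns <- nine_sector(rna, prot)
  expect_equal(ns$sectors$sector[ns$sectors$gene == "a"], 3)  # both up
  expect_equal(ns$sectors$sector[ns$sectors$gene == "b"], 7)  # both down
  expect_equal(ns$sectors$sector[ns$sectors$gene == "c"], 5)  # both NS
  expect_equal(ns$sectors$sector[ns$sectors$gene == "d"], 9)  # discordant
  expect_equal(ns$summary$concordant, 2)
  expect_equal(ns$summary$concordance_fraction, 0.5)

  # random flags: counts sum to the join size and match a brute force grid
  set.seed(33)
  n <- 200
  rna2 <- data.frame(gene = paste0("g", 1:n), log2fc = rnorm(n),
                     significant = runif(n) < 0.4)
  prot2 <- data.frame(gene = paste0("g", 1:n), log2fc = rnorm(n),
                      significant = runif(n) < 0.4)
  ns2 <- nine_sector(rna2, prot2)
  expect_equal(sum(ns2$summary[paste0("sector", 1:9)]), n)
  brute <- mapply(function(rl, rs, pl, ps) {
    rstate <- if (!rs) "NS" else if (rl > 0) "up" else "down"
    pstate <- if (!ps) "NS" else if (pl > 0) "up" else "down"
    3 * (match(pstate, c("up", "NS", "down")) - 1) +
      match(rstate, c("down", "NS", "up"))
  }, rna2$log2fc, rna2$significant, prot2$log2fc, prot2$significant)
  expect_equal(ns2$sectors$sector, unname(brute))
})
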