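test_that("generators are pure functions of (spec, seed)", {
  a1 <- make_annotation(25, seed = 5)
  a2 <- make_annotation(25, seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  write_transcripts(a1, f1); write_transcripts(a2, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical GTF
  expect_false(identical(readLines(f1),
                         {f3 <- tempfile()
                          write_transcripts(make_annotation(25, seed = 6), f3)
                          readLines(f3)}))
  p1 <- perturb_transcripts(a1, n = 50, seed = 3)
  p2 <- perturb_transcripts(a1, n = 50, seed = 3)
  expect_identical(p1$truth, p2$truth)
  m1 <- simulate_motility(seed = 9); m2 <- simulate_motility(seed = 9)
  expect_identical(m1, m2)
  # global RNG stream untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_annotation(5, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("isoform counts follow the requested distribution", {
  p <- default_isoform_distribution()
  ann <- make_annotation(1200, seed = 17)
  counts <- tabulate(isoforms_per_gene(ann), nbins = length(p))
  gof <- suppressWarnings(chisq.test(counts, p = p))
  expect_gt(gof$p.value, 0.001)
  expect_error(make_annotation(10, isoform_count_distribution = c(0, 0)),
               "mass")
  one <- make_annotation(1, isoform_count_distribution = 1, seed = 1)
  expect_equal(length(one$tx), 1)
})

test_that("truth labels are validated by the independent classifier oracle", {
  ann <- make_annotation(60, seed = 21)
  mix <- default_event_mix()
  mix["intronic_fragment"] <- 0.03
  mix["exon_intron_fragment"] <- 0.03
  p <- perturb_transcripts(ann, event_mix = mix / sum(mix), n = 250,
                           seed = 22)
  refs <- unname(ann$tx)
  got <- vapply(p$transcripts, oracle_classify, character(1), refs = refs)
  expect_gte(mean(got == p$truth$class), 0.99)
  # event-type frequencies within binomial error of the mix
  freq <- table(factor(p$truth$event, levels = names(mix)))
  n <- sum(freq)
  for (e in names(mix)) {
    tol <- 4 * sqrt(mix[[e]] * (1 - mix[[e]]) / n) + 0.02
    expect_lt(abs(freq[[e]] / n - mix[[e]] / sum(mix)), tol)
  }
})

test_that("impossible events resample and finally skip with a warning", {
  # mono-exonic-only annotation cannot host an exon skip
  ann <- build_annotation(list(
    transcript_model("t1", "g1", "chr1", "+", cbind(100, 400))))
  expect_warning(
    p <- perturb_transcripts(ann, event_mix = c(exon_skip = 1), n = 5,
                             seed = 1),
    "skipped")
  expect_null(p$truth)
})

test_that("NB counts have the designed moments and switch structure", {
  design <- cohort_design(seed = 2)
  expect_equal(table(design$samples$condition),
               table(factor(rep(c("CTRL", "DCM", "ICM"), c(13, 10, 10)))),
               ignore_attr = TRUE)
  expect_error(cohort_design(n_ctrl = 1), ">= 2")

  # Poisson limit: alpha -> 0, beta = 0, equal library sizes
  d <- cohort_design(seed = 2)
  cm <- simulate_feature_counts(400, d, beta = 0, alpha = 1e-8,
                                libsize_range = c(2e6, 2e6), seed = 3)
  m <- rowMeans(cm$counts)
  v <- apply(cm$counts, 1, var)
  big <- m > 200
  expect_lt(median(v[big] / m[big]), 1.5)   # near-Poisson mean/variance

  # injected beta = 2 -> group mean ratio ~ 4
  cm2 <- simulate_feature_counts(2000, d, beta = 2, alpha = 0.05,
                                 libsize_range = c(2e6, 2e6), seed = 4)
  hf <- cm2$samples$condition != "CTRL"
  ratio <- rowMeans(cm2$counts[, hf]) / rowMeans(cm2$counts[, !hf])
  expect_lt(abs(median(ratio, na.rm = TRUE) - 4) / 4, 0.15)

  # library-size marginal within 3 SD of expectation
  cm3 <- simulate_feature_counts(3000, d, alpha = 0.1,
                                 libsize_range = c(2e6, 2e6), seed = 5)
  tot <- colSums(cm3$counts)
  expect_true(all(abs(tot - 2e6) / sd(tot) < 3 + 1e-9))

  # switch gene proportions recovered from simulated counts
  ann <- make_annotation(40, seed = 6)
  ipg <- isoforms_per_gene(ann)
  multi <- names(which.max(ipg))
  K <- ipg[[multi]]
  expect_gte(K, 2)
  ctrl <- c(0.1, rep(0.9 / (K - 1), K - 1))
  dis <- c(0.6, rep(0.4 / (K - 1), K - 1))
  P <- rbind(CTRL = ctrl, DCM = dis, ICM = dis)
  cm4 <- simulate_counts(ann, d, effect_spec(
    switch_genes = stats::setNames(list(P), multi)), seed = 7)
  ii <- which(cm4$features$gene_id == multi)
  y <- t(cm4$counts[ii, ])
  pr <- isoform_proportions(y, cm4$samples$condition)
  expect_lt(max(abs(pr - P)), 0.05)
})

test_that("proteomics generator honours its degenerate limits", {
  spec0 <- proteomics_study_spec(tau = 0, noise_sd = 0, gamma_age = 0,
                                 gamma_sex = 0, n_genes = 4,
                                 max_groups_per_gene = 2)
  sim <- simulate_proteomics(spec0, seed = 11)
  for (st in sim$studies) {
    gt <- aggregate_protein_groups(st$intensities, st$group2gene)
    eff <- study_effect(gt, st$covariates, st$study_id)
    expect_equal(eff$effect[match(names(sim$beta), eff$gene)],
                 unname(sim$beta), tolerance = 1e-8)
  }
  expect_equal(vapply(sim$studies, function(s) sum(s$covariates$hf),
                      numeric(1)), c(23, 57, 10))
  expect_error(proteomics_study_spec(sizes = list(c(1, 5))), ">= 2")
})

test_that("motility generator sits on the Hill curve and SEM scales", {
  spec <- motility_spec(noise_sd = 0)
  m <- simulate_motility(spec, seed = 1)
  expect_equal(m$velocity,
               hill_velocity(spec$v_min, spec$v_max, spec$pCa50, spec$n_H,
                             m$pCa))
  # at pCa50 the mean velocity is the midpoint
  mid <- motility_spec(noise_sd = 0,
                       grid = data.frame(pCa = 6.6, n = 5))
  expect_equal(unique(simulate_motility(mid, seed = 1)$velocity),
               (728.5 + 120) / 2)
  # SEM per pCa scales as sd/sqrt(n)
  big <- motility_spec(grid = data.frame(pCa = c(5, 9), n = c(400, 100)))
  mm <- simulate_motility(big, seed = 3)
  sems <- vapply(split(mm$velocity, mm$pCa),
                 function(v) sd(v) / sqrt(length(v)), numeric(1))
  expect_lt(abs(sems[["5"]] / sems[["9"]] - 0.5), 0.2)
})
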