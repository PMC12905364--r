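## Negative-binomial Wald differential expression with a permutation-derived
## familywise significance cutoff (minP), plus TPM quantification and
## rank-based per-feature group comparison.
##
## The model is the DESeq-style NB GLM with log link and size-factor offsets,
## variance mu + alpha*mu^2. Dispersion estimation is a deliberately simple
## method-of-moments estimate blended with a 1/mu trend (geometric mean):
## results are "DESeq2-like", not bit-identical to DESeq2's empirical Bayes.

#' Count matrix container
#'
#' @param counts Integer matrix, features x samples.
#' @param samples Data frame of per-sample metadata (must contain a
#'   `condition` column for the cohort workflows; `age`, `sex` optional),
#'   one row per column of `counts`.
#' @param features Optional data frame with `feature_id`, `gene_id`,
#'   `length` (bp, used for TPM).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, features = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (nrow(samples) != ncol(counts))
    stop("samples metadata must have one row per count column",
         call. = FALSE)
  if (is.null(features))
    features <- data.frame(feature_id = rownames(counts) %||%
                             paste0("f", seq_len(nrow(counts))),
                           gene_id = NA_character_, length = NA_real_)
  if (nrow(features) != nrow(counts))
    stop("features metadata must have one row per count row", call. = FALSE)
  if (any(!is.na(features$length) & features$length <= 0))
    stop("feature lengths must be positive", call. = FALSE)
  rownames(counts) <- features$feature_id
  colnames(counts) <- samples$sample %||% colnames(counts)
  structure(list(counts = counts, samples = samples, features = features),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d feature(s) x %d sample(s)\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over features of the ratio of its count to
#' the feature's geometric mean, computed on features positive in every
#' sample, then normalized to geometric mean 1. If no feature is positive
#' everywhere, falls back to total-count ratios with a warning.
#'
#' @param counts Feature x sample count matrix (or `count_matrix`).
#' @return Numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no feature positive in all samples; ",
            "falling back to total-count size factors")
    s <- colSums(counts)
  } else {
    k <- counts[pos, , drop = FALSE]
    logg <- rowMeans(log(k))
    s <- apply(exp(log(k) - logg), 2, stats::median)
  }
  s / exp(mean(log(s)))
}

#' Per-feature NB dispersion with a 1/mu trend blend
#'
#' Method-of-moments per-feature estimate
#' `max(floor, (var - mu) / mu^2)` on size-factor-normalized counts, a
#' least-squares trend `a0 + a1/mu` over features, and a geometric-mean
#' blend of the two on the log scale.
#'
#' @param counts Feature x sample count matrix (or `count_matrix`).
#' @param s Size factors from [size_factors()].
#' @param floor Lower bound for dispersions (default `1e-8`).
#' @return Numeric vector of per-feature dispersions `alpha`.
#' @export
estimate_dispersions <- function(counts, s = size_factors(counts),
                                 floor = 1e-8) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  k <- sweep(counts, 2, s, "/")
  mu <- rowMeans(k)
  v <- apply(k, 1, stats::var)
  a_hat <- pmax(floor, (v - mu) / mu^2)
  a_hat[!is.finite(a_hat)] <- floor
  use <- mu > 0
  if (sum(use) >= 2) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[use]), a_hat[use])
    a0 <- max(fit$coefficients[1], floor)
    a1 <- max(fit$coefficients[2], 0)
    a_tr <- pmax(floor, a0 + a1 / pmax(mu, 1e-6))
  } else a_tr <- pmax(a_hat, floor)
  alpha <- exp(0.5 * log(pmax(a_hat, floor)) + 0.5 * log(a_tr))
  unname(alpha)
}

## Batched IRLS for the NB log-link GLM, one fit per feature with a shared
## design matrix. Weights mu/(1+alpha*mu) are the Fisher-scoring weights for
## known dispersion. p = 2 (intercept + one covariate) is solved in closed
## form across all features; larger designs loop over features for the
## p x p solve only.
nb_irls <- function(Y, X, offset, alpha, tol = 1e-8, max_iter = 100L) {
  nfeat <- nrow(Y); n <- nrow(X); p <- ncol(X)
  O <- matrix(offset, nfeat, n, byrow = TRUE)
  ## initial beta from OLS on log pseudo-counts
  Z0 <- log(sweep(Y + 0.5, 2, exp(offset), "/"))
  XtX_inv <- solve(crossprod(X))
  B <- Z0 %*% X %*% XtX_inv           # nfeat x p
  conv <- rep(FALSE, nfeat)
  xprod <- list()
  for (a in seq_len(p)) for (b in seq_len(a))
    xprod[[paste(a, b)]] <- X[, a] * X[, b]
  for (it in seq_len(max_iter)) {
    eta <- B %*% t(X) + O
    eta <- pmin(pmax(eta, -30), 30)
    Mu <- exp(eta)
    W <- Mu / (1 + alpha * Mu)
    Z <- eta - O + (Y - Mu) / Mu
    WZ <- W * Z
    S <- lapply(xprod, function(xx) as.numeric(W %*% xx))
    R <- lapply(seq_len(p), function(a) as.numeric(WZ %*% X[, a]))
    if (p == 2L) {
      s11 <- S[["1 1"]]; s21 <- S[["2 1"]]; s22 <- S[["2 2"]]
      det <- s11 * s22 - s21^2
      b1 <- (s22 * R[[1]] - s21 * R[[2]]) / det
      b2 <- (s11 * R[[2]] - s21 * R[[1]]) / det
      Bnew <- cbind(b1, b2)
    } else {
      Bnew <- B
      for (f in seq_len(nfeat)) {
        if (conv[f]) next
        A <- matrix(0, p, p)
        for (a in seq_len(p)) for (b in seq_len(a))
          A[a, b] <- A[b, a] <- S[[paste(a, b)]][f]
        rhs <- vapply(R, `[`, numeric(1), f)
        Bnew[f, ] <- tryCatch(solve(A, rhs), error = function(e) rep(NA, p))
      }
    }
    delta <- apply(abs(Bnew - B), 1, max)
    B[!conv, ] <- Bnew[!conv, ]
    conv <- conv | (!is.na(delta) & delta < tol)
    if (all(conv | is.na(delta))) break
  }
  ## covariance at the final fit
  eta <- pmin(pmax(B %*% t(X) + O, -30), 30)
  Mu <- exp(eta)
  W <- Mu / (1 + alpha * Mu)
  SE <- matrix(NA_real_, nfeat, p)
  if (p == 2L) {
    s11 <- as.numeric(W %*% xprod[["1 1"]])
    s21 <- as.numeric(W %*% xprod[["2 1"]])
    s22 <- as.numeric(W %*% xprod[["2 2"]])
    det <- s11 * s22 - s21^2
    SE[, 1] <- sqrt(s22 / det)
    SE[, 2] <- sqrt(s11 / det)
  } else {
    for (f in seq_len(nfeat)) {
      A <- matrix(0, p, p)
      for (a in seq_len(p)) for (b in seq_len(a))
        A[a, b] <- A[b, a] <- sum(W[f, ] * X[, a] * X[, b])
      Ainv <- tryCatch(solve(A), error = function(e) NULL)
      if (!is.null(Ainv)) SE[f, ] <- sqrt(diag(Ainv))
    }
  }
  list(beta = B, se = SE, converged = conv)
}

#' NB Wald differential expression
#'
#' Fits, per feature, a negative-binomial GLM with log link and
#' `log(s)` offsets by iteratively reweighted least squares (convergence
#' `|delta beta| < 1e-8` or 100 iterations) and reports the Wald test for
#' one coefficient. All-zero and non-convergent features get `p = NA` and
#' are excluded from the BH denominator.
#'
#' @param counts Feature x sample count matrix (or `count_matrix`).
#' @param s Size factors.
#' @param alpha Per-feature dispersions (recycled if length 1).
#' @param design Model matrix (samples x coefficients), full rank.
#' @param coef Name or index of the tested coefficient.
#' @return Data frame (`differential_result`): `feature_id`, `baseMean`,
#'   `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`, `converged`.
#' @export
nb_wald <- function(counts, s, alpha, design, coef = 2L) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  X <- as.matrix(design)
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank",
                                 call. = FALSE)
  if (is.character(coef)) coef <- match(coef, colnames(X))
  if (is.na(coef) || coef < 1 || coef > ncol(X))
    stop("unknown coefficient", call. = FALSE)
  alpha <- rep_len(alpha, nrow(counts))
  nonzero <- rowSums(counts) > 0
  nfeat <- nrow(counts)
  beta <- se <- rep(NA_real_, nfeat)
  convv <- rep(NA, nfeat)
  if (any(nonzero)) {
    fit <- nb_irls(counts[nonzero, , drop = FALSE], X, log(s),
                   alpha[nonzero])
    beta[nonzero] <- fit$beta[, coef]
    se[nonzero] <- fit$se[, coef]
    convv[nonzero] <- fit$converged
  }
  stat <- beta / se
  p <- 2 * stats::pnorm(-abs(stat))
  p[!is.na(convv) & !convv] <- NA
  padj <- rep(NA_real_, nfeat)
  ok <- !is.na(p)
  padj[ok] <- stats::p.adjust(p[ok], method = "BH")
  res <- data.frame(
    feature_id = rownames(counts) %||% paste0("f", seq_len(nfeat)),
    baseMean = rowMeans(sweep(counts, 2, s, "/")),
    log2FoldChange = beta / log(2),
    lfcSE = se / log(2),
    stat = stat, pvalue = p, padj = padj,
    converged = convv, stringsAsFactors = FALSE)
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Build a two-condition design matrix from sample metadata
#'
#' @param samples Data frame with a `condition` column; optional covariate
#'   columns are appended.
#' @param contrast Character pair `c(test_level, reference_level)`; samples
#'   of other levels are dropped. The pseudo-level `"HF"` pools DCM and ICM
#'   (the heart-failure-vs-control comparison).
#' @param covariates Character vector of covariate column names.
#' @return List with `X` (model matrix; tested coefficient is `"cond"`) and
#'   `keep` (logical sample selector).
#' @export
condition_design <- function(samples, contrast, covariates = character()) {
  cond_chr <- as.character(samples$condition)
  if ("HF" %in% contrast)
    cond_chr[cond_chr %in% c("DCM", "ICM")] <- "HF"
  keep <- cond_chr %in% contrast
  cond <- as.numeric(cond_chr[keep] == contrast[1L])
  X <- cbind(intercept = 1, cond = cond)
  for (cv in covariates) {
    v <- samples[[cv]][keep]
    if (length(unique(v)) < 2L) {
      warning("dropping constant covariate '", cv, "'")
      next
    }
    X <- cbind(X, as.numeric(v))
    colnames(X)[ncol(X)] <- cv
  }
  list(X = X, keep = keep)
}

#' Permutation-calibrated familywise significance cutoff (minP)
#'
#' Permutes the condition labels `B` times (covariates stay attached to
#' their samples), reruns the Wald test with the original size factors and
#' dispersions, records the minimum raw p-value per permutation, and
#' returns the empirical 5th percentile as the cutoff `alpha_star`
#' (minP familywise calibration at 0.05).
#'
#' @param counts Feature x sample count matrix (or `count_matrix`).
#' @param samples Sample metadata with `condition`.
#' @param contrast `c(test_level, reference_level)`.
#' @param covariates Covariate column names kept in the design.
#' @param B Number of permutations (>= 20; default 100).
#' @param seed RNG seed for the permutation stream.
#' @param s,alpha Optional precomputed size factors / dispersions.
#' @param rule `"minP"` (5th percentile of per-permutation minimum p) or
#'   `"expected1"` (largest cutoff with expected false positives <= 1).
#' @return List of class `permutation_calibration`: `alpha_star`, `min_p`
#'   (length-B vector), `B`, `seed`, `rule`.
#' @export
permutation_cutoff <- function(counts, samples, contrast,
                               covariates = character(), B = 100L,
                               seed = 1L, s = NULL, alpha = NULL,
                               rule = c("minP", "expected1")) {
  rule <- match.arg(rule)
  if (inherits(counts, "count_matrix")) {
    samples <- counts$samples
    counts <- counts$counts
  }
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (rule == "minP" && B < 20L)
    stop("B < 20 gives an unstable 5th percentile; increase B or use ",
         "rule = 'expected1'", call. = FALSE)
  d <- condition_design(samples, contrast, covariates)
  k <- counts[, d$keep, drop = FALSE]
  if (is.null(s)) s <- size_factors(k)
  if (is.null(alpha)) alpha <- estimate_dispersions(k, s)
  cond0 <- d$X[, "cond"]
  perm_p <- with_seed(seed, lapply(seq_len(B), function(b) {
    Xp <- d$X
    Xp[, "cond"] <- sample(cond0)
    nb_wald(k, s, alpha, Xp, coef = "cond")$pvalue
  }))
  min_p <- vapply(perm_p, min, numeric(1), na.rm = TRUE)
  alpha_star <- if (rule == "minP") {
    unname(stats::quantile(min_p, 0.05, type = 7))
  } else {
    ## largest threshold whose expected permutation discovery count is <= 1:
    ## the B-th smallest pooled permutation p-value
    pooled <- sort(unlist(perm_p))
    pooled[min(B, length(pooled))]
  }
  structure(list(alpha_star = alpha_star, min_p = min_p, B = B,
                 seed = seed, rule = rule),
            class = "permutation_calibration")
}

#' Two-condition differential expression with permutation calibration
#'
#' Convenience wrapper: size factors, dispersions, Wald test for
#' `contrast`, BH adjustment, and a `significant` flag at the permutation
#' cutoff (raw `p <= alpha_star`, the scale on which the study reports its
#' cutoffs).
#'
#' @inheritParams permutation_cutoff
#' @param permutations `B` for [permutation_cutoff()]; `0` skips
#'   calibration (no `significant` flag).
#' @return List: `result` (differential_result with `significant`),
#'   `calibration`, `s`, `alpha`.
#' @export
de_analysis <- function(counts, samples = NULL, contrast,
                        covariates = character(), permutations = 100L,
                        seed = 1L) {
  if (inherits(counts, "count_matrix")) {
    samples <- counts$samples
    counts <- counts$counts
  }
  d <- condition_design(samples, contrast, covariates)
  k <- counts[, d$keep, drop = FALSE]
  s <- size_factors(k)
  alpha <- estimate_dispersions(k, s)
  res <- nb_wald(k, s, alpha, d$X, coef = "cond")
  calib <- NULL
  if (permutations > 0L) {
    calib <- permutation_cutoff(k, samples[d$keep, , drop = FALSE],
                                contrast, covariates, B = permutations,
                                seed = seed, s = s, alpha = alpha)
    res$significant <- !is.na(res$pvalue) & res$pvalue <= calib$alpha_star
  }
  list(result = res, calibration = calib, s = s, alpha = alpha)
}

#' Transcripts-per-million normalization
#'
#' `tpm_ij = (k_ij / l_i) / sum_i (k_ij / l_i) * 1e6`.
#'
#' @param counts Feature x sample count matrix (or `count_matrix` with
#'   feature lengths).
#' @param lengths Feature lengths in bp.
#' @return Matrix of TPM values; every column with any signal sums to 1e6.
#' @export
tpm <- function(counts, lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    lengths <- counts$features$length
    counts <- counts$counts
  }
  if (is.null(lengths) || any(is.na(lengths)) || any(lengths <= 0))
    stop("positive feature lengths are required for TPM", call. = FALSE)
  r <- counts / lengths
  sweep(r, 2, colSums(r), "/") * 1e6
}

#' Per-feature Mann-Whitney U comparison of two groups
#'
#' Two-sided; exact when both groups have n <= 8 and no ties, normal
#' approximation with tie correction otherwise (via `stats::wilcox.test`).
#' Identical constant groups give p = 1. BH adjustment across features.
#'
#' @param x Feature x sample numeric matrix (e.g. TPM).
#' @param groups Factor/vector of length `ncol(x)` with two levels.
#' @return Data frame: `feature_id`, `stat` (U), `pvalue`, `padj`.
#' @export
group_compare_tpm <- function(x, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required",
                                  call. = FALSE)
  g1 <- groups == levels(groups)[1L]
  out <- t(apply(x, 1, function(v) {
    if (all(v == v[1L])) return(c(sum(g1) * sum(!g1) / 2, 1))
    exact <- sum(g1) <= 8 && sum(!g1) <= 8 && !anyDuplicated(v)
    w <- suppressWarnings(stats::wilcox.test(v[g1], v[!g1],
                                             exact = exact,
                                             correct = !exact))
    c(unname(w$statistic), w$p.value)
  }))
  data.frame(feature_id = rownames(x) %||% paste0("f", seq_len(nrow(x))),
             stat = out[, 1], pvalue = out[, 2],
             padj = stats::p.adjust(out[, 2], method = "BH"),
             stringsAsFactors = FALSE)
}
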