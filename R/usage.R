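## Dirichlet-multinomial differential isoform usage (DRIMSeq-style) and
## opposing-direction isoform-switch detection.
##
## Precision theta is shared between null and alternative and estimated under
## the null (pooled proportions); the likelihood-ratio statistic is referred
## to chi-square with (G-1)(K-1) degrees of freedom.

#' Dirichlet-multinomial log-likelihood
#'
#' `sum_j [ lgamma(theta) - lgamma(n_j + theta)
#'          + sum_k ( lgamma(y_jk + theta*pi_k) - lgamma(theta*pi_k) ) ]`,
#' with the convention that isoforms with `pi_k = 0` contribute only when
#' their count is nonzero (then the likelihood is `-Inf`).
#'
#' @param y Samples x isoforms count matrix (one gene).
#' @param pi Proportion vector (sums to 1).
#' @param theta Precision (> 0); large theta approaches the multinomial.
#' @return Log-likelihood (scalar).
#' @export
dm_loglik <- function(y, pi, theta) {
  y <- as.matrix(y)
  if (ncol(y) != length(pi)) stop("pi must have one entry per isoform",
                                  call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1", call. = FALSE)
  if (ncol(y) == 1L) return(0)
  n <- rowSums(y)
  a <- theta * pi
  pos <- a > 0
  if (any(!pos) && any(y[, !pos, drop = FALSE] > 0)) return(-Inf)
  sum(lgamma(theta) - lgamma(n + theta)) +
    sum(sweep(lgamma(sweep(y[, pos, drop = FALSE], 2, a[pos], "+")),
              2, lgamma(a[pos]), "-"))
}

## MLE of pi at fixed theta. K = 2 uses 1-D optimize on the logit; larger K
## maximizes over softmax coordinates (Nelder-Mead from the pooled start).
dm_pi_mle <- function(y, theta) {
  K <- ncol(y)
  cs <- colSums(y)
  start <- (cs + 0.5) / sum(cs + 0.5)
  if (K == 2L) {
    f <- function(l) dm_loglik(y, c(stats::plogis(l), 1 - stats::plogis(l)),
                               theta)
    o <- stats::optimize(f, c(-12, 12), maximum = TRUE, tol = 1e-8)
    p1 <- stats::plogis(o$maximum)
    return(c(p1, 1 - p1))
  }
  f <- function(z) {
    w <- exp(c(z, 0))
    -dm_loglik(y, w / sum(w), theta)
  }
  z0 <- log(start[-K] / start[K])
  o <- stats::optim(z0, f, method = "Nelder-Mead",
                    control = list(maxit = 2000, reltol = 1e-10))
  w <- exp(c(o$par, 0))
  w / sum(w)
}

#' Dirichlet-multinomial likelihood-ratio test for one gene
#'
#' Estimates the precision by 1-D maximization on
#' `log(theta) in [log(1e-2), log(1e6)]` under pooled proportions, refines
#' the pooled proportions at that precision (null), fits per-group
#' proportions at the same precision (alternative), and refers
#' `LR = 2 (ll_alt - ll_null)` to chi-square with `(G-1)(K-1)` df.
#'
#' @param y Samples x isoforms count matrix for one gene.
#' @param groups Factor of length `nrow(y)`.
#' @return One-row data frame (`usage_result`): `K`, `theta`, `lr`, `df`,
#'   `pvalue`, plus a `proportions` attribute (groups x isoforms matrix of
#'   alternative-model estimates). Degenerate genes (one expressed isoform)
#'   return `pvalue = NA`.
#' @export
fit_dm <- function(y, groups) {
  y <- as.matrix(y)
  groups <- droplevels(as.factor(groups))
  expressed <- colSums(y) > 0
  y <- y[, expressed, drop = FALSE]
  K <- ncol(y)
  G <- nlevels(groups)
  out <- data.frame(K = K, theta = NA_real_, lr = NA_real_,
                    df = (G - 1) * (K - 1), pvalue = NA_real_)
  if (K < 2L) return(out)
  pooled <- colSums(y) / sum(y)
  prof <- function(lt) dm_loglik(y, pooled, exp(lt))
  o <- stats::optimize(prof, c(log(1e-2), log(1e6)), maximum = TRUE,
                       tol = 1e-6)
  theta <- exp(o$maximum)
  pi0 <- dm_pi_mle(y, theta)
  ll0 <- dm_loglik(y, pi0, theta)
  ll1 <- 0
  props <- matrix(NA_real_, G, K,
                  dimnames = list(levels(groups), colnames(y)))
  for (g in levels(groups)) {
    yg <- y[groups == g, , drop = FALSE]
    pig <- dm_pi_mle(yg, theta)
    props[g, ] <- pig
    ll1 <- ll1 + dm_loglik(yg, pig, theta)
  }
  lr <- max(0, 2 * (ll1 - ll0))
  out$theta <- theta
  out$lr <- lr
  out$pvalue <- if (G < 2L) 1 else stats::pchisq(lr, out$df,
                                                 lower.tail = FALSE)
  attr(out, "proportions") <- props
  attr(out, "null_pi") <- pi0
  out
}

#' Differential isoform usage across all genes
#'
#' Applies the feasibility filter (gene total >= `min_total` in at least
#' half the samples; isoforms with all-zero counts dropped), runs
#' [fit_dm()] per gene, and BH-adjusts across tested genes.
#'
#' @param counts Transcript x sample count matrix (or `count_matrix`).
#' @param tx2gene Named character vector transcript -> gene (or data frame
#'   with `feature_id`, `gene_id`).
#' @param groups Factor of per-sample group labels.
#' @param min_total Minimum gene total per qualifying sample (default 10).
#' @return Data frame, one row per tested gene: `gene_id`, `K`, `theta`,
#'   `lr`, `df`, `pvalue`, `padj`; excluded genes are reported with
#'   `pvalue = NA` and `reason`.
#' @export
dm_usage <- function(counts, tx2gene, groups, min_total = 10) {
  if (inherits(counts, "count_matrix")) {
    if (missing(tx2gene)) tx2gene <- stats::setNames(
      counts$features$gene_id, counts$features$feature_id)
    counts <- counts$counts
  }
  if (is.data.frame(tx2gene))
    tx2gene <- stats::setNames(tx2gene$gene_id, tx2gene$feature_id)
  gene <- tx2gene[rownames(counts)]
  rows <- list()
  for (gg in sort(unique(gene[!is.na(gene)]))) {
    y <- t(counts[which(gene == gg), , drop = FALSE])
    tot <- rowSums(y)
    if (ncol(y) < 2L) {
      rows[[gg]] <- data.frame(gene_id = gg, K = ncol(y), theta = NA,
                               lr = NA, df = NA, pvalue = NA,
                               reason = "single isoform")
      next
    }
    if (sum(tot >= min_total) < nrow(y) / 2) {
      rows[[gg]] <- data.frame(gene_id = gg, K = ncol(y), theta = NA,
                               lr = NA, df = NA, pvalue = NA,
                               reason = "low expression")
      next
    }
    f <- fit_dm(y, groups)
    rows[[gg]] <- cbind(data.frame(gene_id = gg), f,
                        reason = if (is.na(f$pvalue)) "degenerate" else "")
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$padj <- NA_real_
  ok <- !is.na(res$pvalue)
  res$padj[ok] <- stats::p.adjust(res$pvalue[ok], method = "BH")
  res
}

#' Per-group isoform proportion table
#'
#' Pooled counts per group divided by the group's gene total; the stacked
#' representation behind per-condition proportion plots.
#'
#' @param y Samples x isoforms count matrix for one gene.
#' @param groups Factor of length `nrow(y)`.
#' @return Groups x isoforms matrix of proportions (rows sum to 1).
#' @export
isoform_proportions <- function(y, groups) {
  y <- as.matrix(y)
  groups <- droplevels(as.factor(groups))
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    cs <- colSums(y[groups == g, , drop = FALSE])
    cs / sum(cs)
  }))
  rownames(out) <- levels(groups)
  out
}

#' Detect genes with opposing-direction isoform changes
#'
#' Classifies each isoform as UP (significant, positive fold change), DOWN
#' (significant, negative) or NO from a transcript-level differential
#' result, and flags genes carrying at least one UP and one DOWN isoform.
#'
#' @param de A `differential_result` with a `significant` column (or a
#'   logical vector passed as `significant`).
#' @param tx2gene Named character vector transcript -> gene, or data frame
#'   with `feature_id`, `gene_id`.
#' @param significant Optional logical override of the significance flag.
#' @return Data frame, one row per gene: `gene_id`, `n_up`, `n_down`,
#'   `n_no`, `up_isoforms`, `down_isoforms`, `opposing`.
#' @export
detect_opposing <- function(de, tx2gene, significant = de$significant) {
  if (is.data.frame(tx2gene))
    tx2gene <- stats::setNames(tx2gene$gene_id, tx2gene$feature_id)
  if (is.null(significant))
    stop("a significance flag is required (run de_analysis with ",
         "permutations, or pass `significant`)", call. = FALSE)
  dir <- ifelse(!significant | is.na(de$log2FoldChange), "NO",
                ifelse(de$log2FoldChange > 0, "UP", "DOWN"))
  gene <- tx2gene[de$feature_id]
  rows <- lapply(split(seq_along(dir), gene), function(ii) {
    d <- dir[ii]
    ids <- de$feature_id[ii]
    data.frame(n_up = sum(d == "UP"), n_down = sum(d == "DOWN"),
               n_no = sum(d == "NO"),
               up_isoforms = paste(ids[d == "UP"], collapse = ","),
               down_isoforms = paste(ids[d == "DOWN"], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- cbind(data.frame(gene_id = names(rows)), do.call(rbind, rows))
  rownames(out) <- NULL
  out$opposing <- out$n_up > 0 & out$n_down > 0
  out
}
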