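## Gene-level aggregation of protein-group intensities, covariate-adjusted
## per-study effects, inverse-variance random-effects pooling, fold-change
## conversion, forest-table export and nine-sector RNA-protein concordance.

#' Aggregate protein-group intensities to gene level
#'
#' Sums intensities across all protein groups of a gene on the linear
#' (non-log) scale, then log2-transforms. Tables already on the log2 scale
#' are linearized first (`2^x`).
#'
#' @param intensities Protein-group x sample numeric matrix.
#' @param group2gene Named character vector protein group -> gene, or data
#'   frame with columns `protein_group`, `gene`.
#' @param input_scale `"linear"` or `"log2"`.
#' @return Gene x sample matrix of log2 intensities.
#' @export
aggregate_protein_groups <- function(intensities, group2gene,
                                     input_scale = c("linear", "log2")) {
  input_scale <- match.arg(input_scale)
  if (is.data.frame(group2gene))
    group2gene <- stats::setNames(group2gene$gene, group2gene$protein_group)
  x <- as.matrix(intensities)
  if (input_scale == "log2") x <- 2^x
  gene <- group2gene[rownames(x)]
  if (any(is.na(gene)))
    stop("unmapped protein group: ",
         rownames(x)[is.na(gene)][1], call. = FALSE)
  agg <- rowsum(x, gene)
  log2(agg)
}

#' Covariate-adjusted per-study effect sizes
#'
#' Ordinary least squares `y = b0 + b1*HF + b2*age + b3*sex` per gene; the
#' effect is the HF coefficient with its standard error from the unbiased
#' residual-variance estimator. Constant (collinear) covariates are dropped
#' with a warning.
#'
#' @param y Gene x sample matrix of log2 intensities.
#' @param covariates Data frame with `hf` (0/1) and optional `age`, `sex`
#'   columns, one row per sample.
#' @param study_id Label attached to the output rows.
#' @return Data frame (`study_effect`): `study_id`, `gene`, `effect`, `se`,
#'   `n_hf`, `n_ctrl`, plus residual diagnostics `shapiro_p` and
#'   `scale_location_slope` (reported, never gating).
#' @export
study_effect <- function(y, covariates, study_id = "study") {
  y <- as.matrix(y)
  X <- cbind(intercept = 1, hf = as.numeric(covariates$hf))
  for (cv in intersect(c("age", "sex"), names(covariates))) {
    v <- as.numeric(covariates[[cv]])
    if (length(unique(v)) < 2L) {
      warning("study ", study_id, ": dropping constant covariate '", cv, "'")
      next
    }
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X)) {
    ## drop trailing collinear columns
    keep <- qr(X)$pivot[seq_len(qr(X)$rank)]
    warning("study ", study_id, ": rank-deficient design, dropping ",
            paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  fit <- stats::lm.fit(X, t(y))
  B <- t(fit$coefficients)
  res <- t(fit$residuals)
  sigma2 <- rowSums(res^2) / (n - p)
  XtX_inv <- solve(crossprod(X))
  se_hf <- sqrt(sigma2 * XtX_inv["hf", "hf"])
  fitted <- y - res
  diag_rows <- t(vapply(seq_len(nrow(y)), function(i) {
    sh <- tryCatch(stats::shapiro.test(res[i, ])$p.value,
                   error = function(e) NA_real_)
    sl <- tryCatch(unname(stats::coef(stats::lm.fit(
      cbind(1, fitted[i, ]), sqrt(abs(scale(res[i, ])))))[2]),
      error = function(e) NA_real_)
    c(sh, sl)
  }, numeric(2)))
  data.frame(study_id = study_id,
             gene = rownames(y) %||% paste0("g", seq_len(nrow(y))),
             effect = B[, "hf"], se = se_hf,
             n_hf = sum(covariates$hf == 1),
             n_ctrl = sum(covariates$hf == 0),
             shapiro_p = diag_rows[, 1],
             scale_location_slope = diag_rows[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Inverse-variance random-effects meta-analysis for one gene
#'
#' DerSimonian-Laird: with `w_i = 1/se_i^2`, fixed-effect mean `y_F`,
#' `Q = sum w_i (y_i - y_F)^2`,
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, random-effects
#' weights `1/(se_i^2 + tau2)` give the pooled estimate, its SE, a 95% CI,
#' a two-sided normal p, and `I2 = max(0, (Q - (k-1))/Q) * 100`. `"REML"`
#' estimates tau2 by restricted maximum likelihood instead.
#'
#' @param effects Data frame with `effect` and `se` columns (one row per
#'   study), e.g. rows of [study_effect()] for one gene.
#' @param method `"DL"` (default) or `"REML"`.
#' @return One-row data frame (`meta_result`): `k`, `mu`, `se`, `ci_lo`,
#'   `ci_hi`, `z`, `pvalue`, `Q`, `tau2`, `I2`.
#' @export
meta_re <- function(effects, method = c("DL", "REML")) {
  method <- match.arg(method)
  y <- effects$effect; se <- effects$se
  k <- length(y)
  if (k < 2L) stop("meta-analysis requires data from at least two studies",
                   call. = FALSE)
  if (any(se <= 0)) stop("standard errors must be positive", call. = FALSE)
  w <- 1 / se^2
  yF <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yF)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  if (method == "REML") {
    nll <- function(lt2) {
      t2 <- exp(lt2)
      v <- se^2 + t2
      mu <- sum(y / v) / sum(1 / v)
      0.5 * (sum(log(v)) + log(sum(1 / v)) + sum((y - mu)^2 / v))
    }
    o <- stats::optimize(nll, c(log(1e-10), log(1e4)))
    tau2 <- exp(o$minimum)
    if (tau2 < 1e-8) tau2 <- 0
  }
  ws <- 1 / (se^2 + tau2)
  mu <- sum(ws * y) / sum(ws)
  se_mu <- sqrt(1 / sum(ws))
  z <- mu / se_mu
  I2 <- max(0, (Q - (k - 1)) / Q) * 100
  if (Q == 0) I2 <- 0
  data.frame(k = k, mu = mu, se = se_mu,
             ci_lo = mu - 1.96 * se_mu, ci_hi = mu + 1.96 * se_mu,
             z = z, pvalue = 2 * stats::pnorm(-abs(z)),
             Q = Q, tau2 = tau2, I2 = I2)
}

#' Run the meta-analysis across genes
#'
#' Joins per-study effect tables, keeps genes observed in at least two
#' studies, and pools each with [meta_re()].
#'
#' @param effects Data frame of stacked [study_effect()] rows.
#' @param method Passed to [meta_re()].
#' @return Data frame with one row per pooled gene.
#' @export
meta_all <- function(effects, method = "DL") {
  rows <- lapply(split(effects, effects$gene), function(e) {
    if (nrow(e) < 2L) return(NULL)
    cbind(data.frame(gene = e$gene[1L]), meta_re(e, method = method))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Convert a log2 fold change to percent change
#'
#' `(2^beta - 1) * 100`; e.g. a pooled log2 fold change of 0.33 is a 26%
#' increase (nearest integer).
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @return Percent change.
#' @export
percent_change <- function(log2fc) (2^log2fc - 1) * 100

#' Forest-plot-ready table for one gene
#'
#' @param meta One-row [meta_re()] result.
#' @param effects The per-study rows that produced it.
#' @return Data frame with one row per study plus a `pooled` row; columns
#'   `label`, `effect`, `se`, `ci_lo`, `ci_hi`, `weight` (%).
#' @export
forest_table <- function(meta, effects) {
  ws <- 1 / (effects$se^2 + meta$tau2)
  rows <- data.frame(label = effects$study_id,
                     effect = effects$effect, se = effects$se,
                     ci_lo = effects$effect - 1.96 * effects$se,
                     ci_hi = effects$effect + 1.96 * effects$se,
                     weight = 100 * ws / sum(ws),
                     stringsAsFactors = FALSE)
  rbind(rows,
        data.frame(label = "pooled", effect = meta$mu, se = meta$se,
                   ci_lo = meta$ci_lo, ci_hi = meta$ci_hi, weight = 100))
}

#' Nine-sector RNA-protein concordance classification
#'
#' Each axis is classified down / NS / up from its fold change and
#' significance flag; sectors follow the 3x3 grid row-major with protein
#' rows (up, NS, down) and RNA columns (down, NS, up): sector 3 = both up,
#' 7 = both down (concordant); 1 = RNA down & protein up, 9 = RNA up &
#' protein down (discordant); 5 = neither significant.
#'
#' @param rna Data frame with `gene`, `log2fc`, `significant`.
#' @param protein Data frame with `gene`, `log2fc`, `significant`.
#' @return List: `sectors` (per joined gene: states and sector 1..9) and
#'   `summary` (`n`, per-sector counts, `concordant`, `concordance_fraction`
#'   = |sectors 3 and 7| / genes analyzed).
#' @export
nine_sector <- function(rna, protein) {
  common <- intersect(rna$gene, protein$gene)
  r <- rna[match(common, rna$gene), ]
  p <- protein[match(common, protein$gene), ]
  state <- function(lfc, sig)
    ifelse(!sig | is.na(lfc), "NS", ifelse(lfc > 0, "up", "down"))
  rs <- state(r$log2fc, r$significant)
  ps <- state(p$log2fc, p$significant)
  prow <- match(ps, c("up", "NS", "down"))      # grid row
  rcol <- match(rs, c("down", "NS", "up"))      # grid column
  sector <- (prow - 1L) * 3L + rcol
  sectors <- data.frame(gene = common, rna_log2fc = r$log2fc,
                        rna_state = rs, protein_log2fc = p$log2fc,
                        protein_state = ps, sector = sector,
                        stringsAsFactors = FALSE)
  counts <- tabulate(sector, nbins = 9L)
  concordant <- counts[3] + counts[7]
  list(sectors = sectors,
       summary = data.frame(n = length(common),
                            t(stats::setNames(counts, paste0("sector", 1:9))),
                            concordant = concordant,
                            concordance_fraction =
                              if (length(common)) concordant / length(common)
                              else NA_real_))
}
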