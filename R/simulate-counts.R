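## Cohort design and NB count simulation. Counts follow
## NB(mean = libsize_j * q_i * 2^(x_j * beta_i), dispersion alpha_i) with
## variance mu + alpha*mu^2; isoform-switch genes draw per-sample gene
## totals and thin them multinomially with group-specific proportions, which
## induces the within-gene proportion structure the usage test assumes.

#' Heart-failure cohort design
#'
#' Three groups (CTRL, DCM, ICM) with the study's default sizes
#' 13 / 10 / 10. Ages default to Normal(55, 8) truncated to 30..75 years;
#' sex is Bernoulli(0.7) (male-skewed HF cohort). Deterministic per seed.
#'
#' @param n_ctrl,n_dcm,n_icm Group sizes (each >= 2).
#' @param age,sex Optional explicit per-sample covariates.
#' @param seed RNG seed for covariate generation.
#' @return Object of class `cohort_design` with a `samples` data frame
#'   (`sample`, `condition`, `age`, `sex`).
#' @export
cohort_design <- function(n_ctrl = 13L, n_dcm = 10L, n_icm = 10L,
                          age = NULL, sex = NULL, seed = 1L) {
  if (min(n_ctrl, n_dcm, n_icm) < 2L)
    stop("every group needs >= 2 samples for a differential test",
         call. = FALSE)
  n <- n_ctrl + n_dcm + n_icm
  condition <- factor(rep(c("CTRL", "DCM", "ICM"),
                          c(n_ctrl, n_dcm, n_icm)),
                      levels = c("CTRL", "DCM", "ICM"))
  if (is.null(age) || is.null(sex)) {
    gen <- with_seed(seed, {
      a <- round(pmin(pmax(stats::rnorm(n, 55, 8), 30), 75))
      s <- stats::rbinom(n, 1L, 0.7)
      list(a = a, s = s)
    })
    if (is.null(age)) age <- gen$a
    if (is.null(sex)) sex <- gen$s
  }
  samples <- data.frame(
    sample = sprintf("%s_%02d", condition,
                     unlist(lapply(c(n_ctrl, n_dcm, n_icm), seq_len))),
    condition = condition, age = age, sex = sex,
    stringsAsFactors = FALSE)
  structure(list(samples = samples, seed = seed), class = "cohort_design")
}

#' Effect specification for count simulation
#'
#' @param lfc Named numeric vector of gene-level log2 fold changes applied
#'   to both disease groups versus CTRL, or a list
#'   `list(DCM = ..., ICM = ...)` of named vectors per contrast.
#' @param switch_genes Named list: per gene, a groups x isoforms proportion
#'   matrix (rows `CTRL`, `DCM`, `ICM`, each summing to 1) describing an
#'   isoform-usage switch (e.g. a dominant isoform going 0.1 -> 0.6 in
#'   disease, the TPM3-like pattern).
#' @param dispersion_range NB dispersion alpha drawn log-uniformly per
#'   feature from this range (study values are unstated; `c(0.01, 0.5)` is
#'   a typical bulk RNA-seq spread). A length-1 value fixes alpha.
#' @param libsize_range Library sizes drawn uniformly from this range
#'   (default 1e6..3e6).
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(lfc = numeric(0), switch_genes = list(),
                        dispersion_range = c(0.01, 0.5),
                        libsize_range = c(1e6, 3e6)) {
  for (sw in switch_genes) {
    if (any(abs(rowSums(sw) - 1) > 1e-8))
      stop("switch proportion rows must sum to 1", call. = FALSE)
    if (any(sw < 0)) stop("proportions must be >= 0", call. = FALSE)
  }
  if (any(dispersion_range <= 0)) stop("dispersions must be > 0",
                                       call. = FALSE)
  structure(list(lfc = lfc, switch_genes = switch_genes,
                 dispersion_range = dispersion_range,
                 libsize_range = libsize_range), class = "effect_spec")
}

## expand the lfc spec to a feature x condition matrix of log2 effects
expand_lfc <- function(lfc, feature_gene, conditions) {
  B <- matrix(0, length(feature_gene), length(conditions),
              dimnames = list(NULL, conditions))
  if (is.list(lfc)) {
    for (cond in names(lfc)) {
      hit <- match(feature_gene, names(lfc[[cond]]))
      B[!is.na(hit), cond] <- lfc[[cond]][hit[!is.na(hit)]]
    }
  } else if (length(lfc)) {
    hit <- match(feature_gene, names(lfc))
    for (cond in setdiff(conditions, "CTRL"))
      B[!is.na(hit), cond] <- lfc[hit[!is.na(hit)]]
  }
  B
}

#' Simulate an NB transcript count matrix for a cohort
#'
#' Features are the transcripts of an annotation (or rows of an explicit
#' feature table). Baseline relative abundances are log-normal; per-gene
#' totals are shared across isoforms via multinomial thinning with
#' per-group proportions (Dirichlet-distributed at baseline, overridden for
#' switch genes), and disease effects multiply the mean by `2^lfc`.
#'
#' @param ann_or_features An `annotation`, or a data frame with
#'   `feature_id`, `gene_id`, `length`.
#' @param design A [cohort_design()].
#' @param effects An [effect_spec()].
#' @param seed RNG seed.
#' @return A [count_matrix()] with feature metadata and the design's sample
#'   table.
#' @export
simulate_counts <- function(ann_or_features, design = cohort_design(),
                            effects = effect_spec(), seed = 1L) {
  if (inherits(ann_or_features, "annotation")) {
    features <- data.frame(
      feature_id = names(ann_or_features$tx),
      gene_id = unname(ann_or_features$tx_gene),
      length = vapply(ann_or_features$tx, transcript_length, numeric(1)),
      stringsAsFactors = FALSE)
  } else features <- ann_or_features
  samples <- design$samples
  n <- nrow(samples); m <- nrow(features)
  conds <- levels(samples$condition)
  B <- expand_lfc(effects$lfc, features$gene_id, conds)
  genes <- unique(features$gene_id)
  with_seed(seed, {
    libsize <- stats::runif(n, effects$libsize_range[1],
                            effects$libsize_range[2])
    dr <- effects$dispersion_range
    alpha_gene <- if (length(dr) == 1L) rep(dr, length(genes)) else
      exp(stats::runif(length(genes), log(dr[1]), log(dr[2])))
    names(alpha_gene) <- genes
    ## gene relative abundances (log-normal, normalized)
    w <- exp(stats::rnorm(length(genes), 0, 1.5))
    q_gene <- stats::setNames(w / sum(w), genes)
    counts <- matrix(0L, m, n)
    for (g in genes) {
      ii <- which(features$gene_id == g)
      K <- length(ii)
      ## per-group isoform proportions
      if (g %in% names(effects$switch_genes)) {
        P <- effects$switch_genes[[g]][conds, , drop = FALSE]
      } else if (K > 1L) {
        d <- stats::rgamma(K, shape = 2)
        P <- matrix(d / sum(d), length(conds), K, byrow = TRUE,
                    dimnames = list(conds, NULL))
      } else {
        P <- matrix(1, length(conds), 1L, dimnames = list(conds, NULL))
      }
      beta_g <- B[ii[1L], as.character(samples$condition)]
      mu <- libsize * q_gene[[g]] * 2^beta_g
      tot <- stats::rnbinom(n, size = 1 / alpha_gene[[g]], mu = mu)
      for (j in seq_len(n)) {
        pj <- P[as.character(samples$condition[j]), ]
        counts[ii, j] <- if (K == 1L) tot[j] else
          as.integer(stats::rmultinom(1L, tot[j], pj))
      }
    }
    count_matrix(counts, samples, features)
  })
}

#' Simulate independent NB features (no gene structure)
#'
#' Convenience generator for calibration studies: every feature is an
#' independent NB draw with its own baseline, dispersion and log2 effect.
#'
#' @param n_features Number of features.
#' @param design A [cohort_design()].
#' @param beta Per-feature log2 fold change of disease (DCM+ICM) vs CTRL
#'   (recycled; default 0 = pure null).
#' @param alpha NB dispersion (recycled).
#' @param libsize_range Library-size range.
#' @param seed RNG seed.
#' @return A [count_matrix()] (feature lengths fixed at 1 kb).
#' @export
simulate_feature_counts <- function(n_features, design = cohort_design(),
                                    beta = 0, alpha = 0.2,
                                    libsize_range = c(1e6, 3e6),
                                    seed = 1L) {
  samples <- design$samples
  n <- nrow(samples)
  beta <- rep_len(beta, n_features)
  alpha <- rep_len(alpha, n_features)
  with_seed(seed, {
    libsize <- stats::runif(n, libsize_range[1], libsize_range[2])
    w <- exp(stats::rnorm(n_features, 0, 1.5))
    q <- w / sum(w)
    x <- as.numeric(samples$condition != "CTRL")
    mu <- outer(q, libsize) * 2^outer(beta, x)
    counts <- matrix(stats::rnbinom(n_features * n, size = 1 / alpha,
                                    mu = mu), n_features, n)
    features <- data.frame(feature_id = sprintf("f%05d",
                                                seq_len(n_features)),
                           gene_id = sprintf("fg%05d", seq_len(n_features)),
                           length = 1000)
    count_matrix(counts, samples, features)
  })
}
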