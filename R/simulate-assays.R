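## Proteomics pseudo-study and motility-assay generators.

#' Proteomics study specification
#'
#' Emulates three published myocardial proteomics cohorts with group sizes
#' (HF vs control) 23v11, 57v20 and 10v10. Per study s the true gene effect
#' is `beta_s = beta + Normal(0, tau^2)`; log2 gene abundance per sample is
#' `baseline + beta_s*HF + gamma_age*age + gamma_sex*sex + noise`. Genes
#' may map to several protein groups whose linear intensities split the
#' gene value, to exercise the aggregation step.
#'
#' @param sizes List of `c(n_hf, n_ctrl)` per study.
#' @param beta Named numeric of true log2 effects per gene (genes absent
#'   default to 0); the default carries a TPM3-like gene at 0.33 among
#'   nulls.
#' @param tau Between-study SD of the true effect (log2).
#' @param gamma_age,gamma_sex Covariate effects (log2 per year / log2).
#' @param noise_sd Residual SD of log2 intensities.
#' @param n_genes Number of genes when `beta` names do not enumerate them.
#' @param max_groups_per_gene Protein groups per gene drawn uniformly from
#'   1..this.
#' @return Object of class `proteomics_study_spec`.
#' @export
proteomics_study_spec <- function(sizes = list(c(23L, 11L), c(57L, 20L),
                                               c(10L, 10L)),
                                  beta = c(TPM3 = 0.33, TPM1 = -0.08),
                                  tau = 0.15, gamma_age = 0.01,
                                  gamma_sex = 0.2, noise_sd = 0.5,
                                  n_genes = 30L, max_groups_per_gene = 3L) {
  if (any(vapply(sizes, min, numeric(1)) < 2L))
    stop("study group sizes must be >= 2", call. = FALSE)
  if (tau < 0 || noise_sd < 0) stop("SDs must be >= 0", call. = FALSE)
  structure(list(sizes = sizes, beta = beta, tau = tau,
                 gamma_age = gamma_age, gamma_sex = gamma_sex,
                 noise_sd = noise_sd, n_genes = n_genes,
                 max_groups_per_gene = max_groups_per_gene),
            class = "proteomics_study_spec")
}

#' Simulate per-study proteomics intensity tables
#'
#' @param spec A [proteomics_study_spec()].
#' @param seed RNG seed.
#' @return List of studies, each with `intensities` (linear-scale protein
#'   groups x samples), `covariates` (`sample`, `hf`, `age`, `sex`),
#'   `group2gene` (data frame `protein_group`, `gene`) and `study_id`; plus
#'   `beta` (the named per-gene truth) as an attribute-free list element.
#' @export
simulate_proteomics <- function(spec = proteomics_study_spec(), seed = 1L) {
  with_seed(seed, {
    genes <- names(spec$beta)
    if (length(genes) < spec$n_genes)
      genes <- c(genes, sprintf("GENE%03d",
                                seq_len(spec$n_genes - length(genes))))
    beta <- stats::setNames(rep(0, length(genes)), genes)
    beta[names(spec$beta)] <- spec$beta
    baseline <- stats::rnorm(length(genes), 22, 2)
    names(baseline) <- genes
    ngrp <- sample.int(spec$max_groups_per_gene, length(genes),
                       replace = TRUE)
    studies <- lapply(seq_along(spec$sizes), function(s) {
      n_hf <- spec$sizes[[s]][1]; n_ctrl <- spec$sizes[[s]][2]
      n <- n_hf + n_ctrl
      hf <- rep(c(1, 0), c(n_hf, n_ctrl))
      age <- round(pmin(pmax(stats::rnorm(n, 55 + 5 * hf, 9), 25), 85))
      sex <- stats::rbinom(n, 1, 0.65)
      beta_s <- beta + stats::rnorm(length(genes), 0, spec$tau)
      log2_gene <- outer(baseline, rep(1, n)) +
        outer(beta_s, hf) +
        outer(rep(spec$gamma_age, length(genes)), age, "*") +
        outer(rep(spec$gamma_sex, length(genes)), sex, "*") +
        matrix(stats::rnorm(length(genes) * n, 0, spec$noise_sd),
               length(genes))
      ## split the linear gene value across protein groups
      rows <- list(); map <- list()
      for (gi in seq_along(genes)) {
        k <- ngrp[gi]
        frac <- stats::rgamma(k, 3); frac <- frac / sum(frac)
        for (j in seq_len(k)) {
          pg <- sprintf("%s_PG%d", genes[gi], j)
          rows[[pg]] <- frac[j] * 2^log2_gene[gi, ]
          map[[pg]] <- genes[gi]
        }
      }
      intens <- do.call(rbind, rows)
      colnames(intens) <- sprintf("S%d_%02d", s, seq_len(n))
      list(study_id = paste0("study", s),
           intensities = intens,
           covariates = data.frame(sample = colnames(intens), hf = hf,
                                   age = age, sex = sex,
                                   stringsAsFactors = FALSE),
           group2gene = data.frame(protein_group = names(rows),
                                   gene = unlist(map),
                                   stringsAsFactors = FALSE,
                                   row.names = NULL))
    })
    list(studies = studies, beta = beta)
  })
}

#' Motility assay specification
#'
#' Defaults emulate the Tpm3.12 (TPM3-224) dose-response: v_max 728.5 nm/s
#' and pCa50 6.6 at the assay's per-pCa replicate counts; `tpm1_motility_spec()`
#' gives the Tpm1.1 counterpart (780.1 nm/s, pCa50 6.3). The Hill
#' coefficient and the low-calcium plateau are not printed by the assay
#' summaries; n_H = 2 (typical thin-filament cooperativity) and
#' v_min = 120 nm/s with observation SD 80 nm/s are fixed, realistic
#' choices.
#'
#' @param v_max,v_min Plateau velocities (nm/s), `v_max > v_min >= 0`.
#' @param pCa50 pCa at half-maximal velocity.
#' @param n_H Hill coefficient.
#' @param noise_sd Per-measurement SD (nm/s).
#' @param grid Data frame `pCa`, `n` of replicate counts per calcium level.
#' @return Object of class `motility_spec`.
#' @export
motility_spec <- function(v_max = 728.5, v_min = 120, pCa50 = 6.6,
                          n_H = 2, noise_sd = 80,
                          grid = data.frame(
                            pCa = c(9, 8, 7.8, 7.5, 7.3, 7, 6.8, 6.7, 6.5,
                                    6.3, 6, 5.5, 5.3, 5, 4.5, 4),
                            n = c(12L, 20L, 4L, 12L, 5L, 47L, 16L, 14L,
                                  33L, 22L, 37L, 32L, 6L, 35L, 28L, 71L))) {
  if (!(v_max > v_min) || v_min < 0)
    stop("need v_max > v_min >= 0", call. = FALSE)
  if (any(grid$n < 1L)) stop("replicate counts must be >= 1", call. = FALSE)
  structure(list(v_max = v_max, v_min = v_min, pCa50 = pCa50, n_H = n_H,
                 noise_sd = noise_sd, grid = grid),
            class = "motility_spec")
}

#' Tpm1.1 motility preset
#' @return A [motility_spec()] with v_max 780.1 nm/s, pCa50 6.3 and the
#'   Tpm1.1 assay's replicate grid.
#' @export
tpm1_motility_spec <- function() {
  motility_spec(v_max = 780.1, pCa50 = 6.3,
                grid = data.frame(
                  pCa = c(9, 8, 7.5, 7, 6.8, 6.7, 6.5, 6.3, 6, 5.5, 5.3,
                          5, 4.5, 4.3, 4),
                  n = c(9L, 11L, 6L, 30L, 17L, 11L, 20L, 15L, 24L, 13L,
                        10L, 20L, 23L, 6L, 48L)))
}

#' Simulate a sliding-velocity table
#'
#' Gaussian measurement noise around the Hill curve; velocities may dip
#' slightly below zero at the low plateau, as tracking noise does.
#'
#' @param spec A [motility_spec()].
#' @param seed RNG seed.
#' @return Data frame `pCa`, `velocity`, `replicate`.
#' @export
simulate_motility <- function(spec = motility_spec(), seed = 1L) {
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(spec$grid)), function(i) {
      n <- spec$grid$n[i]
      mu <- hill_velocity(spec$v_min, spec$v_max, spec$pCa50, spec$n_H,
                          spec$grid$pCa[i])
      data.frame(pCa = spec$grid$pCa[i],
                 velocity = mu + stats::rnorm(n, 0, spec$noise_sd),
                 replicate = seq_len(n))
    })
    do.call(rbind, rows)
  })
}
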