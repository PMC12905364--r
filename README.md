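# isoformshift

Isoform-level transcriptome analysis for heart-failure cohorts, as one
reusable R package. It targets analysts working with long-read (e.g.
nanopore cDNA) transcript models from diseased and control myocardium who
need to answer, end to end:

1. **Which observed transcripts are novel, and how?** Structural
   classification of each observed transcript against a reference
   annotation into FSM / ISM / NIC / NNC / fusion / genic / antisense /
   intergenic / genic_intron, from junction-chain comparison.
2. **What local splicing events distinguish the isoforms?** Enumeration of
   SE, A5, A3, AF, AL, RI and MX events per gene, with known/novel
   attribution.
3. **What changes between conditions?** Negative-binomial Wald differential
   expression at gene and transcript level with a permutation-calibrated
   familywise significance cutoff, TPM quantification, and Mann–Whitney
   group comparisons.
4. **Does isoform *usage* shift within a gene?** Dirichlet-multinomial
   likelihood-ratio tests of per-gene isoform proportions, plus detection
   of genes whose isoforms move in opposing directions.
5. **Does protein follow RNA?** Covariate-adjusted per-study effects,
   inverse-variance random-effects meta-analysis (DerSimonian–Laird) with
   Q, τ², I², forest tables, and a nine-sector RNA–protein concordance
   classification.
6. **Does the isoform switch matter functionally?** Hill dose-response
   fitting of in vitro motility data (sliding velocity vs pCa), reporting
   v_max, pCa₅₀, n_H and R².

A seeded synthetic-data module generates every input the pipeline consumes
(annotation, observed transcripts with truth labels, cohort count
matrices, proteomics pseudo-studies, motility tables), so all stages are
fully testable offline.

## Core models

**Counts.** For feature *i* and sample *j* with size factor *s_j*
(median-of-ratios),
`K_ij ~ NB(mu_ij, alpha_i)`, `log mu_ij = log s_j + x_j' beta_i`,
variance `mu + alpha mu^2`. Wald tests use `W = beta_hat / SE`; the
significance cutoff `alpha*` is the empirical 5th percentile of the
minimum raw p-value over B = 100 permutations of the condition labels
(minP familywise calibration at 0.05).

**Usage.** Within a gene with isoform counts `y_j` and totals `n_j`, the
Dirichlet-multinomial log-likelihood
`sum_j [ lnG(theta) - lnG(n_j + theta) + sum_k ( lnG(y_jk + theta pi_k) -
lnG(theta pi_k) ) ]` is maximized with a shared precision θ (estimated
under the pooled null); `LR = 2(ll_alt - ll_null)` is referred to
chi-square with `(G-1)(K-1)` df.

**Meta-analysis.** DerSimonian–Laird: `w_i = 1/se_i²`,
`tau² = max(0, (Q - (k-1)) / (Σw - Σw²/Σw))`, pooled
`mu = Σ w*_i y_i / Σ w*_i` with `w*_i = 1/(se_i² + tau²)`,
`I² = max(0, (Q-(k-1))/Q)·100`.

**Motility.** `v(x) = v_min + (v_max - v_min) / (1 + 10^{n_H (x - pCa50)})`
fitted by weighted nonlinear least squares on per-pCa means (weights =
replicate counts) with a multistart over n_H and pCa₅₀.

## Worked example

```r
library(isoformshift)

ann  <- make_annotation(n_genes = 80, seed = 42)
obs  <- perturb_transcripts(ann, n = 500, seed = 43)
calls <- classify_batch(obs$transcripts, ann)
table(calls$calls$category)
#> antisense    FSM  fusion intergenic   ISM   NIC   NNC
#>        12    165       7          8    85    77   146

design <- cohort_design(seed = 44)          # 13 CTRL, 10 DCM, 10 ICM
beta <- rep(0, 2000); beta[1:40] <- 2; beta[41:80] <- -2
cm <- simulate_feature_counts(2000, design, beta = beta, alpha = 0.2,
                              seed = 45)
de <- de_analysis(cm, contrast = c("HF", "CTRL"), permutations = 100,
                  seed = 46)
de$calibration$alpha_star                    # 4.22e-05
sum(de$result$significant, na.rm = TRUE)     # 79 of 80 injected effects

fit <- fit_hill(simulate_motility(motility_spec(), seed = 47))
fit
#> <dose_response_fit> v_max = 733.4 nm/s, v_min = 111.8 nm/s,
#>                     pCa50 = 6.64, n_H = 1.93, R^2 = 0.988

percent_change(0.33)                         # 25.7 -> a ~26% increase
```

The classifier table shows the perturbation mix coming back as its intended
structural classes; `alpha*` is the permutation-calibrated raw-p cutoff
(here ~4e-5, i.e. far stricter than 0.05); the Hill fit recovers the
generating parameters (v_max 728.5 nm/s, pCa₅₀ 6.6) within noise.

A full pipeline run (`simulate → classify → events → DE → usage → meta →
sectors → motility`) with a JSON manifest:

```r
run_pipeline(pipeline_config(outdir = "run1", seed = 7))
```

or from the shell via the CLI dispatcher:

```sh
Rscript inst/cli/isoformshift.R run --outdir run1 --seed 7
Rscript inst/cli/isoformshift.R classify --ref ref.gtf --obs obs.gtf --out calls.tsv
```

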