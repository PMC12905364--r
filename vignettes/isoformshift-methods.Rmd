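---
title: "isoformshift: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isoformshift: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: what each stage
models, which tunable parameters matter and why their defaults are what
they are, what the synthetic-data generators do and do not emulate, and
where the design was genuinely open. It states no empirical result that
the test suite does not itself compute.

# The problem

End-stage heart failure (dilated and ischemic cardiomyopathy) reorganizes
the cardiac transcriptome at the *isoform* level: the same genes are
expressed, but different transcripts of them. Long-read sequencing yields
full-length transcript models that can be compared structurally against a
reference annotation, counted per sample, and tested for shifts in both
absolute expression and within-gene usage; proteomics meta-analysis and in
vitro motility assays then ask whether an RNA-level isoform switch is
visible in protein abundance and in contractile function. `isoformshift`
implements that chain of analyses as small, testable modules over plain
containers (exon-interval transcript models, count matrices with sample
metadata, delimited tables).

# Transcript model and coordinates

A transcript is an ordered list of disjoint `[start, end)` exon intervals.
Internally all coordinates are 0-based half-open; GTF I/O converts at the
boundary (GTF is 1-based inclusive). This keeps interval arithmetic free
of off-by-one cases while the on-disk format stays standard. Junctions
carry a genomic (left, right) boundary pair plus strand-resolved donor and
acceptor (donor = 5' end of the intron in transcript orientation, so
`donor < acceptor` on `+` and `donor > acceptor` on `-`). Duplicate exon
records are collapsed and touching exons merged (a transcript model is a
partition); overlapping exons within one transcript are an error.
`gene_id` is taken verbatim from the annotation — no overlap-based gene
merging — for determinism.

# Structural classification

Classification compares the query's junction chain against the reference:
identical chain → FSM (terminal exon ends are irrelevant, matching how
long-read terminal softclipping blurs transcript ends); consecutive
sub-chain → ISM; exonic overlap with two same-strand genes plus a bridging
junction → fusion; all junctions (or all donors and acceptors) annotated
but the combination novel → NIC; any unannotated donor or acceptor → NNC;
then the mono-exonic and locus-position rules (FSM-by-containment,
genic_intron, antisense, intergenic, genic). The precedence order is fixed
exactly as listed — fusion before NIC/NNC so multi-gene chains are never
mislabeled — because the original tool's internal order is not fully
documented; determinism matters more here than matching an unspecified
tie-break. Ties among identical reference chains resolve to the
lexicographically smallest transcript id. Two numeric choices:

* **Mono-exonic FSM end tolerance: 50 bp per terminus.** Mono-exonic
  long reads have no junction anchor, so terminal wobble of tens of bases
  is expected; 50 bp is conservative relative to typical softclip lengths
  and is a plain argument (`mono_tol`).
* **Strand is trusted as given.** Without sequence there is no junction
  motif to infer strand from; inference is out of scope.

The classifier is validated two ways that deliberately do not share code:
a brute-force oracle that compares junction lists directly against every
reference transcript, and generator truth labels (below).

# Splice-event enumeration

Events are local, per gene, over reference and observed transcripts
jointly (observed transcripts adopt the gene of their structural call);
an event is *novel* iff any transcript on its inclusion or exclusion side
is a non-FSM/ISM observed transcript. Counting events on observed
transcripts only is available by simply not merging. Definitions are the
standard local-event ones: SE (a cassette exon's flanking junctions vs the
direct skip junction), A5/A3 (junction pairs sharing one boundary in
transcript orientation), AF/AL (distinct non-overlapping terminal exons
splicing into the same inner boundary), RI (one exon spanning exactly a
sibling's exon–junction–exon span), MX (two non-overlapping cassettes
sharing both flanks, immediate neighbors only). Signatures are coordinate
tuples (SE 4, A5/A3 3, RI 4, AF/AL 6, MX 8 slots), which makes
deduplication a string-set operation and makes the brute-force pairwise
oracle comparison exact. No PSI or event-level statistics are computed —
events are counted, not tested.

# Differential expression

The count model is the standard NB GLM with log link, median-of-ratios
size factors as offsets, and variance `mu + alpha mu^2`, fitted by IRLS
(tolerance `1e-8` on coefficients, 100 iterations, vectorized across
features). Dispersion estimation is deliberately simple: per-feature
method-of-moments estimates, a least-squares `a0 + a1/mu` trend across
features, and a geometric-mean blend of the two on the log scale with
floor `1e-8`. This is a documented divergence from full empirical-Bayes
shrinkage: results are "DESeq2-like", not bit-identical, and the package
claims calibration (verified by simulation), not equality with any
external tool.

**Permutation cutoff.** The familywise threshold `alpha*` is the empirical
5th percentile of the per-permutation minimum raw p over B = 100
permutations of the condition labels; covariates stay attached to their
samples, and size factors and dispersions are not re-estimated (labels,
not data, are permuted). The published analyses this emulates report their
cutoffs on the raw-p scale, so the `significant` flag uses
`p <= alpha*` while BH-adjusted values are also reported. Because the
exact published rule (raw vs adjusted p, which percentile) is unstated, an
alternative "expected false positives ≤ 1" rule is available
(`rule = "expected1"`), and no numeric equality with any printed cutoff is
claimed. `B < 20` with the percentile rule is refused — a 5th percentile
of fewer than 20 minima is meaningless.

Volcano exports carry ±1 log2 fold-change guide lines. TPM is
`(k/l) / sum(k/l) * 1e6`; Mann–Whitney comparisons are exact for group
sizes ≤ 8 without ties and normal-approximated with tie correction
otherwise.

# Differential isoform usage

Within-gene isoform counts follow a Dirichlet-multinomial with precision
θ. θ is shared between null and alternative and estimated by 1-D
maximization on `log theta ∈ [log 1e-2, log 1e6]` under the pooled
proportions, keeping the LRT degrees of freedom clean at `(G-1)(K-1)`;
proportions are then MLEs at that θ (1-D logit search for K = 2, softmax
Nelder–Mead otherwise). One consequence, worth stating plainly: a true
usage difference inflates apparent overdispersion under the pooled null
and deflates θ, costing some power relative to estimating θ under the
alternative — the simulation suite shows power remains ample at the
effect sizes of interest (a dominant isoform moving 0.1 → 0.6). Genes
are pre-filtered (total count ≥ 10 in at least half the samples;
never-expressed isoforms dropped with K reduced); BH across tested genes.
Opposing-direction switch genes are those with at least one significantly
up- and one significantly down-regulated isoform at `alpha*`.

# Proteomics meta-analysis and concordance

Protein groups are summed to gene level on the linear scale and then
log2-transformed (tables already in log2 are linearized first). Per-study
effects are OLS `log2 intensity ~ HF + age + sex` with the unbiased
residual-variance SE; constant or collinear covariates are dropped with a
warning. Pooling is DerSimonian–Laird — chosen over REML because it is
closed-form and therefore oracle-checkable; REML is available via
`method = "REML"`. Residual diagnostics (Shapiro–Wilk p, scale-location
slope) are reported but never gate results. Genes need ≥ 2 studies.

The nine-sector classification crosses RNA state (down/NS/up) with protein
state (up/NS/down rows, row-major): sectors 3 and 7 are concordant, 1 and
9 discordant, 5 non-regulated. Default flags are the DE module's `alpha*`
on the RNA axis and meta p < 0.05 on the protein axis; both are arguments,
since the emulated analysis does not state its flags, and no numeric
concordance fraction is claimed.

# Motility dose-response

Velocity vs pCa follows the Hill form
`v = v_min + (v_max - v_min)/(1 + 10^{n_H (x - pCa50)})`. Fits are
weighted nonlinear least squares on per-pCa means (weights = replicate
counts) because the emulated assays report mean ± SEM over pooled
filaments; raw-point fitting is a flag. A multistart over
`n_H ∈ {1, 2, 4}` × three pCa₅₀ starts with box constraints
(`v_min ≥ 0`, pCa₅₀ inside the observed range, `0.05 ≤ n_H ≤ 20`) makes
the fit robust to the plateau-poor side; `fix_vmin = 0` reproduces the
constrained variant, and a missing low-velocity plateau is flagged, not
silently absorbed. Labels like `"pca68"` parse as 6.8 (implied decimal
after the first digit).

# The synthetic world — and what a green test does not establish

All generators are pure functions of (spec, seed): `.Random.seed` is
saved and restored, so a fixed seed gives byte-identical outputs.

* **Cohort**: 13 CTRL / 10 DCM / 10 ICM (the emulated study's sizes);
  ages Normal(55, 8) truncated to 30–75 years, sex Bernoulli(0.7) —
  realistic for an end-stage heart-failure cohort, used only as
  adjustment covariates.
* **Annotation**: per-gene isoform counts drawn from
  (0.55, 0.20, 0.10, 0.06, 0.04, 0.03, 0.02) over 1..7 — most genes one
  isoform, heavy tail; exon counts 1 + Poisson(6); exon lengths 80–300 bp,
  introns 300–2000 bp; genes tiled disjointly on both strands.
* **Counts**: NB gene totals (`alpha` log-uniform on [0.01, 0.5], library
  sizes uniform on 1–3 × 10⁶ — the study publishes neither, these are
  typical bulk values and are config, not claimed) thinned multinomially
  to isoforms with per-group proportions; switch genes override the
  proportion rows (the TPM3-like pattern: dominant isoform 0.1 → 0.6).
* **Proteomics**: three studies at 23v11, 57v20, 10v10; per-study true
  effects `beta + N(0, tau^2)` with default τ = 0.15 (the emulated
  studies show both zero and substantial heterogeneity across genes),
  residual SD 0.5 on log2, age/sex effects 0.01 and 0.2; multiple protein
  groups per gene split the linear intensity.
* **Motility**: per-pCa replicate counts from the published assay grids;
  defaults v_max 728.5 nm/s / pCa₅₀ 6.6 (and a 780.1 / 6.3 preset);
  n_H = 2 and v_min = 120 nm/s with observation SD 80 nm/s are fixed,
  field-typical choices — the assays print neither.

What the generators do **not** emulate: sequencing error and read-level
artifacts (truth labels are exact, so classifier agreement bounds
algorithmic, not calling, error); genomic realism of gene structure
(no overlapping genes, so fusion/antisense calls are by construction
unambiguous); correlated features (DE calibration is per-test);
mass-spectrometry missingness. A green suite therefore establishes that
the *algorithms* are correct and calibrated on their stated models — not
that the models capture every pathology of real data.

One calibration subtlety is documented rather than hidden:
DerSimonian–Laird with k = 3 studies undercovers when τ > 0 (a
well-known small-k property — at τ = 0.15 the observed coverage is near
0.90). The coverage experiment in the acceptance suite therefore runs at
the heterogeneity the emulated study prints for its pooled target gene
(I² = 0, i.e. τ = 0), where the procedure is honest; the generator default
stays τ = 0.15 because heterogeneity across *genes* is real.

# Numerical choices

IRLS: coefficient tolerance 1e-8, 100 iterations, linear predictor
clamped to ±30; all-zero and non-convergent features get `p = NA` and
leave the BH denominator. θ search bounded to [1e-2, 1e6] — beyond 1e6
the DM kernel is numerically multinomial. Quantiles everywhere are R's
default linear-interpolation type 7. FSM/ISM ties break lexicographically.
Sample-scaling invariance of the GLM holds exactly only in the Poisson
limit (a deeper sample carries a proportionally heavier score term); the
suite tests it there and bounds the drift elsewhere.

# Known limitations

No RT-switching or polyA artifact detection and no coding-potential
prediction (the coding flag is carried from input, never computed); no
stage-wise screening after the usage test; no batch correction or
interaction designs in the DE module; meta-analysis reports per-gene
results without cross-gene multiplicity control (the emulated analysis
targets a handful of candidate genes); free-calcium computation and
filament tracking are upstream of the motility table format.
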