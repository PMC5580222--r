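---
title: "Methods: signature discovery, single-sample scoring and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature discovery, single-sample scoring and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsig)
```

`radsig` discovers radioresistance gene signatures in HPV-negative head and
neck squamous cell carcinoma (HNSCC) with a three-stage selection funnel,
summarizes a signature as a per-sample enrichment ("RadR") score, and
associates that score with survival, molecular subtype, genotype, hallmark
activity, protein expression and drug sensitivity. This vignette explains
the model behind each step, the tunable parameters and their defaults, what
the synthetic generator does and does not emulate, and the design decisions
taken where the methodology was genuinely open.

## The selection funnel

The funnel encodes a causal argument in three filters:

1. **Tumor vs normal (purity filter).** Tumor biopsies are mixtures of
   malignant and normal cells. A gene that does not differ between tumor
   and patient-matched normal mucosa cannot carry a tumor-intrinsic
   radioresistance signal that survives purity variation, so stage 1 keeps
   only genes differentially expressed across complete tumor/normal pairs:
   a paired Wilcoxon signed-rank test per gene on log2 values, a signed
   linear fold change from the pairs' linear-scale means, and the filter
   (Holm-adjusted p < `fdr_max`, |FC| > `abs_fc_min`).
2. **Radioresistant vs radiosensitive cell lines (mechanism filter).**
   Intrinsic radioresistance is measured in vitro by clonogenic survival:
   the surviving fraction at 2 Gy (SF2 < 0.2 radiosensitive, SF2 > 0.8
   radioresistant, `classify_cell_line()`) or the dose–survival AUC
   dichotomized at 2.0. Lines are profiled at baseline and at 2 h and 6 h
   after a 4 Gy dose; all timepoints are pooled for power and the per-gene
   test is a two-factor additive ANOVA
   `expression ~ rr_label + timepoint`, reporting the group main effect
   with type II sums of squares — i.e. the radioresistance contrast
   *adjusted for* the timepoint, so that radiation-response dynamics shared
   by both groups cannot masquerade as a group difference. The same
   Holm + FC filter applies.
3. **Disease-free survival (clinical filter).** Per candidate gene, a
   multivariate Cox proportional-hazards model (Efron ties) of DFS on the
   gene's log2 expression adjusted for age, nodal stage and tumor stage;
   genes are kept at raw Wald p < `cox_p_max` for the expression term.

The signature is the intersection of the three stages, with stage-1 and
stage-2 directions required to agree (`select_signature(concordance =
TRUE)`); direction membership (UP/DN) follows the shared differential-
expression direction. Concordance with the hazard-ratio direction is *not*
required — in the packaged 13-gene table it happens to hold (all 3 UP genes
have HR > 1, all 10 DN genes HR < 1), but it is an empirical observation,
not a filter.

### Multiplicity semantics

Two decisions here matter more than any other numerical choice:

* **"FDR" is Holm.** The funnel's false-discovery filter is the
  Bonferroni–Holm step-down adjustment, which actually controls the
  family-wise error rate. It is implemented as named
  (`adjust_pvalues(method = "holm")`), with Benjamini–Hochberg available as
  an option, because fidelity to the published procedure beats
  terminological hygiene. Stage 3 deliberately uses *raw* p < 0.05 — the
  published screen applies no adjustment there.
* **The funnel is sequential.** Stage 2 tests only stage-1 survivors and
  stage 3 only stage-1 ∩ stage-2 survivors, and each stage's Holm
  adjustment spans the genes that stage actually tests. This mirrors the
  published workflow ("among the genes differentially expressed…"), and it
  is also the only reading under which the pipeline has usable power: with
  ~50 informative cell-line samples and a twofold planted effect, Holm
  across 2,000 genes leaves per-gene power near 0.66 at stage 2, while
  Holm across the ~dozen stage-1 survivors leaves it near 0.95. The
  stage functions themselves are agnostic (they test whatever matrix they
  are given); `run_discovery()` wires them sequentially.

### Fold-change convention

Fold changes are signed ratios of linear-scale group means:
`m_a / m_b` if ≥ 1, else `−m_b / m_a`, so |FC| ≥ 1 always and the default
threshold |FC| > 1 excludes only exactly-equal means. The convention is
inferred from the magnitudes in the packaged signature table (e.g. −6.5,
impossible on a log scale for these genes). All expression is assumed
log2; `read_gct(linear = TRUE)` applies log2(x+1) on load for linear input.

## Single-sample enrichment and the RadR score

For one sample, genes are ranked 1..N by expression (largest = N, ties
averaged, traversal ties broken by gene symbol for determinism). Walking
genes from the highest rank down, the enrichment score of a set G is the
sum over all positions of the difference between the rank^α-weighted
empirical distribution of in-set genes and the unweighted distribution of
out-of-set genes:

$$ES(G) = \sum_{i=1}^{N} \left[ \frac{\sum_{g \in G,\, pos(g) \le i} r_g^{\alpha}}
{\sum_{g \in G} r_g^{\alpha}} - \frac{\#\{g \notin G,\, pos(g) \le i\}}{N - |G|} \right].$$

Parameters (`ssgsea_params()`):

* `alpha` (default **0.75**, unitless, ≥ 0): the rank-weight exponent of
  the conventional single-sample GSEA implementation. α = 0 gives the
  unweighted Kolmogorov–Smirnov-style running sum; larger α emphasizes the
  extreme ranks. The published procedure does not state its α, so it is
  exposed.
* `mode` (default **directional**): the RadR score is ES(UP) − ES(DN).
  This is the single most consequential gap in the published description,
  which never says whether the 13 genes were scored as one combined set or
  directionally. With 3 UP and 10 DN members, a combined set would let the
  DN genes dominate and partially cancel the intended ordering, so the
  directional difference is the default; `mode = "combined"` is retained
  for sensitivity analysis.
* Weights are **rank values**, not raw expression, making scores invariant
  under any strictly increasing per-sample transform (platform
  robustness); this invariance is property-tested.
* `normalize` (default off) divides each score row by its range across
  samples — useful for cross-set comparability of hallmark ES matrices,
  irrelevant for within-cohort rank-based analyses.

## Downstream associations

* **Survival:** `median_split_survival()` splits at the in-cohort median
  score; subjects *at* the median go to the low group (deterministic tie
  rule; the published text is silent). Kaplan–Meier per group, two-group
  log-rank test.
* **Groups:** `compare_groups()` uses Mann–Whitney for two groups,
  Kruskal–Wallis for more, with singleton groups excluded with a warning.
* **Screens:** `correlate_with_matrix()` computes pairwise-complete
  Pearson correlations (minimum 10 complete pairs per feature, a guard for
  missing-prone protein/drug panels). The hit rule uses *raw* thresholds
  exactly as published (e.g. r > 0.2, p < 0.01 for the drug screen, sign
  "positive"); Holm-adjusted p-values are reported alongside but do not
  gate hits. `multi_dataset_consensus()` keeps features that are hits with
  a consistent sign in every screen.

## Statistical primitives

The rank tests, ANOVA, correlation, adjustment, Cox, Kaplan–Meier and
log-rank operations are thin contract wrappers over base R and the
`survival` package; the wrappers own validation, missing-data policy and
degenerate cases, and each is tested against an independent brute-force
oracle (exhaustive sign/arrangement enumeration, explicit sums of squares,
partial-likelihood grid search, hand product-limit tables). Numerical
choices:

* Wilcoxon/Mann–Whitney: full sign enumeration for ≤ 12 informative pairs
  (exact even under tied |differences|), the exact signed-rank/rank-sum
  distribution for tie-free totals below 25, and the tie-corrected normal
  approximation with continuity correction above. The switch points are
  documented constants, chosen for reproducibility. The normal
  approximation is accurate to ~10% relative at moderate p but only to
  tens of percent deep in the tail (p ≲ 1e−3); tests assert the former
  where it holds and log-scale agreement where it does not.
* Cox: Efron tie handling (the published procedure is silent on ties),
  `iter.max = 50`, `eps = 1e-9`; `converged` reflects the solver's own
  convergence and infinite-coefficient diagnostics, and non-convergent
  per-gene fits are reported and excluded with a warning, never silently.
  Expression enters per log2 unit by default; z-scored coding is an option
  (`standardize = TRUE`).
* Genes with > 20% missing values are excluded from selection stages;
  remaining missingness is dropped pairwise.

## The synthetic world

`generator_config()` fixes a stated world whose defaults mirror the
emulated designs: 2,000 genes, 40 tumor/normal pairs, 32 cell lines
(18 RR / 14 RS) × 3 timepoints, 300 patients, 3 + 10 planted signature
genes, linear FC 4 (stage 1) and 2 (stage 2), per-gene per-log2-unit
log-HR 0.5 (stage 3), log2 noise sd 1.0, 40% censoring, and a
659-line feature panel (the size of the published pancancer drug panel;
140 drugs of which 4 are planted with true r = 0.5 against the latent
score, 48 hallmark sets of which the first is built from a 20-gene
latent-driven program). Subtype labels shift the planted genes
(atypical −1, mesenchymal +1 by default), reproducing the
published ordering of subtype score distributions. Expression is
log-normal on the log2 scale with additive effects — sufficient because
every selection stage is rank- or ratio-based; the generator does **not**
attempt batch effects, platform differences, tumor purity gradients,
correlated co-expression modules or HPV biology. A green recovery test
therefore establishes that the pipeline's logic and power behave as
designed under monotone planted structure, not that the pipeline is robust
to real-data pathologies.

Two generator defaults deserve explicit justification. First, the hazard is
built from *per-gene* effects — every planted gene carries the full
per-log2-unit log-HR of 0.5 — rather than from a single mean-based latent
score; a mean-based hazard would dilute each DN gene's marginal effect to
0.05 per unit (one tenth of the intended effect), leaving the per-gene Cox
screen with ~10% power and making signature-scale recovery impossible.
Second, the feature panel defaults to 659 lines, the size of the emulated
pancancer drug panel; at a small panel of, say, 200 lines the chance that
at least one of the 136 null drugs exceeds r = 0.2 by sampling noise is
~28% per seed, so the "exactly the planted drugs are hits" behaviour the
generator is meant to exhibit only holds at realistic panel sizes.

Determinism: every generator runs under a locally seeded Mersenne–Twister
RNG derived from (seed, stage offset), restores the caller's RNG state,
and hallmark set membership is derived from the configuration alone so
that independently seeded datasets share a feature namespace.

## Known limitations

* Holm at stages 1–2 is conservative; real cohorts with ~20k genes will
  select fewer genes than a BH-controlled analysis would (option
  available).
* The per-gene Cox screen ignores correlation between candidate genes;
  marginal hazard ratios are attenuated by the unmodelled remainder of the
  signature (visible in the generator, where fitted per-gene HRs are
  closer to 1 than exp(0.5)).
* Scores are comparable within a cohort, not across cohorts, unless
  `normalize` or an external anchor is used.
* The ANOVA assumes independent samples; repeated measurements of one cell
  line across timepoints are treated as independent (no line-level random
  effect), matching the emulated design's analysis.
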