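---
title: "Cross-species translation of time-phased fibrosis signatures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species translation of time-phased fibrosis signatures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`phasesig` implements a translational transcriptomics workflow connecting a
mouse model of lung fibrosis to human disease. Intratracheal bleomycin
instillation in mice triggers an inflammatory response over the first days,
active fibrogenesis around days 7–14, and a late, incompletely resolving
fibrotic phase thereafter. The workflow derives per-time-point signatures of
bleomycin-induced genes, asks — quantitatively — whether those signatures are
enriched among the genes most altered in lungs of patients with idiopathic
pulmonary fibrosis (IPF), and characterizes the genes that drive the
enrichment. The reverse question (are clinical IPF signatures enriched along
the mouse time course?) is asked with the same machinery.

Because the workflow is validated against simulation rather than against any
particular microarray deposit, the package ships a synthetic-data module that
plants known phased gene programs into mouse and human studies. Every stage
is tested against that ground truth.

## The synthetic study design

`sim_params()` fixes the study conditions:

* **Mouse**: 2 arms (bleomycin, saline) x 7 time points (days 1, 2, 7, 14,
  21, 28, 35) x 8 animals, i.e. 112 arrays of `n_genes = 2000` genes.
  Exactly one array — the first saline replicate at day 14 — is perturbed by
  a +6 log2 shift on a random half of the genes, emulating a failed
  hybridization that the PCA screen must catch.
* **Human**: control (n = 10), stable IPF (n = 10) and IPF with acute
  exacerbation (n = 8) — typical clinical cohort sizes.
* **Programs**: three disjoint planted programs of 100 genes each.
  *Inflammation* genes shift by `effect_size` (default 1.5 log2 units) in
  the bleomycin arm at days 1–2 only. *Active-fibrosis* genes shift at days
  7–14, with a residual 0.4x shift at days 21–35 (late up-regulation is
  moderate, not absent). *Late-fibrosis* genes shift at days 21–35 only. In
  the human cohort only the active-fibrosis program is shifted: by
  `effect_size` in stable IPF and by `1.75 * effect_size` under
  exacerbation. The inflammation program is deliberately not shifted in any
  human group — the cross-species asymmetry the forward enrichment analysis
  is designed to detect.
* **Noise**: per-gene baselines are drawn once per study from N(7, 1.5²)
  log2 units and observations add i.i.d. Gaussian noise (`noise_sd = 0.5`)
  — the standard log-normal idealization of RMA-normalized intensities.

The default `effect_size = 1.5` log2 units keeps planted genes comfortably
above the 2-fold DEG threshold at n = 8 while leaving the estimation noise
visible (the per-contrast standard error is 0.25 log2 units).

What the generator does *not* emulate: probe-level effects, batch and array
chemistry artifacts, gene–gene correlation beyond the planted programs, and
heavy-tailed biological heterogeneity in the human cohorts. Passing tests
therefore demonstrate correctness of the statistical machinery under a
clean, known truth, not performance on any real deposit.

### Calibration of the exacerbation shift

The exacerbation multiplier (default 1.75) encodes the clinical observation
that acute exacerbations carry the more deranged expression profile; with it,
the exacerbation-vs-stable contrast yields a higher normalized enrichment
score for the active-fibrosis signature than the stable-vs-control contrast.
A property of the gene-permutation null is worth noting here: the NES of a
planted set is **not** monotone in the planted effect. Stronger planted
scores also dominate random same-size gene sets, inflating the null mean ES
and compressing the NES. A moderate planted contrast (t statistics around
4–6) maximizes NES; at very large effects the NES shrinks back toward ~1.3.
The default multiplier was chosen (via a small design pilot over 20
simulation seeds) in the regime where the planted ordering of the two
contrasts is realized robustly, and is not adjusted thereafter.

## Preprocessing

* **Probe collapse** (`collapse_probes_by_variance()`): per gene, the
  maximum-variance probe row is kept verbatim — the common "variance filter"
  convention for summarizing probes to unique genes. Variance ties break
  toward the lexicographically smallest probe ID so output is deterministic.
* **Ortholog mapping** (`map_orthologs()`): rows are renamed to the target
  species; unmapped genes drop; many-to-one collisions resolve by the same
  max-variance rule. With a bijective map, collapse and mapping commute
  (tested).
* **Outlier screen** (`flag_outlier_samples()`): principal components over
  samples; a sample is flagged when its score on either of the first two
  components is more than 4 robust z-units (median/MAD) from the center.
  The two-component, z > 4 rule is a package convention (the choice of PCA
  is standard; the threshold is exposed and logged in the run manifest).
  The screen is invariant to per-gene additive shifts by construction.
* An optional percentile-based background filter
  (`filter_low_expression()`) exists for platforms where low-intensity
  probes should be removed; no default level is claimed.
* Matrices are taken to be log2; apparently linear input (values above 30)
  is rejected unless the caller requests `linear = TRUE`, which floors at
  1.0 before the log.

## Differential expression

`fit_contrasts()` fits, per gene, the treatment x time cell-means model (the
two-way fixed-effects ANOVA with interaction) and tests the
bleomycin−saline contrast at each day by a t statistic on the pooled
residual variance (residual df = samples − cells). Pooling residual variance
across all design cells is the reading of "ANOVA with pairwise comparisons
per time point" adopted here; a `variance = "within"` option degrades to a
per-day two-sample t-test for sensitivity analyses. For a single-factor
two-group design the pooled model reduces *exactly* to the pooled two-sample
t-test (tested against `t.test`). Genes with zero residual variance are
degenerate, not errors: p = 1 when the contrast is 0, else p = 0, with a
logged count.

P-values are adjusted by Benjamini–Hochberg **within each contrast**
(per-day, per-cohort-comparison), matching per-comparison DEG language; the
adjustment is `stats::p.adjust(, "BH")` behind a single package function.
DEG thresholds are inclusive on fold change ("at least 2-fold" keeps an
exact 2.0) and strict on the FDR (q < 0.05 excludes an exact 0.05). Clinical
contrasts use 1.5-fold at the same q.

### Composite ranking

The enrichment substrate is a total order, not a score. Each gene scores

\[ s_g = \mathrm{sign}(\log_2 FC_g)\,\cdot\,(-\log_{10} \max(q_g, q_{floor})) \]

with `q_floor` the smallest nonzero q in the contrast divided by 10, so
q = 0 stays finite. Ties in `s` break by larger `|log2 FC|`, then by gene ID
— a strict, deterministic ranking. The formula is a declared package
convention (one function, `composite_rank()`, isolates it so it can be
swapped); "composite of fold-change and FDR" admits several readings and
this is the simplest monotone one.

## The enrichment engine

`running_es()` walks the ranked list accumulating the weighted hit fraction

\[ P_{hit}(i) = \frac{\sum_{j \le i,\, j \in S} |r_j|^p}{\sum_{j \in S} |r_j|^p},
\qquad P_{miss}(i) = \frac{|\{j \le i,\, j \notin S\}|}{N - N_H} \]

and returns the deviation \(P_{hit} - P_{miss}\) of maximum absolute value,
signed. A magnitude tie between a positive and a negative extreme resolves
to the earlier rank position. The default weight exponent is p = 1 (the
weighted statistic); p = 0 recovers the classic unweighted
Kolmogorov–Smirnov-style statistic, and both limits are verified against
independent brute-force implementations and against `fgsea::calcGseaStat`.

The null is **gene permutation**: `n_permutations` (default 1000) uniform
random same-size gene subsets of the same ranked list, scored identically.
Permutation scoring uses an O(set size) evaluation at hit positions that is
bit-identical to the full running profile (tested), and sets of equal size
share one null, so duplicated sets get identical statistics.

* Nominal p uses the same-sign plus-one estimator
  \(p = (1 + \#\{ES_{null} \ge ES\}) / (1 + \#ES_{null}^{samesign})\), never 0,
  so it survives log-scale reporting.
* NES divides the observed ES by the mean same-sign null ES (absolute
  values), keeping the sign.
* The across-set FDR for a set with score NES\* is the ratio of the pooled
  same-sign null tail fraction to the observed same-sign tail fraction at
  |NES\*|, clipped to [0, 1] and made monotone non-increasing in |NES| by the
  step-up rule (each set takes the minimum over itself and all less extreme
  sets).
* The leading edge is the set members at ranks up to the running-sum peak
  (from the peak onward for negative ES).

Calibration under a fully null configuration (random sets, exchangeable
scores) is part of the acceptance suite: the nominal p is uniform by a
Kolmogorov–Smirnov check at α = 0.01 over 500 replicates.

## Pathway analysis and back-translation

Leading edges of the signatures positively enriched in the vs-control
contrasts are pooled (`leading_edge_union()`) and tested for
over-representation in a pathway collection by the upper-tail
hypergeometric test (`stats::phyper`; verified against exhaustive
enumeration for all universes up to size 12). The universe defaults to the
genes of the ranked lists that produced the leading edges. Cross-system
comparison takes the top-k (default 25) pathways of two tables after a
p < 0.05, FDR < 0.05 significance filter, ranked by p — the ranking key is
an argument since "top" admits p, q or effect orderings.

Back-translation unions clinical DEGs per direction across comparisons
(1.5-fold, q < 0.05); genes up in one comparison and down in another stay in
both unions by default (a logged choice, with a `drop_conflicts`
alternative). The unions are tested against the composite-ranked mouse list
of every time point. On synthetic data the clinical up-union, which consists
of active-fibrosis program genes, enriches at days 7–14 and not at days 1–2.

## Reporting

`run_pipeline()` executes all stages in order and writes every intermediate
as TSV/GMT/RNK plus a `manifest.json` recording seeds, thresholds and stage
cardinalities — sufficient to re-execute the run. All randomness fans out
deterministically from the single config seed, and re-running a config
yields byte-identical outputs (tested). The enrichment heatmap masks cells
failing (nominal p < 0.05 and FDR < 0.25) to zero; passing cells keep the
signed score, positive ("red", case-enriched) or negative ("blue",
control-enriched). The numeric masked matrix is always written as TSV; a
PNG rendering through pheatmap is optional.

## Problem sizes and numerical choices

The shipped analyses and tests run at the default 2000-gene scale with 1000
permutations (the acceptance simulations use 20 seeds); module tests use
smaller studies (400–800 genes, 100–250 permutations) chosen so the whole
suite completes in about a minute on one CPU. Degenerate inputs are handled
explicitly rather than by chance: empty DEG sets are omitted with warnings,
zero-variance genes get correlation distance 1 to everything, degenerate
enrichment sets (empty or full intersection with the ranked list, or
all-zero hit weights under p > 0) raise structured errors, and a missing
same-sign null flags the result rather than fabricating a NES.

## Known limitations

* Gene-permutation FDRs are anti-conservative relative to phenotype
  permutation when genes are co-expressed; phenotype permutation is out of
  scope by design.
* The moderated/shrinkage variance estimators of the limma family are
  deliberately not used — contrasts follow the plain ANOVA convention, so
  very small designs (n = 2–3) will be underpowered.
* The NES compression phenomenon described above means NES magnitudes are
  not comparable across ranked lists with very different score profiles;
  comparisons should stay within the significance framework (p, q) or use
  matched designs, as the acceptance analyses do.
* The synthetic human cohort plants a single disease program; real IPF
  cohorts mix cell-type composition shifts, comorbidity and medication
  signals that this validation surface cannot probe.
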