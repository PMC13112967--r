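---
title: "Screening druggable target genes for cell-type-selective expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening druggable target genes for cell-type-selective expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhetgscreen)
```

## The screening model

`dhetgscreen` asks, for a chosen *target* neuronal cell type, which genes from
a druggable-genome catalogue are expressed clearly higher in that type than in
*contrast* cell populations. The data model is deliberately minimal: a
cells × genes matrix of depth-normalised counts (CPM, taken as given and never
re-normalised) and per-cell annotations `region_label`, `subclass_label`,
`class_label`. Cell sets are always defined by filtering these labels, which
mirrors how large atlas-style single-cell resources are organised; the loader
keeps non-neuronal cells in the dataset and relies on selectors never to pick
them, rather than removing them globally (the alternative reading of the
source procedure; this is the less destructive choice and the results are
identical for any selector-driven analysis).

Per gene and contrast the engine computes mean `log2(1 + CPM)` in each set
(`GE_T`, `GE_C`), their difference `Diff_Mean`, a two-sided Wilcoxon rank-sum
p-value with multiplicity adjustment, and the expressing-cell fractions and
their difference `beta` in percentage points. `Diff_Mean` is computed as a
*difference of set means on the log scale*. The source description mixes two
notations (a log of a ratio of GE values, and a difference of logs, with GE
itself already log-scaled); we resolve the conflict in favour of
difference-of-log-means because only then is the printed 3-fold threshold
`log2(3) ≈ 1.585` directly comparable to `Diff_Mean`, matching standard
DGE-viewer output.

A gene qualifies as a differentially higher expressed target gene (DHETG)
under a `criteria_config()` when every configured comparison passes
*strictly*:

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha` | 0.05 | — | conventional significance level on the adjusted p |
| `correction` | `bonferroni` | — | family-wise control, the conservative default; `bh` (FDR) is the documented relaxation and can only enlarge selections |
| `fold` | 3 | linear fold | `log2(3)` threshold on `Diff_Mean`; 2 inflates candidate lists, 5 leaves almost nothing |
| `min_beta_points` | off (20 when used) | percentage points | demands a spread in the *share* of expressing cells, not just in level |
| `max_contrast_ge` | off (1 when used) | log2 units | demands near-absence of expression in the contrast set |

Strictness at the boundary (a gene exactly at `log2(3)` is excluded) follows
the printed inequalities; the threshold itself is used at full precision, not
the rounded 1.585. The fold threshold is likewise applied to full-precision
`Diff_Mean`.

## Contrast strategies and combination

Three plan builders reproduce the combinatorial designs of the screening
approach:

* **Conservative one-vs-one** (`plan_intra_conservative()`): the target type
  against every other cell type of the same region, one pair at a time; the
  DHETG list is the intersection over all pairs. Per-pair exclusion rules are
  supported for the case where a combined subclass belongs to both sides of a
  specific pair and must be dropped from both. Note that with such an
  exclusion the target cell set differs between pairs — the exclusion rule
  takes precedence over the otherwise-identical-target invariant.
* **Non-conservative one-vs-all** (`plan_intra_onevsall()`): exactly two
  contrasts against all pooled GABAergic and all pooled glutamatergic cells
  of the region, with the target's own cells removed from its class pool.
  Pooling combines *cells* before testing, not per-type means.
* **Inter-regional** (`plan_inter_regional()`): the same cell type compared
  between its home region and pooled region groups (e.g. a sensory group
  pooling several visual/auditory/somatosensory areas). Pooling again happens
  before the test, one contrast per group. A group can be restricted to a
  target class — e.g. a hippocampal group valid only for inhibitory targets,
  because hippocampal excitatory types have no neocortical counterpart —
  and violating the restriction is a configuration error, not an empty set.

`combine_sets()` derives from the per-contrast DHETG sets: the full
intersection, the Venn decomposition, and majority-rule sets for every quorum
k. Because it is not always explicit whether a printed Venn count is
cell-exclusive or cumulative, both are materialised under distinct names
(`venn_exclusive`: genes in exactly that subset of contrasts;
`venn_cumulative`: genes in at least that subset). The decomposition is capped
at 6 contrasts (64 cells); beyond the cap only intersection and majority
results are produced, with a warning. `combine_intra_inter()` intersects an
intra-regional DHETG set with each inter-regional Venn cell, the final step of
the full-selectivity question.

## Numerical choices in the test statistic

The Wilcoxon rank-sum implementation uses midranks for ties throughout.

* **Exact path.** When `min(n_T, n_C) ≤ 8` and the number of subsets
  `choose(N, min(n))` is at most 10^6, the p-value is the exact permutation
  tail `P(|W − E W| ≥ |w_obs − E W|)` enumerated over all equally likely
  assignments of the pooled midranks (`E W` is invariant under ties). On
  tie-free data this equals the classical two-sided exact p; with ties it
  remains exact under the same convention, which the test suite pins against
  an independent bitmask enumeration oracle.
* **Approximate path.** Otherwise a normal approximation with the standard
  tie-corrected variance and a 0.5 continuity correction is used — accurate to
  well under 10^-2 at the group sizes where it activates, as checked against
  Monte-Carlo permutation.
* **Degenerate input.** If all pooled values are identical the p-value is 1
  (no evidence), not an error or NaN; such genes can never be selected.

Multiplicity adjustment is written in-package (a dozen lines) so that
`stats::p.adjust` stays available as an independent oracle in the tests. The
multiplicity `m` may exceed the number of supplied p-values: the default is
the *dataset's* gene count even when only catalogue genes are tested,
mirroring the practice of extracting target genes from a genome-wide corrected
output. `m` restricted to the catalogue is available via configuration. For
Benjamini–Hochberg with `m` larger than the list, the supplied p-values are
treated as the smallest members of the conceptual m-family, which is
conservative.

## What the generator emulates — and what it does not

`sim_config()`/`simulate_dataset()` produce the statistical structure the
screen assumes: several regions × several subclasses nested in the
glutamatergic/GABAergic classes, zero-inflated expression (each cell expresses
each gene with probability π, default 0.3), and expressed CPM drawn log-normal
on the log2 scale (mean 3, sd 1.5 by default — levels and dropout in the range
typical of Smart-seq-style CPM data). Planted effects implement four marker
archetypes: `fully_selective` (level and π shift in the target group only),
`relative_selective` (half the level shift leaks into same-class siblings),
`ladder` (explicit per-group expression tiers, emulating a gene that steps
down ~3-fold from one cell group to the next and is therefore a "hit" at each
step), and `beta_only` (π shift without a level shift — a gene that must fail
the fold criterion).

The expressed-level distribution is log-normal rather than a negative
binomial over counts because the pipeline consumes CPM, and the rank-sum test
is invariant under monotone transforms — the distributional shape affects
neither test validity nor the interpretation of the planted log2 effects,
which stay directly readable as `Diff_Mean` targets. Zero-inflation is
independent per cell; planted `beta_shift`s act additively on π in the target
group, clipped to [0, 1] with a warning.

Seeding contract: one master seed, from which each gene derives its own
stream; adding genes to a config leaves all existing genes' values
byte-identical, which keeps fixtures stable as tests grow.

The generator deliberately does **not** emulate library-size variation, batch
or donor effects, ambient RNA, gene–gene correlation, or the empirical
moments of any real atlas. A green recovery test therefore establishes that
the pipeline's statistics and set algebra behave correctly on data satisfying
its assumptions — not that any particular biological dataset would yield the
same hit lists.

`expected_qualification()` closes the loop: it computes each planted gene's
*population* `Diff_Mean`, `beta` and contrast GE from the generative
parameters (the mean of `log2(1 + 2^X)` is evaluated by numerical
integration, not approximated by the log-mean) and applies the effect-size
criteria to them, providing the oracle for parameter-recovery tests without
touching sampled data.

## Calibration of the stochastic acceptance checks

Two acceptance checks are stochastic and were calibrated once, before their
thresholds were frozen; the tests re-run the identical worlds with fixed
seeds, so their outcomes are reproducible:

* **Null calibration** — 2,000 genes × 6 cell types × 100 cells, no planted
  effects, 20 seeds: the pooled fraction of raw p < 0.05 must lie within
  3 binomial standard errors of 0.05, and Bonferroni-plus-fold selections must
  total at most 4 across all seeds (expected count ≈ 1).
* **Parameter recovery** — a `fully_selective` marker (log2 effect 2.4,
  beta shift 30 points) and a sub-threshold decoy (log2 effect 1.0) at 200
  cells/type: the conservative intra-regional screen must recover the marker
  in ≥ 95% of 20 seeds and must never select the decoy under fold 3. The
  calibration run recovered the marker in all 20 seeds.

## Catalogue construction

`map_orthologues()` and `resolve_aliases()` implement the multi-step
alignment of a human druggable-gene list to a dataset's gene universe:
humans without an orthologue are dropped, multi-orthologue humans expand to
one entry per orthologue, duplicate target symbols collapse to the
first-encountered entry, and symbols absent from the dataset are renamed via
a single-hop alias table or dropped (and listed). Where two human genes of
different IDG classes collapse onto one target symbol the first occurrence's
class is kept and a warning logged — the source procedure is silent here, and
since the IDG classes are non-overlapping by construction such conflicts
should be rare. Symbol comparison is case-sensitive exact match: the dataset
symbols are authoritative. Every stage count is returned in a build report
whose arithmetic is asserted in the tests.

## Reporting conventions

`class_share()` normalises per-class hit counts to the class's catalogue
size, at full precision with a 3-decimal rendering. `multiplicity_report()`
counts how many cell types share each gene; because the natural denominator
for "share of duplicated hits" is ambiguous (total hit occurrences vs
distinct genes), both percentages are emitted under explicit names
(`shared_pct_of_hits`, `shared_pct_of_genes`). The occurrences denominator is
the one that reproduces the printed duplicate-share figures this package's
acceptance tests check.

## Known limitations

* The screen operates on mRNA-level differences; fold-change, p and beta
  thresholds need not translate into protein-level or functional selectivity.
* The BH-with-subset-extraction convention above is conservative rather than
  exact when `m` exceeds the number of extracted p-values.
* Venn decomposition is exponential in the number of contrasts and is
  intentionally capped.
* YAML configs are not supported (no YAML parser among the package's
  dependencies); configs are JSON.
* The generator's independence assumptions (cells i.i.d. within a group,
  genes independent) make power estimates optimistic relative to real data
  with correlated expression programmes.
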