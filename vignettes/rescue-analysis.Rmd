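---
title: "Three-state rescue analysis of wound transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-state rescue analysis of wound transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundrescue)
```

## The question and the model

Diabetic foot ulcers come in three clinically observable states: diabetic
skin without an ulcer (DS), a non-healing ulcer (DFUNH), and a healing
ulcer (DFUH). Reading these as an ordered pseudo-trajectory
DS &rarr; DFUNH &rarr; DFUH, a *rescue entity* is anything — a cell type's
abundance, a gene's expression within a cell type, a bulk expression
trend, a ligand-receptor signal — that moves away from the DS baseline in
the non-healing state and moves back in the healing state. Two contrasts
define every call:

* the **unhealing contrast**, DFUNH vs DS;
* the **healing contrast**, DFUH vs DFUNH.

`rescue_up` means down in the first contrast and up in the second (a
V-shaped, "lost then restored" trajectory); `rescue_down` is the mirrored
peak shape. Everything in this package is a concrete instantiation of that
two-contrast template at a different level of the data.

A note on symmetry, because it drives several tests: reading the
trajectory backwards (swapping the roles of DS and DFUH) maps
`l1 -> -l2, l2 -> -l1` and therefore leaves both rescue classes
*unchanged* — a V read backwards is still a V. What swaps the classes is
negation (inverting the ratios). The test suite asserts reversal
invariance and negation antisymmetry.

## Quality control and normalization

Cells are retained iff genes detected and total UMIs lie in the inclusive
ranges 500–10,000 and 1,000–100,000, and the mitochondrial and hemoglobin
UMI fractions are strictly below 30% and 5%. We read the en-dash ranges as
inclusive and the "<" bounds as strict; that choice is ours and is pinned
by boundary tests. Mitochondrial genes are recognized by the `MT-` id
prefix and hemoglobin genes by an explicit list (`HBB`, `HBA1`, `HBA2`),
both configurable, since no reference annotation is bundled.

After filtering, expression is log-normalized:
`norm = ln(1 + count * 1e4 / total_umi)`. We use plain log-CPX rather than
a regression-based variance-stabilizing transform: every downstream
statistic here is a rank test, a mean, or a correlation, and log-CPX
serves those while keeping the layer cheap, deterministic and exactly
invariant to library-size scaling (a tested property). This is a
deliberate simplification, not an approximation of some other method.

## Composition rescue

Cell-type proportions are cell counts over total cells per clinical group.
With `l1 = log2(p_DFUNH / p_DS)` and `l2 = log2(p_DFUH / p_DFUNH)`, a type
is a rescue type when both |log2FC| exceed 0.1 with opposite signs in the
rescue pattern. Absent cell types get a Haldane-style pseudo-proportion
`0.5 / n_cells(group)` before the log ratio; records that would still be
non-finite are flagged degenerate and never called. Per-sample
proportions feed a Welch two-sample t-test per contrast (the unequal
variance choice is ours; with 2–9 samples per group it is the safer
default). Identical constant samples give p = 1 by rule; fewer than two
samples per group yields `NA` rather than an error, because small groups
are a fact of this design. The same machinery serves fibroblast
subclusters by switching the `by` level.

## Per-cell-type differential expression

Within each eligible cell type (at least 3 cells in *both* groups), each
gene gets a two-sided Mann-Whitney test on the normalized layer. For
tie-free comparisons with `n_a + n_b <= 16` the exact null distribution is
used. Otherwise we use a continuity-corrected normal approximation with
the classical Edgeworth refinement: the fourth cumulant of the tie-free
null is `-mn(N+1)(m^2+n^2+mn+m+n)/120`, and the sixth cumulant is the
analogous degree-6 polynomial (derived exactly against a dynamic-program
enumeration and verified out of sample). With both terms the approximation
matches enumeration within 0.01 for balanced groups of 4–8 (4e-4 at 8 vs
8); at 3 vs 3 the two-sided p takes only five values and every smooth
approximation carries an irreducible ~0.02 error at the extreme split —
which is harmless in practice because that regime always uses the exact
branch. With ties, the variance is tie-corrected and the higher-order
terms keep their tie-free coefficients (they are O(1/N) corrections).

The fold change is `log2(mean(expm1(norm_a)) + 1) -
log2(mean(expm1(norm_b)) + 1)` — back-transformed means with a +1
stabilizer, the marker-test convention of the mainstream single-cell
toolkits; a plain difference of mean logs is available via
`logfc_method = "logmeans"`. BH adjustment is applied within each (cell
type, contrast) stratum, mirroring how per-type marker scans are usually
corrected. Rescue DEGs require both contrasts to pass `|log2FC| > 0.25`
and adjusted p < 0.01 with opposite signs; these defaults follow the
stricter of the two threshold sets in circulation for this analysis
(0.5 / 0.05 also appears in figure legends of comparable work), and both
are plain arguments. No minimum-expression-fraction filter is applied by
default; `min_pct` exposes one.

## Short time-series trend clustering

Group-mean (pseudo-bulk) expression over the ordered states forms a short
series per gene; an independent four-point acute-wound series (days 0, 1,
3, 7) provides the exclusion set. Model profiles are all
`(2c+1)^(T-1)` templates of integer unit steps in `[-c, c]`; when more
than `m` exist, `m` are chosen greedily to maximize the minimum pairwise
distance `1 - Pearson r` of value vectors, always retaining the flat
profile (defaults `c = 2`, `m = 50`; the worked tiny cases use `c = 1`,
where all 9 or 27 profiles are kept). Genes are translated to start at 0
and assigned by maximal Pearson correlation; constant genes go to the
flat profile; ties break to the lowest profile id.

Significance per profile compares the observed membership count with the
mean membership frequency across all `T!` column-order permutations of
the series (sampled when `T! > n_perm`), via a binomial upper tail and
Bonferroni correction over profiles. The class of a profile follows its
interior extremum: net rise before a strictly interior maximum and net
fall after it is `rescue_down`; the mirror around the minimum is
`rescue_up`; extrema at endpoints, flat profiles, and balanced
double-extremum shapes are `other` (when both patterns hold, the larger
amplitude wins and an exact tie is `other`).

The cross-dataset screen is set algebra on uppercased symbols: single-cell
rescue genes ∩ significant bulk rescue-trend genes (direction-matched)
gives the *common* sets, and removing genes with the same reversing trend
during acute healing gives the *unique* sets — changes specific to the
diabetic process.

## Gene-set activity

The per-cell module score bins genes into 24 near-equal bins by average
normalized expression, draws 100 control genes (with replacement) per
member from the member's bin, and reports mean member minus mean control
expression per cell; the draw is seeded. Control draws may include member
genes — with realistic set sizes this dilutes scores by the members' share
of their bins, which the tests quantify.

Preranked GSEA uses the standard weighted running sum (hits add
`|metric|^p` normalized over hits, misses subtract `1/(N - n_set)`); the
ES is the extreme deviation; the null is gene-label permutation (random
same-size sets), NES divides by the mean |same-sign null ES|, the p-value
is the one-sided permutation tail with add-one smoothing, and BH runs
across sets. The ES computation is cross-checked in the tests against an
independent implementation (`fgsea::calcGseaStat`). For single-cell
inputs, `gsea_rank_from_de()` filters a DE table at adjusted p < 0.05 and
|log2FC| > 0.5 before ranking by log2FC.

## Ligand-receptor communication

For each (sender type, receiver type, pair), ligand abundance `L` is the
Tukey trimean `(Q1 + 2 Q2 + Q3)/4` of the ligand's normalized expression
in the sender (geometric mean across multiple ligand genes), receptor
abundance `R` is the geometric mean over subunit trimeans in the
receiver, and the communication probability is the Hill mass-action form
`L·R / (0.5 + L·R)` — zero when either side is silent, monotone in both,
bounded in [0, 1). A plain-mean summary is available via `method`.
Differential edges compute the ligand log2FC inside the sender type and
the receptor log2FC inside the receiver type (within-type is the only
biologically coherent reading; a global fold change would conflate
composition with regulation); `up` needs both >= 0.2, `down` both <=
-0.2, boundaries inclusive. Rescue edges chain the two contrasts exactly
like rescue DEGs. Multi-gene sides aggregate by the mean log2FC of their
genes. Edges touching a type that fails the DE eligibility rule are never
classified. Signaling-role decompositions, permutation p-values on edges
and cofactor modeling are intentionally out of scope — the rescue calls
use only probabilities and thresholded fold changes.

## Differentiation scoring and biomarker screening

The differentiation score retains the core signal of count-based
differentiation inference: per-cell gene counts (genes with count > 0),
per-gene Pearson correlation with those counts, the mean normalized
expression of the top 200 correlated genes (the gene-counts signature),
and rank normalization to [0, 1]. The diffusion smoothing and regression
steps of the full published method are omitted deliberately: on labeled
subclusters the ordering of median scores is the deliverable, and the
signature alone reproduces it on planted-diversity fixtures. Constant
gene counts across cells are degenerate by construction and yield flat
0.5 scores with a flag.

ROC screening uses the Mann-Whitney identity `AUC = U / (n_pos · n_neg)`
with ties counted 1/2 (provably the trapezoidal area under the empirical
ROC curve; asserted to 1e-12 against that construction and against an
independent ROC package). By default the class with the higher mean is
treated as positive, so the reported AUC is >= 0.5 with a `flipped` flag;
`direction = "forward"` scores labels as given. AUC > 0.7 flags a
candidate biomarker.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws negative-binomial UMI counts
(`variance = mu + 0.5 mu^2`) with log-normal baseline abundances
(meanlog 0, sdlog 1) scaled to ~2,000 expected UMIs per cell, log-normal
(sdlog 0.3) library-size variation, 8 cell types with 5 marker genes each
at 5x baseline, group-dependent cell-type proportions, and multiplicative
group factors on planted rescue genes and LR pairs, with every planted
effect recorded in a truth manifest. Gene ids are ordered by decreasing
baseline abundance, so fixtures can plant effects at a known expression
level — the recovery fixtures plant 2-fold reversals on well-expressed
genes in a dominant (30%) cell type, mirroring the fact that the
reported rescue genes of this biology (collagens, HLA class I/II) are
abundant transcripts of abundant cell types; a 2-fold change on a gene
with 0.2 UMIs per cell in a rare cell type is not recoverable by any
method at this design size, and planting it would test nothing.

`simulate_trend_series()` gives every gene a true step profile —
background genes draw each step from {-1, 0, +1} with probabilities
(0.2, 0.6, 0.2), so most transcripts are stable with occasional drifts —
plus a per-gene offset and Gaussian noise (sd 0.1). The planted reversing
fraction defaults to 200 + 200 of 1,000 genes, sized so that profile
enrichment is detectable above the permutation-null expectation at this
gene count; scale-invariant Pearson assignment spreads pure-noise genes
uniformly over sharp profiles, which is exactly what the permutation null
measures.

Not emulated: doublets, ambient RNA, batch and sample-level random
effects, realistic gene-gene correlation, or any attempt to match real
GEO marginals. Passing recovery tests therefore demonstrates that the
*methods* are implemented correctly and are calibrated under their own
assumptions — not that real cohorts of this size would yield the same
power. In particular, cells are exchangeable within groups here, so the
Wilcoxon DE p-values are well calibrated; in real multi-sample data,
within-sample correlation inflates them, which is a known limitation of
the per-cell testing paradigm this package reproduces.

## Numerical and reproducibility choices

* All randomized stages take a single seed; per-stage streams derive from
  it by a deterministic stage-name hash (`stage_seed()`), so re-running
  one stage reproduces its draws. All derived seeds stay below 2^31.
* Problem sizes in the tests and the acceptance script — 3 samples per
  group, 200 cells per sample, 1,000 genes, 20 planted reversal genes, 20
  null seeds, 100-instance oracle sweeps — were chosen once as the
  smallest design at which the planted effects are comfortably
  recoverable and null calibration is measurable.
* Degenerate inputs follow explicit rules rather than errors wherever a
  small real dataset could produce them (absent cell types, constant
  samples, silent genes, constant gene counts); truly malformed inputs
  (metadata mismatches, unknown group labels, empty gene sets) fail fast
  with offender lists.
* The three-state series order is fixed DS &rarr; DFUNH &rarr; DFUH, the
  healing narrative's order; nothing in the machinery depends on it, and
  `pseudobulk_means(order =)` accepts any order.

## Known limitations

The acute-wound exclusion assumes the acute and diabetic series share
gene symbols. The LR fold-change aggregation over multi-subunit receptors
(mean of subunit log2FCs) is one of several defensible conventions.
Subcluster ordering relies on score medians only — no trajectory graph is
inferred. The per-cell-type BH stratification means gene-level unions are
not FDR-controlled at the union level.
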