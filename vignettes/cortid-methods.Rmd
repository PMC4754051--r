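---
title: "cortid: models, methods and parameter choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cortid: models, methods and parameter choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortid)
```

This vignette records the statistical definitions the package
implements, the conventions chosen where a verbal description admits
more than one reading, and the design of the simulators used for
validation.

# The qPCR data model

The raw currency is a wells × genes cycle-threshold (Ct) matrix with a
per-well chip (batch) label, wrapped as a `ct_matrix`. A reaction in
which the fluorescence never crosses threshold has no Ct; such entries
carry the sentinel `CT_SENTINEL = 999`. On input (`read_ct_table()`),
the strings `"999"`, `"Undetermined"`, `"NA"` and empty cells are all
normalised to the sentinel; `write_ct_table()` is its lossless inverse
(doubles are written with 17 significant digits so that
write-then-read reproduces the matrix bit for bit).

## Detection and expression

A gene is **detected** in a well iff its Ct lies strictly below the
limit of detection, `ct < lod` with `lod = 30` by default; a Ct of
exactly 30 is *not* detected (`call_detection()`). The continuous
**expression** scale (`to_expression()`) anchors at the LOD:

$$e = \max(0,\; \mathrm{lod} - \mathrm{ct}),$$

so undetected entries are exactly 0 and each unit is one PCR cycle,
i.e. roughly a two-fold change in template.

## Well quality control

A well is retained iff the housekeeper GAPDH is detected
(`well_qc()`). This is deliberately minimal: a well without
housekeeper signal contains no usable cell, while any further
filtering risks biasing the composition estimates that are the point
of the analysis.

## Cross-chip batch adjustment

Each chip is an independent PCR run, and housekeeper levels should be
comparable across chips. For batch $b$, `batch_adjust()` estimates

$$\widehat{\delta}_b = \frac{1}{|H|}\sum_{h \in H}
  \left(\overline{\mathrm{ct}}_{b,h} -
        \overline{\mathrm{ct}}_{\mathrm{ref},h}\right),
  \qquad H = \{\mathrm{GAPDH}, \mathrm{ACTB}\},$$

with each mean taken over QC-passing wells and detected (non-sentinel,
sub-LOD) entries only, and subtracts $\widehat{\delta}_b$ from every
non-sentinel entry of batch $b$. Sentinels are never shifted — a
failed reaction stays failed. The reference batch defaults to the
first in order of appearance. A batch in which some housekeeper is
never detected is an error, not a silent skip.

## Phenotype and layer classification

`classify_cells()` applies the marker taxonomy of `marker_panel()` on
detection calls over QC-passing wells:

* **neuron**: any of MAP2, NCAM1, TUBB3;
* **layer identity** (neurons only): *deep* if at least one of BCL11B,
  TBR1 and no upper marker; *upper* if at least one of CUX1, POU3F2,
  SATB2 and no deep marker; *mixed* if both classes are present
  (a hallmark of in vitro cultures, essentially absent in vivo);
  *none* otherwise;
* **GABAergic**: GAD1 detected; **glutamatergic**: SLC17A7 detected;
* **glia**: GFAP or OLIG2 detected.

Composition tables are compared between groups with a χ² test without
continuity correction, falling back to Fisher's test with simulated
p-values when more than 20% of expected counts fall below 5.

# Permutation co-expression test

For a gene pair $(x, y)$ over $n$ wells, `perm_corr_test()` compares
the observed Pearson correlation $r_{\mathrm{obs}}$ with a null built
by permuting $y$ across wells while holding $x$ fixed, which preserves
both marginal distributions (including the zero-inflation of the
expression scale) and tests exactly the pairing. The two-sided
empirical p-value uses the add-one rule,

$$p = \frac{1 + \#\{|r_\pi| \ge |r_{\mathrm{obs}}|\}}{1 + n_{\mathrm{perm}}},$$

so p is floored at $1/(n_{\mathrm{perm}}+1)$ and the test is valid at
any $n_{\mathrm{perm}}$. With `exhaustive = TRUE` all $n!$
permutations are enumerated and the p-value is the exact fraction
$\#\{|r_\pi| \ge |r_{\mathrm{obs}}|\}/n!$ (no add-one term: the
enumeration necessarily contains the identity permutation). The
comparison uses a $10^{-12}$ slack so that ties in $|r|$ produced by
floating-point noise count as exceedances. `mode = "detection"`
binarises first, making $r$ the phi coefficient. Pairs with a
zero-variance member are reported `NA`/non-evaluable, and
Benjamini–Hochberg adjustment runs across evaluable pairs only.

The package reports raw and BH-adjusted p-values but does not impose a
correction family on the caller: which tests form a family is an
analysis-level decision (e.g. all pairs on a chip versus a pre-chosen
marker subset), so pipeline outputs carry both `p_emp` and `q`.

# PCA and cluster separation

`pca_expr()` is centred, unscaled PCA (`prcomp`); all genes share the
cycle unit, so variance scaling would up-weight noise in barely
expressed genes. The sign of each component is fixed by requiring the
largest-magnitude loading to be positive, making scores reproducible
across BLAS implementations.

`cluster_separation_test()` asks whether two labelled groups separate
in the first two components: for each point it computes the Euclidean
distance to its own group centroid and to the pooled centroid, and
runs a paired two-sided Wilcoxon signed-rank test on the two distance
sets (zero differences dropped, normal approximation). If the groups
are well separated, each point is systematically closer to its own
centroid. An unpaired rank-sum reading is available via
`paired = FALSE`; the paired form is the default because the two
distances per point share that point's noise.

# Single-cell RNA-seq computations

## Cell quality control

`cell_qc()` evaluates three filters:

1. **low_gene_count** — the number of detected genes (count ≥ 1) falls
   below Tukey's boxplot lower limit, $Q_1 - 1.5\,\mathrm{IQR}$, of
   the cohort;
2. **high_mito** — the fraction of fragments on mitochondrial genes
   exceeds 0.15 (strictly; a cell exactly at the threshold passes);
3. **pca_outlier** — evaluated *sequentially*, only among cells
   passing the first two filters: cells are size-factor normalised,
   log1p-transformed and projected onto the first two principal
   components; a cell whose distance from the centroid exceeds
   $\mathrm{median} + 5 \times \mathrm{MAD}$ of the surviving cells'
   distances is flagged.

Two conventions here deserve a note. First, "more than 5 times the
MAD" is implemented as the robust outlier rule
$d > \mathrm{median}(d) + 5\,\mathrm{MAD}(d)$ rather than the literal
$d > 5\,\mathrm{MAD}(d)$: centroid distances are non-negative with a
positive typical value, so the literal form flags *every* cell
whenever the cohort is homogeneous or clustered (distances concentrate
away from zero with small spread), which cannot be the intent of an
outlier rule. Second, the PCA pass is sequential because a
mitochondria-dominated or collapsed cell is by construction extreme in
PCA space; evaluating the distance rule on the full cohort would
re-flag cells already failed for an interpretable reason and distort
the distance distribution used for the remaining cells.

## Size factors

`size_factors()` is the median-of-ratios estimator: per-gene geometric
means are taken across cells over genes with strictly positive counts
in every cell, and each cell's factor is

$$s_c = \exp\!\left(\mathrm{median}_g
  \left(\log k_{gc} - \overline{\log k_{g\cdot}}\right)\right),$$

i.e. the median of the count/geometric-mean ratios taken **on the log
scale**. The two readings differ only for even numbers of usable
genes (midpoint of logs versus log of midpoint); the log-scale form is
the reference implementation's convention and the package matches
`DESeq2::estimateSizeFactorsForMatrix` to 10⁻⁸ in the test suite.
When no gene is positive in every cell, `pseudocount = TRUE` adds one
to all counts first.

## FPKM and the DE post-filter

$$\mathrm{FPKM}_{gc} = \frac{k_{gc}}
  {\mathrm{len}_g/10^3 \cdot N_c/10^6}.$$

`de_post_filter()` retains a significant gene only if (a) in at least
one group it is detected in more than 10% of cells *and* has mean
FPKM above 1 (both strict), and (b) the between-group difference in
detection fraction and in mean FPKM point the same way; a zero
difference in either fails concordance. This guards against calls
driven by a handful of cells or by dropout artefacts.
`de_flag_ranksum()` is an explicitly labelled stand-in (per-gene
Wilcoxon rank-sum + BH) so that synthetic end-to-end runs can feed the
filter; it is not a recommended DE method.

# Simulators

Problem sizes throughout (478 wells, 96 genes, 50–100 cells, 1000
genes) are the package's own choice: large enough for stable rates,
small enough that every validation runs in seconds to minutes on one
CPU.

## `simulate_qpcr()`

Wells are drawn from archetypes (deep-, upper-, mixed-,
markerless-neuron, glia, failed-well) apportioned by the
largest-remainder method so realised counts match the requested
composition exactly. Each archetype defines the set of expressing
genes; an expressing gene is detected with probability `p_detect`
(default 0.85, a typical single-cell RT-qPCR sensitivity) and, when
detected, its Ct is drawn from
$\mathcal{N}(\texttt{mean\_ct\_on} + \text{shift}, \texttt{ct\_sd})$
with defaults 20 and 2 — mid-range single-cell Ct values, safely below
the LOD of 30. Limits: genes are independent given the archetype (no
correlation structure beyond co-expression of a program), and Ct noise
is homoskedastic, whereas real low-abundance transcripts are noisier.
`worked_example_fixture()` is the fully deterministic counterpart with
a known 478-well composition.

## `simulate_counts()`

Counts are negative binomial with dispersion `size = 10`, per-gene
means log-normal ($\mu = \log 100$, $\sigma = 1.5$) — deep full-length
(plate-based) libraries, not shallow droplet data — scaled by true
per-cell size factors drawn from $U(0.5, 2)$. Mitochondrial genes are
calibrated to ≈5% of the library. Planted outliers either have their
mitochondrial fraction raised to ≈50% (`"mito"`) or 90% of their
non-mitochondrial genes zeroed with mitochondrial counts scaled down
in proportion (`"low_complexity"`; the scaling keeps the planted
failure purely a complexity failure rather than a passive
mitochondrial one). Ground truth (size factors, outlier labels) is
returned alongside.

# Numerical conventions

* All detection boundaries are strict (`ct < lod`, fraction `> 0.15`,
  detection fraction `> 0.10`, FPKM `> 1`).
* Sentinel Ct entries never participate in means, shifts or
  expression; they are data-absent, not large values.
* Permutation exceedance uses a $10^{-12}$ tie slack.
* CSV round-trips write doubles with `%.17g`.
* Every stochastic routine takes an explicit seed and restores nothing
  silently; identical seeds give bit-identical results.
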