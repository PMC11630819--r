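---
title: "Receptor expression logic in VNO single-cell data: models and choices"
author: "vomeroseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor expression logic in VNO single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

The vomeronasal organ detects pheromones through sensory neurons that each
express, canonically, a single receptor drawn from the large V1R and V2R
repertoires (with odorant receptors and formyl peptide receptors as minor
classes). Single-cell RNA-seq of the VNO makes four quantitative questions
tractable, and this package implements one analysis chain for each:

1. How is receptor choice distributed over the repertoire
   (`summarizeReceptors`, `fitPowerLaw`, `expressionCellsRelation`)?
2. Which receptor pairs are co-expressed beyond chance, and do they
   co-localize genomically (`binarizePresence`, `pairwiseFisher`,
   `genomicColocalization`, `shannonPerCell`, `multiplicityTable`)?
3. Which transcription factors and axon-guidance genes are associated
   with each receptor — the putative wiring code (`buildAssociation`,
   `profileCorrelation`, `sequenceSimilarity`, `similarityRelation`,
   `tfAgJaccard`, `receptorTypeCorrelation`)?
4. Are progenitor cell types enriched in the neurogenic marginal zone
   (`assignZones`, `zoneEnrichment`)?

All analyses consume a `SingleCellExperiment` of raw integer counts with a
gene annotation (`gene_class` ∈ V1R/V2R/OR/Fpr/TF/AG/other, chromosome,
1-based inclusive coordinates, pseudogene flag) in `rowData` and cell
metadata in `colData`.

# Statistical models

## Rank–probability power law

Within a receptor class, the expression probability of receptor $r$ is its
share of expressing cells, $p_r = n_r / \sum_k n_k$, where $n_r$ counts
cells with any nonzero detection. Detection — not the ≥ 10-count presence
threshold — is the right notion here, because the question is which
receptor a cell chose, not whether expression is robust; the presence
threshold belongs to co-expression calling. Ranked by decreasing $p_r$, a
power law $p_r \propto r^{-\alpha}$ is fitted by least squares on
$(\log r, \log p_r)$. Receptors detected in fewer than `minCellsFloor`
(default 10) cells are excluded: sparsely detected receptors deviate
sharply below the line for technical (dropout) reasons, and a detection
floor excludes exactly the unreliable points, whereas a rank cutoff would
have to be tuned per dataset.

Because detection is any-nonzero, ambient contamination inflates $n_r$
uniformly and destroys the rank signal. The fit therefore assumes a
decontaminated matrix — the standard upstream step in droplet scRNA-seq
processing — and the package's own recovery experiments run the generator
with `ambientRate = 0` for this analysis only.

## Co-expression calling

Presence is `count >= 10` (boundary inclusive); receptors present in
fewer than 5 cells are dropped from testing. For each retained unordered
pair, the 2×2 table $(n_{11}, n_{10}; n_{01}, n_{00})$ over all cells of
the supplied matrix is tested one-sided for enrichment:
$p = P[X \ge n_{11}]$ with $X$ hypergeometric — identical to a one-sided
Fisher exact test, computed via `phyper` and verified in the test suite
against brute-force enumeration of every table with $N \le 25$ and
against `fisher.test`. Enrichment (not two-sided) is the scientific
question; depletion between receptors is expected under mutually
exclusive choice and is not interpreted. A two-sided variant is exposed
by a flag. BH adjustment is applied once across all pairs of a run
(per-class families by flag); the correction-family boundary is a
genuinely open choice and the joint family is the more conservative
default for cross-class claims. The test universe is all cells in the
matrix — subsetting to a lineage is the caller's decision, made by
subsetting the object, and kept out of the statistics.

Shannon diversity per cell uses natural logarithms over raw receptor
counts (`vegan::diversity`), so $H = 0$ for a single-receptor cell and
$H = \ln k$ for $k$ receptors expressed evenly; cells without receptor
counts are flagged NA rather than silently zero. Genomic distance between
same-chromosome pair members uses interval midpoints; only chromosome
identity enters the headline same-chromosome fraction, which is reported
both pair-level and gene-level because "fraction of co-expressed
receptors on the same chromosome" admits both readings.

## The TF/AG association code

Association tables cross receptor presence (≥ 10 counts) with panel-gene
presence (≥ 3 counts — panel genes are expressed at lower absolute
levels than the chosen receptor) and apply the same enrichment test and a
single BH family across the whole receptor × gene table. The
mean-expression entries use log1p counts scaled to the median cell total:
a deliberately simple normalization, because only the ordering of means
matters for profile correlations, and heavier variance-stabilizing
transforms have parameters that cannot be reproduced from raw counts
alone. Receptor profile similarity is the Pearson correlation between
rows of that matrix (zero-variance rows flagged and excluded); the
combined receptor-type similarity concatenates the TF and AG profiles.
Mean expression was chosen over binary association or $-\log p$ profiles
(both computable from the table) because it degrades most gracefully when
a receptor has few presence cells.

Protein sequence similarity is global pairwise alignment percent identity
(identities / alignment length × 100) under BLOSUM62 with affine gaps
(open 11, extend 1) — the standard protein scoring; the alignment-length
denominator keeps the measure symmetric and bounded. The
similarity-relation summary bins one similarity into 20 equal-width bins
and reports per-bin means/medians of the other plus an overall Spearman
correlation, rather than a rendered density plot, keeping the artifact
machine-readable.

Per-receptor TF × AG Jaccard grids take the receptor's presence cells as
the universe and, for each significantly associated TF and AG gene
(adjusted p ≤ 0.05 — the only significance machinery defined in the
pipeline), the barcode sets where the gene is detected at the panel
threshold; $J = |T \cap A| / |T \cup A|$. Restricting the universe to the
receptor's own cells makes grids comparable across receptors with very
different abundances; the whole-dataset variant can be obtained by
passing `alpha = 1` and the full matrix.

## Spatial zones

Distance is Euclidean to the *nearest* landmark: a VNO section's
neural/non-neuronal boundary is an extended structure, so many landmark
points generalize the single "center" cleanly. Zone boundaries are
inclusive (distance ≤ 750 px marginal, ≤ 1500 px intermediate — "within a
radius" is read as inclusive) and verified at the exact boundary values.
The prediction-score filter (≥ 0.3) is applied before zoning; cells below
it are `unknown`, and an input `exclude` flag (e.g. non-neuronal region,
which is not computable from coordinates alone) yields `excluded`.
Enrichment per focus type is a one-sided Fisher test of type × zone
restricted to marginal vs main (the intermediate zone is descriptive),
BH-corrected across focus types.

# The synthetic-data generator

`SyntheticTruth` fixes every generative parameter plus the seed; all
generators are pure functions of it. A cell of a receptor-bearing type
draws one primary receptor with probability $\propto r^{-\alpha}$ within
its class (default $\alpha = 1.2$, a steep-but-heavy-tailed repertoire
use); primary counts are negative binomial (mean 60, size 5 — clearly
above the presence threshold, overdispersed as in real UMI data);
planted pairs co-express the partner (NB mean 40) with probability 0.8,
multiplied ×2 in immature cells and ×1.5 at P14 (capped at 1), so
specificity increases along maturation; every receptor receives
Poisson(0.5) ambient counts per cell — real enough to exercise the
presence threshold, but below it in expectation so that threshold
behavior, not noise magnitude, drives outcomes; wired TF/AG genes are
Poisson(8) in their receptor's cells against Poisson(0.3) background;
and every count is thinned binomially at capture rate 0.8. Default
composition (GBC 5%, INP 10%, iVSN 20%, mature 60%, sVSN 5%) is a
qualitative mirror of a juvenile/adult VNO lineage, not an estimate of
real proportions. Default planted pairs join consecutive mid-rank
receptors (ranks 3–26) of the largest class: receptors with enough
expected cells to clear the ≥ 5-cell retention filter, so the planted
structure is testable by construction; 8 of 12 pairs share a chromosome
(placed < 1 Mb apart), giving a planted same-chromosome fraction of 2/3.

The spatial generator places cells uniformly, then puts enriched types
inside the marginal zone with probability $q = f(e-1)/(1-f)$ ($f$ =
marginal area fraction, estimated on a grid), which multiplies their
marginal density by exactly $e$ — giving closed-form expected fractions
for power analyses.

What the generator does **not** emulate: UMI/read-level structure,
transcript-length and batch effects, doublets, empty droplets, the broad
V2R C-clade co-expression, or realistic spatial tissue geometry. Passing
recovery tests therefore shows that the analyses are correct under their
own assumptions — thresholds behave as printed, tests match their exact
oracles, planted structure is recovered with calibrated error — not that
the biological conclusions transfer to any particular real dataset.

# Numerical and design details

* Fisher enrichment p-values come from `phyper(n11 - 1, ...)`; odds
  ratios are the sample $(n_{11} n_{00})/(n_{10} n_{01})$ with $\infty$
  when the discordant product vanishes and co-occurrence exists, 0 when
  $n_{11} = 0$.
* Rank ties in receptor summaries are broken by gene id for determinism.
* Mean-expression histogram bins are half-open $[lo, hi)$ with default
  decade edges $\{0, 10, 100, \infty\}$; a mean of exactly 10 falls in
  the second bin.
* Pairs with $n_{11} = 0$ are still tested ($p = 1$), keeping the BH
  family size honest.
* Circos link files copy 1-based inclusive annotation coordinates
  verbatim and report the pair's $n_{11}$ as the co-expressing cell
  count.
* Gene-class labels resolve through a fixed case-insensitive alias table;
  unknown labels demote to `other` with a warning so partial annotations
  remain usable, and panel membership comes only from the annotation —
  no symbol-prefix heuristics.
* All generator randomness flows through the truth's seed with fixed
  stream offsets per generator, so annotation, counts and coordinates are
  individually reproducible.

# Problem sizes used in validation

The recovery experiments in the test suite and `scripts/acceptance.R`
use: exhaustive 2×2 enumeration to $N \le 25$; 3,000 cells × 60 receptors
× 12 planted pairs (20 and 10 seeds respectively) for pair recovery;
20,000 cells × 100 receptors for exponent recovery (10 and 5 seeds); 2,500
cells × 20 coded receptors for code recovery; 2,000 cells × 20 seeds for
zone power. These sizes give comfortable Monte-Carlo margins for the
asserted thresholds (e.g. planted-pair sensitivity ≥ 0.9, empirical FDR
≤ 0.1, exponent within ±0.15) while keeping a full run in minutes on one
CPU.

# Known limitations

* The power-law fit is a descriptive least-squares summary, not a formal
  maximum-likelihood power-law test; no goodness-of-fit p-value is
  produced.
* Mutually exclusive receptor choice induces negative dependence between
  non-planted pairs, making the enrichment tests conservative rather than
  exactly calibrated under the generator's null.
* Sequence similarity ignores alignment uncertainty and treats percent
  identity as a point value.
* The spatial model is a flat field with point landmarks; real sections
  have curved boundaries and nonuniform cell density, so zone area
  fractions in real data must come from the data, not from this model.
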