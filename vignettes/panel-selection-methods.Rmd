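---
title: "Gene panel selection and probe design: models and methods"
author: "ProbePanels authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene panel selection and probe design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Targeted spatial transcriptomics protocols such as SCRINSHOT, MERFISH and
seqFISH+ measure a predefined gene panel in situ.  Because the panel is
small (tens to a few hundred genes) and the probes are expensive to
redesign, the choice of genes determines everything the experiment can
see.  ProbePanels selects such panels from a dissociated single-cell
reference so that two objectives are optimized jointly: the panel must
identify the annotated cell types, and it must recover the continuous
expression variation of the tissue beyond discrete labels.  A probe
design stage then turns the panel into ready-to-order oligo sequences.

This vignette documents the models, the tunable parameters, the
synthetic data used for validation, and the numerical choices made where
the procedure left room for a decision.

## The selection model

The input is a `PanelExperiment` (a `SingleCellExperiment` with raw
counts, a log-normalized layer and a `cell_type` label per cell).
Normalization is total-count scaling to 10,000 counts per cell followed
by `log1p`.  We deliberately use this simple scheme rather than a
pooling-based size factor estimate: every downstream stage consumes only
*a* log-normalized layer and is agnostic to its provenance, and the
simple scheme is deterministic and dependency-free.  Expression
thresholds of the constraint kernel are therefore interpreted on this
scale and are plain configuration values.

Selection proceeds in stages (`selectPanel`, mode `"full"`):

1. **HVG pre-space.** Genes are reduced to the most highly variable
   (default 8,000, rank-limited for smaller references), ranked by
   within-bin normalized dispersion: dispersion = variance/mean of
   `expm1(logcounts)`, z-scored inside 20 equal-frequency bins of mean
   expression with the bin median and MAD (mean/sd when the MAD is
   zero).  Ties break by gene name, so the selection does not depend on
   input order.
2. **Penalized PCA prior.** Each gene is scored by the sum of its
   absolute loadings over the first 20 principal components and, when a
   constraint kernel is configured, multiplied by its low/high
   expression penalties.  The top 100 genes form the prior pool; this
   biases the following stages toward genes that carry broad variation.
3. **Primary trees.** For every cell type a one-vs-rest decision tree of
   depth at most 3 is trained; 50 trees per type are fit on fresh
   balanced samples (1,000 cells per type for training, 3,000 for
   testing, oversampling small types with replacement) and the best tree
   by held-out F1 is kept.  Training observations carry class proportion
   weights — each cell is weighted by its type's frequency in the full
   dataset — which undoes the distortion introduced by uniform per-type
   sampling.  The tree's specificity on every other type,
   s(c) = TN_c / N_c, measures which types it confuses.
4. **Hard negatives and secondary trees.** A type c is a hard negative
   for a target when s(c) < 0.9, or when s(c) lies more than one
   standard deviation below the mean specificity while also at least
   0.02 below it.  For every target with hard negatives, trees are
   retrained on only the target plus its hard negatives; specificities
   combine as the best over levels.  The default of three levels (one
   primary, two secondary) repeats this once more on the re-flagged
   types.
5. **DE reference trees.** In parallel, a tree pool is grown from
   differential expression: starting with the top two one-vs-rest Welch
   t genes per type, trees are trained as above, remaining problem types
   are identified by the same specificity rule, a focused Welch test of
   each problem type against its hard-negative set is run, and the top
   two new genes per type enter the pool.  The loop stops when no type
   is flagged, no new gene can be added, or after 12 iterations.
6. **Reconciliation.** Types that the DE trees classify better than the
   PCA trees (F1 gap above 0.005) pull their most important unused
   DE-tree genes into the PCA pool, one at a time with retraining, until
   parity or exhaustion.
7. **Ranking and completion.** Genes occurring in the final trees are
   ranked by summed impurity-decrease importance (ties by name);
   pre-selected genes are pinned to the top.  If a curated marker list
   is supplied, each type must have a minimum number of markers captured
   (a panel gene correlating above 0.5); missing markers are appended,
   and for marker-list types absent from the data the top markers are
   appended directly.  The panel is truncated or extended (by penalized
   PCA score) to the requested size.

Mode `"cto"` (cell-types-only) skips the PCA stages and finalizes the
panel from the DE reference trees alone; it optimizes classification
only and serves as the comparison point for what the variation-recovery
machinery adds.

## The evaluation suite

`evaluatePanel` computes, against a reference gene space (the HVG
pre-selection):

* **Coarse/fine clustering similarity.** Leiden clusterings at every
  target cluster number from 7 to 60 are produced by binary search over
  the resolution parameter (modularity objective, k = 15 neighbor graph
  over a 50-component PCA embedding; bounds [0.01, 50], at most 30
  bisections, the first exact hit wins, and the partition seed is fixed
  before every Leiden call).  Reference and panel partitions are
  compared by NMI = MI/mean(H_U, H_V) with natural logarithms; cluster
  numbers unreachable in either series are imputed by linear
  interpolation (nearest-value extension at the grid edges).  The
  normalized trapezoidal AUC over cluster numbers 7–20 is the coarse
  metric, over 21–60 the fine metric; normalization by the interval
  width makes a constant curve map to its own value.
* **Neighborhood similarity.** For k in {5, 10, 20, 30, 50}, the mean
  per-cell overlap fraction between the k-nearest-neighbor sets of the
  reference and panel PCA embeddings, linearly interpolated over
  k = 5…50 and integrated the same way.
* **Cell type identification.** Gradient-boosted trees (depth 3,
  learning rate 0.1, 100 rounds — the model family is fixed, these
  regularization values are this package's choice) under stratified
  five-fold cross-validation with five seeds (25 models).  Confusion
  matrices are row-normalized by the true type counts; accuracy is the
  mean diagonal over types and models, and the percentage of captured
  cell types passes each type's mean diagonal through a linearly
  smoothed step rising from 0.75 to 0.85.
* **Marker correlation.** For each curated marker, the maximum Pearson
  correlation with any panel gene on the normalized layer; averaged over
  markers, and (balanced variant) over cell types after taking each
  type's best marker.
* **Gene redundancy.** One minus the mean absolute pairwise correlation,
  and one minus the mean smoothed step of each gene's strongest
  correlation.  Both formulas are kept exactly as defined even though
  their names suggest the complementary quantity; they are reported with
  score semantics (1 = no redundancy), which we flag here rather than
  silently renaming.
* **Expression constraints.** A gene is penalized when its 0.9 quantile
  over positive-expressing cells falls below the low threshold
  (too dim to detect) or its 0.99 quantile over all cells exceeds the
  high threshold (optical crowding).  The penalty decays as a Gaussian
  of the threshold distance; the decay width (0.5 in log-expression
  units) is this package's choice, as only the decay family is fixed.
  The low-expression quantile is taken over positive cells, the high
  quantile over all cells.  Default thresholds 2.3 and 5 are technology
  specific and should be recalibrated per protocol and normalization.

The aggregated score is the mean of two category means: variation
recovery (coarse, fine, neighborhood) and cell type identification
(accuracy, captured types).

NMI of two partitions that are both trivial (single cluster, zero
entropy) is defined as 0.

## Spatial metrics

`moransI` implements the definitional statistic
I = (n/S0) ⋅ Σ w_ij z_i z_j / Σ z_i² over a binary symmetric
neighborhood graph (six nearest neighbors by default, union
symmetrized); a constant gene returns 0 with a warning.  The spatial
variation of a panel is the plain sum of per-gene values.

`fitLinearNcem` is a linear node-centric expression model: for each gene
the expression of cell i is regressed on its (receiver) cell type
one-hot encoding plus receiver × sender interaction indicators, where a
sender type is "present" when the cell has at least one neighbor of that
type in the spatial graph.  The binary presence encoding (rather than
neighbor counts) is chosen for stability on sparse graphs.  Wald tests
on the interaction coefficients give the significance table; aliased
columns (a receiver type that never, or always, sees a sender type) get
p = 1 and a flag rather than failing the fit.  The CCI recovery score
counts entries with p strictly below 0.05 — the boundary case counts as
not recovered, a convention made explicit because step-function
conventions at 0 differ — and no multiple-testing correction is applied
by default (a Benjamini–Hochberg option exists).

Note that the interaction design needs genuine variation in sender
presence: on graphs so dense that every cell sees every type, the
interaction columns become collinear with the receiver encoding and the
affected tests are conservative or aliased.

## Probe design

The pipeline (`designProbes`) takes a genome FASTA and a GTF, extracts
per-gene exon regions, merges blocks shared between isoforms (keeping
the supported transcript ids per block), orients them along the gene
strand and concatenates them into a merged gene coordinate (0-based,
half-open; GTF input is 1-based inclusive and converted at the
boundary).  Candidates are every window of every allowed length;
identical windows within a gene merge, with the union of their
transcripts.

Property filters (each independent and per-probe): unidentified
nucleotides, GC content, nearest-neighbor melting temperature,
homopolymer runs, and per protocol either a padlock ligation split (two
arms, each within the arm Tm window; among admissible splits the one
with the most balanced arm Tm is stored) or a self-complementarity scan
(longest reverse-complement self-match, default threshold 8 nt) standing
in for a full secondary-structure prediction — the scan is a documented
simplification with the free-energy route left as a configuration hook.

Melting temperatures use the unified nearest-neighbor parameter table
with terminal initiation terms, the entropy salt correction
0.368 (N−1) ln[Na+] and a linear formamide correction of −0.65 °C per
percent; defaults are 25/25 nM strand concentrations and 50 mM Na+.
Arm temperatures for all splits of a probe are computed in one pass from
prefix sums of the dinucleotide terms.

Binding-specificity filters use an internal exact k-mer seed (default
12 nt) with ungapped extension, searching both strands; identity is
measured over the aligned span and coverage relative to the probe.
Cross-hybridizing probes of different genes are resolved by repeatedly
removing the probe from the gene with the larger current candidate set
(ties: the lexicographically later gene id loses).  Identical sequences
are found by hashing; near-identical conflicts are located through the
other gene's region sequence and attributed to the best-overlapping
partner probe, which keeps the search linear in the data instead of
quadratic in the probe set.  Off-target hits against the background
(all gene regions minus the probe's own gene) remove a probe when
identity and coverage thresholds are met jointly; in padlock mode a
high-identity hit that spans the ligation-site window (split ± 5 nt)
also removes it, since ligation tolerates almost no mismatch there.

Per gene, the best set of exactly n non-overlapping probes maximizes
the summed score
min(n_tx/n_max, 1) ⋅ exp(−[(GC−GC_opt)²/2σ_GC² + (Tm−Tm_opt)²/2σ_Tm²]),
with σ set to half the allowed half-range — the score's ingredients are
fixed (distance to the GC/Tm optima, weighted by targeted transcripts)
but this explicit form is our own.  The optimum is found by dynamic
programming over the interval order, which is exact for interval
conflicts; among equal optima the leftmost-start set wins.  Genes with
fewer feasible probes than the minimum are reported in a failed-genes
table rather than silently dropped.

Final assembly (padlock): padlock = 3′ arm + backbone + 5′ arm; the
detection oligo crops the probe to the detection length with even
removal from both ends (the extra base of an odd trim comes off the 3′
side — a convention we fixed, as either side is defensible), substitutes
U for T, and annotates the fluorophore on the side with the nearest U
(5′ on ties).  Encoding protocols flank the probe with two (MERFISH) or
four (seqFISH+) readout sequences assigned round-robin from the pool;
full error-correcting codebook construction is out of scope.  Readouts
are random sequences filtered for GC, no GGG runs, off-target hits and
mutual similarity (iteratively dropping the highest-degree sequence in
the similarity graph); the forward primer additionally needs a Tm
window, a 3′ G/C clamp and clean self-complementarity, and is checked
against the background, the encoding probes and the T7 sequence.  The
reverse primer is the 20-nt T7 promoter.

## Synthetic data

All validation inputs are generated in code:

* `simulateReference` draws negative-binomial counts
  (var = μ + μ²/θ, θ = 2 by default) with log-normal base means and
  library sizes, planted per-type marker genes (log2 fold change 4 by
  default) and per-type gradient programs — genes following a uniform
  latent coordinate within their type, emulating continuous cell
  states.  The default scale (1,000 cells, 200 genes, 5 types, 2
  markers and 3 program genes per type) is the study condition used by
  the recovery checks and keeps a full selection run around a minute.
* `simulateSpatialDataset` places cells uniformly (or in per-type
  blobs) on a square, builds spatially smooth genes as sums of four 2-D
  Gaussian bumps scaled to unit field variance over Gaussian noise
  (sd 0.2), and adds an effect β to an interaction gene in receiver
  cells with at least one sender-type neighbor within radius r.  The
  bump construction gives deterministic low-frequency fields without a
  Gaussian-process dependency.
* `simulateTranscriptome` writes a single-chromosome FASTA/GTF with
  multi-isoform genes sharing their first exons, paralog pairs copied
  at a configurable identity, hard-masked genes, and alternating
  strands (which exercises the reverse-complement paths of the region
  extraction and the specificity searches).
* `bootstrapWithNoise` resamples cells with replacement within each
  type, preserving type frequencies exactly, and adds Gaussian noise
  (σ = 0.001) to the normalized values of duplicated cells only.  The
  noise is applied on the normalized layer: it is meant to break exact
  ties among duplicates and is small relative to log-normalized values.

What the simulations do **not** emulate: realistic gene-gene covariance
beyond the planted programs, batch effects, ambient RNA, doublets, or
segmentation error in the spatial data.  Passing recovery tests on these
fixtures therefore demonstrates that the machinery is implemented
correctly and recovers strong planted signal, not that a 20-gene panel
suffices for any particular tissue.

## Reproducibility and problem sizes

All randomness uses R's Mersenne-Twister; every stage seeds explicitly,
and the command-line layer derives independent per-stage seeds from one
global seed, so identical configurations reproduce byte-identical
artifacts.  The test-suite and acceptance problem sizes (hundreds to a
few thousand cells, tens to hundreds of genes, transcriptomes of a few
kilobases) were chosen so that planted effects are comfortably above
sampling noise while a full run stays in the minutes range; they are
stated in the scripts themselves.

## Known limitations

* The Leiden binary search can miss cluster numbers on small or highly
  structured graphs; the interpolation handles isolated gaps, but a
  reference dataset with fewer than ~100 cells cannot support the
  default 7–60 grid.
* The self-complementarity scan is a proxy; probes passing it can still
  fold.  For production MERFISH/seqFISH+ panels an external folding
  oracle should back the configuration hook.
* Sparse PCA selection searches the per-component sparsity level and
  may return a set one or two genes away from the requested size (it
  warns when it does).
* The expression-constraint thresholds are protocol- and
  normalization-specific; the defaults are sensible for log1p-scaled
  data at 10,000 counts per cell but should not be reused blindly.
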