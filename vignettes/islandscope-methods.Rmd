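---
title: "Detecting genomic islands from comparative gene-neighborhood images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genomic islands from comparative gene-neighborhood images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Genomic islands (GIs) are clusters of horizontally acquired genes, typically
10-200 kbp long, that drive much of the strain-to-strain variability of
bacterial genomes. Their most reliable signature is *sporadic distribution*:
an island is present in some isolates of a species and absent from close
relatives. Other signatures follow from their origin — shorter genes than the
host backbone, phage and mobility genes (integrases, transposases, capsid and
tail proteins), insertion near tRNA genes, and a high fraction of genes with
unknown function.

`islandscope` turns these signatures into a computer-vision problem. For each
query gene it builds a *compare region*: the gene's 10 kbp neighborhood
aligned against the homologous neighborhoods of related genomes, anchored at
genes of the same protein family and sorted by phylogenetic distance. The
neighborhood is rasterized as one image — one horizontal band per genome,
each gene a color-coded arrow scaled to its length and pointing with its
strand — and a binary convolutional classifier scores the image. In such
images a conserved backbone locus shows as vertically repeating arrow
columns, while an island gene shows as an empty or discordant pile-up: the
query row has no aligned partners. Per-gene scores are thresholded and merged
into islands, keeping only runs of GI-called genes spanning strictly more
than 8 kbp.

## Neighborhood construction

Homology is family identity: two genes align when they share `family_id`. No
sequence alignment is performed, which is why the package consumes only
annotations (GFF3 or GenBank), never nucleotides. For each reference genome
carrying the query's family, the anchor is the family copy whose midpoint
lies nearest the contig midpoint (ties broken by lowest gene id) — a
deterministic rule for the multi-copy case, which the compare-region idea
itself leaves open. All genes intersecting the `region_size` window (default
10,000 bp, the scale at which island boundaries are visible yet individual
genes remain resolvable) centered on the anchor midpoint enter the row with
signed offsets. When the anchor lies on the strand opposite the query, the
whole row is mirrored (offsets negated, strands flipped) and flagged, so
pile-ups share the query's orientation. Rows are sorted by the supplied
distances (ties by genome id) and truncated to `max_rows` (default 20
reference genomes). Distances are inputs: the package does not select
reference genomes by an evolutionary distance function.

## Rendering

The canvas defaults to 299x299 px — the native input of the Inception V3
family of backbones, so no resampling step is needed — split into 21 equal
bands: the query row plus 20 references. The horizontal scale maps
`region_size` bp onto the full width, so a gene of length L occupies
`round(L * width / region_size) +/- 1` px and the query arrow is centered in
band 1. Color encodes function: red is reserved for the query gene, green
for mobility genes, yellow for tRNA genes, blue for phage-related genes;
every other family gets a stable palette color from a 31-bit string hash of
its family id, so the same family is the same color in every image. Arrow
geometry (a body of 60% band height plus a triangular head of at most 8 px)
is a package choice — any deterministic glyph carries the same information.
Genes overlapping in coordinates are drawn in start order, later arrows
overdrawing earlier ones; genes partially outside the window are clipped.
Rendering is pure: identical inputs give byte-identical arrays, and images
are stored as lossless PNG only, never JPEG, so tests can assert exact
pixels.

## Classifier

The training scheme is transfer learning: a fixed convolutional backbone
extracts features and only a new binary head — global average pooling
followed by a dense sigmoid unit — is trained, with binary cross-entropy and
minibatch Adam (default 10 epochs, batch 32, learning rate 1e-3, 20%
held-out validation split; all randomness flows from one seed, so a rerun
reproduces the report exactly). Two backbones are supported:

* `tiny_cnn` — three 3x3 convolution blocks (3, 8, 16, 32 channels) with
  ReLU and 4x average pooling, weights drawn once from a seeded He
  initialization and then frozen. It ships with the package so the test
  suite never downloads weights. Seeded random convolutional features
  followed by a trained linear head are a well-understood baseline and are
  sufficient for the package's synthetic corpora, where the discriminating
  signal (ink mass and its distribution across bands) is strong.
* `inception_v3_pretrained` — a pluggable externally trained backbone,
  supplied as a checkpoint JSON via `weights_path`. Pre-training itself is
  outside the package's scope; without a weights file the configuration is
  rejected with instructions.

Fine-tuning backbone weights (`freeze_backbone = FALSE`) is deliberately
unsupported: the package trains heads only, which keeps training
deterministic, dependency-free and fast. No data augmentation is applied —
the renderings are canonical (query centered, rows distance-sorted), and
augmentations such as flips or crops would destroy exactly the positional
semantics the encoding creates. Class balance is enforced upstream by
`curate_balanced()` (seeded uniform downsampling of the majority class), not
by loss weighting.

## Training labels and island calling

When training labels come from other tools rather than simulations, the
genome is tiled into non-overlapping 10 kbp windows (a terminal remainder
shorter than half a window merges into its neighbor, avoiding degenerate
slivers) and a window is labeled GI only when *both* label-source prediction
sets cover at least `min_frac` (default 0.5) of its bases — a window-level
operationalization of "predicted by both tools" that a 1-bp touch cannot
satisfy. At inference, per-gene calls are merged: maximal runs of GI-called
genes (optionally tolerating `max_gap_genes` interruptions) become islands
spanning first-gene-start to last-gene-end, and only spans *strictly*
greater than `min_span = 8000` bp are reported ("more than 8 kbp").

## Evaluation framework

* **Keyword features.** GI-related genes are recognized by case-insensitive
  substring keywords in the product annotation, precedence phage > mobility
  > tRNA > unknown. The shipped vocabulary (editable YAML) classes
  "integrase" as mobility, not phage. "Unknown function" means the
  annotation matches markers such as "hypothetical protein".
* **Region-level metrics.** A predicted region is a true positive when it
  contains at least six phage-related genes or at least 50% unknown-function
  genes, else a false positive; a false negative is a run of at least six
  *strictly consecutive* phage-related genes with no overlapping prediction.
  No true-negative is defined at region level.
* **Cross-tool overlap.** Both the base-pair coverage of a target tool's
  islands by a predictor's union, and the percentage of target islands with
  any 1-bp overlap, are implemented (published comparisons have used either
  convention).
* **Gene-level ROC.** Each gene's outcome is judged on the window of the
  gene plus four flanking genes per side: called genes are TPs when the
  window holds a phage-related gene or overlaps another tool's island; genes
  not called are FNs only when the window holds a phage-related gene. The
  curve re-derives outcomes at every distinct probability threshold and
  integrates by the trapezoid rule; with no phage-positive (or no
  phage-negative) gene the AUC is undefined and reported `NA`. Percentages
  over empty denominators are reported `NA` throughout.

## The synthetic-data generator

`simulate_genome_set()` emulates exactly the comparative structure the
method reads: a query genome and 20 references share 300 single-copy
backbone families in conserved order, with per-genome jitter in gene lengths
(normal, mean 900, sd 200, truncated at 90 bp so every arrow is drawable)
and intergenic gaps (exponential, mean 120 bp — typical bacterial gene
density of about one gene per kbp). Three islands with spans drawn in
10-30 kbp are inserted at seeded backbone positions with fresh singleton
families, shorter genes (mean 500, sd 150), and annotations assigned 40%
phage keywords, 40% hypothetical protein, remainder mobility. By default
islands are absent from every reference (`island_presence_prob = 0`), the
sporadic signature in the limit; raising the probability creates harder
benchmarks. Reference distances are a seeded increasing sequence.

What the generator does *not* emulate: nucleotide-level signals (GC content,
codon bias — the encoder never sees sequence), gene loss and rearrangement
in references, partially conserved island fragments, annotation noise, or
multi-copy backbone families. Passing tests on this corpus therefore
demonstrate that the pipeline is wired correctly and that the encoder makes
the sporadic signature learnable — not that the shipped `tiny_cnn`
matches a large pretrained backbone on real genomes.

Because one simulated genome carries ~90 island genes in expectation
(3 islands x ~20 kbp / ~620 bp per gene) with substantial seed-to-seed
spread, `generate_training_corpus()` accepts a list of simulated sets and
pools their genes; corpora of 64 or 100 images per class are drawn from two
independent replicates so the per-class demand sits far below the pooled
supply at any seed.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; conversion
  happens only at file boundaries (GFF3/GenBank 1-based inclusive, BED
  0-based half-open). Strand "." becomes "+" with a warning — the renderer
  needs a direction.
* Window membership is any 1-bp intersection; the terminal tiling window
  merges below half-size; the 8 kbp island filter is strict.
* The separability oracle — count non-background pixels outside the query
  band, threshold at the midpoint of the class means on the training split —
  validates every rendered corpus before a learned accuracy is trusted: if
  this one-feature linear rule cannot reach 0.95 held-out accuracy, the
  corpus is not cleanly separable and a CNN result on it would be
  uninterpretable.
* Problem sizes in the test suite: interval-metric implementations are
  checked against independent per-base bitmap and brute-force oracles on
  1,000 random fixtures per operation (contigs up to 100 kbp); the learning
  study uses a 200-image corpus at the default 299x299 canvas, 10 epochs;
  the recovery study trains on one simulated set (64 images per class) and
  evaluates on an independent one, measuring base-pair F1 against the
  planted truth. These sizes make the full suite reproducible on a single
  CPU in minutes while leaving every stage's default parameters untouched.

## Known limitations

Homology-by-family makes results only as good as the family assignments;
genomes annotated with incompatible family schemes will align nothing.
The pixel-level contract is guaranteed only for the package's own
rasterizer. The region-level metrics inherit the keyword vocabulary's
blind spots — islands carrying none of the listed keywords are invisible
to them. And the shipped backbone is intentionally small; for real genomes
a pretrained backbone supplied through the checkpoint interface is
expected to generalize far better.
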