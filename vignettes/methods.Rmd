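---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind each stage of `cytosweep`, the
parameters that matter, the numerical conventions, and the choices made
where more than one reasonable design existed. It is the reference for
"why does the package do it this way".

## The analysis model

High-dimensional cytometry produces per-event intensity vectors over
dozens of protein markers. The package treats analysis as a fixed sequence
of stages over a single event container (the `cell_table`): ingest,
arcsinh transform, 2-D embedding, clustering, resolution scoring,
summaries, landmark anchoring, and evaluation. Three metadata files steer
everything: the file table (sample, batch, control status per FCS file),
the marker table (which channels feed the embedding, the clustering and
the landmark comparison — three independent boolean flags), and a YAML
configuration holding numeric parameters.

Two conventions hold throughout:

- **Barcodes.** Every event is identified as `<sample_id>_<index>`, with
  the sample id taken from the FCS file name and the index 1-based within
  each file (matching the FCS convention of 1-based event indexing; the
  choice of base is a convention of this package). All joins — ground
  truth, regions, predictions — go through these barcodes.
- **Feature spaces.** The embedding sees `used_for_UMAP` markers; the
  clustering and the Davies–Bouldin index see `used_for_clustering`
  markers; landmark cosine similarity sees `used_for_scaffold` markers.
  All three operate on transformed, unscaled values. Clustering never
  consumes embedding coordinates; the embedding is visualization/QC only.

## Arcsinh transform

`asinh(x / c)` with a single global cofactor `c > 0` per run (default 5,
appropriate for mass-cytometry dual counts; spectral-flow intensities
typically need cofactors in the hundreds to thousands, e.g. 6000). The
transform is linear for `x ≪ c` and logarithmic for `x ≫ c`. A
per-channel cofactor was deliberately rejected to keep the configuration
surface identical to a single-cofactor run; negative inputs (possible
after compensation or unmixing) pass through untruncated since asinh is
defined on all reals.

## Embedding

UMAP via uwot, restricted to the flagged markers, single-threaded with a
fixed seed so coordinates are reproducible. Defaults follow the run
configuration: `n_neighbors = 15`, `min_dist = 0.1`, `spread = 0.1`,
`learning_rate = 0.5`, random initialization. Note that `min_dist` must
not exceed `spread` for the fitted distance curve to exist; when a
configuration violates this the package raises `spread` to `min_dist` and
warns, rather than failing mid-run. The configuration key `k` near the
UMAP block in some published configurations is ambiguous between a graph
connectivity parameter and a metacluster count; here neighborhood
connectivity is governed solely by `n_neighbors`, and `k` under the `som`
block is the metacluster count.

## SOM clustering

The self-organizing map is trained online: the codebook (one prototype
per node of an `xdim × ydim` grid, default 6 × 6) is initialized from a
seeded uniform sample of data rows, then for `rlen = 10` passes events
are presented in seeded random order; the best-matching unit (BMU;
nearest prototype, Euclidean, ties to the lowest node index) and all
nodes within the current grid radius are moved toward the event. The
learning rate decays linearly 0.05 → 0.01 and the bubble (threshold)
neighborhood radius decays linearly from the 0.67 quantile of
node-to-node grid distances to 0. These hyperparameters mirror the
established FlowSOM-style defaults and are exposed through
`train_som(params = ...)`. Markers are not standardized before training
(consistent with reporting unscaled median-expression heatmaps); a user
who wants scaling can scale the matrix before calling.

Every node is a cluster: a 6 × 6 grid defines exactly 36 cluster ids, a
2 × 4 grid exactly 8, and nodes may own zero events. Empty clusters are
carried through summaries (zero frequency, `NA` medians) and excluded
from the DBI, whose within-cluster scatter is undefined for empty sets.

**Metaclustering** merges nodes by average-linkage hierarchical
clustering of the codebook, cut at `k` groups (default 3 when enabled).
Deterministic agglomeration was chosen over consensus metaclustering:
consensus resampling is stochastic and harder to test, and at codebook
sizes of tens of nodes average linkage recovers the same block structure.

## CLARA clustering

For the k-medoids backend (defaults `k = 20`, euclidean, 50 subsamples),
CLARA draws seeded subsamples of size `min(n, 40 + 2k)` — the classical
sample-size rule — fits PAM to each (greedy BUILD, then steepest-descent
SWAP over all medoid/non-medoid exchanges until no exchange lowers the
total dissimilarity), scores each candidate medoid set by the mean
distance of *all* events to their nearest medoid, and keeps the best.
The PAM cost trajectory is recorded and is non-increasing by
construction; the test suite asserts this and cross-checks the attained
optimum against the `cluster` package's PAM on small instances.

## Resolution scoring and grid selection

Each grid in the sweep series (packaged default: 2×2 through 8×8, twelve
grids) is trained with a deterministic per-grid seed and scored with the
Davies–Bouldin index on the clustering feature space:

$$\mathrm{DBI} = \frac{1}{K}\sum_{i=1}^{K}\max_{j\neq i}
\frac{S_i + S_j}{M_{ij}}$$

with $S_i$ the mean Euclidean distance of cluster-$i$ events to their
centroid and $M_{ij}$ the distance between centroids, over the $K$
non-empty clusters. Lower is better. The DBI is computed on **all**
clustered events rather than a subsample — determinism was preferred over
speed at the problem sizes this package targets (the computation is
linear in events). Selection is manual by default, mirroring the
pause-for-user design (the sweep exports a cluster-count-vs-DBI table and
plot and stops); `global_min` (ties: fewest clusters, then lowest xdim)
and `local_min` (first interior minimum in ascending cluster-count order,
falling back to the global minimum with a warning when the sequence is
monotone) are provided for scripted runs.

## Summaries

"Normalized" frequency means within-file proportions (each file row sums
to 1), the convention that matches per-sample composition plots;
alternatives (column-wise or global normalization) were rejected. Median
expression is computed per cluster over **all** markers — annotation
often relies on markers excluded from clustering — on the transformed,
unscaled values. The row-scaled heatmap variant uses
`(x − row mean) / row sd` with constant rows mapped to 0.

## Landmark anchoring

Each gated landmark FCS file defines one reference population, profiled
as the median transformed expression over the `used_for_scaffold`
markers; medians (rather than pooled events) keep the landmark profile
on the same footing as the cluster profiles it is compared to. Each
non-empty cluster is assigned the landmark with maximal cosine
similarity; cosine is scale-invariant, so clusters differing from a
landmark only by intensity scaling still match. Ties break to the
lexicographically first landmark name; zero-norm profiles (possible for
clusters of all-zero events) are reported `unassigned` with a warning
rather than erroring the run. The output is a plain CSV edge list; no
binary graph container is produced.

## Evaluation protocol

Concordance between per-cell predicted annotations and ground truth uses
four metrics over repeated subsamples: per repeat, 10,000 shared barcodes
are drawn **without replacement** (the convention chosen here; repeats
use seeds derived as master + repeat index), and accuracy, adjusted Rand
index (Hubert–Arabie contingency formula), Fowlkes–Mallows
(`TP/√((TP+FP)(TP+FN))` over same-cluster pairs) and mutual information
are computed; means over 10 repeats are reported. Cells lacking a ground
truth label are excluded by the barcode intersection. Accuracy is an
exact string match and therefore requires both sides to share an
annotation vocabulary (cluster labels are expected to be expert-assigned
cell-type strings); no optimal label matching is applied, by design. MI
is reported in nats (a bits option exists). The three partition metrics
are label-permutation invariant; accuracy is not, which is documented
behavior rather than a defect.

The tetramer positivity gate marks events at least 3 standard deviations
above the mean raw intensity. The sd is the sample (n−1) estimator;
`ddof = 0` switches to the population estimator, and the threshold
multiplier is exposed. A zero-variance channel yields no positives and a
warning.

## Spatial enrichment

Imaging tables join cluster labels to centroids and region annotations by
barcode. Region composition normalizes within region (each region column
is a probability vector over clusters); per-cluster enrichment is
`log2(freq_stroma / freq_tumor)`. Clusters with zero frequency in either
region are flagged undefined and excluded from plots — no pseudocount is
added, so reported enrichments are always ratios of observed frequencies.
Note the ratio per cluster is identical whether frequencies are
normalized within region or within cluster, since the within-region
totals cancel; the within-region form is used because its columns are
interpretable compositions.

## The synthetic-data generator

`generate_dataset()` emulates a multi-sample, multi-batch cytometry
experiment: five immune-like populations (CD4 T, CD8 T, B, monocyte, NK)
over a 10-marker panel, each population "high" (arcsinh mean 4) on its
signature markers and "low" (0.5) elsewhere with sd 0.3 — an 11.7 sd
separation between on and off states, i.e. well-separated populations —
at proportions 0.30/0.25/0.20/0.15/0.10, 4 files of 10,000 events in 2
batches with a +0.15 arcsinh shift on the second batch, and optional
control files. Values are drawn on the arcsinh scale and
inverse-transformed (`c · sinh`, truncated at 0 since counts are
non-negative) so that the pipeline's forward transform recovers Gaussian
populations, making separability analytically controllable. The
generator emits the exact input file set of a real run (FCS directory,
the three metadata files, truth labels, a landmark directory with one
file per population).

What it does **not** emulate: spillover/spectral overlap, doublets,
acquisition drift within a file, heavy-tailed or zero-inflated marker
noise, rare populations below ~1%, or continuous phenotype gradients
(e.g. activation continua). Tests passing on this generator therefore
demonstrate correctness of the algorithms and plumbing under idealized,
well-separated mixtures — not clustering performance on hard real data,
where populations overlap and resolution choice is genuinely ambiguous.

## Numerical conventions and degenerate inputs

- All stochastic steps (initialization, presentation order, subsampling,
  CLARA samples, UMAP) run under locally scoped seeds; the session RNG
  state is restored afterwards. Two runs with the same configuration are
  hash-identical in their exports (single-threaded UMAP).
- BMU and nearest-medoid ties break toward the lowest index; landmark
  ties toward the first name alphabetically. These are stated, tested
  tie-breaks, not incidental implementation order.
- Empty FCS files contribute zero rows with a warning; removing all
  events (all-control input) warns and yields an empty table; DBI errors
  below two non-empty clusters; Fowlkes–Mallows errors when a partition
  has no same-cluster pairs; cosine errors on zero-norm vectors.
- FCS support is intentionally minimal: single-dataset list-mode files,
  float/double/integer data, both byte orders on read; files are written
  as FCS 3.1 float little-endian. Keyword handling beyond what the
  pipeline needs (spillover matrices, multi-dataset files) is out of
  scope.
- Boolean metadata accepts `true/false`, `TRUE/FALSE`, `1/0`.
- Unknown CSV columns are dropped with a warning rather than rejected —
  metadata files are routinely edited by hand.

## Checkpoints

Stage numbering is fixed: 1 ingest/transform, 2 embedding, 3 sweep,
4 clustering, 5 summaries, 6 landmark, 7 evaluation, 8 final export.
Each stage persists `checkpoint<k>.rds` and a stage may run only when its
predecessor exists; stage 4 additionally demands an explicit grid (or the
CLARA backend), which is where an interactive run pauses on the DBI plot.
`manifest.json` records completed stages, seeds and MD5 hashes of all CSV
and image exports. The matrix entry point (batch-corrected or imaging
input) replaces stage 1's FCS read via `matrix_path` /
`already_transformed` in the configuration; an already-transformed matrix
is stored directly as transformed expression and the cofactor is not
re-applied.

## Problem sizes in the shipped tests

The test suite and the acceptance script size their simulations to run
comfortably on a laptop core: module tests use hundreds to a few thousand
events; the planted-population recovery check uses 50,000 events × 10 SOM
seeds (the SOM core is C++, so this takes seconds per seed); the
evaluation-protocol checks use 10 × 10,000 subsamples from 20,000–25,000
labelled cells; brute-force metric cross-checks use ≤ 200-event
instances, where exhaustive pair enumeration is exact and fast.

## Known limitations

- No batch correction: batch effects are assessed (split UMAPs, batch
  composition tables) but corrected upstream; the matrix entry point
  exists precisely to accept corrected output.
- No graph-based clustering backends, no minimal-spanning-tree or
  force-directed layouts; landmark output is tabular.
- Accuracy requires shared vocabularies (see above).
- The online SOM, like any SOM, can leave nodes empty or split a
  population across adjacent nodes at fine grids; that is what the DBI
  sweep and metaclustering are for.
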