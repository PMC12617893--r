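---
title: "Zero-shot protein segmentation: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-shot protein segmentation: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zps)
```

## The problem and the model

A protein is a chain of functional units — folded domains, intrinsically
disordered regions (IDRs), compositional-bias regions, targeting signals —
and a protein language model (pLM) assigns each residue a contextual
embedding vector. Within one functional unit the rows of the resulting
`L x D` matrix are statistically homogeneous; at the transition between two
units their distribution shifts. `zps` turns that observation into a
segmentation method that needs no training and no fine-tuning: a
change-point analysis on the rows of the embedding matrix.

### The sliding-window kernel statistic

For a candidate boundary $t$ (a 0-based position between rows), take the
$w$ rows centred on $t$ and compare the two halves under the RBF-kernel
least-squares cost

$$ c(X) \;=\; n - \frac{1}{n}\sum_{i,j}\exp\!\big(-\gamma\,\lVert x_i - x_j\rVert^2\big), $$

which is zero for one row or identical rows and grows with within-block
heterogeneity. The *gain* at $t$ is

$$ g(t) \;=\; c(\text{both halves}) - c(\text{left half}) - c(\text{right half}), $$

large when the $w/2$ residues before $t$ look unlike the $w/2$ after it.
Boundaries are local maxima of the gain curve with positive gain, selected
greedily by decreasing gain under a minimum-spacing constraint, and capped
by a per-length budget. Boundaries $a, b, c$ on a protein of length 100
produce the segments $(0,a), (a,b), (b,c), (c,100)$ — 0-based, half-open,
tiling the protein exactly. Each segment's embedding is the column mean of
its rows (average pooling); fragments are never re-embedded.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window` | 30 | residues | each boundary compares 15 residues against the next 15; small enough to see sub-domain structure, large enough for a stable kernel cost |
| `boundaries_per_100aa` | 3 | boundaries / 100 aa | the budget at which boundary counts saturate: beyond it, gain-curve peaks, not the budget, limit the output |
| `rbf_bandwidth_rule` | median heuristic | — | $\gamma = 1/\mathrm{median}\,\lVert x_i - x_j\rVert^2$ over (sampled) row pairs, resolved once per protein; scale-free across embedding providers; a fixed-$\gamma$ override exists for oracle comparisons |
| `min_spacing` | `window/2` | residues | non-maximum suppression; prevents duplicate boundaries within one window |
| transfer threshold | 30% | fraction of segment | an annotation is transferred when its intersection covers at least 30% of the segment |
| `iou_threshold` | 0.5 | — | IoU at or above which a predicted/annotated pair is a true positive |
| boundary tolerance | 10 | residues | a predicted boundary strictly less than 10 aa from an annotated one counts as recovered |
| `min_n` (label filter) | 25 | occurrences | labels rarer than this in the corpus give confidence intervals too wide to interpret |
| Leiden `resolution` | 2 | — | community granularity for clustering unannotated segments |
| shuffle `n` | 10,000 | permutations | resolution of the empirical p-value (`<1/n` when no null value reaches the observed statistic) |

## Decisions the method description leaves open

Several details are not pinned down by the procedure sketched above; the
package resolves them as follows, and each choice is visible in the API.

**Bandwidth.** No value of $\gamma$ is prescribed anywhere; the median
heuristic is the standard scale-free choice for kernel change-point
methods and makes the statistic invariant to a global rescaling of the
embeddings.

**Peak qualification.** Gains must be strictly positive to qualify, and
gains within `1e-8` (relative) of zero are treated as zero: the windowed
kernel sums are computed from cumulative sums, whose cancellation error
would otherwise create microscopic "positive" peaks in exactly-flat
regions of the curve.

**Boundary scores.** The confidence score of a boundary is the mean
absolute per-dimension Welch $t$ statistic between the up-to-15 rows on
either side; the aggregation over dimensions (mean absolute $t$) is
symmetric and dimension-count invariant. A segment scores the average of
its two boundaries; terminal segments use their single scored boundary.

**Cosine merging.** Over-segmentation correction recomputes the all-pairs
cosine similarity after every merge and iterates to a fixed point
(`iterate = FALSE` gives the single-application variant). The guard that
only proteins with at least 6 segments are corrected is re-checked every
round: with few segments, a middle segment is adjacent to most others and
would merge regardless of similarity.

**Transfer ties.** When two annotations tie on IoU in multi-class
transfer, the longer annotation wins, then the lexicographically smaller
label — determinism over any deeper principle. The IDR flag uses the
union of disorder-annotation overlaps (the more permissive reading of
"overlap with a disordered annotation").

**Evaluation matching.** AIoU, precision and recall use best-IoU-per-side
matching, not one-to-one assignment: each prediction is judged by its best
positive and vice versa. This differs from detection-style Hungarian
matching and is stated in the report metadata. Boundary-distance pairing
requires any positive overlap, ties broken by earlier start; the 10-residue
rule is strict (`< 10`).

**Confidence intervals.** Binomial proportion CIs are Wald
(normal-approximation) intervals at 95%, clamped to $[0,1]$; Wilson is
available by flag.

**Nearest-neighbour exclusions.** Protein-level labels exclude
same-protein neighbours entirely; segment-level labels exclude only
adjacent segments (sharing an endpoint coordinate on the same protein).
When the raw nearest neighbour is excluded the next admissible one is
used. Discovery-mode k-NN excludes exact self matches (same protein and
coordinates).

**Colour map.** The 3-D reducer is a pluggable contract; the default is
UMAP with a fixed seed where `uwot` is installed and a deterministic
principal-component projection otherwise, and tests use a stubbed linear
projection. Channel values are floats in $[0,255]$
($255\,\sigma(X_d - \bar X_d)$); rounding to integers happens only at
serialization. Corpus means are computed once over the whole corpus;
incremental recolouring is deliberately unsupported.

**Leiden stage.** Unannotated segments are clustered on a cosine
k-nearest-neighbour graph (k = 15, union-symmetrized) with
`igraph::cluster_leiden` (modularity objective, resolution 2, iterated to
convergence, fixed seed). A structureless input — all pairwise
similarities equal — returns a single cluster rather than the
over-fragmentation that any resolution-2 quality function produces on a
tiny complete graph.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` builds proteins as sequences of blocks; each block
draws its rows from a class mean plus isotropic Gaussian noise, adjacent
blocks always belong to different classes, and planted boundaries, block
labels and jittered annotation sets are recorded as ground truth.

`mean_separation` is calibrated per dimension: two class means sit at
Euclidean distance $s\,\sigma\sqrt{D/2}$ for separation $s$ and noise SD
$\sigma$ — the distance of two blocks whose means differ by $s$ SDs in
half of the embedding dimensions. This mirrors both the univariate
change-point signal-to-noise convention applied coordinate-wise and the
way classes of real embeddings differ: densely, across many dimensions,
not in a couple of coordinates. The default corpus for boundary-recovery
studies is 100 proteins of length 300 at $D = 32$ with 3 planted
boundaries and separation 2; categorization studies use separation 4. The
dimension 32 (rather than a pLM's 1024) loses no coverage because every
algorithm in the package is dimension-agnostic.

Two fidelity limits matter when reading test results:

* **Noise is i.i.d. across residues.** Real pLM embeddings vary smoothly
  along the chain; neighbouring residues are strongly correlated and
  within-segment rows are nearly constant. With i.i.d. rows the windowed
  kernel gain has a strictly positive null mean
  ($\mathbb{E}[g] = 1 - \bar k > 0$ inside a homogeneous block, at any
  noise level, because the median-heuristic $\gamma$ makes the statistic
  scale-free), so spurious positive-gain peaks appear and the boundary
  budget fills. Budget *saturation* — doubling the budget changing
  nothing — is therefore a property of the smooth/low-noise regime, and
  the package demonstrates it on the noise-free corpus, where qualifying
  peaks coincide exactly with true change points. On noisy i.i.d.
  corpora the budget, not the peaks, limits the output.
* **Noise is isotropic.** Real embedding covariance is anisotropic;
  class structure recovered here at a given separation says nothing
  about the absolute separations present in any particular pLM.

Passing tests on these corpora show that the machinery — statistic,
selection, pooling, merging, transfer, evaluation — is correct under its
stated model, not that any particular biological annotation set will be
reproduced at a given accuracy.

## Numerical choices and degenerate inputs

* Proteins shorter than the window yield one whole-protein segment, not
  an error.
* `rbf_cost` clamps tiny negative distances from the quadratic-form
  expansion to zero; costs are non-negative by construction.
* Degenerate constant matrices fall back to $\gamma = 1$ (the median
  pairwise distance being 0).
* All-identical rows return the stable input order from
  `cluster_leaf_order()` and a single cluster from `residue_cluster()`
  and `cluster_unannotated()`.
* An empty prediction set evaluates to `precision = NA` (undefined, not
  0) and `recall = 0`.
* Coordinates are 0-based half-open internally, everywhere; 1-based
  inclusive tables are converted at the I/O boundary and the conversion
  is an involution.
* The embedding store uses R serialization, so write-then-read is
  bit-exact.

## Problem sizes used by the test suite

The suite regenerates every fixture from seeds at run time: 100 proteins
of length 300 for boundary recovery, 500-segment corpora for the exact
1-NN cross-check, 50 corpora of 48 segments for class separation, 200
random proteins for merge properties, 1,000 random interval pairs for the
IoU oracle, and 200 replicate datasets of 120 residues at 500 shuffles
each for the permutation-test calibration. These sizes give stable
Monte-Carlo estimates for every property tested while keeping the whole
suite fast enough to run on every change.

## Known limitations

* The kernel statistic's localization error grows as separation falls;
  at per-dimension separations well below 2 SDs, boundaries drift by more
  than a few residues and recovery degrades gracefully rather than
  failing loudly.
* The approximate nearest-neighbour backend is a contract only; all
  shipped code paths are exact.
* The pLM adapter validates the 8,000-residue cap and delegates to a
  user-supplied encoder; no model ships with the package, so end-to-end
  runs on real proteins require precomputed embedding matrices.
* `pr_at_k` recomputes the full evaluation per prefix; for very large
  prediction sets an incremental implementation would be preferable.
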