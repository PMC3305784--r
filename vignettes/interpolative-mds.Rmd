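---
title: "Interpolative MDS for sequence clustering: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpolative MDS for sequence clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqmds)
```

## The problem

Amplicon surveys of marker genes such as 16S rRNA produce collections of
10⁵ or more short reads (here: under 200 nt) whose family structure is
unknown. A robust way to expose that structure is to compute a genetic
distance for every read pair by *global pairwise alignment* — which
handles the hypervariable regions of rRNA genes better than multiple
sequence alignment — and to embed the distance matrix into three
dimensions for clustering and visual inspection. The obstacle is cost:
both the all-pairs alignment stage and metric MDS are O(N²).

`seqmds` implements both the basic O(N²) pipeline and an interpolative
variant: a random in-sample subset of size M gets the full treatment, and
each of the N − M remaining reads is placed into the trained embedding
independently, using only its M alignments against the in-sample reads.
The total alignment count drops to M(M−1)/2 + (N−M)·M — checked in this
package as an exact integer, not an asymptotic claim, via a cost ledger
that counts every alignment and majorization iteration.

## Models and procedures

### Genetic distance

Reads are aligned by Needleman–Wunsch global alignment with affine gaps
(Gotoh's three-state recurrence; a gap of length $g$ costs
$\mathrm{open} + g\cdot\mathrm{extend}$; end gaps are penalized). The
distance is

$$\delta = 1 - \frac{\text{identical aligned columns}}{\text{alignment length}},$$

i.e. one minus fractional identity with gap columns counted in the
length, giving values in $[0,1]$. This is the simplest bounded
dissimilarity consistent with feeding distances directly into metric MDS;
it is isolated behind `genetic_distance()` so an alternative definition
is a one-function change. Defaults for the scoring scheme are
EDNAFULL-like magnitudes (match +5, mismatch −4, gap open 10, gap extend
4), all exposed in `alignment_params()`. `N` bases are scored as
mismatches against everything, including `N` — a conservative treatment
of ambiguous calls, which also keeps $\delta = 0$ equivalent to exact
residue identity.

The traceback tie-break is fixed (diagonal over vertical over
horizontal) so that the identity fraction, and hence $\delta$, is a
deterministic function of the inputs. The *score* is tie-break
independent; only the reported alignment path is pinned down.

### Full MDS by SMACOF

The embedding minimizes raw Kruskal stress with uniform weights,
$\sigma(X) = \sum_{i<j} (\delta_{ij} - d_{ij}(X))^2$, by iterating the
Guttman transform $X' = n^{-1} B(X) X$. Uniform weights keep the update a
closed-form averaging with O(N²) cost per iteration, matching the
complexity accounting above. Stress is guaranteed nonincreasing; the
per-iteration trace is stored on the fit and asserted in the tests.

Initialization is classical scaling (Torgerson) by default. We initially
used seeded uniform random starts, but on distance matrices with
well-separated clusters — including the package's own geometric test
fixtures — random starts regularly converge to *cluster-swap local
minima*: configurations in which two points of different clusters have
effectively traded places, leaving stress orders of magnitude above the
global optimum. Classical scaling starts in the basin of the metric
solution, is deterministic (removing one seed from the reproducibility
surface), and on exactly embeddable inputs recovers the generator
configuration to machine precision. `init = "random"` remains available
in `mds_params()` for studying the stress landscape.

### Interpolation of out-of-sample reads

Each out-of-sample read is aligned against all M in-sample reads (this is
precisely the (N−M)·M term; no approximate neighbor search is used), its
k nearest anchors are kept, and its position solves the single-point
stress problem $\min_x \sum_{i=1}^{k} (\delta_i - \|x - p_i\|)^2$ with
anchors fixed, by the per-point majorization

$$x \leftarrow \frac{1}{k} \sum_i \left[ p_i +
  \frac{\delta_i}{\max(\|x - p_i\|, \varepsilon)} (x - p_i) \right],$$

started from the anchor centroid. The per-point stress is nonincreasing
across iterations. A read at distance zero from an anchor (an exact
duplicate) is placed on that anchor directly, with zero iterations.
Because points are placed independently, the stage is embarrassingly
parallel, and the result is bitwise identical for any processing order,
block size or worker count — a property the tests assert on the emitted
points files.

Whether the majorization should run over all M anchors or only the k
nearest is genuinely open; both are supported (`k_neighbors = M` uses
all). The default k = 10 keeps the per-iteration cost constant per point
and, on embeddable fixtures, places points within ~10⁻¹⁰ (unit-RMS
units) of their true positions; anchor distances are not weighted or
thresholded.

### Clustering and evaluation

Cluster labels come from k-medoids (PAM: BUILD, then SWAP until no
medoid exchange lowers total within-cluster distance) run directly on
the in-sample distance matrix via `cluster::pam()`. PAM was chosen
because it consumes pairwise dissimilarities natively — the exact
interface the distance stage provides — is deterministic, and is
verifiable against exhaustive medoid search at small n (the tests do
this at n = 8). The cluster count C is user-supplied; model selection
is out of scope. Out-of-sample reads take the label of the nearest
medoid in *embedded* space, so label propagation adds no alignments and
the cost ledger stays at its closed form.

Two embeddings are compared by Procrustes superimposition. Since MDS
output is defined only up to translation, rotation, reflection and
uniform scale, both configurations are centered and normalized to unit
RMS size before the optimal orthogonal transform (reflections allowed)
and residual scale are fitted by SVD. The reported `rmsd` is therefore
symmetric in its arguments, scale-free, and read directly against the
configurations' unit size (an rmsd of 0.1 means residuals are 10% of the
configuration's RMS radius). Partition agreement is quantified by the
adjusted Rand index (`mclust::adjustedRandIndex` behind
`adjusted_rand_index()`).

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `match`, `mismatch` | +5, −4 | integer per-column scores |
| `gap_open`, `gap_extend` | 10, 4 | gap of length g costs open + g·extend |
| `n_dim` (L) | 3 | embedding dimension; 3 for visual output |
| SMACOF `tolerance` | 1e−6 | relative stress change; stop criterion |
| SMACOF `max_iterations` | 500 | cap |
| `init` | `"torgerson"` | see above; `"random"` uses `seed` |
| `k_neighbors` | 10 | anchors per interpolated point; up to M |
| per-point `tolerance` | 1e−8 | relative point-stress change |
| per-point `max_iterations` | 100 | cap |
| `block_size`, `workers` | 5000, 1 | parallelism only; never affect results |

Numerical guards: coincident points in the Guttman ratio are clamped at
$\varepsilon = 10^{-10}$; an anchor centroid coinciding with an anchor at
$\delta > 0$ is nudged by $10^{-9}$ before iterating; a distance matrix
that is all zeros off the diagonal (e.g. one unique read after
deduplication) is rejected as degenerate rather than embedded.

## What the synthetic data does and does not emulate

`generate_families()` draws C random ancestors (uniformly over
A/C/G/T, re-drawn until every pair differs in ≥ 30% of sites — random
~150 nt sequences differ in ~75%, so this rarely retries), then derives
members by per-site substitution (default rate 0.02) and single-site
indels (default 0.005), with optional verbatim duplicates. Defaults give
mean within-family distances under 0.15 and between-family distances
above 0.25 under the default scoring — comfortably separable, as a
marker-gene family structure is. It does **not** model pyrosequencing
error profiles (homopolymer miscalls), rate heterogeneity across sites,
multi-base indels, or realistic family-size skew (sizes are equal by
default; pass per-family counts where needed). Tests passing on these
fixtures show the pipeline preserves separable structure; they do not
certify behavior on overlapping families.

`generate_geometric()` produces the complementary oracle: Gaussian blobs
in the unit cube whose *exact* Euclidean distances (scaled into [0,1])
form the input, so a zero-stress configuration exists and recovered
coordinates can be compared to the generator's by Procrustes. Sequence
distances have no such ground truth; all exact-recovery claims in the
tests are made on geometric fixtures only.

## Problem sizes and scope

The test and acceptance runs use N = 150–300 reads (and geometric
fixtures up to n = 200) — sizes at which every contract, including the
exact operation counts 19,900 (full, N = 200) and 8,725 (interpolative,
N = 200, M = 50), is verified in seconds while exercising the identical
code paths a large run would use. Parallelism is local forked workers
over row blocks and point chunks with a result-invariance contract;
distributed execution, deterministic-annealing variants of MDS and
clustering, banded or vectorized alignment, and automatic selection of C
or of the in-sample ratio M/N are out of scope. The in-sample subset is
drawn uniformly at random; stratified selection is not implemented, and
choosing the optimal M/N trade-off between cost and within-cluster
resolution is left to the user.
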