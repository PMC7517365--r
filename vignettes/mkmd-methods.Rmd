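---
title: "Multiple kernels over multiple dissimilarities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple kernels over multiple dissimilarities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkmd)
```

## The problem

Protein function prediction from folded structure is hard because the
catalysed reaction leaves only a minor imprint on a protein's global shape.
This package treats each protein as a *contact network*: an unweighted,
undirected graph whose nodes are residues and whose edges connect residue
pairs with alpha-carbon distance in the closed band [4, 8] Angstrom. The
lower bound removes trivial backbone-neighbour contacts (consecutive alpha
carbons sit near 3.8 A), the upper bound reflects peptide geometry (about
two van der Waals radii). Node and edge labels are deliberately discarded:
the classifier sees topology only.

A single graph descriptor rarely suffices, so each network is described by
eight numeric representations:

1. **X(1)** Betti numbers of the clique (Vietoris-Rips) complex;
2. **X(2)** node-centrality profile (degree, closeness, betweenness,
   eigenvector, clustering coefficient; mean and sd over nodes);
3. **X(3)** graph energy and Laplacian energy;
4. **X(4)** network-cartography role fractions plus modularity;
5. **X(5)** heat-content expansion coefficients;
6. **X(6)** heat-kernel trace on a fixed time grid;
7. **X(7)** network size;
8. **X(8)** sampled spectral density of the normalized Laplacian.

## The classifier

Each representation *i* is embedded in a *dissimilarity space*: pattern *x*
becomes the vector of its distances `d(x, p)` to the training patterns
(Euclidean by default, configurable per representation). A binary mask *w*
selects a subset of training patterns as *prototypes*, reducing the columns
of every dissimilarity matrix. On each reduced space an RBF kernel

\[ K^{(i)}_{jk} = \exp(-\gamma_i\,\lVert \bar d_j^{(i)} - \bar d_k^{(i)} \rVert^2) \]

is built, and the final kernel is the convex combination
\(K = \sum_i \beta_i K^{(i)}\) with \(\beta_i \in [0,1]\),
\(\sum_i \beta_i = 1\). Because each summand is a valid Mercer kernel on a
Euclidean embedding and non-negative combinations of PSD matrices stay PSD,
*K* is safe to use inside a nu-SVM solved with a precomputed-kernel
contract (kernlab backend, solver tolerance fixed at `1e-3` so repeated
fits are bit-identical).

A genetic algorithm evolves the genome `[nu, beta, gamma, w]`:

* `nu` in (0, 1] — the SVM regulariser;
* `beta` on the 8-simplex — kernel weights;
* `gamma` in (0, 100] — kernel shapes;
* `w` in {0,1}^N — the prototype mask (optional; the benchmark mode pins it
  to all-ones).

Fitness `f1` is the normalised Youden informedness
\(\bar J = (\text{sensitivity} + \text{specificity})/2\) of the validation
predictions (maximised). Fitness `f2` adds prototype parsimony:
\(f_2 = \omega (1-\bar J) + (1-\omega)\,|\{i: w_i = 1\}| / |w|\)
(minimised), with `omega = 0.5` by default so performance and sparsity
weigh equally.

### Search operators and numerical choices

* **Population/generations** default to 100 x 100 (scaled-down studies in
  this package use 20 x 15, which keeps a five-run experiment within a few
  minutes on one CPU while preserving the qualitative behaviour).
* **Selection** is roulette-wheel on the oriented fitness (`1 - f2` for the
  minimised fitness, so orientation is always higher-is-better); an
  all-zero fitness vector falls back to uniform sampling.
* **Crossover** is scattered: every gene is inherited from a uniformly
  random parent, after which `beta` is re-projected to the simplex (clip to
  [0,1], divide by the sum; an all-zero vector falls back to uniform).
* **Mutation** adds zero-mean Gaussian noise whose sigma decreases linearly
  from 10% of each gene's range to a 1% floor, then clips to the bounds.
  The kernel shapes are mutated on the log10 scale: useful `gamma` values
  span several decades (squared dissimilarity-space distances are large, so
  informative shapes sit around 1e-3..1e-1), and an additive kick of 10% of
  the (0, 100] range would annihilate any refined shape. Mask bits flip
  independently with probability `1/length(w)`, and a fully zero mask is
  repaired by setting one random bit.
* **Initialisation**: `nu` uniform; `gamma` log-uniform over its range;
  `beta` from a sparse symmetric Dirichlet (concentration 0.3), which
  favours interpretable near-one-hot mixtures over diffuse ones; mask bits
  Bernoulli(1/2).
* **Elitism** keeps the top 10% unchanged; the best-ever individual is
  retained. The budget is a fixed generation count (no early stopping).
* Evaluation failures (e.g., a `nu` infeasible for the class balance) give
  the worst fitness with the cause recorded, rather than aborting a run.

### Infeasible configurations

`nu`-SVMs are infeasible when `nu` exceeds twice the minority-class share;
kernlab then fails or returns no support vectors. Such genomes receive
fitness 0 (f1) or 1 (f2) so evolution remains total.

## Evaluation protocol

The 7-class problem (EC top-level classes 1-6 plus non-enzymes as class 7)
is decomposed one-vs-all; each classifier re-draws its own stratified
60/20/20 train/validation/test split (seeded from a master seed plus the
class id), mirroring the label-recoding protocol. The split fractions are a
package default: the three-way protocol needs a validation set for the GA
and an untouched test set, and 60/20/20 is the standard compromise at these
sample sizes. Metrics are accuracy, precision, recall, normalised
informedness, AUC (threshold sweep with trapezoidal area and rank-averaged
ties), and the selected-prototype percentage. Undefined metrics (absent
class, zero denominators) raise errors instead of silently returning 0.

## The one-class baseline

The benchmark classifier models the target class alone: k-medoids
clusterings (default `k = 120` at full scale; desk-scale studies use
`k` of order 10) under a weighted Euclidean dissimilarity, each cluster
equipped with a decision region bounded by `B = delta + sigma` (average
radius plus a tuned threshold) and a sigmoid membership
`mu(d) = 1/(1 + exp((d - b)/a))` with `a = delta`, `b = delta + sigma/2`,
so membership is exactly 0.5 at `b`. Points at distance exactly `B` count
as inside (the region is *bounded by* `B`). Singleton clusters (`a = 0`)
degenerate to a hard indicator. Several clustering instances with random
starting medoids vote by majority (default 5, odd to avoid ties); the soft
score is the mean membership of the closest cluster.

Design choices where the procedure was open:

* The weights of the dissimilarity are tied within each representation
  block (one weight per view instead of one per prototype column), keeping
  the search genome desk-scale while preserving the per-subspace semantics;
* thresholds are matched to clusters by ascending average radius inside
  each instance, so a threshold gene plays the same role across instances;
* the tuning objective mixes validation accuracy and threshold parsimony
  50/50; the threshold upper bound is the maximum pairwise distance among
  the targets;
* the clustering is the Lloyd-style medoid algorithm (nearest-medoid
  assignment, medoid update to convergence), written here because it is
  part of the benchmarked system's specification; `cluster::pam` serves as
  an independent cross-check in the test suite.

## Synthetic data: what it emulates and what it does not

Two generators make the whole system testable without downloads.

**Polymer-like chains.** A self-avoiding-biased random walk with a fixed
3.8 A step, an excluded-volume radius of 3.6 A (rejection sampling), and a
centroid-seeking bias (probability 0.7) that collapses chains into
globule-like shapes. The resulting contact networks have realistic density
and are connected for chains of 30+ residues in nearly all seeds. They do
*not* reproduce secondary-structure statistics; they exercise parsing,
network construction, filtering and the representation pipeline, nothing
more.

**Planted multi-view data.** Each pattern gets eight numeric views
(dimension 6). In the informative views (default: view 3 only) the class
means are separated by `effect_size` noise-sd units (default 5). Every view
is additionally multiplied by a per-pattern log-normal scale
(`scale_sd = 0.5`), a label-independent heterogeneity that emulates how
real graph-descriptor magnitudes vary across proteins; without it the
uninformative views collapse into near-constant kernels and the planted
problem degenerates into a trivially separable one at any weighting. The
default of 60 patterns per class gives the validation fitness enough
resolution to rank genomes at desk scale.

### What the planted experiments can and cannot show

With one strongly informative view, a single-view SVM on that view reaches
validation informedness near 1, and the evolved classifier generalises to
test informedness above 0.9. The *averaged* kernel-weight profile across
GA runs places its largest (or near-largest) weight on the planted view —
this is the knowledge-discovery readout the package reports.

The *per-run* argmax of `beta` is a weaker readout, and it is worth being
explicit about why. In a convex combination of per-view RBF kernels, an
uninformative view can always be *neutralised*: as its shape parameter
tends to 0 the kernel tends to the all-ones matrix, and as it grows the
kernel tends to the identity; both are harmless to the SVM (a constant
offset and a ridge term). Consequently the validation fitness has a plateau
of equally-performing genomes whose weight mass sits partly on neutralised
views, and the single best individual of a run can carry its argmax on any
of them once the plateau is reached. On real-scale data the fitness never
saturates and the plateau is thin; at desk scale it is wide. Passing or
failing a per-run argmax check on synthetic data therefore says little
about the weight analysis on real data; the averaged profile is the
meaningful quantity, and it is what the package's reports compute.

## Problem sizes used by the packaged studies

The test suite and the acceptance script run: five GA runs of 20
individuals x 15 generations on 120 planted patterns (72/24/24 split) for
each fitness; a benchmark comparison with the one-class classifier
(`k = 10`, 5 voting instances, 12 x 15 GA); and the structural/oracle
checks on graphs of 2-40 nodes. These sizes were chosen so a full study
remains a coffee-break computation on a single core while every qualitative
behaviour of the full-scale system (kernel validity, sparsity pressure,
benchmark ordering, weight profiles) is preserved.

## Known limitations

* Real PDB headers vary; the parser reads REMARK-2 resolutions and COMPND
  EC fields and ignores insertion codes beyond the first-occurrence policy.
* The Betti computation enumerates cliques; it is exact but not intended
  for graphs beyond a few thousand triangles.
* The dissimilarity measures default to Euclidean for all eight views;
  standardisation before distances is available (`scale = TRUE`) but off by
  default, since the kernel shapes already absorb per-view scaling.
* Representation vectors are only comparable across patterns for a fixed
  configuration; mixing configurations raises dimension errors by design.
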