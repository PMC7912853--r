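---
title: "Multi-omics network fusion by random walk with restart: models, parameters and design choices"
author: "rwrfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics network fusion by random walk with restart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwrfuse)
```

# The problem

Molecular subtyping asks whether a patient cohort splits into groups with
distinct biology, using several omics layers measured on the same samples
(typically mRNA expression, DNA methylation and miRNA expression).  Each
layer alone is noisy and partial; naive feature concatenation dilutes the
per-layer signal.  `rwrfuse` integrates the layers at the level of
*patient similarity networks*: one affinity matrix per omics layer, fused
into a single network that downstream spectral clustering consumes.

The fusion itself is a random walk with restart (RWR) on a multiplex
network whose layers are the per-omics similarity networks and whose
inter-layer edges connect replicas ("mirror nodes") of the same sample.
The stationary distribution of a walk seeded at one node measures the
proximity of every multiplex node to that seed, using the *global*
topology of every layer at once.  Two coupling variants are provided:

* **RWRF** — each sample is linked only to its own mirror in every other
  layer (identity coupling).
* **RWRNF** — each sample additionally sends directed, weighted edges to
  the mirrors of its `m` nearest neighbors *in its own layer*, so
  layer-specific neighborhood information survives the jump across
  layers.

# Model

## Similarity kernel

For samples $c_x, c_y$ with Euclidean distance $d(c_x,c_y)$ over one
layer's features,

$$S(c_x,c_y) = \exp\!\left(-\frac{d^2(c_x,c_y)}{\mu\,E(c_x,c_y)}\right),
\qquad
E(c_x,c_y) = \frac{\overline{d}(c_x,N_x) + \overline{d}(c_y,N_y) + d(c_x,c_y)}{3},$$

where $\overline{d}(c_x,N_x)$ is the mean distance from $c_x$ to its $N$
nearest neighbors (self excluded, ties broken by sample index).  Defaults
$N = 20$, $\mu = 0.5$.  The local scale $E$ adapts the bandwidth to the
point density; note that the kernel is *not* scale-invariant: since
$E$ is of the order of $d$, the exponent grows like $-2d/\mu$, so the
overall scale of the data sets the sharpness of the affinities.  This is
why the preprocessing chain standardizes every feature (mean 0, sd 1,
population convention by default) before the kernel — it fixes the scale
the kernel operates at.

Duplicate samples ($d = 0$, hence $E = 0$) get similarity 1 by the
limiting convention.  The diagonal is kept at its kernel value 1 and is
consumed by the walk as a self-loop.

## Multiplex walk

With $L$ layers of $n$ samples, the $(Ln)\times(Ln)$ transition matrix
has blocks

$$W_{jj}(i,k) = \lambda_j\,\frac{S_j(i,k)}{\sum_l S_j(i,l)}, \qquad
W_{jl}(i,k) = \lambda_l\,\frac{A_{jl}(i,k)}{\sum_m A_{jl}(i,m)} \ (j\ne l),$$

with layer weights $\lambda_1 = \dots = \lambda_L = 1/L$ by default, so a
walker stays in its layer with probability $1/L$ and jumps to each other
layer with probability $1/L$.  Under RWRF $A_{jl} = I_n$; under RWRNF row
$x$ of $A_{jl}$ carries weight $\beta$ on the mirror of $x$ and
$(1-\beta)/m$ on the mirrors of the $m$ most similar samples to $x$ in
layer $j$ (defaults $m = 10$, $\beta = 0.9$).  Every coupling row sums to
one.

The walk iterates

$$\vec p_{t+1} = (1-\gamma)\,W^{\mathsf T}\vec p_t + \gamma\,\vec p_0$$

until the L1 difference of successive iterates falls below $10^{-10}$
(restart probability $\gamma = 0.7$ by default).  The restart vector
$\vec p_0$ for a seed $(j, x)$ puts mass $\alpha_l = 1/L$ on $x$'s
replica in every layer under RWRF; under RWRNF it puts $\alpha = 0.9$ on
the seed itself and spreads $(1-\alpha)/(L-1)$ over row $x$ of each
coupling block.  Because $W$ is row-stochastic, every iterate remains a
probability vector; with $\gamma = 0.7$ the iteration contracts at rate
$0.3$ and converges in 16–18 iterations at the default tolerance, which
the per-seed iteration counts in `fuse_networks()` make visible.

## Fusion

Seeding the walk at each of the $Ln$ nodes gives $Ln$ stationary
distributions.  The one seeded at $(j, x)$ fills row $x$ of the layer-$j$
proximity matrix $S'_j$ (and of the diagnostic cross blocks $A'_{jl}$).
The integrated network is the symmetrized average

$$S_{\mathrm{fusion}} = \frac{1}{2L}\sum_{j=1}^{L}\left(S'_j + S'^{\mathsf T}_j\right),$$

which for $L = 2$ is $(S'_1 + S'_2 + S'^{\mathsf T}_1 + S'^{\mathsf T}_2)/4$.
The cross blocks are retained for inspection but do not enter
$S_{\mathrm{fusion}}$.  The $Ln$ seeds are independent linear systems, so
the implementation iterates them as one matrix with converged columns
frozen; this is exactly equivalent to looping over seeds (up to last-ulp
BLAS rounding) and an order of magnitude faster.  An exact linear-solve
oracle (`rwr_direct()`) backs the iterative solver in the test suite.

# Downstream analysis

## Spectral clustering

`spectral_clustering()` is the standard normalized variant: form
$D^{-1/2} S D^{-1/2}$, take the top-$k$ eigenvectors, normalize rows,
k-means with 20 restarts under a fixed seed.  One deliberate choice
deserves emphasis: **the affinity diagonal is zeroed before the Laplacian
is formed** (the usual convention for spectral clustering, where the
affinity matrix has $A_{ii} = 0$).  The kernel's unit diagonal is the
right object for the walk's self-loop, but it is poison for the
spectrum: for high-dimensional standardized layers, typical distances are
$\approx\sqrt{2p}$ for $p$ features and the off-diagonal affinities are
of order $e^{-2\sqrt{2p}/\mu}$ — far below machine precision relative to
a unit diagonal once $p$ is a few hundred.  With the diagonal in place
the matrix is numerically the identity and clustering returns noise;
with it removed the (correctly ranked) off-diagonal structure is
recovered exactly, because degree normalization makes the absolute scale
irrelevant.  A flag restores the diagonal for sensitivity analysis.

## Choosing the number of clusters

`validity_index_table()` scans a candidate range (default `2:8`) and
scores each partition with seven statistics: Ratkowsky–Lance, Tau,
Silhouette, C-index, SD-scat, SD-Dis and Calinski–Harabasz, each with its
standard definition and direction (maximize RL, Tau, Silhouette, CH;
minimize C-index, SD-scat, SD-Dis).  Each index votes for its optimal
$k$; the two most voted values are recommended, ties resolved toward the
smaller $k$.

Distance-based indexes need a dissimilarity: the default is
$d = 1 - S/\max_{x \ne y} S$, configurable to Euclidean distances in the
spectral embedding.  Coordinate-based indexes (Ratkowsky–Lance, SD-scat,
SD-Dis) use a fixed spectral embedding with $\max(k)$ dimensions so their
scores are comparable across candidates.  The Tau statistic is computed
as a Kendall-type concordance between the distance vector and the
within/between indicator with an $O(N\log N)$ sorted-count
implementation; its tie-correction denominator treats distance ties as
negligible, which they are for continuous affinities.

## Evaluation

* **Dunn index** — smallest between-cluster nearest-pair distance over
  largest within-cluster diameter, on the same $1 - S/\max S$
  dissimilarity (configurable); checked against an exhaustive
  double-loop oracle in the tests.
* **NMI** — mutual information of the label contingency normalized by
  the arithmetic mean of the label entropies (geometric-mean variant via
  a flag).  The variant affects only the third decimal for near-balanced
  partitions, but is stated because published NMI values rarely name
  theirs.
* **Log-rank test** — standard multi-group chi-square with tie-corrected
  variance via `survival::survdiff`, significance threshold 0.05.
* **Feature ranking** — every feature, alone, is pushed through the same
  kernel-plus-spectral-clustering path and scored by NMI against the
  integrated subtypes; top-$n$ or top-fraction selectors cut marker
  panels.  Constant features are dropped (or scored 0 via a flag).

# The synthetic benchmarks

Real multi-omics cohorts are large, access-controlled and slow to
process, so the package ships generators that emulate the two regimes a
fusion method must handle.  Both are first-class, tested code.

## Two-cluster noise benchmark

`two_cluster_data()` draws 200 two-dimensional samples (100 per class)
with class centers `separation` apart along the all-ones diagonal and
uniform within-class offsets of half-width `spread`; for
`spread * sqrt(dim) < separation/2` the noise-free classes are linearly
separable by construction.  `add_noise()` then corrupts the base with
element-wise Gaussian noise (mean 0, sd 1.5) for one view and Gamma noise
(shape 3, rate 1) for the other.  The Gamma noise is added un-centred;
its mean 3 shifts every entry equally and is immaterial to pairwise
distances, but its heavier tail (sd $\sqrt3$) and right skew make the
Gamma view genuinely harder than the Gaussian one.

The defaults `separation = 4.2`, `spread = 0.7` are calibration
constants.  The intended regime — single noisy views that cluster
imperfectly but well above chance, with fusion recovering most of the
lost structure — pins the geometry only up to a family of equivalent
choices, so the defaults were fixed by a seed-averaged sweep to the
regime NMI values of roughly 0.59 (Gaussian view), 0.54 (Gamma view) and
0.78 (fused, either variant), as recomputed by `scripts/acceptance.R`.
Two geometry findings from that sweep are worth recording: the class axis
is deliberately parallel to the all-ones direction (with an axis-aligned
split, the Gamma skew accumulates orthogonally to the class axis and
produces outlier-versus-rest spectral cuts), and the views are
standardized before the kernel, as in the real pipeline — unstandardized,
the Gamma view's outliers sit far outside the kernel's operating scale
and occasionally hijack the 2-way spectral cut.

## Multi-view cluster benchmark

`multiview_cluster_data()` is a stand-in for simulators of interrelated
omics layers (such as InterSIM, which embeds covariance estimated from
TCGA ovarian-cancer data): 5 clusters shared by 100 samples across three
views of 367, 131 and 160 features, emulating methylation, expression and
protein layers.  Each view's per-cluster feature means are drawn
N(0, signal$^2$) and samples add standard-normal noise, so the per-view
`signal` staggers how recoverable the common structure is.  What it does
*not* model is InterSIM's cross-view correlation structure — views here
are conditionally independent given the clusters — so absolute fused
NMI values from the original simulator are not comparable; the benchmark
property is relative: fused NMI must exceed every single view's.

The default `signal = c(0.29, 0.40, 0.36)` was calibrated (seed-averaged,
fixed base seed chosen a priori) so that each view is individually
informative but imperfect (single-view NMIs about 0.61/0.67/0.65).  On
conditionally independent views, RWRF — identity coupling plus equal seed
weights — behaves close to plain similarity averaging and its gain over
the best view is modest (about 0.70 fused); RWRNF's neighbor coupling and
seed concentration ($\alpha = 0.9$) instead let every seed's stationary
profile localize on its own cluster and reach near-perfect recovery on
this generator.  With one dominant and two weak views, RWRF can even fall
below the best single view — a real property of averaging-style fusion,
not a defect of the implementation.

# Worked example

```{r example, eval = FALSE}
st <- two_cluster_study(seed = 1)                 # two noisy views
views <- lapply(st$views, normalize_features)
sims <- lapply(views, similarity_from_features)   # N = 20, mu = 0.5

mx <- assemble_multiplex(sims, variant = "RWRNF") # m = 10, beta = 0.9
fz <- fuse_networks(mx)                           # gamma = 0.7
cl <- spectral_clustering(fz$s_fusion, k = 2)

nmi(cl$labels, st$truth)
median(fz$iterations)
```

# Numerical choices and limitations

* Convergence is declared on the **L1** difference of successive
  iterates (threshold $10^{-10}$, cap 1000 iterations; non-convergence is
  an error carrying the residual).
* Ties in neighbor selection (kernel and RWRNF coupling) break by sample
  index, making every construction deterministic; k-means uses 20
  restarts under a caller-fixed seed, so clustering is reproducible
  bit-for-bit for identical input.  Permuting samples permutes the
  partition itself, though at a non-natural $k$ the seeded k-means may
  legitimately settle in a different local optimum.
* The missingness filter drops samples then features with strictly more
  than 20% missing entries; one pass is a fixed point on typical data but
  re-application can in principle remove more (fractions are recomputed
  on the reduced matrix).
* Preprocessing order: sample intersection first, per-layer filtering
  second (re-aligned afterwards), imputation, standardization.
* Test-suite problem sizes (cohorts of 40–200 samples, up to three
  layers, 50 seeded replicates for the noise benchmark) were chosen so
  the full suite completes in well under a minute while keeping
  seed-averaged estimates stable to about ±0.01 NMI.
* What passing the synthetic benchmarks does **not** show: robustness to
  batch effects, to informative missingness, to layers measured on
  disjoint sample subsets, or to the cross-view correlation of real
  multi-omics data.  Survival evaluation assumes right-censoring
  uninformative of subtype.
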