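# rwrfuse

Multi-omics data integration by random walk with restart on multiplex
patient-similarity networks, with downstream subtyping and evaluation.

## The problem

Given two or more omics layers (e.g. mRNA expression, DNA methylation,
miRNA expression) measured on the same samples, molecular subtyping wants
one partition of the cohort that uses all layers.  `rwrfuse` integrates at
the network level: each layer becomes a sample-affinity matrix via the
locally scaled exponential kernel

    S(x, y) = exp( -dist²(x, y) / (μ · E(x, y)) ),
    E(x, y) = [ mean dist(x, N_x) + mean dist(y, N_y) + dist(x, y) ] / 3

(N = 20 nearest neighbors, μ = 0.5 by default).  The L layers are stacked
into a multiplex network whose inter-layer edges connect replicas of the
same sample — identity coupling (**RWRF**) or directed edges weighted β to
the own mirror and (1−β)/m to the mirrors of the m nearest within-layer
neighbors (**RWRNF**; m = 10, β = 0.9).  A restart random walk

    p_{t+1} = (1 − γ) Wᵀ p_t + γ p_0        (γ = 0.7, tol 1e-10)

is run from every one of the L·n nodes; the stationary distribution seeded
at (layer j, sample x) fills row x of a per-layer proximity matrix S′_j,
and the integrated network is the symmetrized average

    S_fusion = Σ_j (S′_j + S′_jᵀ) / (2L).

`S_fusion` feeds normalized spectral clustering; the number of clusters can
be recommended by a seven-index validity vote (Ratkowsky–Lance, Tau,
Silhouette, C-index, SD-scat, SD-Dis, Calinski–Harabasz).  Evaluation
utilities include the Dunn index, normalized mutual information (NMI), the
log-rank test on survival, and NMI-based per-feature ranking for marker
selection.

## Worked example

The built-in noise benchmark: 200 samples in two linearly separable
classes, one view corrupted by Gaussian noise (sd 1.5), the other by Gamma
noise (shape 3, rate 1).

```r
library(rwrfuse)

st <- two_cluster_study(seed = 1)                 # two noisy views + truth
views <- lapply(st$views, normalize_features)     # feature-wise mean 0, sd 1
sims  <- lapply(views, similarity_from_features)  # N = 20, mu = 0.5

nmi(spectral_clustering(sims$gaussian, 2)$labels, st$truth)
#> [1] 0.581
nmi(spectral_clustering(sims$gamma, 2)$labels, st$truth)
#> [1] 0.554

mx <- assemble_multiplex(sims, variant = "RWRNF") # m = 10, beta = 0.9
fz <- fuse_networks(mx)                           # gamma = 0.7
fz
#> Fused similarity network (RWRNF): 200 samples
#>   RWR iterations per seed: median 17, max 17

cl <- spectral_clustering(fz$s_fusion, k = 2)
nmi(cl$labels, st$truth)
#> [1] 0.806
dunn_index(cl$labels, similarity_to_distance(fz$s_fusion))
#> [1] 0.529
```

Each noisy view alone recovers the true two-class structure only partially
(NMI ≈ 0.58 and 0.55); fusing the two views lifts agreement with the truth
to NMI ≈ 0.81, with the walk converging in 17 iterations per seed.

For a full run — preprocessing, fusion, validity-index scan, metrics and a
machine-readable manifest written to disk — use `run_pipeline()`, or the
command-line wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/rwrfuse.R", package = "rwrfuse"))')" \
    run --inputs mrna.tsv,methylation.tsv,mirna.tsv --out results/
```

Input files are TSV/CSV feature-by-sample matrices with a header row of
sample ids and an id column of feature ids; an optional survival table
(`sample_id`, `time`, `event`) adds the log-rank evaluation.

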