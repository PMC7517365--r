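# mkmd

Classification of protein contact networks (and structured patterns in
general) by **multiple kernel learning over multiple dissimilarity
representations**, with a genetic algorithm jointly tuning the classifier
and selecting prototype patterns.

## Who this is for

Structural bioinformaticians who want to predict a protein-level property
(here: the EC top-level functional class, with non-enzymes as a seventh
class) from folded structure alone, and machine-learning practitioners who
work with structured data that admits several numeric descriptions of the
same pattern.

## The method in brief

A protein is reduced to its **contact network**: residues are nodes, and an
edge joins two residues whose alpha-carbon distance lies in the closed band
[4, 8] Å. Eight fixed-length descriptors are computed per network — Betti
numbers of the clique complex, centrality profile, graph energies,
cartography role fractions, heat-content invariants, heat-kernel trace,
size, and the sampled spectral density of the normalized Laplacian.

Each descriptor *i* is embedded in a dissimilarity space (vectors of
distances to the training patterns, reduced to a prototype subset by a
binary mask *w*) and kernelised:

    K = Σᵢ βᵢ · exp(−γᵢ · ‖ d̄ⱼ⁽ⁱ⁾ − d̄ₖ⁽ⁱ⁾ ‖²),    βᵢ ∈ [0,1], Σᵢ βᵢ = 1, γᵢ ∈ (0,100]

which is a valid Mercer kernel and feeds a ν-SVM with a precomputed-kernel
contract. A genetic algorithm evolves the genome **[ν, β, γ, w]** against
the normalised Youden informedness J̄ = (sensitivity + specificity)/2 on a
validation split (fitness `f1`), or against a performance/sparsity
trade-off `f2 = ω(1−J̄) + (1−ω)·|w|₁/|w|` when sparse prototype sets are
wanted. Reading the tuned β afterwards reveals which representations
matter; reading *w* reveals which training patterns were pivotal. A
clustering-based one-class classifier (k-medoids decision regions with
sigmoid memberships and GA-tuned weights/thresholds) serves as the
benchmark, evaluated through the identical metric pipeline.

## Worked example

The package ships a synthetic-data module, so the full system runs without
any downloads. Below, a planted multi-view dataset in which only
representation 3 carries class signal (class means 5σ apart) is analysed by
five scaled-down GA runs (20 individuals × 15 generations):

```r
library(mkmd)

ds  <- planted_multiview_dataset(synth_spec(seed = 1))
res <- mkmd_run(ds$representations, ds$y,
                config  = ga_config(population = 20, generations = 15, seed = 1),
                fitness = "f1", seeds = 11:15)

round(res$summary, 3)
#>          accuracy         precision            recall informedness_norm
#>             0.967             1.000             0.933             0.967
#>               auc          sparsity
#>             0.997            51.389

round(res$knowledge$beta_profile, 3)
#> [1] 0.098 0.158 0.241 0.004 0.288 0.068 0.110 0.032
```

The mean test informedness (0.967) and AUC (0.997) show the classifier
solves the planted task; the averaged kernel-weight profile puts weight
0.241 on the planted view 3 — roughly double the uniform share of 0.125 —
while spec-free views such as 4 and 8 are driven to nearly zero. (Several
views can tie near the top at this scale: an uninformative view can always
be neutralised by its shape parameter, so weight profiles are read as
relative importances, not as a hard selection; see the methods vignette.)
Under `f2` the selected-prototype percentage drops from ~51% to ~31% at
unchanged test performance.

Real structures enter through `parse_ca_coordinates()` /
`filter_dataset()` / `build_pcn()` / `extract_all()`; a thin command-line
wrapper (`inst/cli/mkmd`) exposes `synth`, `build-pcn` and `featurize`
subcommands for shell pipelines.

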