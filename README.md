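# trustomics

Trusted multi-omics patient classification with hypergraph convolution
and evidential fusion.

## The problem

Clinical multi-omics studies measure the same patients on several
molecular layers — typically mRNA expression, miRNA expression and DNA
methylation — and ask for a subtype or disease-status call per patient.
Two things make this hard. First, pairwise graphs under-represent the
neighbourhood structure of omics cohorts: a patient resembles a *group*
of patients, not a list of independent pairs. Second, the omics layers
are heterogeneous and of uneven quality, so naive late fusion lets a
noisy layer drag the prediction down, and gives the clinician no signal
that a particular call is unreliable.

`trustomics` addresses both. Each omics block is represented as a
k-nearest-neighbour **hypergraph**: one hyperedge per patient containing
that patient and its k−1 most cosine-similar peers. A small hypergraph
convolutional network per block extracts non-negative per-class
**evidence**, and blocks are fused at the evidence level under
Dempster–Shafer theory, so every prediction carries a per-patient
**uncertainty** that automatically discounts unreliable layers.

## The model

For a block with feature matrix `X` (n samples × d features), cosine
similarity `s(x_i, x_j) = x_i · x_j / (‖x_i‖ ‖x_j‖)` defines, for each
sample, a hyperedge containing the sample and its k−1 nearest
neighbours. With incidence matrix `G` (n × n), vertex degrees
`Dv = diag(G 1)` and hyperedge degrees `De = diag(1ᵀG)`, the normalised
hypergraph Laplacian

    Lh = Dv^{-1/2} G De^{-1} Gᵀ Dv^{-1/2}

is the smoothing operator of each convolution layer
`H^{(l+1)} = LeakyReLU(Lh H^{(l)} Z^{(l)})`, followed by a fully
connected layer and a softplus head that yields evidence `F ≥ 0`
(n × b, b classes).

Evidence parameterises a Dirichlet opinion: `α = F + 1`,
`S_i = Σ_j α_ij`, class confidence `p_ij = f_ij / S_i` and uncertainty
`u_i = b / S_i`, so that `Σ_j p_ij + u_i = 1`. Opinions of two blocks
are combined per sample with the reduced Dempster–Shafer rule

    C    = Σ_{i≠j} p¹_i p²_j              (conflict)
    p_k  = (p¹_k u² + p²_k u¹ + p¹_k p²_k) / (1 − C)
    u    = u¹ u² / (1 − C)

folded sequentially over all blocks; fused Dirichlet parameters are
recovered via `f_ij = b p_ij / u_i`, `α_ij = f_ij + 1`. Training
minimises, on the labelled samples, the Dirichlet-expected
cross-entropy `Σ_j y_ij (ψ(S_i) − ψ(α_ij))` plus an annealed
KL penalty on evidence placed on wrong classes, for the fused opinion
and for every block (one term each).

## Worked example

Simulate a cohort where the class signal is *complementary*: each omics
block can only separate one of the three subtypes from the rest, so no
single block suffices and fusion is required.

```r
library(trustomics)
spec <- synthetic_spec(information_split = "complementary", seed = 42)
ds <- simulate_multiomics(spec)
ds
#> multiomics_dataset: 300 samples, 3 classes, 3 omics block(s)
#>   omics1       100 features
#>   omics2       80 features
#>   omics3       60 features
#>   class sizes: 100/100/100

cfg <- run_config(seed = 42)
fold <- stratified_folds(ds$labels, n_folds = 5, seed = 42)
model <- train_model(ds, train_idx = which(fold != 1), cfg)
model
#> trusted_model: 3 omics network(s), 3 classes, trusted fusion, hypergraph structure
#>   trained 500 epochs, final loss 1.5543, 240 training samples

pred <- predict(model, ds, idx = which(fold == 1))
head(pred, 4)
#>   sample_id true pred     p_0      p_1      p_2      u
#> 1     S0002    1    1 0.01010 9.80e-01 6.09e-05 0.0101
#> 2     S0005    1    1 0.00769 9.44e-01 1.94e-02 0.0286
#> 3     S0021    2    2 0.01305 2.20e-04 9.53e-01 0.0337
#> 4     S0025    0    0 0.91351 3.69e-06 7.53e-02 0.0112

round(compute_metrics(pred$true, pred$pred), 3)
#>         ACC F1_weighted    F1_macro
#>       0.983       0.983       0.983
```

Each held-out patient gets fused per-class confidences `p_0..p_2` and an
uncertainty `u` (`Σ p + u = 1`); a single block alone reaches only about
0.67 accuracy on this design, while the fused model reaches 0.983.
Higher-level drivers: `cross_validate()` (stratified 5-fold protocol
with mean ± SD reporting), `noise_experiment()` (accuracy and
uncertainty vs corruption of one block), `ablation_run()`
(hypergraph vs graph, trusted vs mean-evidence fusion, cosine vs
Euclidean, k sweep, omics subsets) and `feature_importance()`
(permutation-based marker ranking). A command-line wrapper with the
same verbs lives at `inst/cli/trustomics.R`.

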