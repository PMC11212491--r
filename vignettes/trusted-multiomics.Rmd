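---
title: "Trusted multi-omics classification: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trusted multi-omics classification: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`trustomics` classifies patient samples from several omics blocks by
late, evidence-level integration: per-block hypergraph convolutional
networks produce Dirichlet evidence, and blocks are fused with the
reduced Dempster–Shafer combination rule. This vignette is the
package's own account of the method: the model and its assumptions, the
tunable parameters and their defaults, what the simulator does and does
not emulate, and the numerical decisions taken where the design was
genuinely open.

## 1. The model

### Hypergraph representation of one omics block

Every sample is a vertex. For each vertex we form one hyperedge
containing the vertex itself and its $k-1$ nearest neighbours under
cosine similarity (Euclidean distance is available as an ablation
comparator; cosine is the default because omics profiles are better
compared by direction than by absolute magnitude). The incidence matrix
$G \in \{0,1\}^{n \times n}$ therefore has exactly $k$ ones per column,
vertex degrees $\delta(v)$ are its row sums and hyperedge degrees
$\zeta(e) = k$ its column sums. The convolution operand is the
normalised hypergraph Laplacian

$$L_h = D_v^{-1/2}\, G\, D_e^{-1}\, G^{\mathsf T} D_v^{-1/2},$$

a symmetric positive semidefinite smoothing operator with spectrum in
$[0,1]$ (it is a normalised Gram form). All hyperedges carry weight
one: no weight matrix is used, and none is learned. For the
graph-structure ablation the analogous operand is the symmetrically
normalised, mutualised KNN adjacency $D^{-1/2} A D^{-1/2}$ (self-loops
included); in both cases the operator that multiplies the features is
the smoother itself, not $I$ minus it, because the layer computes a
neighbourhood average of the features.

### Evidence networks

Per block, the network stacks hypergraph convolutions
$H^{(l+1)} = \mathrm{LeakyReLU}(L_h H^{(l)} Z^{(l)})$ (input
$H^{(0)} = X$), one affine fully connected layer to $b$ outputs, and a
softplus head. The head is what turns the network into an evidence
model: Dirichlet parameters $\alpha = F + 1$ require $F \ge 0$, and
softplus enforces this smoothly (ReLU and exp heads are selectable;
ReLU has dead gradients at 0, exp is prone to overflow, so softplus is
the default).

### Evidential fusion

Evidence $F$ maps to an opinion with confidences $p_{ij} = f_{ij}/S_i$
and uncertainty $u_i = b/S_i$, $S_i = \sum_j \alpha_{ij}$, so
$\sum_j p_{ij} + u_i = 1$ holds exactly; this identity is asserted by
the opinion constructor everywhere in the package. Opinions are folded
sequentially with the reduced Dempster–Shafer rule; the conflict mass
$C$ renormalises away belief that two blocks place on different
classes. The fused Dirichlet parameter is recovered by inverting the
evidence map, $f = b\,p/u$. The inversion uses the **number of
classes** $b$: only with $b$ does
evidence → opinion → recovery return the original evidence exactly,
which the test suite verifies to $10^{-8}$; using the sample count
instead breaks this identity.

Two properties of the rule matter in practice and are tested: the
vacuous opinion ($p = 0$, $u = 1$) is a neutral element, so a block
that has learned nothing cannot change the fused result; and combining
agreeing opinions decreases uncertainty, which is what lets a clean
block dominate a noisy one.

### Losses

Training minimises, over labelled samples, for the fused opinion and
for every block:

* the Dirichlet-expected cross-entropy
  $\sum_j y_{ij}(\psi(S_i) - \psi(\alpha_{ij}))$ — the closed form of
  $\mathbb E_{\mathrm{Dir}(\alpha)}[-\log p_y]$ — which rewards
  evidence on the true class;
* a penalty $\mathrm{KL}(\mathrm{Dir}(\tilde\alpha)\,\|\,\mathrm{Dir}(\mathbf 1))$
  with $\tilde\alpha = y + (1-y)\odot\alpha$, zero exactly when no
  evidence sits on wrong classes.

The penalty weight ramps linearly, $\lambda = \min(1,
\text{epoch}/\text{annealing\_step})$, so the network is not punished
for its random initial evidence. A ramp clamped to $(0,1]$ is the only
reading consistent with a weight that is meant to stay in $(0,1)$ and
to act as a warm-up; an unclamped $\min(\text{epoch},
\text{annealing\_step})$ would grow without meaning past 1 after the
first epochs.

The per-omics loss terms keep each block individually calibrated; the
fused term trains the combination. Both use means over the training
samples rather than sums, so the loss scale — and hence the learning
rate — does not depend on cohort size.

## 2. Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `k_neighbors` | 10 | hyperedge size; large enough to average noise, small enough to stay within a class at desk-scale cohort sizes. `ablation_run(axis = "k_sweep")` measures sensitivity. |
| `hidden_dims` | 64, 32 | two convolution layers; two rounds of smoothing reach the 2-hop hyperedge neighbourhood, more invites over-smoothing. |
| `learning_rate` | 1e-3 | standard Adam step for full-batch training of small networks. |
| `epochs` | 500 | full-batch epochs; loss curves on the reference simulations flatten well before this. |
| `annealing_step` | 50 | penalty warm-up length, 10% of the default budget. |
| `leaky_slope` | 0.01 | conventional LeakyReLU slope. |
| `weight_decay` | 1e-4 | L2 on all weights, applied to the gradients (decoupled, AdamW-style), i.e. not part of the reported loss value. |
| `test_fraction` | 0.2 | matches the 5-fold protocol's 80/20 split. |

All randomness flows from one integer seed through `derive_seed()`,
which hands decoupled streams to fold assignment, weight
initialisation, simulation and permutations; identical config + seed
reproduces splits and fitted weights bit-for-bit.

## 3. Training protocol and evaluation

The structure is built once over **all** samples (training and held
out) and the loss is evaluated on the training indices only — the
transductive node-classification setting. This is a deliberate choice:
the alternative (build on training samples, extend test samples
afterwards) requires an out-of-sample extension rule that the
hypergraph construction does not naturally provide. The consequence to
keep in mind is that test *features* (never labels) influence the
learned representation, which is standard in this setting but differs
from a strictly inductive classifier.

Evaluation uses stratified k-fold cross-validation (default 5, i.e.
80/20), a fresh model per fold, and mean ± SD reporting. Binary tasks
report ACC, F1 of the positive class and AUC (computed from the fused
confidence of class 1, not renormalised by $1-u$ — the confidence *is*
the framework's score output); multiclass tasks report ACC, weighted F1
and macro F1. Fold assignment continues one round-robin cycle across
classes so total fold sizes differ by at most one while remaining
stratified. Any preprocessing (variance filter → ANOVA-F selection →
min–max scaling) is fitted per fold on training rows only; the test
suite asserts that an extreme value planted in a test row cannot move
the fitted parameters.

## 4. The simulator, and what passing tests do not show

`simulate_multiomics()` draws class-conditional Gaussians: within each
block a chosen fraction of columns is informative and receives a
class-dependent mean shift of `effect_size × noise_sd`; everything else
is noise. Reference conditions: 300 samples, 3 balanced classes, blocks
of 100/80/60 features, 10% informative columns, effect size 5. Three
signal layouts: `redundant` (every block carries every contrast),
`complementary` (block $o$ separates only class $o-1$ from the rest, so
any single block is ambiguous between the remaining classes — the
design that isolates the value of fusion), and `one_noisy` (one block
is pure noise — the design that isolates the value of uncertainty
discounting). The manifest of planted features is returned with the
data, giving ground truth for the feature-importance test.

This generator provides analytic control of separability, which is
exactly what the end-to-end tests need, and exactly what real omics
data are not: no heavy-tailed or bounded marginals (methylation beta
values), no count overdispersion, no correlated feature modules, no
batch effects, no class imbalance. Passing the acceptance suite
therefore demonstrates that the machinery is correct and that fusion
and uncertainty behave as the theory predicts under controlled signal;
it does not certify performance on any real cohort.

## 5. Numerical choices and degenerate inputs

* **Zero-norm feature rows** get cosine similarity 0 to all others and
  1 to themselves, so KNN selection never sees NaN.
* **KNN ties** break by ascending sample index; selection ties in the
  ANOVA-F ranking break by ascending column index; prediction ties
  break to the lowest class index. All three make runs reproducible
  and order-independent.
* **Total conflict** in the combination rule ($1 - C \le 10^{-12}$)
  raises an error naming the sample instead of renormalising: a silent
  division blow-up would corrupt training invisibly.
* **Softplus overflow** is avoided by the linear asymptote for inputs
  above 30; the exp head is capped at $e^{30}$.
* **Constant columns** min–max scale to 0, and are removed by the
  variance filter at the default threshold 0.
* **Sample alignment** across input files is the sorted intersection
  of IDs, so the result cannot depend on file order; dropped IDs are
  reported. Missing values are rejected by default (column-mean
  imputation is opt-in).
* **Initialisation** is Glorot-uniform with zero biases, seeded per
  block.
* The gradient of the full loss — including backpropagation through
  the sequential Dempster–Shafer fold — is hand-derived and verified
  against central finite differences to $10^{-4}$ relative error in
  the test suite.

## 6. Problem sizes used by the test and acceptance runs

Unit tests run on cohorts of 12–48 samples with short training budgets
(structural checks) or 250 epochs (accuracy checks). The end-to-end
acceptance checks use the reference conditions above (300 samples,
full 500-epoch default) with 5-fold cross-validation and five
independent seeds for the fusion, noise and discounting claims; the
noise sweep uses $\sigma \in \{0, 0.5, 1, 2, 5\}$ on one block with one
repeat per seed. These sizes were chosen as the smallest at which the
claims under test are comfortably identifiable.

## 7. Known limitations

* The hypergraph is static: built once before training, never adapted.
* Full-batch dense linear algebra bounds practical cohort size to a
  few thousand samples; there is no minibatching and no sparse path.
* The combination rule is the reduced Dempster–Shafer form only — no
  discounting or averaging operators from the wider subjective-logic
  toolbox.
* The mean-evidence baseline fusion reports no uncertainty (`NA`), by
  construction.
* Permutation feature importance measures *marginal* contribution
  through the fitted model; redundant markers (several features
  carrying the same contrast) can each receive near-zero importance
  even though the group is essential — the binary single-marker test
  fixture exists precisely because of this.
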