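---
title: "Group-common and individual-specific structure-function coupling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-common and individual-specific structure-function coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sfcoupling)
```

## The question

Cortical functional connectivity (FC) — the temporal correlation structure of
regional activity — is shaped by the white-matter structural connectome (SC),
but not edge by edge: much of FC reflects polysynaptic communication over the
network's topology. Structure–function *coupling* quantifies how well a
structural description predicts a subject's FC. Two questions drive this
package:

1. How much of an individual's coupling is a **group-common** property of the
   species-typical connectome, and how much is **individual-specific**?
2. Are the regional group and individual components organized along the
   **sensorimotor–association (S–A) cortical axis**, the dominant axis of
   cortical hierarchy?

`sfcoupling` implements the full analysis chain at desk scale — connectome
preparation, a graph-neural-network (GNN) predictor of FC from SC, the
cross-participant coupling decomposition, topology-randomizing and
spatial-rotation null models, and axis alignment — together with a synthetic
cohort generator with *known* group and individual structure, so that every
stage is testable without access to restricted neuroimaging data.

## Connectome preparation

- **FC construction** (`compute_fc()`): Pearson correlation between every
  pair of regional time series, Fisher z-transformed (`atanh`). `|r|` is
  clipped at `1 - 1e-7` so collinear signals stay finite under `atanh`.
- **SC normalization** (`normalize_and_log_sc()`): streamline counts divided
  by the average volume of the two endpoint regions, then log-transformed.
  The default is `log(1 + w)`, which keeps absent edges at zero and weights
  nonnegative (volume normalization can push weights below 1); a literal
  `log(w)`-on-nonzero mode is available (`log_mode = "log_nonzero"`).
- **Consistency thresholding** (`consistency_mask()`): for every edge present
  in at least one subject, the coefficient of variation of its weight across
  subjects (zeros included as observations, penalizing inconsistent
  presence); edges above the 75th CV percentile are removed. Quantiles use
  linear interpolation (R type 7); the convention is exposed as an argument
  because reasonable alternatives exist and the choice moves the threshold. The mask is computed on training subjects
  only and applied to everyone, preventing test-set leakage; whole-cohort
  computation is available via `mask_scope = "all"`. Removal uses a strict
  inequality against the percentile threshold, so on continuous CV
  distributions just under 25% of evaluated edges are removed; when many
  edges tie exactly at the threshold — e.g. every edge present in exactly
  one of n subjects has CV `sqrt(n)` — the tie block is kept and the
  realized fraction can be noticeably lower.
- **Motion QC** (`qc_filter_runs()`), in a fixed order: (1) drop runs with
  more than 25% of frames above 0.2 mm framewise displacement; (2) pool the
  mean FD of surviving runs across subjects and drop runs above
  Q3 + 1.5 x IQR of that distribution; (3) exclude subjects with fewer than
  four surviving runs.

## The GNN predictor

The predictor is a two-layer graph convolutional encoder with one-hot node
inputs followed by a two-layer perceptron edge decoder:

- Encoder: `H^{l+1} = PReLU(D^{-1/2} (A + I) D^{-1/2} H^l W^l)` with
  `H^0 = I_K`, one trainable PReLU slope per layer (initialized at 0.25).
  Two layers give every node an embedding of its 2-hop neighbourhood.
- Decoder: `pFC_ij = W_2 ReLU(W_1 [h_i, h_j] + b_1) + b_2`; predictions are
  symmetrized as `(pFC_ij + pFC_ji)/2` with zero diagonal.
- Loss: mean squared error over ordered off-diagonal pairs, averaged over a
  batch of 2 subjects, plus an L2 penalty (1e-4) on the decoder weight
  matrices only. Training uses Adam (0.9/0.999, eps 1e-8) with fan-scaled
  uniform initialization, fully deterministic given the seed.

The forward and backward passes are implemented directly (an R reference
implementation plus an identical compiled kernel; the two are asserted equal
to machine precision in the test suite, and both are checked against finite
differences).

**Desk-scale hyperparameters.** The reference-scale configuration
(400x256x256 GCN, 512x64x1 MLP, learning rate 0.001, 400 epochs) was tuned
for cohorts of several hundred subjects, i.e. tens of thousands of Adam
steps. At desk scale (tens of subjects, `K = 60`), 200 epochs are only about
4,000 steps, and at the reference learning rate the model cannot even fit
data generated by its own forward family. The desk-scale defaults in
`gnn_config()` — `K x 64 x 64` encoder, `2C x 64 x 1` decoder, learning rate
0.01, 200 epochs — are the smallest configuration whose final training loss
falls below 10% of the target variance on a noise-free one-hop cohort
(`beta = c(1)`, no group/individual/noise components) at `K = 20`; that
fit-family check is part of the test suite. At `K = 60` the concatenation
decoder cannot reach that floor within the 200-epoch budget — a
representational limit of pairwise decoding from concatenated embeddings,
not of the training code.

## Coupling and its decomposition

Coupling is the Pearson correlation between a structural profile and the
empirical FC profile over unique edges: for the **correlation approach** the
profile is the subject's SC restricted to its nonzero (and unmasked) edges;
for the **GNN approach** it is the predicted FC over all unmasked edges. Both
are computed globally and per region (row profiles, diagonal excluded).

Crossing every subject's source with every subject's FC gives the N x N
**cross-participant coupling matrix**: diagonal entries are *matched*
(within-subject) couplings, off-diagonal entries *mismatched*. The
decomposition is

- total effect = mean matched coupling,
- group-common effect = mean mismatched coupling,
- individual-specific effect = total - group (conserved exactly),
- per subject, `mismatched_i` averages row and column `i` without the
  diagonal; matched vs mismatched vectors are compared with a two-sided
  paired t-test implemented from its closed form (delegation to `t.test()`
  is used as the oracle in tests, never as the implementation).

For mismatched couplings the
source subject's *stored* prediction is reused against every other subject's
FC, and in the correlation approach the source subject's nonzero-edge set
defines the edge set of each pair. A normalized individual effect
(individual/total) guards against scaling artefacts when comparing regions.

## Null models

- **Topology null** (`rewire_sc()`, `rewired_training_run()`): binary
  double-edge swaps (degree-preserving, via igraph) randomize training-set SC
  topology; the original weight multiset is reassigned by ranking rewired
  edges on the sum of their endpoints' original strengths, so degrees and the
  weight multiset are preserved exactly and nodal strengths approximately
  (exact joint preservation is computationally infeasible; this rank-matching
  follows the behaviour of the standard brain-connectivity toolbox). The GNN
  is retrained on rewired SC with unchanged FC targets; test-set SC is never
  rewired. The drop in explained variance, `mean(r_emp^2) - mean(r_null^2)`,
  measures how much of the coupling rides on topology.
- **Spin test** (`spin_rotations()`, `spin_pvalue()`): uniform random 3D
  rotations of each hemisphere's spherical layout (the mirrored rotation on
  the opposite hemisphere), followed by greedy nearest-neighbour reassignment
  *without replacement*, so every rotation yields a true permutation and
  permuted maps keep their value multiset (projection-based variants can
  duplicate assignments; this is a deliberate divergence). The p-value is the
  proportion of null correlations at least as extreme as the empirical one in
  the direction of its sign; a two-sided variant is available, and a p of 0
  is reported as below `1/n_rotations`. Axis alignment (`align_map()`)
  excludes map outliers beyond mean +/- 3 sd, recomputed per map, and applies
  the same exclusion to every rotated map.

## The synthetic cohort

`generate_cohort()` draws one structural backbone from a stochastic block
model (4 modules, within/between edge probabilities 0.7/0.08) with 10% hub
nodes whose incident pairs use the within-module probability (a densely
interconnected core), log-normal edge weights, and connectivity enforced by
bounded resampling. Subjects jitter the backbone multiplicatively
(`exp(N(0, tau_sc))`, default 0.1) and flip edges at rate 0.02. Region
metadata places `K/2` regions per hemisphere on a Fibonacci sphere lattice
and assigns the S-A-like axis rank by decreasing `z`, making the rank map
spatially smooth — a property the spin test requires to be meaningful.

FC is generated by the forward model (`forward_fc()`):

```
FC = standardize(sum_p beta_p Abar^p)            # multi-hop topological signal
   + gamma_g * G                                 # shared non-structural component
   + sqrt(sigma_u sigma_v) * C_i                 # axis-graded individual component
   + N(0, noise_sd)                              # observation noise
```

with `Abar` the symmetrically normalized SC, `sigma(r) = gamma_i (1 + s
(rank - 1)/(K - 1))` increasing along the axis, and defaults `beta = (0.5,
0.5)`, `gamma_g = 0.3`, `gamma_i = 0.5`, `s = 2`, `noise_sd = 0.1`, `N = 80`,
`K = 60` (backbone density about 0.25-0.3; the cross-participant matrix stays
informative while a training run takes well under a minute).

**Why the individual component is structurally expressed.** A tempting
simpler choice is to make `C_i` pure i.i.d. noise. But a component
statistically independent of SC cannot be captured by *any* SC-based
predictor: raising `gamma_i` would then only inflate the FC variance, and the
estimated individual effect would *decrease* — the generator would have no
recoverable individual ground truth, defeating its purpose. `C_i` therefore
blends (with `indiv_struct_share = 0.8` of its variance) the subject's own
standardized latent deviation from the backbone with i.i.d. noise. The
deviation is computed from the *indirect* part of the latent polynomial
(powers >= 2 of `Abar`): individual coupling differences ride on higher-order
polysynaptic communication, which is exactly why a direct edge-wise
correlation underestimates them while the 2-hop GNN can recover them. This
gives the generator the three properties the analysis is tested against:
the estimated individual effect increases in `gamma_i`; the correlation
approach's individual effect does not exceed the GNN's; and the regional
individual (group) effect increases (decreases) along the synthetic axis.

What the generator does **not** emulate: BOLD hemodynamics and autocorrelated
time series (FC matrices are drawn directly on the Fisher-z scale),
tractography error structure, realistic cortical geometry or geodesic
distance effects, heavy-tailed motion artefacts, and any physiological
meaning of the modules. Passing tests therefore demonstrate that the
*estimators* recover planted effects under a known forward family — not that
real cortex behaves like the generator.

## Reproducibility and problem sizes

Every stochastic step derives its seed from a master seed via a stage-tagged
hash (`run_study()` records all stage seeds in its report), and single runs
are bit-reproducible. The test suite and the acceptance script use the
reference conditions `N = 80`, `K = 60`, 200 epochs, 1,000 spin rotations,
10 rewiring swaps per edge; the repeated two-fold cross-validation mode
defaults to 10 repeats at desk scale (the reference analysis used 100).
Degenerate inputs are first-class: isolated nodes, constant maps, regions
with fewer than three usable edges and zero totals are reported as typed
errors or missing values rather than silently propagated.

## Known limitations

- The concatenation MLP decoder limits achievable fit at larger `K` within
  short training budgets (see the hyperparameter note above).
- Strength preservation under rewiring is approximate by construction.
- The greedy spin reassignment is O(K^2) per hemisphere per rotation — fine
  for desk-scale `K`, slow for atlas-scale maps.
- With `K = 60` regions the spin null has limited spatial resolution;
  alignment p-values below `1/n_rotations` are reported as 0 and flagged.
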