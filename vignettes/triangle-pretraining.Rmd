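---
title: "Triangle-aware multimodal molecular pretraining: models, objectives, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangle-aware multimodal molecular pretraining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moltri)
```

## The problem

A molecule admits two natural views: a 2D topological graph `T` (atoms as
typed nodes, chemical bonds as typed edges) and a 3D conformation `C` (atoms
with spatial coordinates, here encoded as a fully connected pairwise-distance
graph). The two views are strongly coupled — most directly, the *type* of a
bond largely determines its *length* — and self-supervised pretraining that
maximizes the mutual information between the views produces embeddings that
transfer to property prediction. This package implements such a pretraining
system: encoders for both views built around a triangle-aware edge-update
mechanism, score-based diffusion objectives for conditional generation in
both directions, a node-level noise-contrastive objective, and two
cross-modal *edge* objectives that supervise each view's pair embeddings with
the other view's edge information.

The mutual-information view motivates the losses: maximizing
`MI(T, C)` is lower-bounded through the two conditional log-likelihoods
`E[log p(C|T)]` and `E[log p(T|C)]`, which the diffusion objectives estimate
by denoising score matching, while the contrastive terms discriminate matched
from mismatched (noised sample, condition) pairs. The package computes the
surrogates, never the mutual information itself.

## Encoders

Both encoders share a block of four updates applied to node embeddings
`h_u` (width `D_h`) and ordered-pair embeddings `z_uv` (width `D_z`):

1. **Node-to-edge.** `z_uv <- z_uv + Linear(f(h_u) * f(h_v))` with
   `f = Linear(LayerNorm(.))`. The product is elementwise, so the update is
   commutative in `(u, v)` and symmetric pairs stay symmetric; a flattened
   outer-product variant is available (`encoder_config(product = "outer")`)
   since the printed operator is ambiguous between the two readings.
2. **Multiplicative triangle update.** For each pair `(u, v)` the third edges
   of triangles through a vertex `w` contribute
   `sum_w LayerNorm(z_uw) * LayerNorm(z_vw)`, which is re-normalized,
   projected, and added under a sigmoid gate computed from a learned linear
   projection of `z_uv`. The gate-on-a-projection choice follows the
   AlphaFold2 triangle-update convention that inspired the mechanism; the
   printed form (sigmoid of `z_uv` itself) is the special case of an identity
   projection.
3. **Attention triangle update.** Per head,
   `a_uvw = softmax_w(q_uv . k_wv / c + b_wu)` and
   `z_uv <- z_uv + gate * sum_w a_uvw v_uw`, with `c = sqrt(per-head width)`.
   The `k_wv` / `b_wu` index pattern is implemented exactly as printed, even
   though the mixed orientation may be a typo for `k_wv`/`b_uw`; with
   `n_heads = 1` the implementation reduces to the printed single-head form
   (no output projection is applied after the head concatenation, so this
   reduction is exact).
4. **Edge-to-node.** Incoming and outgoing pair embeddings are LayerNormed,
   summed separately (the "rows and columns" of the pair array), passed
   through two independent 3-layer MLPs, and added to `h_u`.

**Admissible third vertices.** The printed sum ranges over `w` in
`N(u) | N(v)`, but the product `z_uw * z_vw` needs *both* pair embeddings. On
the fully connected 3D graph every `w != u, v` qualifies. On the sparse 2D
bonded graph the default is the intersection `N(u) & N(v)` — the only reading
with all factors defined — with `encoder_config(w2d = "union")` materializing
missing pair embeddings as a learned null vector to realize the literal
union. Note that with the intersection reading the 2D triangle stage is only
active on graphs that contain 3-cycles; on triangle-free molecules (chains,
5/6-rings) it is the residual identity, which is intended behavior, not a
bug.

**Empty aggregation sets** (a pair with no admissible `w`, an isolated node)
skip their update entirely, leaving the residual stream unchanged — this
avoids LayerNorm of an all-zero vector and makes the degenerate cases exact
identities.

**Initialization stages.** The 2D encoder starts with two bond-type-aware GIN
layers (sum aggregation of `relu(h_v + e_uv)` followed by a 2-layer MLP),
capturing two-hop topology before any triangle update; pair embeddings are
initialized from the endpoint embeddings plus a bond-type embedding. The 3D
encoder starts with one continuous-filter convolution: messages
`Linear(h_v) * MLP(rbf(d_uv))` over a 16-center Gaussian radial basis spanning
0-5 Å, so the whole 3D pathway sees coordinates only through interatomic
distances and is SE(3)-invariant *by construction* (the test suite verifies
this to 1e-4 relative under random rigid motions rather than assuming it).

**Pooling.** Node embeddings are mean-pooled per molecule and projected to a
256-dimensional molecule-level embedding. Only the output width is fixed by
the method's evaluation protocol; mean-then-project is our choice.

**Defaults.** `D_h = D_z = 128`, 3 triangle blocks, 4 heads, 3-layer
edge-to-node MLPs. The method's own hyperparameter table is not public;
these are conventional values for this model family. The test suite and the
acceptance script run reduced widths (8-16) and 1 block: every property they
check (symmetries, oracle agreement, closed forms, trainability) is
width-independent, and the reduced sizes keep the full suite within minutes
on one CPU.

## Diffusion objectives

Coordinates follow a variance-exploding SDE; the kernel std is
`sigma(t) = sigma_min (sigma_max/sigma_min)^t` with
`sigma_min = 0.01`, `sigma_max = 2.0` Å. Relaxed (continuous one-hot) 2D node
and edge features follow a variance-preserving SDE with
`beta` linear from 0.1 to 9.5 and independent Brownian motions for the node
and edge streams. Times are sampled uniformly on `[1e-3, 1]`, one per
molecule per step. The method statement defers the SDE constants to an
external codebase; these are the conventional defaults for the two families
and are config-overridable.

Both perturbation kernels are Gaussian, so the true score
`-(x_t - m(t) x_0) / s(t)^2` is available in closed form; the losses are
Monte-Carlo denoising score matching with the conventional `s(t)^2`
weighting. Under that weighting a zero score network has expectation exactly
equal to the perturbed dimension count (3 x atoms for coordinates; total
relaxed feature dimension for 2D), which the tests exploit as a closed-form
oracle; the unweighted printed form is available via `weighting = "none"`.

The 2D-to-3D score network outputs
`S_u = sum_v w_uv (x_u - x_v)` with scalar weights from an MLP over the
condition embeddings, the radial expansion of the *noised* distances, and a
sinusoidal time embedding. Rotations act only through the relative vectors,
so the output is exactly rotation-equivariant and translation-invariant;
coordinates are centered before perturbation so the translation-invariant
score is well defined. The 3D-to-2D network is per-node/per-edge MLPs
conditioned on the (rigid-motion invariant) 3D embeddings. Both output heads
are zero-initialized, so an untrained network is exactly the zero network —
this makes the Gaussian-identity check an init-time property rather than a
contrived configuration.

## Contrastive objectives

**Node level (EBM-NCE).** The printed objective applies a sigmoid to a
vector-valued score network, which is dimensionally ambiguous, and its second
expectation reuses the same conditional in both branches (a likely typo). We
implement the standard matched-vs-mismatched reading: a scalar discriminator
head on the score network's pooled trunk representation scores (noised
sample, condition) pairs; matched pairs are positives, and negatives pair
each noised sample with the condition of a *different* batch molecule, drawn
by a seeded in-batch derangement (a cyclic shift, which is always
fixed-point-free). Because molecules differ in atom count, the condition
enters the discriminator trunk as a projection of the *pooled* 256-vector of
the other modality broadcast to atoms — this makes cross-molecule pairing
well defined while keeping the discriminator on the score network's own
representation. Each modality term is
`-1/2 E[log sigmoid(D+)] - 1/2 E[log(1 - sigmoid(D-))]`; with zero
discriminator logits each term is exactly `log 2`. A batch of one has no
mismatched pairs and is rejected.

**Edge level.** The distogram objective discretizes true 3D distances into 32
left-closed bins spanning 1.0-2.4 Å (boundary values go up; the end bins
absorb out-of-range distances so the loss stays total and labels stay
one-hot) and trains a linear head by cross-entropy. The printed loss sums
over all node pairs yet normalizes by the bonded-edge count; our default uses
all unordered heavy-atom pairs with mean normalization (scale-stable across
molecule sizes), and `bonded_only = TRUE` restores the literal normalizer.
Whether the 1.0-2.4 Å range was meant to restrict the sum to bonded pairs is
unstated; clamping over all pairs is our reading, with the flag covering the
other. Since the 2D triangle stage is bonded-only, non-bonded pairs have no
`z_uv`; the head therefore reads `[h_u + h_v, z_uv-or-learned-null]`. The
bond-class objective mirrors it: every pair of the fully connected 3D graph
gets one of five labels (single/double/triple/aromatic/no-bond) from the 2D
graph, predicted from `z^3D` by a linear head; the printed loss is an
unnormalized sum, our default is the per-pair mean, `reduce = "sum"` is the
literal form. Labels are constants (no gradient flows into them); only heads
and encoders learn.

**Batch level.** An optional symmetric InfoNCE over the pooled 256-vectors
(cosine similarities, temperature 0.1, both softmax directions) implements
the batch-level mutual-information mechanism; its exact published functional
form is not public, so the standard symmetric InfoNCE is used. It is off by
default (`alpha4 = 0`) and enabled per run.

**Total objective.**
`L = alpha1 (eta1 L_node + eta2 (L_edge_2D + L_edge_3D)) + alpha2 L_2D3D +
alpha3 L_3D2D + alpha4 L_infomax`, all weights defaulting to 1 (the source
gives no values) except `alpha4 = 0`.

## The synthetic fixture generator

`make_fixture_set()` emulates exactly the statistical structure the edge
objectives assume: chains, branched chains and 5/6-rings over {C, N, O} with
3-12 heavy atoms, valence-respecting bond assignment, and 3D coordinates in
which each bonded distance equals its type's mean length plus Gaussian
jitter — single 1.54 Å, double 1.34 Å, aromatic 1.39 Å (carbon-class
textbook values), `sigma_len = 0.01` Å. The jitter was chosen once as a round
value satisfying the generator's separability constraint
(`3 sigma < 0.05` Å, the smallest inter-mean gap) and is not revisited;
molecules are laid out with ~111 degree zig-zag angles and regular-polygon
rings so most non-bonded distances fall at or beyond the 2.4 Å top of the
distogram range, then receive a random rigid motion. Ring sizes 5-6 and
molecule sizes 3-12 keep the brute-force triangle oracles affordable.

What the fixtures deliberately do **not** emulate: conformational ensembles,
torsional flexibility, stereochemistry, hydrogen positions, realistic
force fields, and the long-tailed size and element distributions of real
pretraining corpora. Steric placement of non-bonded atoms is best-effort
(1-3 distances through a double bond can fall slightly below 2.4 Å), so
tests rely only on bonded-pair guarantees. Consequently, a passing suite
demonstrates that the mechanisms are implemented correctly and that the
objectives transfer edge information when that information is present — it
does not certify accuracy on real chemical data.

## Numerical choices

- All model math runs on a small reverse-mode tape written for this package
  (dense matrices, double precision, single-threaded deterministic); gradient
  correctness is tested against central finite differences.
- LayerNorm uses eps 1e-5 with learned gain/shift; attention softmax
  subtracts a detached per-group maximum (exact gradient, stable forward).
- Adam (lr 1e-4 for full pretraining at scale defaults; 1e-3 for the
  desk-scale overfit demonstration; 3e-3 for the 300-step edge-objective
  run), global gradient-norm clip 10 to protect the score-matching terms.
- Deterministic seeding: every stochastic call derives a stream-specific
  child seed (below 2^31) from the user seed, so runs are reproducible and
  individual noise streams can be varied independently. Determinism is
  guaranteed single-threaded.
- Ties in retrieval break by corpus index; the distance-bin boundary goes to
  the upper bin; scaffold-split ties among equal-size groups break by seed.
- Scaffold identity uses exact colored-graph canonical labelling (BLISS on an
  edge-subdivided graph), so no two distinct scaffolds can collide and
  relabeled molecules always group together; acyclic molecules share the
  empty scaffold, as in common benchmark practice.

## Problem sizes used by the tests and the acceptance script

Symmetry and oracle checks run on 20 molecules x 5 rigid motions and 20
random graphs of at most 8 nodes at widths 8-16; the Monte-Carlo Gaussian
identity uses 10^4 kernel draws on one molecule; the cross-modal transfer
demonstration trains the two edge objectives for 300 full-batch steps on 40
generated molecules and probes 15 held-out ones; the end-to-end overfit runs
200 steps on 8 molecules. These sizes were chosen so the whole suite
completes in minutes on a single CPU while every check remains
non-trivially falsifiable.

**Force prediction.** The forces head is trained on molecular *energies*
only (the harmonic bond toy of the fixture generator), and forces are read
out as the negative coordinate gradient of the predicted energy, obtained by
reverse-mode differentiation through the distance map, the radial basis, the
convolution and the triangle blocks. Energy-only supervision constrains the
gradient field only indirectly: in the demonstration setting — one small
molecule, many conformations around its minimum — the per-atom force
directions recover the analytic harmonic gradient (cosine above 0.9 where
the true force is appreciable), but across heterogeneous molecule sets the
alignment degrades even when the energy fit is tight. Proper force matching
would require differentiating the gradient itself (second-order
differentiation), which the engine does not implement.

## Known limitations

- Reverse-SDE sampling (conformer generation) is out of scope; the diffusion
  machinery here exists for the training objectives only.
- The 2D triangle stage is inert on triangle-free bonded graphs under the
  default intersection reading (see above); union mode trades this for a
  learned-null approximation.
- The distogram head's top-1 accuracy on fixtures is bounded by bin-boundary
  effects: the aromatic mean (1.39 Å) sits 0.004 Å below a bin edge, so even
  a perfect predictor of the modal bin misses jittered aromatic bonds that
  cross it. The held-out top-1 accuracy around 0.9 reflects this ceiling,
  not an optimization failure.
- O(n^3) triangle enumeration and dense pair storage limit molecules to the
  tens of atoms; no sparse/cutoff approximations are implemented.
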