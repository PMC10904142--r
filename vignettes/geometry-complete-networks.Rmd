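---
title: "Geometry-complete networks: model, design choices, and what the synthetic tasks show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-complete networks: model, design choices, and what the synthetic tasks show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcpnet)
```

## The model

`gcpnet` implements a graph neural network for 3D point clouds — molecules,
protein fragments, interacting particles — whose scalar outputs are invariant
under rigid motions (SE(3)) of the input and whose vector-valued outputs and
updated coordinates transform with the input. Unlike E(3)-invariant
architectures, its scalar features *change under reflection*, which is what a
model needs to tell a chiral molecule from its mirror image.

A structure is a directed k-nearest-neighbor graph over node coordinates
$X \in \mathbb{R}^{N\times 3}$. Features travel as $(s, V)$ tuples: $s$ holds
invariant scalar channels, $V$ holds equivariant 3-vector channels. Three
ingredients make the architecture work:

1. **Local frames.** After removing the center of mass, every directed edge
   $(i, j)$ receives a right-handed orthonormal triple
   $$a_{ij} = \frac{x_i - x_j}{\lVert x_i - x_j\rVert},\qquad
     b_{ij} = \frac{x_i \times x_j}{\lVert x_i \times x_j\rVert},\qquad
     c_{ij} = a_{ij} \times b_{ij}.$$
   Rotating the cloud rotates all three axes; under point inversion the axes
   pick up signs $(-, +, -)$. The frame is therefore rotation-equivariant but
   *not* reflection-equivariant — the lever that injects chirality sensitivity.

2. **The geometry-complete perceptron (GCP).** One GCP maps an $(s, V)$ tuple
   with widths $(t, r)$ to widths $(t', r')$:
   $$z = V\,w_{dz},\qquad V_s = V\,w_{ds},\qquad
     q = \langle V_s, (a, b, c)\rangle \in \mathbb{R}^9,$$
   $$sv = [\,s \,\|\, q \,\|\, \lVert z\rVert\,]\,w_s + b_s,\qquad
     s' = \sigma_s(sv),$$
   $$V' = (z\,w_{uz}) \odot
     \sigma_g\!\big(\sigma_+(sv)\,w_g + b_g\big).$$
   Every learnable map acts on the channel dimension only and never mixes the
   three Cartesian components of a vector channel; that restriction alone
   guarantees equivariance of $V'$ and invariance of $s'$ under rotation. The
   nine frame projections $q$ (the *scalarization*) are where directional — and
   chiral — information becomes available to the scalar track. For node-level
   tuples, $q$ is averaged over the node's outgoing edges; for edge-level
   tuples it is read off directly.

3. **Graph convolution and position updates.** One layer computes, per directed
   edge, a message from the concatenated destination-node, source-node and edge
   tuples through a depth-$\omega$ stack of GCPs (the first maps widths, the
   remaining $\omega - 1$ are residual), mean-aggregates messages per receiving
   node, and residually updates the node state with one more GCP. When position
   updates are enabled, a dedicated single-vector-channel GCP emits a
   displacement that is added to the coordinates at every layer; after the last
   layer the frames are recomputed from the final coordinates and the original
   center of mass is added back, which makes the position output
   translation-equivariant. When position updates are disabled, the output
   coordinates are — bitwise — the input coordinates.

The full forward pass is: centralize, localize, embed node and edge features
(one GCP each), $L$ convolution layers (edge embeddings are computed once and
reused by every layer), optional re-localization and de-centralization, and a
final projection GCP.

## Training without a framework

No automatic differentiation is used: every GCP caches its intermediates and
`gcp_backward()` / `gcpnet_backward()` implement the exact reverse-mode
gradients, composed across concatenations, mean aggregations, residual
connections and the additive position path. The test suite validates the
gradients against central finite differences (directional derivatives agree to
~1e-13 in double precision).

One deliberate simplification: **gradients do not flow through the geometry**.
Frames and centers are treated as constants of the input. This is exact for
models that do not update positions (frames depend only on input coordinates)
and for losses on output positions (the coordinate path is purely additive and
frames are refreshed only after the last layer, feeding only the final
projection). A loss on the *scalar* outputs of a position-updating model would
miss the small term that travels through the re-localized frames; neither
shipped task has that shape.

Optimization is mini-batch Adam (default learning rate 1e-3 at the API level;
the experiment runners use 2e-3, which converges faster at these widths) with
early stopping on a validation split. The chirality objective has a long
initial plateau — the cross-entropy sits near log 2 for tens of epochs before
the frame-derived features engage, and how long varies with the
initialization — so `train_model()` takes a `min_epochs` warm-up during which
a flat validation loss is not treated as convergence (the chirality runner
uses 35 warm-up epochs out of 60). Graphs are batched block-diagonally with
per-graph centering and pooling, so batched and per-graph forwards agree to
rounding. In reference mode — single-threaded, double precision — training is a
deterministic function of the seed.

## Parameters that matter

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `lambda` | 3 | vector-channel downscale inside a GCP; hidden vector width is `max(1, ceil(r/lambda))` |
| `omega` | 3 | GCP applications per message stack; small constant keeps desk-scale |
| `sigma_s`, `sigma_+` | SiLU | smooth invariant nonlinearities on the scalar track |
| `sigma_g` | sigmoid | (0,1) gate scaling each output vector channel |
| `n_layers` | 4 | convolution rounds |
| hidden widths | node (100, 16), edge (32, 4) | package defaults; the experiment runners use node (32, 8), edge (16, 4) with `omega = 2`, which train in minutes on one CPU at the shipped problem sizes |
| `k` | 16 (molecular default), 4 for the 5-atom tasks | neighbors per node |
| `eps` | 1e-8 | norm guard: all divisions use `sqrt(x^2 + eps^2)`, changing non-degenerate values by under 1e-8 relative |
| RBF basis | 16 Gaussians, `d_max` 10 (molecular units) or 8 (particle task) | smooth invariant distance embedding; any such family satisfies the contract |

Ablation switches (`ablation_config()`): `no_frames` zeroes the nine frame
projections, collapsing the model to E(3) (reflection-invariant scalars);
`no_resgcp` removes residual wrappers; `no_scalars` replaces input scalars with
a constant one-wide channel (keeping the architecture well-formed — this
ablation is known to be collapse-prone); `no_vectors` removes the vector track
entirely, and with it scalarization.

## Numerical choices and degenerate inputs

* **Degenerate frames.** When the two centered endpoints are collinear with the
  origin, $b$ is undefined; the package sets $b = c = 0$ for that edge and
  flags it, rather than inventing an arbitrary axis — a zero contribution is
  symmetry-safe, and the configuration has measure zero in generic clouds (the
  audited degeneracy rate on Gaussian clouds is exactly 0).
* **k-NN ties** break toward the lower node index, with distances compared in
  double precision, so graph topology is bit-reproducible.
* **Directed edges** are kept: $a_{ij} = -a_{ji}$, so collapsing directions
  would destroy information.
* **Empty neighborhoods** (possible only in hand-built graphs) contribute a
  zero scalarization mean rather than NaN.
* **Scalarization layout** is fixed channel-major with axis order $(a, b, c)$:
  columns 1, 4, 7 project on $a$; 2, 5, 8 on $b$; 3, 6, 9 on $c$. Under point
  inversion exactly the $a$- and $c$-columns flip sign.
* **Unit masses** are assumed in the center of mass; the model never introduces
  per-node masses.

## What the synthetic generators emulate — and what they do not

**Chirality task.** Five-atom tetrahedral stereocenters with randomized
directions and bond lengths; substituent priorities are encoded as atom types;
the R/S label is the sign of the signed volume of the priority-ordered
substituents; every molecule ships with its mirror image (opposite label) and
an independent random pose, and mirror pairs never straddle the train/val/test
split. This isolates precisely the property the frames claim to capture. It
does *not* emulate real conformer ensembles, multiple stereocenters,
cheminformatics perception (degrees, hybridizations, bond orders) or label
noise — so the reported ~0.99 accuracy demonstrates the *mechanism*, not
PubChem-scale performance. The frame-free ablation is pinned to 0.5 by
construction: its features are provably identical for the two members of a
mirror pair.

**Many-body task.** Unit-mass particles with balanced ±1 charges under a
softened Coulomb force, optionally composed with uniform gravity or a
Lorentz-like $q\,v \times B$ force, integrated by velocity Verlet
(constants: softening 0.1, $g_0 = 0.2$, $B_0 = 1.0$, $dt = 10^{-2}$, 1200
steps; initial positions N(0, 1), velocities N(0, 0.5); forecast from step 100
to step 1100). Velocity Verlet keeps total ES momentum conserved to rounding
(~1e-15) and energy drift shrinking as $dt^2$; a single charge in the magnetic
field reproduces the analytic cyclotron radius within 0.2% at $dt = 10^{-3}$.
The simulator emulates the *physics class* of the published benchmark, not its
exact datasets: force constants, sampling distributions and trajectory counts
differ, so forecast errors are comparable only against the in-package
baselines (static and free flight), not against published tables.

## Problem sizes

The shipped experiments are sized for a single CPU: chirality uses 2000
molecules (1400 train) with a 2-layer network and trains in roughly three to
four minutes; forecasting uses 200 trajectories (140 train) of 5 bodies with
a 4-layer position-updating network, also minutes. Symmetry audits use
30-node graphs, 100 rigid motions, and 1000 frame edges. Larger widths and
graph sizes scale linearly in edges; nothing in the implementation assumes
small graphs, but pure-R training beyond a few thousand small graphs will be
slow.

## Known limitations

* Training is pure R: fine for the shipped problem sizes, not for
  GPU-scale datasets.
* No periodic boundary conditions; neighbor search is all-pairs
  (O(N²) per graph).
* Vector features are order-1 (plain 3-vectors); no higher spherical-harmonic
  types, no attention.
* The stop-gradient through geometry described above.
* The frame-free ablation changes the number of effective inputs to the scalar
  track; its capacity is therefore not perfectly matched to the full model,
  which is irrelevant for the chance-level chirality result but worth knowing
  for other comparisons.
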