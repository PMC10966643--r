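---
title: "Equivariant atom-pair scoring of protein-ligand binding affinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivariant atom-pair scoring of protein-ligand binding affinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqbind)
```

## The model

`eqbind` is an end-point scoring function: it maps a single static 3-D pose
of a protein-ligand complex to a predicted binding affinity on the pK scale
(pKi, pKd or pEC50 — the negative decadic log of the relevant constant,
linearly related to the binding free energy at fixed temperature). Nothing
else about the thermodynamic ensemble is represented; entropy, strain and
the unbound state enter only implicitly through what can be learned from the
pose.

The prediction decomposes additively:

$$
\widehat{pK} \;=\; s \;+\; \sum_{i \in \mathrm{lig}} c_L\,
\mathrm{NN}_{\mathrm{atm}}(h_i)
\;+\; \sum_{\substack{i \in \mathrm{lig},\, j \in \mathrm{prot} \\ r_{ij} \le r_{\mathrm{pair}}}}
c_P\, \mathrm{NN}_{\mathrm{pair}}\!\left(p_{ij}\right)
$$

* $s$ is a single trainable **shift**, initialized to the mean pK of the
  training labels. Atomic and pair terms therefore model *deviations from
  the average binder*, which is also how their values should be read:
  relative to other atoms in the same system, never in absolute terms.
* $h_i$ are per-atom scalar (rotation-invariant) features produced by an
  E(3)-equivariant message-passing encoder over two *disconnected* graphs —
  one for the ligand, one for the protein — with edges between atoms of the
  same molecule closer than $r_{\mathrm{msg}}$.
* $p_{ij}$ is the invariant feature vector of one ligand-protein atom pair
  within $r_{\mathrm{pair}}$: both atoms' scalar features, the pair distance
  expanded on a Bessel radial basis, the magnitudes of both atoms'
  directional features, their $n_f$ index-wise scalar products, and the
  index-wise cosines. The vector is deliberately *not* symmetrized — the
  ligand block always comes first, keeping the function class maximally
  flexible.
* A **ligand-only** mode drops the pair sum and encodes only the ligand
  graph; it is a 3-D analogue of ligand-based models and needs no protein
  input at all.

Each atom carries $n_s$ scalar features (initialized from a small dense
embedding of the one-hot element identity) and $n_f$ directional features,
each a 3-vector (initialized to zero). A message layer evaluates a dense
network on invariant inputs only — the two endpoint scalar vectors, the
Bessel-expanded edge distance, and the norms of the endpoint directional
features — and splits its output into a scalar message, a gate on the unit
interatomic vector, and a gate on the sender's directional features. Scalars
therefore stay exactly invariant and directional features transform exactly
as vectors under any rigid motion; the equivariance observed in the test
suite is structural, not learned. This gated-vector construction is one
concretization of the equivariant-GNN family; any construction passing the
equivariance property suite would be equally conforming.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `r_msg` | 5 Å | intra-molecular message cutoff; accuracy for this model family converges around 5 Å |
| `r_pair` | 5 Å | ligand-protein pair readout cutoff |
| `n_rbf` | 8 | Bessel radial basis size ("small orthogonal basis") |
| `envelope` | 5 | order of the polynomial cutoff envelope; messages vanish smoothly at `r_msg` |
| `n_passes` | 3 | message-passing layers; the receptive field is `n_passes * r_msg + r_pair` |
| `n_s`, `n_f` | 16, 4 | scalar / directional feature counts |
| `c_L`, `c_P` | 0.1 | fixed scaling of atomic / pair contributions; small values keep early training near the shift |
| `augment_radius` | 0.1 Å | online augmentation sphere (training only) |
| `lr`, `warmup` | 3e-3, 100 | Adam learning rate and linear warm-up steps |

Width and depth defaults are deliberately small: reported accuracy in this
model family is convergent or insensitive to these sizes, and at desk scale
(one CPU, a pure-R implementation with hand-written reverse-mode gradients)
the small widths keep the full parameter-recovery benchmark inside a few
minutes. The readout networks use two hidden layers of width 64, shared
across all atoms and across all pairs respectively; their *output* layers
are zero-initialized so that a freshly initialized model predicts exactly
the training-label mean — a property the acceptance suite checks literally.

Cutoffs matter for cost as well as accuracy: without them message passing
is $O(N^2)$ in the protein size; with them, edge counts grow linearly with
atom count at fixed density (asserted by a slope test), and predictions are
provably unaffected by any protein atom farther than
`n_passes * r_msg + r_pair` from every ligand atom.

## Training, transfer, evaluation

Direct training minimizes mean-squared error on pK with Adam under a linear
warm-up, mini-batched over complexes; every time an example is drawn its
coordinates are independently perturbed within a 0.1 Å sphere (augmentation
is off at inference). Mean displacement of that draw is $3r/4$; the
Monte-Carlo check in the test suite confirms both the bound and the mean.

Datasets are split 80/20 by stratified sampling on activity: labels are
binned into five activity quantiles and each bin contributes its share. The
per-bin counts use floor plus largest-remainder correction so the training
set size is exactly `round(train_frac * n)` — plain per-bin rounding can
overshoot on small sets. Results from trained models are reported as
5-model averages from seeded 5-fold cross-validation.

Transfer learning continues training from a pretrained checkpoint with
**all** weights trainable (freezing early layers was considered and
rejected upstream of this implementation), fresh (zeroed) optimizer
momenta, the warm-up schedule re-applied, and — by default — the shift
re-initialized to the *local* training mean, since congeneric series
occupy pK ranges far from the global mean; `keep_shift = TRUE` retains the
global shift instead.

Metrics are RMSE and MUE in pK units plus $r^2$, the squared Pearson
correlation; zero-variance predictions or labels report $r^2 = 0$ with a
warning rather than NA.

## The synthetic world

Real benchmarks for this problem require third-party structure archives,
docking software and at-scale training. The package instead ships a
generator whose ground truth is an explicit additive oracle:

$$
pK = b + \sum_{i \in \mathrm{lig}} a(Z_i)
  + \sum_{r_{ij} \le r_o} f(Z_i, Z_j)\, e^{-r_{ij}/\lambda}
  + \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2)
$$

with $b = 5$, per-element terms $a$, a rank-1 symmetric coupling matrix
$f = uu^\top$, $\lambda = 2$ Å, $r_o = 5$ Å and label noise $\sigma = 0.2$
pK by default (configurable to 0 for exact-recovery tests; 0.2 pK mimics
typical experimental scatter). Complexes are ligand blobs (5-12 atoms,
C-dominant drug-like element frequencies) inside pocket shells (15-30
protein atoms) with a 1 Å minimum separation. The oracle is *representable*
by the model class — a per-ligand-atom term plus a distance-decaying pair
term — so the parameter-recovery benchmark measures optimization and
implementation correctness, not approximation error. The global generator's
noise-free labels have SD ≈ 1.74 pK (Monte-Carlo, n = 2000; the atomic
terms were calibrated once so this construction-level requirement of ≥ 1.5
pK holds, before any benchmark was run). Local series fix the pocket and
perturb a shared scaffold (≤ 0.5 Å jitter, ≤ 20% element swaps, 0-3 added
atoms), giving the narrow label ranges characteristic of lead series.

What a green test does **not** establish: the synthetic world has no bond
topology, no conformational strain, no solvation, no pose uncertainty, and
its labels come from the very functional family the model can represent.
Passing parameter recovery here says the machinery optimizes and
generalizes on in-family data; it says nothing about accuracy on real
crystal structures.

## Numerical choices

* **Distance floor.** Distances between distinct atoms are floored at
  1e-6 Å before basis expansion (with a message), so duplicate coordinates
  cannot produce infinities.
* **Safe norms.** Directional-feature norms are computed as
  $\sqrt{\sum v^2 + 10^{-12}}$: smooth, with zero gradient at the zero
  vector (where directional features start).
* **Cosine convention.** The pair-feature cosine is defined as 0 when either
  vector's norm is below $10^{-12}$ — a neutral value inside a dense
  network input.
* **Cosine set.** "The cosine of the angle between each pair of directional
  features" is read as *corresponding indices* ($n_f$ values), matching the
  index-wise scalar products next to it; the all-pairs ($n_f^2$) reading
  was considered and not implemented.
* **Determinism.** A single integer seed fans out to split / fold /
  initialization / shuffling / augmentation streams through a small string
  hash; two runs with the same config and seed produce byte-identical
  checkpoints, and checkpoints serialize parameters as hex-float strings so
  reloading is bit-exact (plain JSON doubles are not).
* **Neighbor search.** Brute force below 500 atoms, cell lists above; both
  are exact and tested against each other.
* **Degenerate inputs.** Empty ligands are rejected at parse time;
  ligand-only complexes are valid everywhere the mode allows them; constant
  labels degrade the stratified split to a single bin.

## Design decisions that were genuinely open

* The upstream architecture description leaves the exact equivariant update
  unspecified (coordinate-updating vs persistent vector features); this
  implementation keeps coordinates fixed and stores persistent directional
  features, which suits a static-pose regression and makes locality exact.
* Whether pair readouts carry their own scaling constant is unstated; a
  separate `c_P` mirroring `c_L` was chosen, both fixed (not trained).
* Pocket truncation is permitted upstream but unparameterized; the default
  8 Å radius is the 5 Å message cutoff plus margin, `Inf` disables it, and
  both full proteins and pockets are supported.
* Protein and ligand graphs share one encoder (the weights are the same
  network); un-sharing was left out of scope.
* Training labels, not structures, decide the stratified bins; five bins is
  a convention chosen here, as the upstream description names no count.

## Limitations

* Pure-R training is desk-scale: hundreds of complexes with tens of atoms,
  not thousands of crystal structures. Headline benchmark numbers from
  at-scale training runs are out of reach by design and are not claimed.
* No covalent topology, protonation, tautomers or docking: poses are taken
  as given.
* Higher-order tensor features and attention are out of scope; directional
  features are rank-1 (vectors) only.
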