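---
title: "pocketgraph: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pocketgraph: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic benchmark
does and does not emulate, the numerical choices, and the places where the
design was genuinely open and a decision had to be made.

## The prediction problem

Given a protein structure and a query ligand (its 2D chemistry is enough;
no pose is required), predict which residues form the ligand's binding
pocket, and optionally where the pocket center lies in space. The ground
truth is operational: residue $i$ is a pocket residue iff

$$d_{\min,i} = \min_{j \in \text{ligand}} \lVert x_{\text{protein},i} - x_{\text{ligand},j} \rVert_2 \le \tau, \qquad \tau = 4.0\,\text{Å},$$

with the boundary inclusive. `makeLabels()` measures $d_{\min,i}$ over all
residue heavy atoms by default. The formula above indexes one point per
residue, but "minimum distance to any ligand atom" is most naturally read
— and most commonly implemented — over all residue heavy atoms; that
stricter reading is the default, with `representation = "coarse"`
switching to the two coarse-grained points for users who want the residue
represented exactly as the network sees it.

## Graph construction

Each residue becomes a backbone node at its Cα and a side-chain node at
the unweighted centroid of its side-chain heavy atoms (N, CA, C, O, OXT
excluded). Glycine has no side-chain heavy atom; its SC node sits on the
Cα, which keeps the two-nodes-per-residue invariant uniform — the
alternative (one node for glycine) would thread special cases through
every downstream shape.

Protein edges: consecutive-residue BB–BB edges and intra-residue BB–SC
edges, plus contact edges between any two protein nodes strictly closer
than 8.0 Å. The 5-dimensional edge feature vector
$[d_{ij}, I_{contact}, I_{bond}, I_{p\_global}, I_{l\_global}]$ has no
dedicated backbone flag, so backbone and intra-residue edges carry the
covalent indicator $I_{bond}$ (they are covalent-chain edges in spirit),
contacts carry $I_{contact}$, and an edge may set both when both apply.
Distances enter in Å and are divided by `dScale = 10` before the network,
putting typical contact distances in [0, 1]; nonspatial edges (hub edges,
bonds of a ligand without coordinates) carry $d_{ij} = 0$.

The protein virtual hub connects to all $2m$ structural nodes — the
complexity discussion counts "m" for this term, but the architecture text
says all structural nodes, and we follow the architecture; the count stays
linear either way. Each ligand hub connects to its own atoms only, so a
batch of one true ligand plus decoys shares the protein subgraph without
cross-talk between ligands. The two hubs are not connected to each other
by default (a config flag adds the edge): with decoy batching, a shared
protein-hub–ligand-hub edge would leak pairing information between
candidates in a way a single "joint" node sketch does not anticipate.

Vocabularies: 20 standard amino acids + UNK (21), elements
C, N, O, S, P, F, Cl, Br, I + other (10). Both sizes are our choice; they
cover everything the parsers emit.

## Network and training

The layer scheme (the published description treats the layer as a black
box updating node and edge embeddings jointly) is the minimal such
update:

- edge: $e' = \mathrm{LN}(e + \tanh(W_e [h_i, h_j, e]))$
- message: $m_i = \sum_{j \in N(i)} \tanh(W_m [h_j, e'_{ji}])$
- node: $h' = \mathrm{LN}(h + \tanh(W_h [h_i, m_i]))$

Sum aggregation is the default (`aggregation = "mean"` is available);
layer normalization carries no learned affine parameters. Undirected
edges are expanded into two directed orientations with independent edge
embeddings. All of this is differentiated by a small reverse-mode tape
(`R/autodiff.R`) whose every backward rule, and the full model
composition, is checked against central finite differences in the test
suite (relative tolerance 1e-4 on the full model, 1e-6 per op).

Heads: pairing $= \mathrm{MLP}(h_{PVirt} \odot h_{LVirt})$ (one hidden
tanh layer), pocket $P_i = \sigma(\mathrm{MLP}(h_i \odot h_{LTrue}))$ per
protein node. The per-residue probability is the max of the residue's two
node probabilities (config: mean); max matches the labeling semantics —
a residue is a pocket residue if *any* part of it reaches the ligand.

Losses: $L_{total} = L_{pairing} + L_{pocket}$. $L_{pairing}$ is InfoNCE
over the true ligand and $k$ decoys, softmaxed within one complex (not
across the batch — scores of different proteins are not comparable).
$L_{pocket}$ is weighted BCE with positive weight #neg/#pos per complex
capped at 100 (the published description says "weighted" without the
weight; the inverse class ratio is the standard choice and the cap guards
tiny-pocket outliers), plus a soft Dice term once the running F1 exceeds
0.2. The running F1 is an exponential moving average (decay 0.9) of batch
F1 at threshold 0.5, and the gate *latches* open: "dynamically enabled"
could also mean re-closable, but a re-closing gate makes the loss surface
discontinuous along training and invites oscillation around the
threshold. Dice uses probabilities (soft Dice) with smoothing $s = 1$, so
the empty-pocket/empty-prediction corner is defined and zero.

Optimization: Adam (lr 1e-3), batches of 4 complexes, decoys sampled once
per complex; unstated in the source material, so standard values, all
exposed in config and all behind one seed — the same seed reproduces a
loss curve bit for bit. The desk-scale default network is 4 layers × 64
hidden; the published 16 × 128 is a config away but unnecessary for the
synthetic benchmark.

## Coordinate-level mode

Shrake–Rupley surface points are generated from a deterministic spherical
Fibonacci lattice (default 92 points/atom) scaled to
$r_{vdw} + 1.4$ Å; a point survives iff no other atom's expanded sphere
contains it. The van der Waals table is Bondi-style (C 1.70, N 1.55,
O 1.52, S/P 1.80, halogens 1.47–1.98, other 1.70). A probe is a positive
training example iff it lies strictly within 4.0 Å of the ligand heavy-atom
centroid; negatives are far probes and the same positive probe paired with
a wrong ligand. We label existing surface points rather than inserting a
synthetic point at the ligand center: the deployed scorer only ever sees
real surface points, and training should match that.

Each probe's local graph contains the BB and SC nodes of residues within
10 Å (measured to the nearer of the two nodes), all query-ligand atoms,
and the probe as virtual hub. Probe–residue edges keep their true
distances (they are spatial); probe–atom and bond edges are nonspatial
because the ligand has no pose at prediction time — this also makes
wrong-ligand decoys exactly comparable to the true ligand. The probe
score is a linear head on the probe-node embedding.

Scored probes are condensed by hill climbing: each point adopts as parent
its highest-scoring strictly-better neighbor within 3.0 Å (ties to the
lower index), peaks own themselves, and union-find groups points by peak.
The 3.0 Å radius is roughly twice the surface point spacing at 92
points/atom, so slopes connect without bridging adjacent pockets; it is
config-exposed because no canonical value exists. Strict inequality means
equal-score plateaus fragment into singleton peaks — acceptable because
trained scores are continuous; a plateau-merge variant would need an
arbitrary merge order. Clusters are ranked by peak score (ties to the
lower peak index) and the peak coordinates are the predicted centers.

## The synthetic benchmark

`makeBenchmark()` generates the study conditions: proteins of 30 residues
as a self-avoiding Cα walk (3.8 Å steps, ≥ 4.0 Å non-consecutive
separation) with 1–4 side-chain pseudo-atoms per residue at 1.5–3.0 Å; a
planted pocket of 5 spatially contiguous residues; a true ligand of 6–9
heavy atoms placed atom-by-atom 3.0–4.0 Å from pocket-residue atoms and
≥ 2.5 Å from all protein atoms (round-robin assignment guarantees every
planted residue is inside the labeling shell); 10 decoy ligands per
complex. The conditioning rule: class A pairs oxygen/nitrogen-rich
ligands with pockets drawn from six polar residue types, class B pairs
carbon-rich ligands with six hydrophobic types, and decoys come from the
opposite class. Background residues are drawn from the fourteen amino
acids *outside* the complex's own class set: at 30 residues a uniform
background would frequently contain spurious class-enriched patches that
make the planted rule unidentifiable in principle, which would test the
generator's luck rather than the model. These sizes keep a full
train-and-evaluate cycle in minutes on one CPU; the generator scales up
by argument if wanted.

What the generator does *not* emulate: real backbone chemistry (no N/C/O
atoms), rotamers, physical ligand conformations, crystallographic noise,
or binding driven by anything subtler than residue composition. Passing
the learnability tests therefore shows the architecture, losses and
pipeline can recover a planted structure–chemistry association end to end
— it says nothing about accuracy on experimental complexes, which needs
real training data and the full-size network.

## Numerical choices and degenerate inputs

- Distances by vectorised `tcrossprod` with a `pmax(..., 0)` clamp before
  the square root; identical in exact arithmetic to the scalar double
  loop the tests use as oracle.
- BCE from logits with softplus for stability; probabilities clamped to
  [1e-7, 1 − 1e-7] in the plain-vector loss functions.
- Layer-norm epsilon 1e-5.
- Alternate locations: first conformer kept. Residues without Cα:
  skipped with a warning. Nonstandard residues with Cα: kept as UNK.
  Waters and monoatomic ions: never protein, never ligand.
- Multi-ligand PDB files: HETATM records are split into connected
  components under a covalent distance rule (1.9 Å, 2.1 Å when S/P or a
  heavy halogen is involved); each component is one candidate ligand.
  Which component a study would call "the" ligand is not decidable from
  the file alone, so all are returned.
- A probe with no residue within 10 Å warns and is scored on ligand +
  probe alone; fewer clusters than `topK` returns all with a warning; an
  empty decoy pool falls back to the available size with a warning.
- Checkpoints are JSON (portable, diffable); doubles survive at 15
  significant digits, which changes predictions by < 1e-12.

## Problem sizes used by the tests and acceptance script

The test suite trains a 2-layer × 32-hidden model on 200 generated
complexes for 30 epochs and evaluates on 40 held-out complexes (plus a
60-complex × 6-epoch probe-mode training); the label oracle runs on 500
complexes, the clustering oracle on 1000 random instances. These sizes
were chosen so the whole suite completes in a few minutes while every
statistic is computed on enough cases to be stable.

## Known limitations

- No mmCIF input, no protonation, no bond-order perception; first NMR
  model only.
- The trained models shipped by tests are toy-sized and fit only the
  synthetic rule; the package deliberately ships no pretrained weights.
- Probe scoring encodes one local graph per probe; for large proteins at
  92 points/atom this is the dominant cost (`downsampleProbes()` and the
  lattice count are the knobs).
- Greedy probe selection optimizes batch mean recall (the per-iteration
  argmax reading of "the ligand that contributes the most new coverage");
  a pooled-fraction alternative is a config choice away in the code but
  not a second code path.
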