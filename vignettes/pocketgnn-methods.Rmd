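---
title: "Methods: compound-pocket activity prediction with r-radius subgraph networks"
author: "pocketgnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compound-pocket activity prediction with r-radius subgraph networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketgnn)
```

## The problem and the model

Structure-based virtual screening asks: given a compound and a protein
binding pocket, will the compound be active? `pocketgnn` answers this as a
binary classification on a *pair of graphs*:

* **Compound graph.** A SMILES string is parsed (OpenBabel) into a
  heavy-atom graph. Vertex labels are atom types, with aromatic atoms kept
  as labels distinct from their aliphatic counterparts (an aromatic carbon
  is `C:ar`, not `C`), so that the aromatic/aliphatic distinction survives
  even though bonds also carry an explicit aromatic class alongside
  single/double/triple. Hydrogens are implicit; charges, isotopes and
  stereochemistry are ignored. A SMILES containing a dot encodes a
  disconnected multi-component structure, for which no single molecular
  graph exists; such records are *excluded* (flagged, never silently
  dropped, never half-parsed).

* **Pocket graph.** The pocket is the set of residues in contact with a
  co-crystallized ligand. Each residue is a vertex labeled with a
  20-dimensional one-hot amino-acid indicator (alphabetical three-letter
  order, `ALA` first, `VAL` last). An edge joins two residues whenever
  their C&alpha;&ndash;C&alpha; distance falls into one of five bins:
  I [1.0, 4.8), II [4.8, 7.0), III [7.0, 9.2), IV [9.2, 11.4),
  V [11.4, 13.6) &Aring;. Both bonded and non-bonded residue interactions
  are represented only through these bins; the coarse binning is what lets
  a single graph stand for a pocket despite moderate structural change.

Each branch summarizes its graph with **r-radius subgraph fingerprints**:
the identity of a vertex (or edge) is the isomorphism class of its
r-hop neighborhood. Fingerprints index an embedding table; L rounds of a
message-passing *transition*

$$h_i' \;=\; \sigma\!\Big(h_i + \sum_{j \in N(i)} W_l\,(h_j + e_{ij})\Big),
\qquad \sigma = \mathrm{ReLU},$$

are followed by an *averaging readout* over vertices, giving a compound
vector $y_{molecule}$ and a pocket vector $y_{protein}$ of dimension $d$.
The classifier is a linear head on the ordered concatenation,

$$z = W_{output}\,[\,y_{molecule};\,y_{protein}\,] + b_{output},
\qquad p = \mathrm{softmax}(z),$$

with the second logit (class index 1) the active class. All parameters —
both embedding tables, the per-layer transition matrices of both branches,
and the head — are trained jointly (end to end) with Adam on the softmax
cross-entropy, the canonical companion loss of a softmax output.

## Defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `dim` | 10 | embedding / branch-vector dimension $d$ |
| `r_compound` | 2 | fingerprint radius on the compound graph (hops) |
| `r_pocket` | 1 | fingerprint radius on the pocket graph |
| `layers_compound`, `layers_pocket` | 3, 3 | transition rounds per branch |
| `learning_rate` | 0.001 | initial Adam step size |
| `lr_decay`, `decay_interval` | 0.5, 10 | rate halved at every 10th epoch boundary |
| `epochs`, `batch_size` | 100, 1 | passes over the data; examples per Adam step |
| `contact_cutoff` | 4.5 &Aring; | min heavy-atom distance defining a contact residue |

The neural defaults form the package's reference configuration and are the
ones exercised by the learnability tests. The contact criterion deserves a
note: contact-surface programs define ligand contacts through surface
complementarity, a criterion that is not reproducible from their papers
alone. We instead define a contact residue explicitly — minimum heavy-atom
to heavy-atom distance at or below 4.5 &Aring;, a standard
structural-biology cutoff — and expose it as a parameter. This is a
documented stand-in, not a claim of equivalence.

## Design choices in corners the contracts leave open

* **Interval convention.** The printed distance bins share endpoints
  (4.8 &Aring; closes bin I and opens bin II), so a convention is forced:
  bins are half-open $[lo, hi)$, tiling $[1.0, 13.6)$ without gaps; a
  boundary value belongs to the upper bin. Distances below 1 &Aring; are
  clashes — a data-quality problem, logged, producing no edge rather than
  an error.

* **Fingerprint construction.** Rather than extracting each r-hop
  subgraph and canonicalizing it, fingerprints are computed by iterative
  sorted-multiset relabeling (Weisfeiler–Lehman refinement): radius 0 is
  the vertex label; each round appends the sorted multiset of
  (edge label, neighbor fingerprint) pairs. Isomorphic neighborhoods are
  guaranteed identical fingerprints, and the radius-(r+1) partition
  provably refines the radius-r partition — both properties are tested
  against a VF2 isomorphism oracle. Fingerprints are stable readable
  strings, never platform-dependent hashes. Edge fingerprints combine the
  edge's own label with the unordered pair of endpoint fingerprints, which
  makes them symmetric by construction; the construction for edges is our
  choice, as the r-radius concept is usually stated for vertices.

* **Unseen fingerprints.** Test-time graphs contain neighborhoods absent
  from training. Each vocabulary reserves an UNK index; unseen
  fingerprints map there (counted and reported per graph). The UNK row is
  part of the embedding table from initialization.

* **Transition parameterization.** The verbal recipe "add neighboring
  vertex and edge vectors, then update through the non-linearity" admits
  several readings. We fix the residual form
  $h_i' = \sigma(h_i + \sum_j W_l (h_j + e_{ij}))$ with per-layer weights
  and ReLU (the non-linearity is otherwise unspecified; ReLU is our
  documented choice), and keep edge vectors static across layers — the
  minimal structure consistent with the add-then-update reading. Whether
  edge vectors should also update per layer is genuinely open; static
  edges are simpler and testable.

* **Initialization.** All tables and weights draw from
  $U(-1/\sqrt d, 1/\sqrt d)$ under a recorded seed (head bias zero).
  Training shuffles the data each epoch from the run seed; with batch
  size 1 the visit order matters, so reproducibility requires seeding it.
  Fitting is bitwise reproducible given the seed. No early stopping,
  weight decay or dropout: they are not part of the reference
  configuration.

* **Evaluation.** AUROC is computed by a tie-grouped threshold sweep with
  trapezoidal integration, which equals the normalized Mann–Whitney
  statistic exactly (ties counted half); the suite checks equality against
  a brute-force pairwise oracle at $10^{-12}$. F1 uses the natural softmax
  decision boundary $p_{active} \ge 0.5$ (exposed as a flag), with the
  zero-TP convention F1 = 0 so per-target tables stay total.

## The synthetic data generator

Real screening benchmarks (DUD-E, MUV) need downloads, docking poses and
resolved complexes; the package instead ships a generator whose ground
truth is planted and therefore known exactly.

* **Pockets** are compact random 3D point clouds (radius 8.5 &Aring;
  sphere, 3.8 &Aring; minimum C&alpha; separation — typical packing), 8–16
  residues, converted through the *real* distance-binning code so the
  population exercises all five edge classes. A pocket either carries the
  motif (at least $k = 3$ injected TRP residues) or none at all; other
  residues draw from the remaining 19 types.

* **Compounds** are linear heavy-atom chains of 4–9 atoms (C with
  occasional N). Motif compounds carry an ether oxygen (an O bonded to two
  carbons); motif-free compounds may still carry a terminal hydroxyl, so
  detecting the motif requires the oxygen's *neighborhood*, not its mere
  presence.

* **The planted rule** is conjunctive: active iff the pocket has the
  residue motif AND the compound has the substructure motif, optionally
  label-flipped at a noise rate. Motif presence is drawn at rate
  $1/\sqrt 2$ per side, so classes balance (~50%) while neither motif
  alone determines the label — a model must use both branches. A
  pocket-only variant (`compound_motif = NULL`) exists for ablations that
  must isolate the pocket branch.

* **Finite populations, combination-level splits.** Pairs draw from a
  fixed panel of 40 pockets and a fixed library of 80 compounds;
  `generate_split()` holds out *unseen combinations* of seen molecules
  and seen pockets. This mirrors a screening campaign over a fixed
  library and target panel, and it is also what makes the rule
  identifiable: the classifier head is additive across branches
  ($z$ is linear in $[y_{molecule}; y_{protein}]$), so when every
  compound and every pocket recurs with both labels, no single branch can
  interpolate the training labels and the loss minimum must encode each
  side's motif — which an additive score then ranks perfectly, since
  only motif-motif combinations are active. With a fresh molecule per
  pair, by contrast, the compound branch alone can memorize every label
  through idiosyncratic fingerprints and held-out performance collapses;
  that regime is a capacity statement, not a test of the method.

What passing on this data does **not** show: generalization to unseen
pocket *structures* (every WL fingerprint of a novel pocket maps to UNK —
the cross-target setting of real benchmarks), robustness to decoys
property-matched to actives, or anything about docking-quality geometry.
The generator's geometry is valid but stereotyped.

* **Toy complexes.** `generate_toy_complex_pdb()` emits small PDB files
  in which each residue's nearest heavy atom is placed (by root finding
  along a ray) at a *planned* distance from a clustered ligand, so the
  expected contact set at any cutoff is known by construction and
  verified against the emitted coordinates at PDB precision (0.001
  &Aring;).

## Numerical notes

* Gradients are hand-derived and checked against central finite
  differences (relative error below $10^{-4}$ at $d = 2$, $L = 1$;
  observed around $10^{-10}$).
* Adam updates run densely over every parameter each step, in place, via
  small C++ kernels; gradient tables are preallocated and only touched
  rows are re-zeroed. Training must therefore own unique parameter
  storage — the fit deep-copies its initialization (an R byte-compiler
  constant would otherwise be silently mutated).
* The single-example memorization check (cross-entropy below 0.01 on one
  pair) uses learning rate 0.01 without decay: under the decaying
  reference schedule the total Adam displacement per scalar is bounded by
  roughly $\sum_t \mathrm{lr}_t \approx 0.02$, which cannot produce the
  logit gap such a loss requires; the check is about optimizer/gradient
  correctness, not about the schedule.
* Problem sizes in the test suite — 400 training pairs, 200 held-out
  combinations, five seeds, pockets of at most 30 residues, random graphs
  of at most 8 vertices — were chosen so the full suite runs comfortably
  on a laptop-class single core while keeping every statistical margin
  wide (e.g. the learnability margin is AUROC $\ge 0.90$ against observed
  values near 1.0).

## Known limitations

* WL fingerprints bound what the branches can distinguish: graphs
  WL-equivalent at radius r are identical to the model.
* Pocket vertex fingerprints at $r = 1$ on real structures are near
  unique per residue environment; without pocket reuse between training
  and prediction the pocket branch degrades to its UNK embedding. This is
  a property of the fingerprint-vocabulary approach itself, visible in
  the modest cross-target accuracies such models reach on real
  benchmarks.
* The additive head cannot express compound-pocket interactions beyond
  what each branch encodes separately; it ranks conjunctive rules
  correctly but cannot, for example, represent exclusive-or relations
  between branch features.
* mmCIF input, biological assemblies, protonation and pockets without a
  bound ligand are out of scope; the ligand defines the pocket.
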