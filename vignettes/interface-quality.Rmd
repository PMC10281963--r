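---
title: "Estimating protein-protein interface quality with graph attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating protein-protein interface quality with graph attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifaceqe)
```

## The problem

A docking program or a deep-learning complex predictor emits tens to
hundreds of candidate structural models ("decoys") for a protein dimer.
Selecting a good one requires an estimate of how well each model's
interaction interface matches the (unknown) native interface. `ifaceqe`
estimates that quality from a single model structure — optionally
supplemented by sequence alignments — without access to the native.

## The model

**Interface graph.** Two residues on opposite chains interact when their
Cβ atoms (Cα for glycine) are strictly within 10 Å. The interface is the
graph `G = (V, E)` whose nodes are the residues taking part in at least
one such pair and whose edges are the pairs themselves. Only inter-chain
edges are included: the method scores the *interaction* interface, and the
intra-chain environment enters through the node features instead. (Whether
intra-chain edges between interface residues would help is untested here;
the graph builder exposes only the inter-chain form.)

**Node features (17).** Per interface residue:

* residue-class one-hot (5): polar {S,T,N,Q,C,Y,W}, non-polar
  {A,V,L,I,M,F,P,G}, positively charged {K,R,H}, negatively charged {D,E},
  and a fifth bin for anything non-standard. The partition is a standard
  physicochemical grouping; it is an argument of
  `encode_residue_class()` should a different table be preferred.
* relative position (1): the residue's 1-based index divided by its *own*
  chain length, in (0, 1].
* secondary structure (3) and burial (2) one-hots: 8-state assignments are
  grouped as {H,G,I} → helix, {E,B} → strand, everything else → coil, and
  relative accessible surface area below 0.25 counts as buried. A DSSP
  output file may be supplied; otherwise an internal torsion-window
  assignment and a Shrake–Rupley accessibility computation (golden-spiral
  sphere sampling, Sander–Rost per-residue maxima) keep the pipeline
  self-contained. The two sources agree on the 3-state/2-state labels in
  typical cases but are not bitwise-identical; the fallback is the default.
* backbone geometry (4): sin and cos of φ and ψ. An undefined angle (chain
  terminus or break) encodes as (0, 0), which no real angle can produce.
* evolutionary depth (2): the normalized effective sequence count
  Neff/√L of the residue's monomer alignment, and of the paired
  (row-concatenated) alignment of both chains. Neff is the sum over rows
  of 1 / (number of rows with identity > 80% to that row, including
  itself); identity is the count of positions where both rows carry the
  same non-gap residue, divided by the query length. Gap handling
  conventions vary in the literature; this one is pinned by tests and the
  threshold is an argument.

**Edge features (27).** Per interacting pair: a 17-bin one-hot of the
Cβ–Cβ distance — sixteen half-open 0.5 Å bins covering [2, 10) plus a
17th catch-all for sub-2 Å clashes, so sterically impossible decoys remain
scoreable — and sin/cos of five inter-residue orientation angles. With
`CA→CB` unit vectors on both residues (glycine receives a virtual ideal
Cβ so the direction exists; its *distance* still uses Cα):

* `Ω = dihedral(CA1, CB1, CB2, CA2)` — symmetric torsion about the
  Cβ–Cβ axis;
* `τ12 = dihedral(N1, CA1, CB1, CB2)` and `τ21` with the roles swapped;
* `λ12 = angle(CA1, CB1, CB2)` and `λ21` swapped.

Swapping the residue order leaves Ω unchanged and exchanges the τ and λ
pairs; all five are invariant to rigid motion of the complex. Degenerate
collinear geometry encodes as (0, 0).

**Network.** Four multi-head attention layers (4, 4, 4 and 1 head; per-head
widths 32, 16, 8, 4 — a hidden size of 32 halved at each layer). Per
directed edge and head, the destination and source nodes are each
concatenated with the static edge features and linearly embedded
(`z = W [h ‖ e]`); an attention logit is a learned linear function of the
two embeddings passed through a leaky rectifier (slope 0.2) and normalized
by softmax over each node's incident edges; the node update is the
attention-weighted sum of source embeddings. Heads are concatenated.
Edge features are not updated across layers.

Two activation choices were genuinely open and deserve comment:

* Intermediate node updates use ELU, the customary choice for this family
  of attention networks. The output layer is *linear*: the per-edge score
  is the logistic-squashed dot product of the two endpoint embeddings, and
  a rectifying output layer would force all dot products non-negative —
  every edge score would then exceed 0.5 and labels below 0.5 would be
  unlearnable.
* The output layer's Xavier weights are scaled by 0.1 at initialization
  (`gat_init(output_scale=)`). Unscaled, the raw features (the Neff
  entries are of order 5–7) drive initial dot products to ±30–40, deep in
  the logistic tails where the squared-error gradient vanishes and
  training stalls at whatever the initialization happened to produce.

The overall quality score is `Q = mean(edge scores)` in [0, 1]; larger is
better. A model whose ligand sits too far from the receptor to form any
edge at all receives `Q = 0` by convention (an absent interface is a
maximally wrong interface); `build_interface_graph()` raises a typed
`empty_interface` condition so callers can choose differently.

## Training

The ground-truth label of an edge compares the model and native distances
of the same residue pair (matched by chain and sequential index, with a
95% sequence-identity guard):

`z = 1` if both are under 10 Å, else `z = 1 / (1 + ((d_model −
d_native)/d0)^2)` with `d0 = 10` Å. Since every edge has `d_model < 10` by
construction, the first branch is effectively `d_native < 10`.

Training minimizes the sum (not mean) of squared errors between the
squashed edge scores and `z`, one Adam step per graph (learning rate
0.001, weight decay 0.0005), for at most 500 epochs with early-stopping
patience 40. A fraction of *targets* (default 10%, 20% in the reference
study) is held out; splitting at the target level prevents decoys of one
complex from leaking between sets.

**Model selection.** When per-decoy DockQ values are available (always, in
the synthetic study), the validation criterion is `1 − Spearman(Q, DockQ)`
over the held-out decoys — the ranking objective the estimator is
ultimately judged on — rather than the summed validation regression loss.
Both curves are logged. The regression loss reaches its minimum within a
handful of epochs and then rises: the dominant `z = 1` edges push scores
into the logistic tails, which inflates squared error while ranking
ability is still improving, so loss-based selection systematically returns
an under-trained model. Decoys without an interface enter the validation
ranking with their conventional `Q = 0`.

## Evaluation

Ground truth is DockQ: `( Fnat + 1/(1+(LRMS/8.5)^2) + 1/(1+(iRMS/1.5)^2) ) / 3`.

* `Fnat`: fraction of native inter-chain residue contacts (any heavy-atom
  pair under 5 Å, over whichever atoms the structures carry — backbone
  plus Cβ for typical decoys) reproduced in the model.
* `LRMS`: ligand backbone RMSD after superposing on the receptor backbone
  (Kabsch/SVD, proper rotation).
* `iRMS`: backbone RMSD over the native-interface residues (any
  cross-chain Cβ/Cα pair within 10 Å in the native), superposed on exactly
  those residues.

CAPRI classes follow the standard thresholds (incorrect < 0.23 ≤
acceptable < 0.49 ≤ medium < 0.80 ≤ high), with "acceptable" inclusive at
0.23. Ranking quality is reported as the top-N success rate SR(N) (percent
of targets with ≥1 acceptable decoy in their top N by predicted score),
the top-N hit rate HR(N) (percent of all acceptable decoys captured in
per-target top-N lists), pooled Spearman ρ against DockQ, and ROC-AUC for
separating acceptable from incorrect decoys; ties rank stably in input
order, and AUC counts ties half (Mann–Whitney). `minmax_normalize()`
implements the per-target (X − Xmax)/(Xmin − Xmax) rescaling used to put
raw energy scores on the same higher-is-better [0, 1] scale.

## The synthetic study

`synthetic_spec()` defines the package's reference conditions: 20 dimeric
targets with two 40–60 residue chains, 30 decoys each, 50-row alignments
mutated at 35% per position, and six rigid-body perturbation levels cycled
over the decoys — from (≤2°, ≤0.5 Å), which keeps DockQ above ~0.95, to
(90–180°, 15–30 Å), which destroys the interface — plus 0.05 Å Gaussian
backbone jitter. Natives are self-avoiding ideal-geometry backbones
(alternating helical and extended segments with randomized turns) docked
along a random approach direction until the closest Cβ pair reaches 4 Å,
accepted when at least ten residue pairs fall within 8 Å. Median DockQ
decreases strictly across the levels and the acceptable fraction is about
0.6, so ranking, success/hit rates and ROC analysis are all exercised.
The mean edge label of a decoy correlates with its DockQ at ρ ≈ 0.86–0.88
across the bundle, tying the training signal to the evaluation ground
truth.

What the generator does *not* emulate: side chains beyond Cβ, physically
realistic docking energetics, flexible-backbone deformation, sequence
conservation structure in the alignments (mutations are uniform), and the
target diversity of real benchmark sets. Passing the synthetic study shows
the pipeline is internally consistent and that the network can learn
transferable interface-geometry signal at small scale; it does not certify
performance on real docking decoy sets.

### What the reference study achieves, and its limits

On the reference bundle (an 80/20 target split, three seeds) training
typically reaches held-out pooled Spearman ρ in the 0.4–0.7 range with
ROC-AUC around 0.68–0.82; run `scripts/acceptance.R` to reproduce the
numbers for a given seed. Two facts frame those values. First, an oracle
that predicts each edge's true label perfectly would achieve pooled
ρ ≈ 0.9 on every split, so the ceiling is high. Second, with only 16
training targets the network can lower its training loss fastest by
memorizing each training target's native contact map (training-set ρ
reaches ~0.87 while held-out ρ lags far behind); the same architecture
trained on two orders of magnitude more targets does not have that
shortcut to the same degree. The spread across seeds is therefore wide,
and the median sits near the middle of that range. Feature-noise
augmentation and input standardization were evaluated and did not improve
transfer; they are not part of the method.

## Numerical choices

* Attention logits are clamped to ±50 before exponentiation (gradient zero
  outside) purely as an overflow guard; the clamp is inactive in ordinary
  training.
* The dihedral convention follows IUPAC signs; tests pin it against an
  independent projection-formula implementation and against the handedness
  of the ideal Cβ construction (bond 1.522 Å, angle N–CA–CB 110.4°,
  dihedral C–N–CA–CB −122.6°).
* Shrake–Rupley accessibility uses 192 sphere points by default (92 in
  bulk featurization, 960 in test oracles); at 192 points per-residue
  relative accessibility is converged to well within the 0.25 burial
  threshold's granularity for these chain sizes.
* The training loop runs one graph per optimizer step (graph sizes vary
  widely); an epoch is a shuffled pass over all decoys. The compiled
  attention kernel (`src/gat_core.cpp`) reproduces the base-R reference
  path to machine precision — the test suite asserts it — and exists only
  for speed.
* Problem sizes in the tests: unit tests run on 3–5 target bundles with
  8–18 decoys; the acceptance study uses the full 20 × 30 reference
  conditions.

## Known limitations

* Dimers only; higher-order assemblies are out of scope.
* Decoys must share their native's chain order and (95%+) sequence;
  correspondence is positional, not an alignment.
* The paired-alignment Neff is taken from a supplied coupled alignment;
  the package does not construct species-paired alignments itself.
* `Q` compresses near 1 for good decoys (most edge labels are exactly 1
  there), so resolution among near-native models is limited — a property
  of the label definition, not of the implementation.
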