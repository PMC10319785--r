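---
title: "Predicting collision cross sections from molecular graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting collision cross sections from molecular graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Ion mobility spectrometry separates ions by their mobility through a
buffer gas, summarised by the collision cross section (CCS, in Å²): the
orientation-averaged effective area an ion presents to the gas. Measured
CCS values are a powerful extra dimension for metabolite and lipid
identification, but experimental libraries cover only a small fraction of
chemical space. `graphccs` predicts CCS directly from molecular structure,
so that in-silico CCS libraries can be generated for any compound
collection and used for multidimensional (m/z, retention time, CCS)
candidate filtering.

## The model

A molecule is represented as a graph built from a single 3D conformer.
Each atom contributes a node attribute vector with six blocks, in a fixed
order: element one-hot over the 13 supported elements (C, H, O, N, P, S,
F, Cl, Br, I, Co, As, Se), degree, radius, mass, an in-ring flag, and the
centroid-centred Cartesian coordinates — 20 features in the default
configuration. Each bond contributes two directed edges carrying a one-hot
over the four bond types (single, double, triple, aromatic).

Node features are transformed by edge-conditioned graph convolution (ECC)
layers. Layer output for atom *i* is

    x_i' = x_i W + sum_{j in N(i)} x_j MLP(e_ij) + b

where the filter MLP maps the 4-dim bond attribute to an Fin × Fout
matrix, so that the message a neighbour sends depends on the bond type
connecting it. The root term `x_i W` plays the role a self-loop would,
and self-loops are therefore excluded from the neighbour sum. Every layer
uses ReLU activations. After the last ECC layer, global sum pooling adds
node features across the node dimension to give a fixed-length molecular
representation **p** (length 16 in the reference architecture, which uses
3 ECC layers of width 16).

The adduct ion type determines how a neutral molecule appears in the mass
spectrometer and shifts its CCS. The three most common electrospray
adducts are supported and one-hot encoded — [M+H]+ → (1,0,0),
[M+Na]+ → (0,1,0), [M−H]− → (0,0,1) — and concatenated with **p**. The
fused 19-vector passes through a stack of fully connected ReLU layers
(8 in the reference architecture, geometrically tapering widths) and a
final ReLU output unit producing the CCS in Å². Training minimises the
mean squared error with Adam; L2 regularisation applies to ECC and FC
weights but not to the output layer.

## Conformers

3D conformers are generated by distance geometry with experimental-torsion
knowledge (ETKDG) and minimised with the MMFF94 force field (RDKit
backend, batched). The embedding is seeded and bit-deterministic: the same
molecule and seed always give the same coordinates. SMILES
interpretation, aromaticity perception and canonicalisation use Open
Babel; ring membership is derived from the bond graph (an atom is in a
ring iff it has an incident non-bridge edge). One conformer per molecule
is used — conformer-ensemble averaging is out of scope — and coordinates
are fed to the network raw (centred but not rotation-normalised); the
rotation-robustness analysis below measures, rather than enforces,
orientational invariance.

## Curation and evaluation

Raw CCS tables are cleaned in five ordered steps: (1) SMILES verification
(unparsable strings, unsupported elements), (2) adduct selection (the
three supported types), (3) collapsing duplicate (molecule, adduct)
entries to their median CCS, (4) dropping molecules whose conformer
generation fails, and (5) outlier removal. The outlier rule fits a robust
linear CCS ~ m/z trend per adduct (`MASS::rlm`) and drops records whose
residual exceeds `k` MADs (`k = 5` by default, applied only when a group
has at least 8 labelled records); the rule is deliberately simple and
transparent, and `k` is exposed. Splitting is random at the entry level by
default, with a molecule-level option that keeps every canonical SMILES in
one partition.

Performance is reported as R² (1 − SS_res/SS_tot), median relative error
(median of |pred − obs|/obs × 100%) and RMSE (Å²).

## Synthetic data and the CCS oracle

Because experimental CCS collections cannot be shipped, the package
includes a generator that emulates one. Molecules are drawn as random
bonded trees over a C/N/O/S-weighted palette (3–10 heavy atoms by
default), with optional ring closures (probability 0.4) and double bonds
(0.15 per bond), serialised to SMILES, parsed and embedded like any other
input. Labels come from a deterministic physics-shaped oracle in the
projection-approximation family: the area of the union of projected
atomic disks (van der Waals radius + 1 Å probe), averaged over a
low-discrepancy set of 256 orientations (Halton-sequence quaternions with
a seeded Cranley–Patterson shift), each estimated by a stratified jittered
48 × 48 grid over the bounding square. To this area a fixed per-adduct
offset is added (+0 for [M+H]+, +4 for [M+Na]+, −2 Å² for [M−H]−; values
arbitrary but fixed, giving the network a learnable adduct effect) plus
Gaussian noise of 1.5 Å², roughly the 2–3% inter-laboratory spread of
experimental CCS measurements. m/z is computed from the atomic masses and
the adduct mass shift (+1.00728, +22.98922, −1.00728 Da).

The oracle is *not* a trajectory-method calculator: it ignores
long-range interactions, charge placement and temperature. What it shares
with real CCS is exactly what the tests rely on: rotation invariance (to
within Monte-Carlo error, <1% at 256 orientations), strict monotonicity
under adding non-overlapping atoms, a strong CCS–mass correlation
(Pearson r ≈ 0.9 on default settings), and a closed form on single
spheres (πr²) used for calibration. Passing the synthetic learnability
test therefore shows the architecture can learn a geometry-determined,
adduct-shifted target from molecular graphs — it does not certify
accuracy on experimental data, which requires training on a measured
collection supplied by the user.

## Scaled study conditions

The packaged experiments run a scaled-down configuration chosen to train
in minutes on one CPU: 500 molecules (400 train / 100 held out at the
molecule level, 3 adduct records each), 2 ECC layers of width 8, an
edge MLP with 32 hidden units, FC widths 32/16/8, Adam at learning rate
1e-2 decaying ×0.3 every 400 epochs, batch size 32, up to 800 epochs
with early stopping (patience 120 epochs on validation MSE). Because
networks this small are sensitive to initialisation, training runs 3
independent restarts (consecutive seeds) and keeps the one with the
lowest validation MSE — the same validation-based selection one would
apply when training several models per configuration. Under these
conditions the model reaches R² ≈ 0.83–0.90 and median relative error
≈ 5–6% on held-out molecules across seeds. The reference (full-size)
architecture is available as `model_config()` for users with real
training collections.

Training uses manual backpropagation through the ECC and FC stack over
sparse disjoint-union batches; gradients are verified against central
finite differences in the test suite. Minibatch membership is drawn once
per run from the config seed; all randomness (initialisation, shuffling,
splits) funnels through that seed, so runs are exactly repeatable. The
output unit's bias starts at the mean training CCS so the ReLU output is
active from the first step.

## Interpretation

Feature importance uses inference-time masking: one node-attribute block
at a time is zeroed (on the standardised scale — continuous features are
standardised with training-set statistics stored in the checkpoint, so
zero is the neutral value) and the increase in error over the unmasked
baseline is recorded; negative drops are clipped at zero and the drops
normalised to percentages. Masking at inference, rather than retraining
per mask, matches the "masked model vs original model" comparison and
keeps the analysis cheap; like all masking analyses it measures what the
trained model uses, not what is theoretically sufficient, and correlated
blocks can shadow one another. Rotation robustness predicts one molecule
under uniformly random SO(3) rotations (quaternion sampling) and reports
the spread; the oracle's own rotation invariance (<1%) is the reference
against which the model's coefficient of variation is judged. The pooled
16-dim representations can be exported with ring counts and metadata for
external 2-D embedding (e.g. UMAP); the embedding itself is out of scope.

## Identification by multidimensional filtering

Given a query (observed m/z, optionally RT and CCS) and a candidate
library, filtering proceeds in three nested stages: an m/z window in ppm
(MList), an absolute RT window (RList), then a relative CCS window
(CList). Surviving candidates are ranked by a fused score,
`1 − Σ w_d·|err_d|/tol_d / Σ w_d`, with equal weights by default —
monotone non-increasing in every error dimension; ties break on smaller
m/z error, then identifier, so rankings are deterministic. Entries or
queries lacking a dimension pass that stage unfiltered and contribute
zero to the score. Default windows are 10 ppm and 3% CCS; the CCS window
should be ~3× the model's median relative error (hence 20% for the scaled
synthetic model). Recall@k is the percentage of queries whose true
identifier ranks in the top k.

## Numerical choices and degenerate inputs

Graphs with a single atom have no edges; the ECC neighbour sum is then
empty and the root term alone feeds pooling. Empty graphs, empty
libraries and empty evaluation sets raise typed errors rather than
returning NaN. The checkpoint format is plain JSON at full precision
(round-trip error < 1e-7 on predictions) with an md5 manifest; a schema
version field guards against silently loading incompatible checkpoints.
Conformers whose bonded-atom distances collapse below 0.1 Å are treated
as minimisation failures; curation drops such molecules, prediction mode
flags them. Rotation matrices are validated to 1e-8 (orthonormality and
det +1).

## Known limitations

- The oracle omits every physical effect beyond hard-sphere projection;
  absolute synthetic CCS values are not comparable to experiment.
- Only three adduct types are supported; extending the one-hot requires
  retraining.
- The scaled study uses small molecules (3–10 heavy atoms); behaviour on
  large lipids/peptides is untested here and predictions at or above
  ~380 Å² are flagged as outside the training domain.
- Retention-time prediction is out of scope; RT values in the filtering
  stage are inputs.
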