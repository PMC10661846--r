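---
title: "Methods: dual-graph networks for Minisci reaction screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-graph networks for Minisci reaction screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Minisci-type C–H alkylation couples an electron-deficient N-heteroarene
with an alkyl radical generated by oxidative decarboxylation of a
carboxylic acid (ammonium persulfate oxidant, DMSO, 40 °C under nitrogen
in the plate protocol modeled here). It is a workhorse of late-stage
functionalization (LSF), but whether a given drug-like substrate will
react — and how well — is hard to anticipate from rules alone.
`miniscreen` implements a machine-learning screening pipeline around this
reaction: a dual-graph neural network predicts the reaction yield and the
binary reaction outcome for a (substrate, acid, conditions) triple, an
ensemble of such models scores whole building-block libraries in silico,
and fingerprint clustering turns the scores into a structurally diverse
substrate selection for experimental follow-up.

Two conventions run through the package: yields are percentages in files
and reports, and fractions in `[0, 1]` inside the model (the conversion
happens once, at dataset assembly); a reaction counts as *successful* when
the combined yield of all alkylation products reaches the 5% LCMS
detection threshold. The combined yield is the sum of the product yields
(the two mono-alkylation regioisomers and the di-alkylation product are
all productive outcomes), capped at 100%.

## Model

Each reactant is featurized as a molecular graph with explicit hydrogens.
Atoms carry four features: a 12-symbol element type (H, C, N, O, F, P, S,
Cl, Br, I, Si, Se — anything else is rejected, not bucketed), a ring flag,
an aromaticity flag, and a 4-state hybridization (sp3, sp2, sp, s). In 3D
mode a single conformer is embedded by seeded distance geometry and
relaxed with the universal force field (UFF) via an RDKit helper; edges
connect every atom pair within 4 Å, and each edge carries Fourier features
of its length,

    [sin(k π r / r_max), cos(k π r / r_max)],  k = 1..K,

with `K = 16` and `r_max = 4 Å` by default. In 2D mode the edges are the
covalent bonds and the distance features are omitted; node features are
identical between modes.

The network applies a shared atom-feature embedding (the only weights
shared between the two molecular towers), then per tower an input MLP and
three message-passing layers

    h_i' = φ( h_i, Σ_{j ∈ N(i)} ψ(h_i, h_j, r_ij) ),

where ψ and φ are 2-layer MLPs with SiLU activations and the sum over the
neighborhood is the permutation-invariant pooling operator. The states of
all three layers are concatenated, transformed by an MLP, and pooled to
one vector per molecule by a multiset-transformer-style attention block
(per-head learned scores, softmax within each molecule, attention-weighted
sums of per-head value projections; 4 heads by default). Reaction
conditions are encoded as one-hot/indicator blocks over learned
vocabularies (reagents, solvents, catalysts, additives, atmosphere) with
parallel amount blocks (equivalents, solvent fractions) plus standardized
scalars (equivalents of both reactants, temperature, time, concentration),
and transformed by an MLP. The two molecular vectors and the condition
embedding are concatenated and mapped by a final MLP (first layer 256
units by default) to a single sigmoid output in `[0, 1]` — the predicted
yield fraction, or the success propensity for the binary task. Both tasks
are fit as regression problems: L1 loss for yield, binary cross-entropy on
the logit for the outcome.

Default dimensions are 128 (internal), 64 (embeddings), 256 (first fusion
layer), which puts the default architecture at just under one million
trainable parameters (order 10^6, the scale at which such reaction models
are typically run). `count_parameters()` reports the exact count
and a per-component breakdown.

### Design points the architecture leaves open

Several internals are genuinely open design choices; the package makes
them and documents them as its own:

* **Fourier convention.** Frequencies `k π / r_max` with `K = 16`; the
  encoding is bounded in `[-1, 1]` and resolves sub-Å differences over the
  4 Å edge range. Learned frequencies would also fit the description; the
  fixed grid is simpler and testable.
* **Self-edges** are excluded: the radius test applies only for `i ≠ j`.
* **Layer concatenation** covers `[h¹, h², h³]` and excludes the input
  state `h⁰`.
* **Pooling internals.** One seed query per head, scores scaled by a
  learned per-head vector, heads concatenated — a minimal multiset
  transformer. The head count is configurable (2 and 4 are both sensible
  for a 128-dimensional state); 4 is the default, and the parameter count
  is within the same order either way.
* **MLP depth/activation**: 2 layers, SiLU, everywhere.
* **Output range** is enforced by a sigmoid for both tasks.
* **Base-rate output initialization.** The final bias starts at the logit
  of the training-target mean. Without it, the sigmoid output can saturate
  near 0 under the L1 loss (the gradient through the sigmoid vanishes) and
  training stalls; with it, optimization is stable at the default learning
  rate (Adam, 1e-3).
* **Binary threshold** 0.5 on the propensity for confusion counts.

## Data handling

SURF (Simple User-friendly Reaction Format) tables are tab-separated with
one reaction per row. Because the public schema's exact headers vary, the
reader goes through a *dialect* — a mapping from internal field names to
file columns, with numbered column families for entity lists
(`reagent_1_name`, `reagent_1_equivalents`, …). Unknown columns ride along
as opaque payload and are restored on write, so `write_surf()` followed by
`read_surf()` is the identity on validated records. Malformed SMILES and
outcome flags that contradict the stored yield are *reported* (in the
`problems` attribute), never silently fixed or dropped. Decoy records —
reactions of substrates that cannot undergo Minisci chemistry because they
contain no (hetero)aromatic ring — are generated as the full
substrate × acid grid with zero yield; the aromaticity check is enforced,
not assumed.

## Synthetic data: what it emulates, and what it does not

The generator (`synth_spec()`, `generate_dataset()`) produces SURF data
with the reactivity structure observed on the screening plates: per-class
mean yields of 44% (meta-unsubstituted pyridines), 20% (meta-substituted),
2% (five-membered N-heterocycles) and 0 (decoys) on the substrate side,
and 40% (cyclic ethers), 42% (cyclic alkanes), 8% (Boc-protected amines)
on the acid side, with 30% adopted for n-alkyl acids, for which no class
mean is established. A record's true yield is multiplicative,
`clip(μ_sub · μ_acid / μ̄ + ε, 0, 100)` with `μ̄` the mix-weighted mean
acid effect and ε Gaussian with σ = 10% (a single noise scale chosen once,
between the observed per-class spreads of ±1 and ±15%). Substrate-class
marginals therefore match the planted means exactly; acid marginals follow
up to the multiplicative coupling, and `expected_class_means()` gives the
closed-form truncated-normal expectations for both, which the tests use as
an independent oracle. Templates are small curated sets (≈10 SMILES per
class; 16 decoys; a 23-acid panel spanning the four acid classes on 24-well
plate positions with B4 left for the reference reaction) — representative
structures, not any proprietary library.

What the generator does *not* emulate: condition variability (plates run
under one fixed condition set, so the condition encoder sees constant
input in synthetic training), electronic substituent effects within a
class, regiochemistry, LCMS artifacts, plate-position effects, and the
long tail of structural diversity in a real corporate library. Passing
tests on synthetic data therefore demonstrate that the pipeline learns and
recovers class-level reactivity structure from graph inputs, not how it
would score on real HTE plates: real Minisci data are harder (yield MAEs
around 15–20% and binary accuracies near 80% are typical for models of
this class on hundreds of reactions), while the cleaner synthetic
structure is learned to considerably better metrics. Numbers computed here
on generated data should never be read as real-data claims.

## Problem sizes and numerical choices

Training runs entirely on a small reverse-mode automatic-differentiation
engine over dense matrices written for this package (`R/autograd.R`), with
hand-written Adam; gradients are verified against central finite
differences in the test suite to < 1e-7. The package's working scale was
chosen for single-CPU practicality: screening-scale models use a hidden
dimension of 32 (≈110k parameters), minibatches of 48–64, and 6–15 epochs;
the acceptance workflow trains the 3 + 3 ensemble on an experiment-scale
set of 691 synthetic reactions and the recovery model on 1000. The default
`gtnn_config()` keeps the full-size 128/64/256 dimensions for architecture
reporting and parameter counting. Inference is chunked (64 reactions at a
time) so edge-level intermediates stay small during library screens.

Other numerical details: solvent fractions must sum to 1 within 1e-6;
Pearson r on a zero-variance vector is reported as `NA` with a warning,
never as 0; yield-bin boundaries (1, 11, 35) fall in the lower bin;
selection ties break lexicographically on canonical SMILES and are logged;
clusters smaller than `k_per_cluster` contribute all members with a
warning; empty fingerprints get Jaccard similarity 0 with a warning while
the diagonal of non-empty fingerprints is exactly 1. Agglomerative
clustering uses average linkage on `1 − Jaccard`; sphere exclusion is
greedy in input order, so its labels are deterministic given the library
order. ECFP4 fingerprints are radius-2 circular fingerprints folded to
4096 bits by the OpenBabel backend. Conformer generation is deterministic
given (SMILES, seed): the distance-geometry embedding takes an explicit
random seed and the UFF relaxation is deterministic, so graphs are
bit-reproducible across runs and the seed is recorded in every graph.

Hybridization is perceived from the SDF bond table: hydrogens are `s`;
atoms with a triple bond or two double bonds are `sp`; atoms with a double
bond or in an aromatic ring are `sp2`; all else `sp3`. This is a
deliberate perception rule of this package (the toolkit bindings expose no
per-atom hybridization); it matches the four supported states and fails
loudly for nothing — elements outside the vocabulary fail instead.

## Limitations

* No experimental HTE reaction tables are shipped; all end-to-end numbers
  in the tests and the acceptance report are computed on the synthetic
  generator at realistic plate-campaign scale (hundreds of reactions, a
  23-acid panel, 16 decoy substrates).
* Cluster exclusion before substrate selection (removing clusters of
  heterocycles without free C–H bonds) is a manual/config decision in real
  use; the acceptance workflow stands in for it by excluding the two
  lowest-scoring clusters.
* No regioselectivity or mono/di-ratio prediction; no partial-charge node
  features in the default path (a feature hook exists but no charge
  computer is attached, matching the finding that charges did not improve
  performance); no multi-conformer averaging; no equivariant coordinate
  updates — messages are invariant functions of inter-atomic distances.
* Pure-R training is practical to hidden dimension ≈64 and a few thousand
  reactions; beyond that, expect hours, not minutes.
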