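---
title: "Modeling macrocycle membrane permeability with macroperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling macrocycle membrane permeability with macroperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Passive membrane permeability is a gating property for oral macrocyclic
drugs, and the experimental record for it is noisy: the same compound
measured by different laboratories, or in different assay systems (PAMPA,
Caco-2, MDCK, RRCK), routinely disagrees by several tenths of a -log10
Papp unit, and a sizeable fraction of replicate pairs even disagree about
which side of the standard 1e-6 cm/s decision threshold a compound falls
on. macroperm implements a modeling stack built around that reality:

1. **Noise-aware curation.** Records are canonicalized and deduplicated by
   InChIKey within assay, and labeled by a *swing range*: measurements
   inside the half-open window `[center - h, center + h)` around the
   decision threshold (`center = 6` in -logP units, i.e. Papp = 1e-6 cm/s)
   are excluded as unreliable rather than forced into a class. Widening
   `h` trades dataset size for label fidelity.
2. **Leakage-free evaluation.** Cross-validation folds are assigned to
   structural units — exact canonical structures, Murcko scaffolds, or
   fingerprint clusters — so near-duplicates never straddle a
   train/validation boundary.
3. **A mixture-of-experts graph model (the Macro_PP architecture).** A
   message-passing encoder summarizes the molecular graph; its embedding,
   a physicochemical descriptor block, and ECFP/MACCS fingerprints each
   feed an expert network, combined by a softmax gate into one
   permeability logit.
4. **Knowledge distillation (the Multi_DDPP architecture).** A teacher is
   trained on the large pooled multi-assay set (assay identity as a
   one-hot global feature); its temperature-softened probabilities are
   cached for the task molecules, and the task-specific student minimizes
   `L = L_true + lambda * L_soft`.
5. **Interpretability.** Node-feature-channel masking measures how much
   each input channel (hydrogen-bond donors, lone pairs, large-ring
   membership, ...) contributes to held-out loss, and a conformer-ensemble
   geometry module quantifies polar exposure (Shrake-Rupley SASA of donor
   groups, intramolecular hydrogen bonds) for the most confidently
   classified molecules.

## Models and conventions

### Swing labels

`mp_swing_label()` excludes the half-open interval `[c - h, c + h)`; the
boundary choice mirrors the usual way the window is written
(`5.5 <= -logP < 6.5` at `h = 0.5`). With `h = 0` no record is excluded
and the threshold itself falls on the permeable side. The permeable class
is by default the low--logP (high-permeability) side; the literature also
contains the opposite bookkeeping ("-logP >= 6 as positive"), so
`label_direction = "inverted"` swaps the classes rather than guessing
intent.

Replicate agreement is summarized by `mp_pair_deviation_stats()`: the
fraction of pairs within `delta` (boundary counted as within, to numerical
tolerance) and the fraction straddling the threshold.

### The message-passing encoder

Node features X and bond features E are built by `mp_mol_graph()` on the
heavy-atom graph (hydrogen counts are explicit per-atom features). One
round computes, for every directed edge (u, v),

    m_uv = MLP(e_uv + x_u + x_v)          (concatenation)
    m_v  = sum over incoming edges of m_uv
    e_uv <- MLP(e_uv + m_uv)
    x_v  <- MLP(x_v + m_v)

followed after T rounds by a mean (default) or sum readout. This follows
the update rule as commonly printed — undirected per-edge messages summed
over neighbors — rather than the canonical directed variant that excludes
the reverse edge from the edge-update context; `directed_exclusion = TRUE`
provides that variant. An identity test mode replaces every MLP with
identity-on-concatenation so rounds are hand-traceable and are checked
exactly against a brute-force edge-dictionary oracle in the test suite.

The pooling operation is not standardized in the literature; the package
defaults to the mean so embeddings are size-stable across the 12--21-atom
ring range, with sum available. Hidden width 300 and T = 3 are
conventional defaults; every analysis in this package's tests and
acceptance script uses deliberately smaller models (hidden 8--16, T = 2),
which are stated alongside each result.

### Node feature schema

The exact channel inventory used by the original implementation is not
fully public, so the schema here is reconstructed from the features the
interpretability analysis names — hydrogen-bond donor and acceptor flags,
lone-pair counts, large-ring membership — plus the standard graph-network
atom features (element, degree, charge, aromaticity, hybridization,
chirality, hydrogen count). It is versioned (`mp_feature_schema()`), fully
configurable, and serialized with every checkpoint, so a different channel
list can be swapped in without touching the model code. Two honest
simplifications: chirality and bond-stereo channels exist in the schema
but are populated as "unspecified" for 2D SMILES input, and the
hydrogen-bond-acceptor rule is the plain one (N/O bearing a lone pair).
The `in_large_ring` flag uses a 12-atom threshold, the lower bound of the
macrocycle ring strata (12--15 small, 16--18 medium, >18 large).

Lone pairs follow electron bookkeeping: (valence electrons - formal
charge - heavy-bond orders - attached H) / 2, floored at zero.

### Descriptors and fingerprints

The descriptor family is a fixed 14-vector of interpretable 2D properties
(molecular weight, donor/acceptor counts, ring statistics, rotatable
bonds, aromatic and sp3 fractions, ...) computed from the parsed graph;
descriptors are standardized with training-set statistics only, and
non-finite values are imputed to zero after the fit. Fingerprints are
OpenBabel ECFP (radius 2) OR-folded to 2048 bits and the 166 MACCS keys
stored in the classic 167-slot layout.

### Mixture of experts

Each representation r feeds an expert `e_r = ReLU(W_r r + b_r)`; the gate
is a linear map of the concatenated representations through a row softmax,
so the weights are a strict probability simplex; the output is the
gate-weighted sum of expert outputs through a linear head. By default each
expert sees only its own representation — the natural reading of
"allocating the input to experts" — while `shared_input = TRUE` gives
every expert the full concatenation (the literal reading of the mixture
equations). With a single graph expert the architecture collapses exactly
to a plain message-passing classifier, which the tests verify
parameter-for-parameter.

### Training

Classification minimizes binary cross-entropy (also the reported metric;
no separate training loss is standard here), regression squared error,
both by Adam (lr 1e-3, batch 32 by default) with early stopping on
validation loss and restoration of the best parameters. All gradients are
analytic and are checked against central finite differences at relative
tolerance 1e-4 in the tests. Runs are deterministic under a seed at a
fixed thread count: initialization, batch order, and validation splits all
derive from the user seed via a stable string hash.

### Distillation

Soft targets are temperature-scaled sigmoids `p(z, T) = sigmoid(z / T)`.
The divergence the original formulation leaves unresolved (its printed
defining equation is self-referential) is chosen as the binary KL
divergence between teacher and student temperature-scaled probabilities
with the standard T^2 gradient compensation; squared distance on logits is
available as `divergence = "MSE_LOGITS"`. Defaults `T = 2`,
`lambda = 0.5` are conventional distillation settings, exposed as required
configuration. Teacher logits are computed once with the teacher frozen;
soft targets exist only for the student's own training molecules. With
`lambda = 0` the student reproduces the plain task fit bit-identically —
the loss and every gradient coincide exactly, and both paths consume the
random stream identically.

### Condition-aware regression

The regressor adds multi-head self-attention over final node states
before readout (scaled dot-product per head, concatenated and projected),
and appends physiological conditions as graph-level global features:
either standardized raw pH/temperature (`"GLOBAL"`) or binned one-hots
(`"ONEHOT"`), in both cases with missingness indicator bits after imputing
pH 7.4 / 37 degrees C.

### Interpretability

Channel importance masks one node-feature channel at a time (zeroing its
columns in every evaluation graph), re-evaluates the loss on held-out
records, and reports the increase over the unmasked baseline, with mean
and sd across evaluation folds. Masking operates on channels, not atoms,
and the analysis is run on the graph-only model: the other experts see
unmasked fingerprints and descriptors and would otherwise absorb the
signal, leaving every channel with a near-zero loss difference.

Geometry: hydrogen bonds require d(H...A) <= 2.5 angstrom and a D-H-A
angle >= 120 degrees, with the acceptor neither the donor nor covalently
bonded to the hydrogen. Shrake-Rupley SASA places a deterministic
golden-spiral lattice (960 points by default; the count is a
reproducibility choice, and lattice error shrinks with it) on each
probe-expanded sphere (probe 1.4 angstrom, Bondi radii) and counts points
outside every other expanded sphere. Donor-group SASA sums the donor
heavy atom and its hydrogens. Conformer ensembles are selected greedily by
ascending energy with a heavy-atom Kabsch-RMSD diversity filter
(`rmsd_min = 0.5` angstrom by default; the original selection thresholds
are unpublished). Conformer *generation* is out of scope by design: the
module consumes multi-record SDF ensembles, so all geometry math runs on
fixture coordinates in the tests.

## The synthetic benchmark

No experimental dataset ships with the package. `mp_make_benchmark()`
generates the study conditions instead: peptide-like macrocycles
(head-to-tail amide-closed sequences of 4--7 residues, ring sizes 12--21,
side chains none/methyl/hydroxyl/carboxyl/benzyl, 30% N-methylation) and
acyclic analogs, with a *known linear* latent permeability

    mu = 2.4 + 0.55 HBD + 0.15 MW/100 - 0.8 hydrophobic_frac - 0.3 macrocycle

chosen so the hydrogen-bond-donor count dominates (mirroring the
established medicinal-chemistry role of donor counts in macrocycle
permeability), the population straddles the -logP = 6 threshold with
roughly balanced classes, and every downstream test has closed-form
ground truth. Measurements add per-assay offsets (Caco-2 0, MDCK +0.1,
RRCK +0.1, PAMPA +0.2 -- small relative to the signal, fixed by
convention) and Gaussian noise (sd 0.4 -logP units). Noise streams are
keyed by a stable hash of (molecule, assay), so enlarging a library never
perturbs existing draws. The reference benchmark sizes are 2000 large-set
molecules across 1--4 assays each and 200 all-macrocycle PAMPA task
molecules, disjoint by InChIKey.

What this emulates — and what it does not. The generator reproduces the
*structure* of the problem (shared latent function, assay heterogeneity,
threshold-adjacent label noise, macrocycle ring strata), not the chemistry
of real membrane permeation: no conformational effects, no chameleonic
polarity burial, and a latent function that is exactly linear in features
the model can see. Passing tests therefore demonstrate that the machinery
recovers planted structure under controlled noise, not that it attains any
particular accuracy on experimental data. One visible consequence: at the
reference sizes both the distilled and the plain student often saturate
the validation ranking (AUC near 1), so the distillation comparison is a
paired non-inferiority check (median of per-seed AUC differences), and the
informative control is a permutation null: replacing the teacher's logits
with a random permutation (same distribution, no molecule-specific
information) at a large soft-label weight (`lambda = 4`) measurably
degrades the student. A teacher *trained* on permuted labels is not a
useful control at this scale — it collapses to the class prior, which
damages calibration but not ranking.

Two further consequences of the design are worth stating plainly. First,
the swing analyses quantify label noise as retained mislabeled records
per *candidate* molecule, which is deterministically non-increasing in the
swing half-width because the exclusion windows are nested; the
alternative normalization by retained records is not monotone in general
(widening the window removes many correctly labeled near-threshold
records, shrinking the denominator faster than the flips in the
mid-width range) and is reported only between the extreme widths. Second,
masking-based channel importance on a fully trained model does *not*
single out the donor flag here, even though the latent function is
donor-dominated: donors are jointly encoded by the element, hydrogen-count
and lone-pair channels, and zero-masking any dense channel perturbs every
atom, so attribution lands on those structural channels. The
importance-recovery analysis therefore uses a planted-dependency design —
the classifier is trained on the donor-flag-only view of the graphs (the
untrained input-weight rows, which hold only initialization noise, are
zeroed afterwards), making its output provably a function of that channel
— and verifies that the masking analysis identifies it on held-out full
graphs. Attribution under redundant schemas is a known limitation of
zero-masking importance, not of the planted check.

## Numerical choices and degenerate inputs

* Probabilities are clamped to [1e-7, 1 - 1e-7] inside divergences; BCE is
  evaluated in logit form for stability.
* MCC returns 0 when any denominator factor vanishes; ranking metrics
  refuse single-class inputs; PR-AUC uses conservative step integration.
* Fold assignment requires k no larger than the number of distinct units;
  SCAFFOLD/CLUSTER folds are balanced by greedy bin-packing of units in
  descending size (ties broken lexicographically after a seeded shuffle).
* Cluster-count selection maximizes mean silhouette width (ties to the
  smaller k) and records whether the within-SSE elbow (maximum second
  difference) agrees; identical points raise an error rather than a
  one-cluster result. The 2D embedding is an in-package exact t-SNE
  (perplexity 30, seeded); clustering in raw fingerprint space is
  available via `cluster_space = "fingerprint"` since the original choice
  of space is ambiguous.
* Empty graphs cannot be encoded; isolated nodes receive zero messages.
* Unknown elements map to the schema's "other" slot (featurization) or
  raise an error (SASA radii), each with an explicit message.

## Problem sizes used by the shipped analyses

The test suite and `scripts/acceptance.R` run the full pipeline at sizes
chosen for a single-CPU workstation: encoder width 8--16 with T = 2,
teacher sets of up to ~5000 records (2000 molecules across assays), task
sets of 200 molecules, 3--5 seed replicates, and 30-epoch training with
early stopping. These are the package's reference conditions; all of them
are plain configuration arguments, and nothing in the code depends on
these particular values.

## Known limitations

* 2D topology only: no conformer-aware featurization, and stereochemistry
  channels are placeholders for SMILES input without annotated stereo
  perception.
* Aromaticity uses a pragmatic Hueckel-style rule on kekulized 5--7 rings;
  exotic aromatic systems may be classified differently than by a full
  perception model.
* Ring perception finds the smallest ring through each independent ring
  closure, which matches SSSR for the chemistry generated here but can
  differ on dense fused polycycles.
* The mixture gate always sees all representations even when the expert
  list is restricted, which is the intended design but worth knowing when
  interpreting gate weights.
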