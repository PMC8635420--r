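---
title: "Methods: knowledge-graph-fused DTI prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-graph-fused DTI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what its tests do and do not
demonstrate.

## The problem

Drug–target interaction (DTI) matrices are extremely sparse, and the
practically interesting regime is extrapolation: scoring pairs that involve
a protein with *no* known interactions (cold start for proteins, e.g. a
newly implicated disease target) or a drug with none (cold start for
drugs). Similarity-based methods struggle there; the approach taken here is
to let a knowledge graph (KG) carry the side information — pathway
membership, disease associations, drug annotations — and to learn from it a
geometry in which unseen-but-annotated entities are already well placed.

## Model

**DistMult embeddings.** Entities and relations are embedded in
$\mathbb{R}^d$ and a triple $(h, r, t)$ is scored
$f_r(h,t) = \sum_i r_i h_i t_i$, the diagonal restriction of RESCAL's
bilinear form $h^\top M_r t$. The diagonal form is symmetric in $h$ and
$t$; for the relation types used here (interaction and association edges)
that symmetry is harmless and buys an order of magnitude in parameters.

The training loss is not uniquely determined by the method's description, so
the package fixes the conventional recipe and documents it: binary logistic
loss of the raw score on positives versus $\eta$ corruptions per positive
(head or tail replaced by a uniform entity, resampled whenever the result is
a known triple — *filtered* corruption), plus an L2 penalty on the
embeddings touched by each batch, optimized by Adam over without-replacement
mini-batches. Initialization is Xavier-uniform from the run seed. There is
no entity-norm projection step; L2 plays that role. `epochs = 0`
deliberately returns the seeded initialization, which the determinism and
leakage tests exploit.

**PCA.** Drug-entity and protein-entity embeddings are reduced by PCA
*separately* — the two families occupy different regions of the embedding
space and mixing them would let the dominant family dictate the components.
Relations are never reduced. Whether the two reduced widths should be equal
is unknowable from the method description; they are independent
hyperparameters (`pca_drug`, `pca_protein`, default 8 each against the
default $d = 32$). Components are sign-fixed (largest-magnitude loading
positive) so a fit is a pure function of its inputs.

**The neural factorization machine.** Each pair becomes one dense instance
$x$: PCA(drug KGE) ‖ PCA(protein KGE) ‖ fingerprint ‖ CTD, with block
offsets recorded in a field spec. Every scalar dimension $i$ owns an
embedding $v_i$ scaled by its value $x_i$; Bi-Interaction pooling sums all
pairwise element-wise products and is computed with the $O(nk)$ identity
$\tfrac12[(\sum_i x_i v_i)^{\odot 2} - \sum_i (x_i v_i)^{\odot 2}]$, which
the tests pin against the $O(n^2 k)$ double sum. One ReLU hidden layer
(default width 32, embedding width $k = 16$) and a linear head produce the
raw score; a logistic link yields the probability demanded by AUROC/AUPR
evaluation. Dropout (default 0.2) is applied to the pooled vector during
training only. Batch normalization of the pooled vector was considered and
rejected: at the batch sizes used here it adds train/predict asymmetry and
seed-sensitive statistics for no measurable gain, and dropout plus L2
already regularize the pooling output. Gradients are hand-derived and verified against central finite
differences to $10^{-4}$ relative error.

**Scaling.** Fingerprint bits and CTD fractions have incompatible ranges,
so structural blocks are min–max scaled with statistics from the training
fold only. KGE/PCA blocks are left unscaled: PCA output is already centered
and variance-ordered.

## Evaluation protocol

Known interactions are positives; negatives are unlabeled pairs sampled
uniformly without replacement at 10 per positive (1 per positive in the
balanced setting), never colliding with *any* known positive — a stricter
exclusion than splitting fold-by-fold, chosen so that no known interaction
is ever labeled negative anywhere. Negatives are drawn per fold and per
side after splitting, so in cold scenarios the test negatives respect the
entity disjointness too. If the candidate pool runs out the sample is
capped with a warning.

Three scenarios: warm (positives shuffled into k folds), cold drug (drugs
partitioned into k groups; all of a test drug's pairs go to its fold's test
side), cold protein (symmetric). In every fold the embedding stage is
retrained on the supporting KG plus *that fold's training positives only*;
`leakage_audit()` intersects the actual training triples with the test DTIs
and the suite requires the intersection to be empty in all scenarios.

AUROC uses the mid-rank Mann–Whitney formulation (ties count ½). AUPR is
the step-wise sum of precision × recall-increment over descending
thresholds with tied scores processed as one block — no interpolation.
Both are pinned to independent oracles at $10^{-12}$. Box-plot summaries
(median, type-7 quartiles, min, max) accompany per-fold values.

Cold entities are, by scope, entities that exist in the KG without DTI
edges. Entities absent from the KG altogether are rejected with an
explicit error rather than scored from nothing.

## Structural featurization

CTD descriptors use the standard seven physicochemical properties, each
splitting the 20 residues into 3 classes (hydrophobicity, normalized van
der Waals volume, polarity, polarizability, charge, secondary structure,
solvent accessibility); the partitions are embedded as data and the
cover/disjointness invariant is enforced at load. Per property:
composition (3), unordered-pair transitions (3), and the positions of the
first, 25%, 50%, 75% and last occurrence of each class divided by sequence
length (15), with the $q$-quantile slot defined as the
$\lceil q \cdot n_g\rceil$-th occurrence and absent classes contributing
zeros — 147 values in all.

Fingerprints are hashed circular substructure bits: SMILES are parsed by
ChemmineR/ChemmineOB, and the package iteratively hashes each atom's
neighborhood (element and degree at radius 0; sorted bond-order/neighbor
invariant pairs at each further radius) into `n_bits` positions (default
radius 2, 2048 bits; the exact bit length is configuration since no
canonical value is mandated). The backend is pluggable and any precomputed
feature table bypasses chemistry entirely, so nothing downstream depends on
a chemistry library being present. A drug with neither SMILES nor a
feature-table row is a hard error — silent zero vectors would corrupt
training.

## The synthetic benchmark

The generator plants a ground truth the pipeline should recover: latent
factors $u_d, u_p$ (i.i.d. normal, scaled to unit inner-product variance)
and interaction probability
$\mathrm{logistic}(\beta \langle u_d, u_p\rangle + \sigma\varepsilon + c)$
with effect $\beta = 2$, noise $\sigma = 1$, and intercept $c$ calibrated so
the expected interaction count matches the configured number of positives —
interactions are sparse, so the logistic model needs a negative bias; the
requested count is then drawn without replacement with these probabilities.

The supporting KG mirrors the composition of real DTI benchmarks: each
protein receives a fixed number of pathway/disease annotation edges chosen
with affinity $\exp(a\,\langle u, u'\rangle)$ toward annotations with
aligned latent vectors (default $a = 3$; $a = 0$ severs the KG from the
signal and is used to show the ablation direction), and the drug-side edge
budget is derived from the protein-related fraction knob, default 0.83 —
the strong protein skew seen in real heterogeneous DTI data. Optional
identifier hubs connect to every protein to exercise centrality pruning;
the audit excludes hub edges from the composition count because they are
injected noise, not information. Protein sequences are drawn with
hydrophobicity-class frequencies tied to the first latent coordinate
(giving CTD real, recoverable signal), and synthetic fingerprints are
deterministic random bits with activation probabilities linked to the drug
latents, so the chemistry backend is not needed in tests.

What the generator does *not* emulate: realistic degree distributions
beyond the composition knob, relation-type richness of curated KGs,
chemically valid molecules, or homology structure among proteins. Passing
tests therefore demonstrate internal correctness and the direction of the
fusion effect under a planted low-rank world, not performance on any real
benchmark.

## Problem sizes and numerical choices

The stochastic acceptance battery runs the full pipeline on a planted
benchmark of 200 drugs × 150 proteins with 1000 positives, 5 seeds, one
fold per scenario per seed — sizes chosen so the battery completes in a few
minutes on a single core while keeping ~100 positives per test fold, enough
for stable AUPR. Unit and property tests use smaller instances (oracle
cross-checks on graphs of ≤ 12 nodes, fold invariants over 100 seeds on a
40 × 30 benchmark).

Degenerate inputs are decided, not left to chance: empty triple files parse
to empty KGs; removing absent nodes is a no-op; betweenness normalization
always divides by the full $(N-1)(N-2)/2$ even on disconnected graphs, and
is defined as 0 for $N < 3$; centrality ranks break ties by entity id;
PCA requires $k \le \min(\text{rows}-1, \dim)$; a corruption request that
has no untrue candidate in either slot errors rather than looping;
single-class training labels are an error. Every stochastic component
(initialization, corruption, batching, dropout, splitting, sampling) draws
from streams derived from one top-level seed, and the RNG state is always
restored, so two runs with one config are byte-identical — which the suite
asserts on serialized fits and written metric files.

Reciprocal/inverse triples are not added before embedding training: the
triple set is taken as stated, and the DistMult score is symmetric anyway.

## Known limitations

DistMult's symmetry makes genuinely asymmetric relations (e.g. directed
regulatory edges) indistinguishable from their inverses. The NFM treats
every scalar dimension as a feature with its own embedding; for very wide
fingerprint blocks this is memory-heavy ($n \times k$ parameters). The
planted benchmark's annotation mechanism is deliberately simple, and the
betweenness normalization convention — while internally consistent — is one
of several in circulation, so absolute centrality values should not be
compared across tools.
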