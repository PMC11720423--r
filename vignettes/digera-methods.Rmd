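---
title: "Methods: rank-based modeling of drug-induced expression and composite screening scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based modeling of drug-induced expression and composite screening scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its methods: the models it
fits, the conventions it fixes where several were defensible, the
numerical choices that affect results, and what its synthetic-data tests
do and do not establish about real data.

## 1. Why ranks, and the rank/tier transformation

Level-5 L1000 signatures report a moderated Z-score per landmark gene.
A Z-score measures deviation from that *gene's own* distribution, so
comparing absolute Z-scores across genes is not meaningful; the relative
ordering of genes within one profile is the robust signal. `digera`
therefore converts each 978-gene Z-score vector to ranks with
`zscore_to_ranks()`:

- rank 1 is the largest Z (most up-regulated). The orientation is a
  convention; this one makes "top-K" language line up with up-regulation.
- tied Z-scores receive the average of the positions they span
  (`rank(-z, ties.method = "average")`), so the rank total is always
  `n(n+1)/2`. Tie-averaging matters in practice because moderated
  Z-scores are often reported at limited precision.

The 11-tier categorization (`ranks_to_tiers()`) bins ranks into up-1,
up-10, up-50, up-100, up-200, their down-side mirrors, and `other`.
Bands are half-open — up-10 covers ranks 2–10 — so every gene gets
exactly one label and band sizes are fixed (1, 9, 40, 50, 100 per side
whenever `n_genes >= 400`). Gene counts below 400 are rejected with the
default cuts because the up and down bands would overlap.

## 2. F1@K and the recall denominator

`score_at_k()` evaluates a predicted ranking against a fixed relevant
set: the true top `relevant_n` genes (direction `up`), bottom
`relevant_n` (`down`), or their union (`updown`, where the predicted set
is the predicted top-K plus bottom-K, 2K items). `relevant_n` defaults
to 200, K ∈ {1, 10, 50, 100, 200}.

Precision@K divides the overlap by the predicted-set size. For
Recall@K several denominators are defensible; we divide by the number of
*retrievable* relevant items, `min(|pred|, |relevant|)` — `k` for single
directions, `min(2k, 2·relevant_n)` for `updown`. Two facts pinned this
choice. First, a perfect prediction should score F1@K = 1 at every K; a
fixed denominator of 200 would cap F1@10 at ≈ 0.095, which also
contradicts the magnitudes (≈ 0.6) this family of models reports in the
literature. Second, at `k = relevant_n` the convention reduces F1@K to
the plain overlap fraction between predicted and relevant sets, which is
the quantity the tier scheme is built around. A consequence worth
stating: under this convention precision, recall and F1 coincide at
every K, so F1@K *is* the top-K overlap fraction.

Ties across the top-K boundary are broken by ascending gene index —
deterministic and documented, so repeated evaluations are identical.

`spearman_rank_similarity()` computes Spearman's ρ directly on the
(already tie-averaged) rank vectors; re-ranking tie-averaged ranks is a
no-op, so this equals the textbook definition. Zero-variance input
returns 0 with a warning rather than `NA`, so batch evaluations of
degenerate predictions never abort. For score composition the similarity
is mapped to [0, 1] as `(ρ + 1)/2` (`gene_rank_score()`), because the
composite scores live on [0, 1]; the mapping is a convention of this
package.

## 3. Preprocessing

`filter_profiles()` drops profiles whose SMILES fails chemical parsing
or whose molecular weight exceeds 800 g/mol (the corpus-level cap;
SMILES *encoding* uses a stricter 600 g/mol cap, see §4).

**Duplicate resolution.** Replicate experiments — identical canonical
SMILES, cell line, dose (µM) and time (h) — are collapsed by
`select_duplicate_representative()`: per gene, take the median rank
across replicates; score each replicate by the number of genes whose
rank sits within `tol` of that median; keep the highest scorer, ties
broken by input order. `tol` defaults to 0 rank units (exact median
agreement after tie-averaging); it is exposed because no canonical
tolerance exists and rank noise scales with replicate count.

**Outlier screening.** `kmeans_outlier_filter()` represents each
profile as its 166-bit MACCS fingerprint concatenated with its rank
vector rescaled to [0, 1]. The rescaling puts the binary and rank blocks
on one scale; at landmark-gene counts the rank block then carries the
larger share of squared Euclidean distance, which is what lets the
screen see aberrant *expression* groups rather than just chemistry.
k-means is run at every k in [2, 10]; a profile is removed when it falls
in a cluster smaller than `min_cluster_frac · n` (default 5%) for the
**majority** of the candidate k. We deliberately do not remove at a
single silhouette-selected k: in plant-and-recover simulations the
silhouette criterion regularly prefers k = 2 (two chemistry
super-groups), which merges a small aberrant group into a large cluster
and misses it entirely, while the aberrant group is cleanly isolated at
most other k. The consensus vote recovered 100% of planted aberrant
profiles with zero false removals across 21 generator seeds; the
silhouette-best k is still computed and recorded in the provenance log.
`min_cluster_frac = 0` disables removal exactly.

**Stratified split.** `stratified_split()` draws
`ceiling(test_fraction · n)` test members per stratum by a seeded
shuffle (per-stratum seeds derived by hashing the stratum label, so
adding a stratum does not reshuffle the others). The ceiling convention
is fixed because it reproduces the reconcilable per-stratum counts of
the production corpus (e.g. 1888 → 378 test, 29,863 → 5973, 709 → 142).
Strata of size 1 are rejected by name.

Every preprocessing step appends one provenance entry
`(step, n_before, n_after, parameters)`; `n_after` of step *i* equals
`n_before` of step *i+1* by construction.

## 4. Chemical featurization

Chemistry runs through OpenBabel (via ChemmineR/ChemmineOB): SMILES
validity and canonicalization, molecular weight, LogP, H-bond
donors/acceptors, SMARTS-counted rotatable bonds, and ring/aromaticity
perception.

- **MACCS (166 bits)** come from OpenBabel's MACCS pattern set (the 166
  keys occupy the first positions of the block OpenBabel returns).
- **ECFP6 / FCFP4 (1024 bits)** are Morgan-style hashed circular
  fingerprints implemented in this package: atom invariants are hashed,
  then iteratively combined with sorted (bond-type, neighbor-id) pairs
  up to radius `diameter/2`, and all environment identifiers are folded
  modulo the bit width. ECFP uses connectivity invariants (element,
  degree, hydrogen count, valence, ring membership, aromaticity); FCFP
  uses pharmacophoric roles (donor, acceptor, aromatic, halogen). The
  hashing is a deterministic 31-bit polynomial hash, exact in double
  precision; bit values are therefore stable across platforms but are
  *not* bit-compatible with other toolkits' ECFP implementations.
- **The 881-bit structural fingerprint** reuses the radius-2 machinery
  plus element counts, folded to the PubChem key width. The width
  matches; the key semantics are this package's hashing, not the PubChem
  dictionary.
- **MFBERT and other pretrained embeddings** enter through a provider
  contract (`register_embedding_provider()`: name, dimension, batch
  embed function). A deterministic hash-based provider ships for tests;
  it carries molecule identity and nothing else, which is exactly what a
  determinism/plumbing test needs and nothing a model should learn from.
- **SMILES one-hot** (`smiles_one_hot()`): character-level encoding
  against a dictionary built from the training corpus (pad, start, end,
  then sorted characters; the production corpus yields 47 entries — the
  size is logged on build, not forced). Fixed length 120 including
  start/end; molecules longer than 118 characters or heavier than
  600 g/mol are rejected. `smiles_decode()` inverts the encoding
  exactly.
- **Molecular graphs** (`featurize_graph()`): hydrogen-suppressed, 63
  binary atom features (44-way symbol one-hot with an "other" slot, 6
  degree, 5 implicit-H, 6 valence, 2 aromaticity) and 8 binary bond
  features (4 type: single/double/triple/aromatic, 2 conjugation, 2
  ring). Implicit hydrogen counts are derived from standard valences on
  the kekulized connection table; a bond is flagged conjugated when it
  is aromatic or adjacent to a double/triple/aromatic bond. Formal
  charges are not modeled — acceptable for the neutral drug-like
  chemistry the pipeline targets, a limitation for zwitterions.
- **Cell lines**: `cell_line_pca()` column-mean-imputes missing gene
  effects, centers, fits PCA on *all* rows of the effect matrix and
  projects the assay lines onto the leading components. Fitting on the
  full panel and projecting is the only reading under which more
  components can be kept than there are assay lines (the production
  configuration keeps the components covering about half the variance);
  we flag this as an interpretation. Components can be requested by
  count or by cumulative explained-variance target.
- **Conditions**: `condition_one_hot()` over dose {5, 10} µM and time
  {6, 24} h; exactly two bits set; out-of-vocabulary values are errors.

## 5. Rank predictors

All model families share one contract: fit against tie-averaged true
ranks, predict a per-gene score matrix (higher = more up-regulated), and
convert scores to ranks with the shared tie-averaging rule — so
predicted rank matrices always satisfy rank-sum conservation.

**Listwise rank-cosine loss.** The relevance of gene *i* is
`n_genes − rank_i` (linear; the simplest monotone transform), both the
prediction and relevance vectors are mean-centered for scale stability,
and the loss is `1 − cos(·,·)` ∈ [0, 2]. It is invariant to positive
rescaling of predictions; a constant prediction yields loss 1 with a
warning. `rank_cosine_loss()` is the scalar reference implementation;
training uses a fused autodiff op with the analytically derived
gradient.

**Multi-output random forest** (`fit_rfr()`): one ranger forest per
gene behind a single surface, regressing that gene's relevance on the
concatenated fingerprint + cell + condition bundle. Defaults follow the
regression-forest conventions of the reference stack: `n_estimators`
100, unlimited depth, `max_features` 1/3, `min_node_size` 1. Fits are
seeded and single-threaded, so repeated fits are bitwise identical.
`bootstrap = FALSE` grows every tree on the full sample — the
configuration used by the memorization sanity check (noise-free training
F1@10 ≥ 0.95), since bootstrapped forests smooth in-sample predictions
toward neighbors.

**Neural families.** No deep-learning backend is assumed: the SMILES
LSTM, SMILES Transformer encoder and graph model run on a small
reverse-mode autodiff engine over dense matrices (`R/autodiff.R`) with
hand-derived gradients for matmul, the elementwise nonlinearities,
softmax/log-softmax, and the fused losses. This keeps the package
dependency-light and the models are sized accordingly (desk scale:
`d_model ≤ 128`, few layers, tens of profiles). They are reference
implementations of the architectures, not performance-tuned replicas.

- *SMILES LSTM*: character one-hots × trainable embedding + sinusoidal
  positional encoding (computed for whatever sequence length arrives, so
  re-padding is harmless), a standard 4-gate LSTM cell over non-pad
  positions only, final hidden state concatenated with cell/condition
  features, linear layer, log-softmax over genes.
- *SMILES Transformer encoder*: embeddings + positional encoding,
  multi-head self-attention with additive −10⁹ masking of pad keys,
  residual connections, a two-layer feed-forward block, masked mean
  pooling over non-pad positions, then the same output head. Pad
  positions can never influence predictions (tested by re-encoding at a
  longer padded length).
- *Graph model*: a GCN (`layers` rounds of degree-normalized
  neighborhood averaging, default 2 = radius 2) over the 63-dim atom
  features; a pooled sigmoid fingerprint (`fp_dim`, 1024 at production
  scale); the fingerprint plus cell/condition features form a context
  vector; per head, trainable gene embeddings attend to the context
  (softmax over genes of scaled query–key products) and the attended
  values are concatenated with the embeddings; a two-layer feed-forward
  decoder emits per-gene scores. The baseline configuration is one
  layer, one head, rank-cosine loss. Sum/mean pooling makes predictions
  invariant to atom relabeling. How exactly the cell-line and condition
  vectors enter the attention block is under-determined in the source
  material; here they enter through the context vector, and the
  concatenation points are as stated.

Training uses Adam (full batch), optional early stopping on a held-out
split (`validation_fraction` 0.1, `patience` 10 — a stopping rule we fix
because none is canonical), and restores the best-monitored weights.
Every stochastic fit takes a seed; prediction is deterministic.
Models persist as a directory of `manifest.json` (family,
hyperparameters, gene order) plus an opaque weights blob, and
round-trip to identical predictions.

## 6. Stacking ensembles

`fit_stacker()` combines base-model scores per gene: 978 (or `n_genes`)
independent linear models mapping the base models' scores for that gene
to its relevance. Per-gene fitting (rather than one global combiner)
matches the error-offsetting rationale for stacking gene-wise
predictors. `voting` bypasses fitting — uniform weights `1/n_models`,
zero intercept — and is exactly the arithmetic mean. `lasso`, `ridge`
and `elasticnet` use glmnet (α = 1, 0, 0.5) with standardized inputs;
the penalty is selected from a small grid (default 10⁻⁴…1) on an inner
20% validation split and the model is then refit on all rows at the
selected penalty (select-then-refit; it also makes the vanishing-penalty
limit agree with the normal equations, which the tests check). Genes
whose target is constant across profiles carry no combinable signal and
get zero weights with the mean as intercept; all-zero weight rows are
reported. Base predictions for stacker training should be out-of-fold
predictions — the pipeline driver produces them with a 2-fold scheme —
to avoid rewarding base-model overfit.

## 7. Activity classification and screening scores

`label_activity()` labels a compound `active` iff its best (lowest)
measured Ki/Kd/IC50 is strictly below 1 µM; measured-but-worse or
undetermined compounds are `inactive` ("better than 1 µM" is read
strictly: exactly 1.000 µM is inactive); pre-labeled decoys pass
through. Negative potencies are rejected.

`fit_activity_classifier()` wraps three tree-ensemble families behind
one surface: `rf` (ranger probability forest), `xgb` (xgboost), and
`lgbm` (xgboost with histogram binning and leaf-wise `lossguide` growth,
the defining traits of that family). Data are split 80/20 stratified on
the label, the training portion is evaluated by k-fold cross-validation
(default 10; fold counts exceeding the minority class are rejected), and
accuracy, precision, recall, F1 and MCC are reported for train,
validation and test.

`muegge_filter()` computes the eight-property panel (MW, LogP, HBD,
HBA, rotatable bonds, aromatic rings, heteroatoms, carbons) and applies
the rule set MW ∈ [200, 600], LogP ≤ 6, HBD ≤ 6, HBA ≤ 12, rotatable
bonds ≤ 15, aromatic rings ≤ 7, heteroatoms ≥ 2, carbons ≥ 5, reporting
every violated rule. Decisions are invariant to kekulization variants
because properties are computed on the perceived (canonical) structure.

`clamp_interpolate(x, lo, hi)` maps predicted LogS (bounds −8, −4) and
Caco-2 log-permeability (bounds −6.85, −5.15) onto [0, 1]: 0 at or below
`lo`, 1 at or above `hi`, linear in between, boundaries inclusive.

`compose_scores()` builds the score ladder: Score 1 = target
specificity; Score 2 = mean(target, synthetic accessibility, clamped
solubility); Score 3 adds permeability (= mean of HIA probability and
clamped Caco-2); Score 4 adds drug-likeness (raw model output divided by
100); Score 5 adds the gene-expression rank similarity. Each score is
the *flat* arithmetic mean of its components, not a mean of means:
"adding a component to the previous score" is ambiguous between the
two, and flat averaging keeps every component's weight equal and every
score on one scale. All components must lie in [0, 1]; missing
components are reported by name. Composition is monotone non-decreasing
in every component.

The external predictors behind `s_target`, `s_ra`, LogS, Caco-2, HIA
and drug-likeness are injectable values/callables — the package defines
the composition contract, not the predictors; deterministic stubs serve
in tests. Whether target specificity should be the maximum over several
registered classifiers or a single chosen model is left to the caller
for the same reason.

`triage_hits()` applies the two-tier thresholds — stringent 0.9 on
target specificity, synthetic accessibility, solubility and
permeability; lenient 0.5 on drug-likeness and gene-expression
similarity — and ranks survivors by Score 5 (ties by input order).

## 8. The synthetic-data generators

`gen_profiles()` draws from the planted model
`Z = µ + MACCS(chem)·W + ε`:

- `µ` is a gene-wise baseline (SD 1) shared by every profile. Real
  signature collections exhibit exactly this consensus structure (genes
  differ systematically in their propensity to respond), and it is what
  makes an aberrant rank-permuted group *detectable*: without a
  consensus, a permuted profile is statistically indistinguishable from
  a normal one.
- `W` is Gaussian with SD `1/√166`, so the chemistry signal has roughly
  unit scale; `ε` has SD `noise_sd` (default 0.1 — clearly sub-signal,
  as replicate-collapsed signatures should be).
- replicates are independent noise draws around the same clean profile;
- an optional `outlier_frac` corrupts whole *chemicals*: every replicate
  of the selected chems is rank-permuted by one shared permutation,
  forming a coherent aberrant experimental group — the object the
  k-means screen is designed to remove.

`gen_molecules()` enumerates scaffold × substituent combinations from an
internal library of drug-like cores (benzene, pyridine, naphthalene,
biphenyl, benzamide, benzothiazole, piperidine, sulfonamide) with
substituents from methyl to C40 chains; every output parses, and the
molecular-weight distribution spans both sides of the 200 and 600 g/mol
boundaries so the filters are genuinely exercised. `gen_gene_effects()`
plants a low-rank factor structure plus noise for the PCA tests.
`gen_activity_set()` draws fingerprint bits from Bernoulli profiles that
differ on a fraction `separation` of positions (0 = indistinguishable,
1 = fully separated) with potencies obeying the 1 µM rule.

**What the generator does not emulate:** gene–gene correlation beyond
the shared baseline and the linear chemistry map, dose–response or
time-course structure (conditions are sampled independently of Z),
cell-line-specific responses, heteroscedastic or heavy-tailed noise, and
any nonlinear structure–activity relationship. Consequently, passing
tests establish that the algorithms are implemented correctly and
recover planted structure under favorable conditions — not that the
models reach any particular accuracy on real L1000 data, where signal
strength, noise and chemistry diversity are far less benign.

## 9. Problem sizes and numerical choices

Tests and the acceptance script run at deliberately small scale, chosen
so the full suite completes in a few minutes while preserving the
relevant geometry: oracle checks on 5–50 genes; tier checks at 400–978;
model convergence on 8–10 short molecules × 20 genes; the outlier
plant-and-recover at 50 chems × 3 replicates × 500 genes (500 keeps the
rank block's distance share dominant over the 166-bit fingerprint block,
as at the 978-gene production scale); stacker recovery at n = 500;
PCA plant-and-recover at 300 × 600 with 10 factors against
variance-matched noise. The production-scale figure tied to the external
CRISPR effect matrix (about half the variance in ~150 components) is not
reproduced offline; the machinery it needs (fit-on-full-panel,
variance-target cutoff) is what the tests pin down.

Other numerical conventions: integer hashing is polynomial mod 2³¹−1,
exact in doubles; k-means uses 5 restarts per k with seeds derived from
the user seed; glmnet's default convergence threshold governs the
stacker fits (the α→0 check uses tolerance 10⁻²); Adam uses β = (0.9,
0.999), ε = 10⁻⁸; early-stopping improvement threshold is 10⁻⁵.
Degenerate inputs are defined, not exceptional: empty filter results,
zero-variance Spearman inputs, constant predictions under the
rank-cosine loss, constant stacker targets, and single-heavy-atom
molecules (no bonds) all have documented behavior.

## 10. Known limitations

- Fingerprints are internally consistent but not bit-compatible with
  other toolkits' ECFP/FCFP/PubChem implementations; Tanimoto
  similarities are comparable only within this package.
- The neural families are desk-scale reference implementations; no GPU
  path, no minibatching, no dropout/normalization layers.
- Formal charges and stereochemistry are ignored in graph features and
  Morgan invariants.
- The conjugation flag is a local rule (aromatic or adjacent to a
  multiple bond), which differs from toolkits that propagate full
  conjugated systems.
- SMILES encoding is character-level; multi-character element symbols
  (Cl, Br) occupy two positions, as in the character-dictionary
  convention it follows.
- The screening layer composes and triages scores; the external
  predictor models themselves (target specificity, RAscore, LogS,
  Caco-2, HIA, drug-likeness) are not part of the package.
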