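---
title: "Methods: mining, clustering and substrate-specificity modelling of type III PKS"
author: "t3pkskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining, clustering and substrate-specificity modelling of type III PKS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

Type III polyketide synthases (T3PKS) are homodimeric enzymes that
iteratively condense malonyl-CoA extender units onto a CoA-activated
starter acid in a single active site. Which starter acids a given enzyme
accepts — its substrate specificity — varies widely even between close
homologues and cannot be read off a phylogeny. `t3pkskit` implements a
complete desk workflow for characterising such enzyme families:

1. **Mining** candidate sequences from protein collections by similarity
   to seed queries.
2. **Sequence similarity network (SSN)** construction with
   representative-node collapsing and identity-cutoff clustering.
3. **Active-site mapping** of every candidate onto chalcone-synthase
   (MsCHS) reference numbering, with residue-frequency logos and
   catalytic-triad checks.
4. **Featurisation** of enzymes (mean-pooled per-residue descriptors)
   and substrates (MACCS or circular fingerprints), concatenated into
   pair vectors.
5. **Binary activity classifiers** (decision tree, random forest, MLP)
   with seed-repeated cross-validation, paired model comparison and
   100-run-averaged prediction matrices.
6. A **descriptive importance model** ranking alignment positions by
   their association with activity.
7. A **synthetic-data generator** that makes every step testable
   without any sequence database or model download.

Wet-lab concerns (cell-free expression, LC-MS product assignment,
cyclisation chemistry) are outside the package's scope; activity enters
only as a binary enzyme × substrate label matrix.

# Alignment conventions

All identity computations share one convention: **identical aligned
columns divided by the full alignment length, gap columns included in
the denominator**. Global alignments (SSN edges, repnode collapsing,
active-site mapping) use Needleman–Wunsch with BLOSUM62 and gap open
10 / extend 1; mining uses Smith–Waterman with BLOSUM62 and the BLAST
default gapping 11/1. The backends are `Biostrings::pairwiseAlignment`;
the test suite cross-checks scores and identities against an
independent affine-gap (Gotoh) dynamic-programming oracle written in
plain R.

Two caveats are worth knowing. First, for essentially unrelated
sequences the optimal alignment is not unique, and co-optimal
alignments can differ in identity; identity values for such pairs are
only defined up to that ambiguity (scores are unique). The tests
therefore check exact identity agreement on homologous pairs and score
agreement elsewhere. Second, local-alignment identity is computed over
the local alignment span, which for unrelated pairs is a short
high-scoring segment — filtering mined hits on identity alone is
therefore permissive, and the mining module couples it with a
query-coverage threshold (default 0.5).

# SSN construction

`buildNetwork()` follows the construction used by web SSN tools:
sequences above a high mutual identity (`repnodeThreshold`, default
0.95) collapse into representative nodes; edges join representatives at
identity ≥ `cutoff`; connected components are clusters, numbered by
descending member count with ties broken by the smallest member id so
cluster ids are stable across runs. Collapsing is greedy and
incremental in descending-length order (ties lexicographic): a sequence
joins the best-matching existing representative above the threshold or
founds a new repnode, so the representative is always the longest
member. This approximates CD-HIT-like behaviour without cloning it; at
`repnodeThreshold = 1` the network degenerates, by construction, to the
raw-sequence network.

Identity is computed from global alignments rather than from a
BLAST-score proxy: simpler, symmetric and reproducible. The useful
cutoff range for T3PKS work is roughly 0.57 (separation into broad
phylogenetic clades) to 0.80 (fine functional groups); raising the
cutoff can only split clusters (a property the tests assert). The
all-vs-all cost is quadratic; for collections beyond a few thousand
sequences, precompute `identityMatrix()` once and reuse it across
cutoffs (`buildNetwork(..., idm = )`), and consider the opt-in 4-mer
prefilter (`prefilter = TRUE`), which skips aligning pairs sharing
under 2% of their 4-mers — such pairs sit far below any useful cutoff,
so above-cutoff edges are unaffected (asserted in the tests); their
recorded identities become 0 rather than their true small values.

# Active-site mapping

`mapReferencePositions()` aligns each candidate globally to a
user-supplied reference and reads the residue aligned to each
reference-numbered column; deletions read as `"-"` and insertions in
the query never shift the numbering, which is anchored to reference
columns. The conventional reference is MsCHS (UniProt P30074) with the
catalytic triad C164/H303/N336 and pocket positions 197, G256, F265
(`defaultActiveSitePositions()`); the reference itself is not bundled —
tests and examples use a synthetic reference. Pairwise-to-reference
alignment was chosen over a profile alignment for simplicity and
statelessness; for deeply diverged candidates a profile method would be
a reasonable alternative and the position map is deliberately
backend-agnostic. The gap symbol participates in logos as its own
category, so logo rows always sum to one over residues-plus-gap.

# Featurisation

Enzymes are represented by **mean-pooling per-residue features** into a
fixed-length vector. The embedder interface is pluggable: any function
returning an L × d matrix with fixed d can be registered
(`registerEmbedder()`), which is how transformer protein language-model
embeddings (e.g. ProtTrans-style, d = 1024) slot in when available. The
package ships a deterministic `"fallback-physchem"` embedder — one-hot
residue encoding plus z-scaled hydropathy, volume, polarity and charge
(d = 24) — which needs no download and is what the test suite uses
throughout. Mean pooling is the only pooling implemented, deliberately.

Substrates are parsed from SMILES. MACCS keys (167-bit convention, keys
computed by OpenBabel) and a circular Morgan/ECFP fingerprint (default
radius 2, 2048 bits, binary) are available. The ECFP implementation is
in-package — iterative neighbourhood hashing over the connection table
with aromatic-ring perception so different kekulisations hash
identically — because no installed R package provides it; it is
order-invariant by construction, which the tests verify by fingerprint
equality across rewritten SMILES. Pair features are the concatenation
enzyme-vector ++ substrate-bits, ordered by enzyme id then substrate id.

# Classifiers and evaluation protocol

Three classifiers are exposed through one config object
(`modelConfig()`): `decision_tree` (rpart), `random_forest` (ranger,
500 trees) and `mlp`. The MLP is a single-hidden-layer network (nnet):
8 logistic units, weight decay 0.01, BFGS, inputs standardised with
training-set statistics. A deeper ReLU/adam architecture was
considered and rejected: no installed R backend provides it, and on
mean-pooled features plus fingerprint bits a small shallow network
already saturates the synthetic benchmarks, at a fraction of the fit
cost. All hyperparameters are exposed in the config.

Evaluation is **stratified k-fold cross-validation repeated with
distinct seeds** (default 5 × 20 = 100 fold-fits, mirroring the 100-run
averaging convention used for predictions). Every fold fit is one run;
accuracy and F1 of the active class are reported per run and summarised
as mean ± sd **across runs** — that is the axis behind every ± in the
package's reports. Pairs are split at random over (enzyme, substrate)
pairs by default; evaluating genuinely unseen enzymes is done
separately via `evaluateExternal()` or by holding out enzymes when
building the training `PairDataset`. The decision threshold on
averaged probabilities is 0.5 and the training prevalence (~43%) is
near-balanced, so no class reweighting is applied by default.

`compareModels()` performs a two-sided paired test on per-run F1 over
matched seeds: Wilcoxon signed-rank (normal approximation, ties
allowed) for ≥ 6 runs, paired t-test below that. Two degenerate cases
are defined explicitly: all differences zero gives p = 1, and a
constant nonzero difference (no within-pair variance) gives p = 0.

The test is paired **at the run level**, which defines what it can and
cannot compare. Comparing two models evaluated on the *same* dataset
with matched folds is its intended use, and there it is calibrated: the
test suite draws 200 datasets from one generator and, on each, compares
two equivalent random forests under identical folds but independent
fit randomness (the `seed_offset` hyperparameter), observing a
significance rate near the nominal 5% (slightly below, as the rank
test is conservative under tied runs). What the run-paired test must
**not** be used for is deciding whether two *datasets* come from the
same distribution: a dataset-level noise draw shifts all runs of a
report jointly, the run-level pairing ignores that shared random
effect, and the type-I error inflates drastically (~40% in the same
simulation harness).

`predictMatrix()` trains `nPredictionRuns` models (default 100) with
distinct seeds on the full training set and averages per-pair
probabilities; binary calls threshold the **averaged** probability.

# Descriptive position importance

`rankPositions()` one-hot encodes the residues at every mapped
reference position, fits a random forest, and scores each position by
**grouped permutation importance**: the drop in out-of-bootstrap
accuracy when all dummies of that position are permuted jointly,
averaged over bootstrap replicates (default 20). Constant columns score
exactly zero; irrelevant columns have signed scores centred on zero
(the reported `score` is clamped at zero, the signed mean is kept in
`raw_score`); `stability` is the fraction of replicates in which the
position lands in the top decile. The underlying descriptive-model idea
admits many instantiations; this one was chosen for being
classifier-agnostic in principle, deterministic under a seed, and
honest about uncertainty. It ranks associations and makes no
mechanistic claim.

# The synthetic-data generator

`syntheticSpec()` fixes the study conditions the whole test battery
runs under. Defaults emulate the statistical shape of a realistic
training campaign: 4 homologous families of sizes 6/10/4/11
(31 enzymes, ancestor length 389 — the length scale of chalcone
synthases), an 11-substrate panel of small achiral carboxylic acids
(5 aromatic, 6 aliphatic), and a planted motif × substructure rule —
enzymes carrying F at column 197 accept aromatic substrates (SMARTS
`c`), enzymes carrying V at column 265 accept aliphatic ones (SMARTS
`[CX4]`); family acceptor classes both/aliphatic/aromatic/none make
6·11 + 10·6 + 4·5 = 146 of 341 pairs active (42.8%, matching a ~43%
prevalence). Families grow by point substitutions, uniform over the 19
alternatives: rate 0.05 from the family ancestor (~90% within-family
identity) and 0.45 from the common root (~30–35% between families);
catalytic-triad and motif columns are frozen. Label noise flips each
label independently at a configurable rate (default 0); noise-free rule
labels are retained as ground truth.

What the generator does **not** emulate — indels, rate heterogeneity
across sites, phylogenetic correlation of activity, realistic
CoA-thioester chemistry, assay-dependent label errors — bounds what
passing tests show: they demonstrate that the pipeline recovers planted
structure of the stated form at the stated signal strengths, not that
any particular accuracy will be reached on real enzymes. Seeds are
mandatory; all generation is deterministic given the spec.

# Numerical and determinism choices

- Every run/fold/replicate seed is derived by a stable integer hash of
  the base seed and the protocol indices, so toggling one protocol axis
  never shifts another's randomness; the pipeline driver does the same
  per stage (`stageSeed()`).
- Random forests run with `num.threads = 1` and an explicit seed;
  rerunning any evaluation or prediction with the same config is
  byte-identical, which the pipeline manifest (md5 per artefact)
  asserts end-to-end.
- Floating-point outputs in text artefacts are written with fixed
  formats so reruns compare byte-for-byte.
- Stratified folds require every class to have at least as many
  examples as folds; the assignment is redrawn (up to 20 times) if a
  fold ever lacks a class, then fails loudly.
- F1 is `2TP / (2TP + FP + FN)` with positive class = active; it is
  `NA` only when the test fold contains no positives and none are
  predicted.
- Mining reports each target once, with its best-scoring query;
  dereplication collapses byte-identical residue strings only, keeping
  the first-seen id and recording absorbed ids.
- Ambiguity letters B, Z, J, U, O normalise to X with a warning
  (strict rejection is available); any other residue code is an error
  naming the record.

# Problem sizes

The shipped test and acceptance workloads use the defaults above:
341-pair datasets, 100-fold-fit CV protocols, 18-sequence /
150-residue family fixtures for network oracles, 40 × 25 residue
matrices with 5-bootstrap importance models, and 12-enzyme pipeline
fixtures — sizes at which every check runs comfortably on a single
CPU while still exercising the full code paths. All scale up linearly
(quadratically for the all-vs-all identity matrix) with the same code.

# Known limitations

- SSN identity is global-alignment based; against score-proxy networks
  built by web tools the same numeric cutoff selects somewhat different
  edge sets.
- Active-site extraction trusts a single pairwise alignment per
  sequence; extremely diverged candidates may misalign locally around
  the pocket.
- The fallback embedder captures composition and coarse
  physicochemistry only; transformer embeddings, where available,
  carry far more signal and plug in through the same registry.
- The importance model reports associations under the fitted
  classifier, not causal or structural effects.
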