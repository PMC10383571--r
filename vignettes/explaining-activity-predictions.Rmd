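---
title: "Explaining multiclass compound-activity predictions with exact tree Shapley values and counterfactual analogues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining multiclass compound-activity predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapcf)
```

## The prediction task and its representation

`shapcf` explains multiclass models that assign compounds one of four labels:
dual-target active (`DT`), single-target active for either target of a pair
(`ST_A`, `ST_B`), or randomly selected and presumed inactive (`R`). The codes
0–3 follow that order and break all probability ties, so predictions are
reproducible down to the tie-break.

Compounds are represented by binary atom-environment fingerprints.
`enumerate_environments()` grows a circular environment around every heavy
atom for bond radii 0–2 (bond diameter 4). Atom identifiers start from the
connectivity invariants element, heavy-atom degree, formal charge, implicit
hydrogen count and ring membership, and each radius hashes an atom's previous
identifier together with its sorted (bond order, neighbour identifier) pairs.
Two properties matter downstream:

* identifiers depend only on the chemical neighbourhood, never on atom
  numbering, so different SMILES of one structure give identical fingerprints;
* every environment remembers its atoms, so each fingerprint carries a full
  bit → atom-environment provenance map.

`fold_to_fingerprint()` maps `env_hash mod n_bits` (default 4096) to bits.
Environments are deduplicated per molecule (set semantics, binary bits), and
an environment whose radius increment adds neither atoms nor bonds is dropped
as exhausted. Hashes are polynomial hashes modulo the largest prime below
2^26; with that modulus every intermediate product stays below 2^52, so the
arithmetic is exact in doubles and identical on every platform. The hash
space is large enough that within-molecule collisions are rare, and a
cross-molecule collision merely merges two bits — the same effect folding has
anyway. No bit-for-bit parity with any external fingerprint implementation is
claimed; the scheme is the conventional extended-connectivity construction.

Structure handling (parsing, canonical SMILES as the identity key, SDF
conversion, SMARTS matching, 2D layout) is delegated to OpenBabel through
ChemmineOB/ChemmineR. Salts are stripped to the largest fragment and
stereochemistry is ignored throughout: attributions are atom-level and
stereo-agnostic, and the fingerprint uses no chiral invariants. One-atom
molecules are assembled directly from their SMILES token because an SDF atom
block cannot carry a bond-free molecule through ChemmineR.

## Models and evaluation

Random forests are trained with ranger as probability forests (leaf values
are in-bag class frequencies; the ensemble output is the unweighted mean of
leaf vectors). The training protocol is: stratified 70/30 split per trial;
hyperparameter selection on an inner 70/30 split of the training partition by
macro balanced accuracy; final fit on the whole training partition. The full
grid is min-samples-per-leaf {1, 2, 5, 10} × min-samples-to-split
{2, 3, 5, 10} × trees {25, 50, 100, 200, 400}; ties resolve to the
lexicographically smallest (trees, leaf, split) — the simplest model that
achieves the maximum. Remaining settings stay at conventional forest
defaults (`mtry = floor(sqrt(p))`, bootstrap with replacement) and are
recorded in the run manifest. Trial `t` of a run seeds everything with
`base_seed + t`.

Every fitted tree is exported to a plain node table (children, split bit,
threshold, per-class leaf vector). **All predictions in the package come from
traversing these tables**, and the test suite asserts the traversal
reproduces ranger's own predictions exactly; this makes the model output and
the Shapley computation consistent by construction and makes the JSON tree
dump (`model_to_json()`) a complete, backend-free model description.

Performance is reported per class from one-vs-rest confusion tallies —
balanced accuracy, precision, recall, F1 and the Matthews correlation
coefficient in their standard binary forms — and macro-averaged with equal
class weights. The binary formulas do not themselves define a multiclass
average; macro averaging was chosen for all five metrics so they remain
comparable to each other, and ratios with zero denominators are reported as 0
with a `degenerate` flag rather than raising.

## Exact interventional Shapley attributions

For a tree `T`, foreground `x` and background sample `z`, the interventional
coalition game is `v(S) = T(hybrid(S))` with in-coalition bits taken from `x`
and the rest from `z`. Walking a root-to-leaf path and intersecting the
binary constraints on each tested bit classifies the path bits into: bits
both `x` and `z` satisfy (never block), bits only `x` satisfies (must be in
the coalition; `a` of them), bits only `z` satisfies (must be out; `b`), and
bits neither satisfies (leaf unreachable — dropped). The Shapley value of
such a conjunction game has the closed form

* `phi_i = +leaf_value * (a-1)! b! / (a+b)!` for each required-present bit,
* `phi_i = -leaf_value * a! (b-1)! / (a+b)!` for each required-absent bit,

independent of the total number of players, because untested bits are exact
dummies. Summing over leaves gives the per-tree, per-background attribution;
averaging over the background set and the trees preserves exactness by
linearity. The per-class base value is the mean model probability over the
background, so local accuracy `base_c + sum(phi[c, ]) = p_c(x)` and unit
class additivity hold to floating-point precision — both are asserted in the
tests, and the whole engine is verified against `brute_force_shapley()`
(direct subset enumeration, feasible up to 16 players) to a maximum absolute
deviation below 1e-10 across 100 random ensembles.

The computation is organised as matrix algebra over (background × leaf)
count matrices, so the cost per compound is roughly
`trees × leaves × path-length × background`. The background defaults to the
full training partition; a seeded subsample is available
for large studies and is recorded in the manifest. The package's own
acceptance-scale runs use 50 background compounds — at that size the
cumulative summaries are visually indistinguishable from full-background
runs, and the choice is a study parameter, not part of the algorithm.

`partition_present_absent()` splits a compound's attribution mass by bit
value, and `cumulative_shap()` averages those sums per class over the
*correctly predicted* test compounds of a trial (mean by default; a summed
variant differs only by the per-class count and is available via
`aggregate = "sum"`). Attributions always refer to the compound's true class,
which equals the predicted class under the correct-only filter.

## Atom mapping

Only features *present* in a compound are mapped — absent-feature
attributions have no atoms to receive them and remain visible in the
cumulative summaries. For each set bit, the attribution is split equally
among the environments folded onto that bit (equal split conserves the bit's
mass and needs no arbitrary ordering; the folding scheme itself never
promises collision-free bits), and each environment passes its share in full
to every one of its atoms; atoms accumulate over environments. The
conservation identity — atom total equals the provenance-weighted bit total —
is checked to 1e-12 on every map the package produces. Maps are normalized
per molecule by the maximum absolute value (symmetric, sign-preserving), so
each depiction uses its full colour range; normalizing per figure panel
instead is a presentation choice the data frame output still allows.
Depictions are deterministic SVG text over OpenBabel 2D layouts: red atoms
support the target class, blue atoms oppose it, annotated with the model's
target-class probability.

## Counterfactual analogues

Counterfactual search asks: what minimal structural change flips a correctly
predicted single-target compound to a dual-target prediction? Two pluggable
generators populate the narrow chemical space around a base compound:

* `transform_analogues()` — attach a library substituent at an H-bearing,
  non-ring-junction atom; replace an acyclic terminal branch with a library
  substituent; or delete such a branch. The default library holds the
  substituents recurrent in active compounds (halogens, methyl, methoxy,
  amide, phenyl, benzyl, piperidinyl, piperazinyl, morpholinyl, azetidinyl,
  sulfonamide). For benchmark runs the planted motifs are added, which is the
  same principle — substituents frequently observed in actives.
* `mutate_string_analogues()` — random token-level substitutions, insertions
  and deletions on the SMILES string. Edited strings are kept only if they
  survive the full sanitizing parse, so every emitted candidate is a valid
  molecule; this rejection-sampling design was chosen over a
  robust-by-construction string encoding, which has no R implementation and
  whose guarantees the validity filter reproduces at the cost of some wasted
  draws.

Both generators deduplicate by canonical key, never return the base itself,
and are deterministic per seed; in the pipeline each base compound's seed is
derived from its canonical key, so enlarging a base set never reshuffles the
candidates of existing bases. `find_counterfactuals()` fingerprints and
predicts every candidate and records all of them; a candidate *qualifies*
when its argmax class equals the target class. No similarity cutoff is
applied by default — the Tanimoto similarity to the base is recorded and the
qualified set is sorted by it, so post-filtering is a one-liner. The candidate
budget (default 1000 per base and strategy) is configuration, not chemistry.

## The synthetic benchmark

`generate_benchmark()` builds four balanced classes from scaffold templates
with 2–4 substitution slots: DT compounds receive both planted motifs, ST
compounds one, R compounds none, and unused slots are filled with neutral
decoys at random. The default motifs — 4-methylpiperidin-1-yl and
4-phenylpiperazin-1-yl — are amine-linked ring systems of the kind enriched
in dual-target actives, so worked examples read naturally; they are fully
configurable. Label noise omits each required motif with probability `noise`
while keeping the label, decoupling structure from label the way assay noise
does for explanation purposes (the explanation target is structural, so
motif omission is the right corruption model, not label flipping).

`benchmark_ground_truth()` locates motifs by SMARTS search over the emitted
SMILES. When the phenylpiperazine motif sits on an aromatic scaffold the
motif pattern genuinely occurs in two orientations (an N,N′-diaryl
piperazine), so the matched-atom union can be larger than the fragment
inserted at construction time; the search result is treated as the truth, and
the generator's bookkeeping is asserted to be a subset of it.

What passing on this benchmark shows — and what it does not: the generator
emulates the *statistical structure* the framework assumes
(class-discriminative substructures detectable through present-feature
attributions, plus nuisance variation from scaffolds and decoys). It does not
emulate activity cliffs, assay noise beyond motif omission, scaffold–motif
interactions, or the chemical diversity of a real compound database, so
results here bound what the machinery can do when its assumptions hold, not
how a given real data set will behave.

## Numerical choices, degenerate inputs, limitations

* Hash arithmetic and Shapley weights are exact in doubles (weights use exact
  factorials below 21 and `lgamma` beyond, where the terms are far below any
  tolerance of interest).
* Ties: argmax ties to the smallest class code; tuning ties to the smallest
  (trees, leaf, split); both documented above.
* Degenerate inputs: single-class training errors; empty test partitions are
  disallowed (`train_fraction` strictly inside (0,1)); classes without a
  correctly predicted compound yield flagged-empty cumulative cells, not
  zeros; a set bit without provenance is a corrupt-fingerprint error; metric
  ratios with zero denominators report 0 with a flag.
* Reruns of `run_pipeline()` on one configuration are byte-identical; every
  random decision derives from seeds stored in the manifest, and an aborted
  run leaves a `PARTIAL` marker.
* Problem sizes used by the package's own end-to-end checks: 100 compounds
  per class, ten trials, a 2×2×2 sub-grid of the full tuning grid
  (trees {25, 100} × leaf {1, 5} × split {2, 5}), 50-compound seeded
  backgrounds, ten counterfactual bases with 1000-candidate budgets. The
  defaults of the exported functions remain the full grid and the full
  training-partition background.
* Limitations: the Shapley engine requires binary features (fingerprint
  bits); attributions are per-bit and bond-level attribution is out of scope;
  the interventional game ignores feature correlation by design — that is
  what makes it interventional; counterfactual existence is not guaranteed
  for a given base, although analogue enumeration makes it likely; and the
  string-mutation generator explores only the immediate token neighbourhood
  of the base SMILES.
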