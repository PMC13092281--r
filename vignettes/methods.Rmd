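---
title: "shieldscan: model, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{shieldscan: model, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shieldscan)
```

## The prediction problem

Anti-phage defense genes are a moving target for annotation: new
families keep being discovered, many lack homology to anything known,
and a substantial fraction sits outside the defense islands that
guilt-by-association screens rely on. `shieldscan` frames the problem
as supervised classification of individual protein-coding genes. The
signal available to the classifier is deliberately broader than
homology: the sequence of the protein itself (through a language-model
embedding), the proteins encoded around it, and the compositional
fingerprints that horizontally acquired defense genes tend to carry —
most prominently a GC content below the host genome's.

## Feature construction

For a center gene and its two neighbours on either side we build one
vector of `5 * dim + 119` features (3,319 at the production embedding
dimension of 640):

* **Embedding block** (`5 * dim`): the backend's per-residue vectors
  mean-pooled per protein, window order −2, −1, 0, +1, +2. Pooling
  averages residue positions only; any special begin/end tokens a real
  backend emits are excluded by the backend adapter.
* **Per-gene genomic block** (22 × 5 = 110): mononucleotide (A, C, G,
  T) and overlapping dinucleotide frequencies on the *coding* strand
  (N positions and N-containing windows are excluded from numerator
  and denominator), gene GC minus genome GC, and gene length in raw
  bp.
* **Distances** (4): signed intergenic distances `start(b) − end(a)`
  between consecutive window genes; 0 means abutting, negative means
  overlap.
* **Orientations** (4): ±1 for each neighbour, relative to the center
  gene's strand.
* **Genome GC** (1): the genome-wide GC fraction.

Named feature families here sum to 118 without the genome-GC slot; the
registry commits to genome GC as the 119th slot so that every family
that can plausibly matter is present and the total is fixed. Missing
neighbours at contig edges contribute zeros in all their slots —
embedding, per-gene block, adjacent distance and orientation — keeping
the vector length constant. A zero embedding cannot be produced by the
mock backend for any real sequence, so the padding is distinguishable
from data. Neighbourhoods never cross contig boundaries, and circular
wrap-around is not modelled.

Features are stored raw, not z-scored: gradient-boosted trees are
invariant to monotone transforms, and raw values keep the stored
matrices interpretable. Gene length is raw bp for the same reason.

## Embedding backends

The embedding contract is a deterministic map from an amino-acid
sequence to per-residue vectors of fixed dimension, mean-pooled
downstream. The bundled backend is a *mock* language model built for
desk-scale testing: overlapping 3-mers are hashed into 1,024 buckets
and projected into `dim` dimensions by a seeded Gaussian matrix, so the
pooled vector is a projected 3-mer composition profile. This preserves
exactly the properties the pipeline depends on — determinism,
composition sensitivity (a planted motif shifts the pooled vector),
and sequence-order sensitivity at the 3-mer scale — while being
reproducible from `(dim, seed)` alone. It does not model long-range
residue interactions or evolutionary constraints the way a transformer
PLM does, so absolute performance numbers on mock embeddings say
nothing about real-data performance; they validate the machinery, not
the biology. A real PLM is plugged in by providing the same contract;
long sequences beyond a real backend's context limit are truncated
with a logged warning, and the checkpoint id is recorded in the output
metadata rather than hard-coded.

## Dataset assembly and homology-aware folds

Redundancy reduction clusters proteins greedily, longest first, at
default 30% identity and 80% reciprocal coverage. Identity and aligned
spans come from a standard local alignment (BLOSUM62, gap open 11 /
extend 1); a shared-4-mer prefilter (at least 3 shared distinct
4-mers, configurable) prunes the candidate list before alignment, the
same seed-filter idea fast clustering tools use. The prefilter is
lossless for close homologs but bounds sensitivity near the identity
threshold: two proteins at exactly 30% identity share few conserved
4-mers and can be missed. For the package's use — collapsing paralog
families mutated at ~10% per site — this is immaterial; for
borderline-identity clustering lower `kmer_min` or substitute an
external clusterer through the same `id -> cluster` mapping contract.
One representative per cluster is drawn uniformly at random under the
given seed.

Fold assignment takes a homolog-pair list (in production, the output
of a sensitive all-by-all profile search consumed as a table),
computes connected components, and packs whole components into k = 5
folds. Components carrying positives are sorted by positive count and
placed into the fold with the fewest positives so far; positive-free
components are placed into the fold with the fewest total members. The
second rule is a deliberate refinement of plain positive-count
balancing: control components all tie at zero positives, and placing
them by positive count alone funnels every control into the single
fold with the fewest positives, leaving the remaining folds without
negatives and making per-fold training degenerate. Balancing
positive-free components by totals keeps both class counts within one
component of even. The hard invariant — no homology edge crosses folds
— is checked by `leakage_check()` and enforced by construction.

Validation splits for hyperparameter tuning move whole components from
the training folds until at least a target fraction (default 0.1) of
positives and of controls is covered, so tuning never sees homologs of
its validation proteins.

## Classifier and scoring

One xgboost binary classifier is trained per held-out fold
(single-threaded, seeded; default: 150 rounds, depth 5, learning rate
0.1, row subsample 0.9, column subsample 0.8). Optional tuning
maximizes validation average precision over a documented search space;
`strategy = "random"` draws independent configurations and
`strategy = "bayes"` is a seeded sequential search (random exploration
for a third of the budget, then perturbation of the incumbent) — a
model-free exploit/explore loop, not a Gaussian-process optimizer.
Tuning is per fold; a shared-parameter run is obtained by passing the
chosen parameters with `budget = 0`.

Held-out evaluation scores each gene with the one member that never
saw it in training; scoring a row without a matching held-out member
raises rather than silently leaking. For new genomes the ensemble
probability is the arithmetic mean of the five members — the standard
bagging combination, chosen because the members are exchangeable
models of the same target. Log-odds are `ln(p/(1-p))` with p clamped
to `[1e-9, 1-1e-9]` so saturated trees stay finite; probability 0.98
corresponds to the stringent "log-odds 4" cutoff. Probabilities are
the raw learner outputs — no Platt/isotonic calibration — and class
imbalance reweighting is off by default.

Feature attributions come from the additive tree-attribution output of
the booster (`predcontrib`); the package's own contribution is the
aggregation bookkeeping: per-gene sums within each (feature category ×
window position) block, averaged over a gene set, or per-window-position
sums for neighbour-gene importance. Because the blocks partition the
columns, category sums add back to each gene's total attribution. For
plotting attribution against a feature (e.g. GC content), z-scoring is
applied at plot time only.

## Evaluation protocol and baselines

Discovery-mode evaluation keeps only the top-scoring gene per dedup
group — defense HMM cluster for positives, functional annotation group
for negatives — before ranking; score ties are broken by smallest id
everywhere, so rankings are deterministic. The PR curve groups tied
scores into one block before stepping; AP is the sum of
ΔRecall × precision over blocks, AUROC the rank statistic with half
credit for ties. Baselines: cosine nearest-neighbour over embeddings
(negated when the neighbour is non-defensive; nearest-neighbour ties
prefer a defense reference), signed best-hit bit-score (no-hit queries
score 0, below every scored protein), and guilt-by-association — for
each cluster, a one-sided Fisher exact test on near-defense counts,
where "near" is within ±10 genes on the contig (the defense-island
radius), defensive neighbours of the query's own system are never
counted, and same-fold defensive neighbours can be excluded for
fairness against the classifier. Counting is per gene instance, and
p-values are reported raw (the ranking is by significance; no
multiple-testing correction).

## Genome analyses

Transcriptional units are maximal same-strand runs with every
consecutive gap ≤ 30 bp (inclusive); manual boundary curation is not
modelled. A TU's log-odds is the maximum over member genes. Context
annotation flags defense-island membership (±10 genes of a known
defense gene other than the gene itself), and prophage/plasmid
membership by ≥ 1 bp overlap with supplied interval tables; set-level
frequencies carry 95% percentile CIs from 200 seeded genome-level
bootstrap resamples. Pangenome occupancy flags clusters in ≤ 5 genomes
as accessory and clusters in all genomes as core; accumulation curves
resample genomes without replacement 10 times per step. The
validation-rate curve estimates, at each TU's log-odds L, the mean
outcome of all TUs within ±2 log-odds (boundary inclusive — each TU's
window contains at least itself), with percentile CIs from 1,000 TU
resamples and the Pearson correlation between log-odds and local rate;
a constant rate yields NA with a warning.

## The synthetic cohort

The generator emulates the statistical structure the classifier
exploits, not the biology that produces it. Defaults define the study
conditions used throughout the tests: 4 genomes × 500 genes, genome GC
0.52, 10% defense genes, GC shift −0.10, island placement probability
0.6, motif `WWHHWW`. Proteins are i.i.d. draws from a uniform
amino-acid background (start methionine fixed); defense proteins get
the motif inserted at a random position. Multi-gene systems (1–3
single-protein families) are placed as consecutive, same-strand
operonic blocks; paralog families are simulated by copy-with-mutation
at 10% per site, and the homology graph connects family members.
Coding sequences are produced by reverse translation with
exponentially tilted codon weights (`w ∝ exp(λ·GC)`, λ solved per
sequence so the expected coding GC hits the class target), which
realizes the planted GC shift in expectation regardless of amino-acid
composition. Intergenic gaps mix TU-compatible (≤ 30 bp) and larger
spacings; overlapping genes are not generated. No phylogenetic
realism, codon-usage bias, or sequence-evolution model beyond
substitution is attempted — so a passing test suite demonstrates that
the machinery recovers planted signals of the kind real defense genes
show, not that the model would reach any particular performance on
real genomes.

Problem sizes used by the test suite and the acceptance script —
a 2,000-gene cohort for end-to-end signal recovery, 32-dimensional
mock embeddings, 200-ranking oracle sweeps, 20 × 5 random-graph
leakage checks — were chosen so the full pipeline remains a
single-CPU, minutes-scale computation while every statistic stays
well away from small-sample degeneracy.

## Numerical and degenerate-input policy

* Probabilities clamped at `1e-9` before log-odds; frequencies over
  all-N sequences return zeros rather than NaN.
* Ties: smallest-id everywhere a ranking decision is needed; tie
  blocks grouped before PR stepping; defense-label preference in
  nearest-neighbour and best-hit ties.
* Single-class rankings, empty validation sets, fold labels without
  members, k < 2, and windows < 1 raise classed validation errors
  rather than returning silent results.
* Every stochastic stage (generation, representative choice, tuning,
  training, bootstraps) consumes an explicit seed and restores the
  caller's RNG state; identical seeds give byte-identical outputs.

## Known limitations

* The mock backend measures 3-mer composition; it cannot represent
  remote homology or structure the way a transformer PLM can.
* The GenBank parser covers the flat-file subset the pipeline needs
  (simple and complement locations, translations); compound `join`
  locations are skipped with a warning.
* Non-coding defensive RNAs are out of scope: the unit of
  classification is the protein-coding gene.
* Guilt-by-association counts per gene instance; with very uneven
  genome sizes a per-cluster-occurrence weighting could differ.
* The clustering prefilter bounds sensitivity near the 30% identity
  threshold (see above).
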