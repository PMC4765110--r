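---
title: "Filtering false-positive homology clusters with OrthoSieve"
author: "OrthoSieve authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering false-positive homology clusters with OrthoSieve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrthoSieve)
```

## The classification problem

Heuristic orthology predictors based on reciprocal best BLAST hits
produce pairwise homology calls between proteomes; chaining those calls
by transitive closure (`transitiveClosure()`) turns them into
multi-species clusters. The closure is exactly the connected-components
operation on the relation graph — if A is related to B and B to C, all
three land in one cluster — which is also why errors propagate: one
spurious pairwise hit fuses two unrelated families. Over `pairCount(N)`
pairwise runs for `N` proteomes, the resulting cluster sets carry a
substantial load of false-positive homology, and the load grows as
sequencing depth shrinks.

OrthoSieve scores each cluster's multiple sequence alignment with ten
attributes and classifies the cluster as homology (H) or non-homology
(NH) with supervised learners. The premises are biological: genuinely
homologous sequences accumulate few indels (few gaps), retain similar
lengths (small range), keep their amino-acid composition under
genome-wide selective constraints (small compositional dispersion), and
align non-randomly along most of their length (low randomness count).
Decoys violate most of these at once, which is what makes the
classification easy once ground truth exists.

## The ten attributes

`clusterFeatures()` returns `aliscore`, `length`, `n_sequences`,
`n_gaps`, `n_amino_acids`, `range`, and four class-dispersion values.
Conventions that matter:

* The residue alphabet is the 20 standard amino acids plus `X` (unknown)
  and `-` (gap). `X` counts as a residue for `n_amino_acids` and length
  bookkeeping but is excluded from class composition — an unknown residue
  has no physicochemical class. Stop codons (`*`) are stripped at input
  with a warning, since ORF-predicted proteomes commonly carry trailing
  stops.
* The class assignment is charged = {D, E, K, R, H}, uncharged (polar) =
  {S, T, N, Q, Y}, hydrophobic = {A, V, L, I, M, F, W}, special =
  {C, G, P}. Histidine sits with the charged class by the standard
  grouping; `aminoClassScheme()` accepts any other disjoint partition of
  the 20 residues if a user prefers a different convention.
* Dispersion is computed from per-sequence class proportions taken over
  each sequence's *own* ungapped, non-`X` residue count (this is the
  length correction: a short fragment is not penalised for having fewer
  residues), then the Bessel-corrected (n − 1) variance across sequences
  is reported on the standard-deviation scale. The variance scale carries
  the same information; we emit the square root because it keeps the four
  dispersion features on a comparable magnitude to each other.
* `n_gaps + n_amino_acids = length × n_sequences` holds identically and
  is asserted in the tests.

## The alignment-randomness score

The `aliscore` attribute counts alignment columns whose similarity is
indistinguishable from chance. `randomPositions()` is a parametric
Monte-Carlo sliding-window scorer: for every unordered pair of rows and
every window of `window` columns (default 6), the observed score is the
BLOSUM62 sum over the window's column pairs, with any gap-containing
column contributing `gapScore` (default −1) rather than being skipped —
decoy clusters are gap-rich, and skipping gaps would hide exactly the
signal the feature should carry. The pair's null distribution is the
score of `nResamples` (default 100) windows whose residues are drawn
independently from each row's own ungapped residue frequencies; a window
is non-random iff its observed score exceeds the null's `quantile`
(default 0.95). A column is flagged iff, pooled over all pairs, fewer
than half of the windows covering it are non-random.

This is a stand-in with the same operating principle as the external
ALISCORE program, not a clone of it: the downstream classifier consumes
one scalar per cluster and needs a consistent randomness signal, not
numeric parity with any particular implementation. Users who run the
external program can attach its per-cluster count with
`attachAliscore()`, which then takes precedence verbatim. Degenerate
input (window wider than the alignment) is scored as a single
whole-alignment window with a logged message, not an error.

## Generative ground truth

No curated non-homology cluster sets exist, so training data is
constructed:

* **`makeHSynthetic()`** — homology stand-ins: each cluster is the tip
  set of one shallow random tree evolved from a root drawn from WAG
  equilibrium frequencies. Defaults: cluster size ~ Poisson(44.3056)
  truncated to ≥ 2 by redraw (the calibration constant is the average
  homology-cluster size the generative construction is built around;
  a 0/1-size draw cannot form an alignable cluster), root length uniform
  on 120–400 aa (typical protein lengths), branch lengths i.i.d.
  Exponential with mean 0.05 substitutions/site — conserved but not
  identical families.
* **`makeNHRandom()`** — decoys by random draw: Poisson-sized samples
  without replacement from the pooled proteins, aligned.
* **`makeNHEvolved()`** — decoys by deep divergence: per member of a
  homology cluster, sample a random binary tree (tip count =
  round(Normal(50, 15)) redrawn until ≥ 2; topology by random sequential
  coalescence; branch lengths i.i.d. Exponential with mean 0.5
  substitutions/site), evolve the member along it under WAG+I, and keep
  one random tip. Branch lengths are a free choice of the construction —
  nothing pins them — so they are exposed in `treeParams()`; the default
  mean of 0.5 per edge accumulates several substitutions per site from
  root to tip, far past the twilight zone of homology detection.

The substitution model is WAG+I: the reversible rate matrix
`q_ij = s_ij π_j` built from the published WAG exchangeabilities and
equilibrium frequencies, scaled to one expected substitution per site per
unit branch length, plus a proportion `pInv` of invariable sites (0, 0.25
or 0.5 in the shipped compositions). Structural identities — rows of Q
summing to zero, detailed balance `π_i q_ij = π_j q_ji` to 1e−10,
`P(0) = I`, long-branch convergence of tip composition to the WAG
equilibrium — are asserted in the test suite, and the embedded constants
are cross-checked against an independent copy.

Two numerical choices deserve a note:

* **Invariable sites are an exact-count mask**: `round(pInv × L)` sites
  are chosen once per root and never mutate anywhere in the tree. The
  per-site-Bernoulli alternative would only give the proportion in
  expectation; the exact mask makes "at least half the columns are
  identical across tips at `pInv = 0.5`" a guarantee rather than a
  tendency, which is the property the feature distributions rely on.
* **The Markov collapse in `makeNHEvolved()`**: since only one random
  tip per tree is kept, the pick is drawn first and the root is evolved
  along that tip's root-to-tip path length in a single exact step.
  A continuous-time Markov chain composed along a path is the chain run
  for the summed length, so the result is distributionally identical to
  evolving the whole tree and then picking — at a fraction of the cost.
  `collapse = FALSE` runs the literal full-tree route;
  `evolveOnTree()` itself always evolves every edge.

What the generator does **not** emulate: indels (evolution is
substitution-only, so evolved decoys keep their root's length and the
gaps in their alignments come from the aligner, not the process),
among-site rate variation beyond the invariable class, codon structure,
domain shuffling, and the fragmentary, contamination-prone sequences of
real transcriptome assemblies. Passing tests on synthetic data therefore
demonstrate that the features separate conserved families from random
and saturated-divergence decoys under the stated generative model — they
do not certify performance on any particular real proteome set, where
the NH class is broader and messier.

## Alignment

The package aligns with its own progressive aligner so that it runs
self-contained: a UPGMA guide tree on 3-mer cosine distances, then
profile–profile merges scored by mean-of-pairs BLOSUM62 with affine gaps
(open −10, extend −1; a maximal gap run of length k costs
`open + (k − 1) × extend`). The dynamic program (implemented in C++)
breaks ties deterministically — diagonal, then up, then left — so results
are identical across platforms. Correctness anchors: the pairwise score
equals an exhaustive enumeration oracle on short sequences, and every
aligner output degaps back to its input exactly (residues are never
permuted, dropped or mutated). Alignment quality beyond that contract is
deliberately not a goal — the downstream features are alignment-level
statistics, and any reasonable MSA carries them. Users who want a
production aligner can route clusters through `externalAlign()` (e.g.
MAFFT) and get the same conservation contract enforced on the result.

## Learners

The classifier zoo maps the reference configuration to portable
equivalents: a single-hidden-layer neural network ((features + 2)/2
units, 3000 epochs standalone or 500 inside a stack), a linear-polynomial
SVM with C = 1 fitted with Platt probability scaling, a 10-tree random
forest, Gaussian naive Bayes, and logistic regression. The two stacking
meta-classifiers feed a small neural network with the bases' class
probabilities — probabilities rather than hard labels, because every base
here supplies them and they carry strictly more information — collected
out-of-fold (10-fold) so the meta-learner never sees resubstitution
predictions. The with-LR stack uses all five bases; the without-LR stack
drops logistic regression. Features are standardised to training-set mean
and variance inside the model (zero-variance features get unit scale
rather than dividing by zero); the schema is locked at fit time and
enforced at prediction, and the decision threshold on P(H) defaults to
0.5 and is configurable — the filtering step reports hard decisions plus
the underlying probability in its manifest.

Dataset assembly follows two compositions: EQUAL (the five provenance
classes in equal counts) and PROP (half homology, the rest split equally
among the four NH types), split 80/10/10 into train/validation/test by
unstratified random sampling with the remainder assigned to training.

## Reproducibility and problem sizes

Every stochastic entry point takes a seed and runs on a local RNG stream
(the caller's RNG state is untouched); pipeline stages derive their
streams from one master seed via `deriveSeed(master, stage)`, so a single
integer reproduces a whole run byte-identically — asserted end-to-end in
the tests. Per-cluster randomness-scorer seeds are derived from the
cluster id, making feature tables invariant to cluster order.

The shipped experiment scales: the acceptance script runs the full
625-cluster EQUAL experiment at default generator parameters
(Poisson-44.3056 cluster sizes, 120–400 aa roots); the test suite
exercises the same pipeline at reduced sizes (tens of clusters,
Poisson means 4–8, 40–150 aa roots) chosen so the whole suite stays in
the minutes range — the contracts under test are scale-free, and the
separability check is run at a composition large enough for its
validation set to be meaningful.

## Known limitations

* The NH generative model covers two failure modes (spurious grouping of
  unrelated proteins, and saturated divergence); real false positives
  also include chimeric transcripts, partial ORFs and cross-species
  contamination, which have no generator here.
* The progressive aligner is adequate for feature extraction, not for
  publication-grade alignments.
* The randomness scorer is a principled stand-in; counts are consistent
  within a run of this package but not interchangeable with external
  ALISCORE output — do not mix the two sources within one training set.
* Gene identifiers in pairwise relation files are taken verbatim; no
  cross-species id normalisation is attempted.
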