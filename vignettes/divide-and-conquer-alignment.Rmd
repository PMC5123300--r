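---
title: "Divide-and-conquer multiple sequence alignment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divide-and-conquer multiple sequence alignment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmsa)
```

# The problem

Statistical multiple sequence alignment methods — those that co-estimate an
alignment and a phylogeny under an explicit model of substitutions,
insertions and deletions — are accurate but prohibitively expensive beyond
roughly a hundred sequences. `dcmsa` implements the two standard
divide-and-conquer strategies that let an expensive aligner scale:

1. **Iterative decompose–align–merge.** A guide tree is broken into
   bounded-size subsets by repeatedly deleting *centroid edges* (the edge
   whose removal minimizes the larger component's leaf count). Each subset
   is aligned by a pluggable subset aligner; alignments of subsets adjacent
   in the tree are merged by profile–profile alignment; and a full
   alignment is assembled by *transitivity* — equating columns shared
   through the pairwise merges. A new guide tree is then estimated from the
   alignment and the cycle repeats (three iterations by default, maximum
   subset size 200, with an optional final "boost" iteration that runs a
   premium subset aligner at maximum subset size 100).
2. **Backbone extension with an ensemble of profile HMMs.** A random
   backbone (at most 1000 sequences by default) is aligned with the
   iterative pipeline; profile HMMs are built on a hierarchy of nested
   centroid subsets of the backbone; every remaining sequence is scored
   against all HMMs, aligned to the best-bitscore model by Viterbi, and
   mapped back onto the (immutable) backbone columns. Placements are
   independent, so the stage is linear in the number of queries.

Two supporting components make the package self-contained: a
**posterior-decoding consensus** that compresses a sample of alternative
alignments of the same sequences into the single maximum-weight compatible
column set (the standard protocol for extracting one alignment from a
Bayesian sampler's output), and an **indel-aware sequence evolution
simulator** that provides ground truth for all evaluation.

# The data model

An alignment is a rectangular gapped character matrix over named
sequences; the gap character is `-` (`.` is rejected). Uppercase cells are
*homologous*; lowercase cells mark *non-homologous insertions* introduced
by the HMM-extension stage, each forming a singleton column for scoring
purposes. A column is identified by its *support map* — which sequences it
contains, and at which 0-based ungapped site. Two sites are a homologous
pair iff they share a column and both cells are uppercase. All evaluation
reduces to set operations on pairs and support maps.

# The subset aligner and the profile merge

The subset aligner is a black box behind `subset_aligner()`: either an
external command template (`{input}`/`{output}` placeholders, output
validated against the input sequences) or the built-in progressive
aligner. The built-in path estimates a guide tree by neighbor joining on
5-mer cosine distances and merges profiles in deterministic postorder.

Profile–profile alignment scores a column pair by the expected
sum-of-pairs residue score under the two columns' residue frequencies
(match 5, mismatch −4 by default; IUPAC ambiguity codes score as
mismatches against everything). Gap penalties are affine — a run of length
$k$ costs $g_{open} + (k-1)\,g_{ext}$ with defaults −10 and −0.5 — scaled
by the non-gap occupancy of the column being gapped against, so sparse
columns are cheap to skip. For single-sequence profiles this reduces
exactly to classical affine-gap pairwise alignment, which is how the DP is
oracle-tested. Columns are stacked or interleaved, never split, so each
input alignment is induced exactly by the merge; traceback ties prefer
stacking, then gapping the second profile.

The transitivity merge identifies columns across the pairwise merges with
union–find and orders the resulting column classes topologically (Kahn's
algorithm, smallest-identifier tie-break). Because the merge graph mirrors
the decomposition's spanning tree, the precedence relation cannot cycle; a
cycle is nevertheless checked and raised as an error. After every merge
the package asserts the induction property: the full alignment restricted
to any subset reproduces that subset's alignment.

## Adjacency bookkeeping across nested deletions

When a deleted edge's side is decomposed further, the adjacency for that
edge attaches to the final subset containing the leaf nearest (in edge
counts) to the deleted edge on that side, ties broken lexicographically.
This rule is one concrete reading of "adjacent subsets defined by the
topology in the tree"; it guarantees the adjacency graph is a spanning
tree of the subsets, which in turn makes merge conflicts structurally
impossible.

# The HMM ensemble

Profile HMMs follow standard conventions the package documents rather
than invents: match states are columns with ≥ 50 % non-gap cells;
emissions are column residue *frequencies* blended with
`pseudocount × background` (frequencies, not raw counts, so the model is
invariant to duplicating backbone rows); transitions are estimated from
the observed match/insert/delete paths of the backbone rows with add-α
smoothing (α = the same pseudocount, so the smoothing floor vanishes
together with the emission pseudocount). Model selection uses the
*forward* bitscore — log2 of the forward probability over the background
null — while the final alignment uses the *Viterbi* path, mirroring common
profile-HMM practice. Ties prefer the larger subset, then the
lexicographically smallest. The ensemble retains every intermediate subset
of the recursive centroid decomposition down to `min_subset` (default 10)
leaves.

A re-queried backbone sequence returns to exactly its own columns,
insert-free, whenever every column it occupies is a match column of the
chosen HMM; residues sitting in minority (< 50 % occupied) columns have no
match state to return to and legitimately come back as insertions. The
test suite asserts the former and deliberately not the latter.

# Posterior-decoding consensus

Columns are tallied across samples by support map alone — which sequences
are gapped in a column does not enter its identity, the natural reading of
a column "appearing" in a sample. The decoder selects a maximum-weight set
of pairwise compatible columns (disjoint cells, acyclic precedence).
`greedy` (default) adds columns by decreasing weight, breaking ties by
larger support then lexicographic key, and falls back to the best single
input sample if that sample's total weight is higher — so the output never
scores below the best sample. `exact` is a frontier dynamic program over
per-sequence positions, memoized on reachable states and restricted to ≤ 6
sequences of length ≤ 25; it exists as a provably optimal oracle for
testing, not as the production path. Sites not covered by any selected
column re-enter as weight-0 singletons at the earliest topologically valid
position (Kahn's algorithm prefers available singletons).

# The simulator

`simulate_msa()` evolves a root sequence (drawn from the equilibrium
frequencies) down a rooted tree. Substitutions use exact transition
sampling — the matrix exponential of the scaled GTR rate matrix per branch
and per rate category — rather than event-by-event simulation; this is
exact and fast. Gamma rate heterogeneity is discretized to 4 categories by
the median method; categories are assigned at the root and inherited,
insertions drawing fresh categories. Indels follow the sequential
"number, position, length" recipe: per branch, insertion and deletion
counts are Poisson with mean `rate × branch length × length at branch
start`; positions are uniform; lengths are geometric on {1, 2, ...};
deletions truncate at the sequence end. The Poisson count law is a
documented stand-in — the classical DNA simulators do not publish their
exact event-count law. Global column bookkeeping makes an inserted site
homologous only within the subtree below the insertion, and ungapping the
true alignment reproduces the leaf sequences exactly (asserted).

## Study conditions used by the tests and the acceptance script

The simulated replicates use 100 taxa on a birth–death (Yule) tree scaled
to a mean root-to-tip depth of 0.4 substitutions/site — a moderate rate
giving average p-distances near 45 % — with insertion and deletion rates
of 0.02 events/site/unit branch length, geometric mean indel length 2, and
root length 300; the extension stage uses 150 taxa with a 50-sequence
backbone, and the simulator-calibration check uses two-taxon Jukes-Cantor
trees with 10 000 sites. These sizes keep a full run of the suite in the
low minutes while leaving each stage's decomposition, merge and placement
machinery genuinely exercised (the 100-taxon runs decompose into ~8
subsets at maximum subset size 25). What passing these tests shows is that
the machinery is correct and that iterating helps under the simulator's
homogeneous GTR-with-indels process; it does not certify accuracy on real
data, whose alignment difficulty (selection, structure-driven covariation,
heterotachy, fragmentary sequences) the generator deliberately does not
model.

# Evaluation

Precision (modeller score, 1 − SPFP) and recall (SP score, 1 − SPFN)
compare the homologous pair sets of the estimated and reference
alignments; the total-column (TC) score is the fraction of reference
columns whose full support reappears as a column of the estimate.
Lowercase insertion cells contribute no pairs and are excluded from column
identity, matching the convention used when scoring extension-style output.
Tree error is Robinson–Foulds in its asymmetric normalization — the
percentage of the reference tree's non-trivial bipartitions missing from
the estimate — with the symmetric variant available behind a flag; Delta-RF
is the difference between the RF error of the tree built on the estimated
alignment and that of the tree built on the true alignment, and can be
negative. Method comparisons across replicates use one-sided paired
t-tests with Benjamini–Hochberg control at 5 %; zero-variance differences
degenerate to p ∈ {0, 0.5, 1} by sign, with a warning.

# Numerical and degenerate-input choices

* Distance corrections: the Jukes–Cantor transform saturates at
  p ≥ 0.75; such pairs are capped at distance 5 (deterministically) rather
  than returned as infinite. A pair with no mutually ungapped position is
  an error naming the pair.
* Negative neighbor-joining branch lengths are clamped to zero; NJ input
  rows are sorted by id so the tree never depends on input order.
* All DP tracebacks carry explicit deterministic tie-breaks; every source
  of randomness flows from a single integer seed per entry point.
* Alphabet validation tolerates IUPAC ambiguity codes with a warning
  (they score as mismatches everywhere and are skipped in HMM emission
  counts); a strict flag rejects them.

# Known limitations

* The built-in subset aligner is a deterministic stand-in of progressive
  sum-of-pairs quality; production-quality subset alignments are expected
  to come through the external-command adapter.
* The greedy consensus is not guaranteed optimal (the exact mode is
  size-limited by design); its output is guaranteed only to be a valid MSA
  scoring at least as well as the best single sample.
* The per-iteration tree estimator is neighbor joining on JC-corrected
  distances, not maximum likelihood; an external tree estimator can be
  substituted where ML trees matter.
* Whether a backbone is uniform-random or length-filtered is a flag
  (`full_length_filter`); the default is uniform.
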