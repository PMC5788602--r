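---
title: "Methods: two-layer miRNA–disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-layer miRNA–disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spymir)
```

## The inference problem

The input is a binary matrix `A` of experimentally confirmed
disease–miRNA associations (rows = diseases, columns = miRNAs), together
with two side sources of similarity: a MeSH-style hierarchy of disease
terms (child → parent edges over a shared vocabulary) and a functional
similarity matrix over (a subset of) the miRNAs. The zeroes of `A` are a
mixture of true negatives and undiscovered associations; the task is to
rank them so undiscovered associations surface first. Two structural
assumptions drive everything: functionally similar miRNAs tend to be
associated with phenotypically similar diseases, and the known positives
are scarce relative to the true positives.

## Similarity layers

**Semantic, decay model.** A disease's hierarchy `T(D)` is the term
itself plus all its ancestors. The term `D` contributes 1 to itself and a
term `k` generations up contributes `delta^k` (formally: `delta` times
the maximum contribution among its children inside `T(D)`; the two
formulations coincide because `delta <= 1`). Pairwise similarity is the
sum of both diseases' contributions over shared terms, normalised by the
sum of their self semantic values, which puts it in `[0, 1]` with unit
self-similarity.

**Semantic, information-content model.** The decay model gives all terms
at the same depth the same weight. The second model instead weights term
`t` by `-log(c_t / n)`, where `c_t` counts how many of the `n`
per-disease hierarchies contain `t` — rarer, more specific terms weigh
more. The count includes every vocabulary term's own hierarchy, not only
those of the diseases being scored. Because the pairwise score is a ratio
of sums of these weights, it is invariant to the logarithm's base; the
test suite asserts this, which is why exposing `log_base` as a parameter
is safe. Natural log is the default.

**Gaussian interaction profile kernel.** Each disease's binary
association row (each miRNA's column) is its interaction profile; the
kernel is `exp(-beta * squared profile distance)` with
`beta = beta_prime / mean squared profile norm`. The normalisation makes
the kernel invariant to overall association density. An all-zero matrix
leaves the bandwidth undefined and is rejected.

**Integration.** A disease pair uses the average of the two semantic
scores when both diseases carry hierarchy annotation *and* that average
is positive; otherwise it falls back to the kernel value. Zero shared
ancestry is deliberately treated as "no semantic information" rather than
"semantically unrelated", so the kernel can rescue diseases whose
hierarchies are disjoint or missing. The miRNA side works the same way
with the functional matrix: used where present and positive, kernel
otherwise. Integrated matrices get a forced unit diagonal.

## The classifier and its two refinement layers

The base scorer is a closed-form regularized least-squares smoother
applied from both sides and averaged:
`FS = (SD (SD + lambda_d I)^-1 A + [SR (SR + lambda_r I)^-1 A^T]^T) / 2`.
`lambda_d = lambda_r = 2` is the conventional setting for this model
family and is exposed in `mda_params()`. The implementation performs one
multi-right-hand-side linear solve per side rather than forming the
inverse; the contract (asserted to 1e-10) is agreement with the
explicit-inverse formula. Integrated similarity matrices need not be
positive semidefinite; the solve proceeds whenever `S + lambda I` is
invertible, warns when the condition estimate exceeds 1e8, and errors
when the reciprocal condition falls below 1e-15.

**Spy layer (positive-unlabeled learning).** Each round plants
`spy_fraction` (default 0.10, at least one, at most all-but-one) of the
positives as spies by zeroing them, recomputes `FS`, and takes the
minimum spy score as a threshold: every originally-unknown pair scoring
*strictly* below it becomes a candidate reliable negative. Pairs at
exactly the threshold are kept unlabeled — the conservative reading.
The intersection over `spy_rounds` (default 200) independent rounds is
the final reliable-negative set, entered as −1 in the label matrix. Two
implementation decisions are worth stating. First, the score used inside
rounds is the combined two-sided `FS`, keeping rounds consistent with the
final classifier. Second, similarity matrices are *not* recomputed inside
rounds: spies are label perturbations, and recomputing the kernels 200
times per fit would dominate the runtime for a second-order effect.
Round `r` draws from seed `seed + r`, so the result is reproducible and
independent of execution order.

**Super-cluster layer.** Ward agglomerative clustering (Lance–Williams
recurrence applied to `1 − similarity`, the classical `ward.D`
convention) pools each side into super-entities. The recurrence is
implemented directly rather than delegated, because a deterministic
tie-break is part of the contract: among equally close cluster pairs, the
one whose smallest member names sort first merges. Test oracles are
`stats::hclust(method = "ward.D")` on tie-free instances and a naive
re-derivation of the agglomeration. Ward formally assumes squared
Euclidean distances and `1 − S` is generally not one; this is accepted
as-is — the clustering pools similar entities and is never used for
variance decomposition. The dendrogram is cut at `cut_height_fraction`
(default 0.70) of the maximum merge height, or at an explicit cluster
count. A disease is associated with a super-miRNA when it is associated
with any member; the pooled association is then removed unless at least
one of the disease's `k_neighbors` (default 5) most similar diseases
carries the same *pre-filter* pooled association, making the filter
order-independent. The super-disease side is built and filtered
symmetrically — the mirrored filter is an interpretation, since the
source formulation only says the second side is "constructed in the same
way". Super-associations are rescored with the same RLS solve, and the
final score multiplies the spy score by the average of the two
super-level supports.

## Evaluation protocols

Global LOOCV hides each known association in turn, reruns the entire
pipeline on the reduced matrix, and ranks the held-out pair against all
originally-unknown pairs; local LOOCV restricts the comparison set to the
same disease's unknown pairs. Each case yields the fraction of its
candidate set it outscores (midrank for ties); the protocol AUC is the
mean of these fractions, and the ROC curve is the corresponding
rank-fraction staircase. This per-case formulation is needed because each
case is scored by a different rebuilt model, so pooling raw scores across
cases would compare incommensurable scales. Repeated k-fold CV shuffles
the positives into `k` near-equal folds per repetition (remainder cells
spread one per fold), pools each fold's held-out scores against the
candidate scores from the same rebuilt model via Mann–Whitney AUC,
averages over folds, and reports mean ± sd over repetitions. Stand-alone
`roc_auc()` uses the midrank Mann–Whitney statistic, which equals the
trapezoidal area under its ROC staircase.

By default cross-validation recomputes the Gaussian kernels from each
training matrix, so no information about held-out associations leaks
through the similarity side (`recompute_gip = FALSE` reuses the full-data
kernels — faster and slightly optimistic; both policies exist because the
original protocol descriptions in this literature leave the choice
unstated). Semantic and functional similarities do not depend on `A` and
are computed once.

## The synthetic benchmark

`synth_config()` plants a block structure shared by diseases and miRNAs:
same-block pairs associate with probability 0.6, cross-block pairs with
0.05; each block gets its own term subtree (depth 3, binary branching) so
semantic similarity correlates with blocks; the functional matrix is
two-level (0.8 / 0.2) plus symmetric noise of scale 0.05 clipped to
`[0, 1]`; 30% of true positives are hidden from the observed matrix. The
defaults (30 diseases × 40 miRNAs, 3 blocks) keep a full global LOOCV
with per-case kernel recomputation and 200 spy rounds per case around
twenty seconds, which is what the acceptance script and the recovery
tests run. This generator makes the method's core assumption true by
construction, so above-chance recovery of hidden positives is a
meaningful test of the implementation. It does *not* mimic real
association data in other respects: degree distributions are homogeneous
rather than heavy-tailed, block membership is exact rather than graded,
and hierarchy depth is uniform. Passing tests therefore demonstrate that
the machinery works where its assumptions hold, not that the assumptions
hold for any particular database.

Two observed behaviours of the layers on this benchmark are worth
recording. The 200-round intersection makes the reliable-negative set
small and precise, but pairs involving a nearly isolated disease (one
observed association) can score marginally *negative* — the RLS smoother
is not entrywise nonnegative — and land below every round's spy minimum,
so occasional hidden positives of such diseases are misflagged. And the
k-nearest-neighbour filter only discriminates when spurious pooled
associations are isolated: at the default 0.05 cross-block density about
half the diseases carry a cross-block pooled association, neighbours
mutually support them, and the filter removes little; the filter's
benefit shows at sparser noise (the test suite uses 0.02).

## Numerical and interface choices

- Names are normalised (lowercase, trimmed, internal whitespace
  collapsed) by every reader, because association lists, similarity
  files and hierarchies routinely disagree on casing; `normalize = FALSE`
  disables it.
- Similarity files may be asymmetric up to 1e-8 and are repaired by
  averaging with the transpose; larger asymmetry is treated as data
  corruption and rejected. Internally, symmetry is enforced to 1e-10.
- Hierarchy input is a child → parent edge list, not MeSH tree numbers;
  cycles are detected and reported with an example cycle. A disease's
  matching policy to hierarchy terms is left to the user-supplied file.
- Ranked output covers only unknown pairs, sorted by descending score
  with a stable (disease, miRNA) name tie-break; scores print with 6
  significant digits. AUCs use midranks; reported ranks are positional.
- `growth_rate()` rounds half-up to 2 decimals, matching how such
  percentages are conventionally printed.

## Limitations

- Reproducing published full-database AUCs requires the corresponding
  external inputs (association export, functional similarity matrix,
  MeSH-derived edges) plus parameter details those publications omit
  (decay factor, bandwidths, cut threshold, neighbour count); the
  file-based interface supports such runs but this package ships no
  external data.
- The spy layer assumes low-scoring unlabeled pairs are negatives; for
  weakly annotated diseases this is exactly where undiscovered
  associations live, which bounds its safe aggressiveness (hence the
  conservative strict-inequality threshold and 200-round intersection).
- No alternative linkages, PU heuristics, or learned regularization are
  provided; the scope is this one two-layer model and its evaluation.
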