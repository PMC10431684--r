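---
title: "Negative sample selection for bipartite link prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative sample selection for bipartite link prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A bipartite network `G = (V1, V2, E)` records associations between two kinds
of entities — chemicals and diseases, users and items, authors and papers.
Link prediction asks which unobserved pairs are likely to be true
associations. Supervised approaches, matrix factorization (MF) foremost,
need both positive and negative training samples; but in most association
data an unlinked pair does **not** mean "no association" — it means "not
observed yet". Training an MF model with every unlinked pair as a reliable
zero produces a model biased toward predicting nothing.

`fcalink` implements *negative sample selection* (NSS): before training, it
marks the unobserved pairs that network structure itself suggests are likely
links, and draws negative training samples only from the remaining, unmarked
pairs.

## Maximal bi-cliques as formal concepts

The structural signal comes from *bi-cliques*: fully linked sub-networks
`(Vc1, Vc2)`, which read as clusters of strongly related entities. A maximal
bi-clique of the bi-adjacency matrix is exactly a *formal concept* of the
corresponding formal context `K = (G, M, Y)`: a pair `(A, B)` with

* `A = B'` — the objects incident to every attribute of `B`, and
* `B = A'` — the attributes shared by every object of `A`.

Concepts are partially ordered (`(A1,B1) ⪯ (A2,B2)` iff `A1 ⊇ A2`, i.e.
`B1 ⊆ B2`) and form the concept lattice. `derive_objects()`,
`derive_attrs()` and `closure_of()` expose the derivation machinery;
`enumerate_concepts()` produces every concept exactly once.

### Exactly-once enumeration

Enumeration is a depth-first search from the top concept
`closure_of(integer(0))`. A child is generated from concept `(A, B)` by the
augmentation operator — close `B ∪ {b}` for an attribute `b` outside `B` —
and a canonicity test decides whether the child belongs to this parent.

The package uses the close-by-one (CbO/LCM family) discipline:

* children of a node generated by attribute `y` are tried only for `b > y`,
  and
* the child is accepted iff closing added **no attribute with ID below
  `b`** (prefix preservation).

A weaker and superficially attractive test — "the smallest added attribute
exceeds `max(B)`" — does *not* guarantee uniqueness: in the context
`g1:{1,2}, g2:{1,2,3}, g3:{1}` the concept `{1,2,3}` passes that test both
from parent `{1}` and from parent `{1,2}`. Likewise, restricting candidates
to `b > max(B)` loses concepts when a closure contains attributes above the
augmentation point (context `g1:{1,3}, g2:{2,3}`: the root closes to intent
`{3}`, and `({g1},{1,3})` is reachable only via `b = 1 < 3`). Both
counterexamples are locked into the test suite, and
`enumerate_concepts_bruteforce()` — closure of all `2^|M|` attribute
subsets — certifies the enumerator on hundreds of random contexts. The
exported `is_canonical()` implements the min/max predecessor condition on a
lattice edge for reference; the enumerator's prefix test is strictly
stronger.

The DFS runs on an explicit stack, so pathological lattices cannot exhaust
the C stack; the visitor contract (`function(concept, depth)`, preorder,
exactly once per concept) is unchanged. With no pruning the number of
visits equals `|C|`, the number of concepts — the linear-in-`|C|` cost the
method advertises. `min_extent` pruning is sound because extents only
shrink along any descending chain.

## Overlapping bi-cliques and structural holes

For two comparable concepts (`lower ⪯ upper`), define component sizes
`s1 = |extent|`, `s2 = |intent|` and overlap rates

```
sigma1 = min(|A_l|, |A_u|) / max(|A_l|, |A_u|)
sigma2 = min(|B_l|, |B_u|) / max(|B_l|, |B_u|)
```

A pair is *non-trivial* when all four sizes are at least `alpha` and both
rates at least `rho` (`>=` follows the pseudocode convention of the
algorithm family; both thresholds are user parameters, so an open-interval
reading is one epsilon away). The *structural hole* of the pair is the
Cartesian product of the exclusive regions,
`(A_l − A_u) × (B_u − B_l)`: the pairs that the shared structure of two
heavily overlapping clusters suggests should be linked. Those pairs must
not be used as negatives.

Three facts about chains `c1 ⪯ c2 ⪯ c3` drive the algorithm, and the suite
checks them on every DFS chain of sampled lattices:

1. extents shrink and intents grow monotonically;
2. `sigma1` (and dually `sigma2`) is multiplicative:
   `sigma1(c1,c3) = sigma1(c1,c2) · sigma1(c2,c3)` — so once an ancestor's
   rate with the current concept drops below `rho` it can never recover
   deeper in the chain, making front-pruning of the ancestor chain safe;
3. the extreme pair's hole **contains** every inner pair's hole. The
   containment is strict in general — a pair combining a `c1`-exclusive
   object with a `c3`-beyond-`c2` attribute lies in no inner hole — so the
   equality sometimes quoted for this law is wrong, and the correct
   containment form is precisely why recording each concept against its
   *farthest* qualifying ancestor captures the most pairs per concept.

### The marking pass

`collect_marked_pairs()` walks the DFS once per orientation (objects =
left nodes, then the transpose — chains visible only from the attribute
side are caught by the second pass), maintaining the ancestor chain of the
current concept. For each concept with both components at least `alpha` it
finds the farthest ancestor whose `sigma1` with it still reaches `rho`
(found by a front-scan; correctness rests on multiplicativity), re-checks
the full non-triviality condition on that pair, and emits the pair's hole.
Holes from the transposed pass are transposed back; the union is
deduplicated and any incidence pair is removed — a hole of a non-adjacent
lattice pair can contain an observed link, and marked pairs are defined on
the unobserved part of the network.

Two honest limitations, both inherent to the linear-time chain recording
rather than to this implementation:

* only pairs lying on a DFS chain (in either orientation) can be recorded,
  so the marked set can be a subset of the union over *all* comparable
  non-trivial pairs (the test suite compares against that brute-force union
  on a planted fixture where the two coincide);
* the DFS tree depends on the attribute order, so on arbitrary contexts the
  marked set is not invariant under node relabeling. On planted
  block-structured networks — the regime the method targets — every
  qualifying pair lies on a forced chain and the output is stable under
  relabeling, which is what the suite asserts.

### Selecting negatives

`select_negatives()` forms the pool `(V1 × V2) − E − marked` and draws
exactly `floor(sample_rate · |pool|)` pairs uniformly without replacement,
deterministically per seed. The sample rate is interpreted **relative to
the unmarked pool** (the selection is "from the unmarked node pairs"); the
alternative reading — relative to all unobserved pairs — differs only by
the constant factor `|pool| / |unobserved|`, which the prediction manifest
reports. `select_negatives_random()` is the control: the same draw with no
marking at all.

## The factorization model

Training samples are the present links (value 1) plus the selected
negatives (value 0). The confidence score of pair `(i, j)` is

```
score(i, j) = mu + b_i + b_j + p_i . q_j
```

with `mu` the training-value mean, `b_i`, `b_j` additive biases and
`p_i`, `q_j` rows/columns of the `N × k` and `k × M` factor matrices. The
objective is the regularized squared error over training samples:

```
sum (a_ij - p_i.q_j - b_ij)^2 + lambda (b_i^2 + b_j^2 + ||p_i||^2 + ||q_j||^2)
```

One SGD update for sample `a_ij`, with residual
`e = a_ij - score(i, j)` and pre-update values on all right-hand sides:

```
b_i <- b_i + gamma (e - lambda b_i)        p_i <- p_i + gamma (e q_j - lambda p_i)
b_j <- b_j + gamma (e - lambda b_j)        q_j <- q_j + gamma (e p_i - lambda q_j)
```

Two readings had to be fixed against obvious typos in the printed source
material: the second bias update is the symmetric `b_j` update (the printed
line assigns `b_j + ...` to `b_i`, which is neither symmetric nor
convergent), and the confidence of an unobserved pair is the score above,
not the residual formula (whose `a_ij` is unknown for unobserved pairs).

Training runs `max_iters` epochs, each a fresh uniform shuffle with one
update per sample — this realizes "every sample updated at least i times"
without per-sample counters. The epoch loop is C++ (`src/sgd.cpp`); the
exported `sgd_update()` is the reference R implementation, and the suite
asserts the two agree bit-for-bit, so the fast path never drifts from the
documented arithmetic. The regularized objective is logged per epoch
(`attr(model, "objective_trace")`); a non-finite value aborts with a
diagnostic rather than returning garbage.

Raw MF — the principal comparator — is the same machinery with every
unobserved pair as a value-0 sample (`raw_training_set()`).

### Defaults

| parameter | default | why |
|---|---|---|
| `k` | 16 | small against the benchmark's min(N, M) = 60; rank of block structure plus slack |
| `gamma` | 0.01 | stable for 0/1 targets at these sizes; the objective trace confirms descent |
| `lam` | 0.05 | mild shrinkage; reconstruction tests use 0 where exact fit is the point |
| `max_iters` | 30 | objective plateaus well before this on benchmark-size problems |
| `init_scale` | 0.1 | break symmetry without swamping the biases |
| `alpha` | 2 | smallest size at which "cluster" is meaningful |
| `rho` | 0.3 | below the benchmark's planted overlap (0.4), above noise-level overlaps |
| `sample_rate` | 0.5 | mid-grid; the benchmark sweeps 0.2–1.0 because the best rate is data-dependent |

None of these are claims about optimality; the source method states no
values, so they are package defaults chosen once for the benchmark
geometry, exposed everywhere.

## Evaluation

The evaluation universe is built from a train/target split: positives are
the hidden positive links (or, optionally, all target-present links missing
from the input); negatives are the target's labeled absent links; pairs
with no target label are excluded and the universe size is reported, so a
user always sees how much of the network the numbers describe. Universes
never contain input-present links.

* **AUC** is computed rank-based (Mann-Whitney with ties counted one half);
  the ROC curve is swept over score levels with tied scores grouped, so tie
  blocks appear as diagonal segments and the trapezoidal area equals the
  rank statistic to floating-point accuracy — both routes are computed and
  compared in the tests.
* **AUPR** is average precision over grouped score levels, not a trapezoid
  on PR points (the trapezoid systematically over-estimates PR area).
  Under a constant score it equals prevalence; a perfect ranking gives 1.

## The synthetic world

`generate_planted()` builds the regime the method exploits: a chain of
`n_blocks` full bi-cliques in which consecutive blocks share a fraction
(`overlap_fraction`) of nodes per side. Sharing creates comparable concept
pairs whose holes are analytically known (`known_hole_pairs()`), which
gives the marking stage an exact oracle in the noise-free case.

The generator then realizes the structural-hole premise: a fraction
`hole_link_rate` of the analytic hole pairs are *genuine missing links* —
present in the target, never observable in the input. This is the
curated/inferred structure of association databases: the input holds the
observed cluster structure, the target additionally holds what that
structure implies. A further `hide_fraction` of the observable links is
masked uniformly (round half-up), `noise_rate` adds background edges, and
`absent_label_rate` labels a fraction of target non-edges as known absents.
The input never carries absent labels.

What the generator does **not** emulate: heavy-tailed degree distributions,
rating-threshold label noise, weighted or typed edges, and block structure
that is anything other than a chain. A green benchmark therefore
establishes that the pipeline recovers planted structure and that the
comparative orderings hold *in this world*; it is not a claim about any
external dataset.

The packaged benchmark (acceptance criterion) runs two scenarios on a
60 × 80 network with six 10–12-node blocks over five seeds:

* *link recovery*: defaults (20% masked, half the hole pairs are real
  links, 30% of non-edges labeled absent);
* *aggressive prediction*: every hole pair is a real missing link and every
  non-edge is labeled, emulating dense-target/sparse-input inference.

In both, the suite asserts orderings of means, not magnitudes: MF with
FCA-based selection at its best sample rate is at least as good as raw MF
(AUC and AUPR), and the FCA peak is at least the random-selection peak.
The best-rate comparison is the method's own protocol — the sample rate is
a tuned operating parameter, estimated by sweeping, and the rate grid is
part of the declared benchmark.

## Numerical and design choices

* Threshold comparisons use `>=` for `alpha` and `rho`; documented, and
  both are continuous/integer parameters so either strictness is
  reachable.
* `mask_positives()` rounds half-up; any fixed rule works, this one is
  stated.
* Prediction files sort by descending score with `(left, right)` as the
  tie-break, so outputs are byte-stable.
* All randomness (masking, sampling, initialization, shuffles, generation)
  flows through explicit integer seeds and restores the caller's RNG
  state.
* Degenerate inputs fail loudly: empty training sets, degenerate
  evaluation universes, infeasible block layouts, non-finite scores and
  objectives are errors, not silent results.
* Node identifiers are opaque strings; dense 1-based positions are used
  internally (the canonical order only needs a total order on attributes)
  and names are restored on every outward-facing surface.

## Limitations

`|C|` can grow exponentially with network size; `alpha` pruning is the
practical control, and per-stage counts (`|C|`, marked pairs, pool size)
are logged so users can see the cost. The marking stage's chain recording
trades completeness for linearity in `|C|` (see above). The MF stage is
plain biased factorization — no non-negativity, no implicit-feedback
weighting, no early stopping — because the contribution under study is the
selection of negatives, and a richer factor model would confound it.
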