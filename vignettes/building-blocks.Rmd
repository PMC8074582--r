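---
title: "Building blocks of interest networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building blocks of interest networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netblocks)
```

`netblocks` extracts small subgraphs of undirected networks that act as
*building blocks*: they reproduce the host graph's motif distribution and
carry enough structural signal to predict its diffusion behaviour. This
vignette is the package's account of the underlying models, the defaults
it fixes, and the places where the design was genuinely open.

## The two criteria

**Topological.** Every connected k-node induced subgraph of a graph is an
occurrence of one of a small number of isomorphism classes (2 classes at
k = 3, 6 at k = 4, 21 at k = 5). Normalizing class counts gives the motif
distribution `mdist(G)`. A sample M of host G is judged by the squared
deviation

δ(M, G) = Σ_c (mdist(G)_c − mdist(M)_c)²,

reported as the mean over classes. δ is zero iff the two frequency
vectors coincide, and mean δ over a corpus of hosts, per sampling method
and sample size, is the topological score.

Three census variants are supported, following the standard F-measures of
motif mining: `JOINT_RATIO` counts all occurrences (F1); `DISJOINT_RATIO`
counts only a maximal set of mutually edge-disjoint (F2) or node-disjoint
(F3) occurrences, normalized by the *total* occurrence count so that the
vector also reflects how much of the graph the disjoint set covers; and
the scalar `DISJOINT_TOTAL_RATIO` is the ratio of disjoint to total
occurrences. Disjoint selection uses the shuffle-greedy heuristic: shuffle
all occurrences with a seeded RNG, then keep each occurrence iff it does
not overlap a previously kept one. The result is a maximal independent
set of the overlap graph; the shuffle seed is recorded in the census so
every disjoint count is reproducible. We deliberately use the
shuffle-greedy rule rather than a min-degree heuristic on the overlap
graph: it is the cheapest rule that is unbiased with respect to class,
and its seed-to-seed variability is small (bounded-range property tests
cover this).

A caveat worth stating: greedy selection under the two policies runs
independently, so for an individual class the edge-disjoint count can
occasionally fall below the node-disjoint count even though the
node-disjoint *total* never exceeds the edge-disjoint total. Per-class
monotonicity holds against the joint count only.

**Functional.** Diffusion is the discrete-time susceptible-infected
model: at each synchronous step, a susceptible node with m infected
neighbours becomes infected with probability 1 − (1−r)^m (independent
per-edge Bernoulli exposures at rate r). Its mean-field limit is the
logistic equation dI/dt = C·r·I·(N−I), whose closed form and continuous
transient time are available in `logistic_reference()`, and whose
conductance prefactor C can be fitted to simulated mean infection curves
(`fit_conductance`: log-grid search over C ∈ [1e−6, 1] plus local
refinement, residual tolerance 1e−8). The transient time τ(G) is the
first step at which the infected count reaches θ·N_reachable. The
functional criterion asks whether a regression from sample motif features
(class frequencies plus the disjoint-total scalar) to τ(host) attains a
useful R².

The subgraph-size scaling proposition — τ(M) ≈ (#M/#G)·τ(G) when M and G
share conductance — conflicts with the logistic solution itself, whose
transient scales like ln N/(C r N). The package therefore reports the
ratio (τ(M)·#G)/(τ(G)·#M) as a diagnostic (`scaling_ratio`) and never
asserts it.

## Defaults that matter

| parameter | default | units | why |
|---|---|---|---|
| infection rate `r` | 0.3 | per-edge per-step probability | fast enough that τ is finite at desk scale, slow enough that fronts are stochastic |
| activation fraction θ | 1.0 | fraction of reachable nodes | the only parameter-free reading of "fully activated"; τ is then the full sweep time of the component |
| SI runs per host | 10 | runs | the estimation protocol; the mean is the regression target |
| initial condition | 1 uniform node | — | a single seed makes τ comparable across graphs; a fixed-seed policy exists for tests |
| `max_steps` | 10⁴ | steps | runs not finishing are *censored*, never silently truncated; estimates use uncensored runs and report the censored count |
| motif size k | 4 | nodes | 6 classes give an informative yet cheap feature vector; k configurable in 3–5 |
| overlap policy | edge-disjoint (F2) | — | the weaker, more commonly satisfiable constraint; F3 available |
| snowball branching k | 10 | neighbours | bounds frontier growth without starving the sample |
| jump probability (RWJ) | 0.1 | per step | standard escape rate from closely-knit regions |
| PageRank damping | 0.85 | — | the conventional value |
| boosting iterations | 100 | rounds | the evaluation protocol; otherwise library defaults |
| shuffle splits | 5 × 70/30 | — | R² averaged over five random splits with 30 % held out |
| replicates | 3 | samples per (host, method, size) | averages out sampling noise in δ and triples the regression rows |
| size grid | 10–50 step 10 | nodes | brackets the range where both criteria move and then plateau |

Walk samplers count *distinct visited nodes* toward the target size — the
convention needed for fixed-size samples — and a stall guard aborts a
walk after 1000·#V steps without a new node, restarting from a fresh
uniform seed on the same RNG stream (at most 10 restarts, then an
error naming the method). Metropolis–Hastings "stay" events add no node
but count toward the guard. The non-backtracking walk forbids an
immediate return to the previous node except at degree-1 nodes, where
backtracking is the only continuation.

Two sampler families return different objects by design: node-, walk- and
exploration-based methods return the subgraph *induced* on the selected
node set; uniform edge sampling (RE) returns the sampled edges themselves
with their endpoints (never the induced graph), stopping at the first
edge that reaches the target node count — hence its size contract of
n or n+1 nodes.

Shortest-path sampling anchors each path after the first in the already
collected set (one endpoint inside, one uniform outside) and truncates
the final path from its far end to land exactly on the target size. This
keeps the output connected, which the exploration-family contract
promises; tie-breaking among equally short paths is randomized inside the
BFS.

## The synthetic corpus generator

Real interest-network corpora are not shipped with the package. The
generator reproduces their *statistical profile*: for each topic, a node
count, edge density, global clustering and degree assortativity, and 11
monthly graphs per topic with node counts jittered ±10 % around the
topic average. The bundled table covers 26 topics; the six used as the
default corpus span sparse hub-dominated graphs (counterstrike, density
0.0025, clustering 0.0086) to denser, more clustered ones (stopsmoking,
clustering 0.05) and strongly disassortative ones (freedonuts, −0.38).

Construction is three-phase, each phase controlling one statistic while
approximately holding the earlier ones:

1. **Density.** A random graph with exactly the implied edge count and
   edge probability proportional to the product of power-law-like node
   weights (weight exponent implied by a degree exponent of 2.5). Density
   is thereafter exact by construction. If the realized degree sequence
   cannot support the assortativity target — checked against the sorted
   stub-pairing lower bound, the most disassortative value any simple
   wiring of that degree sequence could reach — the weight tail is
   steepened and the draw repeated (at most three times). This
   target-aware heterogeneity is the package's own choice: without it,
   strongly disassortative topics are unreachable for some seeds no
   matter how the edges are rewired.
2. **Clustering.** Wedge-closing rewiring (or triangle-breaking when the
   start lies above target), paid for by deleting an edge chosen among a
   few candidates to prefer one sitting in no triangle. Triangle and
   connected-triple counts are maintained incrementally, so each of the
   up-to-20m attempts costs O(degree).
3. **Assortativity.** Degree-preserving two-edge swaps, accepted when
   they move the Pearson endpoint-degree correlation toward target
   without pushing clustering out of tolerance. Proposals are targeted:
   the first edge is drawn with probability proportional to its endpoint
   degree product when assortativity must decrease (those are the edges
   that need breaking), and both valid re-pairings are evaluated. Since
   degrees are invariant, the correlation updates from the endpoint
   product sum alone.

Generation *fails loudly* when the achieved statistics miss tolerance
(density 20 % relative — exact here; clustering within the larger of
±0.01 and 50 % relative, loose because very sparse graphs hold few
triangles; assortativity ±0.07; a NaN assortativity, i.e. a regular
graph, passes vacuously since no degree-preserving move can change it).
`generate_corpus` records failures in its manifest without aborting the
corpus.

What the generator does *not* emulate: reply semantics, timestamps,
user overlap across months (monthly graphs are independent draws), and
connectivity — at the tabulated densities the implied edge count is below
n−1, so the graphs are necessarily disconnected, exactly like sparse
monthly reply networks. All stats target the *whole* graph; samplers and
SI simulation operate on the largest connected component, which for the
bundled topics holds a few hundred nodes. Consequently, passing tests
show that the methods behave correctly on graphs with realistic sparse,
heterogeneous, weakly clustered structure — not that the pipeline's
numerical outputs transfer to any particular real corpus.

## The evaluation protocol

One boosted-trees model per (method, size, variant) cell: features are
the sample's class frequency vector plus the disjoint-total scalar, the
target is the host's mean τ. Gradient-boosted trees with 100 iterations
(library defaults otherwise) are fit on five seeded random 70/30 splits;
R² on each held-out part is averaged. The notation of a weighted sum of
motif features suggests a linear model; a least-squares baseline is
available behind `model = "linear"` in `evaluate_prediction()`, but
boosted trees are the protocol default. Cells with fewer than 20 rows or
a constant target raise an error that the pipeline records as a per-cell
failure rather than aborting the run.

Ranking: methods sorted ascending by corpus-mean δ and descending by mean
R²; the recommended method is the first present in both top-5 lists
(smallest worse-of-two-ranks, δ rank breaking ties), with a logged
fallback to the best-R² method when the lists are disjoint. The
recommended size formalizes "changes become significantly lesser": the
smallest grid size from which the step to the next size is below 10 % of
the criterion's range over the grid, for both criteria (threshold
configurable).

## Numerical and degenerate-input choices

* Motif canonicalization minimizes the upper-triangular adjacency bit
  string over all k! permutations — with k ≤ 5 that is at most 120
  permutations per code, precomputed once per k into a 2^C(k,2) lookup
  table, so classification is a table lookup per occurrence.
* Graphs with no k-node connected subgraph yield an all-zero census; the
  frequency functions warn and return zeros, and the feature table flags
  such rows rather than dropping them.
* Degree assortativity is NaN for regular graphs (zero endpoint-degree
  variance) and reported as such, never coerced.
* Ties everywhere (CSE boundary gains, shortest-path neighbour order,
  component-size ties in `largest_component`) are broken uniformly at
  random under the operation's seed — except component ties, which break
  deterministically toward the lexicographically smallest member so that
  host selection never depends on an RNG.
* All pipeline seeds derive from a single master seed via a 31-bit string
  hash; two runs with one master seed produce byte-identical reports.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite stays in minutes on one CPU: ESU-oracle cross-checks on
30 random graphs of up to 12 nodes, walk stationarity at 5·10⁵ steps on a
30-node graph, mean-field agreement on a 100-node complete graph over
200 runs, regression recovery on a 50-host density gradient, and the full
pipeline on the bundled 6-topic, 66-graph corpus. Hosts in that corpus
have 400–900 nodes with largest components of 150–550; the pipeline's
census stage (C++ ESU plus greedy MIS) handles them in milliseconds to
tens of milliseconds per graph.

## Known limitations

* The ESU census is exhaustive; k = 5 on dense hosts with large hubs can
  produce millions of occurrences. The census is built once per host, and
  k = 4 is the default for exactly this reason.
* The shuffle-greedy MIS approximates the maximum independent set; its
  totals vary a few percent across seeds (bounded in tests), and
  per-class disjoint counts across policies are not monotone (see above).
* Conductance fitting assumes logistic-shaped growth; on strongly
  modular graphs the mean infection curve can be multi-phase and the
  single-C fit is then a compromise (the residual is reported).
* The regression criterion needs corpus-level variation in τ; on a corpus
  of near-identical hosts the R² criterion is uninformative and the
  ranking will lean on δ alone.
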