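---
title: "Methods: heterogeneous-network embeddings for SM-miRNA association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterogeneous-network embeddings for SM-miRNA association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Small molecules (SMs) regulate microRNAs, and discovering which SM-miRNA
pairs interact is expensive to do experimentally. `hinmir` treats the
problem as link prediction on a heterogeneous information network (HIN)
with three node types — SM, miRNA, disease — and six sub-networks: three
association networks (SM-miRNA, miRNA-disease, SM-disease) and three
similarity networks (SM-SM, miRNA-miRNA, disease-disease). Nodes are
embedded with two independently implemented representation learners, the
embeddings are merged, and a gradient-boosted tree classifier scores
candidate SM-miRNA pairs.

## Network construction

Mature miRNA identifiers are collapsed to their precursor
(`hsa-miR-21-5p` and `hsa-miR-21-3p` both become `hsa-mir-21`); numeric
paralog suffixes such as `hsa-mir-125b-2` are preserved. Disease names are
matched case-insensitively after trimming; SM accessions are opaque
strings. Edges are undirected — every relation here (association,
similarity) is symmetric — and duplicates per (pair, edge type) are
removed. The `HIN-3N` graph keeps all six networks; the `HIN-2N` ablation
keeps only SM-miRNA, SM-SM and miRNA-miRNA, hence two node types.

### Disease semantic similarity

Each disease is located in a MeSH-style hierarchy by dot-delimited tree
numbers; the prefixes of a tree number are its ancestor categories, and a
disease with several tree numbers owns the union DAG. Ancestor positions
that are not themselves diseases in the table stay anonymous; a position
that *is* another disease's tree number is relabelled with that disease id,
so nested diseases share nodes. With decay factor $\Delta \in (0,1)$
(default 0.5), the contribution of node $t$ to disease $d$ is

$$D_d(d) = 1, \qquad
  D_d(t) = \max\{\Delta \cdot D_d(t') : t' \in \mathrm{children}(t)\},$$

equivalently $\Delta^{\ell}$ with $\ell$ the shortest path from $t$ down to
$d$. The semantic value is $DV(d) = \sum_{t} D_d(t)$ and

$$\mathrm{Sim}(d_i, d_j) =
  \frac{\sum_{t \in T_{d_i} \cap T_{d_j}} \left(D_{d_i}(t) + D_{d_j}(t)\right)}
       {DV(d_i) + DV(d_j)}.$$

Profiles computed with different $\Delta$ refuse to mix. Diseases absent
from the tree table simply get no similarity edges — missing is not
dissimilar.

### Integrated miRNA similarity

Two miRNA similarity sources are combined by average ensemble: the mean
where both cover a pair, the single available value where only one does,
and 0 where neither does. The operation is idempotent and commutative.

### From similarity matrices to edges

How similarity values become graph edges is a genuine design gap; the
package defaults to a threshold rule, $\tau = 0.5$, with a `top_k`
alternative, because thresholding keeps the graph sparse and
deterministic. The disease network uses its own default `tau_dis = 0.42`:
for non-nested diseases the similarity above is bounded by
$1 - 1/DV$, and with $\Delta = 0.5$ the semantic value satisfies
$DV < 2$, so every non-nested pair scores strictly below 0.5 and the
generic threshold would always produce an empty disease network. 0.42
keeps pairs that share their deepest category. Edge weights are carried
into the graph but the embedders treat neighbours uniformly (walks and
adversarial sampling ignore weights); weight-proportional walks are a
config option.

## The relation-typed random-walk learner

Uniform random walks (defaults: 10 per node, length 80) ignore node and
edge types while walking. Every ordered pair of nodes at most $w = 2$ hops
apart yields a positive sample $\langle m, n, r, 1\rangle$ whose relation
$r$ is the sequence of edge types traversed; since each unordered pair of
node types maps to exactly one edge type here, the relation is implied by
the node-type sequence. Each positive spawns 5 negatives by replacing $n$
with a random node of the same type, resampling collisions with observed
positives. A three-layer logistic network scores

$$P(r \mid m, n) = \sigma\!\left(\sum_k W_M[m]_k \, W_N[n]_k \,
  f_{01}(W_R[r])_k\right),$$

with $f_{01}$ the elementwise logistic squashing that keeps relation
vectors in $[0,1]$ (chosen for differentiability; the contract only
requires the range) and no bias term. Stochastic gradient ascent maximises
$L \log P + (1-L)\log(1-P)$ per sample, with the learning rate (default
0.025) decaying linearly over all updates. Node embeddings are the rows of
the start-role matrix $W_M$; $W_N$ is kept separate, with weight tying as
an option. Weights initialise uniformly in $\pm 0.5/d$. The training loop
is compiled (Rcpp); the analytic per-sample gradients are also exposed in
R and are checked against central finite differences in the test suite.

## The adversarial learner

A relation-aware discriminator holds one embedding $e_u$ per node and one
matrix $M_r$ per edge type, scoring
$D(u, v, r) = \sigma(e_u^{\top} M_r e_v)$. Its per-epoch pass over the
shuffled edge list descends binary cross-entropy on three terms per real
edge $(u, v, r)$: the real triple as true; the same pair with a corrupted
relation $r' \ne r$ as false; and a generated fake neighbour as false. The
corrupted relation is drawn uniformly from the other five edge types: in
this schema no *other* edge type is compatible with a given node-type
pair, so restricting to type-compatible corruptions would remove the term
entirely, and the unrestricted draw is what the term exists for — teaching
the discriminator that $(u,v)$ are related by $r$ specifically. The
generalized generator fabricates neighbour embeddings
$g(u, r) = \tanh(e^G_u{}^{\top} M^G_r + \varepsilon)$,
$\varepsilon \sim N(0, \sigma^2 I)$ (default $\sigma = 0.1$; fakes need
not correspond to existing nodes), and ascends $\log D$ of its fakes
through the tanh layer. Minibatch chunks of the two players interleave
(5 each per epoch, 20 epochs). Learning rates default to 0.05: at
$10^{-3}$ the discriminator loss stays flat at $\log 2$ on
thousand-edge graphs and no separation between real and random triples
emerges within the epoch budget, while at $0.1$ training diverges;
0.05 trains stably with bounded embedding norms. Embeddings initialise
from $N(0, 0.1)$ and relation matrices from the identity. The
discriminator node matrix is the embedding used downstream.

## Features, datasets, evaluation

The two embedding matrices merge by `connection` (concatenation; 32+32
dimensions by default), `averaging`, or `multiplication`. An SM-miRNA pair
becomes one vector through `hadamard` (elementwise product, the default),
`average`, `minus`, or `abs_minus`. Known associations are positives;
negatives are drawn uniformly without replacement from the remaining
SM x miRNA grid (ratio 1:1 by default), restricted to entities with at
least one SM-miRNA association edge — mirroring an evaluation vocabulary
of association-network entities rather than every similarity-only node.

Classifiers: gradient-boosted trees (200 trees, depth 6, learning rate
0.1, single-threaded and seeded) plus Gaussian naive Bayes, L2 logistic
regression, k-nearest neighbours (k = 5) and AdaBoost over 100 decision
stumps as baselines.

Metrics: recall, precision, accuracy and F1 at a probability threshold of
0.5 (no threshold is prescribed by the protocol, so the natural one is
used); AUC by trapezoid over the ROC curve and AUPR by step-wise
integration of the PR curve, both with tied scores grouped into single
operating points so the curves are row-order invariant and equal their
brute-force pair-counting / step-integration oracles exactly. Precision
and F1 are defined as 0 when their denominators vanish.

Cross-validation is a stratified pair-level 10-fold split evaluated on the
held-out fold (the protocol's wording is ambiguous between training- and
test-fold evaluation; test-fold evaluation is adopted as the defensible
reading). Fold assignment is keyed on sorted pair ids before the seeded
permutation, so input row order cannot change any pair's fold. Candidate
ranking for one SM scores every embedded candidate miRNA that is not a
known partner and sorts by descending probability, ties broken
lexicographically.

## The synthetic generator

Every entity draws a latent unit vector (4 dimensions by default);
association edges appear with probability $\sigma(6\cos\theta + b)$, where
the intercept $b$ is solved numerically so the expected density matches
the configured 0.05 — the fixed slope 6 gives aligned pairs a clear
advantage over anti-aligned ones. Similarities are clipped noisy latent
cosines (noise sd 0.1), with the second miRNA source covering an 80%
subset to exercise the average-ensemble fallback; about half the emitted
SM-miRNA rows carry mature-arm suffixes so name normalization is exercised
end to end. The disease tree is a depth-3 binary hierarchy clustered on
the disease latents, so DAG similarity correlates with the planted
similarity. A configurable fraction of SM-miRNA positives can be withheld
for hold-out validation.

The default study conditions are 60 SMs, 100 miRNAs and 40 diseases —
roughly 300 planted associations and a two-thousand-edge graph — which one
CPU core processes end to end (both embedders plus 10-fold CV) in well
under a minute; the end-to-end recovery test repeats this over 5 seeds.
The generator emulates the statistical structure the method assumes
(entities sharing latent factors are co-associated and mutually similar)
but not several features of real curated data: no scale-free degree
heterogeneity, no literature-driven ascertainment bias, no noisy or
missing identifiers beyond the arm suffixes, and far smaller vocabularies
than the curated databases. Passing tests therefore demonstrate correct
mechanics and recoverable planted signal, not clinical performance.

## Known limitations

Embeddings are trained on the full graph before cross-validation, so test
positives are visible to the embedders as edges — the protocol being
followed is transductive, and its CV numbers should be read accordingly;
cold-start entity-level splits are out of scope. The adversarial learner
is consistently the weaker single source on this generator (its bilinear
discriminator must learn second-order structure from scratch), which the
feature-merging design tolerates: concatenation lets the classifier lean
on whichever source carries signal. Negative "associations" are unlabelled
pairs, not verified non-interactions; reliable-negative mining is a known
extension and deliberately not attempted.
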