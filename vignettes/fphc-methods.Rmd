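---
title: "Flooding-Pruning Hill-Climbing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flooding-Pruning Hill-Climbing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fphc)
```

## Model and problem statement

Expression data are modelled as i.i.d. samples from a discrete Bayesian
network: a DAG $G$ over genes $X_1,\dots,X_n$ and, for each gene, a
conditional probability table (CPT) $P(X_i \mid Pa_i)$ with one row per
configuration of its parents. The learning task is to recover $G$ (up to
Markov equivalence) from a sample-by-gene matrix of discrete codes
$1,\dots,r$.

Score-based greedy search over DAGs is consistent but local: with many
genes the operator space is huge and greedy BDeu hill climbing both
slows down and accumulates spurious edges. FPHC bounds the search space
first with a per-gene neighbour selection built entirely from pairwise
mutual information, then searches inside it.

## Phase 1 — flooding

For target $T$, let $M$ be the vector of MI values between $T$ and every
other gene, sorted ascending. Genes with no connection to $T$ contribute
estimation noise near zero; related genes sit above. Each candidate split
$k$ is scored with a Gaussian likelihood-ratio statistic

$$Q(k) = 2\left[\ell(M_{1:k}) + \ell(M_{k+1:m}) - \ell(M_{1:m})\right],$$

where $\ell(\cdot)$ is the segment log-likelihood at the maximum-likelihood
normal fit. The breakpoint is the maximizing $k$ (ties to the smallest
$k$, i.e. the larger related set), and the related set $R_T$ is everything
to its right. No significance threshold is applied; a breakpoint is
always declared on the estimated-MI path.

Two implementation decisions matter here:

- **Scale-aware variance floor.** The MLE variance of a one- or two-point
  segment can collapse to zero, and with only a tiny absolute floor
  ($10^{-12}$) a singleton segment contributes an essentially unbounded
  log-density spike. That drives the argmax to the degenerate split
  $k = m - 1$ (keep only the single top-MI gene) on smooth MI vectors —
  the opposite of flooding's deliberately over-inclusive intent.
  `detect_breakpoint()` therefore floors the segment variance at
  $\max(10^{-12}, (0.05\,\mathrm{sd}(M))^2)$ by default: genuinely tight
  clusters (including exact-zero noise groups) still dominate, but the
  spike artefact disappears. The primitives `normal_segment_loglik()` and
  `q_statistic()` keep the plain $10^{-12}$ default, and an explicit
  `var_floor` overrides the adaptive choice.
- **Exact-MI path.** When the MI matrix is an oracle computed from the
  network's enumerated joint distribution (`exact_mi_matrix()`), MIs
  carry no estimation error and the unrelated group consists of *exact*
  zeros — d-separated or disconnected genes. A breakpoint model of two
  noisy clusters is the wrong tool there (with all-positive smooth exact
  MI vectors it has no noise cluster to find and degenerates); instead
  `flood()` applies the analytic rule directly: $R_T$ is exactly the set
  of genes with nonzero MI to $T$. This is also what makes the
  tree-exactness guarantees below hold verbatim.

## Phase 2 — pruning by DPI Level

The data processing inequality says that for a Markov chain
$X \to Y \to Z$, $MI(X;Z) \le \min(MI(X;Y), MI(Y;Z))$. The pruning phase
turns this into an ordinal distance. Walk $R_T$ in MI-descending order;
the first gene gets level 1. For each later gene $X_i$, collect every
already-ranked $X_a$ with

$$MI(T;X_i) \le \min\big(MI(T;X_a),\ MI(X_a;X_i)\big);$$

the level of $X_i$ is one plus the maximum level among those $X_a$, or 1
if none satisfies the inequality. Level 1 genes are candidate direct
neighbours; level $\ell > 1$ genes look like relations mediated through
$\ell - 1$ closer genes.

Pruning keeps levels $\le \theta$. The threshold policy is either a fixed
integer or `"mode"`: the most frequent level in the ranking, never less
than 2 (ties between equally frequent levels go to the smaller level).
The floor of 2 keeps the default conservative — selection errs toward
keeping a too-large candidate set, which the scoring phase can still
correct, rather than deleting true edges, which it cannot.

On tree skeletons with exact MIs this procedure is exact, and the package
treats that as its acceptance anchor:

```{r tree-exact}
st <- random_tree(8, seed = 1)
bn <- random_cpts(st, cardinalities = 3, concentration = 0.25, seed = 2)
sel <- fpns(mi = exact_mi_matrix(bn), theta = 1)
setequal(
  paste(neighbor_pairs(sel)$a, neighbor_pairs(sel)$b),
  paste(skeleton_pairs(st)$a, skeleton_pairs(st)$b)
)
```

Duplicate paths break the single-mediator argument: when two genes share
two or more common causes (the `duplicate_parents` motif), neither cause
can screen the sibling by itself and the sibling can rank at level 1 —
a known false-positive mode that only the scoring phase can remove.

## Phase 3 — restricted hill climbing

The per-target neighbour sets are symmetrized into unordered candidate
pairs (`"union"` rule by default: either endpoint may nominate the pair;
`"and"` requires both). Greedy hill climbing then starts from the empty
graph and repeatedly applies the best add/delete/reverse operator under
the BDeu score (equivalent sample size 1, parent configurations counted
over the full cartesian product), with adds restricted to the candidate
pairs. Deletes and reverses of existing edges are always legal — a
reverse stays inside the (undirected) mask by construction. Ties break
deterministically in (operator, from, to) order; the search stops when no
operator improves the score by more than `tol`.

BDeu is likelihood-equivalent: Markov-equivalent DAGs score identically,
so learned structures are compared on their completed PDAGs
(`dag_to_cpdag()`, v-structures plus the standard orientation-propagation
rules) with `shd()`, and on skeletons with `ushd()` and `edge_fscore()`.

## Synthetic benchmarks

`random_tree()` (random recursive trees) and `random_dag()` provide
skeleton generators; `random_cpts()` parameterizes them with symmetric
Dirichlet CPT rows. The defaults target the expression-data regime:
3 states per gene (under/normal/over-expressed) and concentration 0.25,
which concentrates each CPT row on few states and yields strong
parent-child MI. `forward_sample()` draws ancestral samples with a single
seeded RNG stream; `exact_joint()` enumerates the joint distribution
(capped at $2^{20}$ cells) for the exact-MI oracles. `discretize()`
quantile- or width-bins continuous matrices into codes.

## Problem sizes and limitations

- The package is tuned for desk-scale experiments: tens of genes,
  $10^2$–$10^4$ samples. MI matrices are $O(n^2)$ tables; the exact
  oracles require the full joint ($\le 2^{20}$ states, e.g. 12 ternary
  genes).
- The flooding breakpoint needs at least three other genes, and its power
  grows with the number of genes: with only 7 MI values per target (8
  genes) the noise/related split is identifiable but coarse. The
  method's advantage over plain hill climbing is designed for networks
  an order of magnitude larger.
- For that reason the restricted search does not *dominate* plain hill
  climbing on very small networks: at 8 nodes plain BDeu hill climbing is
  already near-optimal, and across many random trees its mean skeleton
  error can be slightly below FPHC's (any neighbour-selection miss is an
  edge the restricted search can never recover, while spurious-edge
  pruning — FPHC's actual payoff — has little to do at this size). On
  the package's fixed acceptance fixture the two tie; treat small-network
  comparisons as sanity checks, not as the method's operating regime.
- DPI-based pruning at $\theta = 1$ is provably exact only on tree
  skeletons with exact MIs. Cyclic gene regulation cannot be represented
  (structures may hold cycles for diagnostics, but models, sampling and
  scoring require DAGs), and duplicate-path motifs inflate level-1 sets.

## Determinism

Every stochastic step (generators, sampling) takes an explicit seed and
is wrapped in an isolated RNG scope, so identical inputs produce
identical outputs; selection and search are fully deterministic given the
data. The command-line tools write a manifest (configuration, derived
seeds, package version) next to their outputs.
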