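---
title: "The hierarchical map equation: model, search and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hierarchical map equation: model, search and benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiermap)
```

## The model

hiermap scores a hard partition of a network by how concisely it lets you
describe a random walk on that network. A walker moves along the (weighted,
possibly directed) links; to report its position step by step you assign
codewords to events. With a modular code you keep one *module codebook* per
module — codewords for the member nodes plus an "exit" codeword — and an
*index codebook* whose codewords name the module being entered. Codewords can
be reused across module codebooks, so if the walker stays inside small, dense
regions for a long time, the description gets shorter than the one-codebook
bound. Shannon's source-coding theorem turns each codebook into a number: a
codebook used at rate $r$ whose codewords occur with relative rates $p_i$
contributes at least $r\,H(p)$ bits per step. For a flat partition
$\mathsf{M}$ into modules $i$,

$$
L(\mathsf{M}) \;=\; q\,H(Q) \;+\; \sum_i p_i^\circlearrowright H(P^i),
$$

where $q_i$ is the rate at which the walker enters module $i$,
$q = \sum_i q_i$, $H(Q)$ is the entropy of the relative enter rates,
$p_i^\circlearrowright$ is the rate of use of module codebook $i$ (member
node visit rates plus the module's exit rate), and $H(P^i)$ the entropy of
that codebook's distribution. Minimizing $L$ over partitions is the two-level
map equation approach to community detection.

The hierarchical generalization frees the code from a single index codebook:
modules may contain submodules, each level adding a nested index codebook.
The root codebook names the coarsest module being entered; each intermediate
module keeps a subindex codebook over its children's enter rates plus its own
exit codeword; each finest module keeps the node-level codebook. Every
codebook again contributes rate × entropy, and the total is the hierarchical
codelength. Its minimum over all trees decides *how many levels* the network
supports, how many modules each level has, and who belongs where: a level
survives only if the index bits it saves exceed the bits it costs. All
codelengths here are in bits, with the convention $0 \log 0 = 0$.

### The 27-node example

A network of nine triangles, ring-linked in groups of three, with the groups
themselves ring-linked (total degree 78), makes the mechanics concrete. All
rates follow from counting link ends:

```{r example}
fx <- triangle_hierarchy_network()
fl <- network_flow(fx$network)
two_level_codelength(fl, rep(1, 27))$total_bits      # one module: 4.75 bits
two_level_codelength(fl, fx$triangles)$total_bits    # nine triangles: 3.57
hierarchical_codelength(fl, fx$partition)$total_bits # 3-level tree: 3.48
```

The three-level description wins because naming one of nine modules through a
two-stage index (group, then triangle) is cheaper on average than a flat
nine-way index: the index codebooks shrink by 0.09 bits per step while the
module codebooks are untouched. `nested_clique_network()` generalizes the
construction (clique size, branching, levels); the ring links are placed on
nodes that carry no other ring link, which pins the degree sequence — 24
nodes of degree 3 and 3 of degree 2 — and with it all three codelengths.

## Flow

For undirected networks the walker's stationary visit rate is node strength
over total strength, in closed form; no iteration is run. Directed networks
are made ergodic by uniform teleportation at rate $\tau$ (default 0.15, the
convention of this method family; exposed everywhere as a parameter), with
dangling nodes teleporting uniformly. The stationary distribution comes from
power iteration (uniform start, L1 tolerance $10^{-12}$, at most 10,000
iterations, an error carrying the residual otherwise).

Teleportation is a regularization, not part of the system being described, so
the description afterwards excludes it: each link carries the probability
that the walker follows *that* link rather than teleporting; these flows are
renormalized to sum to one per step, and node visit rates are updated to the
total inflow along links. Inflow (rather than outflow) defines the updated
rate because a "visit" is an arrival; for directed networks the two differ,
and in- and outflow of a node need no longer balance. Index codebooks list
child *enter* rates (plus the module's own exit codeword in its parent's
codebook); for undirected networks enter and exit coincide.

## Search

Minimizing the hierarchical codelength is combinatorial, so the package uses
a stochastic recursive search:

* **Core.** Every node starts in its own module; in random sequential order
  each node moves to the neighboring module that most decreases the
  codelength (ties keep the current module, then the lowest-index candidate,
  so runs are reproducible given the seed). When a full pass makes no move,
  the network is rebuilt with modules as nodes and the procedure repeats.
* **Refinements.** Aggregated nodes can get stuck together, so two
  module-breaking moves alternate while they help: treating each module as a
  network of its own and recursively splitting it into freely movable
  submodules, and freeing every single node while keeping the current
  partition as the starting point. Both only ever accept improvements.
* **Recursion over levels.** For any module the algorithm first asks whether
  submodules shorten the description at all; if not, that branch ends. If
  they do, it tries to compress further both *below* (recursing into every
  submodule's internal network) and *above* (clustering the network formed
  by the modules themselves, whose codeword rates are their enter rates — the
  aggregate problem has exactly the same algebraic form, so one engine serves
  both directions). An extra index codebook is kept only when it saves more
  than the improvement threshold (default $10^{-10}$ bits, absorbing
  floating-point noise). Branch depths grow and shrink independently; a
  safety cap of 20 levels guards pathological inputs.
* **Restarts.** The whole construction restarts from scratch `n_restarts`
  times (default 100; tests and examples use 3–10) and the best tree wins.

Flow is computed once on the full network; aggregate moves operate on summed
visit rates and boundary flows, which aggregate exactly — the codelength
depends on rates only. Every accepted move strictly decreases the total, and
the codelength is bounded below, so the search terminates. On all small
graphs we can check exhaustively (every isomorphism class of connected
graphs up to six nodes, random seven-node graphs, and all depth-≤3
hierarchies of the seven-node path) the search returns the global optimum.

## Benchmarks and their feasibility region

`generate_hierarchical_benchmark()` plants a three-level structure: degrees
from a truncated power law (exponent −2; the lower cutoff is calibrated so
the mean matches `k_mean`), coarse and fine module sizes from truncated
power laws (exponent −1) that tile the node set, and each node's links split
between three pools — a fraction $\mu_1$ to other coarse modules, $\mu_2$ to
other fine modules inside its coarse module, the rest within its fine
module. Stubs are matched within each pool configuration-model style with
swap rewiring against self-loops, multi-edges and wrong-pool pairs. Small
fine modules can demand up to ~90% of their possible internal links, which
random matching cannot realize, so a largest-first greedy matcher takes over
per pool when rewiring stalls; stubs no pool can place are promoted one pool
coarser (never into a pool whose target fraction is zero — $\mu = 0$ must
mean no such links at all). Stub counts use randomized rounding, so realized
mixing is unbiased; the generator reports the realized fractions, which land
within about 1% (relative) of the targets at the sizes used in the tests.

The planted hierarchy is *well defined* when per-available-pair link
densities are ordered: within-fine > within-coarse-between-fine >
between-coarse. Approximating the available links as $n_f \bar k$,
$(n_c - n_f)\bar k$ and $(N - n_c)\bar k$ turns this chain into two lines in
the $\mu_2$–$\mu_1$ plane,

$$
\mu_1 < \mu_2\,\frac{N - n_c}{n_c - n_f}, \qquad
\mu_1 < 1 - \mu_2\,\frac{n_c}{n_c - n_f},
$$

evaluated at the worst-case (extreme) module sizes: largest coarse and
smallest fine for the first line, smallest coarse and largest fine for the
second. Both inequalities cap $\mu_1$ given $\mu_2$ (equivalently they
bracket $\mu_2$ from below and above given $\mu_1$); `feasible_mu1_bounds()`
returns the two lines and their minimum. The region is non-empty at small
$\mu_2$, the lines cross, and the region closes at
$\mu_2 = (n_{c,\min} - n_{f,\max})/n_{c,\min}$:

```{r region}
sp <- benchmark_spec(n_nodes = 10000, k_mean = 20, k_max = 100,
                     coarse_range = c(400, 4000), fine_range = c(10, 100))
feasible_mu1_bounds(sp, mu2 = c(0.1, 0.3, 0.5, 0.8))
```

### Scaled test conditions

The recovery tests run at $N = 1000$, $\bar k = 20$, coarse sizes 100–400,
fine sizes 10–50, $\mu_1 = 0.1$, $\mu_2 = 0.2$ — inside the well-defined
region — with the maximum degree set to 50, the largest fine size, mirroring
the reference setup where the degree cap equals the largest fine size (100 at
$N = 10{,}000$). A larger cap at these module sizes would make the planted
model itself infeasible: a hub's within-fine stubs could exceed what any fine
module can host. Five seeds, three restarts each, are enough for median NMI
at both levels to exceed 0.95 (in practice ≥ 0.99); the search takes a few
seconds per instance at this size.

## Evaluation

`normalized_mutual_information()` implements the contingency-table form
$2I(X,Y)/(H(X)+H(Y))$ in bits: 1 for identical partitions (including the
degenerate all-in-one vs all-in-one pair, by convention), 0 for independent
ones. Inferred trees are compared level-wise against the planted truth via
`level_slices()`: the coarsest slice, and the finest slice in which each
branch contributes its own deepest module — branches need not share a depth.
`hierarchy_statistics()` reports per-node averages (depth, finest-module
size), as module-level averages would over-weight small modules.

## Numerical choices and degenerate inputs

* Entropies use base-2 logarithms throughout; zero-rate codewords and
  zero-flow modules contribute 0 bits.
* Duplicate links aggregate by summed weight at load time; self-loops are
  kept (they are within-module steps for every partition and count twice in
  undirected strength, the usual random-walk convention).
* A partition tree never has an internal vertex whose only child is itself
  internal (such chains collapse on construction); the one-module partition
  keeps its single module vertex, so leaves sit at depth ≥ 2.
* The one-module codelength equals the entropy of the visit rates exactly;
  a depth-2 tree evaluates identically under the two-level and hierarchical
  implementations (two independent code paths, equal to $10^{-12}$).
* Node ids are contiguous 1-based integers internally; edge-list labels and
  Pajek's 1-based ids convert at the boundary, and original labels survive
  into `.tree` output.

## What the synthetic tests do and do not show

The nested-clique fixtures have exactly symmetric, noiseless structure, and
the benchmark generator plants clean power-law degrees and sizes with
independent stub matching. Passing tests on them demonstrates that the
codelength arithmetic is exact and the search reliably finds planted or
provably optimal structure; they do not demonstrate robustness to degree
correlations, overlapping communities, weighted heterogeneity, or flows for
which a random walker is a poor proxy. The method also inherits the map
equation's resolution behavior: modules with very little flow contribute
little codelength, so very small peripheral structures may be absorbed. The
search is a stochastic local optimizer — global optimality is verified only
on small instances; on large networks more restarts buy reliability at
linear cost.
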