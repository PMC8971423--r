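---
title: "Locating the sources of a spread from one infection snapshot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the sources of a spread from one infection snapshot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silocate)
library(igraph)
```

## The problem

A rumor, a computer worm or an infectious agent starts at a small unknown
set of seed nodes in a contact network and spreads along its edges. Some
time later we observe a single *snapshot*: which nodes are infected, and
nothing else — no infection times, no transmission routes, and no
knowledge of how many seeds there were. Source localization is the inverse
problem: recover the seed set from the snapshot and the network topology.
It is harder than the single-source version of the problem in two ways —
the number of sources must itself be estimated, and nearby sources produce
overlapping infection regions that confuse partition-based approaches.

## The diffusion model

We assume susceptible–infected (SI) dynamics in discrete time. Each edge
$(u,v)$ carries a transmission probability $P_{uv} \in (0,1)$, one value
per edge (the network is undirected and static). At every step each
infected node independently tries to infect each susceptible neighbour,
so a susceptible node $v$ turns with the hazard

$$\lambda(v) = 1 - \prod_{u \in N(v) \cap V_I} \left(1 - P_{uv}\right),$$

the product running over its currently infected neighbours; infected nodes
never recover. Updates are synchronous: step-$t$ infections are computed
from the step-$(t-1)$ state. `simulate_si()` implements exactly this and
stops at the first step where the infected fraction *strictly exceeds* the
`stop_fraction` (default 0.30), or at a `max_steps` cap (default
$10\,|V|$) that guarantees termination. Because each step can infect many
nodes at once, the final fraction typically overshoots the threshold —
with $P_{uv} \sim U(0,1)$ on a mean-degree-10 graph the last step can
double the infected set, so a 30 % rule commonly ends near 60 %. That
overshoot is a property of the threshold-stopped synchronous protocol
itself, and all benchmark results in this package are reported under it.
We validate the simulator against the hazard's closed form by Monte Carlo
rather than solving the marginal recursion
$P_I(v,t) = \lambda(v,t)\,P_S(v,t-1) + P_I(v,t-1)$ as a separate system.

## Scoring nodes by neighborhood entropy (SLBNE)

The first locator ranks every infected node by how much infection
information its neighbourhood carries, on the intuition that a source has
been infected the longest and therefore shows the most *fully infected*
neighbourhood, while late-infected nodes sit at the frontier next to many
susceptible nodes.

Five per-node quantities build on each other ($|N(i)|$ is always the
full-network degree; $U_i$ the uninfected neighbours of $i$):

* **Infection intensity**
  $\xi_i = \frac{|N(i)| - |U_i|}{|N(i)|} \cdot \frac{1}{1+e^{-|N(i)|}}$ —
  the infected fraction of the neighbourhood, damped by a sigmoid so that
  very low-degree nodes cannot reach high intensity on one lucky
  neighbour.
* **Intensity entropy** $IE_i = -\xi_i \log_2 \xi_i$ (with
  $0\log 0 := 0$) — the uncertainty carried by the uninfected
  neighbourhood; it is the penalty term.
* **Infection degree**
  $\eta_j = \sum_{t} \frac{\xi_t}{|N(t)|}$ — how plausibly $j$ is the
  *parent* of its neighbourhood.
* **Contribution** $\psi_i(j) = \frac{1/|N(i)|}{\eta_j}$ — node $i$'s
  share of neighbour $j$'s infection degree. $\psi$ can exceed 1 and is
  deliberately not clamped.
* **Adjacency entropy**
  $AE_i = -\sum_j \psi_i(j)\log_2\psi_i(j)$ — the information $i$
  contributes across its infected neighbours. Terms with $\psi > 1$ are
  negative, so $AE$ (and everything downstream) may be negative.

The node score is the **neighborhood entropy**

$$NE_i = AE_i - \alpha\, IE_i,$$

with $\alpha = 4$ by default; larger $\alpha$ punishes nodes sitting next
to many susceptibles harder. The default follows the empirical observation
that localization quality peaks there; it is exposed as a parameter
(`alpha`) because the optimum is data-dependent.

Infected nodes whose $NE$ strictly exceeds that of every infected
neighbour form the **core convex set** $C_s$ — the SLBNE prediction. Its
size doubles as the estimate of the number of sources.

### Neighbourhood conventions

The sums in $\eta$, $\psi$, $AE$ and the core-set comparison run over
*infected* neighbours only, while $\xi$ alone sees the full neighbourhood
(it explicitly measures the effect of uninfected neighbours). This is a
deliberate design choice with two consequences we rely on: $\eta_j > 0$
for every infected node that has an infected neighbour (an infected node's
infected neighbour always has $\xi > 0$), so $\psi$ is always defined; and
the score is computable from the infection subgraph plus degrees, the data
a practitioner actually has. `entropy_table()` exposes an
`eta_neighbors = "all"` switch for the alternative reading in which $\eta$
sums over all neighbours; it is not the default because it can zero out
$\eta$ for nodes whose neighbours are all uninfected, leaving $\psi$
undefined exactly where the locator needs it.

Degenerate inputs are resolved as follows: an isolated infected node (no
infected neighbour) gets $AE = 0$, $\eta = 0$ and qualifies for $C_s$
vacuously — it is plausibly a seed that never spread. On entropy-symmetric
snapshots (a fully infected cycle, twin bridge endpoints) the strict rule
selects nothing; the locator then falls back to the single node of
globally maximal $NE$, ties broken by smallest id, because a locator must
always return at least one candidate. All id-based tie-breaks use radix
(byte) ordering, which is locale-independent; ids are opaque strings
throughout and never coerced to numbers.

## Cluster division and cohesion (SLBIC)

Two sources that are direct neighbours can never both be local $NE$
maxima, so SLBNE systematically underestimates clustered seed sets. SLBIC
addresses this by dividing the infected set into $r = |C_s|$ *infection
clusters*, one per core, and adding each cluster's most central member.

Division is two-step, everything measured in the infected subgraph:

1. every infected direct neighbour of a core joins the cluster of the core
   with maximal similarity
   $$Sim(n_1,n_2)=\frac{Com(n_1,n_2)}{|N(n_1)\cup N(n_2)|}
     +\sum_{i\in N(n_1)}\sum_{j\in N(n_2)}\frac{Com(i,j)}{|N(i)\cup N(j)|},$$
   where $Com$ counts common neighbours. The double sum is taken
   literally, including $i=j$ pairs, with the convention
   $Com(x,x)=|N(x)|$ (so a self-pair contributes 1); the convention is
   isolated in `common_neighbors()` so it can be revisited.
2. the remaining infected nodes are swept outward in breadth-first order
   from the assigned frontier (equal depths in ascending id order, for
   determinism); each joins the cluster(s) it has most edges to among
   already-assigned neighbours, and joins *all* tied clusters on an exact
   tie — this is the only way cluster overlap arises. Nodes disconnected
   from every cluster join the nearest core's cluster by shortest path.

Similarity ties in step 1 are broken by proximity first (nearest core by
shortest path in the infected subgraph), then larger $NE$, then smaller
id. Proximity must lead: on sparse infection networks the similarity above
is frequently 0 to *every* core — a path's interior node shares no
common neighbour with either endpoint, and across disconnected components
everything is 0 — and an entropy-only tie-break would then happily assign
a node to a core in a different component.

Within each cluster, every member $i$ gets a **cohesion** score. Its
shortest-path distances to the other members (measured in the infected
subgraph, so paths may route through members of other clusters) are binned
into a histogram $\{d : count_d\}$, and with $M$ the largest observed
distance,

$$\delta_i = \sum_{d}\frac{M+1-d}{M+1}\cdot\frac{count_d}{APN}\cdot 0.5
  + NE_i \cdot 0.5 .$$

$APN$, "the number of all possible path lengths", defaults to the number
of distinct observed distances; `apn = "reachable"` normalizes by the
number of reachable members instead, making $count_d/APN$ a proper
distribution. Both conventions are implemented and tested because the
phrase is genuinely ambiguous; the distinct-count reading is the literal
one and is the default. $NE$ enters raw, exactly as defined — an option to
rescale it was considered and rejected as a silent change of the method;
the consequence, visible in our fixtures, is that the $NE$ term can
dominate the bounded distance term, e.g. pulling the condensed node of a
star-shaped cluster onto a well-connected bridge leaf rather than the hub.

The per-cluster cohesion maximizer (ties: larger $NE$, then smaller id) is
the **condensed node**; the SLBIC prediction is the union
$\hat S = C_s \cup C_{s1}$. The union can only add nodes, so SLBIC recall
is never below SLBNE recall on the same snapshot, at the price of up to
twice as many predictions — precision can drop. This trade is the point of
the method: it targets regimes with many, possibly adjacent, sources.

## Evaluation

`precision_recall_f()` scores predictions with the $\beta = 1$ F-score.
`average_error_distance()` implements

$$\Delta = \frac{1}{|S^*|}\left(\sum_{i \in S^*}\min_{j\in\hat S} dis(i,j)
  + \rho\,\bigl||S^*|-|\hat S|\bigr|\right), \qquad \rho = 0.5,$$

with distances in the full network and unreachable pairs capped at $|V|$
so that $\Delta$ stays finite on disconnected graphs. The count-mismatch
penalty is added once, inside the $1/|S^*|$ factor — the reading under
which $\Delta$ is a single number and equals 0 exactly on a perfect
prediction. `count_accuracy()` reports how often $|\hat S| = |S^*|$.

`run_benchmark()` wires everything together: per replicate it draws the
network (ER or BA generators, or a fixed graph), assigns fresh
$U(0,1)$ edge probabilities, samples $m$ sources uniformly (adjacency
unconstrained), simulates to the stop fraction, runs each locator, and
scores it. All per-replicate seeds derive from one master seed, so results
are bit-reproducible. The bundled `"random"` baseline guesses uniformly
among infected nodes, size-matched to the first real locator in the run —
the fairest chance control for a method that chooses its own prediction
size.

## What the synthetic benchmark does and does not show

The default study conditions mirror a desk-scale sweep: ER networks with
$N \in \{500, 1000\}$ and mean degree 8–12 (BA as the scale-free
counterpart), $m = 5$ sources, $P_{uv}\sim U(0,1)$, stop at 30 %
infected, 50–100 replicates. At these settings the acceptance suite
verifies that SLBNE beats the size-matched random baseline by more than a
factor of 3 in mean F-score, that SLBIC's recall is never below SLBNE's,
and that earlier snapshots (10 % stop) localize at least as well as later
ones (20 %) — the early-detection trend one expects, since a fresher
infection boundary carries more signal.

Synthetic SI diffusion on ER/BA graphs emulates the *mechanism* the
locators assume: independent per-edge transmission on a known static
topology with a complete, noise-free snapshot. Real contact data violate
most of that — observation noise (unreported infections), temporal edges,
transmission heterogeneity correlated with degree, and community structure
far stronger than ER's. Passing these tests therefore shows the
implementation is faithful and the method behaves as designed under its
own assumptions; it does not certify field performance. The karate-club
fixture is included as the classic small real topology (its clustering
coefficient 0.571 and mean path length 2.41 are verified in the test
suite) rather than as evidence of real-world accuracy.

Problem sizes in the test suite (graphs of 10–50 nodes for the oracle
equivalence checks, 500 for benchmarks, $10^4$ Monte-Carlo replicates for
the hazard calibration) were chosen so every property is exercised at a
scale where an independent brute-force oracle is feasible.

## Worked example

```{r example, eval = FALSE}
library(silocate)

g <- assign_edge_probabilities(bundled_network("karate"), seed = 1)
truth <- sample_sources(g, 2, seed = 2)
tr <- simulate_si(g, truth, si_config(stop_fraction = 0.30, seed = 3))

res <- slbic(g, tr$final_snapshot)
res$predicted
precision_recall_f(res$predicted, truth)
average_error_distance(res$predicted, truth, g)
```

## Known limitations

* The locators assume a complete and correct snapshot; a single
  misreported node can create or destroy a local $NE$ maximum.
* The similarity of the cluster-division step degenerates to 0 on very
  sparse infection subgraphs; the proximity tie-break keeps the division
  sensible but the step carries little information there.
* Cohesion mixes a bounded distance term with unbounded $NE$; on clusters
  with strong $NE$ spread the distance term is effectively ignored. A
  min–max rescaling is a plausible variant but is deliberately not the
  default (see above).
* Everything is $O(|V_I|^2)$ or better per snapshot except the similarity
  matrix, which is dense in the infected subgraph; snapshots beyond a few
  thousand infected nodes will want a sparse implementation.
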