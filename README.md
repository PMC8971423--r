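# silocate

Multi-source epidemic/rumor source localization on contact networks.

Given an undirected contact network and a single snapshot of which nodes
are infected, `silocate` infers the set of nodes the spread started from —
without knowing the infection times, the transmission routes, or even how
many sources there were. It is aimed at researchers studying rumor
containment, outbreak tracing and diffusion inference who need a tested,
reproducible implementation of entropy-based multi-source localization
together with the simulation and evaluation machinery around it.

## The method

Diffusion is modelled as discrete-time susceptible–infected (SI) dynamics:
each edge $(u,v)$ carries a transmission probability $P_{uv}\in(0,1)$ and
a susceptible node $v$ turns at each step with hazard
$\lambda(v)=1-\prod_{u\in N(v)\cap V_I}(1-P_{uv})$; infected nodes never
recover.

Two locators are implemented:

* **SLBNE** (source localization by neighborhood entropy). Every infected
  node $i$ is scored by its *neighborhood entropy*
  $NE_i = AE_i - \alpha\,IE_i$, where the adjacency entropy
  $AE_i=-\sum_j \psi_i(j)\log_2\psi_i(j)$ aggregates $i$'s contribution
  $\psi_i(j)$ to each infected neighbour's infection degree, and the
  intensity entropy $IE_i=-\xi_i\log_2\xi_i$ penalizes nodes whose
  neighbourhood is still largely uninfected
  ($\xi_i$ is the damped infected-neighbour fraction; $\alpha=4$ by
  default). The predicted sources are the *core convex set* $C_s$: the
  infected nodes whose $NE$ strictly exceeds that of every infected
  neighbour.
* **SLBIC** (source localization based on infection clusters). Because two
  adjacent sources can never both be local $NE$ maxima, the infected set
  is divided into $|C_s|$ clusters around the cores (common-neighbour
  similarity for direct neighbours, then an edge-count breadth-first
  sweep with tie-overlap), each cluster's most *cohesive* member —
  maximizing a mix of a distance-decay histogram term and $NE$,
  $\delta_i=\sum_d \frac{M+1-d}{M+1}\frac{count_d}{APN}\cdot 0.5 +
  NE_i\cdot 0.5$ — is selected, and the prediction is the union
  $\hat S = C_s \cup C_{s1}$. Recall never falls below SLBNE's.

Evaluation uses the $\beta=1$ F-score, the average error distance
$\Delta=\frac{1}{|S^*|}\bigl(\sum_{i\in S^*}\min_{j\in\hat S}dis(i,j)
+\rho\,||S^*|-|\hat S||\bigr)$ with $\rho=0.5$, and source-count accuracy.
See the methods vignette (`vignettes/source-localization.Rmd`) for the
full model, conventions and limitations.

## Worked example

Simulate a two-source spread on Zachary's karate club and locate the
sources:

```r
library(silocate)

g <- assign_edge_probabilities(bundled_network("karate"), seed = 5)
truth <- sample_sources(g, 2, seed = 105)            # "24" "23"
tr <- simulate_si(g, truth, si_config(stop_fraction = 0.30, seed = 205))
tr
#> <si_trace> 2 source(s), 13/34 infected after 2 step(s)

res <- slbic(g, tr$final_snapshot)
res$predicted
#> [1] "10" "14" "20" "21" "23" "24" "29"

precision_recall_f(res$predicted, truth)
#> $precision 0.2857143   $recall 1   $f_score 0.4444444
average_error_distance(res$predicted, truth, g)
#> [1] 1.25

head(res$table[order(-res$table$ne), c("node", "ne")], 3)
#>    node      ne
#> 6    24 2.05276
#> 4    21 0.38818
#> 5    23 0.38818
```

Both true sources are recovered (recall 1); the highest-entropy node is
the true source `24`. Precision is diluted by the five extra local maxima
— typical behaviour when the snapshot has already overshot the 30 % stop
rule — which the error distance summarizes: predictions average 1.25 hops
from the nearest true source (here dominated by the 0.5-per-node
count-mismatch penalty and adjacent false positives).

Benchmarks over many replicates:

```r
cfg <- benchmark_config(list(model = "er", n = 500, mean_degree = 10),
                        m = 5, stop_fraction = 0.30, replicates = 50,
                        seed = 1)
run_benchmark(cfg, c("slbne", "slbic", "random"))$summary
```

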