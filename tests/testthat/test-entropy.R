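# The 3-path a-b-c with every node infected is the worked example used
# throughout: all five entropy quantities are small enough to evaluate by
# hand from the definitions.
#   xi_a = xi_c = 1/(1+e^-1), xi_b = 1/(1+e^-2)
#   eta_a = eta_c = xi_b / 2, eta_b = xi_a + xi_c
#   psi_a(b) = 1/eta_b,  psi_b(a) = (1/2)/eta_a

path3_snapshot <- function() {
  infection_snapshot(path3(), c("a", "b", "c"))
}

test_that("infection intensity follows the damped infected-fraction form", {
  g <- star_graph(4)
  # all neighbours uninfected -> 0
  snap <- infection_snapshot(g, "c")
  expect_equal(infection_intensity("c", snap), 0)

  # degree 1, its neighbour infected -> sigmoid(1)
  expect_equal(infection_intensity("l1", snap), 1 / (1 + exp(-1)))

  # degree 4 with 3 infected neighbours -> 0.75 * sigmoid(4)
  snap3 <- infection_snapshot(g, c("l1", "l2", "l3"))
  expect_equal(infection_intensity("c", snap3), 0.75 / (1 + exp(-4)))

  # isolated node: undefined, returns 0 with a warning
  g2 <- igraph::add_vertices(path3(), 1, name = "iso")
  expect_warning(xi <- infection_intensity("iso",
                                           infection_snapshot(g2, "a")),
                 "isolated")
  expect_equal(xi, 0)
})

test_that("intensity is non-decreasing in infected neighbours at fixed degree", {
  for (deg in 1:20) {
    g <- star_graph(deg)
    leaves <- paste0("l", seq_len(deg))
    xi <- vapply(0:deg, function(k) {
      infected <- if (k == 0) "c" else leaves[seq_len(k)]
      infection_intensity("c", infection_snapshot(g, infected))
    }, 0)
    expect_true(all(diff(xi) >= 0), info = paste("degree", deg))
  }
})

test_that("intensity entropy uses the 0 log 0 convention and is validated", {
  expect_equal(intensity_entropy(0), 0)
  expect_equal(intensity_entropy(0.5), 0.5)
  xi <- 1 / (1 + exp(-1))
  expect_equal(intensity_entropy(xi), -xi * log2(xi))
  expect_error(intensity_entropy(-0.1), "\\[0, 1\\]")
  expect_error(intensity_entropy(1.5), "\\[0, 1\\]")
})

test_that("infection degree is the degree-weighted intensity sum", {
  snap <- path3_snapshot()
  xi_b <- 1 / (1 + exp(-2))
  expect_equal(infection_degree("a", snap), xi_b / 2)

  # star centre with L infected degree-1 leaves, all xi = sigmoid(1)
  g <- star_graph(5)
  leaves <- paste0("l", 1:5)
  snapL <- infection_snapshot(g, c("c", leaves))
  expect_equal(infection_degree("c", snapL), 5 / (1 + exp(-1)))

  # no infected neighbours -> 0
  lone <- infection_snapshot(g, "c")
  expect_equal(infection_degree("c", lone), 0)
})

test_that("contribution cancels to 1/xi when i is j's only infected neighbour", {
  snap <- path3_snapshot()
  # b is a's only infected neighbour: psi_b(a) = (1/2)/((1/2) xi_b) = 1/xi_b
  xi_b <- 1 / (1 + exp(-2))
  expect_equal(contribution("b", "a", snap), 1 / xi_b)

  # contributions to j sum to (sum of 1/deg) / eta_j on random graphs
  for (s in 1:10) {
    g <- random_test_graph(20, 4, seed = s)
    snapr <- random_snapshot(g, 0.6, seed = s + 50)
    inf <- snapr$infected
    for (j in inf[1:min(3, length(inf))]) {
      nbs <- intersect(igraph::neighbors(g, j)$name, inf)
      if (length(nbs) == 0) next
      eta_j <- infection_degree(j, snapr)
      total <- sum(vapply(nbs, function(i) contribution(i, j, snapr), 0))
      expect_equal(total,
                   sum(1 / igraph::degree(g, nbs)) / eta_j,
                   tolerance = 1e-12)
    }
  }
})

test_that("adjacency and neighborhood entropy match the hand-worked 3-path", {
  snap <- path3_snapshot()
  xi_a <- 1 / (1 + exp(-1)); xi_b <- 1 / (1 + exp(-2))
  eta_a <- xi_b / 2; eta_b <- 2 * xi_a
  psi_ab <- 1 / eta_b          # leaf a contributing to centre b
  psi_ba <- 0.5 / eta_a        # centre b contributing to leaf a

  ae_a <- -psi_ab * log2(psi_ab)
  ae_b <- -2 * psi_ba * log2(psi_ba)  # two symmetric leaves; terms negative
  expect_equal(adjacency_entropy("a", snap), ae_a)
  expect_equal(adjacency_entropy("b", snap), ae_b)
  expect_lt(ae_b, 0)  # psi > 1 terms are kept, not clamped

  ie_a <- -xi_a * log2(xi_a); ie_b <- -xi_b * log2(xi_b)
  expect_equal(neighborhood_entropy("a", snap), ae_a - 4 * ie_a)
  expect_equal(neighborhood_entropy("b", snap), ae_b - 4 * ie_b)
  # alpha = 0 reduces NE to AE
  expect_equal(neighborhood_entropy("b", snap, alpha = 0), ae_b)

  # two infected ends of a single edge: eta_y = xi_x, so
  # psi_x(y) = 1/sigmoid(1) = 1 + e^-1 for both, symmetric
  edge <- igraph::graph_from_edgelist(rbind(c("x", "y")), directed = FALSE)
  snap_e <- infection_snapshot(edge, c("x", "y"))
  psi <- 1 + exp(-1)
  expect_equal(adjacency_entropy("x", snap_e), -psi * log2(psi))
  expect_equal(adjacency_entropy("y", snap_e),
               adjacency_entropy("x", snap_e))
})

test_that("the entropy table agrees with the per-node accessors", {
  for (s in c(2, 7)) {
    g <- random_test_graph(25, 4, seed = s)
    snap <- random_snapshot(g, 0.5, seed = s + 10)
    tab <- entropy_table(snap)
    expect_setequal(tab$node, snap$infected)
    expect_equal(tab$ne, tab$ae - 4 * tab$ie)
    for (v in tab$node[1:min(5, nrow(tab))]) {
      k <- match(v, tab$node)
      expect_equal(tab$xi[k], suppressWarnings(infection_intensity(v, snap)))
      expect_equal(tab$eta[k], infection_degree(v, snap))
      expect_equal(tab$ae[k], adjacency_entropy(v, snap))
    }
  }
})

test_that("entropy pipeline matches the naive oracle on random graphs", {
  for (s in 1:20) {
    g <- random_test_graph(10 + (s %% 5) * 10, 4, seed = s)
    snap <- random_snapshot(g, 0.5, seed = s + 30)
    tab <- entropy_table(snap)
    ne_oracle <- vapply(tab$node,
                        function(v) oracle_ne(g, v, snap$infected), 0)
    expect_equal(tab$ne, unname(ne_oracle), tolerance = 1e-9)
    expect_identical(as.character(core_convex_set(snap, tab)),
                     oracle_core_set(g, snap$infected))
  }
})

test_that("the core convex set picks strict local NE maxima with fallback", {
  snap <- path3_snapshot()
  core <- core_convex_set(snap)
  expect_setequal(as.character(core), c("a", "c"))
  expect_false(attr(core, "fallback"))

  # vertex-transitive cycle: all NE equal, strict rule empty -> fallback
  g <- cycle_graph(4)
  snap4 <- infection_snapshot(g, igraph::V(g)$name)
  core4 <- core_convex_set(snap4)
  expect_length(core4, 1)
  expect_true(attr(core4, "fallback"))

  # strict-rule members are never adjacent within the infected subgraph
  for (s in 1:15) {
    gr <- random_test_graph(30, 4, seed = s)
    snr <- random_snapshot(gr, 0.5, seed = s + 60)
    cr <- core_convex_set(snr)
    if (attr(cr, "fallback")) next
    H <- infected_subgraph(snr)
    if (length(cr) > 1) {
      sub <- igraph::induced_subgraph(H, as.character(cr))
      expect_equal(igraph::ecount(sub), 0)
    }
  }
})

test_that("slbne is deterministic and handles degenerate snapshots", {
  g <- random_test_graph(30, 4, seed = 8)
  snap <- infection_snapshot(g, igraph::V(g)$name[5])
  expect_equal(slbne(g, snap)$predicted, igraph::V(g)$name[5])

  snap2 <- random_snapshot(g, 0.4, seed = 9)
  r1 <- slbne(g, snap2); r2 <- slbne(g, snap2)
  expect_identical(r1$predicted, r2$predicted)
  expect_identical(r1$table, r2$table)
})

test_that("slbne is invariant under node relabeling", {
  for (s in 1:10) {
    g <- random_test_graph(20, 4, seed = s)
    snap <- random_snapshot(g, 0.5, seed = s + 40)
    core <- core_convex_set(snap)
    if (attr(core, "fallback")) next  # fallback tie-break is id-dependent
    ids <- igraph::V(g)$name
    set.seed(s)
    relabel <- stats::setNames(sample(sprintf("n%03d", seq_along(ids))), ids)
    g2 <- g
    igraph::V(g2)$name <- unname(relabel[ids])
    snap2 <- infection_snapshot(g2, unname(relabel[snap$infected]))
    pred2 <- slbne(g2, snap2)$predicted
    expect_setequal(pred2, unname(relabel[slbne(g, snap)$predicted]))
  }
})
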