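# Small graph builders used across the suite. All graphs are contact
# networks: undirected igraphs with character vertex names.

graph_from_edges <- function(...) {
  el <- matrix(as.character(unlist(list(...))), ncol = 2, byrow = TRUE)
  igraph::graph_from_edgelist(el, directed = FALSE)
}

path3 <- function() graph_from_edges("a", "b", "b", "c")

star_graph <- function(n_leaves, center = "c") {
  leaves <- paste0("l", seq_len(n_leaves))
  igraph::graph_from_edgelist(cbind(center, leaves), directed = FALSE)
}

cycle_graph <- function(n) {
  ids <- paste0("v", seq_len(n))
  igraph::graph_from_edgelist(cbind(ids, ids[c(2:n, 1)]), directed = FALSE)
}

# two complete K4 blocks joined by a single bridge edge a4--b1
barbell_graph <- function() {
  a <- paste0("a", 1:4)
  b <- paste0("b", 1:4)
  block <- function(v) t(utils::combn(v, 2))
  el <- rbind(block(a), block(b), c("a4", "b1"))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# ER graph guaranteed to have at least one edge, for property tests
random_test_graph <- function(n, mean_degree = 4, seed = 1) {
  g <- generate_er(n, mean_degree, seed = seed)
  while (igraph::ecount(g) == 0) {
    seed <- seed + 1000
    g <- generate_er(n, mean_degree, seed = seed)
  }
  g
}

random_snapshot <- function(g, frac = 0.5, seed = 1) {
  set.seed(seed)
  ids <- igraph::V(g)$name
  k <- max(1, round(frac * length(ids)))
  infection_snapshot(g, sample(ids, k))
}

write_lines_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
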