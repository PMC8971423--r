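#' Infection cluster division
#'
#' After SLBNE has produced the core convex set `C_s` with `r` members,
#' the infected node set is divided into `r` infection clusters, one per
#' core, in two steps:
#'
#' 1. every infected node directly adjacent to at least one core joins the
#'    cluster of the core with maximal structural similarity. Similarity
#'    ties are broken by proximity -- the nearest core by shortest path in
#'    the infected subgraph -- then by larger NE, then by smaller id.
#'    (Proximity must come first: on sparse or disconnected infection
#'    networks the similarity can be 0 to *every* core, including an
#'    adjacent one, and an entropy tie-break alone could then send a node
#'    to a core in a different component.);
#' 2. the remaining infected nodes are swept in breadth-first order from
#'    the already-assigned frontier; each joins the cluster(s) it has most
#'    edges to among its already-assigned neighbours, joining *all* tied
#'    clusters on an exact tie (this is how cluster overlap arises).
#'    Infected nodes disconnected from every cluster join the cluster
#'    whose core is nearest by shortest path in the infected subgraph.
#'
#' All neighbourhoods, similarities and distances here live in the
#' *infected subgraph*: the division operates on the infection network.
#'
#' The similarity between nodes `n1`, `n2` is
#' \deqn{Sim(n_1,n_2) = \frac{Com(n_1,n_2)}{|N(n_1)\cup N(n_2)|}
#'   + \sum_{i\in N(n_1)}\sum_{j\in N(n_2)}\frac{Com(i,j)}{|N(i)\cup N(j)|},}
#' where `Com(x, y)` is the number of common neighbours, with the
#' convention `Com(x, x) = |N(x)|` so the literal double sum (which can hit
#' `i = j`) is well defined.
#'
#' @name infection-clusters
NULL

#' Number of common neighbours
#'
#' `|N(x) - N(y)|` intersection count, with the diagonal convention
#' `Com(x, x) = |N(x)|`.
#'
#' @param x,y node ids.
#' @param network the graph whose neighbourhoods are used (for cluster
#'   division this is the infected subgraph).
#' @return a nonnegative integer count.
#' @export
common_neighbors <- function(x, y, network) {
  if (x == y) return(unname(igraph::degree(network, x)))
  nx <- igraph::neighbors(network, x)$name
  ny <- igraph::neighbors(network, y)$name
  length(intersect(nx, ny))
}

#' Structural similarity between two nodes
#'
#' The Jaccard-style common-neighbour ratio of the pair plus the same
#' ratio summed over all pairs of their neighbours (second-order term).
#' Symmetric; 0 when neither level shares any neighbour.
#'
#' @param n1,n2 distinct node ids.
#' @param network the graph whose neighbourhoods are used.
#' @return a nonnegative similarity score.
#' @export
node_similarity <- function(n1, n2, network) {
  stopifnot(n1 != n2)
  adj <- adjacency_sets(network)
  similarity_from_sets(n1, n2, adj)
}

# neighbourhood sets keyed by node id, computed once per graph
adjacency_sets <- function(network) {
  ids <- node_ids(network)
  adj <- igraph::as_adj_list(network, mode = "all")
  stats::setNames(lapply(adj, function(a) ids[as.integer(a)]), ids)
}

com_sets <- function(x, y, adj) {
  if (x == y) return(length(adj[[x]]))
  length(intersect(adj[[x]], adj[[y]]))
}

jacc_term <- function(x, y, adj) {
  u <- length(union(adj[[x]], adj[[y]]))
  if (u == 0) return(0)
  com_sets(x, y, adj) / u
}

similarity_from_sets <- function(n1, n2, adj) {
  first <- jacc_term(n1, n2, adj)
  second <- 0
  for (i in adj[[n1]]) {
    for (j in adj[[n2]]) {
      second <- second + jacc_term(i, j, adj)
    }
  }
  first + second
}

# All similarities to the cores at once. With A the 0/1 adjacency matrix,
# Com = A^2 (diagonal overwritten with the degree convention),
# |N(x) u N(y)| = deg_x + deg_y - Com, J = Com / union elementwise, and
# the neighbour-pair double sum is (A J A); so Sim = J + A J A, of which
# only the core columns are needed.
similarity_to_cores <- function(H, core) {
  ids <- node_ids(H)
  A <- igraph::as_adjacency_matrix(H, sparse = FALSE)
  deg <- rowSums(A)
  com <- A %*% A
  diag(com) <- deg
  un <- outer(deg, deg, "+") - com
  J <- matrix(0, nrow(A), ncol(A))
  pos <- un > 0
  J[pos] <- com[pos] / un[pos]
  ci <- match(core, ids)
  simmat <- J[, ci, drop = FALSE] +
    A %*% (J %*% A[, ci, drop = FALSE])
  dimnames(simmat) <- list(ids, core)
  simmat
}

#' Divide the infected nodes into infection clusters
#'
#' Two-step division of the infected node set around the core convex
#' nodes; see [infection-clusters] for the procedure. Deterministic for a
#' fixed snapshot and core set: the breadth-first sweep processes nodes in
#' increasing distance from the assigned frontier, ascending id within a
#' distance level.
#'
#' @param snapshot an infection snapshot.
#' @param core the core convex set (character vector of infected node
#'   ids), e.g. from [core_convex_set()].
#' @param table an [entropy_table()] supplying NE values for similarity
#'   tie-breaks; computed with defaults when omitted.
#' @return an object of class `cluster_assignment`: list with `clusters`
#'   (list of `list(core, members)`, cores sorted by id; each core belongs
#'   to its own cluster only) and `membership` (named list mapping each
#'   infected node to the integer indices of its clusters; overlap means
#'   more than one index).
#' @export
divide_clusters <- function(snapshot, core, table = NULL) {
  stopifnot(inherits(snapshot, "infection_snapshot"))
  core <- unique(as.character(core))
  if (length(core) == 0) stop("`core` must be non-empty", call. = FALSE)
  if (!all(core %in% snapshot$infected)) {
    stop("every core node must be infected", call. = FALSE)
  }
  if (is.null(table)) table <- entropy_table(snapshot)
  ne <- stats::setNames(table$ne, table$node)

  core <- order_ids(core)
  r <- length(core)
  H <- infected_subgraph(snapshot)
  adj <- adjacency_sets(H)
  ids <- node_ids(H)

  # cluster index per node; a list since overlap is allowed
  membership <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_len(r)) membership[[core[k]]] <- k

  # --- step 1: direct neighbours of any core ------------------------------
  direct <- setdiff(unique(unlist(adj[core], use.names = FALSE)), core)
  direct <- order_ids(direct)
  if (length(direct) > 0) {
    simmat <- similarity_to_cores(H, core)
    ddist <- igraph::distances(H, v = direct, to = core)
    for (v in direct) {
      sims <- simmat[v, ]
      top <- max(sims)
      cand <- which(sims >= top - 1e-9 * max(1, abs(top)))
      if (length(cand) > 1) {
        # nearest core first, then larger NE, then smaller id
        cand <- cand[order(ddist[v, cand], -ne[core[cand]], core[cand],
                           method = "radix")]
      }
      membership[[v]] <- cand[1]
    }
  }

  # --- step 2: BFS sweep from the assigned frontier -----------------------
  assigned <- c(core, direct)
  remaining <- setdiff(ids, assigned)
  if (length(remaining) > 0 && length(assigned) > 0) {
    d <- igraph::distances(H, v = remaining, to = assigned)
    depth <- apply(d, 1, min)
    finite <- remaining[is.finite(depth)]
    finite <- finite[order(depth[is.finite(depth)], finite, method = "radix")]
    for (v in finite) {
      nb <- adj[[v]]
      counts <- integer(r)
      for (u in nb) {
        ku <- membership[[u]]
        if (!is.null(ku)) counts[ku] <- counts[ku] + 1L
      }
      top <- max(counts)
      membership[[v]] <- which(counts == top)  # exact tie -> all tied
    }
    # disconnected from every cluster: nearest core wins, ties by index
    orphan <- remaining[!is.finite(depth)]
    if (length(orphan) > 0) {
      dc <- igraph::distances(H, v = orphan, to = core)
      for (k in seq_along(orphan)) {
        dd <- dc[k, ]
        dd[!is.finite(dd)] <- igraph::vcount(H) + 1
        membership[[orphan[k]]] <- which.min(dd)
      }
    }
  }

  clusters <- lapply(seq_len(r), function(k) {
    mem <- ids[vapply(membership, function(m) k %in% m, logical(1))]
    list(core = core[k], members = order_ids(mem))
  })
  structure(list(clusters = clusters, membership = membership),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), 0L)
  cat("<cluster_assignment> ", length(x$clusters), " cluster(s), sizes: ",
      paste(sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}
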