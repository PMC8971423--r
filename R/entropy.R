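#' Neighborhood-entropy source scoring
#'
#' The entropy locator ranks each infected node by how much infection
#' information its neighbourhood carries. Five per-node quantities are
#' stacked:
#'
#' * infection intensity `xi_i = ((|N(i)| - |U_i|) / |N(i)|) *
#'   1 / (1 + exp(-|N(i)|))` -- the infected fraction of i's full-graph
#'   neighbourhood, damped by a sigmoid in the degree. `U_i` is the set of
#'   uninfected neighbours; `xi` is the one quantity computed on the full
#'   network, because it explicitly measures the weakening effect of
#'   uninfected neighbours.
#' * intensity entropy `IE_i = -xi_i * log2(xi_i)` (with `0 log 0 := 0`).
#' * infection degree `eta_j = sum_t xi_t / |N(t)|` over j's infected
#'   neighbours `t` -- how plausibly j is the parent of its neighbourhood.
#' * contribution `psi_i(j) = (1 / |N(i)|) / eta_j`, node i's share of
#'   neighbour j's infection degree. `psi` can exceed 1; it is not clamped.
#' * adjacency entropy `AE_i = -sum_j psi_i(j) log2 psi_i(j)` over i's
#'   infected neighbours (terms with `psi > 1` contribute negatively).
#'
#' The node score is the neighborhood entropy `NE_i = AE_i - alpha * IE_i`;
#' `alpha` (default 4) weights the uninfected-neighbour penalty. Infected
#' nodes whose NE strictly exceeds that of every infected neighbour form
#' the core convex set -- the SLBNE source predictions.
#'
#' All degrees `|N(.)|` are full-network degrees; all sums over neighbours
#' (`eta`, `psi`, `AE`, and the core-set maximum) run over *infected*
#' neighbours only. This restriction guarantees `eta_j > 0` for every
#' infected node with an infected neighbour, so `psi` is always defined.
#'
#' @name neighborhood-entropy
NULL

default_alpha <- 4

sigmoid <- function(x) 1 / (1 + exp(-x))

xlog2x <- function(x) ifelse(x > 0, x * log2(x), 0)

#' Infection intensity of a node
#'
#' @param i a node id with degree >= 1 in the full network (an isolated
#'   node has no neighbourhood to measure; 0 is returned with a warning).
#' @param snapshot an infection snapshot.
#' @return the intensity `xi_i` in \[0, 1).
#' @export
infection_intensity <- function(i, snapshot) {
  stopifnot(inherits(snapshot, "infection_snapshot"))
  g <- snapshot$network
  deg <- igraph::degree(g, i)
  if (deg == 0) {
    warning("infection intensity of isolated node '", i,
            "' is undefined; returning 0")
    return(0)
  }
  nb <- igraph::neighbors(g, i)$name
  n_inf <- sum(nb %in% snapshot$infected)
  unname((n_inf / deg) * sigmoid(deg))
}

#' Intensity entropy
#'
#' `-xi * log2(xi)`, with the standard `0 log 0 := 0` convention.
#'
#' @param xi an infection intensity in \[0, 1\].
#' @return entropy in bits, >= 0 on \[0, 1\].
#' @export
intensity_entropy <- function(xi) {
  if (any(!is.finite(xi)) || any(xi < 0) || any(xi > 1)) {
    stop("`xi` must lie in [0, 1]", call. = FALSE)
  }
  -xlog2x(xi)
}

#' Infection degree of a node
#'
#' `eta_j = sum over infected neighbours t of xi_t / |N(t)|`, degrees taken
#' in the full network. By default the sum runs over infected neighbours
#' only (uninfected neighbours have `xi` conceptually irrelevant to
#' parenthood); `neighbors = "all"` includes every neighbour.
#'
#' @param j an infected node id.
#' @param snapshot an infection snapshot.
#' @param neighbors `"infected"` (default) or `"all"`.
#' @return the infection degree, >= 0.
#' @export
infection_degree <- function(j, snapshot, neighbors = c("infected", "all")) {
  stopifnot(inherits(snapshot, "infection_snapshot"))
  neighbors <- match.arg(neighbors)
  g <- snapshot$network
  nb <- igraph::neighbors(g, j)$name
  if (neighbors == "infected") nb <- nb[nb %in% snapshot$infected]
  if (length(nb) == 0) return(0)
  xi <- vapply(nb, infection_intensity, 0, snapshot = snapshot)
  sum(xi / igraph::degree(g, nb))
}

#' Contribution of a node to a neighbour's infection degree
#'
#' `psi_i(j) = (1 / |N(i)|) / eta_j`. May exceed 1.
#'
#' @param i,j adjacent infected node ids.
#' @param snapshot an infection snapshot.
#' @param neighbors neighbour convention passed to [infection_degree()].
#' @return the contribution ratio, > 0.
#' @export
contribution <- function(i, j, snapshot, neighbors = c("infected", "all")) {
  stopifnot(inherits(snapshot, "infection_snapshot"))
  neighbors <- match.arg(neighbors)
  eta_j <- infection_degree(j, snapshot, neighbors)
  if (eta_j <= 0) {
    stop("infection degree of node '", j, "' is zero; the contribution ",
         "ratio is undefined", call. = FALSE)
  }
  unname((1 / igraph::degree(snapshot$network, i)) / eta_j)
}

#' Adjacency entropy of an infected node
#'
#' `AE_i = -sum over infected neighbours j of psi_i(j) log2 psi_i(j)`.
#' Terms with `psi > 1` are negative and kept; an infected node with no
#' infected neighbour gets `AE = 0`.
#'
#' @inheritParams contribution
#' @return entropy in bits; may be negative.
#' @export
adjacency_entropy <- function(i, snapshot, neighbors = c("infected", "all")) {
  stopifnot(inherits(snapshot, "infection_snapshot"))
  neighbors <- match.arg(neighbors)
  nb <- igraph::neighbors(snapshot$network, i)$name
  nb <- nb[nb %in% snapshot$infected]
  if (length(nb) == 0) return(0)
  psi <- vapply(nb, function(j) contribution(i, j, snapshot, neighbors), 0)
  -sum(xlog2x(psi))
}

#' Neighborhood entropy of an infected node
#'
#' `NE_i = AE_i - alpha * IE_i`.
#'
#' @inheritParams contribution
#' @param alpha weight of the intensity-entropy penalty; default 4.
#' @return the node score; any real.
#' @export
neighborhood_entropy <- function(i, snapshot, alpha = default_alpha,
                                 neighbors = c("infected", "all")) {
  neighbors <- match.arg(neighbors)
  adjacency_entropy(i, snapshot, neighbors) -
    alpha * intensity_entropy(infection_intensity(i, snapshot))
}

#' Entropy table for all infected nodes
#'
#' Computes `xi`, `IE`, `eta`, `AE` and `NE` for every infected node in one
#' vectorized pass. This is the workhorse behind [slbne()] and [slbic()];
#' the per-node accessors above exist for inspection and testing and agree
#' with the table exactly.
#'
#' @param snapshot an infection snapshot.
#' @param alpha weight of the intensity-entropy penalty; default 4.
#' @param eta_neighbors neighbour convention for the `eta` sum:
#'   `"infected"` (default) or `"all"`.
#' @return a `data.frame` of class `entropy_table` with columns `node`,
#'   `xi`, `ie`, `eta`, `ae`, `ne`, one row per infected node, and
#'   attribute `alpha`.
#' @examples
#' g <- bundled_network("karate")
#' snap <- infection_snapshot(g, as.character(1:10))
#' head(entropy_table(snap))
#' @export
entropy_table <- function(snapshot, alpha = default_alpha,
                          eta_neighbors = c("infected", "all")) {
  stopifnot(inherits(snapshot, "infection_snapshot"))
  eta_neighbors <- match.arg(eta_neighbors)
  g <- snapshot$network
  ids <- node_ids(g)
  inf <- ids %in% snapshot$infected
  deg <- igraph::degree(g)

  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  n_inf_nb <- vapply(adj, function(a) sum(inf[a]), 0L)

  # xi on the full neighbourhood; isolated nodes get xi = 0
  xi <- ifelse(deg > 0, (n_inf_nb / pmax(deg, 1)) * sigmoid(deg), 0)
  w <- ifelse(deg > 0, xi / pmax(deg, 1), 0)  # xi_t / |N(t)| per node t

  which_inf <- which(inf)
  eta <- numeric(length(ids))
  ae <- numeric(length(ids))
  for (v in which_inf) {
    nb <- adj[[v]]
    nb_use <- if (eta_neighbors == "infected") nb[inf[nb]] else nb
    eta[v] <- sum(w[nb_use])
  }
  inv_deg <- 1 / pmax(deg, 1)
  for (v in which_inf) {
    nb <- adj[[v]]
    nb_i <- nb[inf[nb]]
    if (length(nb_i) == 0) next
    psi <- inv_deg[v] / eta[nb_i]
    ae[v] <- -sum(xlog2x(psi))
  }
  ie <- -xlog2x(xi)
  ne <- ae - alpha * ie

  out <- data.frame(node = ids[which_inf],
                    xi = xi[which_inf], ie = ie[which_inf],
                    eta = eta[which_inf], ae = ae[which_inf],
                    ne = ne[which_inf], stringsAsFactors = FALSE)
  out <- out[order(out$node, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("entropy_table", "data.frame")
  out
}

#' Core convex set
#'
#' The infected nodes whose neighborhood entropy strictly exceeds that of
#' every infected neighbour. An infected node with no infected neighbour
#' qualifies vacuously (a plausibly un-spread source). On entropy-symmetric
#' snapshots the strict rule can select nothing; the locator then falls
#' back to the single infected node of globally maximal NE (ties broken by
#' smallest node id).
#'
#' @param snapshot an infection snapshot.
#' @param table an [entropy_table()] for the snapshot (computed with
#'   default settings when omitted).
#' @return a character vector of node ids (the set `C_s`), sorted; the
#'   attribute `fallback` is `TRUE` when the strict rule selected nothing.
#' @export
core_convex_set <- function(snapshot, table = NULL) {
  stopifnot(inherits(snapshot, "infection_snapshot"))
  if (is.null(table)) table <- entropy_table(snapshot)
  ne <- stats::setNames(table$ne, table$node)
  g <- snapshot$network
  inf_set <- snapshot$infected
  adj <- igraph::as_adj_list(g, mode = "all")
  ids <- node_ids(g)
  is_core <- vapply(inf_set, function(v) {
    nb <- ids[as.integer(adj[[match(v, ids)]])]
    nb <- nb[nb %in% inf_set]
    length(nb) == 0 || ne[[v]] > max(ne[nb])
  }, logical(1))
  core <- inf_set[is_core]
  fallback <- FALSE
  if (length(core) == 0) {
    fallback <- TRUE
    top <- max(ne)
    core <- order_ids(names(ne)[ne == top])[1]
  }
  structure(order_ids(core), fallback = fallback)
}

#' SLBNE: source localization by neighborhood entropy
#'
#' Scores every infected node with [entropy_table()] and predicts the core
#' convex set as the sources. Deterministic for a fixed snapshot.
#'
#' @param network a contact network (accepted for interface symmetry with
#'   [slbic()]; the snapshot's own network is used).
#' @param snapshot an infection snapshot.
#' @param alpha entropy weight factor; default 4.
#' @param eta_neighbors neighbour convention for the `eta` sum.
#' @return an object of class `localization_result`: list with `method`,
#'   `predicted` (character vector), `core_set`, `table`.
#' @examples
#' g <- assign_edge_probabilities(bundled_network("karate"), seed = 1)
#' tr <- simulate_si(g, sample_sources(g, 2, seed = 2), si_config(seed = 3))
#' slbne(g, tr$final_snapshot)
#' @export
slbne <- function(network = NULL, snapshot, alpha = default_alpha,
                  eta_neighbors = c("infected", "all")) {
  stopifnot(inherits(snapshot, "infection_snapshot"))
  eta_neighbors <- match.arg(eta_neighbors)
  tab <- entropy_table(snapshot, alpha = alpha, eta_neighbors = eta_neighbors)
  core <- core_convex_set(snapshot, tab)
  structure(list(method = "SLBNE",
                 predicted = as.character(core),
                 core_set = as.character(core),
                 condensed_set = character(0),
                 table = tab),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat("<localization_result> ", x$method, ": ",
      length(x$predicted), " predicted source(s): ",
      paste(utils::head(x$predicted, 10), collapse = ", "),
      if (length(x$predicted) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}
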