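#' Cohesion scoring and the SLBIC locator
#'
#' A single infection cluster can hide more than one source: two sources
#' that are neighbours can never both be local NE maxima, so SLBNE reports
#' at most one of them. SLBIC therefore re-examines each infection cluster
#' and adds its most *cohesive* member, i.e. the member most central to the
#' cluster, as a condensed node.
#'
#' For a cluster member `i`, shortest-path distances to the other cluster
#' members are binned into a histogram `path_dic = {dis : count}`;
#' distances are measured in the infected subgraph (paths may route
#' through any infected node; endpoints are cluster members), unreachable
#' members are omitted. With `M_dis` the largest observed distance the
#' cohesion is
#' \deqn{\delta_i = \sum_{d \in path\_dic} \frac{M_{dis}+1-d}{M_{dis}+1}
#'   \cdot \frac{count_d}{APN} \cdot 0.5 + NE_i \cdot 0.5,}
#' a half-weighted mix of a distance-decay mass term and the node's
#' neighborhood entropy (entered raw, exactly as defined). `APN` -- the
#' number of all possible path lengths -- defaults to the number of
#' distinct observed distances; `apn = "reachable"` instead uses the
#' number of reachable members, turning `count_d / APN` into a proper
#' distribution.
#'
#' The per-cluster cohesion maximizer is the condensed node; the SLBIC
#' prediction is the union of the core convex set and the condensed nodes.
#'
#' @name cohesion
NULL

#' Path-length histogram of a node within its cluster
#'
#' @param i a node id, member of the cluster.
#' @param cluster_members character vector of the cluster's members
#'   (including `i`).
#' @param snapshot an infection snapshot.
#' @return a named integer vector mapping distance (as names, increasing)
#'   to the count of members at that distance; empty for a singleton
#'   cluster or a fully unreachable one.
#' @export
path_length_histogram <- function(i, cluster_members, snapshot) {
  stopifnot(inherits(snapshot, "infection_snapshot"))
  cluster_members <- unique(as.character(cluster_members))
  stopifnot(i %in% cluster_members)
  others <- setdiff(cluster_members, i)
  if (length(others) == 0) return(stats::setNames(integer(0), character(0)))
  H <- infected_subgraph(snapshot)
  d <- igraph::distances(H, v = i, to = others)[1, ]
  d <- d[is.finite(d)]
  if (length(d) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(d)
  stats::setNames(as.integer(tab), names(tab))
}

#' Cohesion of a node within an infection cluster
#'
#' See [cohesion] for the score. An empty histogram (singleton cluster)
#' contributes 0 to the distance term, leaving `0.5 * NE_i`.
#'
#' @inheritParams path_length_histogram
#' @param table an [entropy_table()] carrying `NE_i`.
#' @param apn normalizer convention: `"distinct"` (default; number of
#'   distinct observed distances) or `"reachable"` (number of reachable
#'   cluster members).
#' @return the cohesion score `delta_i`.
#' @export
cohesion <- function(i, cluster_members, snapshot, table,
                     apn = c("distinct", "reachable")) {
  apn <- match.arg(apn)
  stopifnot(inherits(table, "entropy_table"))
  ne_i <- table$ne[match(i, table$node)]
  if (is.na(ne_i)) stop("node '", i, "' missing from the entropy table",
                        call. = FALSE)
  hist <- path_length_histogram(i, cluster_members, snapshot)
  delta_from_histogram(hist, ne_i, apn)
}

delta_from_histogram <- function(hist, ne_i, apn) {
  dist_term <- 0
  if (length(hist) > 0) {
    d <- as.numeric(names(hist))
    counts <- as.numeric(hist)
    m_dis <- max(d)
    norm <- if (apn == "distinct") length(hist) else sum(counts)
    dist_term <- sum((m_dis + 1 - d) / (m_dis + 1) * counts / norm) * 0.5
  }
  dist_term + ne_i * 0.5
}

#' Condensed nodes of a cluster assignment
#'
#' For each infection cluster, the member of maximal cohesion (ties:
#' larger NE, then smaller id). The returned set `C_s1` has one node per
#' cluster; it may intersect the core set.
#'
#' @param assignment a [divide_clusters()] result.
#' @param snapshot an infection snapshot.
#' @param table an [entropy_table()].
#' @param apn normalizer convention, as in [cohesion()].
#' @return a character vector of node ids, sorted; attribute `delta` holds
#'   the per-node cohesion scores of all cluster members (a `data.frame`
#'   with columns `cluster`, `node`, `delta`).
#' @export
condensed_nodes <- function(assignment, snapshot, table,
                            apn = c("distinct", "reachable")) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  apn <- match.arg(apn)
  ne <- stats::setNames(table$ne, table$node)
  H <- infected_subgraph(snapshot)
  dall <- igraph::distances(H)  # one all-pairs pass, reused per cluster
  ids <- rownames(dall)

  score_rows <- list()
  picks <- character(0)
  for (k in seq_along(assignment$clusters)) {
    mem <- assignment$clusters[[k]]$members
    deltas <- vapply(mem, function(i) {
      d <- dall[match(i, ids), match(setdiff(mem, i), ids)]
      d <- d[is.finite(d)]
      hist <- if (length(d) == 0) stats::setNames(integer(0), character(0))
              else {
                tab <- table(d)
                stats::setNames(as.integer(tab), names(tab))
              }
      delta_from_histogram(hist, ne[[i]], apn)
    }, 0)
    ord <- order(-deltas, -ne[mem], mem, method = "radix")
    picks <- c(picks, mem[ord[1]])
    score_rows[[k]] <- data.frame(cluster = k, node = mem, delta = deltas,
                                  stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(order_ids(unique(picks)),
            delta = do.call(rbind, score_rows))
}

#' SLBIC: source localization based on infection clusters
#'
#' The full pipeline: SLBNE for the core convex set, infection-cluster
#' division around the cores, condensed-node selection by cohesion, and
#' the union prediction `S-hat = C_s + C_s1`. Since the union can only
#' add nodes, SLBIC's prediction always contains SLBNE's and
#' `|C_s| <= |S-hat| <= 2 |C_s|`.
#'
#' @inheritParams slbne
#' @param apn cohesion normalizer convention, as in [cohesion()].
#' @return a `localization_result` with `method = "SLBIC"`, `predicted`,
#'   `core_set`, `condensed_set`, `clusters` (the assignment), `table`,
#'   and `delta` (per-member cohesion scores).
#' @examples
#' g <- assign_edge_probabilities(bundled_network("karate"), seed = 1)
#' tr <- simulate_si(g, sample_sources(g, 2, seed = 2), si_config(seed = 3))
#' slbic(g, tr$final_snapshot)
#' @export
slbic <- function(network = NULL, snapshot, alpha = default_alpha,
                  eta_neighbors = c("infected", "all"),
                  apn = c("distinct", "reachable")) {
  stopifnot(inherits(snapshot, "infection_snapshot"))
  eta_neighbors <- match.arg(eta_neighbors)
  apn <- match.arg(apn)
  tab <- entropy_table(snapshot, alpha = alpha, eta_neighbors = eta_neighbors)
  core <- core_convex_set(snapshot, tab)
  assignment <- divide_clusters(snapshot, core, tab)
  cond <- condensed_nodes(assignment, snapshot, tab, apn)
  predicted <- order_ids(union(as.character(core), as.character(cond)))
  structure(list(method = "SLBIC",
                 predicted = predicted,
                 core_set = as.character(core),
                 condensed_set = as.character(cond),
                 clusters = assignment,
                 table = tab,
                 delta = attr(cond, "delta")),
            class = "localization_result")
}
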