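#' Contact networks and infection snapshots
#'
#' A contact network is an undirected [igraph::igraph] graph whose vertices
#' carry character names (node ids are opaque strings; numeric-looking ids
#' are never coerced) and whose edges may carry a transmission probability
#' in the edge attribute `p`, strictly inside (0, 1) and symmetric by
#' construction (the graph is undirected, so one value serves both
#' directions).
#'
#' An infection snapshot pairs a contact network with the observed set of
#' infected nodes: the data actually available to a source locator.
#'
#' @name contact-network
NULL

#' Validate a contact network
#'
#' Checks the structural contract every function in the package relies on:
#' an undirected simple graph (no self-loops, no multi-edges), named
#' vertices, and -- when the edge attribute `p` is present -- a probability
#' strictly in (0, 1) on every edge.
#'
#' @param network an igraph object.
#' @return the network, invisibly, after validation.
#' @export
validate_contact_network <- function(network) {
  if (!igraph::is_igraph(network)) {
    stop("`network` must be an igraph object", call. = FALSE)
  }
  if (igraph::is_directed(network)) {
    stop("contact networks are undirected", call. = FALSE)
  }
  if (igraph::any_loop(network)) {
    stop("contact networks must not contain self-loops", call. = FALSE)
  }
  if (igraph::any_multiple(network)) {
    stop("duplicate edges are not allowed; collapse them first", call. = FALSE)
  }
  if (igraph::vcount(network) > 0 &&
      is.null(igraph::vertex_attr(network, "name"))) {
    stop("contact network vertices must be named", call. = FALSE)
  }
  p <- igraph::edge_attr(network, "p")
  if (!is.null(p)) {
    if (anyNA(p) || length(p) != igraph::ecount(network)) {
      stop("edge probability `p`, when present, must cover every edge",
           call. = FALSE)
    }
    if (any(p <= 0 | p >= 1)) {
      stop("edge probabilities must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  invisible(network)
}

has_edge_probabilities <- function(network) {
  !is.null(igraph::edge_attr(network, "p"))
}

node_ids <- function(network) {
  if (igraph::vcount(network) == 0) return(character(0))
  as.character(igraph::V(network)$name)
}

# Stable, locale-independent id ordering used by every deterministic
# tie-break in the package.
order_ids <- function(ids) ids[order(ids, method = "radix")]

#' Read a contact network from an edge list
#'
#' Reads a plain-text edge list with two node-id columns and an optional
#' third column giving the per-edge transmission probability. Columns are
#' separated by whitespace or commas; lines starting with `#` and blank
#' lines are ignored. Duplicate edges -- including reversed duplicates --
#' collapse to a single undirected edge.
#'
#' @param path path to the edge-list file.
#' @return a contact network (undirected igraph with named vertices and,
#'   when the third column is present, edge attribute `p`).
#' @seealso [write_edge_list()], [read_graphml()]
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy", "a b 0.4", "b c 0.6"), f)
#' g <- read_edge_list(f)
#' igraph::ecount(g)
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(validate_contact_network(
      igraph::make_empty_graph(0, directed = FALSE)))
  }
  tokens <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  nf <- lengths(tokens)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad) > 0) {
    stop("malformed edge-list line ", idx[bad[1]], ": '",
         lines[idx[bad[1]]], "'", call. = FALSE)
  }
  from <- vapply(tokens, `[`, "", 1)
  to <- vapply(tokens, `[`, "", 2)
  if (any(from == to)) {
    stop("self-loop on edge-list line ", idx[which(from == to)[1]],
         call. = FALSE)
  }
  probs <- rep(NA_real_, length(tokens))
  with_p <- nf == 3
  if (any(with_p)) {
    if (!all(with_p)) {
      stop("edge-list mixes 2- and 3-column lines (first offender: line ",
           idx[which(with_p != with_p[1])[1]], ")", call. = FALSE)
    }
    probs <- suppressWarnings(
      as.numeric(vapply(tokens, `[`, "", 3)))
    if (anyNA(probs)) {
      stop("non-numeric probability on edge-list line ",
           idx[which(is.na(probs))[1]], call. = FALSE)
    }
    if (any(probs <= 0 | probs >= 1)) {
      stop("edge probability outside (0, 1) on edge-list line ",
           idx[which(probs <= 0 | probs >= 1)[1]], call. = FALSE)
    }
  }
  # collapse duplicates, treating (u, v) and (v, u) as the same edge
  key_a <- pmin(from, to)
  key_b <- pmax(from, to)
  first <- !duplicated(paste0(key_a, "\r", key_b))
  dup_key <- paste0(key_a, "\r", key_b)
  if (any(with_p)) {
    # duplicate rows must agree on the probability
    agg <- tapply(probs, dup_key, function(x) diff(range(x)))
    if (any(agg > 1e-12)) {
      stop("conflicting probabilities for a duplicated edge", call. = FALSE)
    }
  }
  from <- from[first]; to <- to[first]; probs <- probs[first]
  verts <- order_ids(unique(c(from, to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  if (any(with_p)) igraph::E(g)$p <- probs
  validate_contact_network(g)
  g
}

#' Write a contact network as an edge list
#'
#' Inverse of [read_edge_list()]: one `u v [p]` line per edge, probabilities
#' printed with 12 significant digits so that a read/write/read cycle
#' reproduces the network exactly.
#'
#' @param network a contact network.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  validate_contact_network(network)
  el <- igraph::as_edgelist(network, names = TRUE)
  if (nrow(el) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (has_edge_probabilities(network)) {
    lines <- sprintf("%s %s %s", el[, 1], el[, 2],
                     formatC(igraph::E(network)$p, digits = 12, format = "g"))
  } else {
    lines <- sprintf("%s %s", el[, 1], el[, 2])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a contact network from GraphML
#'
#' Interchange reader: the GraphML edge attribute `p` (when present) maps
#' to the package's edge transmission probability.
#'
#' @param path path to a GraphML file.
#' @return a contact network.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  if (is.null(igraph::vertex_attr(g, "name")) && igraph::vcount(g) > 0) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  igraph::V(g)$name <- as.character(igraph::V(g)$name)
  validate_contact_network(g)
  g
}

#' Bundled example networks
#'
#' Returns a contact network shipped with the package. Currently the only
#' fixture is `"karate"`: Zachary's karate-club friendship network
#' (34 nodes, 78 edges), the classic small benchmark for source-location
#' experiments.
#'
#' @param name fixture name; one of `"karate"`.
#' @return a contact network.
#' @examples
#' g <- bundled_network("karate")
#' igraph::vcount(g)
#' @export
bundled_network <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  files <- c(karate = "karate.edgelist")
  if (!name %in% names(files)) {
    stop("unknown bundled network '", name, "'; available: ",
         paste(names(files), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", files[[name]], package = "silocate",
                      mustWork = TRUE)
  read_edge_list(path)
}

#' Construct an infection snapshot
#'
#' @param network a contact network.
#' @param infected character vector of infected node ids; must be a
#'   non-empty subset of the network's nodes.
#' @return an object of class `infection_snapshot`: a list with elements
#'   `network` and `infected` (sorted, deduplicated).
#' @examples
#' g <- bundled_network("karate")
#' snap <- infection_snapshot(g, c("1", "2", "3"))
#' @export
infection_snapshot <- function(network, infected) {
  validate_contact_network(network)
  infected <- unique(as.character(infected))
  if (length(infected) == 0) {
    stop("the infected set must be non-empty", call. = FALSE)
  }
  missing <- setdiff(infected, node_ids(network))
  if (length(missing) > 0) {
    stop("infected node(s) not in the network: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(network = network, infected = order_ids(infected)),
            class = "infection_snapshot")
}

#' @export
print.infection_snapshot <- function(x, ...) {
  cat("<infection_snapshot> ", length(x$infected), " infected of ",
      igraph::vcount(x$network), " nodes\n", sep = "")
  invisible(x)
}

#' Read an infection snapshot from CSV
#'
#' Expects a CSV with header `node,state` and states in `{S, I}`. Nodes of
#' the network absent from the file default to susceptible.
#'
#' @param path path to the snapshot CSV.
#' @param network the contact network the snapshot was observed on.
#' @return an [infection_snapshot()].
#' @export
read_snapshot <- function(path, network) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("node", "state") %in% names(df))) {
    stop("snapshot CSV must have columns `node` and `state`", call. = FALSE)
  }
  bad_state <- setdiff(unique(df$state), c("S", "I"))
  if (length(bad_state) > 0) {
    stop("unknown state token(s): ", paste(bad_state, collapse = ", "),
         "; states must be S or I", call. = FALSE)
  }
  missing <- setdiff(df$node, node_ids(network))
  if (length(missing) > 0) {
    stop("snapshot refers to node(s) not in the network: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  infection_snapshot(network, df$node[df$state == "I"])
}

#' Write an infection snapshot as CSV
#'
#' Writes one `node,state` row for every node of the network (`I` for
#' infected, `S` otherwise), the format [read_snapshot()] consumes.
#'
#' @param snapshot an infection snapshot.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "infection_snapshot"))
  ids <- order_ids(node_ids(snapshot$network))
  df <- data.frame(node = ids,
                   state = ifelse(ids %in% snapshot$infected, "I", "S"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Infected subgraph of a snapshot
#'
#' The subgraph induced by the infected nodes: node set equals the infected
#' set, edges are the parent network's edges with both endpoints infected,
#' edge probabilities carried over. This is the graph a locator actually
#' observes.
#'
#' @param snapshot an infection snapshot.
#' @return a contact network on the infected nodes.
#' @export
infected_subgraph <- function(snapshot) {
  stopifnot(inherits(snapshot, "infection_snapshot"))
  igraph::induced_subgraph(snapshot$network, snapshot$infected)
}
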