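#' Discrete-time SI diffusion
#'
#' The spreading model is the classical susceptible-infected (SI) process
#' in discrete time: at every step each infected node independently tries
#' to infect each susceptible neighbour `v` across edge `(u, v)` with the
#' edge's transmission probability `P_uv`; infected nodes never recover.
#' The marginal one-step infection probability of a susceptible node `v` is
#' therefore the hazard
#' \deqn{\lambda(v) = 1 - \prod_{u \in N(v) \cap V_I} (1 - P_{uv}),}
#' the product running over v's currently infected neighbours. Updates are
#' synchronous: all infections at step `t` are computed from the state at
#' `t - 1`.
#'
#' @name si-model
NULL

#' Simulation configuration
#'
#' @param stop_fraction the run ends at the first step where the infected
#'   fraction strictly exceeds this value; in (0, 1], default 0.30.
#' @param max_steps hard step cap guaranteeing termination; default
#'   `10 * |V|` (resolved at simulation time when `NULL`).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return a list of class `si_config`.
#' @export
si_config <- function(stop_fraction = 0.30, max_steps = NULL, seed = NULL) {
  stopifnot(is.numeric(stop_fraction), length(stop_fraction) == 1,
            stop_fraction > 0, stop_fraction <= 1)
  if (!is.null(max_steps)) {
    stopifnot(is.numeric(max_steps), length(max_steps) == 1, max_steps >= 1)
    max_steps <- as.integer(max_steps)
  }
  structure(list(stop_fraction = stop_fraction, max_steps = max_steps,
                 seed = seed),
            class = "si_config")
}

#' Assign uniform edge transmission probabilities
#'
#' Draws an independent `Uniform(0, 1)` transmission probability for every
#' edge and stores it in the edge attribute `p`. The draw is per edge (one
#' value for both directions) and held fixed for the whole run: the result
#' is a static weighted network. Reproducible from `seed`.
#'
#' @param network a contact network.
#' @param seed integer RNG seed, or `NULL`.
#' @return the network with edge attribute `p` set.
#' @export
assign_edge_probabilities <- function(network, seed = NULL) {
  validate_contact_network(network)
  if (!is.null(seed)) set.seed(seed)
  m <- igraph::ecount(network)
  p <- stats::runif(m)
  # runif can in principle return exactly 0; the open interval is required
  eps <- .Machine$double.eps
  p <- pmin(pmax(p, eps), 1 - eps)
  igraph::E(network)$p <- p
  network
}

#' One-step infection hazard of a susceptible node
#'
#' Closed form `1 - prod(1 - P_uv)` over the infected neighbours `u` of
#' `v`; 0 when no neighbour is infected.
#'
#' @param v a node id.
#' @param snapshot the current infection snapshot (network must carry edge
#'   probabilities).
#' @return a probability in \[0, 1\].
#' @export
step_hazard <- function(v, snapshot) {
  stopifnot(inherits(snapshot, "infection_snapshot"))
  g <- snapshot$network
  if (!has_edge_probabilities(g)) {
    stop("network has no edge probabilities; call ",
         "assign_edge_probabilities() first", call. = FALSE)
  }
  if (v %in% snapshot$infected) {
    stop("node '", v, "' is already infected", call. = FALSE)
  }
  inc <- igraph::incident(g, v)
  if (length(inc) == 0) return(0)
  other <- igraph::ends(g, inc, names = TRUE)
  nb <- ifelse(other[, 1] == v, other[, 2], other[, 1])
  p <- inc$p[nb %in% snapshot$infected]
  if (length(p) == 0) return(0)
  1 - prod(1 - p)
}

#' Sample source nodes uniformly
#'
#' Draws `m` distinct nodes uniformly without replacement, with no
#' adjacency constraint (sampled sources may be neighbours).
#'
#' @param network a contact network.
#' @param m number of sources, `1 <= m <= |V|`.
#' @param seed integer RNG seed, or `NULL`.
#' @return a character vector of `m` node ids.
#' @export
sample_sources <- function(network, m, seed = NULL) {
  validate_contact_network(network)
  n <- igraph::vcount(network)
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m > n) {
    stop("`m` must be an integer in [1, ", n, "]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sample(node_ids(network), as.integer(m))
}

#' Run an SI diffusion
#'
#' Synchronous discrete-time SI spread from `sources` until the infected
#' fraction strictly exceeds `config$stop_fraction` or `max_steps` is hit.
#' Each step, every susceptible node with at least one infected neighbour
#' becomes infected with probability [step_hazard()] (all of its infected
#' neighbours attempt independently).
#'
#' @param network a contact network with edge probabilities assigned.
#' @param sources non-empty character vector of seed node ids.
#' @param config an [si_config()].
#' @return an object of class `si_trace`: list with `sources`,
#'   `infection_time` (named integer vector, step at which each infected
#'   node turned; sources are 0), `final_snapshot`, and `steps_run`.
#' @examples
#' g <- assign_edge_probabilities(bundled_network("karate"), seed = 1)
#' tr <- simulate_si(g, sources = "1", si_config(seed = 2))
#' length(tr$final_snapshot$infected)
#' @export
simulate_si <- function(network, sources, config = si_config()) {
  validate_contact_network(network)
  stopifnot(inherits(config, "si_config"))
  sources <- unique(as.character(sources))
  if (length(sources) == 0) stop("`sources` must be non-empty", call. = FALSE)
  ids <- node_ids(network)
  if (!all(sources %in% ids)) {
    stop("source(s) not in the network: ",
         paste(setdiff(sources, ids), collapse = ", "), call. = FALSE)
  }
  if (!has_edge_probabilities(network)) {
    stop("network has no edge probabilities; call ",
         "assign_edge_probabilities() first", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- igraph::vcount(network)
  max_steps <- if (is.null(config$max_steps)) 10L * n else config$max_steps

  # integer-indexed adjacency with per-incidence probabilities, built once
  adj <- igraph::as_adj_list(network, mode = "all")
  adj <- lapply(adj, as.integer)
  inc <- igraph::as_adj_edge_list(network, mode = "all")
  ep <- igraph::E(network)$p
  adj_p <- lapply(inc, function(e) ep[as.integer(e)])

  infected <- logical(n)
  names_v <- ids
  src_idx <- match(sources, ids)
  infected[src_idx] <- TRUE
  t_inf <- rep(NA_integer_, n)
  t_inf[src_idx] <- 0L

  steps <- 0L
  while (sum(infected) / n <= config$stop_fraction && steps < max_steps) {
    if (all(infected)) break  # nothing left to infect
    steps <- steps + 1L
    frontier <- which(!infected)
    newly <- integer(0)
    for (v in frontier) {
      pv <- adj_p[[v]][infected[adj[[v]]]]
      if (length(pv) == 0) next
      hazard <- 1 - prod(1 - pv)
      if (stats::runif(1) < hazard) newly <- c(newly, v)
    }
    if (length(newly) > 0) {
      infected[newly] <- TRUE
      t_inf[newly] <- steps
    }
  }

  it <- t_inf[infected]
  names(it) <- names_v[infected]
  structure(list(
    sources = order_ids(sources),
    infection_time = it,
    final_snapshot = infection_snapshot(network, names_v[infected]),
    steps_run = steps
  ), class = "si_trace")
}

#' @export
print.si_trace <- function(x, ...) {
  n <- igraph::vcount(x$final_snapshot$network)
  cat("<si_trace> ", length(x$sources), " source(s), ",
      length(x$infection_time), "/", n, " infected after ",
      x$steps_run, " step(s)\n", sep = "")
  invisible(x)
}

#' Write a simulation trace as CSV
#'
#' @param trace an `si_trace`.
#' @param path output file; columns `node,infection_time`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "si_trace"))
  df <- data.frame(node = names(trace$infection_time),
                   infection_time = as.integer(trace$infection_time))
  df <- df[order(df$infection_time, df$node, method = "radix"), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
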