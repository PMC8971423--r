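#' Locator evaluation metrics and benchmark harness
#'
#' Predictions are scored against the true seed set with three standard
#' measures:
#'
#' * **F-score** (beta = 1): harmonic mean of precision
#'   `|S-hat ^ S*| / |S-hat|` and recall `|S-hat ^ S*| / |S*|`.
#' * **average error distance**
#'   \deqn{\Delta = \frac{1}{|S^*|}\Big(\sum_{i \in S^*}
#'     \min_{j \in \hat S} dis(i,j) + \rho\,\big||S^*| - |\hat S|\big|\Big),}
#'   with `dis` the shortest-path length in the full network, a penalty
#'   weight `rho = 0.5` on the source-count mismatch, and unreachable
#'   pairs capped at `|V|` so that Delta stays finite on disconnected
#'   graphs. `Delta = 0` exactly when the prediction equals the truth.
#' * **count accuracy**: the fraction of replicates with
#'   `|S-hat| = |S*|`.
#'
#' @name locator-metrics
NULL

#' Precision, recall and F-score of a prediction
#'
#' @param predicted character vector of predicted source ids (may be
#'   empty: precision, recall and F are then 0).
#' @param truth non-empty character vector of true source ids.
#' @return a list with `precision`, `recall`, `f_score`.
#' @examples
#' precision_recall_f(c("a", "b"), c("b", "c"))
#' @export
precision_recall_f <- function(predicted, truth) {
  truth <- unique(as.character(truth))
  if (length(truth) == 0) stop("`truth` must be non-empty", call. = FALSE)
  predicted <- unique(as.character(predicted))
  hit <- length(intersect(predicted, truth))
  precision <- if (length(predicted) == 0) 0 else hit / length(predicted)
  recall <- hit / length(truth)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f_score = f)
}

#' Average error distance between prediction and truth
#'
#' See [locator-metrics] for the formula.
#'
#' @param predicted non-empty character vector of predicted source ids.
#' @param truth non-empty character vector of true source ids.
#' @param network the full contact network distances are measured in.
#' @param rho penalty weight on the source-count mismatch; default 0.5.
#' @return the average error distance, >= 0.
#' @export
average_error_distance <- function(predicted, truth, network, rho = 0.5) {
  truth <- unique(as.character(truth))
  predicted <- unique(as.character(predicted))
  if (length(truth) == 0) stop("`truth` must be non-empty", call. = FALSE)
  if (length(predicted) == 0) {
    stop("`predicted` must be non-empty", call. = FALSE)
  }
  d <- igraph::distances(network, v = truth, to = predicted)
  d[!is.finite(d)] <- igraph::vcount(network)
  (sum(apply(d, 1, min)) + rho * abs(length(truth) - length(predicted))) /
    length(truth)
}

#' Source-count accuracy over replicates
#'
#' @param reports a list of per-replicate evaluation records, each with a
#'   logical element `count_correct` (as produced by [run_benchmark()]'s
#'   internals), or a logical vector.
#' @return the fraction of replicates that predicted the true number of
#'   sources.
#' @export
count_accuracy <- function(reports) {
  if (is.list(reports)) {
    reports <- vapply(reports, function(r) isTRUE(r$count_correct), logical(1))
  }
  if (length(reports) == 0) stop("no reports supplied", call. = FALSE)
  mean(reports)
}

#' Erdos-Renyi contact network
#'
#' `G(n, p)` with `p = mean_degree / (n - 1)`; vertices named `"1"..."n"`.
#'
#' @param n number of nodes, >= 2.
#' @param mean_degree target mean degree, in (0, n).
#' @param seed integer RNG seed, or `NULL`.
#' @return a contact network (without edge probabilities; see
#'   [assign_edge_probabilities()]).
#' @export
generate_er <- function(n, mean_degree, seed = NULL) {
  stopifnot(n >= 2)
  if (mean_degree <= 0 || mean_degree >= n) {
    stop("`mean_degree` must lie in (0, n)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnp(n, p = mean_degree / (n - 1), directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Barabasi-Albert contact network
#'
#' Preferential attachment from `m_attach` initial isolated nodes; each
#' subsequent node attaches `m_attach` edges, so the edge count is exactly
#' `m_attach * (n - m_attach)`. Vertices named `"1"..."n"`.
#'
#' @param n number of nodes.
#' @param m_attach edges added per new node, `1 <= m_attach < n`.
#' @param seed integer RNG seed, or `NULL`.
#' @return a contact network.
#' @export
generate_ba <- function(n, m_attach, seed = NULL) {
  stopifnot(n >= 2)
  if (m_attach < 1 || m_attach >= n) {
    stop("`m_attach` must lie in [1, n)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_pa(n, power = 1, m = m_attach, directed = FALSE,
                         start.graph = igraph::make_empty_graph(
                           m_attach, directed = FALSE))
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Uniform random locator baseline
#'
#' Predicts `k` infected nodes uniformly at random -- the chance control
#' every informed locator must beat.
#'
#' @param snapshot an infection snapshot.
#' @param k number of nodes to guess, `1 <= k <= |V_I|`.
#' @param seed integer RNG seed, or `NULL`.
#' @return a character vector of `k` infected node ids.
#' @export
random_baseline <- function(snapshot, k, seed = NULL) {
  stopifnot(inherits(snapshot, "infection_snapshot"))
  n_i <- length(snapshot$infected)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n_i) {
    stop("`k` must be an integer in [1, ", n_i, "]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sample(snapshot$infected, as.integer(k))
}

#' Benchmark configuration
#'
#' @param network either a contact network, or a list describing a
#'   generator: `list(model = "er", n, mean_degree)` or
#'   `list(model = "ba", n, m_attach)` (a fresh graph per replicate), or a
#'   bundled fixture name such as `"karate"`.
#' @param m number of true sources per replicate.
#' @param stop_fraction infected-fraction stopping rule for the SI runs.
#' @param replicates number of independent runs; default 100.
#' @param seed master RNG seed; every per-replicate seed derives from it.
#' @param alpha entropy weight passed to the locators.
#' @return a list of class `benchmark_config`.
#' @export
benchmark_config <- function(network, m, stop_fraction = 0.30,
                             replicates = 100, seed = 1,
                             alpha = default_alpha) {
  stopifnot(replicates >= 1, m >= 1)
  structure(list(network = network, m = m, stop_fraction = stop_fraction,
                 replicates = as.integer(replicates), seed = seed,
                 alpha = alpha),
            class = "benchmark_config")
}

resolve_benchmark_network <- function(spec, seed) {
  if (igraph::is_igraph(spec)) return(spec)
  if (is.character(spec) && length(spec) == 1) return(bundled_network(spec))
  if (is.list(spec) && !is.null(spec$model)) {
    return(switch(spec$model,
      er = generate_er(spec$n, spec$mean_degree, seed = seed),
      ba = generate_ba(spec$n, spec$m_attach, seed = seed),
      stop("unknown network model '", spec$model, "'", call. = FALSE)))
  }
  stop("unrecognized network specification", call. = FALSE)
}

#' Run a repeated-simulation locator benchmark
#'
#' For each replicate: draw (or reuse) the network, assign fresh
#' `Uniform(0, 1)` edge probabilities, sample `m` sources uniformly,
#' simulate SI diffusion to the stopping fraction, run every requested
#' locator on the final snapshot, and score it against the true sources.
#' Fully reproducible: all per-replicate seeds are drawn once from the
#' master seed.
#'
#' The built-in method names are `"slbne"`, `"slbic"` and `"random"`; the
#' random baseline is size-matched to the first non-random method's
#' prediction in the same replicate (falling back to `m` when it is the
#' only method). A custom locator may be supplied as a named function
#' `function(network, snapshot) -> character vector`; a three-argument
#' function additionally receives the true source set (useful for oracle
#' or cheating controls that calibrate the harness itself).
#'
#' @param config a [benchmark_config()].
#' @param methods character vector of built-in method names and/or a named
#'   list mixing names and locator functions.
#' @return a list with `summary` (a `data.frame`: one row per method with
#'   mean and sd of F-score and error distance, mean precision/recall, and
#'   count accuracy) and `replicates` (the long per-replicate
#'   `data.frame`).
#' @examples
#' cfg <- benchmark_config(list(model = "er", n = 100, mean_degree = 8),
#'                         m = 2, replicates = 3, seed = 7)
#' run_benchmark(cfg, c("slbne", "random"))$summary
#' @export
run_benchmark <- function(config, methods = c("slbne", "slbic", "random")) {
  stopifnot(inherits(config, "benchmark_config"))
  if (is.character(methods)) methods <- stats::setNames(as.list(methods),
                                                        methods)
  method_names <- names(methods)
  if (is.null(method_names) || any(method_names == "")) {
    stop("`methods` must be named", call. = FALSE)
  }

  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 4L, config$replicates)

  rows <- list()
  for (i in seq_len(config$replicates)) {
    s <- rep_seeds[i]
    g <- resolve_benchmark_network(config$network, seed = s)
    g <- assign_edge_probabilities(g, seed = s + 1L)
    truth <- sample_sources(g, config$m, seed = s + 2L)
    tr <- simulate_si(g, truth,
                      si_config(stop_fraction = config$stop_fraction,
                                seed = s + 3L))
    snap <- tr$final_snapshot

    first_pred_size <- NA_integer_
    for (nm in method_names) {
      meth <- methods[[nm]]
      pred <- if (is.function(meth)) {
        if (length(formals(meth)) >= 3) as.character(meth(g, snap, truth))
        else as.character(meth(g, snap))
      } else if (identical(meth, "slbne")) {
        slbne(g, snap, alpha = config$alpha)$predicted
      } else if (identical(meth, "slbic")) {
        slbic(g, snap, alpha = config$alpha)$predicted
      } else if (identical(meth, "random")) {
        k <- if (is.na(first_pred_size)) config$m else first_pred_size
        random_baseline(snap, min(k, length(snap$infected)), seed = s + 4L)
      } else {
        stop("unknown method '", meth, "'", call. = FALSE)
      }
      if (!identical(meth, "random") && is.na(first_pred_size)) {
        first_pred_size <- length(pred)
      }
      prf <- precision_recall_f(pred, truth)
      rows[[length(rows) + 1]] <- data.frame(
        replicate = i, method = nm,
        n_infected = length(snap$infected),
        n_predicted = length(pred),
        precision = prf$precision, recall = prf$recall,
        f_score = prf$f_score,
        error_distance = average_error_distance(pred, truth, g),
        count_correct = length(pred) == length(truth),
        stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)

  summ <- do.call(rbind, lapply(method_names, function(nm) {
    x <- long[long$method == nm, ]
    data.frame(method = nm,
               replicates = nrow(x),
               mean_f = mean(x$f_score), sd_f = stats::sd(x$f_score),
               mean_precision = mean(x$precision),
               mean_recall = mean(x$recall),
               mean_delta = mean(x$error_distance),
               sd_delta = stats::sd(x$error_distance),
               count_accuracy = mean(x$count_correct),
               stringsAsFactors = FALSE)
  }))
  summ$sd_f[is.na(summ$sd_f)] <- 0
  summ$sd_delta[is.na(summ$sd_delta)] <- 0
  list(summary = summ, replicates = long)
}
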