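test_that("precision, recall and F cover the boundary cases", {
  r <- precision_recall_f(c("a", "b"), c("a", "b"))
  expect_equal(r$f_score, 1)
  r2 <- precision_recall_f(c("a", "x"), c("a", "b"))
  expect_equal(r2$precision, 0.5)
  expect_equal(r2$recall, 0.5)
  expect_equal(r2$f_score, 0.5)
  expect_equal(precision_recall_f(c("x", "y"), c("a", "b"))$f_score, 0)
  expect_equal(precision_recall_f(character(0), "a")$f_score, 0)
  expect_error(precision_recall_f("a", character(0)), "non-empty")
})

test_that("average error distance follows the penalised nearest-source form", {
  p5 <- igraph::graph_from_edgelist(
    cbind(paste0("v", 1:4), paste0("v", 2:5)), directed = FALSE)
  # perfect prediction
  expect_equal(average_error_distance(c("v1", "v3"), c("v1", "v3"), p5), 0)
  # S* = {u, v}, S-hat = {u}: (0 + d + 0.5)/2
  d <- 3  # dis(v1, v4)
  expect_equal(average_error_distance("v1", c("v1", "v4"), p5), (d + 0.5) / 2)
  # every true source adjacent to its nearest prediction, sizes equal
  expect_equal(average_error_distance(c("v2", "v5"), c("v1", "v4"), p5), 1)
  # unreachable pairs are capped at |V|
  g2 <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("x", "y")),
                                    directed = FALSE)
  expect_equal(average_error_distance("a", "x", g2), 4)
  expect_error(average_error_distance(character(0), "a", g2), "non-empty")
})

test_that("metrics agree with scratch implementations on random set pairs", {
  g <- generate_er(40, 5, seed = 21)
  ids <- igraph::V(g)$name
  set.seed(22)
  for (k in 1:200) {
    pred <- sample(ids, sample(1:6, 1))
    truth <- sample(ids, sample(1:6, 1))
    expect_equal(precision_recall_f(pred, truth)$f_score,
                 oracle_f(pred, truth))
    expect_equal(average_error_distance(pred, truth, g),
                 oracle_error_distance(g, pred, truth),
                 tolerance = 1e-12)
  }
})

test_that("count accuracy is the fraction of exact source-count calls", {
  expect_equal(count_accuracy(c(TRUE, TRUE, TRUE)), 1)
  expect_equal(count_accuracy(c(FALSE, FALSE)), 0)
  expect_equal(count_accuracy(c(TRUE, TRUE, TRUE, FALSE)), 0.75)
  expect_equal(count_accuracy(list(list(count_correct = TRUE),
                                   list(count_correct = FALSE))), 0.5)
  expect_error(count_accuracy(logical(0)), "no reports")
})

test_that("the ER generator hits its target mean degree", {
  degs <- vapply(1:50, function(s) {
    mean(igraph::degree(generate_er(500, 10, seed = s)))
  }, 0)
  # binomial se of the mean degree over 50 draws
  se <- sqrt(2 * 10 / 500) / sqrt(50)  # var(mean deg) ~ 2p(1-p)(n-1)/n
  expect_lt(abs(mean(degs) - 10), 3 * max(se, 0.05))
  expect_identical(igraph::as_edgelist(generate_er(100, 5, seed = 3)),
                   igraph::as_edgelist(generate_er(100, 5, seed = 3)))
  expect_error(generate_er(100, 100), "mean_degree")
})

test_that("the BA generator satisfies the attachment edge-count identity", {
  for (prm in list(c(50, 2), c(80, 3), c(30, 1))) {
    g <- generate_ba(prm[1], prm[2], seed = prm[1])
    expect_equal(igraph::ecount(g), prm[2] * (prm[1] - prm[2]))
  }
  expect_identical(igraph::as_edgelist(generate_ba(60, 2, seed = 9)),
                   igraph::as_edgelist(generate_ba(60, 2, seed = 9)))
  # heavy tail: the hub dwarfs the mean degree
  g <- generate_ba(1000, 3, seed = 4)
  expect_gt(max(igraph::degree(g)), 5 * mean(igraph::degree(g)))
  expect_error(generate_ba(10, 10), "m_attach")
})

test_that("the random baseline samples infected nodes uniformly", {
  g <- random_test_graph(30, 4, seed = 31)
  snap <- random_snapshot(g, 0.5, seed = 32)
  n_i <- length(snap$infected)
  expect_setequal(random_baseline(snap, n_i, seed = 1), snap$infected)
  expect_error(random_baseline(snap, 0), "k")
  expect_error(random_baseline(snap, n_i + 1), "k")

  # with m true sources among |V_I| infected, expected recall of a
  # k-guess is k/|V_I| (hypergeometric)
  truth <- snap$infected[1:3]
  k <- 5
  rec <- vapply(1:400, function(s) {
    precision_recall_f(random_baseline(snap, k, seed = s), truth)$recall
  }, 0)
  expected <- k / n_i
  se <- stats::sd(rec) / sqrt(length(rec))
  expect_lt(abs(mean(rec) - expected), 4 * se)
})

test_that("the benchmark harness scores a perfect oracle perfectly", {
  cfg <- benchmark_config(list(model = "er", n = 60, mean_degree = 6),
                          m = 2, replicates = 3, seed = 5)
  out <- run_benchmark(cfg, list(
    oracle = function(g, snap, truth) truth,
    everything = function(g, snap) snap$infected))
  ev <- out$summary[out$summary$method == "oracle", ]
  expect_equal(ev$mean_f, 1)
  expect_equal(ev$mean_delta, 0)
  expect_equal(ev$count_accuracy, 1)
  # predicting every infected node guarantees recall 1 on every replicate
  expect_equal(out$summary$mean_recall[out$summary$method == "everything"], 1)
  expect_equal(nrow(out$replicates), 6)
})

test_that("benchmarks are bit-reproducible from the master seed", {
  cfg <- benchmark_config(list(model = "er", n = 80, mean_degree = 6),
                          m = 2, replicates = 4, seed = 17)
  a <- run_benchmark(cfg, c("slbne", "random"))
  b <- run_benchmark(cfg, c("slbne", "random"))
  expect_identical(a$summary, b$summary)
  expect_identical(a$replicates, b$replicates)

  # one replicate: sd collapses to 0 by convention
  cfg1 <- benchmark_config(list(model = "er", n = 60, mean_degree = 6),
                           m = 2, replicates = 1, seed = 3)
  s1 <- run_benchmark(cfg1, "slbne")$summary
  expect_equal(s1$sd_f, 0)
  expect_equal(s1$sd_delta, 0)
})

test_that("slbic batch recall never falls below slbne batch recall", {
  cfg <- benchmark_config(list(model = "er", n = 120, mean_degree = 8),
                          m = 3, replicates = 8, seed = 23)
  out <- run_benchmark(cfg, c("slbne", "slbic"))
  s <- out$summary
  expect_gte(s$mean_recall[s$method == "slbic"],
             s$mean_recall[s$method == "slbne"])
  # per replicate too: the prediction superset forces it
  wide_ne <- out$replicates[out$replicates$method == "slbne", "recall"]
  wide_ic <- out$replicates[out$replicates$method == "slbic", "recall"]
  expect_true(all(wide_ic >= wide_ne))
})
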