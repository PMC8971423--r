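# Independent, naively-coded reference implementations used as oracles.
# These deliberately share no helpers with the package: every quantity is
# recomputed from first principles with plain loops and igraph primitives.

oracle_xi <- function(g, v, infected) {
  nb <- igraph::neighbors(g, v)$name
  if (length(nb) == 0) return(0)
  n_uninf <- sum(!(nb %in% infected))
  ((length(nb) - n_uninf) / length(nb)) * (1 / (1 + exp(-length(nb))))
}

oracle_ie <- function(xi) if (xi > 0) -xi * log2(xi) else 0

oracle_eta <- function(g, j, infected, neighbors = "infected") {
  nb <- igraph::neighbors(g, j)$name
  if (neighbors == "infected") nb <- nb[nb %in% infected]
  total <- 0
  for (t in nb) {
    total <- total + oracle_xi(g, t, infected) / length(igraph::neighbors(g, t))
  }
  total
}

oracle_psi <- function(g, i, j, infected) {
  (1 / length(igraph::neighbors(g, i))) / oracle_eta(g, j, infected)
}

oracle_ae <- function(g, i, infected) {
  nb <- igraph::neighbors(g, i)$name
  nb <- nb[nb %in% infected]
  total <- 0
  for (j in nb) {
    psi <- oracle_psi(g, i, j, infected)
    if (psi > 0) total <- total - psi * log2(psi)
  }
  total
}

oracle_ne <- function(g, i, infected, alpha = 4) {
  oracle_ae(g, i, infected) - alpha * oracle_ie(oracle_xi(g, i, infected))
}

oracle_core_set <- function(g, infected, alpha = 4) {
  ne <- vapply(infected, function(v) oracle_ne(g, v, infected, alpha), 0)
  names(ne) <- infected
  core <- character(0)
  for (v in infected) {
    nb <- igraph::neighbors(g, v)$name
    nb <- nb[nb %in% infected]
    if (length(nb) == 0 || ne[[v]] > max(ne[nb])) core <- c(core, v)
  }
  if (length(core) == 0) {
    best <- names(ne)[ne == max(ne)]
    core <- sort(best, method = "radix")[1]
  }
  sort(core, method = "radix")
}

# Eq.-8 similarity by literal double enumeration over neighbourhoods
oracle_com <- function(g, x, y) {
  if (x == y) return(length(igraph::neighbors(g, x)))
  length(intersect(igraph::neighbors(g, x)$name,
                   igraph::neighbors(g, y)$name))
}

oracle_similarity <- function(g, n1, n2) {
  jac <- function(x, y) {
    u <- length(unique(c(igraph::neighbors(g, x)$name,
                         igraph::neighbors(g, y)$name)))
    if (u == 0) 0 else oracle_com(g, x, y) / u
  }
  total <- jac(n1, n2)
  for (i in igraph::neighbors(g, n1)$name) {
    for (j in igraph::neighbors(g, n2)$name) {
      total <- total + jac(i, j)
    }
  }
  total
}

# cohesion by direct evaluation of the distance-histogram formula
oracle_delta <- function(H, i, members, ne_i, apn = "distinct") {
  others <- setdiff(members, i)
  if (length(others) == 0) return(0.5 * ne_i)
  dvec <- numeric(0)
  for (j in others) {
    d <- igraph::distances(H, v = i, to = j)[1, 1]
    if (is.finite(d)) dvec <- c(dvec, d)
  }
  if (length(dvec) == 0) return(0.5 * ne_i)
  m_dis <- max(dvec)
  norm <- if (apn == "distinct") length(unique(dvec)) else length(dvec)
  term <- 0
  for (d in unique(dvec)) {
    cnt <- sum(dvec == d)
    term <- term + (m_dis + 1 - d) / (m_dis + 1) * cnt / norm
  }
  0.5 * term + 0.5 * ne_i
}

# scratch metric implementations
oracle_f <- function(pred, truth) {
  tp <- sum(pred %in% truth)
  p <- if (length(pred) == 0) 0 else tp / length(pred)
  r <- tp / length(truth)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

oracle_error_distance <- function(g, pred, truth, rho = 0.5) {
  acc <- 0
  for (i in truth) {
    best <- Inf
    for (j in pred) {
      d <- igraph::distances(g, v = i, to = j)[1, 1]
      if (!is.finite(d)) d <- igraph::vcount(g)
      if (d < best) best <- d
    }
    acc <- acc + best
  }
  (acc + rho * abs(length(truth) - length(pred))) / length(truth)
}
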