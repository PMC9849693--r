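## Independent oracles used across the suite. These deliberately avoid the
## code paths they check: root-finding instead of closed forms, exhaustive
## enumeration instead of graph algorithms.

## Fraction bound for 1:1 binding by bisection on the free mass balance:
## complex c solves (x - c)(L - c) = kd * c, c in [0, min(x, L)].
oracle_fraction_bound <- function(x, L, kd, tol = 1e-14) {
  if (x == 0) return(0)
  f <- function(c) (x - c) * (L - c) - kd * c
  lo <- 0
  hi <- min(x, L)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * min(x, L)) break
  }
  ((lo + hi) / 2) / L
}

## Per-injection ITC heats with the complex concentration obtained by
## uniroot on the mass balance rather than the quadratic closed form.
oracle_itc_heats <- function(protocol, n_sites, kd, dh) {
  v <- protocol$injection_volumes
  V0 <- protocol$cell_volume
  d <- 1 - v / V0
  m <- protocol$cell_conc
  x <- 0
  mx_prev <- 0
  q <- numeric(length(v))
  for (i in seq_along(v)) {
    m <- m * d[i]
    x <- x * d[i] + protocol$syringe_conc * (v[i] / V0)
    sites <- n_sites * m
    g <- function(c) (sites - c) * (x - c) - kd * c
    hi <- min(sites, x)
    mx <- if (hi <= 0) 0 else stats::uniroot(g, c(0, hi), tol = 1e-18)$root
    q[i] <- V0 * dh * (mx - mx_prev * d[i])
    mx_prev <- mx
  }
  q / (protocol$syringe_conc * v)
}

## Exhaustive shortest-path enumeration by depth-first search over simple
## paths, from an adjacency list. Returns list(l, n).
oracle_shortest_paths <- function(adj, X, Y) {
  best <- Inf
  count <- 0L
  walk <- function(node, depth, visited) {
    if (depth > best) return()
    if (node == Y) {
      if (depth < best) { best <<- depth; count <<- 1L }
      else count <<- count + 1L
      return()
    }
    for (nb in adj[[node]])
      if (!(nb %in% visited)) walk(nb, depth + 1L, c(visited, nb))
  }
  walk(X, 0L, X)
  if (is.infinite(best)) list(l = Inf, n = 0L) else list(l = best, n = count)
}

## Random undirected graph as an edge data.frame plus adjacency list.
random_test_graph <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- paste0("r", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- pairs[keep, , drop = FALSE]
  adj <- stats::setNames(lapply(nodes, function(x) character()), nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  list(nodes = nodes, edges = edges, adj = adj)
}

## Wrap an edge table into a persistence_matrix-backed PSN at a given pT.
psn_from_edges <- function(edges, nodes, pt = 0.5, persistence = 0.9) {
  if (nrow(edges) == 0) {
    pairs <- data.frame(residue_i = character(), residue_j = character(),
                        interaction_class = character(),
                        persistence = numeric(), stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(residue_i = edges[, 1], residue_j = edges[, 2],
                        interaction_class = "hbond",
                        persistence = persistence, stringsAsFactors = FALSE)
  }
  pm <- structure(list(pairs = pairs, nodes = nodes, n_frames = 1L),
                  class = "persistence_matrix")
  build_psn(pm, pt = pt, nodes = nodes)
}

## Random orthonormal basis (columns) in n dimensions.
random_orthobasis <- function(n, k) {
  qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))[, seq_len(k), drop = FALSE]
}
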