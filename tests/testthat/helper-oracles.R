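# Independent brute-force oracles used to validate the package's metric
# implementations. These deliberately use naive algorithms (literal
# triple-loop Floyd-Warshall, exhaustive simple-path enumeration, direct
# triangle sums) so they share no code path with the package.

# Literal triple-loop Floyd-Warshall on lengths 1/w.
oracle_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) d[i, j] <- 0 else if (w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# All simple paths between s and t (list of node vectors), by DFS.
enumerate_simple_paths <- function(w, s, t) {
  n <- nrow(w)
  paths <- list()
  walk <- function(path, visited) {
    u <- path[length(path)]
    if (u == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (v in which(w[u, ] > 0)) {
      if (!visited[v]) walk(c(path, v), `[<-`(visited, v, TRUE))
    }
  }
  walk(s, `[<-`(logical(n), s, TRUE))
  paths
}

path_length <- function(w, path) {
  if (length(path) < 2) return(0)
  sum(1 / w[cbind(path[-length(path)], path[-1])])
}

# Betweenness by exhaustive enumeration: for each unordered pair, find all
# simple paths, keep those within tolerance of the minimum length, and credit
# interior nodes with the tied-path fraction.
oracle_betweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- enumerate_simple_paths(w, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, function(p) path_length(w, p), numeric(1))
    best <- min(lens)
    shortest <- paths[lens <= best * (1 + tol)]
    for (p in shortest) {
      interior <- setdiff(p, c(s, t))
      bc[interior] <- bc[interior] + 1 / length(shortest)
    }
  }
  bc
}

# Onnela clustering by direct triangle sums (triple loop).
oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  wh <- w / mx
  ncp <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j < h && wh[i, j] > 0 && wh[i, h] > 0 && wh[j, h] > 0)
        acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    ncp[i] <- 2 * acc / (k * (k - 1))
  }
  list(Cp = mean(ncp), NCp = ncp)
}

# Union-find connectivity oracle.
oracle_connected <- function(w) {
  n <- nrow(w)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (w[i, j] > 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1L
}

# Literal Benjamini-Hochberg step-up: reject H_(1..k*) where k* is the
# largest k with p_(k) <= k/m * alpha.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * alpha)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# Random connected weighted graph (weights in (0.2, 1]); retries until
# connected.
random_connected_graph <- function(n, p = 0.5) {
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    on <- ut & matrix(runif(n * n) < p, n, n)
    w[on] <- runif(sum(on), 0.2, 1)
    w <- w + t(w)
    if (oracle_connected(w)) return(w)
  }
}

# Tiny helper: a ring over n nodes with unit weights.
ring_graph <- function(n, weight = 1) {
  w <- matrix(0, n, n)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  w[idx] <- weight
  w[idx[, c(2, 1)]] <- weight
  w
}
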