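# Weighted graph-theory metrics for FA connectomes. Path-based metrics use
# edge length 1/weight (strong connections = short distances), the standard
# convention for FA-weighted networks.

#' Weighted shortest-path distance matrix
#'
#' Distance between two nodes is the minimum over paths of the sum of inverse
#' edge weights (edge length = 1/w). Implemented as an all-pairs relaxation;
#' `d(i,i) = 0`, `d(i,j) = Inf` between disconnected components.
#'
#' @param w Connectivity matrix (symmetric, non-negative, zero diagonal).
#' @param require_connected Error if the graph is not fully connected
#'   (path-based global metrics assume the fully-connected analysis set).
#' @return Symmetric numeric distance matrix.
#' @export
shortest_path_lengths <- function(w, require_connected = TRUE) {
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  d <- .fw_dist_cpp(unclass(len))
  if (require_connected && any(!is.finite(d)))
    stop("graph is not fully connected; filter scans before computing path metrics")
  dimnames(d) <- dimnames(w)
  d
}

#' Characteristic path length
#'
#' Mean weighted shortest-path distance over all unordered node pairs.
#'
#' @param w Connectivity matrix.
#' @param d Optional precomputed distance matrix.
#' @return Scalar Lp.
#' @export
characteristic_path_length <- function(w, d = shortest_path_lengths(w)) {
  n <- nrow(d)
  sum(d[upper.tri(d)]) / (n * (n - 1) / 2)
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over unordered pairs; indexes the
#' capacity for parallel information transfer.
#'
#' @inheritParams characteristic_path_length
#' @return Scalar Eg in \[0, 1\] for weights in \[0, 1\].
#' @export
global_efficiency <- function(w, d = shortest_path_lengths(w)) {
  n <- nrow(d)
  sum(1 / d[upper.tri(d)]) / (n * (n - 1) / 2)
}

#' Nodal efficiency
#'
#' For each node, the mean inverse distance to every other node.
#'
#' @inheritParams characteristic_path_length
#' @return Numeric vector of length `nrow(w)`.
#' @export
nodal_efficiency <- function(w, d = shortest_path_lengths(w)) {
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' Weighted clustering coefficients
#'
#' Onnela-type weighted clustering: with weights normalized by the network
#' maximum (`wh = w / max(w)`), the nodal coefficient is
#' `NCp(i) = 2 / (k_i (k_i - 1)) * sum_{j<h} (wh_ij wh_ih wh_jh)^(1/3)`,
#' zero for nodes of degree < 2. The global coefficient Cp averages over all
#' nodes (constant denominator across scans).
#'
#' @param w Connectivity matrix.
#' @return List with `Cp` (scalar) and `NCp` (length-n vector).
#' @export
clustering_coefficients <- function(w) {
  n <- nrow(w)
  k <- rowSums(w > 0)
  mx <- max(w)
  if (mx == 0) return(list(Cp = 0, NCp = rep(0, n)))
  wh <- (w / mx)^(1 / 3)
  tri <- diag(wh %*% wh %*% wh)   # 2 * sum over triangles at i
  ncp <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  list(Cp = mean(ncp), NCp = as.numeric(ncp))
}

#' Degree centrality
#'
#' Number of strictly positive-weight connections per node, plus the network
#' mean degree.
#'
#' @param w Connectivity matrix.
#' @return List with `Dc` (integer vector) and `mean_degree` (scalar).
#' @export
degree_centrality <- function(w) {
  dc <- as.integer(rowSums(w > 0))
  list(Dc = dc, mean_degree = mean(dc))
}

#' Betweenness centrality (weighted, Brandes)
#'
#' Brandes' accumulation over weighted shortest paths (edge length 1/w).
#' `Bc(i)` sums, over unordered source-target pairs not involving i, the
#' fraction of tied shortest paths passing through i.
#'
#' @param w Connectivity matrix (fully connected).
#' @param tol Relative tolerance for path-length ties.
#' @return Numeric vector of length `nrow(w)`.
#' @export
betweenness_centrality <- function(w, tol = 1e-10) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- Inf
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    visited <- logical(n)
    preds <- vector("list", n)
    order_out <- integer(0)
    repeat {
      cand <- which(!visited & is.finite(dist))
      if (!length(cand)) break
      u <- cand[which.min(dist[cand])]
      visited[u] <- TRUE
      order_out <- c(order_out, u)
      nb <- which(is.finite(len[u, ]) & !visited)
      if (length(nb)) {
        alt <- dist[u] + len[u, nb]
        eps <- tol * pmax(1, alt)
        better <- alt < dist[nb] - eps
        tied <- !better & abs(alt - dist[nb]) <= eps
        for (idx in which(better)) {
          v <- nb[idx]
          dist[v] <- alt[idx]
          sigma[v] <- sigma[u]
          preds[[v]] <- u
        }
        for (idx in which(tied)) {
          v <- nb[idx]
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (u in rev(order_out)) {
      for (p in preds[[u]]) {
        delta[p] <- delta[p] + sigma[p] / sigma[u] * (1 + delta[u])
      }
      if (u != s) bc[u] <- bc[u] + delta[u]
    }
  }
  bc / 2  # undirected: each unordered pair visited from both endpoints
}

#' Degree-preserving null network ensemble
#'
#' Each null network is obtained from the observed network by degree-
#' preserving double-edge swaps: two edges (a,b), (c,d) are replaced by
#' (a,d), (c,b), each edge carrying its weight, with swaps creating
#' self-loops or duplicate edges rejected. Rewiring continues until
#' `swaps_per_edge * n_edges` swaps have been accepted. Nulls that come out
#' disconnected are resampled so the null path length is always finite. The
#' construction preserves the degree sequence and the edge-weight multiset
#' exactly.
#'
#' @param w Connectivity matrix (fully connected).
#' @param n_null Number of null networks (production default 1000; tests use
#'   50-100).
#' @param seed Integer seed for the rewiring stream.
#' @param swaps_per_edge Accepted swaps per edge (default 10).
#' @param max_connect_retries Resampling attempts per null before erroring.
#' @return Object of class `null_ensemble`: list with per-null `Cp`, `Lp`,
#'   their means, and `n_null`.
#' @export
generate_null <- function(w, n_null = 1000L, seed = 1L, swaps_per_edge = 10L,
                          max_connect_retries = 20L) {
  stopifnot(n_null >= 1L)
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 2L) stop("need at least 2 edges to rewire")
  wts <- w[ut]
  cp <- numeric(n_null)
  lp <- numeric(n_null)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(n_null)) {
    wn <- NULL
    for (try in seq_len(max_connect_retries)) {
      el <- rewire_edges(ut, n, swaps_per_edge * m)
      wn <- matrix(0, n, n)
      wn[el] <- wts
      wn[el[, c(2L, 1L)]] <- wts
      if (is_fully_connected(wn)) break
      wn <- NULL
    }
    if (is.null(wn)) stop("could not generate a connected null network")
    d <- shortest_path_lengths(wn)
    cp[r] <- clustering_coefficients(wn)$Cp
    lp[r] <- characteristic_path_length(wn, d)
  }
  structure(list(n_null = n_null, Cp_null = cp, Lp_null = lp,
                 mean_Cp = mean(cp), mean_Lp = mean(lp)),
            class = "null_ensemble")
}

# One Maslov-Sneppen rewiring pass: `target` accepted double-edge swaps on the
# edge list `el` (2-column, i<j not required). Errors if acceptance stalls.
rewire_edges <- function(el, n, target, max_attempt_factor = 200L) {
  storage.mode(el) <- "integer"
  .rewire_cpp(el, as.integer(n), as.integer(target),
              as.integer(max_attempt_factor) * as.integer(target))
}

#' Small-worldness via random-network standardization
#'
#' Standardizes the observed clustering coefficient and characteristic path
#' length against the null-ensemble means: `gamma = Cp / mean(Cp_null)`,
#' `lambda = Lp / mean(Lp_null)`, `sigma = gamma / lambda`. `sigma > 1`
#' indicates small-world organization.
#'
#' @param cp,lp Observed global clustering coefficient and path length.
#' @param ensemble A `null_ensemble` from [generate_null()].
#' @return List with `gamma`, `lambda`, `sigma`.
#' @export
small_worldness <- function(cp, lp, ensemble) {
  gamma <- cp / ensemble$mean_Cp
  lambda <- lp / ensemble$mean_Lp
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Compute all global and nodal metrics for one scan
#'
#' Global: Cp, Lp, gamma, lambda, sigma, Eg, mean degree. Nodal: NCp, Ne, Bc,
#' Dc per node. Gamma/lambda/sigma require the null ensemble; set
#' `n_null = 0` to skip standardization (NA values).
#'
#' @param w Fully connected connectivity matrix.
#' @param n_null Number of null networks for small-worldness.
#' @param seed Seed for the null ensemble.
#' @param scan_id Scan identifier for the output tables.
#' @return List with data.frames `global` (`scan_id`, `metric`, `value`) and
#'   `nodal` (`scan_id`, `region`, `hemisphere`, `metric`, `value`).
#' @export
compute_scan_metrics <- function(w, n_null = 1000L, seed = 1L,
                                 scan_id = attr(w, "scan_id")) {
  if (is.null(scan_id) || is.na(scan_id)) scan_id <- "scan"
  d <- shortest_path_lengths(w)
  cl <- clustering_coefficients(w)
  lp <- characteristic_path_length(w, d)
  eg <- global_efficiency(w, d)
  ne <- nodal_efficiency(w, d)
  bc <- betweenness_centrality(w)
  dc <- degree_centrality(w)
  if (n_null >= 1L) {
    ens <- generate_null(w, n_null = n_null, seed = seed)
    sw <- small_worldness(cl$Cp, lp, ens)
  } else {
    sw <- list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
  }
  labels <- rownames(w)
  if (is.null(labels)) labels <- paste0("N", seq_len(nrow(w)))
  global <- data.frame(
    scan_id = scan_id,
    metric = c("Cp", "Lp", "gamma", "lambda", "sigma", "Eg", "mean_degree"),
    value = c(cl$Cp, lp, sw$gamma, sw$lambda, sw$sigma, eg, dc$mean_degree),
    stringsAsFactors = FALSE
  )
  hemi <- aal90_hemispheres(nrow(w))
  nodal <- data.frame(
    scan_id = scan_id,
    region = rep(labels, 4L),
    hemisphere = rep(hemi, 4L),
    metric = rep(c("NCp", "Ne", "Bc", "Dc"), each = nrow(w)),
    value = c(cl$NCp, ne, bc, as.numeric(dc$Dc)),
    stringsAsFactors = FALSE
  )
  list(global = global, nodal = nodal)
}

#' Long-format metrics table for a set of scans
#'
#' Stacks per-scan metric results into the pipeline's long CSV schema:
#' `scan_id, level, region, hemisphere, metric, value` (region/hemisphere NA
#' for global rows).
#'
#' @param per_scan List of results from [compute_scan_metrics()].
#' @return data.frame.
#' @export
metrics_long_table <- function(per_scan) {
  rows <- lapply(per_scan, function(res) {
    g <- res$global
    g$level <- "global"; g$region <- NA_character_; g$hemisphere <- NA_character_
    nd <- res$nodal
    nd$level <- "nodal"
    cols <- c("scan_id", "level", "region", "hemisphere", "metric", "value")
    rbind(g[, cols], nd[, cols])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
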