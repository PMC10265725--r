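#' Assemble an FA-weighted connectivity matrix from fibre assignments
#'
#' Each reconstructed fibre is assigned to an unordered pair of parcellation
#' regions together with its mean fractional anisotropy (FA). The edge weight
#' of a region pair is the arithmetic mean FA over all fibres assigned to that
#' pair; pairs with no fibres get weight 0. The result is a symmetric,
#' zero-diagonal adjacency matrix.
#'
#' @param fibres data.frame with columns `fibre_id`, `node_i`, `node_j`
#'   (1-based region indices) and `mean_fa` (FA in \[0,1\]). May have zero rows.
#' @param n_nodes Number of parcellation regions (default 90).
#' @param labels Optional node labels; defaults to [aal90_labels()] when
#'   `n_nodes == 90`, else `"N1"..`.
#' @param scan_id Optional scan identifier stored as an attribute.
#' @return A `connectivity_matrix`: numeric `n_nodes x n_nodes` matrix with
#'   attributes `scan_id`, `hemisphere`, and dimnames set to region labels.
#' @export
assemble_matrix <- function(fibres, n_nodes = 90L,
                            labels = NULL, scan_id = NA_character_) {
  if (is.null(labels)) {
    labels <- if (n_nodes == 90L) aal90_labels() else paste0("N", seq_len(n_nodes))
  }
  stopifnot(length(labels) == n_nodes)
  w <- matrix(0, n_nodes, n_nodes, dimnames = list(labels, labels))
  if (nrow(fibres) > 0L) {
    need <- c("node_i", "node_j", "mean_fa")
    if (!all(need %in% names(fibres)))
      stop("fibre table must have columns node_i, node_j, mean_fa")
    i <- as.integer(fibres$node_i)
    j <- as.integer(fibres$node_j)
    fa <- as.numeric(fibres$mean_fa)
    if (any(i < 1L | i > n_nodes | j < 1L | j > n_nodes))
      stop("fibre node index out of range 1..", n_nodes)
    if (any(i == j))
      stop("self-loop fibre assignment (node_i == node_j) is not allowed")
    if (any(fa < 0 | fa > 1))
      stop("mean_fa outside [0, 1]")
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- (lo - 1L) * n_nodes + hi
    sums <- tapply(fa, key, sum)
    cnts <- tapply(fa, key, length)
    kk <- as.integer(names(sums))
    li <- (kk - 1L) %/% n_nodes + 1L
    hj <- (kk - 1L) %% n_nodes + 1L
    mean_fa <- as.numeric(sums) / as.numeric(cnts)
    w[cbind(li, hj)] <- mean_fa
    w[cbind(hj, li)] <- mean_fa
  }
  new_connectivity_matrix(w, scan_id = scan_id)
}

new_connectivity_matrix <- function(w, scan_id = NA_character_) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  attr(w, "scan_id") <- scan_id
  attr(w, "hemisphere") <- aal90_hemispheres(nrow(w))
  class(w) <- c("connectivity_matrix", class(w))
  w
}

#' Validate a connectivity matrix
#'
#' Checks the invariants a per-scan FA adjacency matrix must satisfy:
#' square, symmetric, zero diagonal, weights in \[0,1\].
#'
#' @param w Numeric matrix.
#' @param tol Symmetry tolerance.
#' @return Invisibly `TRUE`; signals an error describing the first violation.
#' @export
validate_matrix <- function(w, tol = 1e-8) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop("matrix must be square")
  if (any(abs(diag(w)) > tol)) stop("diagonal must be zero")
  if (max(abs(w - t(w))) > tol) stop("matrix must be symmetric")
  if (any(w < -tol) || any(w > 1 + tol)) stop("weights must lie in [0, 1]")
  invisible(TRUE)
}

#' Test whether a weighted graph is fully connected
#'
#' A scan's network is fully connected when the graph whose edges are the
#' strictly positive weights has a single connected component spanning all
#' nodes. Scans failing this are excluded from analysis.
#'
#' @param w Connectivity matrix.
#' @return `TRUE`/`FALSE`.
#' @export
is_fully_connected <- function(w) {
  n <- nrow(w)
  if (n == 0L) return(FALSE)
  adj <- w > 0
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Partition scans by the fully-connected filter
#'
#' @param matrices Named list of connectivity matrices (names = scan ids; a
#'   `scan_id` attribute is used when names are absent).
#' @return List with `kept` (list of matrices) and `excluded` (data.frame
#'   `scan_id`, `reason`). The partition is exhaustive.
#' @export
filter_scans <- function(matrices) {
  ids <- names(matrices)
  if (is.null(ids)) {
    ids <- vapply(matrices, function(m) {
      s <- attr(m, "scan_id"); if (is.null(s)) NA_character_ else s
    }, character(1))
  }
  ok <- vapply(matrices, is_fully_connected, logical(1))
  excluded <- data.frame(
    scan_id = ids[!ok],
    reason = rep("not fully connected", sum(!ok)),
    stringsAsFactors = FALSE
  )
  list(kept = matrices[ok], excluded = excluded)
}

#' Read a fibre assignment table
#'
#' CSV with columns `fibre_id,node_i,node_j,mean_fa`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_fibre_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fibre_id", "node_i", "node_j", "mean_fa")
  if (!all(need %in% names(df)))
    stop("fibre table must have columns ", paste(need, collapse = ","))
  df
}

#' Read / write a plain-text adjacency matrix
#'
#' Matrices are stored as whitespace-delimited text, one row per line
#' (90 lines for AAL-90).
#'
#' @param path File path.
#' @param scan_id Scan identifier to attach on read.
#' @return `read_matrix_txt`: a `connectivity_matrix`.
#' @export
read_matrix_txt <- function(path, scan_id = sub("\\.txt$", "", basename(path))) {
  w <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(w) <- NULL
  n <- nrow(w)
  labels <- if (n == 90L) aal90_labels() else paste0("N", seq_len(n))
  dimnames(w) <- list(labels, labels)
  new_connectivity_matrix(w, scan_id = scan_id)
}

#' @rdname read_matrix_txt
#' @param w Connectivity matrix to write.
#' @export
write_matrix_txt <- function(w, path) {
  utils::write.table(format(unclass(w), digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
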