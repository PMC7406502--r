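#' Edge index table for an undirected graph on n nodes
#'
#' All unordered node pairs (i < j) in upper-triangle, row-major order:
#' (1,2), (1,3), ..., (1,n), (2,3), ... This ordering is the package-wide
#' edge-vectorization convention; every subjects-by-edges matrix uses it.
#'
#' @param n_nodes number of nodes (>= 2)
#' @return data.frame with integer columns `i`, `j` (1-based node ids, i < j)
#'   and `n_nodes(n_nodes-1)/2` rows
#' @export
edge_index <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2L) stop("edge_index: n_nodes must be >= 2")
  i <- rep.int(seq_len(n_nodes - 1L), (n_nodes - 1L):1L)
  j <- sequence((n_nodes - 1L):1L) + i
  data.frame(i = i, j = as.integer(j))
}

#' Extract the edge vector of a symmetric matrix
#'
#' @param m square symmetric matrix
#' @return numeric vector in [edge_index()] order
#' @export
matrix_to_edges <- function(m) {
  idx <- edge_index(nrow(m))
  m[cbind(idx$i, idx$j)]
}

#' Rebuild a symmetric matrix (zero diagonal) from an edge vector
#'
#' @param v edge vector in [edge_index()] order
#' @param n_nodes number of nodes
#' @return n_nodes x n_nodes symmetric matrix with zero diagonal
#' @export
edges_to_matrix <- function(v, n_nodes) {
  idx <- edge_index(n_nodes)
  if (length(v) != nrow(idx)) {
    stop("edges_to_matrix: length(v) != n_nodes*(n_nodes-1)/2")
  }
  m <- matrix(0, n_nodes, n_nodes)
  m[cbind(idx$i, idx$j)] <- v
  m[cbind(idx$j, idx$i)] <- v
  m
}

#' Fisher z transform of correlations with clamping
#'
#' atanh with |r| clamped to 1 - 1e-7 so degenerate (perfectly correlated)
#' pairs stay finite.
#'
#' @param r correlations
#' @param clamp clamp on |r| (default `1 - 1e-7`)
#' @return Fisher z values
#' @export
fisher_z <- function(r, clamp = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clamp), clamp))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. seed = NULL leaves the stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible 32-bit sub-seed from a master seed and a stream index.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9973L) %% 2147483629L
}

# Truncated-normal draws by rejection (narrow truncation bands only).
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}
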