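# Shared fixtures and independent oracles for the test-suite.

# small atlas used across tests (4 networks, 12 cortical + 2 subcortical)
tiny_atlas <- function() {
  make_atlas(12, c("L_thal", "R_thal"), c("A", "B", "C", "D"), seed = 42)
}

# a minimal run_timeseries with controllable pieces
make_run <- function(data, tr = 2.5, motion = NULL, task = NULL,
                     nuisance = NULL, fd = NULL, subject = "S1",
                     session = "baseline", run_id = "run1") {
  tt <- ncol(data)
  if (is.null(motion)) motion <- matrix(rnorm(6 * tt, 0, 0.01), 6, tt)
  if (is.null(task)) task <- matrix(numeric(0), 0, tt)
  if (is.null(nuisance)) nuisance <- matrix(numeric(0), 0, tt)
  if (is.null(fd)) fd <- c(0, abs(rnorm(tt - 1, 0, 0.05)))
  nbsconn:::new_run_timeseries(subject, session, run_id, data, tr,
                               motion, task, nuisance, fd)
}

# independent union-find (path compression) component oracle on an edge list
union_find_components <- function(i, j) {
  nodes <- sort(unique(c(i, j)))
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(i)) {
    a <- find(match(i[e], nodes))
    b <- find(match(j[e], nodes))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  # return edge partition: list of sorted edge-index vectors, largest first
  edge_root <- roots[match(i, nodes)]
  parts <- split(seq_along(i), edge_root)
  parts <- lapply(parts, sort)
  parts[order(-lengths(parts),
              vapply(parts, function(p) min(c(i[p], j[p])), numeric(1)))]
}

# brute-force BH step-up by definition: find the largest k with
# p_(k) <= k q / m, reject exactly those k smallest p-values; adjusted
# p-values by the running-minimum definition.
brute_force_bh <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- seq_len(m) * q / m
  k <- suppressWarnings(max(which(ps <= thresh)))
  reject_sorted <- rep(FALSE, m)
  if (is.finite(k)) reject_sorted[seq_len(k)] <- TRUE
  adj_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  reject <- logical(m)
  reject[o] <- reject_sorted
  list(adjusted = adjusted, reject = reject)
}

# two vectors with exact sample correlation r (length n)
exact_corr_pair <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  e <- resid(lm(e ~ x))
  e <- e / sd(e)
  y <- r * x + sqrt(1 - r^2) * e
  list(x = x, y = y)
}
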