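#' Assemble a subjects-by-edges matrix from connectomes
#'
#' @param connectomes list of `connectome` objects (one session per subject)
#' @return matrix (subjects x edges) in [edge_index()] order, rownames =
#'   subject ids
#' @export
connectomes_to_edge_matrix <- function(connectomes) {
  if (!length(connectomes)) stop("connectomes_to_edge_matrix: empty list")
  mats <- lapply(connectomes, function(cn) matrix_to_edges(cn$z_matrix))
  out <- do.call(rbind, mats)
  rownames(out) <- vapply(connectomes, function(cn) cn$subject_id, character(1))
  out
}

# column-standardize; zero-variance columns become all-zero (flagged)
standardize_cols <- function(x) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  s <- sqrt(colSums(xc^2) / (nrow(x) - 1L))
  flat <- s == 0
  s[flat] <- 1
  out <- sweep(xc, 2L, s, "/")
  attr(out, "flat") <- flat
  out
}

r_to_p <- function(r, n, tail) {
  df <- n - 2L
  tstat <- r * sqrt(df / pmax(1 - r^2, 1e-15))
  p <- switch(tail,
    two_sided = 2 * stats::pt(-abs(tstat), df),
    negative = stats::pt(tstat, df),
    positive = stats::pt(tstat, df, lower.tail = FALSE)
  )
  pmin(pmax(p, .Machine$double.xmin), 1)
}

t_to_p <- function(tstat, df, tail) {
  p <- switch(tail,
    two_sided = 2 * stats::pt(-abs(tstat), df),
    negative = stats::pt(tstat, df),
    positive = stats::pt(tstat, df, lower.tail = FALSE)
  )
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Edgewise association statistics
#'
#' For `kind = "correlation"`: Pearson r of each edge with a continuous
#' outcome, with p-values from the exact t transform
#' `t = r * sqrt((n-2)/(1-r^2))` on n-2 df. For `kind = "two_sample_t"`:
#' pooled-variance two-sample t (first group level minus second) on n-2 df.
#' Zero-variance edges get statistic 0 and p = 1 (never suprathreshold).
#'
#' @param edge_matrix subjects x edges matrix (see
#'   [connectomes_to_edge_matrix()])
#' @param outcome numeric outcome (correlation) or a 2-level grouping
#'   (two_sample_t)
#' @param kind `"correlation"` or `"two_sample_t"`
#' @param tail `"two_sided"`, `"negative"` or `"positive"`
#' @return an `edge_statistics` list: `statistic`, `p_value`, `tail`, `kind`,
#'   `n_subjects`, `edges` (the [edge_index()] table when the edge count is
#'   triangular, otherwise positional)
#' @export
edgewise_statistic <- function(edge_matrix, outcome,
                               kind = c("correlation", "two_sample_t"),
                               tail = c("two_sided", "negative", "positive")) {
  kind <- match.arg(kind)
  tail <- match.arg(tail)
  n <- nrow(edge_matrix)
  if (n < 4L) stop("edgewise_statistic: need >= 4 subjects")
  es <- standardize_cols(edge_matrix)
  flat <- attr(es, "flat")
  if (kind == "correlation") {
    outcome <- as.numeric(outcome)
    if (length(outcome) != n) stop("edgewise_statistic: outcome length mismatch")
    if (stats::var(outcome) == 0) {
      stop("edgewise_statistic: outcome has zero variance")
    }
    ys <- (outcome - mean(outcome)) / (stats::sd(outcome))
    r <- as.numeric(crossprod(es, ys)) / (n - 1L)
    r[flat] <- 0
    p <- r_to_p(r, n, tail)
    p[flat] <- 1
    statistic <- r
  } else {
    g <- as.factor(outcome)
    if (nlevels(g) != 2L) stop("edgewise_statistic: need exactly 2 groups")
    n1 <- sum(g == levels(g)[1L])
    n2 <- n - n1
    if (min(n1, n2) < 2L) stop("edgewise_statistic: need >= 2 per group")
    m1 <- colMeans(edge_matrix[g == levels(g)[1L], , drop = FALSE])
    m2 <- colMeans(edge_matrix[g == levels(g)[2L], , drop = FALSE])
    ss <- colSums(edge_matrix^2) - n1 * m1^2 - n2 * m2^2
    sp <- sqrt(pmax(ss, 0) / (n - 2L))
    denom <- sp * sqrt(1 / n1 + 1 / n2)
    tstat <- ifelse(denom > 0, (m1 - m2) / denom, 0)
    p <- t_to_p(tstat, n - 2L, tail)
    p[flat | denom == 0] <- 1
    tstat[flat | denom == 0] <- 0
    statistic <- tstat
  }
  n_edges <- ncol(edge_matrix)
  nn <- (1 + sqrt(1 + 8 * n_edges)) / 2
  edges <- if (nn == round(nn)) edge_index(as.integer(nn)) else {
    stop("edgewise_statistic: edge count is not n*(n-1)/2 for integer n")
  }
  structure(list(statistic = statistic, p_value = p, tail = tail, kind = kind,
                 n_subjects = n, edges = edges),
            class = "edge_statistics")
}

#' Connected components of the suprathreshold graph
#'
#' Edges with `p < threshold_p` form a graph; its connected components are
#' returned sorted by edge count ("extent"), descending (ties broken by
#' smallest node id). One-sided tails are already encoded in the p-values,
#' so sign selection is implicit.
#'
#' @param stats an `edge_statistics` object
#' @param threshold_p component-forming p threshold (default 0.001)
#' @return list of components, each a list with `edges` (indices into the
#'   edge vector), `nodes` (node ids), and `n_edges`; empty list if no edge
#'   is suprathreshold
#' @export
form_components <- function(stats, threshold_p = 0.001) {
  stopifnot(threshold_p > 0, threshold_p < 1)
  supra <- which(stats$p_value < threshold_p)
  component_partition(stats$edges$i[supra], stats$edges$j[supra], supra)
}

# Shared component machinery: given suprathreshold endpoints and their edge
# indices, return components sorted by extent.
component_partition <- function(i, j, edge_ids) {
  if (!length(edge_ids)) return(list())
  verts <- sort(unique(c(i, j)))
  g <- igraph::graph_from_edgelist(cbind(match(i, verts), match(j, verts)),
                                   directed = FALSE)
  comp <- igraph::components(g)
  membership_edge <- comp$membership[match(i, verts)]
  out <- lapply(seq_len(comp$no), function(k) {
    sel <- membership_edge == k
    list(edges = edge_ids[sel],
         nodes = verts[comp$membership == k],
         n_edges = sum(sel))
  })
  sizes <- vapply(out, `[[`, integer(1), "n_edges")
  firsts <- vapply(out, function(cm) min(cm$nodes), numeric(1))
  out[order(-sizes, firsts)]
}

# max component edge count given suprathreshold endpoints (0 if none)
max_component_size <- function(i, j) {
  if (!length(i)) return(0L)
  verts <- unique(c(i, j))
  g <- igraph::graph_from_edgelist(cbind(match(i, verts), match(j, verts)),
                                   directed = FALSE)
  comp <- igraph::components(g)
  max(tabulate(comp$membership[match(i, verts)], comp$no))
}

# critical |r| (or signed r) corresponding to an edgewise p threshold
critical_r <- function(threshold_p, n, tail) {
  df <- n - 2L
  tcrit <- switch(tail,
    two_sided = stats::qt(1 - threshold_p / 2, df),
    stats::qt(1 - threshold_p, df)
  )
  tcrit / sqrt(df + tcrit^2)
}

#' Network-based statistic with a permutation max-component null
#'
#' Thresholds edgewise statistics at `threshold_p`, finds connected
#' components among suprathreshold edges, and assesses each observed
#' component's extent (edge count) against the null distribution of the
#' maximal component extent over `n_perm` random shuffles of the outcome
#' (or group labels). The familywise-corrected p-value of a component of
#' size s is `(1 + #{permutation max >= s}) / (1 + n_perm)` (ties count
#' toward the null; the corrected p is never exactly 0).
#'
#' With `covariates`, both outcome and edges are first residualized on the
#' covariates (plus intercept) and the residualized outcome is permuted
#' (Freedman-Lane style).
#'
#' @inheritParams edgewise_statistic
#' @param threshold_p component-forming edgewise p threshold (default 0.001)
#' @param n_perm number of permutations (default 5000)
#' @param alpha componentwise familywise significance level (default 0.05)
#' @param seed integer seed for the permutation stream
#' @param covariates optional numeric matrix/data.frame (subjects x k)
#' @return an `nbs_result`: `components` (each with `edges`, `nodes`,
#'   `n_edges`, `corrected_p`), `component_sizes`, `corrected_p`,
#'   `null_max_sizes`, `significant_edges` (data.frame `i`,`j`, union over
#'   components with corrected p < alpha), `stats`, and the call parameters
#' @export
nbs <- function(edge_matrix, outcome,
                kind = c("correlation", "two_sample_t"),
                threshold_p = 0.001, n_perm = 5000L, alpha = 0.05,
                tail = c("two_sided", "negative", "positive"),
                seed = 1L, covariates = NULL) {
  kind <- match.arg(kind)
  tail <- match.arg(tail)
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) {
    warning("nbs: n_perm < 100 gives a very coarse corrected-p resolution")
  }
  n <- nrow(edge_matrix)

  if (!is.null(covariates)) {
    cv <- cbind(1, as.matrix(covariates))
    resid_on <- function(y) stats::lm.fit(cv, y)$residuals
    edge_matrix <- resid_on(edge_matrix)
    if (kind == "correlation") outcome <- resid_on(as.numeric(outcome))
    # group labels are never residualized; covariates for the two-sample
    # kind only adjust the edges
  }

  obs_stats <- edgewise_statistic(edge_matrix, outcome, kind, tail)
  components <- form_components(obs_stats, threshold_p)
  obs_sizes <- vapply(components, `[[`, integer(1), "n_edges")

  es <- standardize_cols(edge_matrix)
  flat <- attr(es, "flat")
  ei <- obs_stats$edges

  null_max <- with_seed(seed, {
    if (kind == "correlation") {
      y <- as.numeric(outcome)
      perms <- vapply(seq_len(n_perm), function(k) sample(y), numeric(n))
      ps <- standardize_cols(perms)
      rmat <- crossprod(es, ps) / (n - 1L)      # edges x n_perm
      rmat[flat, ] <- 0
      rc <- critical_r(threshold_p, n, tail)
      vapply(seq_len(n_perm), function(k) {
        supra <- switch(tail,
          two_sided = which(abs(rmat[, k]) > rc),
          negative = which(rmat[, k] < -rc),
          positive = which(rmat[, k] > rc)
        )
        max_component_size(ei$i[supra], ei$j[supra])
      }, integer(1))
    } else {
      g <- as.factor(outcome)
      lev <- levels(g)
      n1 <- sum(g == lev[1L])
      n2 <- n - n1
      sstot <- colSums(edge_matrix^2)
      stot <- colSums(edge_matrix)
      df <- n - 2L
      tcrit <- switch(tail,
        two_sided = stats::qt(1 - threshold_p / 2, df),
        stats::qt(1 - threshold_p, df)
      )
      vapply(seq_len(n_perm), function(k) {
        g1 <- sample.int(n, n1)
        s1 <- colSums(edge_matrix[g1, , drop = FALSE])
        m1 <- s1 / n1
        m2 <- (stot - s1) / n2
        sp <- sqrt(pmax(sstot - n1 * m1^2 - n2 * m2^2, 0) / df)
        denom <- sp * sqrt(1 / n1 + 1 / n2)
        tstat <- ifelse(denom > 0, (m1 - m2) / denom, 0)
        supra <- switch(tail,
          two_sided = which(abs(tstat) > tcrit),
          negative = which(tstat < -tcrit),
          positive = which(tstat > tcrit)
        )
        max_component_size(ei$i[supra], ei$j[supra])
      }, integer(1))
    }
  })

  corrected_p <- vapply(obs_sizes, function(s) {
    (1 + sum(null_max >= s)) / (1 + n_perm)
  }, numeric(1))
  for (k in seq_along(components)) components[[k]]$corrected_p <- corrected_p[k]

  sig <- which(corrected_p < alpha)
  sig_edges <- if (length(sig)) {
    eidx <- sort(unique(unlist(lapply(components[sig], `[[`, "edges"))))
    data.frame(i = ei$i[eidx], j = ei$j[eidx], edge = eidx)
  } else {
    data.frame(i = integer(), j = integer(), edge = integer())
  }

  structure(list(components = components,
                 component_sizes = obs_sizes,
                 corrected_p = corrected_p,
                 null_max_sizes = null_max,
                 significant_edges = sig_edges,
                 stats = obs_stats,
                 threshold_p = threshold_p, n_perm = n_perm, alpha = alpha,
                 tail = tail, kind = kind, seed = seed),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %s, tail %s, threshold p<%g, %d permutations\n",
              x$kind, x$tail, x$threshold_p, x$n_perm))
  if (!length(x$components)) {
    cat("  no suprathreshold components\n")
  } else {
    for (k in seq_along(x$components)) {
      cm <- x$components[[k]]
      cat(sprintf("  component %d: %d edges over %d nodes, corrected p = %.4g%s\n",
                  k, cm$n_edges, length(cm$nodes), cm$corrected_p,
                  if (cm$corrected_p < x$alpha) " *" else ""))
    }
  }
  invisible(x)
}

#' Jaccard overlap between two edge sets
#'
#' @param a,b data.frames with columns `i`, `j` (unordered pairs, i < j)
#' @return |intersection| / |union|
#' @export
edge_jaccard <- function(a, b) {
  ka <- paste(pmin(a$i, a$j), pmax(a$i, a$j))
  kb <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  length(intersect(ka, kb)) / length(union(ka, kb))
}
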