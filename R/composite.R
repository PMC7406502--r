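#' Per-subject composite connectivity metric over an edge set
#'
#' The unweighted mean Fisher-z over the edges of an identified subnetwork,
#' one scalar per subject.
#'
#' @param connectomes list of `connectome` objects, or a subjects x edges
#'   matrix in [edge_index()] order
#' @param edge_set data.frame with node columns `i`, `j`
#' @param n_nodes node count (required when `connectomes` is a matrix whose
#'   edge columns must be indexed; inferred from `connectome` objects)
#' @return named numeric vector (one value per subject)
#' @export
composite_metric <- function(connectomes, edge_set, n_nodes = NULL) {
  if (!nrow(edge_set)) stop("composite_metric: empty edge set")
  if (is.matrix(connectomes)) {
    if (is.null(n_nodes)) {
      nn <- (1 + sqrt(1 + 8 * ncol(connectomes))) / 2
      if (nn != round(nn)) stop("composite_metric: supply n_nodes")
      n_nodes <- as.integer(nn)
    }
    idx <- edge_index(n_nodes)
    if (any(edge_set$i < 1) || any(edge_set$j > n_nodes)) {
      stop("composite_metric: edge references an unknown node")
    }
    lin <- match(paste(pmin(edge_set$i, edge_set$j),
                       pmax(edge_set$i, edge_set$j)),
                 paste(idx$i, idx$j))
    if (anyNA(lin)) stop("composite_metric: edge references an unknown node")
    return(rowMeans(connectomes[, lin, drop = FALSE]))
  }
  vapply(connectomes, function(cn) {
    nn <- nrow(cn$z_matrix)
    if (any(edge_set$i < 1) || any(edge_set$j > nn) || any(edge_set$i == edge_set$j)) {
      stop("composite_metric: edge references an unknown node")
    }
    mean(cn$z_matrix[cbind(edge_set$i, edge_set$j)])
  }, numeric(1))
}

#' Per-subject network-pair mean connectivity
#'
#' Groups the edges of a subnetwork by the unordered pair of intrinsic
#' networks of their endpoints and returns the per-pair unweighted mean z
#' per subject. The edge-count-weighted mean across pairs reconstructs the
#' composite metric exactly.
#'
#' @inheritParams composite_metric
#' @param atlas a `parcel_atlas` covering all nodes in `edge_set`
#' @return list with `pairs` (data.frame: `pair`, `edge_count`) and `values`
#'   (subjects x pairs matrix of mean z)
#' @export
network_pair_means <- function(connectomes, atlas, edge_set, n_nodes = NULL) {
  if (!nrow(edge_set)) stop("network_pair_means: empty edge set")
  labels <- network_pair_labels(atlas, edge_set)
  pair_levels <- sort(unique(labels))
  values <- vapply(pair_levels, function(pl) {
    composite_metric(connectomes, edge_set[labels == pl, , drop = FALSE],
                     n_nodes = n_nodes %||% nrow(atlas))
  }, numeric(if (is.matrix(connectomes)) nrow(connectomes) else length(connectomes)))
  values <- matrix(values, ncol = length(pair_levels),
                   dimnames = list(NULL, pair_levels))
  list(pairs = data.frame(pair = pair_levels,
                          edge_count = as.integer(table(labels)[pair_levels])),
       values = values)
}

#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' @param p_values raw p-values in (0, 1]
#' @param q FDR level (default 0.05)
#' @return list with `adjusted` (BH-adjusted p-values) and `reject`
#'   (`adjusted <= q`); empty input gives empty output
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(list(adjusted = numeric(), reject = logical()))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("bh_fdr: p-values must lie in (0, 1]")
  }
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Baseline group comparisons of a connectivity measure
#'
#' One-way ANOVA comparing the pooled patient group (responders plus
#' nonresponders) against controls, then pairwise Welch contrasts:
#' responders vs controls, nonresponders vs controls, responders vs
#' nonresponders. Contrasts with a group below 2 members are skipped with a
#' warning. P-values are raw; FDR adjustment across measures is the
#' caller's responsibility (see [bh_fdr()]).
#'
#' @param values per-subject scalar (e.g. a composite metric)
#' @param groups factor/character with levels among
#'   `c("responder", "nonresponder", "control")`
#' @return data.frame: `contrast`, `estimate` (mean difference, first-named
#'   group minus second), `statistic` (F or Welch t), `df`, `p`
#' @export
baseline_group_tests <- function(values, groups) {
  groups <- as.character(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- groups[ok]
  bad <- setdiff(unique(groups), c("responder", "nonresponder", "control"))
  if (length(bad)) stop("baseline_group_tests: unknown group(s): ",
                        paste(bad, collapse = ", "))
  rows <- list()
  ptsd <- groups %in% c("responder", "nonresponder")
  if (sum(ptsd) >= 2L && sum(!ptsd) >= 2L) {
    g2 <- factor(ifelse(ptsd, "PTSD", "control"), c("PTSD", "control"))
    a <- stats::anova(stats::aov(values ~ g2))
    rows$ptsd <- data.frame(
      contrast = "PTSD_vs_control",
      estimate = mean(values[ptsd]) - mean(values[!ptsd]),
      statistic = a[["F value"]][1L], df = a[["Df"]][1L], p = a[["Pr(>F)"]][1L])
  }
  pairwise <- list(c("responder", "control"), c("nonresponder", "control"),
                   c("responder", "nonresponder"))
  for (pr in pairwise) {
    x <- values[groups == pr[1L]]
    y <- values[groups == pr[2L]]
    if (length(x) < 2L || length(y) < 2L) {
      warning("baseline_group_tests: skipping ", pr[1L], "_vs_", pr[2L],
              " (a group has < 2 members)")
      next
    }
    tt <- stats::t.test(x, y)
    rows[[paste(pr, collapse = "_vs_")]] <- data.frame(
      contrast = paste(pr, collapse = "_vs_"),
      estimate = mean(x) - mean(y),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Mixed between-within (group x time) ANOVA with post hoc contrasts
#'
#' Repeated-measures ANOVA with time (pre vs post) as the within-subject
#' factor and group as the between-subject factor, via
#' `aov(value ~ group * time + Error(subject))`. Subjects missing either
#' time point are excluded listwise (with a message). When the interaction
#' is significant at `alpha`, post hoc contrasts are computed: paired t
#' (pre vs post) within each group and Welch t between groups at each time,
#' BH-FDR adjusted. With a single group the model reduces to the paired
#' t-test on time.
#'
#' @param values_pre,values_post per-subject scalars (NA = missing)
#' @param groups group labels, one per subject
#' @param alpha significance gate for running post hoc contrasts
#' @return list with `anova` (data.frame: effect, df, F, p) and `posthoc`
#'   (data.frame or NULL)
#' @export
group_by_time_anova <- function(values_pre, values_post, groups, alpha = 0.05) {
  groups <- as.character(groups)
  keep <- !is.na(values_pre) & !is.na(values_post) & !is.na(groups)
  if (any(!keep)) {
    message("group_by_time_anova: excluding ", sum(!keep),
            " subject(s) without both time points")
  }
  pre <- values_pre[keep]
  post <- values_post[keep]
  grp <- factor(groups[keep])
  ns <- length(pre)
  if (ns < 3L) stop("group_by_time_anova: too few complete subjects")
  long <- data.frame(
    value = c(pre, post),
    time = factor(rep(c("pre", "post"), each = ns), c("pre", "post")),
    group = factor(rep(grp, 2L)),
    subject = factor(rep(seq_len(ns), 2L))
  )
  one_group <- nlevels(grp) < 2L
  form <- if (one_group) value ~ time + Error(subject) else
    value ~ group * time + Error(subject)
  fit <- stats::aov(form, data = long)
  s <- summary(fit)
  # collect effect rows across error strata
  tab <- do.call(rbind, lapply(s, function(stratum) {
    d <- as.data.frame(stratum[[1L]])
    d$effect <- trimws(rownames(stratum[[1L]]))
    d
  }))
  tab <- tab[tab$effect != "Residuals", , drop = FALSE]
  anova_tab <- data.frame(effect = tab$effect, df = tab$Df,
                          ss = tab$`Sum Sq`,
                          F = tab$`F value`, p = tab$`Pr(>F)`,
                          row.names = NULL)
  # an effect whose sum of squares is zero (to machine precision relative to
  # the data's total variation) carries no evidence, even when the error
  # stratum is equally degenerate (0/0): report F = 0, p = 1
  tol <- 1e-12 * sum((long$value - mean(long$value))^2)
  degen <- anova_tab$ss <= tol
  anova_tab$F[degen] <- 0
  anova_tab$p[degen] <- 1
  interaction_p <- if (one_group) NA_real_ else
    anova_tab$p[anova_tab$effect == "group:time"]

  posthoc <- NULL
  gate <- if (one_group) anova_tab$p[anova_tab$effect == "time"] else interaction_p
  if (is.finite(gate) && gate < alpha) {
    rows <- list()
    for (g in levels(grp)) {
      selg <- grp == g
      if (sum(selg) < 2L) next
      tt <- stats::t.test(post[selg], pre[selg], paired = TRUE)
      rows[[paste0("within_", g)]] <- data.frame(
        contrast = paste0(g, ": post_vs_pre"),
        estimate = mean(post[selg] - pre[selg]),
        statistic = unname(tt$statistic), p = tt$p.value)
    }
    if (!one_group) {
      gl <- levels(grp)
      for (tp in c("pre", "post")) {
        v <- if (tp == "pre") pre else post
        combos <- utils::combn(gl, 2L, simplify = FALSE)
        for (pr in combos) {
          x <- v[grp == pr[1L]]
          y <- v[grp == pr[2L]]
          if (length(x) < 2L || length(y) < 2L) next
          tt <- stats::t.test(x, y)
          rows[[paste0(tp, "_", pr[1L], "_", pr[2L])]] <- data.frame(
            contrast = paste0(tp, ": ", pr[1L], "_vs_", pr[2L]),
            estimate = mean(x) - mean(y),
            statistic = unname(tt$statistic), p = tt$p.value)
        }
      }
    }
    posthoc <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    fdr <- bh_fdr(posthoc$p)
    posthoc$p_adjusted <- fdr$adjusted
    posthoc$significant <- fdr$reject
  }
  list(anova = anova_tab, posthoc = posthoc)
}

#' Covariate-adjusted association (partial correlation)
#'
#' Partial Pearson correlation of `x` and `y` controlling for `covariates`:
#' both variables are residualized on the covariates (plus intercept), the
#' residuals are correlated, and the t-test uses `n - 2 - k` df.
#'
#' @param x,y numeric vectors
#' @param covariates numeric matrix/data.frame (subjects x k)
#' @return list with `estimate` (partial r), `statistic`, `df`, `p`
#' @export
adjusted_association <- function(x, y, covariates) {
  cv <- cbind(1, as.matrix(covariates))
  k <- ncol(cv) - 1L
  n <- length(x)
  if (n != length(y) || n != nrow(cv)) stop("adjusted_association: length mismatch")
  rx <- stats::lm.fit(cv, x)$residuals
  ry <- stats::lm.fit(cv, y)$residuals
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  if (df < 1L) stop("adjusted_association: not enough residual df")
  tstat <- r * sqrt(df / (1 - r^2))
  list(estimate = r, statistic = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df))
}
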