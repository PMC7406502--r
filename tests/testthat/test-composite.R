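random_connectomes <- function(n_sub, n_nodes, seed) {
  set.seed(seed)
  lapply(seq_len(n_sub), function(s) {
    nbsconn:::new_connectome(
      edges_to_matrix(rnorm(n_nodes * (n_nodes - 1) / 2), n_nodes),
      sprintf("S%02d", s), "baseline", "test")
  })
}

test_that("composite metric is the plain mean over listed edges", {
  conns <- random_connectomes(6, 10, seed = 1)
  one_edge <- data.frame(i = 3L, j = 7L)
  cm <- composite_metric(conns, one_edge)
  expect_equal(cm, vapply(conns, function(cn) cn$z_matrix[3, 7], numeric(1)))

  set.seed(2)
  idx <- edge_index(10)
  edge_set <- idx[sample(nrow(idx), 10), ]
  cm10 <- composite_metric(conns, edge_set)
  brute <- vapply(conns, function(cn) {
    mean(vapply(seq_len(10), function(k) {
      cn$z_matrix[edge_set$i[k], edge_set$j[k]]
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cm10, brute, tolerance = 1e-12)

  # linearity: doubling z doubles the composite
  conns2 <- lapply(conns, function(cn) { cn$z_matrix <- 2 * cn$z_matrix; cn })
  expect_equal(composite_metric(conns2, edge_set), 2 * cm10, tolerance = 1e-12)

  expect_error(composite_metric(conns, data.frame(i = 1L, j = 99L)), "unknown")
  expect_error(composite_metric(conns, idx[0, ]), "empty")
})

test_that("matrix and connectome-list inputs agree", {
  conns <- random_connectomes(5, 8, seed = 3)
  em <- connectomes_to_edge_matrix(conns)
  edge_set <- data.frame(i = c(1L, 2L, 5L), j = c(4L, 3L, 8L))
  expect_equal(unname(composite_metric(em, edge_set, n_nodes = 8)),
               unname(composite_metric(conns, edge_set)))
})

test_that("network-pair means reconstruct the composite exactly", {
  atlas <- tiny_atlas()
  conns <- random_connectomes(7, nrow(atlas), seed = 4)
  set.seed(5)
  idx <- edge_index(nrow(atlas))
  edge_set <- idx[sample(nrow(idx), 20), ]
  npm <- network_pair_means(conns, atlas, edge_set)
  expect_equal(sum(npm$pairs$edge_count), nrow(edge_set))
  w <- npm$pairs$edge_count / sum(npm$pairs$edge_count)
  recon <- as.numeric(npm$values %*% w)
  expect_equal(recon, unname(composite_metric(conns, edge_set)),
               tolerance = 1e-10)
})

test_that("edges within one network collapse to a single pair", {
  atlas <- tiny_atlas()
  in_a <- which(atlas$network == "A")
  edge_set <- data.frame(i = in_a[1], j = in_a[2])
  npm <- network_pair_means(random_connectomes(3, nrow(atlas), 6), atlas, edge_set)
  expect_equal(nrow(npm$pairs), 1)
  expect_equal(npm$pairs$pair, "A--A")
})

test_that("baseline group tests behave at the null and match F = t^2", {
  vals <- rep(c(0.1, 0.5, -0.2, 0.3), 9)  # identical distribution per group
  groups <- rep(c("responder", "nonresponder", "control"), each = 12)
  tab <- baseline_group_tests(vals, groups)
  aov_row <- tab[tab$contrast == "PTSD_vs_control", ]
  expect_lt(aov_row$statistic, 1e-20)
  expect_gt(aov_row$p, 0.999)

  set.seed(7)
  vals2 <- rnorm(36)
  tab2 <- baseline_group_tests(vals2, groups)
  ptsd <- groups != "control"
  tt <- t.test(vals2[ptsd], vals2[!ptsd], var.equal = TRUE)
  expect_equal(tab2$statistic[tab2$contrast == "PTSD_vs_control"],
               unname(tt$statistic)^2, tolerance = 1e-8)
})

test_that("groups shifted by a standard deviation are detected at the analytic power", {
  # oracle: noncentral-t power of the Welch contrast at d = 1, sigma = 1
  welch_power <- function(n1, n2, d = 1, alpha = 0.05) {
    se <- sqrt(1 / n1 + 1 / n2)
    df <- se^4 / ((1 / n1)^2 / (n1 - 1) + (1 / n2)^2 / (n2 - 1))
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp = d / se, lower.tail = FALSE) +
      pt(-crit, df, ncp = d / se)
  }
  hits <- t(vapply(1:100, function(seed) {
    set.seed(seed)
    vals <- c(rnorm(25, -1), rnorm(11, 1), rnorm(36, 0))
    groups <- rep(c("responder", "nonresponder", "control"), c(25, 11, 36))
    tab <- baseline_group_tests(vals, groups)
    c(resp = tab$p[tab$contrast == "responder_vs_control"] < 0.05,
      nonresp = tab$p[tab$contrast == "nonresponder_vs_control"] < 0.05)
  }, logical(2)))
  expect_lt(abs(mean(hits[, "resp"]) - welch_power(25, 36)), 0.12)
  expect_lt(abs(mean(hits[, "nonresp"]) - welch_power(11, 36)), 0.12)
  expect_gte(mean(hits[, "resp"]), 0.9)
})

test_that("contrasts with undersized groups are skipped with a warning", {
  vals <- rnorm(10)
  groups <- c(rep("responder", 5), "nonresponder", rep("control", 4))
  warns <- testthat::capture_warnings(tab <- baseline_group_tests(vals, groups))
  expect_match(warns, "skipping", all = TRUE)
  expect_length(warns, 2)  # both contrasts involving the singleton group
  expect_false("nonresponder_vs_control" %in% tab$contrast)
})

test_that("group-by-time ANOVA is null when nothing changes", {
  set.seed(8)
  pre <- rnorm(30)
  groups <- rep(c("responder", "nonresponder", "control"), each = 10)
  out <- group_by_time_anova(pre, pre, groups)
  expect_equal(out$anova$p[out$anova$effect == "group:time"], 1)
  expect_equal(out$anova$p[out$anova$effect == "time"], 1)
  expect_null(out$posthoc)
})

test_that("mixed ANOVA matches a hand sums-of-squares oracle on a balanced design", {
  # 6 subjects, 2 groups x 2 times
  pre <- c(1.0, 1.2, 0.8, 2.0, 2.2, 1.9)
  post <- c(1.5, 1.9, 1.4, 1.1, 0.9, 1.3)
  groups <- rep(c("g1", "g2"), each = 3)
  out <- group_by_time_anova(pre, post, groups, alpha = 1)

  y <- cbind(pre, post)
  n <- 6; a <- 2
  grand <- mean(y)
  subj_mean <- rowMeans(y)
  grp_mean <- tapply(subj_mean, groups, mean)
  time_mean <- colMeans(y)
  cell_mean <- rbind(colMeans(y[1:3, ]), colMeans(y[4:6, ]))
  ss_group <- 2 * 3 * sum((grp_mean - grand)^2)
  ss_subj_within <- 2 * sum((subj_mean - grp_mean[rep(1:2, each = 3)])^2)
  ss_time <- n * sum((time_mean - grand)^2)
  ss_cells <- 3 * sum((cell_mean - grand)^2)
  ss_interaction <- ss_cells - ss_group - ss_time
  ss_total <- sum((y - grand)^2)
  ss_resid <- ss_total - ss_group - ss_subj_within - ss_time - ss_interaction
  f_int <- (ss_interaction / 1) / (ss_resid / (n - a))
  p_int <- pf(f_int, 1, n - a, lower.tail = FALSE)

  got <- out$anova[out$anova$effect == "group:time", ]
  expect_equal(got$F, f_int, tolerance = 1e-8)
  expect_equal(got$p, p_int, tolerance = 1e-8)
  f_grp <- (ss_group / 1) / (ss_subj_within / (n - a))
  expect_equal(out$anova$F[out$anova$effect == "group"], f_grp,
               tolerance = 1e-8)
})

test_that("a single group reduces the model to the paired t-test", {
  set.seed(9)
  pre <- rnorm(12)
  post <- pre + rnorm(12, 0.4, 0.5)
  out <- group_by_time_anova(pre, post, rep("responder", 12))
  tt <- t.test(post, pre, paired = TRUE)
  expect_equal(out$anova$p[out$anova$effect == "time"], tt$p.value,
               tolerance = 1e-6)
})

test_that("crossover interactions produce directional post hoc contrasts", {
  set.seed(10)
  pre <- c(rnorm(10, -1, 0.3), rnorm(10, 1, 0.3), rnorm(10, 0, 0.3))
  post <- c(rnorm(10, 0, 0.3), rnorm(10, 0, 0.3), rnorm(10, 0, 0.3))
  groups <- rep(c("responder", "nonresponder", "control"), each = 10)
  out <- group_by_time_anova(pre, post, groups)
  expect_lt(out$anova$p[out$anova$effect == "group:time"], 0.05)
  ph <- out$posthoc
  expect_gt(ph$estimate[ph$contrast == "responder: post_vs_pre"], 0)
  expect_lt(ph$estimate[ph$contrast == "nonresponder: post_vs_pre"], 0)
})

test_that("subjects missing a time point are excluded listwise", {
  set.seed(11)
  pre <- rnorm(20)
  post <- pre + 1
  post[3] <- NA
  groups <- rep(c("responder", "control"), each = 10)
  expect_message(out <- group_by_time_anova(pre, post, groups), "excluding 1")
  expect_equal(sum(out$anova$df[out$anova$effect == "group"]), 1)
})

test_that("bh_fdr matches the hand-executed step-up on the worked example", {
  res <- bh_fdr(c(0.001, 0.02, 0.03, 0.8), q = 0.05)
  expect_equal(res$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$adjusted, c(0.004, 0.04, 0.04, 0.8), tolerance = 1e-12)
  expect_equal(bh_fdr(rep(1, 5))$reject, rep(FALSE, 5))
  expect_true(bh_fdr(0.04, q = 0.05)$reject)
  expect_length(bh_fdr(numeric())$adjusted, 0)
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("bh_fdr agrees with a brute-force step-up over random vectors", {
  set.seed(12)
  for (k in 1:200) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    got <- bh_fdr(p)
    oracle <- brute_force_bh(p)
    expect_equal(got$adjusted, oracle$adjusted, tolerance = 1e-12)
    expect_equal(got$reject, oracle$reject)
  }
})

test_that("adjusted association recovers a partial correlation with correct df", {
  set.seed(13)
  n <- 40
  z <- rnorm(n)
  x <- z + rnorm(n, sd = 0.5)
  y <- -x + 2 * z + rnorm(n, sd = 0.5)
  out <- adjusted_association(x, y, cbind(z))
  # oracle: correlation of lm residuals, t on n - 3 df
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  r <- cor(rx, ry)
  tstat <- r * sqrt((n - 3) / (1 - r^2))
  expect_equal(out$estimate, r, tolerance = 1e-12)
  expect_equal(out$df, n - 3)
  expect_equal(out$p, 2 * pt(-abs(tstat), n - 3), tolerance = 1e-12)
  expect_lt(out$estimate, 0)
})
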