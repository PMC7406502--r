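test_that("censor mask retains clean frames and flags motion-contaminated ones", {
  tt <- 50
  data <- matrix(1, 5, tt)  # constant data: DVARS degenerate, all retained
  m <- compute_censor_mask(rep(0, tt), data)
  expect_true(all(m$retained))
  expect_true(m$usable)

  set.seed(1)
  data <- matrix(rnorm(5 * tt), 5, tt)
  fd <- rep(0.1, tt); fd[1] <- 0; fd[20] <- 5  # 10x the 0.5 mm threshold
  m <- compute_censor_mask(fd, data, dvars_threshold = 999)
  expect_equal(which(!m$retained), 20L)
})

test_that("unusable runs (too few retained frames) are flagged", {
  tt <- 40
  fd <- c(0, rep(10, tt - 1))
  expect_warning(m <- compute_censor_mask(fd, matrix(rnorm(5 * tt), 5, tt)),
                 "unusable")
  expect_false(m$usable)
})

test_that("nuisance design has the documented column structure", {
  set.seed(2)
  tt <- 60
  run <- make_run(matrix(rnorm(10 * tt), 10, tt),
                  motion = matrix(rnorm(6 * tt, 0, 0.01), 6, tt))
  mask <- compute_censor_mask(run$fd_trace, run$data, dvars_threshold = 999)
  x <- build_nuisance_design(run, mask)
  # intercept + drift + Friston-24 (6 params, lags, squares of both)
  expect_equal(ncol(x), 2 + 24)

  # censored frames contribute one spike column each, with a single 1
  fd <- run$fd_trace; fd[c(10, 20, 30)] <- 5
  run2 <- make_run(run$data, motion = run$motion_params, fd = fd)
  mask2 <- compute_censor_mask(run2$fd_trace, run2$data, dvars_threshold = 999)
  x2 <- build_nuisance_design(run2, mask2)
  spikes <- x2[, startsWith(colnames(x2), "spike_"), drop = FALSE]
  expect_equal(ncol(spikes), 3)
  expect_equal(colSums(spikes), c(spike_t10 = 1, spike_t20 = 1, spike_t30 = 1))
  expect_equal(unname(which(spikes == 1, arr.ind = TRUE)[, 1]), c(10, 20, 30))

  # constant motion parameters drop out as zero-variance
  run3 <- make_run(run$data, motion = matrix(0.3, 6, tt))
  x3 <- build_nuisance_design(run3, mask)
  expect_false(any(startsWith(colnames(x3), "mot")))
})

test_that("denoising removes the design space exactly", {
  set.seed(3)
  tt <- 80
  run <- make_run(matrix(rnorm(6 * tt), 6, tt))
  mask <- compute_censor_mask(run$fd_trace, run$data, dvars_threshold = 999)
  x <- build_nuisance_design(run, mask)

  # data lying in the design span has ~zero residuals
  coefs <- matrix(rnorm(ncol(x) * 4), ncol(x), 4)
  lindata <- t(x %*% coefs)
  res <- denoise(lindata, x)
  expect_lt(max(abs(res)), 1e-8 * max(abs(lindata)))

  # intercept-only design mean-centers
  res2 <- denoise(run$data, matrix(1, tt, 1))
  expect_equal(res2, run$data - rowMeans(run$data), tolerance = 1e-12)

  # residuals orthogonal to every design column
  res3 <- denoise(run, x)
  inner <- abs(res3 %*% x)
  norms <- outer(sqrt(rowSums(res3^2)), sqrt(colSums(x^2)))
  expect_lt(max(inner / norms), 1e-8)

  expect_error(denoise(matrix(c(1, NA), 1, 2), matrix(1, 2, 1)), "non-finite")
})

test_that("rank-deficient designs warn but still project correctly", {
  set.seed(4)
  tt <- 40
  x <- cbind(1, seq_len(tt), seq_len(tt) * 2)  # collinear
  data <- matrix(rnorm(3 * tt), 3, tt)
  expect_warning(res <- denoise(data, x), "rank-deficient")
  expect_lt(max(abs(res %*% x[, 1:2])) / max(abs(res)), 1e-6)
})

test_that("band-pass filter has the specified frequency response at TR 2.5 s", {
  tr <- 2.5
  tt <- 480
  tsec <- (seq_len(tt) - 1) * tr
  amp_ratio <- function(f) {
    x <- sin(2 * pi * f * tsec)
    y <- bandpass(x, tr)
    mid <- seq(tt * 0.25, tt * 0.75)
    fit_in <- lm(x[mid] ~ sin(2 * pi * f * tsec[mid]) + cos(2 * pi * f * tsec[mid]))
    fit_out <- lm(y[mid] ~ sin(2 * pi * f * tsec[mid]) + cos(2 * pi * f * tsec[mid]))
    sqrt(sum(coef(fit_out)[-1]^2)) / sqrt(sum(coef(fit_in)[-1]^2))
  }
  dc <- bandpass(rep(1, tt), tr)
  expect_lt(max(abs(dc)), 0.01)
  expect_gt(amp_ratio(0.03), 0.9)
  expect_lt(amp_ratio(0.19), 0.1)
  expect_error(bandpass(rnorm(tt), tr, high_hz = 0.3), "Nyquist")
})

test_that("connectome construction clamps, transforms, and zeroes correctly", {
  atlas <- make_atlas(4, character(), c("A", "B"), seed = 1)
  tt <- 200
  pair <- exact_corr_pair(0.5, tt, seed = 5)
  set.seed(6)
  data <- rbind(pair$x, pair$y, pair$x, rnorm(tt))  # rows 1 & 3 identical
  mask <- compute_censor_mask(rep(0, tt), data, dvars_threshold = 999)
  cn <- compute_connectome(list(data), list(mask), atlas, "S1")
  expect_equal(cn$z_matrix[1, 3], atanh(1 - 1e-7))      # clamped
  expect_equal(cn$z_matrix[1, 2], atanh(0.5), tolerance = 1e-4)
  expect_equal(cn$n_retained_frames, tt)

  # zero-variance node: edges set to 0 with a warning
  data0 <- data
  data0[4, ] <- 7
  expect_warning(cn0 <- compute_connectome(list(data0), list(mask), atlas, "S1"),
                 "zero-variance")
  expect_equal(cn0$z_matrix[4, ], rep(0, 4))
})

test_that("independent white-noise nodes give near-zero z at T = 500", {
  set.seed(7)
  atlas <- make_atlas(6, character(), c("A", "B"), seed = 1)
  data <- matrix(rnorm(6 * 500), 6, 500)
  mask <- compute_censor_mask(rep(0, 500), data, dvars_threshold = 999)
  cn <- compute_connectome(list(data), list(mask), atlas, "S1")
  expect_lt(mean(abs(cn$z_matrix[upper.tri(cn$z_matrix)])), 0.1)
})

test_that("the connectome is invariant to per-node scaling", {
  set.seed(8)
  atlas <- make_atlas(5, character(), c("A"), seed = 1)
  data <- matrix(rnorm(5 * 150), 5, 150)
  mask <- compute_censor_mask(rep(0, 150), data, dvars_threshold = 999)
  cn1 <- compute_connectome(list(data), list(mask), atlas, "S1")
  cn2 <- compute_connectome(list(data * 37.5), list(mask), atlas, "S1")
  expect_equal(cn1$z_matrix, cn2$z_matrix, tolerance = 1e-12)
})

test_that("censored frames have zero influence on the correlation", {
  set.seed(9)
  atlas <- make_atlas(5, character(), c("A", "B"), seed = 1)
  tt <- 120
  data <- matrix(rnorm(5 * tt), 5, tt)
  retained <- rep(TRUE, tt)
  retained[c(3, 40, 41, 100)] <- FALSE
  mask <- structure(list(retained = retained, usable = TRUE,
                         fd_threshold = 0.5, dvars_threshold = 1.5),
                    class = "censor_mask")
  mask_all <- structure(list(retained = rep(TRUE, sum(retained)), usable = TRUE,
                             fd_threshold = 0.5, dvars_threshold = 1.5),
                        class = "censor_mask")
  cn_masked <- compute_connectome(list(data), list(mask), atlas, "S1")
  cn_deleted <- compute_connectome(list(data[, retained]), list(mask_all),
                                   atlas, "S1")
  expect_identical(cn_masked$z_matrix, cn_deleted$z_matrix)
})

test_that("unusable runs are dropped from concatenation with a warning", {
  set.seed(10)
  atlas <- make_atlas(4, character(), c("A", "B"), seed = 1)
  tt <- 60
  good <- matrix(rnorm(4 * tt), 4, tt)
  bad <- matrix(rnorm(4 * tt), 4, tt)
  mgood <- compute_censor_mask(rep(0, tt), good, dvars_threshold = 999)
  mbad <- suppressWarnings(
    compute_censor_mask(c(0, rep(9, tt - 1)), bad, dvars_threshold = 999))
  expect_warning(
    cn <- compute_connectome(list(good, bad), list(mgood, mbad), atlas, "S1"),
    "unusable")
  expect_equal(cn$n_retained_frames, tt)
})
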