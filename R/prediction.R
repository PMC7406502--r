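# L2-penalized logistic regression via iteratively reweighted least squares.
# The intercept is unpenalized; lambda is a fixed, weak ridge penalty that
# keeps coefficients finite under separation and near-collinearity.
# Deterministic; no random initialization.
ridge_logistic <- function(x, y, lambda = 1, maxit = 200L, tol = 1e-9) {
  x <- as.matrix(x)
  n <- nrow(x)
  xd <- cbind(intercept = 1, x)
  p <- ncol(xd)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(xd * w)
    beta_new <- solve(xtw %*% xd + pen, xtw %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

predict_ridge_logistic <- function(beta, x) {
  stats::plogis(drop(cbind(1, as.matrix(x)) %*% beta))
}

#' Leave-one-out cross-validated treatment-response prediction
#'
#' For each subject, an L2-regularized logistic model is trained on the
#' remaining n-1 subjects and the held-out subject is predicted at a 0.5
#' probability cutoff. Features are standardized with training-fold means
#' and SDs only (zero-variance training features are left unscaled), so no
#' information from the held-out subject leaks into its own fold. Training
#' folds containing a single class predict that majority class (with a
#' warning).
#'
#' @param features data.frame or matrix (subjects x features); non-numeric
#'   columns are converted via `model.matrix`-style dummy coding
#' @param labels logical vector (TRUE = responder)
#' @param lambda ridge penalty of the logistic model (default 1)
#' @param seed recorded in the result for provenance (the fit itself is
#'   deterministic)
#' @return a `prediction_result`: `predicted` (logical), `probability`,
#'   `labels`, `accuracy`, `sensitivity`, `specificity` (percentages, one
#'   decimal), `feature_names`, `lambda`, `seed`
#' @export
loocv_predict <- function(features, labels, lambda = 1, seed = NULL) {
  x <- to_numeric_matrix(features)
  y <- as.logical(labels)
  n <- nrow(x)
  if (n < 6L) stop("loocv_predict: need >= 6 subjects")
  if (length(y) != n) stop("loocv_predict: labels length mismatch")
  if (length(unique(y)) < 2L) stop("loocv_predict: both classes required")
  prob <- numeric(n)
  for (holdout in seq_len(n)) {
    xt <- x[-holdout, , drop = FALSE]
    yt <- y[-holdout]
    if (length(unique(yt)) < 2L) {
      warning("loocv_predict: one-class training fold; predicting majority class")
      prob[holdout] <- mean(yt)
      next
    }
    mu <- colMeans(xt)
    sdv <- apply(xt, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    xs <- sweep(sweep(xt, 2L, mu), 2L, sdv, "/")
    beta <- ridge_logistic(xs, yt, lambda = lambda)
    xh <- (x[holdout, ] - mu) / sdv
    prob[holdout] <- predict_ridge_logistic(beta, matrix(xh, nrow = 1L))
  }
  predicted <- prob >= 0.5
  metrics <- confusion_metrics(predicted, y)
  structure(c(list(predicted = predicted, probability = prob, labels = y,
                   feature_names = colnames(x), lambda = lambda, seed = seed),
              metrics),
            class = "prediction_result")
}

to_numeric_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  features <- as.data.frame(features)
  cols <- lapply(names(features), function(nm) {
    col <- features[[nm]]
    if (is.numeric(col)) {
      out <- matrix(col, dimnames = list(NULL, nm))
    } else {
      f <- as.factor(col)
      out <- matrix(as.numeric(f == levels(f)[-1L][1L]),
                    dimnames = list(NULL, paste0(nm, "_", levels(f)[2L])))
      if (nlevels(f) > 2L) {
        out <- do.call(cbind, lapply(levels(f)[-1L], function(lv) {
          matrix(as.numeric(f == lv), dimnames = list(NULL, paste0(nm, "_", lv)))
        }))
      }
    }
    out
  })
  do.call(cbind, cols)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(paste0("<prediction_result> %d folds | accuracy %.1f%%, ",
                     "sensitivity %.1f%%, specificity %.1f%%\n"),
              length(x$predicted), x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Confusion-matrix summary of a binary prediction
#'
#' Sensitivity is the true-positive rate on the responder (TRUE) class,
#' specificity the true-negative rate. Percentages are reported to one
#' decimal. A class absent from the true labels makes the corresponding
#' rate `NA`.
#'
#' @param predicted,truth logical vectors of equal, nonzero length
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent)
#' @export
confusion_metrics <- function(predicted, truth) {
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  if (!length(truth) || length(predicted) != length(truth)) {
    stop("confusion_metrics: inputs must be nonempty and of equal length")
  }
  acc <- 100 * mean(predicted == truth)
  sens <- if (any(truth)) 100 * mean(predicted[truth]) else NA_real_
  spec <- if (any(!truth)) 100 * mean(!predicted[!truth]) else NA_real_
  list(accuracy = round(acc, 1), sensitivity = round(sens, 1),
       specificity = round(spec, 1))
}

#' Paired permutation comparison of two cross-validated models
#'
#' Tests whether the augmented model's per-subject correctness differs from
#' the base model's, by randomly swapping the two models' correctness
#' indicators within subjects (a paired sign-flip null). Two-sided p with
#' the plus-one convention; identical correctness vectors give p = 1.
#'
#' @param base,augmented `prediction_result` objects on the same subjects
#' @param n_perm number of permutations (default 10000)
#' @param seed integer seed
#' @return list with `p`, `observed_diff` (augmented minus base accuracy,
#'   proportion scale), `n_discordant`
#' @export
compare_models <- function(base, augmented, n_perm = 10000L, seed = 1L) {
  if (!identical(base$labels, augmented$labels)) {
    stop("compare_models: models must share subjects and true labels")
  }
  cb <- base$predicted == base$labels
  ca <- augmented$predicted == augmented$labels
  n <- length(cb)
  obs <- mean(ca) - mean(cb)
  discordant <- which(ca != cb)
  p <- with_seed(seed, {
    exceed <- vapply(seq_len(n_perm), function(k) {
      flip <- stats::runif(n) < 0.5
      d <- ifelse(flip, cb - ca, ca - cb)
      abs(mean(d)) >= abs(obs) - 1e-12
    }, logical(1))
    (1 + sum(exceed)) / (1 + n_perm)
  })
  list(p = p, observed_diff = obs, n_discordant = length(discordant))
}
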