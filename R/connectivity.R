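#' Motion/intensity censor mask for one run
#'
#' A frame is retained iff its framewise displacement (FD) is at or below
#' `fd_threshold` and its median-normalized DVARS (frame-to-frame RMS signal
#' change) is at or below `dvars_threshold`. DVARS is undefined for the first
#' frame, which is therefore judged on FD alone (and FD is defined as 0
#' there). A run keeping fewer than `max(5, 0.1 * n_timepoints)` frames is
#' flagged unusable.
#'
#' @param fd_trace nonnegative FD vector (mm), first element 0
#' @param data node-by-time matrix used for DVARS
#' @param fd_threshold FD censoring threshold in mm (default 0.5)
#' @param dvars_threshold DVARS threshold in median-normalized units
#'   (default 1.5)
#' @return a `censor_mask`: list with `retained` (logical vector), `usable`,
#'   and the thresholds used
#' @export
compute_censor_mask <- function(fd_trace, data, fd_threshold = 0.5,
                                dvars_threshold = 1.5) {
  stopifnot(fd_threshold > 0, dvars_threshold > 0)
  tt <- length(fd_trace)
  if (ncol(data) != tt) stop("compute_censor_mask: fd_trace/data length mismatch")
  if (any(!is.finite(fd_trace)) || any(fd_trace < 0)) {
    stop("compute_censor_mask: fd_trace must be finite and nonnegative")
  }
  d <- diff(t(data))                       # (tt-1) x nodes
  dvars <- c(0, sqrt(rowMeans(d^2)))
  med <- stats::median(dvars[-1L])
  dvars_norm <- if (med > 0) dvars / med else rep(0, tt)
  dvars_norm[1L] <- 0                      # undefined -> retained on FD alone
  retained <- fd_trace <= fd_threshold & dvars_norm <= dvars_threshold
  usable <- sum(retained) >= max(5, 0.1 * tt)
  if (!usable) {
    warning("compute_censor_mask: run unusable (", sum(retained), "/", tt,
            " frames retained)")
  }
  structure(list(retained = retained, usable = usable,
                 fd_threshold = fd_threshold,
                 dvars_threshold = dvars_threshold),
            class = "censor_mask")
}

# Friston-24 expansion: [R, R(t-1), R^2, R(t-1)^2]; the lag is padded by
# repeating the first frame so a constant parameter stays constant.
friston24 <- function(motion) {
  r <- t(motion)                                   # time x 6
  rlag <- rbind(r[1L, , drop = FALSE], r[-nrow(r), , drop = FALSE])
  out <- cbind(r, rlag, r^2, rlag^2)
  colnames(out) <- c(sprintf("mot%d", 1:6), sprintf("mot%d_lag", 1:6),
                     sprintf("mot%d_sq", 1:6), sprintf("mot%d_lagsq", 1:6))
  out
}

#' Nuisance design matrix for one run
#'
#' Columns: intercept, linear drift, task covariates, the Volterra
#' (Friston-24) expansion of the six realignment parameters, any additional
#' nuisance signals (e.g. white-matter and ventricle means), and one spike
#' indicator per censored frame. Columns with zero variance over the retained
#' frames (other than the intercept) are dropped.
#'
#' @param run a `run_timeseries`
#' @param mask a `censor_mask` aligned with the run
#' @return design matrix (time x columns) with informative column names
#' @export
build_nuisance_design <- function(run, mask) {
  tt <- ncol(run$data)
  if (length(mask$retained) != tt) stop("build_nuisance_design: mask/run mismatch")
  cols <- list(intercept = rep(1, tt),
               drift = seq(-0.5, 0.5, length.out = tt))
  x <- do.call(cbind, cols)
  if (!is.null(run$task_covariates) && nrow(run$task_covariates) > 0) {
    tc <- t(run$task_covariates)
    colnames(tc) <- sprintf("task%d", seq_len(ncol(tc)))
    x <- cbind(x, tc)
  }
  if (!is.null(run$motion_params) && nrow(run$motion_params) > 0) {
    x <- cbind(x, friston24(run$motion_params))
  }
  if (!is.null(run$nuisance_signals) && nrow(run$nuisance_signals) > 0) {
    ns <- t(run$nuisance_signals)
    colnames(ns) <- sprintf("nuis%d", seq_len(ncol(ns)))
    x <- cbind(x, ns)
  }
  censored <- which(!mask$retained)
  if (length(censored)) {
    spikes <- matrix(0, tt, length(censored),
                     dimnames = list(NULL, sprintf("spike_t%d", censored)))
    spikes[cbind(censored, seq_along(censored))] <- 1
    x <- cbind(x, spikes)
  }
  # drop zero-variance columns on retained frames (keep the intercept and
  # the spike columns, whose support is entirely in censored frames)
  keep <- colnames(x) == "intercept" | startsWith(colnames(x), "spike_t")
  v <- apply(x[mask$retained, , drop = FALSE], 2L, stats::var)
  keep <- keep | (!is.na(v) & v > 0)
  x[, keep, drop = FALSE]
}

#' Regress nuisance structure out of node time series
#'
#' Per-node ordinary least squares of the time series on the design;
#' residuals are orthogonal to every design column. Rank-deficient designs
#' are handled by pivoting (a warning is emitted); residuals remain the
#' projection onto the orthogonal complement of the column space.
#'
#' @param run a `run_timeseries` (or a node-by-time matrix)
#' @param design design matrix from [build_nuisance_design()]
#' @return residual node-by-time matrix
#' @export
denoise <- function(run, design) {
  data <- if (inherits(run, "run_timeseries")) run$data else run
  if (any(!is.finite(data)) || any(!is.finite(design))) {
    stop("denoise: non-finite values in data or design")
  }
  if (nrow(design) != ncol(data)) stop("denoise: design/data length mismatch")
  fit <- stats::lm.fit(design, t(data))
  if (fit$rank < ncol(design)) {
    warning("denoise: rank-deficient design (rank ", fit$rank, " of ",
            ncol(design), " columns); proceeding via pivoted least squares")
  }
  t(fit$residuals)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' (`signal::filtfilt`), preserving phase. Defaults pass 0.009-0.08 Hz.
#'
#' @param x node-by-time matrix (or a vector)
#' @param tr_seconds sampling interval in seconds
#' @param low_hz,high_hz pass-band edges in Hz (default 0.009 and 0.08)
#' @param order filter order (default 4)
#' @return filtered matrix of the same shape
#' @export
bandpass <- function(x, tr_seconds, low_hz = 0.009, high_hz = 0.08,
                     order = 4L) {
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("bandpass: need 0 < low_hz < high_hz")
  }
  if (high_hz >= nyquist) {
    stop("bandpass: high_hz (", high_hz, " Hz) must be below the Nyquist ",
         "frequency (", nyquist, " Hz) for TR ", tr_seconds, " s")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  tt <- ncol(x)
  # demean (DC is removed exactly) and reflect-pad both ends so the
  # forward-backward pass has settled initial conditions near the low cutoff
  npad <- min(tt - 1L, ceiling(2 / (low_hz * tr_seconds)))
  out <- t(apply(x, 1L, function(row) {
    row <- row - mean(row)
    padded <- c(2 * row[1L] - rev(row[seq_len(npad) + 1L]),
                row,
                2 * row[tt] - rev(row[tt - seq_len(npad)]))
    signal::filtfilt(bf, padded)[npad + seq_len(tt)]
  }))
  if (vec) out[1L, ] else out
}

#' Correlate denoised runs into one Fisher-z connectome
#'
#' Node series are z-scored per run over the retained frames, retained
#' frames are concatenated across usable runs, Pearson correlations are
#' computed per node pair, and correlations are Fisher z transformed with
#' |r| clamped at `1 - 1e-7`. The diagonal is exactly 0. Zero-variance node
#' series have all their edges set to 0 (with a warning).
#'
#' @param filtered_runs list of node-by-time matrices (denoised + filtered)
#' @param masks list of `censor_mask` objects, parallel to `filtered_runs`
#' @param atlas a `parcel_atlas` (node count must match)
#' @param subject_id,session identifiers carried into the result
#' @return a `connectome`
#' @export
compute_connectome <- function(filtered_runs, masks, atlas,
                               subject_id = "subject", session = "baseline") {
  if (!length(filtered_runs)) stop("compute_connectome: no runs supplied")
  if (length(masks) != length(filtered_runs)) {
    stop("compute_connectome: runs/masks length mismatch")
  }
  usable <- vapply(masks, function(m) isTRUE(m$usable), logical(1))
  if (!any(usable)) stop("compute_connectome: no usable runs")
  if (!all(usable)) {
    warning("compute_connectome: dropping ", sum(!usable), " unusable run(s)")
  }
  nn <- nrow(atlas)
  pieces <- lapply(which(usable), function(k) {
    x <- filtered_runs[[k]][, masks[[k]]$retained, drop = FALSE]
    if (nrow(x) != nn) stop("compute_connectome: run/atlas node-count mismatch")
    mu <- rowMeans(x)
    sdv <- apply(x, 1L, stats::sd)
    sdv[sdv == 0] <- 1               # zero-variance nodes handled below
    (x - mu) / sdv
  })
  concat <- do.call(cbind, pieces)
  n_frames <- ncol(concat)
  sdv <- apply(concat, 1L, stats::sd)
  flat <- which(sdv == 0)
  r <- suppressWarnings(stats::cor(t(concat)))
  if (length(flat)) {
    warning("compute_connectome: ", length(flat),
            " zero-variance node series; their edges set to 0")
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  z <- fisher_z(r)
  diag(z) <- 0
  z[lower.tri(z)] <- t(z)[lower.tri(z)]   # enforce exact symmetry
  new_connectome(z, subject_id, session,
                 atlas_id = attr(atlas, "atlas_id") %||% "atlas",
                 n_retained_frames = n_frames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full per-subject intrinsic-connectivity stage
#'
#' Convenience wrapper chaining censoring, nuisance design, denoising,
#' band-pass filtering, and run concatenation into one connectome.
#'
#' @param runs list of `run_timeseries` for one subject/session
#' @param atlas a `parcel_atlas`
#' @param fd_threshold,dvars_threshold censoring thresholds
#' @param low_hz,high_hz band-pass edges in Hz
#' @return a `connectome`
#' @export
intrinsic_connectome <- function(runs, atlas, fd_threshold = 0.5,
                                 dvars_threshold = 1.5,
                                 low_hz = 0.009, high_hz = 0.08) {
  masks <- lapply(runs, function(r) {
    suppressWarnings(compute_censor_mask(r$fd_trace, r$data,
                                         fd_threshold, dvars_threshold))
  })
  filtered <- mapply(function(r, m) {
    design <- build_nuisance_design(r, m)
    bandpass(denoise(r, design), r$tr_seconds, low_hz, high_hz)
  }, runs, masks, SIMPLIFY = FALSE)
  compute_connectome(filtered, masks, atlas,
                     subject_id = runs[[1L]]$subject_id,
                     session = runs[[1L]]$session)
}
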