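#' Simulation configuration for synthetic treatment-outcome cohorts
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults describe the study design the package targets: 36 patients and
#' 36 controls, two imaging sessions (baseline and post treatment), five
#' runs of 120 frames at TR 2.5 s, a 40-node atlas with six cortical
#' networks plus subcortical nodes, and a 15-edge planted subnetwork whose
#' baseline connectivity is (negatively) linearly related to symptom
#' improvement.
#'
#' @param atlas a `parcel_atlas`; default is a 40-node atlas (36 cortical
#'   nodes over 6 networks + 4 subcortical) built with [make_atlas()]
#' @param n_patients,n_controls group sizes (default 36/36)
#' @param n_timepoints_per_run,n_runs run geometry (default 120 frames, 5 runs)
#' @param tr_seconds repetition time in seconds (default 2.5)
#' @param ar_coefficient AR(1) coefficient of node noise, in `[0,1)`
#' @param within_network_coupling,between_network_coupling target Pearson
#'   correlation between node pairs within / between networks, in `[-1,1]`
#'   with `within >= between >= 0` for the factor construction
#' @param planted_edges data.frame (`i`,`j`) of planted edges; default is a
#'   connected 15-edge subgraph on nodes 1..8
#' @param effect_size slope linking planted-edge mean baseline z to the
#'   improvement fraction (positive = lower connectivity, more improvement)
#' @param noise_sd SD of the improvement-fraction noise
#' @param planted_sd SD of the per-subject planted-connectivity deviation
#'   (a scalar shift applied to all planted edges)
#' @param edge_noise_sd SD of independent per-edge measurement noise in z units
#' @param responder_fraction expected fraction of patients with >= 50%
#'   improvement, in (0,1); default 25/36
#' @param group_time_shift fraction (0..1) by which the planted-edge deviation
#'   moves toward the control mean at the post session (both response groups)
#' @param motion_spike_rate per-frame probability of a motion spike, in `[0,1)`
#' @param seed integer master seed
#' @return a validated `sim_config` list
#' @export
sim_config <- function(atlas = NULL,
                       n_patients = 36L, n_controls = 36L,
                       n_timepoints_per_run = 120L, n_runs = 5L,
                       tr_seconds = 2.5,
                       ar_coefficient = 0.3,
                       within_network_coupling = 0.35,
                       between_network_coupling = 0.10,
                       planted_edges = NULL,
                       effect_size = 1.5,
                       noise_sd = 0.1,
                       planted_sd = 0.15,
                       edge_noise_sd = 0.1,
                       responder_fraction = 25 / 36,
                       group_time_shift = 0.8,
                       motion_spike_rate = 0.05,
                       seed = 1L) {
  if (is.null(atlas)) {
    atlas <- make_atlas(
      36L,
      c("L_caudate", "R_caudate", "L_thalamus", "R_thalamus"),
      c("DMN", "FPN", "CO", "SAL", "DAN", "Visual"),
      seed = 101L
    )
  }
  if (is.null(planted_edges)) planted_edges <- default_planted_edges()
  cfg <- list(
    atlas = validate_atlas(atlas),
    n_nodes = nrow(atlas),
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    n_timepoints_per_run = as.integer(n_timepoints_per_run),
    n_runs = as.integer(n_runs),
    tr_seconds = tr_seconds,
    ar_coefficient = ar_coefficient,
    within_network_coupling = within_network_coupling,
    between_network_coupling = between_network_coupling,
    planted_edges = planted_edges,
    effect_size = effect_size,
    noise_sd = noise_sd,
    planted_sd = planted_sd,
    edge_noise_sd = edge_noise_sd,
    responder_fraction = responder_fraction,
    group_time_shift = group_time_shift,
    motion_spike_rate = motion_spike_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config a `sim_config` candidate
#' @export
validate_sim_config <- function(config) {
  stopifnot(
    config$n_patients >= 1L, config$n_controls >= 1L,
    config$n_timepoints_per_run >= 1L, config$n_runs >= 1L,
    config$tr_seconds > 0,
    config$ar_coefficient >= 0, config$ar_coefficient < 1,
    abs(config$within_network_coupling) <= 1,
    abs(config$between_network_coupling) <= 1,
    config$noise_sd >= 0, config$planted_sd >= 0, config$edge_noise_sd >= 0,
    config$responder_fraction > 0, config$responder_fraction < 1,
    config$motion_spike_rate >= 0, config$motion_spike_rate < 1,
    config$group_time_shift >= 0, config$group_time_shift <= 1
  )
  pe <- config$planted_edges
  if (!is.null(pe) && nrow(pe)) {
    if (any(pe$i >= pe$j)) stop("sim_config: planted_edges must have i < j")
    if (any(pe$j > config$n_nodes) || any(pe$i < 1L)) {
      stop("sim_config: planted edge references a node outside the atlas")
    }
    if (anyDuplicated(paste(pe$i, pe$j))) {
      stop("sim_config: duplicate planted edges")
    }
  }
  structure(config, class = "sim_config")
}

#' Default planted subnetwork: a connected 15-edge subgraph on nodes 1..8
#'
#' A ring over nodes 1..8 plus seven chords; connected by construction, so a
#' successful recovery should return it as a single component.
#'
#' @return data.frame with columns `i`, `j`
#' @export
default_planted_edges <- function() {
  ring <- cbind(1:8, c(2:8, 1))
  chords <- rbind(c(1, 3), c(1, 5), c(2, 6), c(3, 7), c(4, 8), c(2, 5), c(6, 8))
  e <- rbind(ring, chords)
  data.frame(i = as.integer(pmin(e[, 1], e[, 2])),
             j = as.integer(pmax(e[, 1], e[, 2])))
}

# Group-mean z matrix implied by the block (network) structure.
block_mean_matrix <- function(config) {
  nets <- config$atlas$network
  same <- outer(nets, nets, "==")
  m <- matrix(fisher_z(config$between_network_coupling),
              config$n_nodes, config$n_nodes)
  m[same] <- fisher_z(config$within_network_coupling)
  diag(m) <- 0
  m
}

new_connectome <- function(z_matrix, subject_id, session, atlas_id,
                           n_retained_frames = NA_integer_) {
  structure(list(subject_id = subject_id, session = session,
                 z_matrix = z_matrix, atlas_id = atlas_id,
                 n_retained_frames = n_retained_frames),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> subject %s, session %s, %d nodes, atlas '%s'\n",
              x$subject_id, x$session, nrow(x$z_matrix), x$atlas_id))
  invisible(x)
}

#' Simulate a two-session cohort of connectomes with a planted outcome effect
#'
#' Generates symmetric Fisher-z connectomes for patients and controls at a
#' baseline and a post-treatment session, together with a clinical table.
#' Patient improvement is linearly (negatively, for positive `effect_size`)
#' related to the mean baseline z over the planted edges:
#' `improvement = a - effect_size * mean_planted_z + N(0, noise_sd)`,
#' with the intercept `a` chosen so the expected responder fraction matches
#' `config$responder_fraction`. Post-treatment CAPS totals are derived from
#' the improvement fraction; responders follow the inclusive 50% rule. At the
#' post session the planted-edge deviation of every patient shrinks by
#' `group_time_shift` toward the control mean (responders, who start low,
#' move up; nonresponders, who start high, move down); controls get fresh
#' measurement noise but no systematic change.
#'
#' @param config a [sim_config()]
#' @return list with elements `connectomes` (list of `connectome`, two per
#'   subject, named `<subject>_<session>`), `cohort` (clinical data.frame:
#'   subject_id, group, age, sex, dass_*, mdd, ssri, caps_pre, caps_post,
#'   improvement, responder, residual_change), and `planted_edges`
#' @export
simulate_cohort_connectomes <- function(config) {
  config <- validate_sim_config(config)
  with_seed(config$seed, {
    n_pat <- config$n_patients
    n_ctl <- config$n_controls
    n <- n_pat + n_ctl
    nn <- config$n_nodes
    idx <- edge_index(nn)
    m0 <- block_mean_matrix(config)
    pe <- config$planted_edges
    pe_lin <- match(paste(pe$i, pe$j), paste(idx$i, idx$j))
    z0_planted <- mean(m0[cbind(pe$i, pe$j)])
    atlas_id <- sprintf("sim_atlas_%d_nodes", nn)

    subject_id <- c(sprintf("P%03d", seq_len(n_pat)),
                    sprintf("C%03d", seq_len(n_ctl)))
    group <- rep(c("patient", "control"), c(n_pat, n_ctl))
    is_pat <- group == "patient"

    # per-subject planted deviation (patients only)
    delta <- ifelse(is_pat, stats::rnorm(n, 0, config$planted_sd), 0)

    # improvement fraction: intercept calibrated to the responder fraction
    sd_tot <- sqrt(config$effect_size^2 *
                     (config$planted_sd^2 + config$edge_noise_sd^2 / nrow(pe)) +
                     config$noise_sd^2)
    intercept <- 0.5 + stats::qnorm(config$responder_fraction) * sd_tot +
      config$effect_size * z0_planted

    base_edges <- function(subject) {
      v <- matrix_to_edges(m0)
      v[pe_lin] <- v[pe_lin] + delta[subject]
      v + stats::rnorm(length(v), 0, config$edge_noise_sd)
    }
    post_edges <- function(subject) {
      v <- matrix_to_edges(m0)
      v[pe_lin] <- v[pe_lin] + (1 - config$group_time_shift) * delta[subject]
      v + stats::rnorm(length(v), 0, config$edge_noise_sd)
    }

    connectomes <- vector("list", 2L * n)
    nm <- character(2L * n)
    mean_planted_z <- numeric(n)
    for (s in seq_len(n)) {
      vb <- base_edges(s)
      vp <- post_edges(s)
      mean_planted_z[s] <- mean(vb[pe_lin])
      connectomes[[2L * s - 1L]] <- new_connectome(
        edges_to_matrix(vb, nn), subject_id[s], "baseline", atlas_id)
      connectomes[[2L * s]] <- new_connectome(
        edges_to_matrix(vp, nn), subject_id[s], "post", atlas_id)
      nm[2L * s - 1L] <- paste0(subject_id[s], "_baseline")
      nm[2L * s] <- paste0(subject_id[s], "_post")
    }
    names(connectomes) <- nm

    improvement <- rep(NA_real_, n)
    improvement[is_pat] <- intercept -
      config$effect_size * mean_planted_z[is_pat] +
      stats::rnorm(n_pat, 0, config$noise_sd)

    caps_pre <- rep(NA_real_, n)
    caps_pre[is_pat] <- rnorm_trunc(n_pat, 72, 14, 45, 120)
    caps_post <- caps_pre * (1 - improvement)
    caps_max <- 136  # CAPS-total scale ceiling
    if (any(caps_post < 0 | caps_post > caps_max, na.rm = TRUE)) {
      warning("simulate_cohort_connectomes: ",
              sum(caps_post < 0 | caps_post > caps_max, na.rm = TRUE),
              " post-treatment CAPS value(s) clipped to [0, ", caps_max, "]")
      caps_post <- pmin(pmax(caps_post, 0), caps_max)
    }

    cohort <- data.frame(
      subject_id = subject_id,
      group = group,
      age = round(rnorm_trunc(n, 39, 11, 18, 65), 1),
      sex = sample(c("F", "M"), n, replace = TRUE),
      dass_depression = round(pmax(stats::rnorm(n, ifelse(is_pat, 10.9, 3), ifelse(is_pat, 5.5, 2)), 0), 1),
      dass_anxiety = round(pmax(stats::rnorm(n, ifelse(is_pat, 8.1, 2), ifelse(is_pat, 4.4, 1.5)), 0), 1),
      dass_stress = round(pmax(stats::rnorm(n, ifelse(is_pat, 12, 4), ifelse(is_pat, 4.4, 2.5)), 0), 1),
      mdd = is_pat & stats::runif(n) < 19 / 36,
      ssri = is_pat & stats::runif(n) < 10 / 36,
      caps_pre = caps_pre,
      caps_post = caps_post,
      improvement = improvement,
      stringsAsFactors = FALSE
    )
    cohort$responder <- NA
    cohort$responder[is_pat] <- classify_response(caps_pre[is_pat], caps_post[is_pat])
    cohort$residual_change <- NA_real_
    cohort$residual_change[is_pat] <-
      residual_change_scores(caps_pre[is_pat], caps_post[is_pat])

    list(connectomes = connectomes, cohort = cohort,
         planted_edges = pe, atlas = config$atlas)
  })
}

new_run_timeseries <- function(subject_id, session, run_id, data, tr_seconds,
                               motion_params, task_covariates,
                               nuisance_signals, fd_trace) {
  structure(list(subject_id = subject_id, session = session, run_id = run_id,
                 data = data, tr_seconds = tr_seconds,
                 motion_params = motion_params,
                 task_covariates = task_covariates,
                 nuisance_signals = nuisance_signals,
                 fd_trace = fd_trace),
            class = "run_timeseries")
}

#' @export
print.run_timeseries <- function(x, ...) {
  cat(sprintf("<run_timeseries> %s/%s run %s: %d nodes x %d frames (TR %.2fs)\n",
              x$subject_id, x$session, x$run_id, nrow(x$data), ncol(x$data),
              x$tr_seconds))
  invisible(x)
}

# One run: latent network factors + global signal + AR(1) node noise, with
# task contamination, slow drift, and motion spikes.
simulate_one_run <- function(config, subject_id, session, run_id) {
  nn <- config$n_nodes
  tt <- config$n_timepoints_per_run
  phi <- config$ar_coefficient
  w <- config$within_network_coupling
  b <- config$between_network_coupling
  if (w < b || b < 0) {
    stop("simulate_one_run: requires within_network_coupling >= between_network_coupling >= 0")
  }
  alpha <- sqrt(w - b)
  beta <- sqrt(b)
  sig <- sqrt(max(1 - w, 0))

  ar1 <- function(k) {
    e <- matrix(stats::rnorm(k * tt), k, tt)
    if (phi > 0) {
      e <- t(apply(e * sqrt(1 - phi^2), 1L,
                   function(x) stats::filter(x, phi, method = "recursive")))
      e <- matrix(e, k, tt)
    }
    e
  }

  nets <- config$atlas$network
  net_levels <- unique(nets)
  f <- ar1(length(net_levels))            # per-network latent factors
  g <- ar1(1L)                            # global factor
  eps <- ar1(nn)                          # node noise
  data <- alpha * f[match(nets, net_levels), , drop = FALSE] +
    beta * matrix(g, nn, tt, byrow = TRUE) + sig * eps

  # task covariates: two boxcars (blocks of 12 frames, second phase-shifted),
  # smoothed with an exponential kernel to mimic hemodynamic sluggishness
  smooth_reg <- function(x) {
    as.numeric(stats::filter(x * 0.3, 0.7, method = "recursive"))
  }
  block <- rep(rep(c(1, 0), each = 12L), length.out = tt)
  task <- rbind(smooth_reg(block),
                smooth_reg(c(rep(0, 6L), block[seq_len(tt - 6L)])))
  data <- data + outer(stats::rnorm(nn, 0, 0.7), task[1L, ]) +
    outer(stats::rnorm(nn, 0, 0.7), task[2L, ])

  # slow linear drift
  data <- data + outer(stats::rnorm(nn, 0, 1), seq(-0.5, 0.5, length.out = tt))

  # motion: smooth random walks, spikes add bursts to both data and FD
  motion <- t(apply(matrix(stats::rnorm(6L * tt, 0, 0.02), 6L, tt), 1L, cumsum))
  fd <- abs(stats::rnorm(tt, 0, 0.08))
  fd[1L] <- 0
  spikes <- which(stats::runif(tt) < config$motion_spike_rate)
  spikes <- setdiff(spikes, 1L)
  if (length(spikes)) {
    data[, spikes] <- data[, spikes] +
      matrix(stats::rnorm(nn * length(spikes), 0, 4), nn)
    fd[spikes] <- 1.5 + abs(stats::rnorm(length(spikes), 0, 0.5))
    motion[, spikes] <- motion[, spikes] + 0.5
  }

  # nuisance (WM / ventricle-like) signals share the global factor
  nuis <- 0.5 * matrix(g, 2L, tt, byrow = TRUE) + 0.5 * ar1(2L)

  new_run_timeseries(subject_id, session, run_id, data, config$tr_seconds,
                     motion, task, nuis, fd)
}

#' Simulate parcel-level run time series for a cohort
#'
#' Produces the raw input of the intrinsic-connectivity stage: per-run
#' node-by-time matrices built from latent per-network factors, a global
#' factor, and AR(1) node noise, contaminated with boxcar task covariates,
#' slow drift, and motion spikes (bursts in the data co-registered with large
#' framewise-displacement values). The network block structure is recoverable
#' after denoising.
#'
#' @param config a [sim_config()]
#' @param sessions sessions to generate (default baseline only)
#' @param subjects optional subset of subject ids (default: all patients and
#'   controls of the configured cohort)
#' @return list of `run_timeseries` objects
#' @export
simulate_timeseries_cohort <- function(config, sessions = "baseline",
                                       subjects = NULL) {
  config <- validate_sim_config(config)
  if (config$n_timepoints_per_run < 27L) {
    stop("simulate_timeseries_cohort: n_timepoints_per_run too short for ",
         "band-pass filtering (need >= 27 frames, three filter lengths)")
  }
  if (is.null(subjects)) {
    subjects <- c(sprintf("P%03d", seq_len(config$n_patients)),
                  sprintf("C%03d", seq_len(config$n_controls)))
  }
  with_seed(config$seed, {
    runs <- list()
    for (subj in subjects) {
      for (sess in sessions) {
        for (r in seq_len(config$n_runs)) {
          runs[[paste(subj, sess, sprintf("run%d", r), sep = "_")]] <-
            simulate_one_run(config, subj, sess, sprintf("run%d", r))
        }
      }
    }
    runs
  })
}
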