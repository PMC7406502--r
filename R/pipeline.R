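#' End-to-end analysis pipeline
#'
#' Runs the full stepwise analysis on a cohort of two-session connectomes
#' and a clinical table: (1) derived outcome scores (residualized change,
#' responder labels), (2) NBS on baseline patient connectomes against the
#' residual change score (negative and positive tails run separately),
#' (3) composite and network-pair connectivity metrics over the significant
#' edge set, (4) baseline group comparisons (responders / nonresponders /
#' controls) with BH-FDR across measures, (5) group-by-time ANOVA with post
#' hoc contrasts, (6) covariate-adjusted re-test of the association, and
#' (7) LOOCV response prediction with and without the connectivity
#' composite, compared by a paired permutation test.
#'
#' Inputs come either from a simulation config (`sim`) or from caller-
#' provided `connectomes` + `cohort` (+ `atlas`). When `out_dir` is given,
#' every intermediate artifact is written there (TSV/CSV/JSON) together with
#' a `run_log.json` carrying parameters and seeds; rerunning the same
#' config reproduces all outputs.
#'
#' @param sim optional [sim_config()]; when supplied the cohort is simulated
#' @param connectomes,cohort,atlas cohort inputs when `sim` is NULL:
#'   a named list of `connectome`s (`<subject>_<session>`), a clinical
#'   data.frame, and a `parcel_atlas`
#' @param nbs_threshold_p component-forming threshold (default 0.001)
#' @param n_perm NBS permutations (default 5000)
#' @param alpha componentwise significance level (default 0.05)
#' @param tails tails to run (default `c("negative", "positive")`, reported
#'   separately; significant edges are pooled)
#' @param seed master seed for permutation streams
#' @param out_dir optional output directory
#' @return a `pipeline_report` list with elements `cohort`, `nbs` (one
#'   result per tail), `significant_edges`, `composite`, `network_pairs`,
#'   `baseline_tests`, `time_tests`, `adjusted_association`, `prediction`
#' @export
run_pipeline <- function(sim = NULL, connectomes = NULL, cohort = NULL,
                         atlas = NULL,
                         nbs_threshold_p = 0.001, n_perm = 5000L,
                         alpha = 0.05, tails = c("negative", "positive"),
                         seed = 1L, out_dir = NULL) {
  if (!is.null(sim)) {
    simdat <- simulate_cohort_connectomes(sim)
    connectomes <- simdat$connectomes
    cohort <- simdat$cohort
    atlas <- simdat$atlas
  }
  if (is.null(connectomes) || is.null(cohort) || is.null(atlas)) {
    stop("run_pipeline: need either `sim` or all of connectomes/cohort/atlas")
  }
  atlas <- validate_atlas(atlas)
  nn <- nrow(atlas)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- stage 1: clinical scores -------------------------------------------
  cohort <- derive_outcomes(cohort)
  is_pat <- cohort$group == "patient"
  patients <- cohort$subject_id[is_pat]
  controls <- cohort$subject_id[!is_pat]

  pick <- function(subjects, session) {
    keys <- paste0(subjects, "_", session)
    missing <- setdiff(keys, names(connectomes))
    if (length(missing)) {
      stop("run_pipeline: missing connectome(s): ",
           paste(utils::head(missing, 3L), collapse = ", "))
    }
    connectomes[keys]
  }
  edges_baseline_pat <- connectomes_to_edge_matrix(pick(patients, "baseline"))

  # ---- stage 2: NBS on baseline patients vs residual change ---------------
  outcome <- cohort$residual_change[is_pat]
  nbs_results <- lapply(stats::setNames(tails, tails), function(tl) {
    nbs(edges_baseline_pat, outcome, kind = "correlation",
        threshold_p = nbs_threshold_p, n_perm = n_perm, alpha = alpha,
        tail = tl, seed = derive_seed(seed, match(tl, tails)))
  })
  sig_edges <- unique(do.call(rbind, lapply(nbs_results, function(r) {
    r$significant_edges[, c("i", "j"), drop = FALSE]
  })))

  report <- list(cohort = cohort, nbs = nbs_results,
                 significant_edges = sig_edges, atlas = atlas,
                 parameters = list(nbs_threshold_p = nbs_threshold_p,
                                   n_perm = n_perm, alpha = alpha,
                                   tails = tails, seed = seed))
  class(report) <- "pipeline_report"

  if (!nrow(sig_edges)) {
    message("run_pipeline: no significant subnetwork; downstream stages skipped")
    write_pipeline_outputs(report, out_dir)
    return(invisible(report))
  }

  # ---- stage 3: composite and network-pair metrics ------------------------
  all_subjects <- cohort$subject_id
  groups3 <- ifelse(!is_pat, "control",
                    ifelse(cohort$responder, "responder", "nonresponder"))
  comp <- data.frame(
    subject_id = all_subjects, group = groups3,
    baseline = composite_metric(pick(all_subjects, "baseline"), sig_edges),
    post = composite_metric(pick(all_subjects, "post"), sig_edges),
    row.names = NULL)
  npm_base <- network_pair_means(pick(all_subjects, "baseline"), atlas, sig_edges)
  npm_post <- network_pair_means(pick(all_subjects, "post"), atlas, sig_edges)

  measures_base <- cbind(whole_network = comp$baseline, npm_base$values)
  measures_post <- cbind(whole_network = comp$post, npm_post$values)

  # ---- stage 4: baseline group tests with FDR across measures -------------
  baseline_tests <- do.call(rbind, lapply(colnames(measures_base), function(ms) {
    tab <- baseline_group_tests(measures_base[, ms], groups3)
    if (is.null(tab) || !nrow(tab)) return(NULL)
    cbind(measure = ms, tab)
  }))
  if (!is.null(baseline_tests)) {
    baseline_tests$p_adjusted <- NA_real_
    for (ct in unique(baseline_tests$contrast)) {
      sel <- baseline_tests$contrast == ct
      baseline_tests$p_adjusted[sel] <- bh_fdr(baseline_tests$p[sel])$adjusted
    }
  }

  # ---- stage 5: group x time ANOVA per measure ----------------------------
  time_tests <- lapply(stats::setNames(colnames(measures_base),
                                       colnames(measures_base)), function(ms) {
    group_by_time_anova(measures_base[, ms], measures_post[, ms], groups3,
                        alpha = alpha)
  })

  # ---- stage 6: covariate-adjusted association re-test --------------------
  adj <- adjusted_association(
    comp$baseline[is_pat], cohort$residual_change[is_pat],
    cbind(dass_anxiety = cohort$dass_anxiety[is_pat],
          comorbidity = as.numeric(cohort$mdd[is_pat])))

  # ---- stage 7: LOOCV prediction ------------------------------------------
  base_features <- data.frame(
    age = cohort$age[is_pat], sex = cohort$sex[is_pat],
    caps_pre = cohort$caps_pre[is_pat],
    dass_depression = cohort$dass_depression[is_pat],
    dass_anxiety = cohort$dass_anxiety[is_pat],
    dass_stress = cohort$dass_stress[is_pat])
  aug_features <- cbind(base_features, composite = comp$baseline[is_pat])
  labels <- cohort$responder[is_pat]
  pred_base <- loocv_predict(base_features, labels, seed = derive_seed(seed, 11L))
  pred_aug <- loocv_predict(aug_features, labels, seed = derive_seed(seed, 12L))
  model_cmp <- compare_models(pred_base, pred_aug, seed = derive_seed(seed, 13L))

  report$composite <- comp
  report$network_pairs <- npm_base$pairs
  report$baseline_tests <- baseline_tests
  report$time_tests <- time_tests
  report$adjusted_association <- adj
  report$prediction <- list(base = pred_base, augmented = pred_aug,
                            comparison = model_cmp)
  write_pipeline_outputs(report, out_dir)
  invisible(report)
}

write_pipeline_outputs <- function(report, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  write_clinical(report$cohort, file.path(out_dir, "cohort.csv"))
  nbs_summary <- lapply(report$nbs, function(r) {
    list(tail = r$tail, component_sizes = r$component_sizes,
         corrected_p = r$corrected_p, n_perm = r$n_perm, seed = r$seed,
         threshold_p = r$threshold_p)
  })
  sig <- report$significant_edges
  if (nrow(sig)) {
    sig$network_i <- report$atlas$network[sig$i]
    sig$network_j <- report$atlas$network[sig$j]
    utils::write.table(sig, file.path(out_dir, "significant_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$composite)) {
    utils::write.table(report$composite, file.path(out_dir, "composite.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$baseline_tests)) {
    utils::write.table(report$baseline_tests,
                       file.path(out_dir, "baseline_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$time_tests)) {
    anova_rows <- do.call(rbind, lapply(names(report$time_tests), function(ms) {
      cbind(measure = ms, report$time_tests[[ms]]$anova)
    }))
    utils::write.table(anova_rows, file.path(out_dir, "time_anova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log <- list(package_version = as.character(utils::packageVersion("nbsconn")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC"),
              parameters = report$parameters,
              nbs = nbs_summary)
  if (!is.null(report$prediction)) {
    log$prediction <- list(
      accuracy_base = report$prediction$base$accuracy,
      accuracy_augmented = report$prediction$augmented$accuracy,
      comparison_p = report$prediction$comparison$p)
  }
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (tl in names(x$nbs)) {
    r <- x$nbs[[tl]]
    n_sig <- sum(r$corrected_p < r$alpha)
    cat(sprintf("  NBS (%s tail): %d component(s), %d significant\n",
                tl, length(r$components), n_sig))
  }
  cat(sprintf("  significant edge set: %d edges\n", nrow(x$significant_edges)))
  if (!is.null(x$prediction)) {
    cat(sprintf("  LOOCV accuracy: base %.1f%%, augmented %.1f%% (p = %.4g)\n",
                x$prediction$base$accuracy, x$prediction$augmented$accuracy,
                x$prediction$comparison$p))
  }
  invisible(x)
}
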