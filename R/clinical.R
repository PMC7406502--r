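#' Residualized change scores from pre/post symptom totals
#'
#' Fits the least-squares line predicting post-treatment totals from
#' pre-treatment totals and returns the sign-flipped residual
#' (fitted - observed), so that higher scores mean greater improvement
#' independent of initial severity. In-sample scores have exactly zero mean
#' and zero correlation with the pre-treatment scores.
#'
#' @param caps_pre,caps_post pre- and post-treatment totals (>= 3 subjects)
#' @param direction `"post_on_pre"` (default; the residualized-gain
#'   convention) or `"pre_on_post"` (the literal alternative reading:
#'   residualize pre on post and flip the sign so higher still means a
#'   larger pre-to-post drop)
#' @return numeric vector of residual change scores
#' @export
residual_change_scores <- function(caps_pre, caps_post,
                                   direction = c("post_on_pre", "pre_on_post")) {
  direction <- match.arg(direction)
  if (length(caps_pre) != length(caps_post)) {
    stop("residual_change_scores: length mismatch")
  }
  if (length(caps_pre) < 3L) stop("residual_change_scores: need >= 3 subjects")
  if (any(!is.finite(caps_pre)) || any(!is.finite(caps_post))) {
    stop("residual_change_scores: non-finite inputs")
  }
  x <- if (direction == "post_on_pre") caps_pre else caps_post
  y <- if (direction == "post_on_pre") caps_post else caps_pre
  if (stats::var(x) == 0) {
    stop("residual_change_scores: degenerate fit (predictor has zero variance)")
  }
  beta <- stats::cov(x, y) / stats::var(x)
  fitted <- mean(y) + beta * (x - mean(x))
  if (direction == "post_on_pre") fitted - y else y - fitted
}

#' Classify treatment response by the 50% improvement rule
#'
#' Responder iff the pre-to-post reduction is at least half of the
#' pre-treatment total: `(pre - post) / pre >= 0.5` (boundary inclusive).
#'
#' @param caps_pre,caps_post pre- and post-treatment totals; `caps_pre > 0`
#' @return logical vector
#' @examples
#' classify_response(71.9, 17.2)  # TRUE
#' classify_response(72.7, 51.0)  # FALSE
#' @export
classify_response <- function(caps_pre, caps_post) {
  if (any(!is.finite(caps_pre)) || any(!is.finite(caps_post))) {
    stop("classify_response: non-finite inputs")
  }
  if (any(caps_pre <= 0)) {
    stop("classify_response: caps_pre must be > 0 (improvement undefined)")
  }
  (caps_pre - caps_post) / caps_pre >= 0.5
}

#' Append derived outcome columns to a clinical table
#'
#' Computes `residual_change` and `responder` for the patient rows of a
#' cohort table (controls keep NA). Existing derived columns are replaced;
#' raw columns are never overwritten.
#'
#' @param cohort data.frame with `group`, `caps_pre`, `caps_post`
#' @return the cohort with `residual_change` and `responder` columns
#' @export
derive_outcomes <- function(cohort) {
  stopifnot(all(c("group", "caps_pre", "caps_post") %in% names(cohort)))
  is_pat <- cohort$group == "patient" & !is.na(cohort$caps_pre) &
    !is.na(cohort$caps_post)
  cohort$residual_change <- NA_real_
  cohort$responder <- NA
  if (any(is_pat)) {
    cohort$residual_change[is_pat] <-
      residual_change_scores(cohort$caps_pre[is_pat], cohort$caps_post[is_pat])
    cohort$responder[is_pat] <-
      classify_response(cohort$caps_pre[is_pat], cohort$caps_post[is_pat])
  }
  cohort
}

#' Summarize a cohort table
#'
#' Group sizes and the percentages typically reported in a participant
#' characteristics table (responder split, SSRI use, comorbidity), with
#' percentages to one decimal.
#'
#' @param cohort a clinical data.frame (see [derive_outcomes()])
#' @return list with `n_patients`, `n_controls`, `n_responders`,
#'   `n_nonresponders`, `ssri_pct`, `responder_pct`
#' @export
summarize_cohort <- function(cohort) {
  pat <- cohort[cohort$group == "patient", , drop = FALSE]
  n_pat <- nrow(pat)
  pct <- function(k, n) if (n > 0) round(100 * k / n, 1) else NA_real_
  list(
    n_patients = n_pat,
    n_controls = sum(cohort$group == "control"),
    n_responders = sum(pat$responder, na.rm = TRUE),
    n_nonresponders = sum(!pat$responder, na.rm = TRUE),
    ssri_pct = pct(sum(pat$ssri, na.rm = TRUE), n_pat),
    responder_pct = pct(sum(pat$responder, na.rm = TRUE), n_pat)
  )
}
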