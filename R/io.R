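fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a connectome as TSV plus JSON sidecar
#'
#' The TSV holds the square z-matrix with a `node` id column and one column
#' per node id; values are written with 17 significant digits so a
#' write-read-write round trip is bit-identical on the decimal
#' representation. The sidecar (`<path>.json` with the `.tsv` extension
#' replaced) records subject, session, atlas id, and retained-frame count.
#'
#' @param connectome a `connectome`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_connectome <- function(connectome, path) {
  z <- connectome$z_matrix
  check_connectome_matrix(z)
  nn <- nrow(z)
  ids <- sprintf("n%03d", seq_len(nn))
  lines <- c(paste(c("node", ids), collapse = "\t"),
             vapply(seq_len(nn), function(r) {
               paste(c(ids[r], fmt17(z[r, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  sidecar <- sub("\\.tsv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(subject_id = connectome$subject_id, session = connectome$session,
         atlas_id = connectome$atlas_id, n_nodes = nn,
         n_retained_frames = connectome$n_retained_frames),
    sidecar, auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

check_connectome_matrix <- function(z) {
  if (!is.matrix(z) || nrow(z) != ncol(z)) {
    stop("connectome: matrix must be square")
  }
  if (any(is.na(z)) || any(!is.finite(z))) {
    bad <- which(!is.finite(z), arr.ind = TRUE)[1L, ]
    stop("connectome: non-finite value at (", bad[1L], ",", bad[2L], ")")
  }
  if (max(abs(z - t(z))) > 1e-9) {
    stop("connectome: matrix asymmetric beyond 1e-9")
  }
  invisible(z)
}

#' @rdname write_connectome
#' @param atlas optional `parcel_atlas`; the matrix header must then match
#'   the atlas node count
#' @return for `read_connectome`: a `connectome`
#' @export
read_connectome <- function(path, atlas = NULL) {
  if (!file.exists(path)) stop("read_connectome: file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1L] != "node") stop("read_connectome: first column must be 'node'")
  header <- names(tab)[-1L]
  rows <- tab[[1L]]
  z <- as.matrix(tab[, -1L, drop = FALSE])
  if (nrow(z) != ncol(z)) stop("read_connectome: matrix not square")
  if (!identical(header, rows)) {
    bad <- which(header != rows)[1L]
    stop("read_connectome: header/row mismatch at node '", header[bad], "'")
  }
  if (!is.null(atlas) && nrow(atlas) != nrow(z)) {
    stop("read_connectome: matrix has ", nrow(z), " nodes but atlas has ",
         nrow(atlas), "; missing node '",
         if (nrow(atlas) > nrow(z)) atlas$node_name[nrow(z) + 1L] else header[nrow(atlas) + 1L],
         "'")
  }
  storage.mode(z) <- "double"
  dimnames(z) <- NULL
  check_connectome_matrix(z)
  sidecar <- sub("\\.tsv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  new_connectome(z,
                 subject_id = meta$subject_id %||% "unknown",
                 session = meta$session %||% "unknown",
                 atlas_id = meta$atlas_id %||% "atlas",
                 n_retained_frames = meta$n_retained_frames %||% NA_integer_)
}

#' Write / read a clinical cohort table as CSV
#'
#' @param cohort clinical data.frame
#' @param path CSV path
#' @return `path` invisibly; for `read_clinical`, the data.frame with
#'   logical columns (`responder`, `ssri`, `mdd`) restored
#' @export
write_clinical <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("read_clinical: file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(c("responder", "ssri", "mdd"), names(tab))) {
    tab[[nm]] <- as.logical(tab[[nm]])
  }
  tab
}

#' Write / read one run of parcel time series with nuisance companions
#'
#' One directory per run: `data.tsv` (nodes x time), `motion.tsv` (6 x
#' time), `task.tsv`, `nuisance.tsv`, `fd.tsv`, and `meta.json`.
#'
#' @param run a `run_timeseries`
#' @param dir output directory (created if needed)
#' @return `dir` invisibly; for `read_run`, the `run_timeseries`
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, f) {
    utils::write.table(m, file.path(dir, f), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  wm(run$data, "data.tsv")
  wm(run$motion_params, "motion.tsv")
  wm(run$task_covariates, "task.tsv")
  wm(run$nuisance_signals, "nuisance.tsv")
  wm(matrix(run$fd_trace, nrow = 1L), "fd.tsv")
  jsonlite::write_json(
    list(subject_id = run$subject_id, session = run$session,
         run_id = run$run_id, tr_seconds = run$tr_seconds),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_run
#' @export
read_run <- function(dir) {
  rm_ <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("read_run: missing ", f, " in ", dir)
    as.matrix(utils::read.table(p, sep = "\t"))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  new_run_timeseries(meta$subject_id, meta$session, meta$run_id,
                     rm_("data.tsv"), meta$tr_seconds,
                     rm_("motion.tsv"), rm_("task.tsv"),
                     rm_("nuisance.tsv"), as.numeric(rm_("fd.tsv")))
}
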