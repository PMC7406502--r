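#' Build a parcellation atlas with intrinsic-network labels
#'
#' Constructs a node table for a parcellation with `n_cortical` cortical
#' parcels assigned (randomly, but reproducibly) to named intrinsic functional
#' networks, plus optional subcortical regions labeled `"subcortical"`.
#' Every network receives at least one cortical node; hemispheres alternate
#' L/R across cortical nodes.
#'
#' @param n_cortical number of cortical parcels (>= number of networks)
#' @param subcortical_names character vector of subcortical region names
#'   (possibly empty); must be unique
#' @param network_names character vector of intrinsic-network names
#' @param seed integer seed controlling the label assignment
#' @return a `parcel_atlas`: data.frame with columns `node_id` (consecutive
#'   integers from 1), `node_name`, `network`, `hemisphere`
#' @examples
#' atlas <- make_atlas(20, c("L_thalamus", "R_thalamus"), c("DMN", "FPN"), seed = 1)
#' nrow(atlas)  # 22
#' @export
make_atlas <- function(n_cortical, subcortical_names = character(),
                       network_names, seed = 1L) {
  n_cortical <- as.integer(n_cortical)
  network_names <- as.character(network_names)
  subcortical_names <- as.character(subcortical_names)
  if (length(network_names) < 1L) stop("make_atlas: need at least one network name")
  if (n_cortical < length(network_names)) {
    stop("make_atlas: n_cortical must be >= number of networks")
  }
  if (anyDuplicated(subcortical_names)) {
    stop("make_atlas: duplicate subcortical names")
  }
  if (anyDuplicated(network_names)) {
    stop("make_atlas: duplicate network names")
  }
  k <- length(network_names)
  labels <- with_seed(seed, {
    lab <- c(network_names,
             sample(network_names, n_cortical - k, replace = TRUE))
    sample(lab)  # shuffle so guaranteed nodes are not clustered at the front
  })
  hemi <- rep_len(c("L", "R"), n_cortical)
  cortical_names <- sprintf("%s_%s_%03d", hemi, labels,
                            stats::ave(seq_len(n_cortical), labels, hemi,
                                       FUN = seq_along))
  node_name <- c(cortical_names, subcortical_names)
  if (anyDuplicated(node_name)) stop("make_atlas: duplicate node names")
  atlas <- data.frame(
    node_id = seq_along(node_name),
    node_name = node_name,
    network = c(labels, rep("subcortical", length(subcortical_names))),
    hemisphere = c(hemi, rep("subcortical", length(subcortical_names))),
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("parcel_atlas", "data.frame")
  validate_atlas(atlas)
}

#' Validate a parcellation atlas table
#'
#' @param atlas data.frame with columns `node_id`, `node_name`, `network`
#' @return the atlas (invisibly classed `parcel_atlas`), or an error
#'   describing the first offending row
#' @export
validate_atlas <- function(atlas) {
  required <- c("node_id", "node_name", "network")
  missing_cols <- setdiff(required, names(atlas))
  if (length(missing_cols)) {
    stop("atlas: missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  ids <- atlas$node_id
  if (anyDuplicated(ids)) {
    stop("atlas: duplicate node_id at line ", which(duplicated(ids))[1L] + 1L)
  }
  if (!identical(as.integer(ids), seq_len(nrow(atlas)))) {
    bad <- which(as.integer(ids) != seq_len(nrow(atlas)))[1L]
    stop("atlas: node_ids must be consecutive from 1; first gap at line ", bad + 1L)
  }
  if (anyDuplicated(atlas$node_name)) {
    stop("atlas: duplicate node_name at line ",
         which(duplicated(atlas$node_name))[1L] + 1L)
  }
  if (any(is.na(atlas$network) | atlas$network == "")) {
    stop("atlas: missing network label at line ",
         which(is.na(atlas$network) | atlas$network == "")[1L] + 1L)
  }
  if (!inherits(atlas, "parcel_atlas")) {
    class(atlas) <- c("parcel_atlas", class(atlas))
  }
  atlas
}

#' Read an atlas TSV
#'
#' Expects tab-separated columns `node_id`, `node_name`, `network` and
#' optionally `hemisphere`; validates id consecutiveness and label coverage.
#'
#' @param path path to the TSV file
#' @return a `parcel_atlas`
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("read_atlas: file not found: ", path)
  atlas <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_atlas(atlas)
}

#' Write an atlas TSV
#'
#' @param atlas a `parcel_atlas`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  utils::write.table(as.data.frame(atlas), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged atlas fixtures
#'
#' `default_atlas()` loads the packaged 343-node parcellation stand-in
#' (333 cortical parcels across 12 intrinsic networks plus 10 subcortical
#' regions; a synthetic label table with the same node/network structure as
#' a standard high-resolution cortical template). `test_atlas()` loads the
#' small 40-node atlas used throughout the test-suite and examples.
#'
#' @return a `parcel_atlas`
#' @export
default_atlas <- function() {
  read_atlas(system.file("extdata", "atlas_343_synthetic.tsv",
                         package = "nbsconn", mustWork = TRUE))
}

#' @rdname default_atlas
#' @export
test_atlas <- function() {
  read_atlas(system.file("extdata", "atlas_test40.tsv",
                         package = "nbsconn", mustWork = TRUE))
}

#' Map edges to unordered network-pair labels
#'
#' @param atlas a `parcel_atlas`
#' @param edges data.frame with node columns `i`, `j`
#' @return character vector of labels `"netA--netB"` with the two network
#'   names in alphabetical order (so (FPN, CO) and (CO, FPN) coincide)
#' @export
network_pair_labels <- function(atlas, edges) {
  a <- atlas$network[edges$i]
  b <- atlas$network[edges$j]
  paste(pmin(a, b), pmax(a, b), sep = "--")
}
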