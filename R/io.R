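#' Read and write trial tables as TSV
#'
#' The on-disk schema carries the documented columns (trial_id, block,
#' goal labels, stimulus/response bins, errors) plus the continuous
#' feature columns used by the relabeling analyses.
#'
#' @param trials a trial table.
#' @param path file path.
#' @return \code{read_trials} returns a \code{trial_table}.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(as.data.frame(trials), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "block", "goal_size", "goal_color", "size_bin",
            "color_bin", "response_size_bin", "response_color_bin",
            "size_error", "color_error")
  missing <- setdiff(need, names(d))
  if (length(missing))
    abort_geomstate(sprintf("trial table is missing columns: %s",
                            paste(missing, collapse = ", ")),
                    "parse_error")
  class(d) <- c("trial_table", "data.frame")
  d
}

#' Read and write epoch arrays
#'
#' Epoch arrays are serialized with R's native binary serialization,
#' preserving the data array, time axis, sampling rate, channel names and
#' channel groups exactly.
#'
#' @param epochs an \code{epoch_array}.
#' @param path file path (conventionally \code{.rds}).
#' @return \code{read_epochs} returns an \code{epoch_array}.
#' @export
write_epochs <- function(epochs, path) {
  saveRDS(unclass(epochs), path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  need <- c("data", "times", "sfreq", "channel_names", "channel_groups")
  if (!all(need %in% names(x)))
    abort_geomstate("file does not contain an epoch array", "parse_error")
  structure(x[need], class = "epoch_array")
}

#' Read and write beta volumes as NIfTI
#'
#' The 4D coefficient array (x, y, z, trial) and the 3D mask are written
#' as separate NIfTI files; the affine encodes the isotropic voxel size.
#'
#' @param betas a \code{beta_volume}.
#' @param path path of the 4D betas file (e.g., \code{betas.nii.gz}).
#' @param mask_path path of the mask file (default: path with
#'   \code{_mask} inserted).
#' @return \code{read_beta_volume} returns a \code{beta_volume}.
#' @export
write_beta_volume <- function(betas, path,
                              mask_path = sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)) {
  vs <- betas$voxel_size
  img <- RNifti::asNifti(betas$data)
  RNifti::pixdim(img) <- c(vs, vs, vs, 1)
  RNifti::writeNifti(img, path)
  mimg <- RNifti::asNifti(array(as.integer(betas$mask), dim(betas$mask)))
  RNifti::pixdim(mimg) <- c(vs, vs, vs)
  RNifti::writeNifti(mimg, mask_path)
  invisible(path)
}

#' @rdname write_beta_volume
#' @export
read_beta_volume <- function(path,
                             mask_path = sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)) {
  img <- RNifti::readNifti(path)
  mimg <- RNifti::readNifti(mask_path)
  vs <- RNifti::pixdim(img)[1]
  structure(list(data = array(as.numeric(img), dim(img)),
                 mask = array(as.numeric(mimg) > 0.5, dim(mimg)),
                 voxel_size = vs, labels = NULL),
            class = "beta_volume")
}

#' Write an RDM as TSV with a label header
#'
#' @param x an \code{rdm}.
#' @param path file path.
#' @export
write_rdm <- function(x, path) {
  utils::write.table(x$distances, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  d <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  rdm(d)
}

#' Serialize geometry results to JSON
#'
#' Polygons, subspaces and time courses are written as plain JSON for
#' fixtures and reports.
#'
#' @param x a \code{polygon_coords}, \code{subspace},
#'   \code{circ_timecourse} or plain list.
#' @param path file path.
#' @export
write_json_result <- function(x, path) {
  obj <- if (inherits(x, "polygon_coords")) {
    list(order_label = x$order_label,
         vertices = apply(x$vertices, 1, as.numeric, simplify = FALSE))
  } else if (inherits(x, "subspace")) {
    list(column_means = x$column_means, column_sds = x$column_sds,
         components = asplit(x$components, 1))
  } else if (inherits(x, "circ_timecourse")) {
    list(window_centers = x$window_centers, values = x$values,
         window_length = x$window_length, n_resamples = x$n_resamples)
  } else x
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
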