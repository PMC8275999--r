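# Plain-text writers/readers for the standard interchange formats used by
# the pipeline: BIDS-events-style TSV trial tables, 6-column motion text
# (rp_*.txt dialect), trial-by-voxel beta TSVs, 4D NIfTI volumes (via
# RNifti, when installed), and JSON configs/ground truth.

#' Write a trial table as a BIDS-events-style TSV
#'
#' Columns written: onset, duration, trial_type, response, response_time.
#'
#' @param trial_table A `trial_table` data frame.
#' @param path Output path.
#' @export
write_events_tsv <- function(trial_table, path) {
  cols <- c("onset", "duration", "trial_type", "response", "response_time")
  utils::write.table(trial_table[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-events-style TSV trial table
#'
#' Restores the numeric valence code from `trial_type` when the standard
#' labels (negative/neutral/positive) are used.
#'
#' @param path Input path.
#' @return A `trial_table` data frame.
#' @export
read_events_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  codes <- c(negative = -1L, neutral = 0L, positive = 1L)
  if (all(tab$trial_type %in% names(codes)))
    tab$valence <- unname(codes[tab$trial_type])
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Write motion parameters as 6-column whitespace text
#' @param motion_params n_scans x 6 matrix.
#' @param path Output path.
#' @export
write_motion_txt <- function(motion_params, path) {
  stopifnot(ncol(motion_params) == 6)
  utils::write.table(format(motion_params, digits = 10), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read 6-column motion-parameter text
#' @param path Input path.
#' @return n_scans x 6 numeric matrix.
#' @export
read_motion_txt <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) stop("motion file must have 6 columns")
  dimnames(m) <- NULL
  m
}

#' Write a trial-by-voxel beta matrix as TSV
#' @param betas Trials x voxels matrix.
#' @param path Output path.
#' @export
write_betas_tsv <- function(betas, path) {
  utils::write.table(betas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trial-by-voxel beta matrix TSV
#' @param path Input path.
#' @return Numeric matrix.
#' @export
read_betas_tsv <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
}

#' Write a scans-by-voxels signal matrix as a 4D NIfTI volume
#'
#' Voxels are laid out along the x axis of a `n_voxels x 1 x 1 x n_scans`
#' image. Requires the RNifti package.
#'
#' @param signals n_scans x n_voxels matrix.
#' @param path Output path (.nii or .nii.gz).
#' @param TR Repetition time (s), stored in the header.
#' @export
write_nifti_4d <- function(signals, path, TR = 2.5) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writing NIfTI requires the RNifti package")
  arr <- array(t(signals), dim = c(ncol(signals), 1, 1, nrow(signals)))
  img <- RNifti::asNifti(arr, pixdim = c(1, 1, 1, TR))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a generator config (and optional ground truth) as JSON
#' @param config A `generator_config`.
#' @param path Output path.
#' @param truth Optional ground-truth list/data frame to embed.
#' @export
write_config_json <- function(config, path, truth = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing JSON requires the jsonlite package")
  obj <- unclass(config)
  if (!is.null(truth)) obj$ground_truth <- truth
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a connectivity table as edge-list CSV
#' @param table A `connectivity_table`.
#' @param path Output path.
#' @export
write_connectivity_csv <- function(table, path) {
  stopifnot(inherits(table, "connectivity_table"))
  cols <- intersect(c("contrast", "source", "target", "pe", "pp"),
                    names(table))
  utils::write.csv(as.data.frame(table)[, cols], path, row.names = FALSE)
  invisible(path)
}
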