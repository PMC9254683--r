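#' Read a NIfTI volume
#' @param path Path to a NIfTI-1/2 file.
#' @return Numeric array with the 4x4 affine in attribute `affine`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  attr(a, "affine") <- structure(as.matrix(RNifti::xform(img)),
                                 dimnames = NULL, code = NULL)
  a
}

#' Write a NIfTI volume
#' @param data Numeric array (3D or 4D).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine Optional 4x4 voxel-to-world matrix.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, affine = NULL) {
  a <- array(as.numeric(data), dim(data))
  if (!is.null(affine))
    attr(a, "pixdim") <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(a, datatype = "double")
  if (!is.null(affine)) {
    RNifti::qform(img) <- structure(affine, code = 2L)
    RNifti::sform(img) <- structure(affine, code = 2L)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that two volumes share a grid
#' @param a,b Arrays.
#' @param names Labels used in the error message.
#' @return TRUE invisibly, or an error spelling out both shapes.
#' @export
check_same_grid <- function(a, b, names = c("a", "b")) {
  da <- dim(a)[1:3]; db <- dim(b)[1:3]
  if (!identical(da, db))
    stop(sprintf("grid mismatch: %s is %s but %s is %s",
                 names[1], paste(da, collapse = "x"),
                 names[2], paste(db, collapse = "x")))
  invisible(TRUE)
}

#' Write / read a CO2 trace as 2-column TSV
#' @param sim A `co2_sim` or `co2_trace`.
#' @param path Output path.
#' @return `path` invisibly (`write_co2_tsv`); a data frame with `time_s`
#'   and `co2_mmhg` (`read_co2_tsv`).
#' @export
write_co2_tsv <- function(sim, path) {
  tr <- if (inherits(sim, "co2_sim")) sim$trace else sim
  utils::write.table(data.frame(time_s = tr$time_s, co2_mmhg = tr$co2_mmhg),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_co2_tsv
#' @export
read_co2_tsv <- function(path)
  utils::read.delim(path, check.names = FALSE)

#' Write / read motion parameters as 6-column TSV
#' @param motion Matrix with 6 columns.
#' @param path Output path.
#' @return `path` invisibly; `read_motion_tsv` returns a matrix.
#' @export
write_motion_tsv <- function(motion, path) {
  stopifnot(ncol(motion) == 6)
  utils::write.table(as.data.frame(motion), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path)
  as.matrix(utils::read.delim(path, check.names = FALSE))

#' Write a regressor set as TSV plus JSON sidecar
#'
#' The TSV holds one row per lag (first column `lag_s`); the sidecar
#' records the lag grid, baseline, TR and HRF parameters.
#' @param rs A `regressor_set`.
#' @param path TSV path; the sidecar replaces the extension with `.json`.
#' @return `path` invisibly; `read_regressors_tsv` rebuilds the
#'   `regressor_set`.
#' @export
write_regressors_tsv <- function(rs, path) {
  stopifnot(inherits(rs, "regressor_set"))
  df <- data.frame(lag_s = rs$lags_s, rs$regressors, check.names = FALSE)
  names(df) <- c("lag_s", paste0("vol", seq_len(ncol(rs$regressors))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(lag_limit_s = rs$lag_limit_s, lag_step_s = rs$lag_step_s,
               tr_s = rs$tr_s, baseline_mmhg = rs$baseline_mmhg,
               sample_times_s = rs$sample_times_s,
               boundary_rows = rs$boundary_rows,
               hrf = attr(rs$hrf_kernel, "parameters"))
  jsonlite::write_json(side, sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regressors_tsv
#' @export
read_regressors_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  side <- jsonlite::read_json(sub("\\.[^.]+$", ".json", path),
                              simplifyVector = TRUE)
  hrf <- do.call(canonical_hrf,
                 c(list(dt_s = side$lag_step_s),
                   side$hrf[setdiff(names(side$hrf), "normalize")],
                   list(normalize = side$hrf$normalize)))
  structure(list(lags_s = df$lag_s,
                 regressors = as.matrix(df[, -1, drop = FALSE]),
                 hrf_kernel = hrf, tr_s = side$tr_s,
                 baseline_mmhg = side$baseline_mmhg,
                 sample_times_s = side$sample_times_s,
                 boundary_rows = side$boundary_rows,
                 lag_limit_s = side$lag_limit_s,
                 lag_step_s = side$lag_step_s),
            class = "regressor_set")
}

#' Provenance metadata for an output file
#' @param config A `study_config`.
#' @param seed Integer seed.
#' @param stage Stage label.
#' @return List suitable for `jsonlite::write_json`.
#' @export
provenance <- function(config, seed, stage) {
  list(package = "lagcvr",
       version = as.character(utils::packageVersion("lagcvr")),
       stage = stage, seed = seed,
       config = unclass(config))
}
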