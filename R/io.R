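#' Read a connectivity matrix from TSV/CSV
#'
#' Expects an N x N numeric table in atlas order, optionally preceded by a
#' single header row of parcel ids. Near-symmetric input (asymmetry below
#' `tol`) is symmetrized by averaging; anything worse is rejected. NaN cells
#' are rejected: missingness must arrive through the `valid` sidecar, not
#' through the weights.
#'
#' @param path file path; tab-separated by default, comma accepted.
#' @param atlas [parcel_atlas()] defining the expected dimension and order.
#' @param modality `"SC"` or `"FC"`.
#' @param valid optional logical node mask to attach.
#' @param tol symmetrization tolerance.
#' @return A [connectivity_matrix()].
#' @export
read_matrix <- function(path, atlas, modality = c("SC", "FC"), valid = NULL,
                        tol = 1e-8) {
  modality <- match.arg(modality)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  nums <- suppressWarnings(as.numeric(fields))
  has_header <- any(is.na(nums) & !is.nan(nums)) ||
    (identical(suppressWarnings(as.integer(fields)), seq_along(fields)) &&
       length(fields) > 1)
  m <- as.matrix(utils::read.table(path, sep = sep, header = has_header,
                                   check.names = FALSE))
  n <- n_parcels(atlas)
  if (nrow(m) != n || ncol(m) != n) {
    stop(sprintf("matrix is %d x %d but atlas has %d parcels",
                 nrow(m), ncol(m), n))
  }
  storage.mode(m) <- "double"
  if (any(is.na(m))) stop("NaN/NA cells in matrix file; use a valid-mask sidecar")
  connectivity_matrix(m, modality, valid = valid, symmetrize_tol = tol)
}

#' Write a connectivity matrix to TSV
#'
#' Writes the weights as a tab-separated table with a header row of parcel
#' ids, at full double precision so read/write round-trips are the identity
#' to 1e-12.
#'
#' @param mat a [connectivity_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  m <- mat$weights
  colnames(m) <- seq_len(ncol(m))
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an atlas label volume from NIfTI
#'
#' @param path NIfTI-1 file (`.nii` / `.nii.gz`) with integer parcel labels
#'   (0 = background).
#' @return 3D integer array with a `pixdim` attribute (voxel dimensions).
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(as.vector(img))), dim = dim(img))
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' Read a lesion mask from NIfTI
#'
#' The mask is binarized at `> 0`. When `label_volume` is supplied the
#' shapes must agree (inputs are assumed co-registered; no resampling is
#' performed).
#'
#' @param path NIfTI-1 file.
#' @param label_volume optional label array to check alignment against.
#' @return 3D logical array with a `pixdim` attribute.
#' @export
read_lesion_mask <- function(path, label_volume = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img) > 0, dim = dim(img))
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  if (!is.null(label_volume) && !identical(dim(arr), dim(label_volume))) {
    stop(sprintf("lesion mask shape (%s) does not match label volume (%s)",
                 paste(dim(arr), collapse = "x"),
                 paste(dim(label_volume), collapse = "x")))
  }
  arr
}

#' Write a 3D array as NIfTI
#' @param arr 3D numeric/integer/logical array.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(arr, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(arr), dim = dim(arr))),
                     path)
  invisible(path)
}

# recursively order list keys so report serialization is deterministic
order_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x)) {
    x <- x[order(names(x))]
    lapply(x, order_keys)
  } else if (is.list(x)) {
    lapply(x, order_keys)
  } else x
}

#' Write an analysis report to JSON
#'
#' Scalars, vectors, matrices and data.frames are serialized with
#' deterministic key order and full precision (round-trips losslessly at
#' 1e-12). Unserializable objects (functions, environments) are an error.
#'
#' @param results named list of results.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  check <- function(x) {
    if (is.function(x) || is.environment(x)) {
      stop("unserializable object in report (function/environment)")
    }
    if (is.list(x)) lapply(x, check)
    invisible(NULL)
  }
  check(results)
  json <- jsonlite::toJSON(order_keys(results), digits = NA, auto_unbox = TRUE,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#' @param path `.json` path.
#' @return named list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Write a ranking / result table to TSV
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
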