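#' Parcel atlas
#'
#' A cortical parcellation table in the style of HCP-MMP1: one row per
#' parcel with a stable integer id, a name, hemisphere, a canonical
#' functional-network assignment (DMN, FPN, VAN, ...) and the parcel volume
#' in voxels. Node order is atlas order everywhere in the package; no file
#' reader ever reorders nodes.
#'
#' @param parcel_id integer vector `1..N`, unique and sorted.
#' @param name character parcel names.
#' @param hemisphere `"L"` or `"R"` per parcel.
#' @param network functional network label per parcel.
#' @param node_volume positive parcel volume (voxels or mm^3).
#' @param label_volume optional 3D integer array whose voxel values are
#'   parcel ids (0 = background).
#' @return An object of class `parcel_atlas`: a list with a `parcels`
#'   data.frame and the optional `label_volume`.
#' @export
parcel_atlas <- function(parcel_id, name, hemisphere, network, node_volume,
                         label_volume = NULL) {
  parcel_id <- as.integer(parcel_id)
  n <- length(parcel_id)
  if (anyDuplicated(parcel_id)) stop("parcel_id values must be unique")
  if (!identical(parcel_id, seq_len(n))) {
    stop("parcel_id must be the contiguous sequence 1..N in atlas order")
  }
  if (any(node_volume <= 0)) stop("node_volume must be positive for every parcel")
  hemisphere <- as.character(hemisphere)
  if (!all(hemisphere %in% c("L", "R"))) stop("hemisphere must be 'L' or 'R'")
  if (!is.null(label_volume)) {
    vals <- unique(as.integer(label_volume))
    vals <- vals[vals != 0L]
    if (!all(vals %in% parcel_id)) {
      stop("label_volume contains voxel values that are not known parcel ids")
    }
  }
  structure(list(
    parcels = data.frame(
      parcel_id = parcel_id,
      name = as.character(name),
      hemisphere = hemisphere,
      network = as.character(network),
      node_volume = as.numeric(node_volume),
      stringsAsFactors = FALSE
    ),
    label_volume = label_volume
  ), class = "parcel_atlas")
}

#' @export
print.parcel_atlas <- function(x, ...) {
  n <- nrow(x$parcels)
  cat("Parcel atlas:", n, "parcels (",
      sum(x$parcels$hemisphere == "L"), "L /",
      sum(x$parcels$hemisphere == "R"), "R )\n")
  cat("Networks:", paste(sort(unique(x$parcels$network)), collapse = ", "), "\n")
  if (!is.null(x$label_volume)) {
    cat("Label volume:", paste(dim(x$label_volume), collapse = " x "), "voxels\n")
  }
  invisible(x)
}

#' Number of parcels in an atlas
#' @param atlas a [parcel_atlas()].
#' @return integer parcel count.
#' @export
n_parcels <- function(atlas) nrow(atlas$parcels)

#' Connectivity matrix
#'
#' Square symmetric weighted connectivity over atlas parcels, either
#' structural (`SC`, nonnegative streamline-count-derived weights) or
#' functional (`FC`, Pearson correlations). Missingness is carried by the
#' logical `valid` node mask, never by NaN inside the weights: rows/columns
#' of invalid nodes are retained but every metric in the package restricts
#' itself to the valid submatrix.
#'
#' @param weights N x N numeric matrix, symmetric with zero diagonal.
#' @param modality `"SC"` or `"FC"`.
#' @param valid logical node-inclusion mask of length N (default all TRUE).
#' @param subject_id optional subject identifier.
#' @param symmetrize_tol asymmetries up to this magnitude are averaged away;
#'   larger asymmetry is an error.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, modality = c("SC", "FC"),
                                valid = NULL, subject_id = NA_character_,
                                symmetrize_tol = 1e-8) {
  modality <- match.arg(modality)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  n <- nrow(weights)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(valid) != n) stop("valid mask length must match matrix dimension")
  if (any(is.na(weights[valid, valid]))) {
    stop("NaN/NA weights are not allowed on valid nodes; use the valid mask")
  }
  asym <- max(abs(weights - t(weights)), na.rm = TRUE)
  if (asym > symmetrize_tol) {
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g", asym, symmetrize_tol))
  }
  if (asym > 0) weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (modality == "SC" && any(weights[valid, valid] < 0)) {
    stop("SC weights must be nonnegative")
  }
  dimnames(weights) <- NULL
  structure(list(
    weights = weights,
    modality = modality,
    valid = as.logical(valid),
    subject_id = subject_id
  ), class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  n <- length(x$valid)
  w <- x$weights[x$valid, x$valid, drop = FALSE]
  ut <- w[upper.tri(w)]
  cat(sprintf("%s connectivity: %d nodes (%d valid), density %.3f\n",
              x$modality, n, sum(x$valid),
              if (length(ut)) mean(ut != 0) else NA_real_))
  if (!is.na(x$subject_id)) cat("Subject:", x$subject_id, "\n")
  invisible(x)
}

# valid-node submatrix; keeps parcel ids of the retained nodes as an attribute
valid_submatrix <- function(mat) {
  idx <- which(mat$valid)
  w <- mat$weights[idx, idx, drop = FALSE]
  attr(w, "parcel_id") <- idx
  w
}

#' Regional lesion profile
#'
#' Per-parcel lesion overlap fractions plus the subject's total lesion load
#' (lesioned voxels / intracranial voxels).
#'
#' @param proportion numeric vector in `[0, 1]`, one entry per parcel; NA
#'   marks parcels absent from the label volume.
#' @param total_lesion_load nonnegative scalar.
#' @param subject_id optional identifier.
#' @return An object of class `lesion_profile`.
#' @export
lesion_profile <- function(proportion, total_lesion_load = 0,
                           subject_id = NA_character_) {
  ok <- !is.na(proportion)
  if (any(proportion[ok] < 0 | proportion[ok] > 1)) {
    stop("lesion proportions must lie in [0, 1]")
  }
  if (total_lesion_load < 0) stop("total_lesion_load must be nonnegative")
  structure(list(
    proportion = as.numeric(proportion),
    total_lesion_load = as.numeric(total_lesion_load),
    subject_id = subject_id
  ), class = "lesion_profile")
}

#' Atrophy / deformation map
#'
#' Per-parcel group-difference t-statistics for a morphometry metric
#' (cortical thickness by default). This is the empirical spatial pattern
#' the Network Diffusion Model seed sweep is correlated against.
#'
#' @param tstat numeric vector, one t-statistic per parcel (NA on invalid
#'   parcels).
#' @param metric morphometry metric name.
#' @param sign_convention free-text note on the direction of positive values
#'   (the default records that positive = thicker in patients).
#' @return An object of class `atrophy_map`.
#' @export
atrophy_map <- function(tstat, metric = "thickness",
                        sign_convention = "positive = greater in patients") {
  if (!any(is.finite(tstat))) stop("atrophy map has no finite values")
  structure(list(
    tstat = as.numeric(tstat),
    metric = metric,
    sign_convention = sign_convention
  ), class = "atrophy_map")
}
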