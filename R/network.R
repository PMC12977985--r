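#' Pearson functional connectivity from parcel time series
#'
#' @param ts T x N matrix of denoised BOLD time series (T >= 3 time
#'   points, one column per parcel).
#' @param subject_id optional identifier.
#' @return An `FC` [connectivity_matrix()]. Zero-variance columns are
#'   marked invalid rather than propagating NaN.
#' @export
build_fc <- function(ts, subject_id = NA_character_) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 time points")
  n <- ncol(ts)
  sds <- apply(ts, 2, stats::sd)
  valid <- is.finite(sds) & sds > 0
  w <- matrix(0, n, n)
  if (sum(valid) >= 2) {
    r <- stats::cor(ts[, valid, drop = FALSE])
    diag(r) <- 0
    w[valid, valid] <- r
  }
  connectivity_matrix(w, "FC", valid = valid, subject_id = subject_id)
}

#' Inverse-node-volume normalization of streamline counts
#'
#' Corrects parcel-size bias in tractography-derived edge weights:
#' `SC[i, j] = counts[i, j] / (vol_i + vol_j)`.
#'
#' @param raw_counts N x N nonnegative symmetric matrix of (SIFT2-weighted)
#'   streamline counts.
#' @param node_volumes positive parcel volumes, length N.
#' @param subject_id optional identifier.
#' @return An `SC` [connectivity_matrix()].
#' @export
normalize_sc_invnodevol <- function(raw_counts, node_volumes,
                                    subject_id = NA_character_) {
  if (any(node_volumes <= 0)) stop("node volumes must be positive")
  raw_counts <- as.matrix(raw_counts)
  if (any(raw_counts < 0)) stop("streamline counts must be nonnegative")
  denom <- outer(node_volumes, node_volumes, "+")
  connectivity_matrix(raw_counts / denom, "SC", subject_id = subject_id)
}

#' Exclude lesion-overlapped nodes from a connectivity matrix
#'
#' Nodes whose lesion overlap proportion is at or above `cutoff` (the
#' boundary is inclusive, matching a ">= 50%" exclusion rule) are flagged
#' invalid; all downstream metrics ignore them.
#'
#' @param mat a [connectivity_matrix()].
#' @param lesions a [lesion_profile()].
#' @param cutoff overlap fraction at which a node is excluded.
#' @return The matrix with an updated valid mask; the number of newly
#'   excluded nodes is attached as attribute `n_excluded`.
#' @export
apply_lesion_mask <- function(mat, lesions, cutoff = 0.5) {
  p <- lesions$proportion
  if (length(p) != length(mat$valid)) stop("lesion profile length mismatch")
  excl <- !is.na(p) & p >= cutoff
  valid <- mat$valid & !excl
  if (!any(valid)) stop("empty network: every node excluded by the lesion mask")
  out <- mat
  out$valid <- valid
  attr(out, "n_excluded") <- sum(mat$valid & !valid)
  out
}

#' Proportional thresholding
#'
#' Keeps the `ceiling(density * M)` strongest edges among the `M` possible
#' upper-triangle edges over valid nodes and zeroes the rest; symmetry is
#' preserved. For functional matrices negative edges are zeroed first
#' (negative correlations are not treated as connection strengths). Ties at
#' the cutoff weight are broken deterministically in favour of the
#' lexicographically smaller `(i, j)` index pair.
#'
#' @param mat a [connectivity_matrix()].
#' @param density fraction of possible edges to retain, in `(0, 1]`.
#' @return A thresholded [connectivity_matrix()].
#' @export
proportional_threshold <- function(mat, density) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  w <- mat$weights
  if (mat$modality == "FC") w[w < 0] <- 0
  idx <- which(mat$valid)
  sub <- w[idx, idx, drop = FALSE]
  n <- length(idx)
  ut <- which(upper.tri(sub), arr.ind = TRUE)
  m_possible <- nrow(ut)
  k <- ceiling(density * m_possible)
  vals <- sub[upper.tri(sub)]
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  new_sub <- matrix(0, n, n)
  ij <- ut[keep, , drop = FALSE]
  new_sub[ij] <- vals[keep]
  new_sub <- new_sub + t(new_sub)
  out <- mat
  out$weights[idx, idx] <- new_sub
  # invalid rows/cols untouched; they are masked anyway
  out
}
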