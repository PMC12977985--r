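#' Per-node structure-function coupling
#'
#' For each node valid in both matrices, the Spearman rank correlation
#' between that node's structural and functional connectivity profiles
#' (rows restricted to the joint valid mask, excluding the self-
#' connection; ties receive average ranks). Zero structural entries are
#' kept as data — an absent connection is informative. Nodes with a
#' constant structural profile (isolated nodes) have undefined coupling
#' and are flagged NA rather than set to 0.
#'
#' @param sc structural [connectivity_matrix()].
#' @param fc functional [connectivity_matrix()] on the same atlas.
#' @return An object of class `coupling_profile`: list with `rho` (length
#'   N, NA where undefined), `valid` (joint mask) and `subject_id`.
#' @export
sc_fc_coupling <- function(sc, fc) {
  n <- length(sc$valid)
  if (length(fc$valid) != n) stop("sc and fc must share an atlas")
  valid <- sc$valid & fc$valid
  if (sum(valid) < 3) stop("need at least 3 jointly valid nodes")
  rho <- rep(NA_real_, n)
  idx <- which(valid)
  for (i in idx) {
    j <- setdiff(idx, i)
    x <- sc$weights[i, j]
    y <- fc$weights[i, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # undefined, stays NA
    rho[i] <- stats::cor(x, y, method = "spearman")
  }
  structure(list(rho = rho, valid = valid, subject_id = sc$subject_id),
            class = "coupling_profile")
}

#' @export
print.coupling_profile <- function(x, ...) {
  ok <- !is.na(x$rho)
  cat(sprintf("SC-FC coupling: %d nodes, mean rho = %.3f (range %.3f..%.3f)\n",
              sum(ok), mean(x$rho[ok]), min(x$rho[ok]), max(x$rho[ok])))
  invisible(x)
}

#' Mean coupling per canonical network
#'
#' Unweighted mean of node coupling over valid nodes in each network;
#' networks with fewer than 2 valid nodes are reported NA and flagged.
#'
#' @param profile a `coupling_profile` from [sc_fc_coupling()].
#' @param atlas the [parcel_atlas()] supplying network labels.
#' @param networks optional subset of network labels (default: all in the
#'   atlas); an unknown label is an error.
#' @return data.frame with `network`, `mean_rho`, `n_valid`, `low_n`.
#' @export
network_mean_coupling <- function(profile, atlas, networks = NULL) {
  labs <- atlas$parcels$network
  if (is.null(networks)) networks <- unique(labs)
  unknown <- setdiff(networks, labs)
  if (length(unknown)) {
    stop("unknown network label(s): ", paste(unknown, collapse = ", "))
  }
  out <- lapply(networks, function(nw) {
    nodes <- which(labs == nw & profile$valid & !is.na(profile$rho))
    data.frame(network = nw,
               mean_rho = if (length(nodes) >= 2) mean(profile$rho[nodes]) else NA_real_,
               n_valid = length(nodes),
               low_n = length(nodes) < 2)
  })
  do.call(rbind, out)
}
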