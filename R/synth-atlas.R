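# Synthetic atlas: rectangular parcel blocks tiling a toy 3D grid.
# Block side is 4 voxels, so every parcel has 64 voxels; leftover blocks are
# background. Networks are assigned cyclically over the seven canonical
# systems so every network is represented at any n_nodes.

synth_networks <- c("DMN", "FPN", "VAN", "DAN", "Visual", "Somatomotor",
                    "Limbic")

#' Build a synthetic parcel atlas with a toy label volume
#'
#' Parcels are 4x4x4-voxel blocks tiling a small 3D grid (left hemisphere =
#' first half of ids, right = second half); functional networks cycle
#' through the seven canonical systems (DMN, FPN, VAN, DAN, Visual,
#' Somatomotor, Limbic). The label volume makes lesion growth and overlap
#' computations exact at voxel resolution.
#'
#' @param n_nodes number of parcels (>= 4; default 90).
#' @param block voxel side length of each cubic parcel block.
#' @return A [parcel_atlas()] with `label_volume` attached.
#' @export
synthetic_atlas <- function(n_nodes = 90, block = 4L) {
  if (n_nodes < 4) stop("n_nodes must be >= 4")
  a <- ceiling(n_nodes^(1 / 3))
  b <- ceiling(sqrt(n_nodes / a))
  cc <- ceiling(n_nodes / (a * b))
  dims <- c(a, b, cc) * block
  lab <- array(0L, dim = dims)
  id <- 0L
  for (k in seq_len(cc)) for (j in seq_len(b)) for (i in seq_len(a)) {
    id <- id + 1L
    if (id > n_nodes) break
    xs <- ((i - 1L) * block + 1L):(i * block)
    ys <- ((j - 1L) * block + 1L):(j * block)
    zs <- ((k - 1L) * block + 1L):(k * block)
    lab[xs, ys, zs] <- id
  }
  half <- ceiling(n_nodes / 2)
  hemi <- ifelse(seq_len(n_nodes) <= half, "L", "R")
  net <- synth_networks[((seq_len(n_nodes) - 1L) %% length(synth_networks)) + 1L]
  parcel_atlas(
    parcel_id = seq_len(n_nodes),
    name = sprintf("%s_parcel_%03d", hemi, seq_len(n_nodes)),
    hemisphere = hemi,
    network = net,
    node_volume = rep(block^3, n_nodes),
    label_volume = lab
  )
}

#' Parcel ids belonging to a functional network
#' @param atlas a [parcel_atlas()].
#' @param network network label, e.g. `"DMN"`.
#' @return integer vector of parcel ids.
#' @export
network_parcels <- function(atlas, network) {
  ids <- atlas$parcels$parcel_id[atlas$parcels$network == network]
  if (!length(ids)) stop(sprintf("unknown or empty network '%s'", network))
  ids
}
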