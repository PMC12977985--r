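# weighted shortest-path distance matrix over valid nodes; edge length 1/w
sp_distances <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, nrow(w), nrow(w)); diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

efficiency_from_weights <- function(w) {
  n <- nrow(w)
  d <- sp_distances(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0  # disconnected pairs contribute 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted global efficiency
#'
#' Edges are converted to lengths `l = 1/w`; shortest-path distances are
#' computed by Dijkstra over valid nodes, and efficiency is the mean of
#' `1/d_ij` over ordered node pairs, with disconnected pairs contributing 0
#' (Latora-Marchiori convention). A complete unit-weight graph scores 1.
#'
#' @param mat a [connectivity_matrix()].
#' @return scalar efficiency.
#' @export
global_efficiency <- function(mat) {
  w <- valid_submatrix(mat)
  if (nrow(w) < 2) stop("global efficiency needs at least 2 valid nodes")
  if (mat$modality == "FC") w[w < 0] <- 0
  efficiency_from_weights(w)
}

#' Onnela weighted clustering coefficient
#'
#' Weights are rescaled by the network maximum (`w_hat = w / max(w)`); each
#' node's coefficient is the geometric-mean triangle intensity
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{jh} (w_hat_ij w_hat_jh w_hat_hi)^(1/3)`,
#' and the network value is the mean over all valid nodes, with nodes of
#' degree < 2 contributing 0. The matrix is proportionally thresholded to
#' `density` first (pass `density = 1` for no thresholding).
#'
#' @param mat a [connectivity_matrix()].
#' @param density proportional threshold applied before clustering.
#' @return scalar mean clustering coefficient.
#' @export
clustering_coefficient <- function(mat, density = 1) {
  mat <- proportional_threshold(mat, density)
  w <- valid_submatrix(mat)
  if (mat$modality == "FC") w[w < 0] <- 0
  if (max(w) == 0) {
    warning("empty graph; clustering coefficient is 0")
    return(0)
  }
  what <- (w / max(w))^(1 / 3)
  k <- rowSums(w > 0)
  num <- diag(what %*% what %*% what)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(ci)
}

#' Node strength ranks
#'
#' Strength is the row sum of weights over valid nodes; rank 1 is the
#' strongest. Ties are broken deterministically by lower parcel id, and the
#' presence of ties is flagged in the `tied` attribute.
#'
#' @param mat a [connectivity_matrix()].
#' @param use_degree rank by binary degree instead of strength.
#' @return data.frame with `parcel_id`, `strength`, `rank`; attribute
#'   `tied` is TRUE when any strengths were equal.
#' @export
node_strength_rank <- function(mat) node_rank_impl(mat, use_degree = FALSE)

#' @rdname node_strength_rank
#' @export
node_degree_rank <- function(mat) node_rank_impl(mat, use_degree = TRUE)

node_rank_impl <- function(mat, use_degree = FALSE) {
  w <- valid_submatrix(mat)
  if (nrow(w) < 1) stop("no valid nodes")
  if (mat$modality == "FC") w[w < 0] <- 0
  s <- if (use_degree) rowSums(w > 0) else rowSums(w)
  ids <- attr(w, "parcel_id")
  ord <- order(-s, ids)
  rank <- integer(length(s))
  rank[ord] <- seq_along(s)
  out <- data.frame(parcel_id = ids, strength = s, rank = rank)
  attr(out, "tied") <- anyDuplicated(s) > 0
  out
}

#' Virtual lesion: targeted node removal vs a random-attack null
#'
#' Removes the target node (row and column) and measures the percentage
#' drop in global efficiency; the null distribution is built from `n_null`
#' uniform draws of a single non-target node removed the same way. The
#' one-sided p-value uses the add-one correction
#' `p = (1 + #\{null >= observed\}) / (n_null + 1)`.
#'
#' @param mat a [connectivity_matrix()] with >= 3 valid nodes.
#' @param target_node parcel id of the node to remove (must be valid).
#' @param n_null number of random single-node removals.
#' @return An object of class `virtual_lesion` with fields `target_node`,
#'   `E_base`, `E_removed`, `delta_pct`, `null_deltas`, `p_value`, `n_null`.
#' @export
virtual_lesion <- function(mat, target_node, n_null = 1000) {
  if (!mat$valid[target_node]) stop("target node is not valid")
  idx <- which(mat$valid)
  if (length(idx) < 3) stop("need at least 3 valid nodes")
  w <- valid_submatrix(mat)
  if (mat$modality == "FC") w[w < 0] <- 0
  e_base <- efficiency_from_weights(w)
  tpos <- match(target_node, idx)
  drop_one <- function(pos) efficiency_from_weights(w[-pos, -pos, drop = FALSE])
  e_removed <- drop_one(tpos)
  delta <- 100 * (e_base - e_removed) / e_base
  others <- setdiff(seq_along(idx), tpos)
  draws <- sample(others, n_null, replace = TRUE)
  # each distinct node's removal is computed once and reused across draws
  uniq <- unique(draws)
  e_uniq <- vapply(uniq, drop_one, 0)
  null_deltas <- 100 * (e_base - e_uniq[match(draws, uniq)]) / e_base
  p <- (1 + sum(null_deltas >= delta)) / (n_null + 1)
  structure(list(target_node = target_node, E_base = e_base,
                 E_removed = e_removed, delta_pct = delta,
                 null_deltas = null_deltas, p_value = p, n_null = n_null),
            class = "virtual_lesion")
}

#' @export
print.virtual_lesion <- function(x, ...) {
  cat(sprintf("Virtual lesion of node %d\n", x$target_node))
  cat(sprintf("  E_base = %.6f, E_removed = %.6f (delta = %.4f%%)\n",
              x$E_base, x$E_removed, x$delta_pct))
  cat(sprintf("  one-sided p = %.4f vs %d random removals\n",
              x$p_value, x$n_null))
  invisible(x)
}
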