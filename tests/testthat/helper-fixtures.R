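# shared fixture builders and independent oracles

cm <- function(w, modality = "SC", ...) connectivity_matrix(w, modality, ...)

# adjacency of a few canonical graphs (unit weights unless given)
complete_graph <- function(n, w = 1) {
  m <- matrix(w, n, n); diag(m) <- 0; m
}
path_graph <- function(n, w = 1) {
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- w
  m
}
star_graph <- function(n, w = 1) {
  m <- matrix(0, n, n)
  m[1, 2:n] <- m[2:n, 1] <- w
  m
}
triangle_graph <- function(w12 = 1, w13 = 1, w23 = 1) {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- w12
  m[1, 3] <- m[3, 1] <- w13
  m[2, 3] <- m[3, 2] <- w23
  m
}

random_weighted_graph <- function(n, p = 0.4) {
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  on <- runif(sum(ut)) < p
  w <- runif(sum(ut), 0.1, 2) * on
  m[ut] <- w
  m + t(m)
}

# Floyd-Warshall shortest paths (independent oracle for Dijkstra-based
# efficiency); lengths = 1/weight
fw_distances <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}
fw_efficiency <- function(w) {
  d <- fw_distances(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (nrow(w) * (nrow(w) - 1))
}

# explicit rank-then-Pearson Spearman (oracle for the coupling module)
spearman_oracle <- function(x, y) stats::cor(rank(x), rank(y))

# brute-force per-node transitivity for unweighted graphs (clustering oracle)
transitivity_oracle <- function(a) {
  a <- (a > 0) * 1
  n <- nrow(a)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- sum(a[nb, nb]) / 2
    ci[i] <- 2 * tri / (k * (k - 1))
  }
  mean(ci)
}

tiny_atlas <- function(n = 12) synthetic_atlas(n)
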