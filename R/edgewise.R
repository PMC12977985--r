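# vectorized OLS of many responses on one shared design; returns the
# t-statistic (and p) of a single term for every response column
vectorized_term_test <- function(ymat, design, term) {
  qrx <- qr(design)
  if (qrx$rank < ncol(design)) stop("rank-deficient design")
  coefs <- qr.coef(qrx, ymat)
  res <- ymat - design %*% coefs
  n <- nrow(design)
  p <- ncol(design)
  sigma2 <- colSums(res^2) / (n - p)
  xtx_inv <- chol2inv(qr.R(qrx))
  j <- match(term, colnames(design))
  if (is.na(j)) stop("term not in design: ", term)
  se <- sqrt(xtx_inv[j, j] * sigma2)
  tval <- coefs[j, ] / se
  pval <- 2 * stats::pt(-abs(tval), n - p)
  list(t = tval, p = pval, df = n - p)
}

#' Edgewise group comparison of functional connectivity
#'
#' For each upper-triangle edge over jointly valid nodes, the group-term
#' t-statistic from an OLS of the Fisher-z transformed edge weight on
#' group + covariates (mean framewise displacement should be among them
#' for functional data). Edges missing (invalid end node) in more than
#' half the subjects are excluded; remaining partial missingness is
#' handled per edge on complete cases. Returns the hyper-connected (top-k
#' most positive t, patients > controls) and hypo-connected (top-k most
#' negative) edge sets.
#'
#' @param fc_patients,fc_controls lists of `FC` [connectivity_matrix()].
#' @param covariates data.frame of per-subject covariates, patients first
#'   then controls (or NULL).
#' @param k number of edges per hyper/hypo set.
#' @param fisher_z transform correlations by `atanh` first.
#' @return list with `t_matrix`, `p_matrix` (N x N symmetric, NA off
#'   mask), `edges` (data.frame per tested edge), `hyper`, `hypo`
#'   (data.frames `i`, `j`, `t`), and `df`.
#' @export
edgewise_group_ttest <- function(fc_patients, fc_controls, covariates = NULL,
                                 k = 200, fisher_z = TRUE) {
  if (length(fc_patients) < 3 || length(fc_controls) < 3) {
    stop("need at least 3 subjects per group")
  }
  all_fc <- c(fc_patients, fc_controls)
  n <- length(all_fc[[1]]$valid)
  ns <- length(all_fc)
  group <- c(rep(1, length(fc_patients)), rep(0, length(fc_controls)))
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ymat <- matrix(NA_real_, ns, nrow(ut))
  for (s in seq_len(ns)) {
    w <- all_fc[[s]]$weights
    v <- all_fc[[s]]$valid
    wv <- w[ut]
    wv[!(v[ut[, 1]] & v[ut[, 2]])] <- NA
    ymat[s, ] <- wv
  }
  if (fisher_z) ymat <- atanh(pmin(pmax(ymat, -0.999999), 0.999999))
  miss_frac <- colMeans(is.na(ymat))
  tested <- which(miss_frac <= 0.5)
  if (!length(tested)) stop("no testable edges")
  design <- cbind(`(Intercept)` = 1, group = group)
  if (!is.null(covariates)) {
    design <- cbind(design, build_design(covariates)[, -1, drop = FALSE])
  }
  tvec <- rep(NA_real_, nrow(ut))
  pvec <- rep(NA_real_, nrow(ut))
  complete <- tested[miss_frac[tested] == 0]
  if (length(complete)) {
    vt <- vectorized_term_test(ymat[, complete, drop = FALSE], design, "group")
    tvec[complete] <- vt$t
    pvec[complete] <- vt$p
  }
  partial <- setdiff(tested, complete)
  for (e in partial) {
    ok <- !is.na(ymat[, e])
    vt <- vectorized_term_test(ymat[ok, e, drop = FALSE],
                               design[ok, , drop = FALSE], "group")
    tvec[e] <- vt$t
    pvec[e] <- vt$p
  }
  t_matrix <- matrix(NA_real_, n, n)
  p_matrix <- matrix(NA_real_, n, n)
  t_matrix[ut] <- tvec; t_matrix[ut[, c(2, 1)]] <- tvec
  p_matrix[ut] <- pvec; p_matrix[ut[, c(2, 1)]] <- pvec
  edges <- data.frame(i = ut[tested, 1], j = ut[tested, 2],
                      t = tvec[tested], p = pvec[tested])
  kk <- min(k, nrow(edges))
  if (kk < k) warning("k exceeds the number of tested edges; returning all")
  ord_pos <- order(-edges$t)
  ord_neg <- order(edges$t)
  hyper <- edges[ord_pos[seq_len(kk)], c("i", "j", "t")]
  hypo <- edges[ord_neg[seq_len(kk)], c("i", "j", "t")]
  list(t_matrix = t_matrix, p_matrix = p_matrix, edges = edges,
       hyper = hyper, hypo = hypo,
       n_excluded = sum(miss_frac > 0.5))
}

#' Aggregate edge strength over an edge set
#'
#' Mean functional weight over a fixed edge set for one subject (used to
#' relate hyper-/hypo-connected subnetwork strength to cognition).
#'
#' @param fc an `FC` [connectivity_matrix()].
#' @param edge_set data.frame with columns `i`, `j`.
#' @return scalar mean weight.
#' @export
aggregate_edge_strength <- function(fc, edge_set) {
  if (!nrow(edge_set)) stop("empty edge set")
  mean(fc$weights[cbind(edge_set$i, edge_set$j)])
}

#' Per-parcel morphometry group-difference t-map
#'
#' For each parcel, the t-statistic of the group term from an OLS of the
#' morphometry value on group + covariates (age, sex and total
#' intracranial volume for structural comparisons). Parcels with constant
#' values are flagged NA. The result feeds the NDM epicenter sweep as the
#' empirical map.
#'
#' @param values subjects x parcels numeric matrix.
#' @param group 0/1 numeric vector (1 = patient) or character labels.
#' @param covariates data.frame or NULL.
#' @param metric morphometry metric label.
#' @param patient_level which label codes patients when `group` is
#'   character (default `"AVM"`); positive t then means greater values in
#'   patients.
#' @return An [atrophy_map()]; the per-parcel p-values are attached as
#'   attribute `p`.
#' @export
regional_morphometry_tmap <- function(values, group, covariates = NULL,
                                      metric = "thickness",
                                      patient_level = "AVM") {
  values <- as.matrix(values)
  g <- if (is.numeric(group)) group else as.numeric(group == patient_level)
  if (length(unique(g)) != 2) stop("group must have exactly 2 levels")
  if (min(table(g)) < 3) stop("need at least 3 subjects per group")
  design <- cbind(`(Intercept)` = 1, group = g)
  if (!is.null(covariates)) {
    design <- cbind(design, build_design(covariates)[, -1, drop = FALSE])
  }
  const <- apply(values, 2, function(v) stats::sd(v) == 0)
  tstat <- rep(NA_real_, ncol(values))
  pval <- rep(NA_real_, ncol(values))
  ok <- which(!const)
  if (length(ok)) {
    vt <- vectorized_term_test(values[, ok, drop = FALSE], design, "group")
    tstat[ok] <- vt$t
    pval[ok] <- vt$p
  }
  out <- atrophy_map(tstat, metric = metric)
  attr(out, "p") <- pval
  out
}
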