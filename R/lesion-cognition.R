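#' Total lesion load
#'
#' Aggregate lesioned voxel count divided by the total intracranial volume
#' in voxels.
#'
#' @param lesion_grid 3D logical lesion mask.
#' @param tiv_voxels total intracranial voxel count (> 0).
#' @return dimensionless scalar load.
#' @export
total_lesion_load <- function(lesion_grid, tiv_voxels) {
  if (tiv_voxels <= 0) stop("TIV must be positive")
  sum(lesion_grid) / tiv_voxels
}

#' Regional lesion proportion per parcel
#'
#' For every atlas parcel, the fraction of its voxels overlapped by the
#' lesion mask. Parcels with no voxels in the label volume are flagged NA
#' (missing), not 0.
#'
#' @param lesion_grid 3D logical lesion mask.
#' @param label_volume 3D integer parcel-label array, same shape.
#' @param atlas the [parcel_atlas()].
#' @param subject_id optional identifier.
#' @return A [lesion_profile()] (total load left at 0; see
#'   [total_lesion_load()]).
#' @export
regional_lesion_proportion <- function(lesion_grid, label_volume, atlas,
                                       subject_id = NA_character_) {
  if (!identical(dim(lesion_grid), dim(label_volume))) {
    stop("lesion mask and label volume shapes differ")
  }
  n <- n_parcels(atlas)
  sizes <- tabulate(label_volume[label_volume > 0L], nbins = n)
  hits <- tabulate(label_volume[lesion_grid & label_volume > 0L], nbins = n)
  prop <- ifelse(sizes > 0, hits / sizes, NA_real_)
  lesion_profile(prop, 0, subject_id = subject_id)
}

#' Mean intra-network structural integrity
#'
#' Mean structural edge weight over all unordered pairs of valid nodes in
#' the given parcel set (zeros count as edges of weight 0), the standard
#' proxy for preservation of the white-matter tracts supporting a
#' functional network such as the DMN.
#'
#' @param sc structural [connectivity_matrix()].
#' @param parcels parcel ids of the network (e.g. from
#'   [network_parcels()]).
#' @return scalar mean intra-network weight.
#' @export
dmn_integrity <- function(sc, parcels) {
  keep <- parcels[sc$valid[parcels]]
  if (length(keep) < 2) stop("need at least 2 valid network parcels")
  w <- sc$weights[keep, keep, drop = FALSE]
  mean(w[upper.tri(w)])
}

#' Mean lesion proportion over a network's parcels
#'
#' Size-invariant regional gray-matter damage index: the mean lesion
#' overlap fraction across the network's parcels.
#'
#' @param profile a [lesion_profile()].
#' @param parcels parcel ids of the network.
#' @return scalar in `[0, 1]`.
#' @export
dmn_local_lesion_load <- function(profile, parcels) {
  if (!length(parcels)) stop("empty parcel set")
  p <- profile$proportion[parcels]
  mean(p, na.rm = TRUE)
}

#' Control-referenced cognitive Z-scores and domain composites
#'
#' Each test is standardized against the healthy-control mean and SD;
#' latency-flagged tests (reaction times and completion times, where
#' larger raw values mean worse performance) are inverted at the z level
#' (`z -> -z`) so that higher always means better. Domain scores are the
#' mean of their constituent test z-scores; the Global domain is the mean
#' of the MMSE and MoCA z-scores.
#'
#' @param raw subjects x tests numeric matrix of raw scores (rownames =
#'   subject ids).
#' @param control_stats data.frame with columns `test`, `mean`, `sd`
#'   (healthy-control reference), or NULL to estimate from `control_ids`.
#' @param domain_map named list: domain -> character vector of test names.
#' @param latency_flags named logical vector over tests.
#' @param control_ids subject ids of the control group (used when
#'   `control_stats` is NULL).
#' @return list with `z` (subjects x tests) and `domains` (subjects x
#'   domains data.frame).
#' @export
zscore_battery <- function(raw, control_stats = NULL, domain_map,
                           latency_flags, control_ids = NULL) {
  raw <- as.matrix(raw)
  tests <- colnames(raw)
  missing_flag <- setdiff(unlist(domain_map), names(latency_flags))
  if (length(missing_flag)) {
    stop("tests without a latency flag: ", paste(missing_flag, collapse = ", "))
  }
  if (is.null(control_stats)) {
    if (is.null(control_ids)) stop("need control_stats or control_ids")
    ref <- raw[rownames(raw) %in% control_ids, , drop = FALSE]
    control_stats <- data.frame(test = tests,
                                mean = colMeans(ref),
                                sd = apply(ref, 2, stats::sd))
  }
  stats_idx <- match(tests, control_stats$test)
  if (anyNA(stats_idx)) stop("control stats missing for some tests")
  mu <- control_stats$mean[stats_idx]
  sdv <- control_stats$sd[stats_idx]
  bad <- which(sdv <= 0)
  if (length(bad)) {
    stop("zero control SD for test(s): ", paste(tests[bad], collapse = ", "))
  }
  z <- sweep(sweep(raw, 2, mu), 2, sdv, "/")
  inv <- tests[latency_flags[tests]]
  z[, inv] <- -z[, inv, drop = FALSE]
  domains <- sapply(domain_map, function(members) {
    rowMeans(z[, members, drop = FALSE])
  })
  list(z = z, domains = as.data.frame(domains, check.names = FALSE))
}

#' Residualize scores on demographic covariates
#'
#' Per-column OLS of each score on the covariates (sex coded 0/1), with
#' residuals divided by their sample SD. Residuals are exactly orthogonal
#' to every design column.
#'
#' @param scores numeric matrix/data.frame (subjects x domains).
#' @param covariates data.frame of covariates (e.g. age, sex, education).
#' @return matrix of standardized residuals.
#' @export
residualize <- function(scores, covariates) {
  scores <- as.matrix(scores)
  x <- build_design(covariates)
  if (nrow(scores) <= ncol(x)) stop("need n > number of covariates + 1")
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]], collapse = ", "))
  }
  res <- qr.resid(qrx, scores)
  sds <- apply(res, 2, stats::sd)
  if (any(sds < .Machine$double.eps^0.5)) {
    stop("residuals have (near-)zero variance for: ",
         paste(colnames(scores)[sds < .Machine$double.eps^0.5], collapse = ", "),
         " — scores are an exact function of the covariates")
  }
  sweep(res, 2, sds, "/")
}

# numeric design matrix with intercept; factors/characters (e.g. sex)
# become 0/1 dummies
build_design <- function(covariates) {
  df <- as.data.frame(covariates)
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.character(v) || is.factor(v)) {
      lv <- sort(unique(as.character(v)))
      if (length(lv) > 2) {
        m <- sapply(lv[-1], function(l) as.numeric(v == l))
        colnames(m) <- paste0(nm, lv[-1])
        m
      } else {
        m <- matrix(as.numeric(v == lv[length(lv)]), ncol = 1)
        colnames(m) <- nm
        m
      }
    } else {
      m <- matrix(as.numeric(v), ncol = 1)
      colnames(m) <- nm
      m
    }
  })
  x <- do.call(cbind, c(list(`(Intercept)` = rep(1, nrow(df))), cols))
  colnames(x)[1] <- "(Intercept)"
  x
}
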