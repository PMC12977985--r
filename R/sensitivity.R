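#' Parameter sensitivity sweep of the brain-behaviour regressions
#'
#' Re-runs the key cognition regressions over a grid of network sparsity
#' thresholds and lesion-overlap exclusion cut-offs. At each grid point
#' three predictors are recomputed per patient and regressed on the
#' cognitive composite (adjusting for age, sex and education): white-matter
#' integrity (mean intra-network edge weight of the lesion-masked,
#' unthresholded SC — thresholding applies to topology metrics, not to mean
#' edge strength), global efficiency of the masked SC thresholded at the
#' grid density, and total lesion load. A term is flagged `robust` only if
#' the sign of its coefficient and its significance status are constant
#' across the whole grid.
#'
#' @param cohort a cohort list from [gen_cohort()] (or a like-shaped list
#'   with `sc`, `lesions`, `subjects`, `atlas` and a `cognition` vector).
#' @param cognition per-subject cognitive composite; defaults to the
#'   cohort's latent composite.
#' @param density_grid sparsity thresholds (fractions of edges retained).
#' @param lesion_cutoff_grid lesion-overlap exclusion cut-offs.
#' @param network network whose integrity is the predictor of interest.
#' @param alpha significance threshold.
#' @return list with `table` (one row per grid point and term) and
#'   `robust` (named logical per term); attribute `degenerate_grid` is
#'   TRUE for a single-point grid.
#' @export
sensitivity_sweep <- function(cohort, cognition = NULL,
                              density_grid = c(0.08, 0.12, 0.16, 0.20),
                              lesion_cutoff_grid = 0.5,
                              network = "DMN", alpha = 0.05) {
  if (is.null(cognition)) cognition <- cohort$cognition_latent
  pat <- which(cohort$subjects$group == "AVM")
  net_ids <- network_parcels(cohort$atlas, network)
  covars <- cohort$subjects[pat, c("age", "sex", "education")]
  cogp <- cognition[pat]
  rows <- list()
  for (dens in density_grid) for (cut in lesion_cutoff_grid) {
    cell <- tryCatch({
      masked <- lapply(pat, function(s) {
        apply_lesion_mask(cohort$sc[[s]], cohort$lesions[[s]], cutoff = cut)
      })
      integrity <- vapply(masked, dmn_integrity, 0, parcels = net_ids)
      eff <- vapply(masked, function(m) {
        global_efficiency(proportional_threshold(m, dens))
      }, 0)
      load <- vapply(cohort$lesions[pat], function(l) l$total_lesion_load, 0)
      fit_i <- ols_fit(cogp, cbind(data.frame(integrity = integrity), covars))
      fit_e <- ols_fit(cogp, cbind(data.frame(efficiency = eff), covars))
      fit_l <- ols_fit(cogp, cbind(data.frame(lesion_load = load), covars))
      ci <- fit_i$coefficients[fit_i$coefficients$term == "integrity", ]
      ce <- fit_e$coefficients[fit_e$coefficients$term == "efficiency", ]
      cl <- fit_l$coefficients[fit_l$coefficients$term == "lesion_load", ]
      data.frame(density = dens, lesion_cutoff = cut,
                 term = c("integrity", "efficiency", "lesion_load"),
                 beta = c(ci$beta, ce$beta, cl$beta),
                 p = c(ci$p, ce$p, cl$p),
                 failed = FALSE)
    }, error = function(e) {
      data.frame(density = dens, lesion_cutoff = cut,
                 term = c("integrity", "efficiency", "lesion_load"),
                 beta = NA_real_, p = NA_real_, failed = TRUE)
    })
    rows[[length(rows) + 1]] <- cell
  }
  tab <- do.call(rbind, rows)
  tab$significant <- !is.na(tab$p) & tab$p < alpha
  robust <- vapply(split(tab, tab$term), function(d) {
    if (any(d$failed)) return(FALSE)
    length(unique(sign(d$beta))) == 1 && length(unique(d$significant)) == 1
  }, TRUE)
  out <- list(table = tab, robust = robust, alpha = alpha)
  attr(out, "degenerate_grid") <-
    length(density_grid) * length(lesion_cutoff_grid) == 1
  out
}
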