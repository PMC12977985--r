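#' Default pipeline configuration
#'
#' The configuration drives [run_pipeline()] end to end: synthetic cohort
#' parameters, network construction choices (proportional threshold
#' density, lesion exclusion cut-off), diffusion-model settings, the
#' virtual-lesion null size, and the stratified covariate lists used by
#' the statistical stage (structural models: age, sex, TIV; functional
#' models additionally mFD; cognitive models additionally education).
#'
#' @param ... overrides for any top-level field.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    synth = list(n_nodes = 90, n_patients = 20, n_controls = 20),
    density = 0.15,
    lesion_cutoff = 0.5,
    beta = 1,
    t_grid = list(from = 0, to = 10, by = 0.05),
    n_null = 1000,
    rng_seed = 1L,
    with_fc = TRUE,
    run_sweep = TRUE,
    covariates = list(
      structural = c("age", "sex", "TIV"),
      functional = c("age", "sex", "TIV", "mFD"),
      cognitive = c("age", "sex", "education")
    ),
    output_dir = NULL
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' Checks every field and aggregates problems rather than failing on the
#' first one.
#'
#' @param config a [pipeline_config()].
#' @return character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  push <- function(msg) errs <<- c(errs, msg)
  if (is.null(config$density) || config$density <= 0 || config$density > 1) {
    push("density must be in (0, 1]")
  }
  if (is.null(config$lesion_cutoff) || config$lesion_cutoff < 0 ||
      config$lesion_cutoff > 1) {
    push("lesion_cutoff must be in [0, 1]")
  }
  tg <- config$t_grid
  if (is.null(tg$from) || is.null(tg$to) || is.null(tg$by) ||
      tg$by <= 0 || tg$to <= tg$from || tg$from < 0) {
    push("t_grid must define an increasing nonnegative sequence")
  }
  if (is.null(config$beta) || config$beta <= 0) push("beta must be positive")
  if (is.null(config$n_null) || config$n_null < 1) push("n_null must be >= 1")
  if (!is.null(config$domain_map)) {
    known <- c("Executive", "Memory", "Attention/Speed", "Language", "Global")
    bad <- setdiff(names(config$domain_map), known)
    if (length(bad)) push(paste0("unknown cognitive domain(s): ",
                                 paste(bad, collapse = ", ")))
  }
  if (is.null(config$synth)) {
    # real-data mode: every input path must exist before execution starts
    for (fld in c("sc_dir", "cohort_csv")) {
      if (is.null(config[[fld]])) {
        push(paste0("real-data mode requires '", fld, "'"))
      } else if (!file.exists(config[[fld]])) {
        push(paste0(fld, " does not exist: ", config[[fld]]))
      }
    }
  } else {
    sc <- tryCatch({
      do.call(synth_config, c(config$synth,
                              list(rng_seed = config$rng_seed %||% 1L)))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(sc)) push(paste0("synth config: ", sc))
  }
  errs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: synthetic cohort generation, network
#' construction (lesion masking, thresholding), graph topology metrics,
#' structure-function coupling, group statistics (Welch/Mann-Whitney,
#' morphometry-style atrophy map, brain-behaviour regressions with OLS
#' and Huber RLM, BH-FDR), the Network Diffusion Model epicenter sweep,
#' virtual-lesion resilience of the epicenter, and the parameter
#' sensitivity sweep. Reruns with the same config and seed reproduce all
#' numbers exactly; a manifest records the seed and the report checksum.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param output_dir where to write the JSON report and TSV tables
#'   (created if needed); NULL returns results without writing.
#' @return list with `report` (nested results), `cohort`, `ndm` fit,
#'   `virtual_lesion`, and output paths when written.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = config$output_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "))
  }
  if (is.null(config$synth)) {
    stop("real-data mode is configured per study; this runner executes synthetic mode")
  }
  seed <- config$rng_seed %||% 1L
  scfg <- do.call(synth_config, c(config$synth, list(rng_seed = seed)))

  # --- stage 1: synthesize -------------------------------------------------
  cohort <- gen_cohort(scfg, with_fc = isTRUE(config$with_fc))
  atlas <- cohort$atlas
  pat <- which(cohort$subjects$group == "AVM")
  con <- which(cohort$subjects$group == "NC")

  # --- stage 2: network construction --------------------------------------
  set.seed(seed + 1L)
  sc_masked <- lapply(seq_along(cohort$sc), function(s) {
    apply_lesion_mask(cohort$sc[[s]], cohort$lesions[[s]],
                      cutoff = config$lesion_cutoff)
  })
  sc_thr <- lapply(sc_masked, proportional_threshold, density = config$density)

  # --- stage 3: topology metrics ------------------------------------------
  eff <- vapply(sc_thr, global_efficiency, 0)
  clust <- vapply(sc_thr, function(m) clustering_coefficient(m, density = 1), 0)
  metrics_tab <- data.frame(subject_id = cohort$subjects$subject_id,
                            group = cohort$subjects$group,
                            global_efficiency = eff,
                            clustering = clust)

  # --- stage 4: coupling ---------------------------------------------------
  coupling_tab <- NULL
  mean_coupling <- rep(NA_real_, nrow(cohort$subjects))
  if (!is.null(cohort$fc)) {
    profiles <- lapply(seq_along(cohort$sc), function(s) {
      sc_fc_coupling(sc_masked[[s]], cohort$fc[[s]])
    })
    mean_coupling <- vapply(profiles, function(p) mean(p$rho, na.rm = TRUE), 0)
    netm <- lapply(profiles[pat], network_mean_coupling, atlas = atlas)
    coupling_tab <- do.call(rbind, Map(cbind,
      subject_id = cohort$subjects$subject_id[pat], netm))
  }

  # --- stage 5: statistics -------------------------------------------------
  set.seed(seed + 2L)
  subj <- cohort$subjects
  age_t <- welch_t(mean(subj$age[pat]), stats::sd(subj$age[pat]), length(pat),
                   mean(subj$age[con]), stats::sd(subj$age[con]), length(con))
  sex_tab <- table(factor(subj$group, c("AVM", "NC")),
                   factor(subj$sex, c("M", "F")))
  sex_chi <- chi2_2x2(sex_tab[1, 1], sex_tab[1, 2], sex_tab[2, 1], sex_tab[2, 2])
  eff_mw <- mann_whitney(eff[pat], eff[con])

  zb <- zscore_battery(cohort$battery$raw,
                       domain_map = cohort$battery$domain_map,
                       latency_flags = cohort$battery$latency_flags,
                       control_ids = subj$subject_id[con])
  resid_scores <- residualize(zb$domains,
                              subj[, config$covariates$cognitive, drop = FALSE])
  cog <- resid_scores[, "Global"]

  net_ids <- network_parcels(atlas, "DMN")
  integrity <- vapply(sc_masked[pat], dmn_integrity, 0, parcels = net_ids)
  lesion_load <- vapply(cohort$lesions[pat], function(l) l$total_lesion_load, 0)
  dmn_load <- vapply(cohort$lesions[pat], dmn_local_lesion_load, 0,
                     parcels = net_ids)
  covars <- subj[pat, config$covariates$cognitive, drop = FALSE]
  predictors <- data.frame(integrity = integrity, lesion_load = lesion_load,
                           dmn_lesion_load = dmn_load)
  # constant predictors (e.g. saturated network lesion load in small runs)
  # carry no information and would make the design singular
  keep <- vapply(predictors, function(v) stats::sd(v) > 0, TRUE)
  predictors <- predictors[, keep, drop = FALSE]
  fit_ols <- ols_fit(cog[pat], cbind(predictors, covars))
  fit_rlm <- huber_rlm_fit(cog[pat], cbind(predictors, covars))
  fit_load <- ols_fit(cog[pat], cbind(data.frame(lesion_load = lesion_load),
                                      covars))

  # --- stage 6: NDM epicenter sweep ---------------------------------------
  set.seed(seed + 3L)
  group_sc_w <- Reduce(`+`, lapply(cohort$sc[pat], function(m) m$weights)) /
    length(pat)
  group_valid <- Reduce(`&`, lapply(sc_masked[pat], function(m) m$valid))
  group_sc <- connectivity_matrix(group_sc_w, "SC", valid = group_valid,
                                  subject_id = "group_mean_AVM")
  atrophy <- gen_atrophy_from_seed(group_sc, scfg$ndm_seed_parcel,
                                   scfg$ndm_time, noise_sd = scfg$atrophy_noise_sd)
  tg <- config$t_grid
  ndm <- ndm_fit(group_sc, atrophy, t_grid = seq(tg$from, tg$to, by = tg$by),
                 beta = config$beta)

  # --- stage 7: virtual lesion of the epicenter ---------------------------
  set.seed(seed + 4L)
  vl <- virtual_lesion(group_sc, ndm$epicenter, n_null = config$n_null)
  ranks <- node_strength_rank(group_sc)
  epi_rank <- ranks$rank[ranks$parcel_id == ndm$epicenter]

  # --- stage 8: sensitivity sweep -----------------------------------------
  sweep_res <- NULL
  if (isTRUE(config$run_sweep)) {
    sweep_res <- sensitivity_sweep(cohort, cognition = cog)
  }

  term_row <- function(fit, term) {
    r <- fit$coefficients[fit$coefficients$term == term, ]
    list(beta = r$beta, se = r$se, stat = r$stat, p = r$p)
  }
  report <- list(
    seed = seed,
    n_patients = length(pat), n_controls = length(con),
    demographics = list(age_welch = age_t, sex_chi2 = sex_chi),
    topology = list(
      efficiency_mw = eff_mw,
      mean_efficiency_avm = mean(eff[pat]),
      mean_efficiency_nc = mean(eff[con]),
      mean_clustering_avm = mean(clust[pat]),
      mean_clustering_nc = mean(clust[con])
    ),
    coupling = list(mean_coupling_avm = mean(mean_coupling[pat]),
                    mean_coupling_nc = mean(mean_coupling[con])),
    cognition = list(
      integrity_model = list(OLS = term_row(fit_ols, "integrity"),
                             HuberRLM = term_row(fit_rlm, "integrity")),
      lesion_load_model = term_row(fit_load, "lesion_load")
    ),
    ndm = list(epicenter = ndm$epicenter, t_opt = ndm$t_opt,
               r_max = ndm$r_max, seed_parcel = scfg$ndm_seed_parcel,
               epicenter_strength_rank = epi_rank,
               n_ranked = nrow(ranks)),
    virtual_lesion = list(delta_pct = vl$delta_pct, p = vl$p_value,
                          n_null = vl$n_null),
    sensitivity = if (!is.null(sweep_res)) {
      list(robust = as.list(sweep_res$robust))
    }
  )

  paths <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      report = file.path(output_dir, "report.json"),
      metrics = file.path(output_dir, "metrics.tsv"),
      ranking = file.path(output_dir, "ndm_ranking.tsv"),
      manifest = file.path(output_dir, "manifest.json")
    )
    write_report(report, paths$report)
    write_table_tsv(metrics_tab, paths$metrics)
    write_table_tsv(ndm$ranking, paths$ranking)
    if (!is.null(coupling_tab)) {
      paths$coupling <- file.path(output_dir, "coupling.tsv")
      write_table_tsv(coupling_tab, paths$coupling)
    }
    manifest <- list(seed = seed,
                     r_version = as.character(getRversion()),
                     report_md5 = unname(tools::md5sum(paths$report)))
    write_report(manifest, paths$manifest)
  }
  invisible(list(report = report, cohort = cohort, ndm = ndm,
                 virtual_lesion = vl, metrics = metrics_tab,
                 coupling = coupling_tab, sweep = sweep_res,
                 fits = list(ols = fit_ols, rlm = fit_rlm, load = fit_load),
                 paths = paths))
}
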