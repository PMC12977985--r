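#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic data generator. Defaults are the
#' study conditions the package's tests and acceptance runs use: a 90-node
#' atlas (360 supported), 44 patients vs 72 controls, distance-decay
#' structural connectivity with a rich-club-like hub boost, functional
#' connectivity statistically coupled to structure with strength `gamma`,
#' a contiguous lesion grown around a DMN parcel, an atrophy map generated
#' by forward network diffusion from a known seed, and cognitive scores
#' whose variance is driven by white-matter integrity rather than lesion
#' volume.
#'
#' @param n_nodes parcels in the synthetic atlas.
#' @param n_patients,n_controls group sizes.
#' @param sc_density target edge density of the structural connectome.
#' @param hub_fraction fraction of nodes given boosted connection odds.
#' @param coupling_strength gamma in `[0, 1]`: structural constraint on the
#'   functional signal model.
#' @param fc_noise_sd innovation SD of the linear-Gaussian functional model.
#' @param lesion_center_parcel parcel the lesion grows from (default: first
#'   DMN parcel).
#' @param lesion_extent lesion size in voxels (default 1.5 parcel volumes).
#' @param ndm_seed_parcel seed parcel for the forward diffusion atrophy map
#'   (default: the mid-atlas parcel at 54% of the id range, parcel 49 on the
#'   90-node atlas).
#' @param ndm_time diffusion time `t*` at which atrophy is read out.
#' @param atrophy_noise_sd SD of noise added to the standardized atrophy
#'   pattern (signal has unit SD, so 0.1 = 10% noise).
#' @param cog_effect slope of the cognitive composite on the white-matter
#'   integrity factor `q ~ U(0.3, 1)`.
#' @param lesion_load_effect (small) slope on total lesion load; the
#'   defaults realise the dissociation in which integrity predicts
#'   cognition and lesion volume does not.
#' @param rng_seed integer seed fixing every downstream draw.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_nodes = 90, n_patients = 44, n_controls = 72,
                         sc_density = 0.15, hub_fraction = 0.1,
                         coupling_strength = 0.6, fc_noise_sd = 1,
                         lesion_center_parcel = NULL, lesion_extent = NULL,
                         ndm_seed_parcel = NULL, ndm_time = 2.5,
                         atrophy_noise_sd = 0.1, cog_effect = 4,
                         lesion_load_effect = 0.5, rng_seed = 1) {
  cfg <- list(
    n_nodes = as.integer(n_nodes), n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls), sc_density = sc_density,
    hub_fraction = hub_fraction, coupling_strength = coupling_strength,
    fc_noise_sd = fc_noise_sd, lesion_center_parcel = lesion_center_parcel,
    lesion_extent = lesion_extent,
    ndm_seed_parcel = if (is.null(ndm_seed_parcel)) {
      max(1L, as.integer(round(0.544 * n_nodes)))
    } else as.integer(ndm_seed_parcel),
    ndm_time = ndm_time, atrophy_noise_sd = atrophy_noise_sd,
    cog_effect = cog_effect, lesion_load_effect = lesion_load_effect,
    rng_seed = as.integer(rng_seed)
  )
  if (cfg$n_nodes < 4) stop("n_nodes must be >= 4")
  if (cfg$n_patients < 2 || cfg$n_controls < 2) stop("group sizes must be >= 2")
  if (cfg$sc_density <= 0 || cfg$sc_density > 1) stop("sc_density must be in (0, 1]")
  if (cfg$hub_fraction < 0 || cfg$hub_fraction > 1) stop("hub_fraction must be in [0, 1]")
  if (cfg$coupling_strength < 0 || cfg$coupling_strength > 1) {
    stop("coupling_strength must be in [0, 1]")
  }
  if (cfg$ndm_time <= 0) stop("ndm_time must be positive")
  if (cfg$ndm_seed_parcel < 1 || cfg$ndm_seed_parcel > cfg$n_nodes) {
    stop("ndm_seed_parcel must be a parcel id in 1..n_nodes")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic structural connectome
#'
#' Nodes are placed uniformly in the unit cube; edge probability and weight
#' decay exponentially with Euclidean distance (`w = exp(-d/lambda)` times a
#' lognormal multiplier), a `hub_fraction` of nodes get boosted connection
#' probability (rich-club-like), and a minimum spanning tree over distances
#' is always added so the graph has exactly one connected component.
#'
#' @param config a [synth_config()].
#' @param lambda distance decay length.
#' @return A `SC` [connectivity_matrix()] with node coordinates attached as
#'   attribute `coords` and hub indices as attribute `hubs`.
#' @export
gen_structural_connectome <- function(config, lambda = 0.3) {
  set.seed(config$rng_seed)
  n <- config$n_nodes
  coords <- matrix(stats::runif(3 * n), n, 3)
  d <- as.matrix(stats::dist(coords))
  score <- exp(-d / lambda)
  n_hubs <- round(config$hub_fraction * n)
  hubs <- if (n_hubs > 0) sample.int(n, n_hubs) else integer(0)
  boost <- rep(1, n)
  boost[hubs] <- 3
  pscore <- score * outer(boost, boost)
  diag(pscore) <- 0
  ut <- upper.tri(pscore)
  m_possible <- sum(ut)
  target_edges <- max(1L, round(config$sc_density * m_possible))
  # scale so expected edge count hits the target density (probabilities
  # capped at 1, solved monotonically)
  s <- pscore[ut]
  f <- function(cc) sum(pmin(1, cc * s)) - target_edges
  cmax <- target_edges / sum(s) * 50 + 1
  cscale <- stats::uniroot(f, c(1e-12, max(cmax, 1 / min(s[s > 0]))))$root
  p <- pmin(1, cscale * s)
  keep <- stats::runif(m_possible) < p
  w <- matrix(0, n, n)
  mult <- exp(stats::rnorm(m_possible, 0, 0.5))
  wvals <- exp(-d[ut] / lambda) * mult
  w[ut][keep] <- wvals[keep]
  w <- w + t(w)
  # enforce a single connected component via the distance MST
  g_full <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                                weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g_full)
  me <- igraph::as_edgelist(mst, names = FALSE)
  for (r in seq_len(nrow(me))) {
    i <- me[r, 1]; j <- me[r, 2]
    if (w[i, j] == 0) {
      wij <- exp(-d[i, j] / lambda) * exp(stats::rnorm(1, 0, 0.5))
      w[i, j] <- wij
      w[j, i] <- wij
    }
  }
  out <- connectivity_matrix(w, "SC", subject_id = "template")
  attr(out, "coords") <- coords
  attr(out, "hubs") <- sort(hubs)
  out
}

# spectral radius scaling used by the functional generator
scale_spectral <- function(w, radius = 0.6) {
  sr <- max(abs(eigen(w, symmetric = TRUE, only.values = TRUE)$values))
  if (sr == 0) stop("degenerate input: zero structural matrix")
  w * (radius / sr)
}

#' Generate functional connectivity coupled to a structural connectome
#'
#' Functional connectivity is the correlation matrix of `t_len` samples
#' from the linear-Gaussian model `x = gamma * (A x) + e`, where `A` is the
#' structural matrix rescaled to spectral radius 0.6 and `e ~ N(0,
#' noise_sd^2)` i.i.d.; equivalently `x = (I - gamma A)^{-1} e`, whose
#' analytic covariance `(I-gamma A)^{-1} (I-gamma A)^{-T}` serves as an
#' oracle in tests. Node-wise structure-function coupling increases
#' monotonically with `gamma`.
#'
#' @param sc structural [connectivity_matrix()].
#' @param gamma structural constraint strength in `[0, 1]`.
#' @param noise_sd innovation SD.
#' @param t_len number of pseudo-time samples.
#' @return An `FC` [connectivity_matrix()] (zero diagonal).
#' @export
gen_functional_from_structural <- function(sc, gamma, noise_sd = 1,
                                           t_len = 500) {
  stopifnot(gamma >= 0, gamma <= 1)
  a <- scale_spectral(valid_submatrix(sc))
  n <- nrow(a)
  solve_mat <- solve(diag(n) - gamma * a)
  eps <- matrix(stats::rnorm(t_len * n, 0, noise_sd), t_len, n)
  x <- eps %*% t(solve_mat)
  fc <- stats::cor(x)
  diag(fc) <- 0
  w <- matrix(0, length(sc$valid), length(sc$valid))
  idx <- which(sc$valid)
  w[idx, idx] <- fc
  connectivity_matrix(w, "FC", valid = sc$valid, subject_id = sc$subject_id)
}

#' Grow a contiguous synthetic lesion and compute its parcel profile
#'
#' The lesion is grown from the center parcel's voxels: first the center
#' parcel is filled (breadth-first from its central voxel), then the lesion
#' expands into neighbouring brain voxels layer by layer (6-connectivity,
#' array order within a layer for determinism) until `extent` voxels are
#' covered. Extents beyond the brain are clipped with a warning.
#'
#' @param atlas a [parcel_atlas()] with a label volume.
#' @param center_parcel parcel id the lesion originates in.
#' @param extent lesion size in voxels.
#' @param tiv_voxels intracranial voxel count used for the total load
#'   (default: number of nonzero label voxels).
#' @return A [lesion_profile()]; the voxel mask is attached as attribute
#'   `mask`.
#' @export
gen_lesion_profile <- function(atlas, center_parcel, extent,
                               tiv_voxels = NULL) {
  lab <- atlas$label_volume
  if (is.null(lab)) stop("atlas has no label volume")
  n <- n_parcels(atlas)
  if (!(center_parcel %in% seq_len(n))) stop("invalid center parcel")
  dims <- dim(lab)
  brain <- which(lab > 0L)
  if (is.null(tiv_voxels)) tiv_voxels <- length(brain)
  if (extent > length(brain)) {
    warning("lesion extent exceeds brain size; clipping")
    extent <- length(brain)
  }
  center_vox <- which(lab == center_parcel)
  # voxel linear index -> 3D coords
  to_xyz <- function(v) {
    v0 <- v - 1L
    cbind(v0 %% dims[1], (v0 %/% dims[1]) %% dims[2],
          v0 %/% (dims[1] * dims[2])) + 1L
  }
  manh <- function(v, ctr) rowSums(abs(to_xyz(v) -
                                         matrix(ctr, length(v), 3, byrow = TRUE)))
  ctr <- round(colMeans(to_xyz(center_vox)))
  # phase 1: fill the center parcel outward from its central voxel
  ord <- center_vox[order(manh(center_vox, ctr), center_vox)]
  lesion <- ord[seq_len(min(extent, length(ord)))]
  # phase 2: BFS layers into the rest of the brain
  if (extent > length(lesion)) {
    in_lesion <- logical(prod(dims))
    in_lesion[lesion] <- TRUE
    eligible <- logical(prod(dims))
    eligible[brain] <- TRUE
    frontier <- lesion
    strides <- c(1L, -1L, dims[1], -dims[1], dims[1] * dims[2],
                 -dims[1] * dims[2])
    while (length(lesion) < extent && length(frontier)) {
      xyz <- to_xyz(frontier)
      nbrs <- integer(0)
      for (s in seq_along(strides)) {
        ax <- (s + 1L) %/% 2L  # axis 1..3
        cand <- frontier + strides[s]
        # stay inside the grid along the shifted axis
        coord <- xyz[, ax] + ifelse(s %% 2L == 1L, 1L, -1L)
        ok <- coord >= 1L & coord <= dims[ax]
        nbrs <- c(nbrs, cand[ok])
      }
      nbrs <- sort(unique(nbrs))
      nbrs <- nbrs[eligible[nbrs] & !in_lesion[nbrs]]
      if (!length(nbrs)) break
      take <- nbrs[seq_len(min(extent - length(lesion), length(nbrs)))]
      in_lesion[take] <- TRUE
      lesion <- c(lesion, take)
      frontier <- take
    }
  }
  mask <- array(FALSE, dim = dims)
  mask[lesion] <- TRUE
  prof <- regional_lesion_proportion(mask, lab, atlas)
  prof$total_lesion_load <- total_lesion_load(mask, tiv_voxels)
  attr(prof, "mask") <- mask
  prof
}

#' Generate an atrophy map by forward network diffusion
#'
#' Diffuses a unit impulse at `seed_parcel` over the structural connectome
#' for time `t_star` (heat kernel on the normalized Laplacian), standardizes
#' the pattern to zero mean / unit variance over valid nodes, and adds
#' `N(0, noise_sd^2)` noise. With `noise_sd = 0` the epicenter sweep
#' recovers the seed exactly.
#'
#' @param sc structural [connectivity_matrix()].
#' @param seed_parcel seed node (must be valid).
#' @param t_star diffusion time.
#' @param noise_sd noise SD on the standardized (unit-variance) scale.
#' @param beta diffusion constant.
#' @return An [atrophy_map()].
#' @export
gen_atrophy_from_seed <- function(sc, seed_parcel, t_star, noise_sd = 0,
                                  beta = 1) {
  idx <- which(sc$valid)
  if (!(seed_parcel %in% idx)) stop("seed parcel is not a valid node")
  lap <- normalized_laplacian(sc)
  x0 <- as.numeric(idx == seed_parcel)
  xt <- diffuse(lap, x0, beta = beta, t = t_star)
  z <- (xt - mean(xt)) / stats::sd(xt)
  z <- z + stats::rnorm(length(z), 0, noise_sd)
  tstat <- rep(NA_real_, length(sc$valid))
  tstat[idx] <- z
  atrophy_map(tstat, metric = "synthetic_diffusion",
              sign_convention = "positive = greater simulated burden")
}

#' Generate a full synthetic cohort
#'
#' Controls receive the template structural connectome perturbed by
#' subject-level lognormal edge noise; patients additionally have their
#' intra-lesion-network edges (the canonical network containing the lesion
#' center, DMN by default) attenuated by a subject-specific white-matter
#' integrity factor `q ~ U(0.3, 1)`. The cognitive composite is
#' `cog_effect * q + lesion_load_effect * total lesion load + demographic
#' terms + N(0,1)`, so that regressions on integrity are significant while
#' regressions on lesion volume are not — the dissociation the analysis is
#' designed to detect. Raw neuropsychological test scores are derived from
#' the composite per domain (latency tests recorded on an inverted scale).
#'
#' @param config a [synth_config()].
#' @param with_fc also simulate per-subject functional connectivity
#'   (set `FALSE` to skip the most expensive stage in replicate studies).
#' @return A list with elements `atlas`, `subjects` (data.frame),
#'   `sc`/`fc` (lists of [connectivity_matrix()]), `lesions` (list of
#'   [lesion_profile()]), `integrity` (named q factors, 1 for controls),
#'   `battery` (raw scores, domain map, latency flags), `template_sc`,
#'   and `config`.
#' @export
gen_cohort <- function(config = synth_config(), with_fc = TRUE) {
  atlas <- synthetic_atlas(config$n_nodes)
  template <- gen_structural_connectome(config)  # seeds the RNG stream
  dmn <- network_parcels(atlas, "DMN")
  center <- config$lesion_center_parcel
  if (is.null(center)) center <- dmn[1]
  lesion_net <- atlas$parcels$network[center]
  net_ids <- network_parcels(atlas, lesion_net)
  parcel_vol <- atlas$parcels$node_volume[center]
  base_extent <- config$lesion_extent
  if (is.null(base_extent)) base_extent <- round(1.5 * parcel_vol)

  n_pat <- config$n_patients
  n_con <- config$n_controls
  n_tot <- n_pat + n_con
  ids <- sprintf("S%03d", seq_len(n_tot))
  group <- c(rep("AVM", n_pat), rep("NC", n_con))

  # demographics emulate the study cohort's profile
  age <- round(c(stats::rnorm(n_pat, 40.3, 13.2), stats::rnorm(n_con, 45.7, 14.9)), 1)
  age <- pmax(age, 18)
  sex <- c(sample(c("M", "F"), n_pat, TRUE, prob = c(0.57, 0.43)),
           sample(c("M", "F"), n_con, TRUE, prob = c(0.40, 0.60)))
  education <- round(pmax(c(stats::rnorm(n_pat, 11.3, 4.4),
                            stats::rnorm(n_con, 13.0, 2.8)), 2))
  mfd <- round(exp(stats::rnorm(n_tot, log(0.12), 0.3)), 4)
  tiv_vox <- round(stats::rnorm(n_tot, 1.1, 0.08) * sum(atlas$label_volume > 0))
  seizure <- c(stats::runif(n_pat) < 0.16, rep(FALSE, n_con))
  sm_grade <- c(sample(1:4, n_pat, TRUE, prob = c(0.3, 0.35, 0.25, 0.1)),
                rep(NA_integer_, n_con))

  q <- c(stats::runif(n_pat, 0.3, 1), rep(1, n_con))
  names(q) <- ids

  w0 <- template$weights
  n <- config$n_nodes
  ut <- upper.tri(w0)
  sc_list <- vector("list", n_tot)
  lesions <- vector("list", n_tot)
  extents <- pmax(8L, round(base_extent * stats::runif(n_pat, 0.4, 1.6)))
  for (s in seq_len(n_tot)) {
    noise <- matrix(0, n, n)
    noise[ut] <- exp(stats::rnorm(sum(ut), 0, 0.1))
    noise <- noise + t(noise)
    w <- w0 * noise
    if (group[s] == "AVM") {
      w[net_ids, net_ids] <- w[net_ids, net_ids] * q[s]
      lesions[[s]] <- gen_lesion_profile(atlas, center, extents[s],
                                         tiv_voxels = tiv_vox[s])
      lesions[[s]]$subject_id <- ids[s]
    } else {
      lesions[[s]] <- lesion_profile(rep(0, n), 0, subject_id = ids[s])
    }
    sc_list[[s]] <- connectivity_matrix(w, "SC", subject_id = ids[s])
  }

  fc_list <- NULL
  if (with_fc) {
    fc_list <- lapply(sc_list, gen_functional_from_structural,
                      gamma = config$coupling_strength,
                      noise_sd = config$fc_noise_sd)
  }

  lesion_load <- vapply(lesions, function(l) l$total_lesion_load, 0)
  cog <- config$cog_effect * q +
    config$lesion_load_effect * lesion_load -
    0.02 * (age - 43) + 0.05 * (education - 12) +
    stats::rnorm(n_tot, 0, 1)

  battery <- gen_battery(cog, ids)

  subjects <- data.frame(
    subject_id = ids, group = group, age = age, sex = sex,
    education = education, mFD = mfd, TIV = tiv_vox, seizure = seizure,
    sm_grade = sm_grade, stringsAsFactors = FALSE
  )
  list(atlas = atlas, subjects = subjects, sc = sc_list, fc = fc_list,
       lesions = lesions, integrity = q, battery = battery,
       template_sc = template, cognition_latent = cog, config = config)
}

# raw neuropsychological scores linked to the latent composite; latency
# tests (Trail Making) are emitted on an inverted (time) scale
gen_battery <- function(cog, ids) {
  tests <- data.frame(
    test = c("MMSE", "MoCA", "Stroop", "VerbalFluency", "DigitOrdering",
             "AVLT_DelayedRecall", "SDMT", "TrailMaking", "BostonNaming"),
    mu = c(27, 25, 45, 18, 10, 8, 50, 60, 24),
    sigma = c(2, 3, 8, 5, 3, 3, 10, 20, 4),
    latency = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  z <- scale(cog)[, 1]
  raw <- sapply(seq_len(nrow(tests)), function(k) {
    signal <- 0.7 * z + 0.3 * stats::rnorm(length(z))
    if (tests$latency[k]) signal <- -signal
    tests$mu[k] + tests$sigma[k] * signal
  })
  colnames(raw) <- tests$test
  rownames(raw) <- ids
  domain_map <- list(
    Executive = c("Stroop", "VerbalFluency", "DigitOrdering"),
    Memory = "AVLT_DelayedRecall",
    `Attention/Speed` = c("SDMT", "TrailMaking"),
    Language = c("BostonNaming", "VerbalFluency"),
    Global = c("MMSE", "MoCA")
  )
  latency_flags <- stats::setNames(tests$latency, tests$test)
  list(raw = raw, domain_map = domain_map, latency_flags = latency_flags)
}
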