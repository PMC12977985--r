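test_that("structural generator is seed-deterministic, connected, and hub-boosted", {
  cfg <- synth_config(n_nodes = 20, sc_density = 0.2, rng_seed = 1)
  a <- gen_structural_connectome(cfg)
  b <- gen_structural_connectome(cfg)
  expect_identical(a$weights, b$weights)

  # single connected component by construction, any config
  for (seed in 1:3) {
    cfg2 <- synth_config(n_nodes = 25, sc_density = 0.05, rng_seed = seed)
    w <- gen_structural_connectome(cfg2)$weights
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    expect_equal(igraph::components(g)$no, 1)
  }

  # hub boost: top-decile strength nodes have higher mean degree
  cfg3 <- synth_config(n_nodes = 60, sc_density = 0.15, hub_fraction = 0.1,
                       rng_seed = 4)
  sc <- gen_structural_connectome(cfg3)
  strength <- rowSums(sc$weights)
  degree <- rowSums(sc$weights > 0)
  top <- strength >= stats::quantile(strength, 0.9)
  expect_gt(mean(degree[top]), mean(degree[!top]))
})

test_that("functional generator: zero diagonal, gamma = 0 null, monotone coupling", {
  cfg <- synth_config(n_nodes = 30, rng_seed = 6)
  sc <- gen_structural_connectome(cfg)
  set.seed(10)
  fc0 <- gen_functional_from_structural(sc, gamma = 0)
  expect_identical(diag(fc0$weights), rep(0, 30))
  expect_lt(abs(mean(fc0$weights[upper.tri(fc0$weights)])), 0.02)

  set.seed(10)
  c_lo <- mean(sc_fc_coupling(sc, gen_functional_from_structural(sc, 0.3))$rho,
               na.rm = TRUE)
  set.seed(10)
  c_hi <- mean(sc_fc_coupling(sc, gen_functional_from_structural(sc, 0.9))$rho,
               na.rm = TRUE)
  expect_gt(c_hi, c_lo)

  zero <- cm(matrix(0, 4, 4))
  expect_error(gen_functional_from_structural(zero, 0.5), "degenerate")
})

test_that("lesion growth covers the requested extent with exact voxel conservation", {
  atlas <- synthetic_atlas(27)
  vol <- atlas$parcels$node_volume[1]

  # full center parcel only
  prof <- gen_lesion_profile(atlas, center_parcel = 14, extent = vol)
  expect_equal(prof$proportion[14], 1)
  expect_equal(sum(prof$proportion[-14]), 0)

  # half the center parcel
  half <- gen_lesion_profile(atlas, 14, extent = vol / 2)
  expect_equal(half$proportion[14], 0.5, tolerance = 1 / vol)

  # conservation: parcel-weighted proportions sum to the lesion voxel count
  big <- gen_lesion_profile(atlas, 14, extent = 3 * vol)
  mask <- attr(big, "mask")
  expect_equal(sum(round(big$proportion * atlas$parcels$node_volume)),
               sum(mask))
  expect_true(all(big$proportion >= 0 & big$proportion <= 1))

  # extent beyond the brain is clipped with a warning
  expect_warning(huge <- gen_lesion_profile(atlas, 14, extent = 1e6), "clipping")
  expect_equal(sum(attr(huge, "mask")), sum(atlas$label_volume > 0))
  expect_error(gen_lesion_profile(atlas, 999, 10), "invalid center")
})

test_that("atrophy noise degrades epicenter recovery monotonically", {
  cfg <- synth_config(n_nodes = 40, rng_seed = 8)
  sc <- gen_structural_connectome(cfg)
  rates <- vapply(c(0, 0.3, 3), function(ns) {
    hits <- vapply(1:15, function(r) {
      set.seed(500 + r)
      at <- gen_atrophy_from_seed(sc, 20, 2.5, noise_sd = ns)
      ndm_fit(sc, at, t_grid = seq(0, 6, by = 0.5))$epicenter == 20
    }, TRUE)
    mean(hits)
  }, 0)
  expect_true(all(diff(rates) <= 0))
  expect_equal(rates[1], 1)
})

test_that("cohort generator is deterministic with the configured group structure", {
  cfg <- synth_config(n_nodes = 30, n_patients = 5, n_controls = 7, rng_seed = 2)
  co <- gen_cohort(cfg, with_fc = FALSE)
  expect_identical(as.integer(table(co$subjects$group)[c("AVM", "NC")]), c(5L, 7L))
  expect_length(co$sc, 12)
  expect_length(co$lesions, 12)
  # controls intact (q = 1), patients attenuated (q < 1)
  expect_true(all(co$integrity[co$subjects$group == "NC"] == 1))
  expect_true(all(co$integrity[co$subjects$group == "AVM"] < 1))
  # controls carry no lesion
  expect_true(all(vapply(co$lesions[co$subjects$group == "NC"],
                         function(l) l$total_lesion_load, 0) == 0))

  co2 <- gen_cohort(cfg, with_fc = FALSE)
  expect_identical(co$subjects, co2$subjects)
  expect_identical(co$sc[[3]]$weights, co2$sc[[3]]$weights)
  expect_identical(co$battery$raw, co2$battery$raw)

  # patient SC is the template attenuated inside the lesioned network:
  # intra-network integrity correlates with q across patients
  dmn <- network_parcels(co$atlas, "DMN")
  pat <- which(co$subjects$group == "AVM")
  integ <- vapply(co$sc[pat], dmn_integrity, 0, parcels = dmn)
  expect_gt(stats::cor(integ, co$integrity[pat]), 0.9)
})
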