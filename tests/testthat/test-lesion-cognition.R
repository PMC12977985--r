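test_that("total lesion load is an aggregate voxel fraction", {
  grid <- array(FALSE, c(10, 10, 10))
  grid[1:50] <- TRUE
  expect_equal(total_lesion_load(grid, 1000), 0.05)
  expect_equal(total_lesion_load(array(FALSE, c(5, 5, 5)), 100), 0)
  # two disjoint lesions aggregate
  g2 <- array(FALSE, c(10, 10, 10))
  g2[1:30] <- TRUE; g2[501:520] <- TRUE
  expect_equal(total_lesion_load(g2, 1000), 0.05)
  expect_error(total_lesion_load(grid, 0), "positive")
})

test_that("regional lesion proportion is exact per parcel and flags missing parcels", {
  atlas <- synthetic_atlas(8)
  lab <- atlas$label_volume
  mask <- array(FALSE, dim(lab))
  mask[lab == 3L] <- TRUE                     # parcel 3 fully covered
  p2vox <- which(lab == 2L)
  mask[p2vox[1:32]] <- TRUE                   # half of parcel 2 (64 voxels)
  prof <- regional_lesion_proportion(mask, lab, atlas)
  expect_equal(prof$proportion[3], 1)
  expect_equal(prof$proportion[2], 0.5)
  expect_equal(sum(prof$proportion[-c(2, 3)]), 0)

  # lesion entirely in background
  bg <- array(FALSE, dim(lab))
  bg[lab == 0L] <- TRUE
  expect_equal(sum(regional_lesion_proportion(bg, lab, atlas)$proportion), 0)

  # a parcel absent from the label volume is NA, not 0
  lab9 <- lab; lab9[lab9 == 5L] <- 0L
  atlas9 <- atlas; atlas9$label_volume <- lab9
  prof9 <- regional_lesion_proportion(mask, lab9, atlas9)
  expect_true(is.na(prof9$proportion[5]))

  expect_error(regional_lesion_proportion(array(FALSE, c(2, 2, 2)), lab, atlas),
               "shapes differ")
})

test_that("network integrity is the mean intra-network edge weight over valid pairs", {
  w <- matrix(0, 5, 5)
  dmn <- c(1, 2, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[1, 3] <- w[3, 1] <- 3
  # pair (2,3) has weight 0 and still counts
  sc <- cm(w)
  expect_equal(dmn_integrity(sc, dmn), (1 + 3 + 0) / 3)

  # one excluded node restricts to the remaining pairs
  sc2 <- cm(w, valid = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(dmn_integrity(sc2, dmn), 1)
  expect_error(dmn_integrity(sc2, c(1, 3)), "at least 2")

  # attenuating any intra-network edge never increases integrity
  set.seed(9)
  wr <- random_weighted_graph(6, p = 1)
  base <- dmn_integrity(cm(wr), 1:4)
  wr2 <- wr; wr2[1, 2] <- wr2[2, 1] <- wr[1, 2] * 0.5
  expect_lt(dmn_integrity(cm(wr2), 1:4), base)
})

test_that("network-local lesion load is the mean parcel proportion", {
  prof <- lesion_profile(c(0.2, 0.4, 0, 0))
  expect_equal(dmn_local_lesion_load(prof, c(1, 2)), 0.3)
  expect_equal(dmn_local_lesion_load(lesion_profile(rep(0, 4)), 1:4), 0)
  expect_equal(dmn_local_lesion_load(lesion_profile(rep(1, 4)), 1:4), 1)
  expect_error(dmn_local_lesion_load(prof, integer(0)), "empty")
})

test_that("z-scoring is control-referenced with latency inversion and domain means", {
  raw <- rbind(S1 = c(T1 = 10, T2 = 20, MMSE = 28, MoCA = 26),
               S2 = c(T1 = 12, T2 = 30, MMSE = 26, MoCA = 24))
  stats_df <- data.frame(test = c("T1", "T2", "MMSE", "MoCA"),
                         mean = c(10, 20, 27, 25), sd = c(2, 10, 2, 2))
  dm <- list(Executive = c("T1", "T2"), Global = c("MMSE", "MoCA"))
  lf <- c(T1 = FALSE, T2 = TRUE, MMSE = FALSE, MoCA = FALSE)
  zb <- zscore_battery(raw, stats_df, dm, lf)
  expect_equal(zb$z["S1", "T1"], 0)          # raw at control mean
  expect_equal(zb$z["S2", "T2"], -1)         # one SD slower, inverted
  expect_equal(zb$domains["S1", "Global"], (0.5 + 0.5) / 2)
  expect_equal(zb$domains["S2", "Executive"], (1 - 1) / 2)

  bad <- stats_df; bad$sd[2] <- 0
  expect_error(zscore_battery(raw, bad, dm, lf), "T2")
  expect_error(zscore_battery(raw, stats_df, dm, lf[-2]), "latency")

  # NC self-standardization: mean 0 / sd 1 per test by construction
  set.seed(44)
  big <- matrix(rnorm(40, 10, 3), 10, 4,
                dimnames = list(paste0("C", 1:10), names(lf)))
  zb2 <- zscore_battery(big, domain_map = dm, latency_flags = lf,
                        control_ids = rownames(big))
  expect_equal(unname(colMeans(zb2$z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(zb2$z, 2, sd)), c(1, 1, 1, 1), tolerance = 1e-12)
})

test_that("residualization produces SD-1 residuals orthogonal to the design", {
  set.seed(54)
  n <- 60
  cov <- data.frame(age = rnorm(n, 45, 12), sex = sample(c("M", "F"), n, TRUE),
                    education = rnorm(n, 12, 3))
  scores <- cbind(Global = 2 * cov$age + rnorm(n),
                  Memory = rnorm(n))
  res <- residualize(scores, cov)
  expect_lt(abs(cor(res[, "Global"], cov$age)), 1e-10)
  expect_lt(abs(cor(res[, "Global"], as.numeric(cov$sex == "M"))), 1e-10)
  expect_equal(unname(apply(res, 2, sd)), c(1, 1))

  # exact linear function of the covariates: clear degenerate error
  exact <- cbind(Global = 3 * cov$age - 1)
  expect_error(residualize(exact, cov), "zero variance")

  # collinear design is reported
  cov2 <- cov; cov2$age2 <- 2 * cov$age
  expect_error(residualize(scores, cov2), "collinear")
})
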