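test_that("Pearson FC has the forced closed-form values", {
  set.seed(1)
  base <- rnorm(50)
  ts <- cbind(base, base, -base, rnorm(50))
  fc <- build_fc(ts)
  expect_equal(fc$weights[1, 2], 1)
  expect_equal(fc$weights[1, 3], -1)
  expect_identical(diag(fc$weights), rep(0, 4))
  expect_equal(fc$weights, t(fc$weights))
})

test_that("independent time series give near-zero FC and constant columns are masked", {
  set.seed(7)
  ts <- matrix(rnorm(100 * 8), 100, 8)
  fc <- build_fc(ts)
  off <- abs(fc$weights[upper.tri(fc$weights)])
  expect_lt(mean(off), 0.2)

  ts[, 3] <- 5  # zero variance
  fc2 <- build_fc(ts)
  expect_false(fc2$valid[3])
  expect_true(all(fc2$valid[-3]))
  expect_false(anyNA(fc2$weights))
  expect_error(build_fc(ts[1:2, ]), "3 time points")
})

test_that("inverse-node-volume normalization divides by summed endpoint volumes", {
  counts <- matrix(0, 3, 3)
  counts[1, 2] <- counts[2, 1] <- 10
  sc <- normalize_sc_invnodevol(counts, c(2, 3, 4))
  expect_equal(sc$weights[1, 2], 2)  # 10 / (2 + 3)

  # homogeneity: doubling volumes halves every edge
  set.seed(3)
  raw <- random_weighted_graph(6)
  vols <- runif(6, 1, 5)
  a <- normalize_sc_invnodevol(raw, vols)
  b <- normalize_sc_invnodevol(raw, 2 * vols)
  expect_equal(b$weights, a$weights / 2)

  expect_equal(normalize_sc_invnodevol(matrix(0, 3, 3), c(1, 1, 1))$weights,
               matrix(0, 3, 3))
  expect_error(normalize_sc_invnodevol(counts, c(0, 1, 1)), "positive")
})

test_that("lesion masking excludes nodes at the inclusive overlap boundary", {
  m <- cm(complete_graph(4))
  prof <- lesion_profile(c(0, 0.49, 0.5, 1.0))
  masked <- apply_lesion_mask(m, prof, cutoff = 0.5)
  expect_identical(masked$valid, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(attr(masked, "n_excluded"), 2L)

  # all-zero lesion: identity
  clean <- apply_lesion_mask(m, lesion_profile(rep(0, 4)))
  expect_identical(clean$valid, rep(TRUE, 4))

  # cutoff above 1 keeps every touched parcel; cutoff 0 excludes them all
  expect_true(all(apply_lesion_mask(m, prof, cutoff = 1.01)$valid))
  expect_error(apply_lesion_mask(m, lesion_profile(rep(1, 4))), "empty network")
})

test_that("proportional thresholding keeps exactly the top-k edges with a deterministic tie-break", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 6; w[1, 3] <- 5; w[1, 4] <- 4; w[2, 3] <- 3; w[2, 4] <- 2; w[3, 4] <- 1
  w <- w + t(w)
  m <- cm(w)
  thr <- proportional_threshold(m, 1 / 3)  # ceil(6/3) = 2 edges survive
  kept <- which(thr$weights > 0, arr.ind = TRUE)
  expect_equal(sum(thr$weights[upper.tri(thr$weights)] > 0), 2)
  expect_equal(thr$weights[1, 2], 6)
  expect_equal(thr$weights[1, 3], 5)

  # density 1 is the identity; thresholding is idempotent
  expect_equal(proportional_threshold(m, 1)$weights, w)
  expect_equal(proportional_threshold(thr, 1 / 3)$weights, thr$weights)

  # tie at the cutoff: lexicographically smaller (i, j) wins
  wt <- matrix(0, 4, 4)
  wt[1, 2] <- 5; wt[1, 3] <- 3; wt[2, 4] <- 3; wt[3, 4] <- 1
  wt <- wt + t(wt)
  thr2 <- proportional_threshold(cm(wt), 2 / 6)
  expect_equal(thr2$weights[1, 3], 3)
  expect_equal(thr2$weights[2, 4], 0)

  expect_error(proportional_threshold(m, 0), "density")
  expect_error(proportional_threshold(m, 1.2), "density")
})

test_that("surviving edge count equals ceiling(density * M) on random graphs", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(6:15, 1)
    w <- random_weighted_graph(n, p = 1)  # fully weighted
    dens <- runif(1, 0.1, 0.9)
    thr <- proportional_threshold(cm(w), dens)
    m_possible <- n * (n - 1) / 2
    expect_equal(sum(thr$weights[upper.tri(thr$weights)] > 0),
                 ceiling(dens * m_possible))
  }
})

test_that("FC sampled from the analytic covariance matches the generator oracle", {
  cfg <- synth_config(n_nodes = 30, rng_seed = 5)
  sc <- gen_structural_connectome(cfg)
  gamma <- 0.6
  a <- avmnet:::scale_spectral(sc$weights)
  s <- solve(diag(30) - gamma * a)
  sigma <- s %*% t(s)
  r_true <- stats::cov2cor(sigma)
  set.seed(99)
  fc <- gen_functional_from_structural(sc, gamma, t_len = 500)
  ut <- upper.tri(r_true)
  # Fisher-z residuals should be on the sampling-error scale, SE ~ 1/sqrt(T-3)
  zdiff <- atanh(pmin(pmax(fc$weights[ut], -0.999), 0.999)) - atanh(r_true[ut])
  expect_lt(mean(abs(zdiff)), 3 / sqrt(500 - 3))
})
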