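test_that("Welch t from summaries: hand case and Student-t reduction", {
  # hand formula: t = (1 - 2) / sqrt(1/5 + 1/5) = -1.5811, df = 8
  r <- welch_t(1, 1, 5, 2, 1, 5)
  expect_equal(r$t, -1 / sqrt(0.4), tolerance = 1e-10)
  expect_equal(r$df, 8)

  # identical summaries
  same <- welch_t(3, 1.5, 10, 3, 1.5, 12)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # equal SDs and ns: identical to pooled Student t (algebraic identity)
  w <- welch_t(0.3, 1.2, 20, -0.1, 1.2, 20)
  pooled_t <- (0.3 - -0.1) / (1.2 * sqrt(2 / 20))
  expect_equal(w$t, pooled_t, tolerance = 1e-12)
  expect_equal(w$df, 38)

  expect_error(welch_t(1, 0, 5, 2, 0, 5), "zero SD")
  expect_error(welch_t(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("2x2 chi-square uses Yates correction by default", {
  flat <- chi2_2x2(10, 10, 10, 10)
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  prop <- chi2_2x2(20, 10, 40, 20)  # identical row proportions
  expect_equal(prop$chi2, 0)

  # Yates vs uncorrected differ
  y <- chi2_2x2(25, 19, 29, 43)
  u <- chi2_2x2(25, 19, 29, 43, yates = FALSE)
  expect_gt(u$chi2, y$chi2)
  expect_error(chi2_2x2(0, 0, 5, 5), "marginal")
})

test_that("Mann-Whitney: exact enumeration for separated small samples", {
  r <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_true(r$U %in% c(0, 9))
  expect_equal(r$p, 2 / 20)  # 2 of the C(6,3) = 20 orderings are as extreme

  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_lt(abs(same$Z), 0.5)
  expect_gt(same$p, 0.9)

  expect_warning(tied <- mann_whitney(rep(5, 4), rep(5, 6)), "tied")
  expect_equal(tied$p, 1)

  # large shifted normals: decisive rejection
  set.seed(64)
  x <- rnorm(50); y <- rnorm(50) + 1
  expect_lt(mann_whitney(x, y)$p, 0.01)
})

test_that("Shapiro-Wilk adapter enforces its domain", {
  set.seed(74)
  ok <- shapiro_wilk(rnorm(100))
  expect_true(ok$W > 0 && ok$W <= 1)
  expect_lt(shapiro_wilk(rexp(100))$p, 0.05)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(1, 10)))
})

test_that("OLS: exact line, adjusted R2, standardized betas, rank check", {
  x <- data.frame(x = 1:10)
  fit <- ols_fit(2 * (1:10) + 1, x)
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-12)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-12)

  set.seed(84)
  n <- 100
  xx <- rnorm(n); y <- 3 * xx + rnorm(n)
  fs <- ols_fit(y, data.frame(x = xx), standardized = TRUE)
  # standardized beta equals the sample correlation for a single predictor
  expect_equal(unname(coef(fs)["x"]), cor(y, xx), tolerance = 1e-10)

  expect_error(ols_fit(y, data.frame(a = xx, b = 2 * xx)), "collinear")
})

test_that("OLS matches summary.lm term statistics", {
  set.seed(94)
  d <- data.frame(x1 = rnorm(40), x2 = rnorm(40), sex = sample(c("M", "F"), 40, TRUE))
  y <- 1 + 0.5 * d$x1 + rnorm(40)
  fit <- ols_fit(y, d)
  ref <- summary(lm(y ~ x1 + x2 + I(sex == "M"), data = d))
  expect_equal(unname(fit$coefficients$beta[2]), unname(ref$coefficients["x1", 1]),
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients$p[2]), unname(ref$coefficients["x1", 4]),
               tolerance = 1e-10)
  expect_equal(fit$adj_r2, ref$adj.r.squared, tolerance = 1e-10)
})

test_that("Huber RLM: exact line, OLS limit at huge c, outlier resistance case", {
  x <- data.frame(x = 1:10)
  exact <- huber_rlm_fit(2 * (1:10) + 1, x)
  expect_equal(unname(coef(exact)), c(1, 2), tolerance = 1e-10)

  set.seed(104)
  n <- 80
  xx <- rnorm(n); y <- 2 * xx + rnorm(n)
  big_c <- huber_rlm_fit(y, data.frame(x = xx), c = 1e6)
  ols <- ols_fit(y, data.frame(x = xx))
  expect_equal(unname(coef(big_c)), unname(coef(ols)), tolerance = 1e-6)

  # one gross outlier: Huber slope closer to truth than OLS
  y2 <- y; y2[1] <- y2[1] + 50
  rob <- huber_rlm_fit(y2, data.frame(x = xx))
  ols2 <- ols_fit(y2, data.frame(x = xx))
  expect_lt(abs(coef(rob)["x"] - 2), abs(coef(ols2)["x"] - 2))
  expect_true(rob$converged)
})

test_that("BH-FDR: hand-computed step-up example and invariants", {
  r <- bh_fdr(c(0.01, 0.02, 0.04))
  expect_equal(r$adjusted, c(0.03, 0.03, 0.04))
  expect_identical(r$reject, c(TRUE, TRUE, TRUE))

  expect_equal(bh_fdr(0.03)$adjusted, 0.03)
  expect_equal(bh_fdr(rep(0.2, 5))$adjusted, rep(0.2, 5))

  set.seed(114)
  p <- runif(50)
  adj <- bh_fdr(p)$adjusted
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in raw p
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("edgewise comparison recovers a planted edge effect and behaves under the null", {
  make_fc <- function(base, shift_edge = NULL, shift = 0) {
    w <- base + matrix(rnorm(length(base), 0, 0.05), nrow(base))
    w <- (w + t(w)) / 2
    if (!is.null(shift_edge)) {
      w[shift_edge[1], shift_edge[2]] <- w[shift_edge[1], shift_edge[2]] + shift
      w[shift_edge[2], shift_edge[1]] <- w[shift_edge[1], shift_edge[2]]
    }
    w <- pmin(pmax(w, -0.9), 0.9)
    diag(w) <- 0
    cm(w, "FC")
  }
  set.seed(124)
  base <- random_weighted_graph(12, p = 1) / 4

  # null: identically generated groups -> mean T near zero
  pats <- lapply(1:15, function(i) make_fc(base))
  cons <- lapply(1:15, function(i) make_fc(base))
  res0 <- edgewise_group_ttest(pats, cons, k = 10)
  expect_lt(abs(mean(res0$edges$t)), 0.15)

  # planted +0.3 (Fisher z) shift in patients at edge (2, 5)
  hit <- replicate(20, {
    pats <- lapply(1:15, function(i) make_fc(base, c(2, 5), tanh(0.3)))
    cons <- lapply(1:15, function(i) make_fc(base))
    res <- edgewise_group_ttest(pats, cons, k = 10)
    any(res$hyper$i == 2 & res$hyper$j == 5)
  })
  expect_gte(mean(hit), 0.95)

  expect_warning(edgewise_group_ttest(pats, cons, k = 1e5), "exceeds")
  expect_error(edgewise_group_ttest(pats[1:2], cons), "3 subjects")
})

test_that("aggregate edge strength averages the designated edges", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.4; w[3, 4] <- w[4, 3] <- 0.8
  fc <- cm(w, "FC")
  expect_equal(aggregate_edge_strength(fc, data.frame(i = 1, j = 2)), 0.4)
  expect_equal(aggregate_edge_strength(fc, data.frame(i = c(1, 3), j = c(2, 4))), 0.6)
  expect_error(aggregate_edge_strength(fc, data.frame(i = integer(), j = integer())),
               "empty")
})

test_that("morphometry t-map recovers planted thinning and removes TIV confounds", {
  set.seed(134)
  n_par <- 20; n_sub <- 30
  group <- rep(c(1, 0), each = n_sub / 2)
  hits <- replicate(20, {
    vals <- matrix(rnorm(n_sub * n_par, 2.5, 0.2), n_sub, n_par)
    vals[group == 1, 7] <- vals[group == 1, 7] - 0.4
    tm <- regional_morphometry_tmap(vals, group)
    which.max(abs(tm$tstat)) == 7
  })
  expect_gte(mean(hits), 0.95)

  # identical groups: t near zero
  vals0 <- matrix(rnorm(n_sub * n_par, 2.5, 0.2), n_sub, n_par)
  tm0 <- regional_morphometry_tmap(vals0, group)
  expect_lt(mean(abs(tm0$tstat)), 1.5)

  # effect carried purely by TIV disappears under adjustment
  tiv <- rnorm(n_sub, 1.5e6, 1e5) + group * 2e5
  vals_tiv <- matrix(rnorm(n_sub * n_par, 0, 0.05), n_sub, n_par) +
    matrix(tiv / 1e6, n_sub, n_par)
  tm_adj <- regional_morphometry_tmap(vals_tiv, group,
                                      covariates = data.frame(TIV = tiv))
  expect_gt(min(attr(tm_adj, "p"), na.rm = TRUE), 0.001)
  expect_lt(mean(abs(tm_adj$tstat)), 2)

  # constant parcel flagged NA
  vals_c <- vals0; vals_c[, 3] <- 1
  expect_true(is.na(regional_morphometry_tmap(vals_c, group)$tstat[3]))
})
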