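#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom,
#' computed directly from group means, SDs and sizes (the form under which
#' published demographic tables are reproducible).
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list with `t`, `df`, `p` (two-tailed).
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 <= 0 && sd2 <= 0) stop("zero SD in both groups")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tstat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Chi-square test for a 2x2 table
#'
#' Pearson chi-square with Yates continuity correction by default (the
#' standard report for 2x2 demographic comparisons).
#'
#' @param a,b,c,d cell counts, rows = groups, columns = categories.
#' @param yates apply the continuity correction.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi2_2x2 <- function(a, b, c, d, yates = TRUE) {
  tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal total")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Mann-Whitney U test
#'
#' U statistic with a tie-corrected, continuity-corrected normal
#' approximation for Z; the p-value is from exact enumeration when
#' `n1 * n2 <= 400` and there are no ties, otherwise from the normal
#' approximation.
#'
#' @param x,y numeric samples.
#' @return list with `U`, `Z`, `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # U for x
  ties <- table(r)
  if (length(ties) == 1) {
    warning("all values tied across both samples")
    return(list(U = u, Z = 0, p = 1))
  }
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term))
  zval <- (u - mu - sign(u - mu) * 0.5) / sigma
  has_ties <- any(ties > 1)
  if (n1 * n2 <= 400 && !has_ties) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    p <- 2 * stats::pnorm(-abs(zval))
  }
  list(U = u, Z = zval, p = min(p, 1))
}

#' Shapiro-Wilk normality test
#'
#' Thin adapter over the standard implementation, with the sample-size
#' domain made explicit.
#'
#' @param sample numeric vector, `3 <= n <= 5000`.
#' @return list with `W`, `p`.
#' @export
shapiro_wilk <- function(sample) {
  n <- sum(is.finite(sample))
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  sw <- stats::shapiro.test(sample)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values with monotonicity enforcement; rejection at
#' adjusted p <= q.
#'
#' @param pvals raw p-values in `[0, 1]`.
#' @param q FDR level.
#' @return list with `adjusted` and logical `reject`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= q)
}

# shared fitted-model container ------------------------------------------

new_regression_result <- function(coefficients, method, n, adj_r2 = NA_real_,
                                  converged = TRUE, model = NULL) {
  structure(list(coefficients = coefficients, method = method, n = n,
                 adj_r2 = adj_r2, converged = converged, model = model),
            class = "avm_lm")
}

#' @export
print.avm_lm <- function(x, ...) {
  cat(sprintf("%s regression (n = %d)\n", x$method, x$n))
  printable <- x$coefficients
  printable[-1] <- lapply(printable[-1], function(v) signif(v, 4))
  print(printable, row.names = FALSE)
  if (is.finite(x$adj_r2)) cat(sprintf("adjusted R-squared: %.4f\n", x$adj_r2))
  if (!x$converged) cat("WARNING: IRLS did not converge\n")
  invisible(x)
}

#' @export
coef.avm_lm <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' Ordinary least squares regression
#'
#' OLS of `y` on the covariate set (intercept added automatically), with
#' per-term SE, t and p and adjusted R-squared. With `standardized = TRUE`
#' the response and all non-constant numeric predictors are z-scored, so
#' the betas are standardized regression coefficients.
#'
#' @param y response vector.
#' @param x data.frame or matrix of predictors (no intercept column).
#' @param standardized report standardized coefficients.
#' @return An object of class `avm_lm`.
#' @export
ols_fit <- function(y, x, standardized = FALSE) {
  design <- build_design(x)
  if (standardized) {
    y <- as.numeric(scale(y))
    for (j in 2:ncol(design)) {
      if (stats::sd(design[, j]) > 0) design[, j] <- as.numeric(scale(design[, j]))
    }
  }
  qrx <- qr(design)
  if (qrx$rank < ncol(design)) {
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(design)[qrx$pivot[(qrx$rank + 1):ncol(design)]],
               collapse = ", "))
  }
  n <- length(y)
  p <- ncol(design)
  if (n <= p) stop("need n > number of model terms")
  fit <- stats::lm.fit(design, y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), n - p)
  tss <- sum((y - mean(y))^2)
  adj_r2 <- 1 - (rss / (n - p)) / (tss / (n - 1))
  coefs <- data.frame(term = colnames(design), beta = fit$coefficients,
                      se = se, stat = tval, p = pval, row.names = NULL)
  new_regression_result(coefs, "OLS", n, adj_r2 = adj_r2)
}

#' Huber robust linear regression
#'
#' M-estimation with the Huber psi function (tuning constant `c`, MAD
#' scale), fit by iteratively reweighted least squares; as `c` grows the
#' estimates converge to OLS. Non-convergence is flagged on the result,
#' not raised.
#'
#' @param y response vector.
#' @param x data.frame or matrix of predictors (no intercept column).
#' @param c Huber tuning constant (1.345 gives 95% Gaussian efficiency).
#' @param standardized report standardized coefficients.
#' @param maxit IRLS iteration cap.
#' @return An object of class `avm_lm` with `method = "HuberRLM"`.
#' @export
huber_rlm_fit <- function(y, x, c = 1.345, standardized = FALSE, maxit = 50) {
  design <- build_design(x)
  if (standardized) {
    y <- as.numeric(scale(y))
    for (j in 2:ncol(design)) {
      if (stats::sd(design[, j]) > 0) design[, j] <- as.numeric(scale(design[, j]))
    }
  }
  # an exact fit has zero residual scale: the M-estimate coincides with OLS
  ls0 <- stats::lm.fit(design, y)
  if (max(abs(ls0$residuals)) <= 1e-10 * (stats::sd(y) + 1)) {
    coefs <- data.frame(term = colnames(design), beta = unname(ls0$coefficients),
                        se = 0, stat = NA_real_, p = NA_real_, row.names = NULL)
    return(new_regression_result(coefs, "HuberRLM", length(y)))
  }
  fit <- withCallingHandlers(
    MASS::rlm(design, y, psi = MASS::psi.huber, k = c, maxit = maxit,
              scale.est = "MAD", acc = 1e-8),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")  # reported via the converged flag
      }
    })
  sm <- summary(fit)
  coefs <- data.frame(term = colnames(design),
                      beta = unname(fit$coefficients),
                      se = unname(sm$coefficients[, "Std. Error"]),
                      stat = unname(sm$coefficients[, "t value"]),
                      p = 2 * stats::pt(-abs(unname(sm$coefficients[, "t value"])),
                                        length(y) - ncol(design)),
                      row.names = NULL)
  new_regression_result(coefs, "HuberRLM", length(y),
                        converged = isTRUE(fit$converged))
}
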