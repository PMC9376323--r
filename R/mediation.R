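# Regression machinery for the mindfulness-rumination-well-being pathway:
# ordinary least squares solved directly from the normal equations, forward
# stepwise selection under a partial-F inclusion rule, Baron-Kenny style
# mediation with a percentile-bootstrap indirect effect, a centered
# product-term moderation fit, and a Welch two-group comparison computed
# from group moments.

#' Ordinary least squares via the normal equations
#'
#' Fits `y ~ X` (with an intercept by default), solving
#' `X'X beta = X'y` directly. Reports coefficients, standard errors, t
#' statistics and two-sided p values, the coefficient of determination R²
#' and the multiple correlation R = sqrt(R²).
#'
#' @param X Predictor matrix or data frame (columns are named predictors).
#' @param y Numeric outcome vector.
#' @param intercept Include an intercept column? Default `TRUE`.
#' @return Object of class `ols_fit`: coefficients, `se`, `t`, `p`,
#'   `r_squared`, `r`, `df_residual`, `fitted`, `residuals`, `sigma`.
#' @export
ols_fit <- function(X, y, intercept = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (nrow(X) != n) stop("X and y dimensions disagree")
  if (n < 10L) stop("need at least 10 observations, got ", n)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in the design or outcome")
  Xd <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  p <- ncol(Xd)
  if (n <= p) stop("more coefficients (", p, ") than observations (", n, ")")
  qrX <- qr(Xd)
  if (qrX$rank < p) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  XtX <- crossprod(Xd)
  beta <- drop(solve(XtX, crossprod(Xd, y)))
  fitted <- drop(Xd %*% beta)
  res <- y - fitted
  df <- n - p
  sse <- sum(res^2)
  sst <- if (intercept) sum((y - mean(y))^2) else sum(y^2)
  sigma2 <- sse / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  structure(list(coefficients = beta, se = se, t = tval,
                 p = 2 * stats::pt(-abs(tval), df),
                 r_squared = r2, r = sqrt(pmax(r2, 0)),
                 df_residual = df, fitted = fitted, residuals = res,
                 sigma = sqrt(sigma2)),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit: R =", format(x$r, digits = 4),
      " R^2 =", format(x$r_squared, digits = 4),
      " df =", x$df_residual, "\n")
  print(data.frame(estimate = x$coefficients, se = x$se, t = x$t, p = x$p))
  invisible(x)
}

#' Forward stepwise selection under a partial-F inclusion rule
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' predictor with the smallest partial-F p value, as long as that p value
#' is below `alpha_in`; stops otherwise. Deterministic given the data.
#'
#' @param X Candidate predictor matrix or data frame with named columns.
#' @param y Outcome vector.
#' @param alpha_in Inclusion threshold on the partial-F p value; default
#'   0.07.
#' @return List with `selected` (character vector, in order of entry) and
#'   `fit` (the final [ols_fit()], or `NULL` when nothing is selected).
#' @export
stepwise_select <- function(X, y, alpha_in = 0.07) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(alpha_in >= 0, alpha_in <= 1)
  selected <- character(0)
  sse_curr <- sum((y - mean(y))^2)
  df_curr <- length(y) - 1L
  repeat {
    candidates <- setdiff(colnames(X), selected)
    if (!length(candidates)) break
    best <- NULL
    for (v in candidates) {
      f <- try(ols_fit(X[, c(selected, v), drop = FALSE], y), silent = TRUE)
      if (inherits(f, "try-error")) next
      sse_new <- sum(f$residuals^2)
      Fstat <- (sse_curr - sse_new) / (sse_new / f$df_residual)
      pval <- stats::pf(Fstat, 1, f$df_residual, lower.tail = FALSE)
      if (is.null(best) || pval < best$p)
        best <- list(v = v, p = pval, fit = f, sse = sse_new)
    }
    if (is.null(best) || best$p >= alpha_in) break
    selected <- c(selected, best$v)
    sse_curr <- best$sse
  }
  list(selected = selected,
       fit = if (length(selected))
         ols_fit(X[, selected, drop = FALSE], y) else NULL)
}

# slope of m ~ x (with intercept), closed form
.slope1 <- function(x, m) {
  xc <- x - mean(x)
  sum(xc * (m - mean(m))) / sum(xc * xc)
}

# coefficients of y ~ x + m (with intercept), closed form via centered 2x2
.slopes2 <- function(x, m, y) {
  xc <- x - mean(x); mc <- m - mean(m); yc <- y - mean(y)
  sxx <- sum(xc * xc); smm <- sum(mc * mc); sxm <- sum(xc * mc)
  det <- sxx * smm - sxm * sxm
  if (det <= 0) stop("x and m are collinear")
  sxy <- sum(xc * yc); smy <- sum(mc * yc)
  c(x = (smm * sxy - sxm * smy) / det,
    m = (sxx * smy - sxm * sxy) / det)
}

#' Mediation analysis with a bootstrap indirect effect
#'
#' Fits the three regressions of the classical mediation procedure — the
#' total effect `y ~ x` (path c), the first stage `m ~ x` (path a), and the
#' joint model `y ~ x + m` (paths b and c') — by [ols_fit()], estimates the
#' indirect effect `a * b` with a nonparametric percentile bootstrap, and
#' classifies the result: `"none"` when the bootstrap interval covers zero,
#' `"full"` when it excludes zero and the direct path c' is not significant,
#' `"partial"` when both the indirect and direct paths are supported. For
#' OLS on a common sample the decomposition `c = c' + a * b` holds exactly.
#' The fit index is the multiple correlation R of the joint model
#' (`fit_index^2` equals the joint model's R²).
#'
#' @param x,m,y Numeric vectors: predictor, mediator, outcome.
#' @param n_boot Bootstrap resamples, default 2000 (minimum 200).
#' @param seed Optional integer seed for the bootstrap.
#' @param conf Confidence level of the percentile interval, default 0.95.
#' @param alpha Two-sided significance level for the direct path c',
#'   default 0.05.
#' @return Object of class `mediation_result`: `paths` (a, b, c, c_prime),
#'   `indirect`, `ci`, `classification`, `fit_index`, `p_c_prime`,
#'   `n`, `n_boot`, and the three `ols_fit`s in `fits`.
#' @export
mediate <- function(x, m, y, n_boot = 2000L, seed = NULL,
                    conf = 0.95, alpha = 0.05) {
  n <- length(x)
  if (length(m) != n || length(y) != n) stop("x, m, y must have equal length")
  if (n_boot < 200L) stop("n_boot must be at least 200")
  fit_c <- ols_fit(cbind(x = x), y)
  fit_a <- ols_fit(cbind(x = x), m)
  fit_j <- ols_fit(cbind(x = x, m = m), y)
  a <- fit_a$coefficients[["x"]]
  b <- fit_j$coefficients[["m"]]
  c_tot <- fit_c$coefficients[["x"]]
  c_pr <- fit_j$coefficients[["x"]]
  p_cp <- fit_j$p[["x"]]
  if (!is.null(seed)) set.seed(seed)
  boot <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]; mb <- m[idx]; yb <- y[idx]
    boot[i] <- .slope1(xb, mb) * .slopes2(xb, mb, yb)[["m"]]
  }
  ci <- unname(stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  classification <-
    if (ci[1] <= 0 && ci[2] >= 0) "none"
    else if (p_cp < alpha) "partial"
    else "full"
  structure(list(paths = c(a = a, b = b, c = c_tot, c_prime = c_pr),
                 indirect = a * b, ci = ci,
                 classification = classification,
                 fit_index = fit_j$r, p_c_prime = p_cp,
                 n = n, n_boot = n_boot,
                 fits = list(total = fit_c, a = fit_a, joint = fit_j)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  p <- x$paths
  cat(sprintf("Mediation (n = %d, %d bootstrap resamples)\n", x$n, x$n_boot))
  cat(sprintf("  a = %.4f  b = %.4f  c = %.4f  c' = %.4f\n",
              p["a"], p["b"], p["c"], p["c_prime"]))
  cat(sprintf("  indirect a*b = %.4f, 95%% CI [%.4f, %.4f]\n",
              x$indirect, x$ci[1], x$ci[2]))
  cat(sprintf("  classification: %s mediation;  fit index R = %.4f\n",
              x$classification, x$fit_index))
  invisible(x)
}

#' Moderation (product-term) analysis
#'
#' Centers `x` and `m`, forms their product, and fits
#' `y ~ x_c + m_c + x_c * m_c`. The product-term coefficient and its t
#' statistic carry the moderation test.
#'
#' @param x,m,y Numeric vectors.
#' @return List with the full `fit` ([ols_fit()]) and the product term's
#'   `estimate`, `t` and `p`.
#' @export
moderate <- function(x, m, y) {
  xc <- x - mean(x)
  mc <- m - mean(m)
  fit <- ols_fit(cbind(x = xc, m = mc, `x:m` = xc * mc), y)
  list(fit = fit,
       estimate = fit$coefficients[["x:m"]],
       t = fit$t[["x:m"]], p = fit$p[["x:m"]])
}

#' Welch two-group comparison
#'
#' Two-sample t test with unequal variances, computed directly from the
#' group moments (means, variances, sizes) with the Welch-Satterthwaite
#' degrees of freedom. When both groups are constant with equal means the
#' convention `t = 0, p = 1` applies.
#'
#' @param group_a,group_b Numeric vectors, each of length at least 2.
#' @return List: `mean_diff`, `t`, `df`, `p`, and per-group summaries.
#' @export
group_compare <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 observations")
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  diff <- ma - mb
  sa <- va / na; sb <- vb / nb
  if (sa + sb == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    df <- na + nb - 2
  } else {
    t <- diff / sqrt(sa + sb)
    df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(mean_diff = diff, t = t, df = df, p = p,
       n = c(a = na, b = nb), means = c(a = ma, b = mb),
       vars = c(a = va, b = vb))
}
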