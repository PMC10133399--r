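#' Fit the gene-gene interaction model by ordinary least squares
#'
#' Fits `y ~ x * group` with treatment (dummy) coding, the reference level
#' being the first requested subgroup. Differential co-expression is tested
#' with the F-test comparing the full model against the reduced model
#' without the `x:group` interaction terms (`df = (k - 1, n - 2k)` for `k`
#' groups). For two groups this is the F-test on the single Gene x Group
#' coefficient; for `k > 2` the joint test over all slope offsets is the
#' one-way-ANOVA-style generalization.
#'
#' Degenerate inputs never yield a hard error or a fake p-value: the result
#' carries a missing `p_interaction` plus a machine-readable `reason`
#' (`"insufficient_n"`, `"zero_variance"`, `"insufficient_df"`).
#'
#' @param data A `pair_data` object from [build_pair_data()].
#' @return A `deggs_fit` object: coefficients (`beta0`, `beta1`, `beta2`,
#'   `beta3`), per-group slopes and intercepts, `f_statistic`, `df_num`,
#'   `df_den`, `p_interaction`, `method`, `converged`.
#' @export
fit_ols_interaction <- function(data) {
  reason <- fit_degeneracy(data)
  if (!is.na(reason)) return(degenerate_fit(data, reason, "ols"))
  df <- data.frame(y = data$y, x = data$x, group = data$group)
  full <- stats::lm(y ~ x * group, data = df)
  reduced <- stats::lm(y ~ x + group, data = df)
  an <- stats::anova(reduced, full)
  build_fit_result(stats::coef(full), data,
                   f_statistic = an$F[2L], df_num = an$Df[2L],
                   df_den = an$Res.Df[2L], p_interaction = an$`Pr(>F)`[2L],
                   method = "ols", converged = TRUE)
}

#' Fit the gene-gene interaction model by Huber M-estimation
#'
#' Same design matrix as [fit_ols_interaction()], fitted by iteratively
#' reweighted least squares with the Huber psi (tuning constant 1.345,
#' scale = normalized MAD of the residuals re-estimated each iteration,
#' convergence when the largest coefficient change drops below `tol`).
#' Outlying samples are down-weighted rather than allowed to dominate the
#' slope estimates.
#'
#' The differential test is a Wald-type F on the interaction block using the
#' M-estimator's asymptotic covariance
#' \eqn{\hat V = \frac{\sum \psi_i^2/(n-p)}{(\bar{\psi'})^2} (X'X)^{-1}},
#' with `df = (k - 1, n - 2k)`. When no residual is down-weighted this
#' reduces exactly to the OLS F-test. If IRLS fails to converge within
#' `max_iter` iterations the OLS result is returned with `converged = FALSE`
#' and a warning.
#'
#' @param data A `pair_data` object.
#' @param tuning Huber tuning constant (default 1.345, ~95% Gaussian
#'   efficiency).
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @return A `deggs_fit` object (`method = "huber"`).
#' @export
fit_robust_interaction <- function(data, tuning = 1.345, tol = 1e-8,
                                   max_iter = 50L) {
  reason <- fit_degeneracy(data)
  if (!is.na(reason)) return(degenerate_fit(data, reason, "huber"))
  X <- stats::model.matrix(~ x * group,
                           data.frame(x = data$x, group = data$group))
  y <- data$y
  n <- length(y)
  p <- ncol(X)
  beta <- stats::lm.fit(X, y)$coefficients
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    s <- stats::mad(r)
    if (!is.finite(s) || s < .Machine$double.eps^0.5) {
      # (near-)exact fit for most samples: weights are all 1, IRLS is done
      converged <- TRUE
      break
    }
    w <- pmin(1, tuning * s / abs(r))
    w[abs(r) < .Machine$double.eps] <- 1
    beta_new <- stats::lm.wfit(X, y, w)$coefficients
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("Huber IRLS did not converge in ", max_iter,
            " iterations; falling back to OLS", call. = FALSE)
    out <- fit_ols_interaction(data)
    out$converged <- FALSE
    return(out)
  }
  r <- y - drop(X %*% beta)
  s <- stats::mad(r)
  if (!is.finite(s) || s < .Machine$double.eps^0.5) s <- stats::sd(r)
  psi <- pmax(pmin(r, tuning * s), -tuning * s)
  psi_prime <- as.numeric(abs(r) <= tuning * s)
  kappa <- mean(psi_prime)
  sigma2 <- sum(psi^2) / (n - p)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  vcov_beta <- (sigma2 / kappa^2) * xtx_inv
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  idx <- grep("^x:group", colnames(X))
  b3 <- beta[idx]
  df_num <- length(idx)
  df_den <- n - p
  f_stat <- drop(t(b3) %*% solve(vcov_beta[idx, idx, drop = FALSE]) %*% b3) /
    df_num
  p_int <- stats::pf(f_stat, df_num, df_den, lower.tail = FALSE)
  build_fit_result(beta, data, f_statistic = f_stat, df_num = df_num,
                   df_den = df_den, p_interaction = p_int,
                   method = "huber", converged = TRUE)
}

# Shared degeneracy contract for both fitting paths.
fit_degeneracy <- function(data) {
  if (isTRUE(data$degenerate)) return(data$reason)
  k <- nlevels(data$group)
  v <- tapply(data$x, data$group, stats::var)
  if (any(is.na(v)) || any(v <= 0)) return("zero_variance")
  if (data$n - 2L * k <= 0L) return("insufficient_df")
  NA_character_
}

degenerate_fit <- function(data, reason, method) {
  lev <- levels(data$group)
  structure(list(
    beta0 = NA_real_, beta1 = NA_real_,
    beta2 = stats::setNames(rep(NA_real_, max(length(lev) - 1L, 1L)),
                            lev[-1L]),
    beta3 = stats::setNames(rep(NA_real_, max(length(lev) - 1L, 1L)),
                            lev[-1L]),
    per_group_slope = stats::setNames(rep(NA_real_, length(lev)), lev),
    group_intercepts = stats::setNames(rep(NA_real_, length(lev)), lev),
    f_statistic = NA_real_, df_num = NA_integer_, df_den = NA_integer_,
    p_interaction = NA_real_, method = method, converged = NA,
    n = data$n, groups = lev, predictor = data$predictor,
    response = data$response, degenerate = TRUE, reason = reason),
    class = "deggs_fit")
}

build_fit_result <- function(beta, data, f_statistic, df_num, df_den,
                             p_interaction, method, converged) {
  lev <- levels(data$group)
  nonref <- lev[-1L]
  beta0 <- unname(beta["(Intercept)"])
  beta1 <- unname(beta["x"])
  beta2 <- stats::setNames(unname(beta[paste0("group", nonref)]), nonref)
  beta3 <- stats::setNames(unname(beta[paste0("x:group", nonref)]), nonref)
  slopes <- stats::setNames(c(beta1, beta1 + beta3), lev)
  intercepts <- stats::setNames(c(beta0, beta0 + beta2), lev)
  structure(list(
    beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
    per_group_slope = slopes, group_intercepts = intercepts,
    f_statistic = unname(f_statistic), df_num = as.integer(df_num),
    df_den = as.integer(df_den), p_interaction = unname(p_interaction),
    method = method, converged = converged, n = data$n, groups = lev,
    predictor = data$predictor, response = data$response,
    degenerate = FALSE, reason = NA_character_),
    class = "deggs_fit")
}

#' @export
coef.deggs_fit <- function(object, ...) {
  c("(Intercept)" = object$beta0, x = object$beta1,
    stats::setNames(object$beta2, paste0("group", names(object$beta2))),
    stats::setNames(object$beta3, paste0("x:group", names(object$beta3))))
}

#' @export
print.deggs_fit <- function(x, ...) {
  cat("Gene-gene interaction model (", x$method, "): ",
      x$response, " ~ ", x$predictor, " * group\n", sep = "")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate fit (", x$reason, "); p-value missing\n", sep = "")
    return(invisible(x))
  }
  cat("  n =", x$n, " groups:", paste(x$groups, collapse = ", "), "\n")
  cat("  per-group slopes:",
      paste(sprintf("%s=%.4g", names(x$per_group_slope), x$per_group_slope),
            collapse = ", "), "\n")
  cat(sprintf("  interaction F(%d, %d) = %.4g, p = %.4g\n",
              x$df_num, x$df_den, x$f_statistic, x$p_interaction))
  if (!isTRUE(x$converged)) cat("  note: IRLS did not converge\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment with explicit missing handling
#'
#' Step-up false-discovery-rate adjustment of the per-edge interaction
#' p-values. Missing entries (degenerate fits) stay missing and do not count
#' toward the number of comparisons `m` (only actually performed tests are
#' corrected for). `method = "none"` is the identity.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`, possibly with `NA`s.
#' @param method `"bh"` (default) or `"none"`.
#' @return Adjusted p-values, same length and `NA` pattern.
#' @export
adjust_pvalues <- function(pvals, method = c("bh", "none")) {
  method <- match.arg(method)
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop_input("p-values must lie in [0, 1]")
  if (method == "none") return(pvals)
  stats::p.adjust(pvals, method = "BH")
}
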