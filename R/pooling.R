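pooled_estimate <- function(method, point, total_variance, components,
                            alpha, safeguard_applied = FALSE) {
  zq <- stats::qnorm(1 - alpha / 2)
  hw <- zq * sqrt(total_variance)
  structure(list(method = method, point = point,
                 total_variance = total_variance, components = components,
                 ci_low = point - hw, ci_high = point + hw, alpha = alpha,
                 safeguard_applied = safeguard_applied),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("%s pooling: %.4f [%.4f, %.4f] (total variance %.3g%s)\n",
              tools::toTitleCase(x$method), x$point, x$ci_low, x$ci_high,
              x$total_variance,
              if (x$safeguard_applied) ", safeguard applied" else ""))
  cat("  components:", paste(sprintf("%s = %.3g", names(x$components),
                                     unlist(x$components)), collapse = ", "), "\n")
  invisible(x)
}

#' Pool multiply imputed estimates with Rubin's rules
#'
#' The pooled point estimate is the mean of the per-imputation estimates.
#' With `W` the mean within-imputation variance and `B` the
#' between-imputation variance of the estimates (denominator `nbimp - 1`),
#' the total variance is `W + (1 + 1/nbimp) B`.  Confidence intervals use
#' normal quantiles.
#'
#' @param estimates Numeric vector of per-imputation point estimates.
#' @param variances Their within-imputation variances (same length, > 0).
#' @param alpha Two-sided miscoverage level (default 0.05).
#' @return A `pooled_estimate` with components `W`, `B`.
#' @export
rubin_pool <- function(estimates, variances, alpha = 0.05) {
  m <- length(estimates)
  if (m < 2L) {
    stop("Rubin's rules need at least 2 imputations", call. = FALSE)
  }
  stopifnot(length(variances) == m, all(is.finite(estimates)),
            all(is.finite(variances)), all(variances > 0))
  point <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  total <- W + (1 + 1 / m) * B
  pooled_estimate("rubin", point, total, list(W = W, B = B), alpha)
}

#' Pool two-stage multiply imputed estimates with Reiter's rules
#'
#' Estimates are arranged as an `nbimp x nbrep` matrix: row `k` holds the
#' `nbrep` replicate estimates sharing parameter draw `k`.  With row means
#' `theta_k` and grand mean `theta`, the components are the grand mean of
#' the within-dataset variances (`W~`), the between-draw variance of the
#' row means (`B~`, denominator `nbimp - 1`), and the within-draw
#' between-replicate variance
#' `U = sum_k sum_j (theta_kj - theta_k)^2 / (nbimp (nbrep - 1))`.
#' The total variance is `W~ + (1 + 1/nbimp) B~ - (1 + 1/nbrep) U`: the
#' subtracted `U` term removes the replication variability that Rubin's
#' rules double-count when the analysis discards some of the units the
#' imputation model used.  The subtraction is not guaranteed to leave a
#' positive total; when it does not, the safeguard drops the `U` term
#' (falling back to the Rubin-form component sum) and flags the result.
#'
#' @param estimates `nbimp x nbrep` matrix of point estimates.
#' @param variances Matching matrix of within-dataset variances (> 0).
#' @param alpha Two-sided miscoverage level (default 0.05).
#' @return A `pooled_estimate` with components `W_tilde`, `B_tilde`, `U`
#'   and a `safeguard_applied` flag.
#' @export
reiter_pool <- function(estimates, variances, alpha = 0.05) {
  if (!is.matrix(estimates) || !is.matrix(variances)) {
    stop("Reiter's rules need nbimp x nbrep matrices; ",
         "for single-stage imputation use rubin_pool()", call. = FALSE)
  }
  m <- nrow(estimates)
  r <- ncol(estimates)
  if (m < 2L) stop("Reiter's rules need nbimp >= 2", call. = FALSE)
  if (r < 2L) {
    stop("Reiter's rules need nbrep >= 2 (U has denominator nbrep - 1)",
         call. = FALSE)
  }
  stopifnot(identical(dim(estimates), dim(variances)),
            all(is.finite(estimates)), all(is.finite(variances)),
            all(variances > 0))
  row_means <- rowMeans(estimates)
  point <- mean(row_means)
  W_tilde <- mean(variances)
  B_tilde <- stats::var(row_means)
  U <- sum((estimates - row_means)^2) / (m * (r - 1))
  total <- W_tilde + (1 + 1 / m) * B_tilde - (1 + 1 / r) * U
  safeguard <- FALSE
  if (total <= 0) {
    total <- W_tilde + (1 + 1 / m) * B_tilde
    safeguard <- TRUE
  }
  pooled_estimate("reiter", point, total,
                  list(W_tilde = W_tilde, B_tilde = B_tilde, U = U),
                  alpha, safeguard_applied = safeguard)
}

#' Pool a list of effect estimates
#'
#' Convenience wrapper dispatching to [rubin_pool()] or [reiter_pool()].
#' All estimates must share one scale; mixing `"rd"` and `"logor"` is an
#' error.  For Reiter pooling the estimates are arranged by their
#' `draw_k` / `rep_j` tags.
#'
#' @param effects List of `effect_estimate`s.  For `method = "reiter"`
#'   each must carry `draw_k` and `rep_j` attributes (as produced by the
#'   harness) or be supplied in draw-major order with `nbimp`/`nbrep`.
#' @param method `"rubin"` or `"reiter"`.
#' @param alpha Miscoverage level.
#' @param nbimp,nbrep Matrix layout for `"reiter"` when the list is in
#'   draw-major order.
#' @return A `pooled_estimate`.
#' @export
pool_effects <- function(effects, method = c("rubin", "reiter"),
                         alpha = 0.05, nbimp = NULL, nbrep = NULL) {
  method <- match.arg(method)
  scales <- vapply(effects, function(e) e$scale, character(1L))
  if (length(unique(scales)) != 1L) {
    stop("cannot pool estimates on mixed scales: ",
         paste(unique(scales), collapse = ", "), call. = FALSE)
  }
  est <- vapply(effects, function(e) e$estimate, numeric(1L))
  va <- vapply(effects, function(e) e$variance, numeric(1L))
  if (method == "rubin") {
    return(rubin_pool(est, va, alpha))
  }
  if (is.null(nbimp) || is.null(nbrep)) {
    stop("reiter pooling needs nbimp and nbrep", call. = FALSE)
  }
  if (length(est) != nbimp * nbrep) {
    stop("expected nbimp * nbrep estimates", call. = FALSE)
  }
  reiter_pool(matrix(est, nrow = nbimp, ncol = nbrep, byrow = TRUE),
              matrix(va, nrow = nbimp, ncol = nbrep, byrow = TRUE),
              alpha)
}
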