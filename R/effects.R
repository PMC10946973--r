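effect_estimate <- function(scale, estimate, variance, n_units, meta = list()) {
  structure(list(scale = scale, estimate = estimate, variance = variance,
                 n_units = as.integer(n_units), meta = meta),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Effect estimate (%s): %.4f (SE %.4f, n = %d)\n",
              x$scale, x$estimate, sqrt(x$variance), x$n_units))
  invisible(x)
}

#' Serialize an effect estimate to JSON
#'
#' @param est An `effect_estimate`.
#' @return A JSON string with fields `scale`, `estimate`, `variance`,
#'   `n_units`, `meta`.
#' @export
effect_to_json <- function(est) {
  stopifnot(inherits(est, "effect_estimate"))
  jsonlite::toJSON(unclass(est), auto_unbox = TRUE, digits = NA)
}

# Sandwich variance of the treatment coefficient in the saturated
# intercept + treatment model.  Rows are grouped by `cluster`; `mu` is the
# fitted mean (p1 on treated rows, p0 on controls), `v` the GLM variance
# weight (1 for the identity link, mu(1-mu) for the logit link), `w`
# optional known case weights.  The estimating-equation score of row i is
# w_i * x_i * (y_i - mu_i) for both links (canonical logit, least-squares
# identity), so only the bread differs.
sandwich_treatment_var <- function(y, z, mu, v, cluster, w = NULL,
                                   cr_correction = TRUE) {
  if (is.null(w)) w <- rep(1, length(y))
  X <- cbind(1, z)
  A <- crossprod(X * (w * v), X)
  resid <- w * (y - mu)
  U <- rowsum(X * resid, group = cluster)
  M <- crossprod(U)
  Ainv <- solve(A)
  V <- Ainv %*% M %*% Ainv
  if (cr_correction) {
    G <- nrow(U)
    V <- V * G / (G - 1)
  }
  V[2L, 2L]
}

#' ATT on a matched sample with pair-clustered standard errors
#'
#' Intercept + treatment regression restricted to the matched rows: the
#' identity link gives the risk difference (the difference in arm
#' proportions), the logit link gives the log odds ratio (the log
#' cross-product ratio of the matched 2x2 table).  Both have closed forms
#' for this saturated one-regressor model, which are used directly rather
#' than iterated.  The variance is the cluster-robust sandwich with the
#' matched pair as the cluster and the CR1 small-sample factor
#' `G/(G-1)` (`G` pairs), accounting for within-pair outcome correlation.
#'
#' @param matched A `matched_sample`.
#' @param y Binary outcome vector for the full dataset the match indexes.
#' @param z Binary treatment vector (used for validation only; matched
#'   roles come from the pair list).
#' @param scale `"rd"` (risk difference) or `"logor"` (log odds ratio).
#' @return An `effect_estimate`; `meta` records `n_pairs` and
#'   `n_treated_unmatched`.
#' @export
att_estimate <- function(matched, y, z, scale = c("rd", "logor")) {
  scale <- match.arg(scale)
  stopifnot(inherits(matched, "matched_sample"))
  G <- nrow(matched$pairs)
  if (G < 2L) stop("need at least 2 matched pairs", call. = FALSE)
  yt <- y[matched$pairs$treated]
  yc <- y[matched$pairs$control]
  p1 <- mean(yt)
  p0 <- mean(yc)
  yy <- c(yt, yc)
  zz <- rep(c(1L, 0L), each = G)
  mu <- ifelse(zz == 1L, p1, p0)
  cl <- rep(seq_len(G), times = 2L)
  if (scale == "rd") {
    est <- p1 - p0
    vv <- rep(1, 2L * G)
  } else {
    if (p1 %in% c(0, 1) || p0 %in% c(0, 1)) {
      stop("zero cell in the matched 2x2 table: log odds ratio undefined",
           call. = FALSE)
    }
    est <- log(p1 / (1 - p1)) - log(p0 / (1 - p0))
    vv <- mu * (1 - mu)
  }
  variance <- sandwich_treatment_var(yy, zz, mu, vv, cl)
  effect_estimate(scale, est, variance, 2L * G,
                  meta = list(n_pairs = G,
                              n_treated_unmatched = matched$n_treated_unmatched))
}

#' ATE by inverse probability of treatment weighting
#'
#' Unstabilized weights `w = z/ps + (1-z)/(1-ps)` reweight both arms to
#' the full population; the estimate is the weighted intercept + treatment
#' regression on the declared scale (closed-form weighted arm proportions
#' for this saturated model).  The variance is the
#' heteroscedasticity-robust sandwich treating the weights as known —
#' propensity-estimation uncertainty is deliberately ignored.
#'
#' @param completed A `completed_sample` (supplies `y` and `z`).
#' @param fit A `propensity_fit` for the same dataset.
#' @param scale `"rd"` or `"logor"`.
#' @return An `effect_estimate`; `meta` summarises the weights.
#' @export
iptw_ate <- function(completed, fit, scale = c("rd", "logor")) {
  scale <- match.arg(scale)
  stopifnot(inherits(fit, "propensity_fit"))
  ps <- fit$ps
  if (any(ps <= 0 | ps >= 1)) {
    stop("positivity violation: propensity scores at 0 or 1", call. = FALSE)
  }
  z <- completed$z
  y <- completed$y
  w <- z / ps + (1 - z) / (1 - ps)
  p1 <- sum(w * z * y) / sum(w * z)
  p0 <- sum(w * (1 - z) * y) / sum(w * (1 - z))
  mu <- ifelse(z == 1L, p1, p0)
  if (scale == "rd") {
    est <- p1 - p0
    vv <- rep(1, length(y))
  } else {
    if (p1 %in% c(0, 1) || p0 %in% c(0, 1)) {
      stop("zero weighted cell: log odds ratio undefined", call. = FALSE)
    }
    est <- log(p1 / (1 - p1)) - log(p0 / (1 - p0))
    vv <- mu * (1 - mu)
  }
  variance <- sandwich_treatment_var(y, z, mu, vv,
                                     cluster = seq_along(y), w = w,
                                     cr_correction = FALSE)
  effect_estimate(scale, est, variance, length(y),
                  meta = list(weight_range = range(w), weight_mean = mean(w)))
}

#' Crude (unadjusted) treatment effect
#'
#' Arm contrast of outcome by treatment with the standard large-sample
#' variance: binomial variance of the two proportions for the risk
#' difference, `1/a + 1/b + 1/c + 1/d` for the log odds ratio.
#'
#' @param sample Any data frame with binary columns `z` and `y`.
#' @param scale `"rd"` or `"logor"`.
#' @return An `effect_estimate`.
#' @export
crude_estimate <- function(sample, scale = c("rd", "logor")) {
  scale <- match.arg(scale)
  z <- sample$z
  y <- sample$y
  n1 <- sum(z == 1L)
  n0 <- sum(z == 0L)
  if (n1 == 0L || n0 == 0L) stop("both arms must be non-empty", call. = FALSE)
  a <- sum(z == 1L & y == 1L)
  b <- n1 - a
  c_ <- sum(z == 0L & y == 1L)
  d <- n0 - c_
  p1 <- a / n1
  p0 <- c_ / n0
  if (scale == "rd") {
    est <- p1 - p0
    variance <- p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0
  } else {
    if (min(a, b, c_, d) == 0L) {
      stop("zero cell in the 2x2 table: log odds ratio undefined",
           call. = FALSE)
    }
    est <- log(a * d / (b * c_))
    variance <- 1 / a + 1 / b + 1 / c_ + 1 / d
  }
  effect_estimate(scale, est, variance, n1 + n0,
                  meta = list(table = c(a = a, b = b, c = c_, d = d)))
}
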