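#' Estimate the propensity score by logistic regression
#'
#' Maximum-likelihood logistic regression of treatment on `x1`, `x2`,
#' `x3` (with intercept).  Requires a completed dataset: no missing
#' values, and both treatment groups present.
#'
#' @param completed A `completed_sample` (or data frame with columns
#'   `x1,x2,x3,z` and no `NA`s).
#' @return An object of class `propensity_fit`: `coefficients` (length
#'   4), fitted probabilities `ps` and their logits `logit_ps`.
#' @export
estimate_propensity <- function(completed) {
  if (anyNA(completed[c("x1", "x2", "x3", "z")])) {
    stop("propensity model requires a completed dataset (no missing values)",
         call. = FALSE)
  }
  z <- completed$z
  if (length(unique(z)) < 2L) {
    stop("both treatment groups must be non-empty", call. = FALSE)
  }
  X <- cbind("(Intercept)" = 1, x1 = completed$x1,
             x2 = completed$x2, x3 = completed$x3)
  fit <- suppressWarnings(
    stats::glm.fit(X, z, family = stats::binomial(), intercept = FALSE))
  if (!fit$converged || fit$boundary) {
    stop("propensity model did not converge (possible separation)",
         call. = FALSE)
  }
  eta <- drop(X %*% fit$coefficients)
  structure(list(coefficients = fit$coefficients,
                 ps = stats::plogis(eta), logit_ps = eta),
            class = "propensity_fit")
}

#' Caliper width: 0.2 standard deviations of the logit propensity score
#'
#' @param logit_ps Numeric vector of logit propensity scores over the
#'   full completed dataset.
#' @return `0.2 * sd(logit_ps)` (sample SD, denominator N-1).
#' @export
compute_caliper <- function(logit_ps) {
  if (length(logit_ps) < 2L) stop("need at least two units", call. = FALSE)
  s <- stats::sd(logit_ps)
  if (!is.finite(s) || s == 0) {
    stop("degenerate propensity scores: constant logit", call. = FALSE)
  }
  0.2 * s
}

#' Greedy 1:1 nearest-neighbour matching without replacement
#'
#' Treated units are processed in decreasing order of logit propensity
#' score (hardest to match first; ties broken by row index).  Each
#' receives the not-yet-used control with the smallest absolute logit
#' difference, provided that difference is within the caliper; otherwise
#' the treated unit is left unmatched.  Among equidistant controls the
#' one with the smaller logit (then smaller row index) is taken.  The
#' procedure is deterministic given its inputs.
#'
#' @param fit A `propensity_fit` (or a numeric vector of logit scores).
#' @param z Binary treatment vector, same length as the scores.
#' @param caliper Positive caliper on the logit scale; see
#'   [compute_caliper()].
#' @return An object of class `matched_sample`: `pairs` (data frame with
#'   columns `treated`, `control`, 1-based row indices), `caliper`, and
#'   `n_treated_unmatched`.
#' @export
greedy_match <- function(fit, z, caliper) {
  lps <- if (inherits(fit, "propensity_fit")) fit$logit_ps else fit
  stopifnot(is.numeric(lps), length(lps) == length(z), caliper > 0)
  res <- greedy_match_cpp(as.numeric(lps), as.integer(z), as.numeric(caliper))
  pairs <- data.frame(treated = res$treated, control = res$control)
  structure(list(pairs = pairs, caliper = caliper,
                 n_treated_unmatched = sum(z == 1L) - nrow(pairs)),
            class = "matched_sample")
}

#' @export
print.matched_sample <- function(x, ...) {
  cat(sprintf("Matched sample: %d pairs (caliper %.4f, %d treated unmatched)\n",
              nrow(x$pairs), x$caliper, x$n_treated_unmatched))
  invisible(x)
}

#' Absolute standardized mean differences between treatment groups
#'
#' For each covariate, `|mean_treated - mean_control| / s` with pooled
#' denominator `s = sqrt((s2_treated + s2_control)/2)`.  The denominator
#' is always computed on the full (pre-matching) sample, so before- and
#' after-matching values share a scale — the convention of standard
#' balance software; `subset` restricts only the group means.
#'
#' @param x Numeric matrix or data frame of covariates.
#' @param z Binary treatment vector.
#' @param subset Optional integer vector of row indices over which the
#'   group means are computed (e.g. the matched rows); defaults to all.
#' @return Named numeric vector of ASMD values.
#' @export
asmd <- function(x, z, subset = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(z))
  v1 <- apply(x[z == 1L, , drop = FALSE], 2L, stats::var)
  v0 <- apply(x[z == 0L, , drop = FALSE], 2L, stats::var)
  s <- sqrt((v1 + v0) / 2)
  if (any(!is.finite(s)) || any(s == 0)) {
    stop("degenerate covariate: zero pooled standard deviation", call. = FALSE)
  }
  if (is.null(subset)) subset <- seq_len(nrow(x))
  xs <- x[subset, , drop = FALSE]
  zs <- z[subset]
  if (!any(zs == 1L) || !any(zs == 0L)) {
    stop("both treatment groups must be non-empty in the evaluated set",
         call. = FALSE)
  }
  m1 <- colMeans(xs[zs == 1L, , drop = FALSE])
  m0 <- colMeans(xs[zs == 0L, , drop = FALSE])
  abs(m1 - m0) / s
}

#' Covariate balance before and after matching
#'
#' @param completed A `completed_sample`.
#' @param matched A `matched_sample` for that dataset.
#' @return A tidy data frame with columns `covariate`, `stage`
#'   (`"before"`/`"after"`) and `asmd`.
#' @export
balance_report <- function(completed, matched) {
  stopifnot(inherits(matched, "matched_sample"))
  x <- as.matrix(completed[c("x1", "x2", "x3")])
  z <- completed$z
  rows <- c(matched$pairs$treated, matched$pairs$control)
  before <- asmd(x, z)
  after <- asmd(x, z, subset = rows)
  data.frame(covariate = rep(colnames(x), 2L),
             stage = rep(c("before", "after"), each = ncol(x)),
             asmd = c(before, after), row.names = NULL)
}
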