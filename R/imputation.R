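#' Fit the imputation model for x2
#'
#' Ordinary least squares of `x2` on an intercept, `x1`, `x3`, the
#' treatment `z` and the outcome `y`, over the rows where `x2` is
#' observed.  Including the outcome in the imputation model keeps the
#' imputation congenial with the downstream treatment-effect analysis.
#' The returned fit parameterises the posterior of the imputation-model
#' coefficients under the standard noninformative prior.
#'
#' @param obs An `observed_sample` (or any data frame with columns
#'   `x1,x2,x3,z,y` and `NA`s only in `x2`).
#' @return An object of class `imputation_fit`: coefficient vector,
#'   unscaled covariance `(X'X)^-1`, residual sum of squares `rss`,
#'   residual degrees of freedom `df`, and the observed-row count.
#' @export
fit_imputation_model <- function(obs) {
  observed <- !is.na(obs$x2)
  p <- 5L
  if (sum(observed) < p + 1L) {
    stop("need at least ", p + 1L, " rows with x2 observed to fit the ",
         "imputation model (got ", sum(observed), ")", call. = FALSE)
  }
  X <- cbind("(Intercept)" = 1, x1 = obs$x1, x3 = obs$x3,
             z = obs$z, y = obs$y)[observed, , drop = FALSE]
  v <- obs$x2[observed]
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("singular imputation design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qx, v)
  res <- v - drop(X %*% coef)
  rss <- sum(res^2)
  R <- qr.R(qx)[, order(qx$pivot), drop = FALSE]
  xtx_inv <- chol2inv(chol(crossprod(R)))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  structure(list(coef = coef, xtx_inv = xtx_inv, rss = rss,
                 tss = sum((v - mean(v))^2),
                 df = sum(observed) - p, n_observed = sum(observed),
                 predictors = colnames(X)),
            class = "imputation_fit")
}

#' Draw imputation-model parameters from their posterior
#'
#' One draw from the standard noninformative-prior Bayesian linear
#' regression posterior: `sigma^2 = rss / g` with `g ~ chi-square(df)`,
#' then `coef ~ N(coef_hat, sigma^2 (X'X)^-1)`.  With a perfect fit
#' (`rss = 0`) the draw degenerates to the least-squares solution.
#'
#' @param fit An `imputation_fit`.
#' @param k Optional draw index stored on the result.
#' @return An object of class `parameter_draw`: list with `coef`,
#'   `sigma` (residual SD) and `k`.
#' @export
draw_parameters <- function(fit, k = NA_integer_) {
  stopifnot(inherits(fit, "imputation_fit"))
  # a numerically perfect fit degenerates to the least-squares point mass
  if (fit$rss <= .Machine$double.eps^0.75 * max(fit$tss, 1)) {
    return(structure(list(coef = fit$coef, sigma = 0, k = k),
                     class = "parameter_draw"))
  }
  sigma2 <- fit$rss / stats::rchisq(1L, fit$df)
  pert <- drop(crossprod(chol(fit$xtx_inv), stats::rnorm(length(fit$coef))))
  structure(list(coef = fit$coef + sqrt(sigma2) * pert,
                 sigma = sqrt(sigma2), k = k),
            class = "parameter_draw")
}

#' Impute missing x2 values from one parameter draw
#'
#' Fills every masked `x2` entry with `coef'(1, x1, x3, z, y) + sigma*eps`,
#' `eps ~ N(0,1)`; observed entries are returned untouched.
#'
#' @param obs An `observed_sample`.
#' @param draw A `parameter_draw`.
#' @param rep_j Optional replicate index stored on the result.
#' @return A data frame of class `completed_sample` with no missing
#'   entries and attributes `draw_k` and `rep_j`.
#' @export
impute_from_draw <- function(obs, draw, rep_j = 1L) {
  stopifnot(inherits(draw, "parameter_draw"))
  mask <- is.na(obs$x2)
  out <- data.frame(x1 = obs$x1, x2 = obs$x2, x3 = obs$x3,
                    z = obs$z, y = obs$y)
  if (any(mask)) {
    Xm <- cbind(1, obs$x1[mask], obs$x3[mask], obs$z[mask], obs$y[mask])
    out$x2[mask] <- drop(Xm %*% draw$coef) +
      draw$sigma * stats::rnorm(sum(mask))
  }
  class(out) <- c("completed_sample", "data.frame")
  attr(out, "draw_k") <- draw$k
  attr(out, "rep_j") <- as.integer(rep_j)
  out
}

#' Classic multiple imputation of x2
#'
#' Creates `nbimp` completed datasets, each from its own posterior
#' parameter draw (one imputation per draw — the classic scheme whose
#' estimates are pooled with Rubin's rules).
#'
#' @param obs An `observed_sample`.
#' @param nbimp Number of imputations (at least 2; the between-imputation
#'   variance is undefined below that).
#' @param seed Optional integer seed.
#' @return A list of `nbimp` `completed_sample`s with `draw_k = 1..nbimp`
#'   and `rep_j = 1`.
#' @export
multiple_impute <- function(obs, nbimp = 20L, seed = NULL) {
  if (nbimp < 2L) {
    stop("nbimp must be at least 2 (between-imputation variance undefined)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  fit <- fit_imputation_model(obs)
  out <- lapply(seq_len(nbimp), function(k) {
    impute_from_draw(obs, draw_parameters(fit, k = k), rep_j = 1L)
  })
  attr(out, "nbimp") <- as.integer(nbimp)
  out
}

#' Two-stage multiple imputation of x2
#'
#' The two-stage scheme behind Reiter's combining rules: `nbimp`
#' posterior parameter draws, and for each draw `nbrep` completed
#' datasets that share the drawn parameters and differ only through the
#' imputation noise on masked rows.  Equivalent to running a
#' chained-equations engine on `nbrep` concatenated copies of the data
#' with all but the first copy ignored during model fitting; here the
#' structure is implemented natively (fit once, draw `nbimp` times,
#' impute `nbrep` times per draw).
#'
#' @param obs An `observed_sample`.
#' @param nbimp Number of parameter draws (>= 2).
#' @param nbrep Number of replicate imputations per draw (>= 2; the
#'   within-draw variance `U` has denominator `nbrep - 1`).
#' @param seed Optional integer seed.
#' @return A flat list of `nbimp * nbrep` `completed_sample`s, ordered by
#'   draw then replicate, each tagged with attributes `draw_k`, `rep_j`;
#'   the list carries attributes `nbimp` and `nbrep`.
#' @export
two_stage_impute <- function(obs, nbimp = 20L, nbrep = 10L, seed = NULL) {
  if (nbimp < 2L) {
    stop("nbimp must be at least 2 (between-draw variance undefined)",
         call. = FALSE)
  }
  if (nbrep < 2L) {
    stop("nbrep must be at least 2 (within-draw variance U undefined)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  fit <- fit_imputation_model(obs)
  out <- vector("list", nbimp * nbrep)
  idx <- 0L
  for (k in seq_len(nbimp)) {
    draw <- draw_parameters(fit, k = k)
    for (j in seq_len(nbrep)) {
      idx <- idx + 1L
      out[[idx]] <- impute_from_draw(obs, draw, rep_j = j)
    }
  }
  attr(out, "nbimp") <- as.integer(nbimp)
  attr(out, "nbrep") <- as.integer(nbrep)
  out
}

#' Turn a complete cohort into a fully observed completed dataset
#'
#' Convenience for reference analyses on the pre-missingness data: keeps
#' the observable columns and tags the result as a completed dataset.
#'
#' @param sample A `complete_sample`.
#' @return A `completed_sample` with `draw_k = 0`, `rep_j = 0`.
#' @export
as_completed <- function(sample) {
  stopifnot(inherits(sample, "complete_sample"))
  out <- data.frame(x1 = sample$x1, x2 = sample$x2, x3 = sample$x3,
                    z = sample$z, y = sample$y)
  class(out) <- c("completed_sample", "data.frame")
  attr(out, "draw_k") <- 0L
  attr(out, "rep_j") <- 0L
  out
}
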