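#' Generate a complete synthetic cohort (both potential outcomes)
#'
#' Draws `n_patients` subjects with three independent standard-normal
#' confounders, Bernoulli treatment assignment from the scenario's logistic
#' treatment model, and both potential outcomes `y0`, `y1` from the logistic
#' outcome model (with and without the treatment effect).  The observed
#' outcome is assembled by consistency, `y = z*y1 + (1-z)*y0`.  The two
#' potential outcomes are drawn independently; the ATT and ATE depend only
#' on their marginal distributions.
#'
#' @param scenario A [make_scenario()] object.
#' @param seed Optional integer.  When given, independent sub-seeds are
#'   derived for the confounder, treatment and outcome draws so that each
#'   stage is individually reproducible; when `NULL` the current RNG
#'   stream is used.
#' @return A data frame of class `complete_sample` with columns
#'   `x1,x2,x3,z,y0,y1,y`.
#' @seealso [impose_missingness()], [compute_true_estimands()]
#' @export
generate_complete <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "ps_scenario"))
  n <- scenario$n_patients
  seeds <- NULL
  if (!is.null(seed)) {
    seeds <- derive_seeds(seed, c("confounders", "treatment", "outcomes"))
    set.seed(seeds[["confounders"]])
  }
  x <- matrix(stats::rnorm(3L * n), n, 3L,
              dimnames = list(NULL, c("x1", "x2", "x3")))
  if (!is.null(seeds)) set.seed(seeds[["treatment"]])
  p_treat <- stats::plogis(scenario$beta0 + drop(x %*% scenario$beta))
  z <- stats::rbinom(n, 1L, p_treat)
  if (!is.null(seeds)) set.seed(seeds[["outcomes"]])
  lp0 <- scenario$outcome_intercept + drop(x %*% scenario$gamma)
  y0 <- stats::rbinom(n, 1L, stats::plogis(lp0))
  y1 <- stats::rbinom(n, 1L, stats::plogis(lp0 + scenario$theta))
  y <- as.integer(z * y1 + (1L - z) * y0)
  out <- data.frame(x, z = z, y0 = y0, y1 = y1, y = y)
  class(out) <- c("complete_sample", "data.frame")
  out
}

#' Impose missing-at-random missingness on x2
#'
#' Draws a missingness indicator from the scenario's logistic missingness
#' model `logit P(miss) = -2 + 0.1 x1 + x3 + 1.1 z` and blanks `x2` where
#' it fires.  The mechanism depends only on fully observed variables
#' (`x1`, `x3`, `z`), so the data are missing at random by construction.
#' Potential outcomes are dropped: they are not observable.
#'
#' @param sample A `complete_sample` from [generate_complete()].
#' @param scenario The scenario the sample was generated under.
#' @param seed Optional integer seed for the missingness draw only.
#' @return A data frame of class `observed_sample` with columns
#'   `x1,x2,x3,z,y`; missing `x2` entries are `NA`.
#' @export
impose_missingness <- function(sample, scenario, seed = NULL) {
  stopifnot(inherits(sample, "complete_sample"), inherits(scenario, "ps_scenario"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  mc <- scenario$miss_coef
  p_miss <- stats::plogis(mc[1] + mc[2] * sample$x1 + mc[3] * sample$x3 + mc[4] * sample$z)
  mask <- stats::rbinom(nrow(sample), 1L, p_miss) == 1L
  out <- data.frame(x1 = sample$x1, x2 = sample$x2, x3 = sample$x3,
                    z = sample$z, y = sample$y)
  out$x2[mask] <- NA_real_
  class(out) <- c("observed_sample", "data.frame")
  out
}

#' Missingness mask of an observed sample
#'
#' @param obs An `observed_sample`.
#' @return Logical vector, `TRUE` where `x2` is missing.
#' @export
miss_mask <- function(obs) is.na(obs$x2)

#' True ATT and ATE by large-sample potential-outcome simulation
#'
#' Simulates a large cohort under the scenario and compares the drawn
#' potential outcomes directly: the ATT contrasts `mean(y1)` and `mean(y0)`
#' among the treated, the ATE over everyone, each expressed as a risk
#' difference and as a log odds ratio.  Monte-Carlo precision scales as
#' `n_large^(-1/2)`; the default of one million patients gives roughly
#' three-decimal precision on the risk difference.
#'
#' @param scenario A `ps_scenario`.  Its `n_patients` is ignored in favour
#'   of `n_large`.
#' @param n_large Simulation size (default `1e6`).
#' @param seed Optional integer seed.
#' @return An object of class `true_estimands`: list with `att_rd`,
#'   `att_logor`, `ate_rd`, `ate_logor`, plus the `n_large` used.
#' @export
compute_true_estimands <- function(scenario, n_large = 1e6, seed = NULL) {
  stopifnot(inherits(scenario, "ps_scenario"), n_large >= 1)
  big <- scenario
  big$n_patients <- as.integer(n_large)
  sam <- generate_complete(big, seed = seed)
  treated <- sam$z == 1L
  if (!any(treated)) {
    stop("no treated patients in the large sample; cannot compute the ATT",
         call. = FALSE)
  }
  contrast <- function(y1, y0) {
    p1 <- mean(y1); p0 <- mean(y0)
    list(rd = p1 - p0,
         logor = log(p1 / (1 - p1)) - log(p0 / (1 - p0)))
  }
  att <- contrast(sam$y1[treated], sam$y0[treated])
  ate <- contrast(sam$y1, sam$y0)
  structure(list(att_rd = att$rd, att_logor = att$logor,
                 ate_rd = ate$rd, ate_logor = ate$logor,
                 n_large = as.integer(n_large)),
            class = "true_estimands")
}

#' @export
print.true_estimands <- function(x, ...) {
  cat(sprintf("True estimands (Monte Carlo, n = %d):\n", x$n_large))
  cat(sprintf("  ATT: risk difference %.4f, log odds ratio %.4f\n",
              x$att_rd, x$att_logor))
  cat(sprintf("  ATE: risk difference %.4f, log odds ratio %.4f\n",
              x$ate_rd, x$ate_logor))
  invisible(x)
}

#' Write / read an observed sample as CSV
#'
#' Missing `x2` values are encoded as empty fields, so the round trip
#' preserves the missingness mask exactly.
#'
#' @param obs An `observed_sample`.
#' @param path Output file path.
#' @return `write_observed_csv` returns `path` invisibly;
#'   `read_observed_csv` returns an `observed_sample`.
#' @export
write_observed_csv <- function(obs, path) {
  stopifnot(inherits(obs, "observed_sample"))
  utils::write.csv(as.data.frame(obs)[c("x1", "x2", "x3", "z", "y")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_observed_csv
#' @export
read_observed_csv <- function(path) {
  out <- utils::read.csv(path, na.strings = "")
  need <- c("x1", "x2", "x3", "z", "y")
  if (!all(need %in% names(out))) {
    stop("observed-sample CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  out <- out[need]
  if (anyNA(out[c("x1", "x3", "z", "y")])) {
    stop("only x2 may contain missing values", call. = FALSE)
  }
  out$z <- as.integer(out$z)
  out$y <- as.integer(out$y)
  class(out) <- c("observed_sample", "data.frame")
  out
}
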