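#' Scenario configuration for synthetic cohorts
#'
#' A scenario bundles the coefficients of the three logistic models that
#' drive cohort generation: the treatment-assignment model, the outcome
#' model, and the missingness model for the partially observed confounder
#' `x2`.  The three named confounding levels carry fixed slope sets; the
#' treatment-model intercept `beta0` controls treatment prevalence
#' (roughly 30%, 20% and 10% treated for `beta0` of -1, -1.4 and -2.2).
#'
#' The named levels are:
#' \describe{
#'   \item{strong}{treatment slopes (-0.5, -0.4, -0.7), outcome slopes
#'     (0.4, 0.5, 0.9), conditional log-odds treatment effect 1.2.}
#'   \item{moderate}{treatment slopes (-0.3, -0.4, -0.3), outcome slopes
#'     (0.4, 0.5, 0.3), treatment effect 1.2.}
#'   \item{weak}{treatment slopes (-0.01, -0.05, 0.01), outcome slopes
#'     (0.1, 0.1, -0.1), treatment effect 3.}
#' }
#'
#' The outcome-model intercept is fixed at -1 and the missingness model is
#' `logit P(x2 missing) = -2 + 0.1 x1 + x3 + 1.1 z`, a missing-at-random
#' mechanism depending only on fully observed quantities.
#'
#' @param level One of `"strong"`, `"moderate"`, `"weak"`.
#' @param beta0 Treatment-model intercept (any real; -1, -1.4 and -2.2 are
#'   the calibrated prevalence settings).
#' @param n_patients Cohort size N.
#' @return An object of class `ps_scenario`: a list with elements `level`,
#'   `beta0`, `beta`, `gamma`, `theta`, `outcome_intercept`, `miss_coef`
#'   and `n_patients`.
#' @examples
#' sc <- make_scenario("strong", beta0 = -1, n_patients = 1000)
#' sc$theta
#' @export
make_scenario <- function(level = c("strong", "moderate", "weak"),
                          beta0 = -1, n_patients = 10000L) {
  if (length(level) != 1L || !level %in% c("strong", "moderate", "weak")) {
    stop("unknown confounding level: ", paste(level, collapse = ", "),
         " (must be one of 'strong', 'moderate', 'weak')", call. = FALSE)
  }
  stopifnot(is.numeric(beta0), length(beta0) == 1L, is.finite(beta0),
            is.numeric(n_patients), length(n_patients) == 1L, n_patients >= 1)
  coefs <- switch(level,
    strong   = list(beta = c(-0.5, -0.4, -0.7),  gamma = c(0.4, 0.5, 0.9),  theta = 1.2),
    moderate = list(beta = c(-0.3, -0.4, -0.3),  gamma = c(0.4, 0.5, 0.3),  theta = 1.2),
    weak     = list(beta = c(-0.01, -0.05, 0.01), gamma = c(0.1, 0.1, -0.1), theta = 3))
  structure(list(
    level = level,
    beta0 = beta0,
    beta = coefs$beta,
    gamma = coefs$gamma,
    theta = coefs$theta,
    outcome_intercept = -1,
    miss_coef = c(-2, 0.1, 1, 1.1),
    n_patients = as.integer(n_patients)
  ), class = "ps_scenario")
}

#' @export
print.ps_scenario <- function(x, ...) {
  cat(sprintf("Scenario: %s confounding, beta0 = %g, N = %d\n",
              x$level, x$beta0, x$n_patients))
  cat(sprintf("  treatment slopes: (%s)\n", paste(x$beta, collapse = ", ")))
  cat(sprintf("  outcome slopes:   (%s), theta = %g\n",
              paste(x$gamma, collapse = ", "), x$theta))
  cat(sprintf("  missingness:      logit = %g + %g x1 + %g x3 + %g z\n",
              x$miss_coef[1], x$miss_coef[2], x$miss_coef[3], x$miss_coef[4]))
  invisible(x)
}

#' Read a scenario from a YAML or JSON configuration file
#'
#' Recognised keys: `level`, `beta0`, `n_patients` (and optionally `seed`,
#' returned as an attribute).  The format is inferred from the extension.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `ps_scenario`; any `seed` key is attached as attribute `"seed"`.
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  for (key in c("level", "beta0", "n_patients")) {
    if (is.null(cfg[[key]])) stop("scenario config missing key: ", key, call. = FALSE)
  }
  sc <- make_scenario(cfg$level, cfg$beta0, cfg$n_patients)
  if (!is.null(cfg$seed)) attr(sc, "seed") <- as.integer(cfg$seed)
  sc
}

# Derive reproducible purpose-specific sub-seeds from one master seed, so
# e.g. missingness can be re-imposed without regenerating the cohort.
derive_seeds <- function(seed, purposes) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- sample.int(.Machine$integer.max - 1L, length(purposes))
  names(out) <- purposes
  out
}
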