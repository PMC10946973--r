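#' Specify an analysis method for the simulation harness
#'
#' A method describes one end-to-end analysis of a replicate cohort: which
#' data it sees (`"imputed"` = the observed sample after multiple
#' imputation, `"complete"` = the pre-missingness cohort), which analysis
#' it runs (propensity score matching, IPTW, or the crude contrast), how
#' estimates are pooled, and on which scale.
#'
#' @param label Unique method label.
#' @param analysis `"psm"` (1:1 caliper matching, ATT), `"iptw"`
#'   (weighting, ATE) or `"crude"` (unadjusted contrast).
#' @param data `"imputed"` or `"complete"`.
#' @param pooling `"rubin"`, `"reiter"` or `"none"` (single analysis).
#' @param scale `"rd"` or `"logor"`.
#' @param nbimp,nbrep Imputation counts where applicable.
#' @param estimand Which true value the method targets (`"att"` or
#'   `"ate"`); defaults to `"att"` for matching and `"ate"` otherwise.
#' @return A `method_spec` object.
#' @export
method_spec <- function(label,
                        analysis = c("psm", "iptw", "crude"),
                        data = c("imputed", "complete"),
                        pooling = c("rubin", "reiter", "none"),
                        scale = c("rd", "logor"),
                        nbimp = 20L, nbrep = 10L, estimand = NULL) {
  analysis <- match.arg(analysis)
  data <- match.arg(data)
  pooling <- match.arg(pooling)
  scale <- match.arg(scale)
  if (data == "complete" && pooling != "none") {
    stop("complete-data methods take pooling = 'none'", call. = FALSE)
  }
  if (data == "imputed" && pooling == "none") {
    stop("imputed-data methods need Rubin or Reiter pooling", call. = FALSE)
  }
  if (is.null(estimand)) estimand <- if (analysis == "psm") "att" else "ate"
  structure(list(label = label, analysis = analysis, data = data,
                 pooling = pooling, scale = scale,
                 nbimp = as.integer(nbimp), nbrep = as.integer(nbrep),
                 estimand = estimand),
            class = "method_spec")
}

#' The default method set of the simulation study
#'
#' MI + matching pooled with Rubin's rules, two-stage MI + matching
#' pooled with Reiter's rules, MI + IPTW pooled with Rubin's rules (the
#' non-discarding control), full-data matching (no missingness), and the
#' crude contrast.
#'
#' @param scale `"rd"` or `"logor"`.
#' @param nbimp,nbrep Imputation counts for the MI methods.
#' @return Named list of `method_spec`s.
#' @export
default_methods <- function(scale = "rd", nbimp = 20L, nbrep = 10L) {
  list(
    mi_psm_rubin = method_spec("mi_psm_rubin", "psm", "imputed", "rubin",
                               scale, nbimp = nbimp),
    mi_psm_reiter = method_spec("mi_psm_reiter", "psm", "imputed", "reiter",
                                scale, nbimp = nbimp, nbrep = nbrep),
    mi_iptw_rubin = method_spec("mi_iptw_rubin", "iptw", "imputed", "rubin",
                                scale, nbimp = nbimp),
    full_data_psm = method_spec("full_data_psm", "psm", "complete", "none",
                                scale),
    crude = method_spec("crude", "crude", "complete", "none", scale)
  )
}

# One analysis of one completed dataset.
analyse_completed <- function(completed, analysis, scale) {
  switch(analysis,
    crude = crude_estimate(completed, scale),
    psm = {
      fit <- estimate_propensity(completed)
      cal <- compute_caliper(fit$logit_ps)
      m <- greedy_match(fit, completed$z, cal)
      att_estimate(m, completed$y, completed$z, scale)
    },
    iptw = {
      fit <- estimate_propensity(completed)
      iptw_ate(completed, fit, scale)
    })
}

run_method <- function(spec, complete, obs, seed, alpha) {
  row <- data.frame(method = spec$label, scale = spec$scale,
                    estimand = spec$estimand,
                    estimate = NA_real_, variance = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    failed = FALSE, error = NA_character_,
                    safeguard = FALSE, n_pairs = NA_real_,
                    n_treated_unmatched = NA_real_,
                    stringsAsFactors = FALSE)
  fill <- function(row) {
    if (spec$data == "complete") {
      e <- analyse_completed(as_completed(complete), spec$analysis, spec$scale)
      zq <- stats::qnorm(1 - alpha / 2)
      row$estimate <- e$estimate
      row$variance <- e$variance
      row$ci_low <- e$estimate - zq * sqrt(e$variance)
      row$ci_high <- e$estimate + zq * sqrt(e$variance)
      if (!is.null(e$meta$n_pairs)) {
        row$n_pairs <- e$meta$n_pairs
        row$n_treated_unmatched <- e$meta$n_treated_unmatched
      }
      return(row)
    }
    set.seed(seed)
    completed <- if (spec$pooling == "reiter") {
      two_stage_impute(obs, spec$nbimp, spec$nbrep)
    } else {
      multiple_impute(obs, spec$nbimp)
    }
    effects <- lapply(completed, analyse_completed,
                      analysis = spec$analysis, scale = spec$scale)
    pe <- if (spec$pooling == "reiter") {
      pool_effects(effects, "reiter", alpha,
                   nbimp = spec$nbimp, nbrep = spec$nbrep)
    } else {
      pool_effects(effects, "rubin", alpha)
    }
    row$estimate <- pe$point
    row$variance <- pe$total_variance
    row$ci_low <- pe$ci_low
    row$ci_high <- pe$ci_high
    row$safeguard <- pe$safeguard_applied
    if (spec$analysis == "psm") {
      row$n_pairs <- mean(vapply(effects, function(e) e$meta$n_pairs,
                                 numeric(1L)))
      row$n_treated_unmatched <-
        mean(vapply(effects, function(e) e$meta$n_treated_unmatched,
                    numeric(1L)))
    }
    row
  }
  tryCatch(fill(row), error = function(e) {
    row$failed <- TRUE
    row$error <- conditionMessage(e)
    row
  })
}

#' Run one simulation replicate
#'
#' Generates one cohort, imposes missingness once, and runs every method
#' on it: MI methods each impute the observed sample (matching, effect
#' estimation and pooling per completed dataset, the "within" approach);
#' complete-data methods analyse the pre-missingness cohort.  Component
#' errors (separation, zero cells, no pairs) mark that method failed for
#' the replicate and never abort the run.  The result is bit-for-bit
#' reproducible from the seed.
#'
#' @param scenario A `ps_scenario`.
#' @param methods List of `method_spec`s.
#' @param seed Integer replicate seed.
#' @param alpha Confidence level parameter (default 0.05).
#' @return A data frame with one row per method: estimate, variance, CI
#'   bounds, failure and safeguard flags, pair counts.
#' @export
run_replicate <- function(scenario, methods, seed, alpha = 0.05) {
  labels <- vapply(methods, function(m) m$label, character(1L))
  if (anyDuplicated(labels)) stop("method labels must be unique", call. = FALSE)
  seeds <- derive_seeds(seed, c("cohort", "missingness",
                                paste0("method_", labels)))
  complete <- generate_complete(scenario, seed = seeds[["cohort"]])
  obs <- impose_missingness(complete, scenario, seed = seeds[["missingness"]])
  rows <- lapply(seq_along(methods), function(i) {
    run_method(methods[[i]], complete, obs,
               seeds[[paste0("method_", labels[i])]], alpha)
  })
  do.call(rbind, rows)
}

#' Run a Monte Carlo simulation study
#'
#' Runs `nsim` independent replicates of [run_replicate()] on seeds
#' derived from `seed` (one sub-seed per replicate, so results do not
#' depend on execution order), computes the true estimands once, and
#' summarises performance per method with [performance_metrics()].
#'
#' @param scenario A `ps_scenario`.
#' @param methods List of `method_spec`s (default [default_methods()]).
#' @param nsim Number of replicates (>= 2).
#' @param seed Master seed.
#' @param truth Optional precomputed `true_estimands` (e.g. cached across
#'   studies of the same scenario); computed here when `NULL`.
#' @param n_true Simulation size for the truth computation.
#' @param alpha Miscoverage level for all confidence intervals.
#' @param verbose Print a progress line every 50 replicates.
#' @return An object of class `ps_study`: list with `scenario`, `truth`,
#'   `replicates` (long data frame) and `summary` (per-method metrics).
#' @export
run_study <- function(scenario, methods = default_methods(), nsim = 1000L,
                      seed = 1L, truth = NULL, n_true = 1e6, alpha = 0.05,
                      verbose = FALSE) {
  stopifnot(nsim >= 2L)
  seeds <- derive_seeds(seed, c("truth", paste0("replicate_", seq_len(nsim))))
  if (is.null(truth)) {
    truth <- compute_true_estimands(scenario, n_large = n_true,
                                    seed = seeds[["truth"]])
  }
  reps <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    r <- run_replicate(scenario, methods,
                       seed = seeds[[paste0("replicate_", i)]], alpha = alpha)
    r$replicate <- i
    reps[[i]] <- r
    if (verbose && i %% 50L == 0L) {
      message(sprintf("replicate %d / %d", i, nsim))
    }
  }
  replicates <- do.call(rbind, reps)
  summary <- do.call(rbind, lapply(methods, function(m) {
    truth_value <- truth[[paste(m$estimand,
                                if (m$scale == "rd") "rd" else "logor",
                                sep = "_")]]
    performance_metrics(replicates[replicates$method == m$label, ,
                                   drop = FALSE],
                        truth_value)
  }))
  rownames(summary) <- NULL
  structure(list(scenario = scenario, truth = truth, methods = methods,
                 replicates = replicates, summary = summary),
            class = "ps_study")
}

#' Performance metrics of a simulation study
#'
#' Computed over the non-failed replicates of each method: mean estimate;
#' relative bias `(mean - truth)/truth` (reported as absolute bias with a
#' flag when the truth is zero); empirical coverage of the confidence
#' intervals with its binomial Monte Carlo standard error; the empirical
#' SE of the point estimates and the mean model SE (mean of the square
#' roots of the reported variances) — over-coverage shows up as the model
#' SE exceeding the empirical SE.
#'
#' @param results Replicate rows as produced by [run_replicate()] /
#'   [run_study()]; may contain several methods.
#' @param truth The true estimand value the estimates target.
#' @return A data frame with one row per method.
#' @export
performance_metrics <- function(results, truth) {
  stopifnot(is.finite(truth))
  parts <- split(results, results$method)
  out <- lapply(parts, function(res) {
    ok <- res[!res$failed, , drop = FALSE]
    n <- nrow(ok)
    if (n < 2L) {
      stop("need at least 2 non-failed replicates for method ",
           res$method[1L], call. = FALSE)
    }
    mean_est <- mean(ok$estimate)
    absolute_bias <- truth == 0
    rel_bias <- if (absolute_bias) mean_est else (mean_est - truth) / truth
    cov <- mean(ok$ci_low <= truth & truth <= ok$ci_high)
    emp_se <- stats::sd(ok$estimate)
    data.frame(method = res$method[1L], scale = res$scale[1L],
               truth = truth, n_used = n,
               n_failed = sum(res$failed),
               mean_estimate = mean_est,
               rel_bias = rel_bias, absolute_bias = absolute_bias,
               coverage = cov,
               coverage_mc_se = sqrt(cov * (1 - cov) / n),
               empirical_se = emp_se,
               mean_model_se = mean(sqrt(ok$variance)),
               estimate_mc_se = emp_se / sqrt(n),
               n_safeguard = sum(ok$safeguard),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.ps_study <- function(x, ...) {
  cat(sprintf("Simulation study: %s confounding, beta0 = %g, N = %d, nsim = %d\n",
              x$scenario$level, x$scenario$beta0, x$scenario$n_patients,
              max(x$replicates$replicate)))
  print(x$truth)
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write study outputs to a directory
#'
#' Emits `replicates.csv` (the long per-replicate table),
#' `study_summary.json` (scenario, truth and per-method metrics) and
#' `metrics.csv` (the tidy summary).
#'
#' @param study A `ps_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ps_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$replicates, file.path(dir, "replicates.csv"),
                   row.names = FALSE)
  utils::write.csv(study$summary, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(scenario = unclass(study$scenario),
         truth = unclass(study$truth),
         summary = study$summary),
    file.path(dir, "study_summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
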