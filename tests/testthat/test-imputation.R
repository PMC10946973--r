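test_that("imputation model fit matches a normal-equations oracle", {
  obs <- make_obs_fixture(n = 50, seed = 101, miss_frac = 0.2)
  fit <- fit_imputation_model(obs)
  keep <- !is.na(obs$x2)
  X <- cbind(1, obs$x1[keep], obs$x3[keep], obs$z[keep], obs$y[keep])
  oracle <- oracle_ols(X, obs$x2[keep])
  expect_equal(unname(fit$coef), oracle$coef, tolerance = 1e-10)
  expect_equal(fit$rss, oracle$rss, tolerance = 1e-10)
  expect_equal(unname(fit$xtx_inv), unname(oracle$xtx_inv), tolerance = 1e-10)
  expect_equal(fit$df, sum(keep) - 5L)
})

test_that("a noiseless linear x2 is fit exactly and degenerate inputs error", {
  obs <- make_obs_fixture(n = 60, seed = 102)
  w <- c(0.3, 0.6, -0.2, 0.4, 0.25)
  obs$x2 <- w[1] + w[2] * obs$x1 + w[3] * obs$x3 + w[4] * obs$z + w[5] * obs$y
  fit <- fit_imputation_model(obs)
  expect_equal(fit$rss, 0, tolerance = 1e-18)
  expect_equal(unname(fit$coef), w, tolerance = 1e-10)

  all_na <- obs
  all_na$x2 <- NA_real_
  expect_error(fit_imputation_model(all_na), "at least 6 rows")

  few <- obs[1:5, ]
  expect_error(fit_imputation_model(few), "at least 6 rows")

  collinear <- make_obs_fixture(n = 60, seed = 103)
  collinear$x3 <- collinear$x1
  expect_error(fit_imputation_model(collinear), "collinear")
})

test_that("parameter draws follow the noninformative-prior posterior", {
  obs <- make_obs_fixture(n = 120, seed = 104)
  fit <- fit_imputation_model(obs)
  set.seed(105)
  ndraw <- 5000L
  draws <- replicate(ndraw, {
    d <- draw_parameters(fit)
    c(d$coef, d$sigma^2)
  })
  coef_draws <- draws[1:5, , drop = FALSE]
  sig2_draws <- draws[6, ]

  # posterior mean of the coefficients is the least-squares solution
  for (i in 1:5) {
    mc_se <- sd(coef_draws[i, ]) / sqrt(ndraw)
    expect_lt(abs(mean(coef_draws[i, ]) - fit$coef[i]), 3 * mc_se)
  }

  # E[sigma^2] = rss / (df - 2) for the scaled inverse chi-square
  mc_se <- sd(sig2_draws) / sqrt(ndraw)
  expect_lt(abs(mean(sig2_draws) - fit$rss / (fit$df - 2)), 3 * mc_se)

  # a perfect fit degenerates to a point mass
  exact <- obs
  exact$x2 <- 1 + exact$x1
  dfit <- fit_imputation_model(exact)
  d <- draw_parameters(dfit)
  expect_identical(d$sigma, 0)
  expect_identical(d$coef, dfit$coef)
})

test_that("imputation fills only masked rows, exactly as the draw dictates", {
  obs <- make_obs_fixture(n = 100, seed = 106)
  fit <- fit_imputation_model(obs)
  set.seed(107)
  draw <- draw_parameters(fit, k = 1L)
  mask <- is.na(obs$x2)

  set.seed(108)
  comp1 <- impute_from_draw(obs, draw)
  expect_false(anyNA(comp1$x2))
  expect_identical(comp1$x2[!mask], obs$x2[!mask])

  # a different noise stream changes only the masked entries
  set.seed(109)
  comp2 <- impute_from_draw(obs, draw)
  expect_identical(comp1$x2[!mask], comp2$x2[!mask])
  expect_false(any(comp1$x2[mask] == comp2$x2[mask]))

  # sigma = 0 reproduces the linear predictor exactly
  det_draw <- draw
  det_draw$sigma <- 0
  comp3 <- impute_from_draw(obs, det_draw)
  Xm <- cbind(1, obs$x1[mask], obs$x3[mask], obs$z[mask], obs$y[mask])
  expect_equal(comp3$x2[mask], drop(Xm %*% det_draw$coef), tolerance = 1e-12)

  # no masked rows: output equals input for any draw
  full <- obs
  full$x2[mask] <- 0
  comp4 <- impute_from_draw(full, draw)
  expect_identical(comp4$x2, full$x2)
})

test_that("classic and two-stage imputation have the promised structure", {
  obs <- make_obs_fixture(n = 150, seed = 110)

  imps <- multiple_impute(obs, nbimp = 20, seed = 111)
  expect_length(imps, 20L)
  expect_identical(vapply(imps, attr, integer(1L), "draw_k"), 1:20)
  expect_true(all(vapply(imps, attr, integer(1L), "rep_j") == 1L))
  expect_error(multiple_impute(obs, nbimp = 1), "at least 2")

  ts <- two_stage_impute(obs, nbimp = 4, nbrep = 3, seed = 112)
  expect_length(ts, 12L)
  expect_identical(vapply(ts, attr, integer(1L), "draw_k"),
                   rep(1:4, each = 3L))
  expect_identical(vapply(ts, attr, integer(1L), "rep_j"),
                   rep(1:3, times = 4L))
  expect_error(two_stage_impute(obs, nbimp = 4, nbrep = 1), "nbrep")
  expect_error(two_stage_impute(obs, nbimp = 1, nbrep = 3), "nbimp")

  # within a draw, datasets share parameters: unmasked rows identical and
  # masked rows differ only through the imputation noise
  mask <- is.na(obs$x2)
  expect_identical(ts[[1]]$x2[!mask], ts[[2]]$x2[!mask])
  expect_false(any(ts[[1]]$x2[mask] == ts[[2]]$x2[mask]))

  # a fully observed input yields identical completed datasets
  full <- obs
  full$x2[mask] <- 1.5
  ts_full <- two_stage_impute(full, nbimp = 3, nbrep = 2, seed = 113)
  for (d in ts_full) expect_identical(d$x2, full$x2)
})

test_that("imputation variance decomposes into within- and between-draw parts", {
  sc <- make_scenario("moderate", beta0 = -1, n_patients = 5000)
  obs <- impose_missingness(generate_complete(sc, seed = 114), sc, seed = 115)
  fit <- fit_imputation_model(obs)
  mask <- is.na(obs$x2)

  # across replicates of one draw, the per-cell variance averages sigma_k^2
  set.seed(116)
  draw <- draw_parameters(fit, k = 1L)
  reps <- replicate(200, impute_from_draw(obs, draw)$x2[mask])
  within_var <- mean(apply(reps, 1L, var))
  expect_lt(abs(within_var - draw$sigma^2) / draw$sigma^2, 0.05)

  # between-draw variability of the imputed-value mean exceeds the
  # within-draw variability of the same mean (what Reiter's U exploits)
  set.seed(117)
  ts <- two_stage_impute(obs, nbimp = 15, nbrep = 15)
  means <- matrix(vapply(ts, function(d) mean(d$x2[mask]), numeric(1L)),
                  nrow = 15, ncol = 15, byrow = TRUE)
  draw_means <- rowMeans(means)
  between <- var(draw_means)
  within <- mean(apply(means, 1L, var))
  expect_gt(between, within / 15)  # B exceeds its pure-noise expectation U/nbrep
})
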