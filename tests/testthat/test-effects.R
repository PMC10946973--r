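test_that("matched ATT has closed-form risk difference and log odds ratio", {
  # 3 pairs: treated outcomes {1,1,0}, controls {0,1,0} -> rd = 1/3
  y <- c(1, 1, 0, 0, 1, 0)
  m <- fake_matched(treated = 1:3, control = 4:6)
  z <- c(1L, 1L, 1L, 0L, 0L, 0L)
  est <- att_estimate(m, y, z, "rd")
  expect_equal(est$estimate, 1 / 3, tolerance = 1e-12)
  expect_equal(est$n_units, 6L)
  expect_equal(est$meta$n_pairs, 3L)

  # 2x2 table (a,b;c,d) = (30,20;10,40): logor = log 6
  y2 <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40))
  m2 <- fake_matched(treated = 1:50, control = 51:100)
  z2 <- rep(c(1L, 0L), each = 50L)
  est2 <- att_estimate(m2, y2, z2, "logor")
  expect_equal(est2$estimate, log(6), tolerance = 1e-12)

  # zero cell: log odds ratio flagged, not patched
  y3 <- c(rep(1, 50), rep(0, 50))
  expect_error(att_estimate(m2, y3, z2, "logor"), "zero cell")
  expect_error(att_estimate(fake_matched(1L, 2L), c(1, 0), c(1L, 0L), "rd"),
               "at least 2")
})

test_that("pair-clustered sandwich equals a direct score-sum oracle", {
  set.seed(301)
  for (scale in c("rd", "logor")) {
    for (case in 1:20) {
      G <- 10L
      yt <- rbinom(G, 1L, 0.6)
      yc <- rbinom(G, 1L, 0.4)
      if (scale == "logor" &&
          (mean(yt) %in% c(0, 1) || mean(yc) %in% c(0, 1))) next
      y <- c(yt, yc)
      z <- rep(c(1L, 0L), each = G)
      m <- fake_matched(treated = 1:G, control = (G + 1):(2L * G))
      est <- att_estimate(m, y, z, scale)
      p1 <- mean(yt); p0 <- mean(yc)
      mu <- ifelse(z == 1L, p1, p0)
      v <- if (scale == "rd") rep(1, 2L * G) else mu * (1 - mu)
      want <- oracle_cluster_sandwich(y, z, mu, v, rep(1:G, 2L))
      expect_equal(est$variance, want, tolerance = 1e-10)
    }
  }
})

test_that("pair-clustered sandwich agrees with an independent library oracle", {
  set.seed(302)
  G <- 40L
  yt <- rbinom(G, 1L, 0.65)
  yc <- rbinom(G, 1L, 0.35)
  y <- c(yt, yc)
  z <- rep(c(1L, 0L), each = G)
  pair <- rep(1:G, 2L)
  m <- fake_matched(treated = 1:G, control = (G + 1):(2L * G))

  fit <- glm(y ~ z, family = binomial())
  V <- sandwich::vcovCL(fit, cluster = pair, type = "HC0", cadjust = TRUE)
  expect_equal(att_estimate(m, y, z, "logor")$variance, V["z", "z"],
               tolerance = 1e-8)

  lmfit <- glm(y ~ z)
  Vlm <- sandwich::vcovCL(lmfit, cluster = pair, type = "HC0", cadjust = TRUE)
  expect_equal(att_estimate(m, y, z, "rd")$variance, Vlm["z", "z"],
               tolerance = 1e-8)
})

test_that("singleton clusters recover the i.i.d. robust variance", {
  set.seed(303)
  n <- 30L
  y <- rbinom(n, 1L, 0.5)
  z <- rep(c(1L, 0L), each = n / 2L)
  p1 <- mean(y[z == 1L]); p0 <- mean(y[z == 0L])
  mu <- ifelse(z == 1L, p1, p0)
  v_pairs <- psmi:::sandwich_treatment_var(y, z, mu, rep(1, n), seq_len(n),
                                           cr_correction = FALSE)
  want <- oracle_cluster_sandwich(y, z, mu, rep(1, n), seq_len(n),
                                  cr_correction = FALSE)
  expect_equal(v_pairs, want, tolerance = 1e-12)
})

test_that("IPTW reduces to the plain contrast under a constant score", {
  set.seed(304)
  n <- 400L
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$z <- rbinom(n, 1L, 0.5)
  d$y <- rbinom(n, 1L, 0.3 + 0.2 * d$z)
  class(d) <- c("completed_sample", "data.frame")
  fit <- structure(list(coefficients = c(0, 0, 0, 0),
                        ps = rep(0.5, n), logit_ps = rep(0, n)),
                   class = "propensity_fit")
  est <- iptw_ate(d, fit, "rd")
  expect_equal(est$estimate,
               mean(d$y[d$z == 1L]) - mean(d$y[d$z == 0L]),
               tolerance = 1e-12)
})

test_that("IPTW weighted means match a Horvitz-Thompson oracle", {
  set.seed(305)
  n <- 20L
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$z <- rep(c(1L, 0L), times = n / 2L)
  d$y <- rbinom(n, 1L, 0.5)
  class(d) <- c("completed_sample", "data.frame")
  ps <- runif(n, 0.2, 0.8)
  fit <- structure(list(coefficients = rep(0, 4), ps = ps,
                        logit_ps = qlogis(ps)),
                   class = "propensity_fit")
  w <- d$z / ps + (1 - d$z) / (1 - ps)
  ht <- sum(w * d$z * d$y) / sum(w * d$z) -
    sum(w * (1 - d$z) * d$y) / sum(w * (1 - d$z))
  est <- iptw_ate(d, fit, "rd")
  expect_equal(est$estimate, ht, tolerance = 1e-12)

  # the weighted contrast is invariant to rescaling all weights
  w7 <- 7 * w
  ht7 <- sum(w7 * d$z * d$y) / sum(w7 * d$z) -
    sum(w7 * (1 - d$z) * d$y) / sum(w7 * (1 - d$z))
  expect_equal(ht7, ht, tolerance = 1e-12)

  bad <- fit
  bad$ps[1] <- 1
  expect_error(iptw_ate(d, bad, "rd"), "positivity")
})

test_that("crude estimates follow the 2x2 closed forms", {
  balanced <- data.frame(z = rep(c(1L, 0L), each = 20L),
                         y = rep(c(1L, 0L, 1L, 0L), each = 10L))
  expect_equal(crude_estimate(balanced, "logor")$estimate, 0, tolerance = 1e-12)
  expect_equal(crude_estimate(balanced, "rd")$estimate, 0, tolerance = 1e-12)

  tab <- data.frame(z = rep(c(1L, 0L), times = c(50L, 50L)),
                    y = c(rep(1L, 30), rep(0L, 20), rep(1L, 10), rep(0L, 40)))
  est <- crude_estimate(tab, "logor")
  expect_equal(est$estimate, log(6), tolerance = 1e-12)
  expect_equal(est$variance, 1 / 30 + 1 / 20 + 1 / 10 + 1 / 40,
               tolerance = 1e-12)

  zero <- data.frame(z = rep(c(1L, 0L), each = 5L),
                     y = c(rep(1L, 5), rep(0L, 5)))
  expect_error(crude_estimate(zero, "logor"), "zero cell")
  one_arm <- data.frame(z = rep(1L, 5), y = rep(0L, 5))
  expect_error(crude_estimate(one_arm, "rd"), "non-empty")
})

test_that("effect estimates serialize to JSON with all declared fields", {
  est <- crude_estimate(data.frame(z = rep(c(1L, 0L), each = 10L),
                                   y = rep(c(1L, 0L), times = 10L)), "rd")
  parsed <- jsonlite::fromJSON(effect_to_json(est))
  expect_named(parsed, c("scale", "estimate", "variance", "n_units", "meta"))
  expect_equal(parsed$estimate, est$estimate)
})
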