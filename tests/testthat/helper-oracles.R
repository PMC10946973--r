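# Independent oracles used to cross-check the implementation.  Each is a
# deliberately plain, direct computation (loops, normal equations,
# exhaustive replay) kept free of the package's own code paths.

# Logistic regression by hand-rolled Newton-Raphson (IRLS) on a design
# matrix with intercept included as the first column.
oracle_logit_irls <- function(X, y, tol = 1e-12, maxit = 100L) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * W, X)
    step <- solve(info, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(coef = beta, vcov = solve(crossprod(X * W, X)))
}

# Normal-equations least squares: solve X'X b = X'y directly.
oracle_ols <- function(X, y) {
  b <- solve(crossprod(X), crossprod(X, y))
  res <- y - drop(X %*% b)
  list(coef = drop(b), rss = sum(res^2), xtx_inv = solve(crossprod(X)))
}

# Greedy caliper matching replayed step by step in plain R, following the
# documented rule: treated in decreasing logit order (ties by index);
# candidate controls ranked by (distance, logit value, index); skip if the
# best distance exceeds the caliper; matched controls are consumed.
oracle_greedy_match <- function(lps, z, caliper) {
  treated <- which(z == 1L)
  treated <- treated[order(-lps[treated], treated)]
  avail <- which(z == 0L)
  t_out <- integer(0)
  c_out <- integer(0)
  for (t in treated) {
    if (length(avail) == 0L) break
    d <- abs(lps[avail] - lps[t])
    ord <- order(d, lps[avail], avail)
    best <- avail[ord[1L]]
    if (d[ord[1L]] <= caliper) {
      t_out <- c(t_out, t)
      c_out <- c(c_out, best)
      avail <- setdiff(avail, best)
    }
  }
  data.frame(treated = t_out, control = c_out)
}

# Cluster-robust sandwich variance of the treatment coefficient assembled
# term by term: bread from the weighted information, meat from the sum of
# per-cluster score outer products, optional G/(G-1) correction.
oracle_cluster_sandwich <- function(y, z, mu, v, cluster, w = NULL,
                                    cr_correction = TRUE) {
  if (is.null(w)) w <- rep(1, length(y))
  X <- cbind(1, z)
  A <- matrix(0, 2, 2)
  for (i in seq_along(y)) {
    A <- A + w[i] * v[i] * tcrossprod(X[i, ])
  }
  M <- matrix(0, 2, 2)
  for (g in unique(cluster)) {
    u <- c(0, 0)
    for (i in which(cluster == g)) {
      u <- u + w[i] * X[i, ] * (y[i] - mu[i])
    }
    M <- M + tcrossprod(u)
  }
  V <- solve(A) %*% M %*% solve(A)
  if (cr_correction) {
    G <- length(unique(cluster))
    V <- V * G / (G - 1)
  }
  V[2, 2]
}

# Two-pass sample standard deviation.
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Small observed sample with missing x2, generated from an arbitrary
# (non-scenario) joint model; handy for imputation and matching unit tests.
make_obs_fixture <- function(n = 200L, seed = 1L, miss_frac = 0.3) {
  set.seed(seed)
  x1 <- rnorm(n)
  x3 <- rnorm(n)
  z <- rbinom(n, 1L, plogis(-0.4 + 0.5 * x1 - 0.3 * x3))
  x2 <- 0.3 + 0.6 * x1 - 0.2 * x3 + 0.4 * z + rnorm(n, sd = 0.8)
  y <- rbinom(n, 1L, plogis(-0.5 + 0.4 * x1 + 0.5 * x2 + 0.7 * z))
  obs <- data.frame(x1 = x1, x2 = x2, x3 = x3, z = z, y = y)
  obs$x2[runif(n) < miss_frac] <- NA_real_
  class(obs) <- c("observed_sample", "data.frame")
  obs
}

# Hand-built matched sample (bypasses greedy_match) for effect tests.
fake_matched <- function(treated, control, caliper = 1, unmatched = 0L) {
  structure(list(pairs = data.frame(treated = treated, control = control),
                 caliper = caliper, n_treated_unmatched = unmatched),
            class = "matched_sample")
}
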