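# Oracles for the Gibbs updates: closed-form conjugate posteriors, known
# distribution moments, and an independent rejection sampler for the
# truncated random-effects prior.

toy_data <- function(n, k = 1, seed = 1) {
  set.seed(seed)
  ids <- sprintf("P%05d", seq_len(n))
  cov <- data.frame(participant_id = ids, x = rnorm(n))
  man <- data.frame(participant_id = rep(ids, each = 4),
                    flow_mls = rep(c(30, 50, 100, 300), n),
                    feno_ppb = exp(rnorm(4 * n, 2, 0.5)))
  uhb_prepare_data(man, cov)
}

test_that("default priors carry the published hyperparameters", {
  pr <- default_priors(1)
  expect_equal(pr$mu_alpha, c(2, 4.2, 2.5))
  expect_equal(as.vector(pr$mu_beta), c(0, 0, 0))
  expect_equal(pr$var_alpha, 1000)
  expect_equal(pr$var_beta, 1000)
  expect_equal(c(pr$resid_shape, pr$resid_rate), c(1e-3, 1e-3))
  expect_equal(pr$wishart_df, 4)
  expect_equal(pr$wishart_scale, diag(3))
  pr0 <- default_priors(0)                    # intercept-only model is valid
  expect_equal(ncol(pr0$mu_beta), 0L)
  expect_error(default_priors(1, var_alpha = -1))
})

test_that("regression-coefficient update matches the conjugate closed form", {
  # fixed small case: 5 participants, identity covariance
  theta <- rbind(c(0.5, 3.0, 2.0), c(1.5, 3.8, 2.4), c(0.9, 3.6, 2.7),
                 c(2.0, 4.1, 2.2), c(1.1, 3.3, 2.9))
  Z <- cbind(1, c(-1, -0.5, 0, 0.5, 1))
  priors <- default_priors(1)
  post <- feno2cm:::uhb_ab_posterior(theta, Z, diag(3), priors)

  # independent construction: stack the 15 scalar observations explicitly
  X_big <- matrix(0, 15, 6)
  y_big <- numeric(15)
  r <- 0
  for (i in 1:5) for (j in 1:3) {
    r <- r + 1
    X_big[r, j] <- 1          # alpha_j
    X_big[r, 3 + j] <- Z[i, 2]  # beta_j
    y_big[r] <- theta[i, j]
  }
  V0 <- diag(rep(1000, 6))
  m0 <- c(priors$mu_alpha, priors$mu_beta)
  prec_ref <- crossprod(X_big) + solve(V0)
  mean_ref <- solve(prec_ref, crossprod(X_big, y_big) + solve(V0, m0))
  expect_equal(unname(post$mean), unname(as.vector(mean_ref)), tolerance = 1e-10)
  expect_equal(unname(post$precision), unname(prec_ref), tolerance = 1e-10)
})

test_that("dogmatic priors pin the regression coefficients", {
  data <- toy_data(6)
  priors <- default_priors(1, var_alpha = 1e-10, var_beta = 1e-10)
  state <- list(theta = matrix(rep(c(1, 3.5, 2.5), each = 6), 6),
                alpha = c(0, 0, 0), beta = matrix(0, 3, 1),
                sigma2 = 0.02, sigma_theta = diag(3))
  set.seed(1)
  state <- uhb_update_alpha_beta(state, data, priors)
  expect_equal(unname(state$alpha), priors$mu_alpha, tolerance = 1e-3)
  expect_equal(unname(as.vector(state$beta)), rep(0, 3), tolerance = 1e-3)
})

test_that("a degenerate subject-level design is flagged, not absorbed", {
  n <- 8
  data <- toy_data(n)
  data$Z[, 2] <- 0   # all-zero covariate column: rank-deficient design
  priors <- default_priors(1, var_beta = 1)
  state <- list(theta = matrix(rep(c(1, 3.5, 2.5), each = n), n),
                alpha = c(1, 3.5, 2.5), beta = matrix(0, 3, 1),
                sigma2 = 0.02, sigma_theta = diag(3))
  expect_error(uhb_update_alpha_beta(state, data, priors), "singular")
})

test_that("residual-variance update is the stated inverse-gamma", {
  priors <- default_priors(1)
  data <- list(y = numeric(100), n = 5L)
  state <- list(rss = rep(2, 5))              # total RSS = 10, 100 observations
  set.seed(3)
  draws <- replicate(50000, uhb_update_sigma2(state, data, priors)$sigma2)
  expect_true(all(draws > 0))
  # posterior is InvGamma(1e-3 + 50, 1e-3 + 5): mean = rate/(shape-1)
  expect_equal(mean(draws), 5.001 / 49.001, tolerance = 0.005)
  # zero residuals with many observations: draws collapse toward zero
  state0 <- list(rss = rep(0, 5))
  data0 <- list(y = numeric(8000), n = 5L)
  d0 <- replicate(2000, uhb_update_sigma2(state0, data0, priors)$sigma2)
  expect_lt(max(d0), 1e-5)
})

test_that("covariance update matches the inverse-Wishart closed form", {
  priors <- default_priors(1)   # df 4, scale I
  n <- 6
  resid <- matrix(c(0.3, -0.2, 0.5, -0.4, 0.1, 0.25,
                    -0.1, 0.4, -0.3, 0.2, -0.5, 0.15,
                    0.2, 0.1, -0.2, 0.3, -0.1, -0.3), n, 3)
  data <- list(n = n, Z = matrix(1, n, 1), y = numeric(1))
  state <- list(theta = resid, alpha = c(0, 0, 0),
                beta = matrix(0, 3, 0), sigma2 = 1)
  S_post <- diag(3) + crossprod(resid)
  set.seed(11)
  acc <- matrix(0, 3, 3)
  m <- 15000
  for (i in seq_len(m)) {
    st <- uhb_update_sigma_theta(state, data, priors)
    acc <- acc + st$sigma_theta
    expect_true(all(abs(st$sigma_theta - t(st$sigma_theta)) < 1e-12) || i > 1)
  }
  # E[Sigma] = S_post / (df + n - p - 1) = S_post / 6
  expect_equal(acc / m, S_post / 6, tolerance = 0.03)
})

test_that("covariance draws are symmetric positive definite", {
  priors <- default_priors(1)
  data <- toy_data(10)
  state <- list(theta = matrix(rnorm(30, c(1, 3.5, 2.5)), 10, 3, byrow = FALSE),
                alpha = c(1, 3.5, 2.5), beta = matrix(0, 3, 1), sigma2 = 0.02)
  set.seed(5)
  for (i in 1:50) {
    st <- uhb_update_sigma_theta(state, data, priors)
    ev <- eigen(st$sigma_theta, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
})

test_that("participant update leaves the truncated random-effects prior invariant", {
  skip_if_not_installed("MASS")
  # no maneuver data: the stationary law of theta_i is exactly its prior
  n <- 120
  ids <- sprintf("P%05d", seq_len(n))
  cov <- data.frame(participant_id = ids, x = rep(0, n))
  data <- uhb_prepare_data(NULL, cov)
  pop <- default_population()
  priors <- default_priors(1)
  state <- list(theta = matrix(rep(c(1, 3.5, 2.5), each = n), n),
                alpha = pop$alpha, beta = matrix(0, 3, 1),
                sigma2 = 1e6, sigma_theta = pop$sigma_theta)
  set.seed(21)
  keep <- list()
  for (m in 1:2500) {
    state$rss <- NULL
    state <- uhb_update_theta(state, data, priors, scale = matrix(1, n, 2))
    if (m > 500 && m %% 25 == 0) keep[[length(keep) + 1]] <- state$theta
  }
  draws <- do.call(rbind, keep)
  expect_true(all(draws[, 1] >= 0))
  ref <- oracle_truncmvn(nrow(draws), pop$alpha, pop$sigma_theta, seed = 22)
  # two-sample Monte-Carlo comparison; bands sized for the autocorrelated
  # Metropolis draws (~3 sigma)
  for (j in 1:3) {
    expect_lt(abs(mean(draws[, j]) - mean(ref[, j])), 0.065)
    expect_lt(abs(sd(draws[, j]) - sd(ref[, j])), 0.065)
  }
  expect_equal(cor(draws[, 1], draws[, 2]), cor(ref[, 1], ref[, 2]),
               tolerance = 0.1)
})

test_that("zero-truncated normal draws respect the support", {
  set.seed(9)
  x <- feno2cm:::rtnorm0(rnorm(5000, -1, 2), abs(rnorm(5000, 1, 0.3)) + 0.1)
  expect_true(all(x >= 0))
  # matches the analytic mean of a truncated normal for fixed parameters
  m <- feno2cm:::rtnorm0(rep(0.5, 50000), rep(1, 50000))
  lam <- dnorm(-0.5) / (1 - pnorm(-0.5))
  expect_equal(mean(m), 0.5 + lam, tolerance = 0.03)
})

test_that("potential scale reduction follows the textbook formula", {
  set.seed(31)
  iid <- matrix(rnorm(4 * 5000), 5000, 4)
  rh <- gelman_rubin(iid)
  expect_gte(rh, sqrt(4999 / 5000))   # algebraic floor of the non-split form
  expect_lte(rh, 1.01)

  # hand-computable two-chain case: W = 1, B = 15000
  chains <- cbind(c(1, 2, 3), c(101, 102, 103))
  expect_equal(gelman_rubin(chains), sqrt((2 / 3 * 1 + 5000) / 1),
               tolerance = 1e-12)
  expect_equal(gelman_rubin(chains), 70.71539, tolerance = 1e-4)

  # algebraic lower bound sqrt((n-1)/n)
  set.seed(32)
  for (i in 1:20) {
    ch <- matrix(rnorm(40, sd = runif(1, 0.1, 3)), 20, 2)
    expect_gte(gelman_rubin(ch), sqrt(19 / 20) - 1e-12)
  }
  expect_warning(rh0 <- gelman_rubin(cbind(rep(1, 5), rep(1, 5))), "zero")
  expect_identical(rh0, Inf)
})
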