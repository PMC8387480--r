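test_that("forward and successive-conditional simulation agree (Geweke)", {
  # Joint-distribution check of the full sweep: iterating (parameter updates
  # given data) with (data regeneration given parameters) must preserve the
  # prior marginals of the parameters.  Toy priors keep the c_alv truncation
  # mass negligible so the conjugate updates are exact here.
  set.seed(99)
  n <- 20
  flows <- c(30, 50, 100, 300)
  X <- matrix(seq(-1, 1, length.out = n), n, 1)
  ids <- sprintf("P%05d", seq_len(n))
  cov <- data.frame(participant_id = ids, x = X[, 1])
  priors <- default_priors(1, mu_alpha = c(2, 3.5, 2.5), var_alpha = 0.09,
                           var_beta = 0.04, resid_shape = 3, resid_rate = 0.1,
                           wishart_df = 12, wishart_scale = diag(3) * 0.4)
  draw_prior <- function() {
    list(alpha = rnorm(3, priors$mu_alpha, 0.3),
         beta = matrix(rnorm(3, 0, 0.2), 3, 1),
         sigma_theta = solve(rWishart(1, 12, solve(diag(3) * 0.4))[, , 1]),
         sigma2 = 1 / rgamma(1, 3, rate = 0.1))
  }
  gen_theta <- function(p) {
    R <- chol(p$sigma_theta)
    mu <- matrix(p$alpha, n, 3, byrow = TRUE) + X %*% t(p$beta)
    th <- matrix(NA_real_, n, 3); pend <- seq_len(n)
    while (length(pend)) {
      cand <- mu[pend, , drop = FALSE] +
        matrix(rnorm(3 * length(pend)), ncol = 3) %*% R
      ok <- cand[, 1] >= 0
      th[pend[ok], ] <- cand[ok, , drop = FALSE]; pend <- pend[!ok]
    }
    th
  }
  gen_y <- function(th, s2) {
    as.vector(t(log_feno_mean(th, flows))) + rnorm(n * 4, 0, sqrt(s2))
  }
  mon <- function(p) c(p$alpha, as.vector(p$beta), diag(p$sigma_theta),
                       log(p$sigma2))
  M <- 2500
  fw <- t(replicate(M, { p <- draw_prior(); gen_theta(p); mon(p) }))

  p <- draw_prior(); th <- gen_theta(p)
  man0 <- data.frame(participant_id = rep(ids, each = 4),
                     flow_mls = rep(flows, n),
                     feno_ppb = exp(gen_y(th, p$sigma2)))
  data <- uhb_prepare_data(man0, cov)
  data$prop <- feno2cm:::uhb_theta_proposal(man0, data)
  state <- list(theta = th, alpha = p$alpha, beta = p$beta,
                sigma2 = p$sigma2, sigma_theta = p$sigma_theta)
  thin <- 5
  sc <- matrix(NA_real_, M, ncol(fw))
  for (m in seq_len(M * thin)) {
    state <- uhb_update_theta(state, data, priors, scale = matrix(0.4, n, 2))
    state <- uhb_update_translation(state, data, priors)
    state <- uhb_update_rescale(state, data, priors, scale = 0.05)
    state <- uhb_update_alpha_beta(state, data, priors)
    state <- uhb_update_sigma_theta(state, data, priors)
    state <- uhb_update_sigma2(state, data, priors)
    data$y <- gen_y(state$theta, state$sigma2)
  data$ymat <- matrix(data$y, n, 4, byrow = TRUE)
    state$rss <- NULL
    if (m %% thin == 0) sc[m / thin, ] <- mon(state)
  }
  bmse <- function(x) {
    nb <- 30; bs <- floor(length(x) / nb)
    sd(colMeans(matrix(x[seq_len(nb * bs)], bs, nb))) / sqrt(nb)
  }
  for (j in seq_len(ncol(fw))) {
    se <- sqrt(bmse(sc[, j])^2 + var(fw[, j]) / M)
    z <- (mean(sc[, j]) - mean(fw[, j])) / se
    expect_lt(abs(z), 4)
  }
})

test_that("with the likelihood disabled the chain recovers the prior", {
  # no maneuvers: alpha and beta marginals must match their priors.  The
  # c_alv intercept prior sits far from the truncation boundary so that the
  # conjugate updates' neglect of the truncation mass (a documented
  # approximation, negligible in that regime) does not confound the check.
  n <- 5
  ids <- sprintf("P%05d", seq_len(n))
  cov <- data.frame(participant_id = ids, x = seq(-1, 1, length.out = n))
  data <- uhb_prepare_data(NULL, cov)
  priors <- default_priors(1, mu_alpha = c(6, 3.5, 2.5), var_alpha = 1,
                           var_beta = 1, wishart_df = 12,
                           wishart_scale = diag(3) * 0.4)
  state <- list(theta = matrix(rep(c(6, 3.5, 2.5), each = n), n),
                alpha = c(6, 3.5, 2.5), beta = matrix(0, 3, 1),
                sigma2 = 1, sigma_theta = diag(3) * 0.05)
  set.seed(41)
  keep <- matrix(NA_real_, 2500, 6)
  for (m in 1:25000) {
    state <- uhb_update_theta(state, data, priors, scale = matrix(1.2, n, 2))
    state <- uhb_update_translation(state, data, priors, scales = rep(0.8, 4))
    state <- uhb_update_alpha_beta(state, data, priors)
    state <- uhb_update_sigma_theta(state, data, priors)
    state$rss <- NULL
    if (m %% 10 == 0) keep[m / 10, ] <- c(state$alpha, as.vector(state$beta))
  }
  mu_ref <- c(6, 3.5, 2.5, 0, 0, 0)
  for (j in 1:6) {
    expect_lt(abs(mean(keep[, j]) - mu_ref[j]), 0.2)   # prior mean, var 1
    expect_lt(abs(sd(keep[, j]) - 1), 0.2)
  }
})

test_that("seeded sampler runs are reproducible and structurally sound", {
  pop <- population_params(c(1, 3.5, 2.5), c(0.3, 0, 0),
                           sigma_theta = default_population()$sigma_theta,
                           sigma_resid = 0.15)
  sim <- simulate_dataset(pop, 60, seed = 8)
  cov <- sim$participants[, c("participant_id", "x")]
  ctl <- uhb_control(warmup = 300, check_every = 200, retained_total = 900,
                     max_iter = 1200)
  f1 <- uhb_fit(sim$maneuvers, cov, seed = 4, control = ctl)
  f2 <- uhb_fit(sim$maneuvers, cov, seed = 4, control = ctl)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), 900L)
  expect_equal(f1$n_chains, 3L)
  expect_setequal(
    c("alpha1", "alpha2", "alpha3", "beta1", "beta2", "beta3", "sigma2",
      "s11", "s21", "s31", "s22", "s32", "s33"),
    f1$summary$parameter)
  expect_true(all(f1$summary$q2_5 <= f1$summary$q97_5))
  expect_true(all(f1$summary$sd >= 0))
  # every retained participant-level draw satisfies the state invariants
  expect_gt(length(f1$theta_draws), 0)
  for (th in f1$theta_draws) expect_true(all(th[, 1] >= 0))
  # effect rows in the common layout
  expect_equal(f1$effects$parameter, c("c_alv", "log_caw", "log_daw"))
  expect_equal(f1$effects$n_used, rep(60L, 3))
})

test_that("airway-flux posterior is the per-draw product transform", {
  # degenerate draws: point mass at the product
  d <- matrix(rep(c(1.2, 0.8), each = 50), 50, 2,
              dimnames = list(NULL, c("alpha2", "alpha3")))
  pj <- posterior_jaw(d, "alpha2", "alpha3")
  expect_equal(pj$mean, exp(2), tolerance = 1e-12)
  expect_equal(pj$sd, 0)
  expect_equal(pj$q2_5, exp(2))

  # lognormal moment identity for independent normal draws
  set.seed(51)
  m <- cbind(alpha2 = rnorm(200000, 3.5, 0.1), alpha3 = rnorm(200000, 2.5, 0.2))
  pj2 <- posterior_jaw(m, "alpha2", "alpha3")
  expect_equal(pj2$mean, exp(6 + (0.01 + 0.04) / 2), tolerance = 0.005)

  # monotone transform: interval endpoints commute with exp (up to the
  # interpolation of empirical quantiles)
  s <- m[1:999, "alpha2"] + m[1:999, "alpha3"]
  pj3 <- posterior_jaw(m[1:999, ], "alpha2", "alpha3")
  expect_equal(pj3$q2_5, exp(quantile(s, 0.025, names = FALSE)),
               tolerance = 1e-3)
  expect_equal(pj3$q97_5, exp(quantile(s, 0.975, names = FALSE)),
               tolerance = 1e-3)
})
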