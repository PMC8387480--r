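test_that("NLS recovers the generating parameters exactly on noise-free data", {
  man <- one_participant(sigma = 0)
  fit <- nls_fit(man$flow_mls, man$feno_ppb)
  expect_true(fit$converged)
  expect_theta_equal(fit$theta_hat, theta_ref, 1e-6)
  # a converged fit can never do worse than the generating parameters
  man_noisy <- one_participant(sigma = 0.15, seed = 2)
  fitn <- nls_fit(man_noisy$flow_mls, man_noisy$feno_ppb)
  sse_truth <- sum((log(man_noisy$feno_ppb) -
                      log_feno_mean(theta_ref, man_noisy$flow_mls))^2)
  expect_true(fitn$converged)
  expect_lte(fitn$sse, sse_truth)
})

test_that("NLS objective matches a brute-force grid search", {
  man <- one_participant(sigma = 0.15, seed = 3)
  y <- log(man$feno_ppb)
  fit <- nls_fit(man$flow_mls, man$feno_ppb)
  expect_true(fit$converged)
  g <- expand.grid(ca = seq(0, 10, length.out = 35),
                   lcaw = seq(1, 6, length.out = 35),
                   ldaw = seq(0, 5, length.out = 35))
  obj <- vapply(seq_len(nrow(g)), function(i) {
    sum((y - log_feno_mean(as.numeric(g[i, ]), man$flow_mls))^2)
  }, numeric(1))
  expect_lte(fit$sse, min(obj) + 1e-4)
})

test_that("NLS structural preconditions are distinguished from optimizer failure", {
  man <- one_participant()
  r1 <- nls_fit(rep(c(30, 100), 3), man$feno_ppb[1:6])
  expect_false(r1$converged)
  expect_match(r1$reason, "distinct flows")
  r2 <- nls_fit(c(30, 100, 300), man$feno_ppb[1:3])
  expect_false(r2$converged)
  expect_match(r2$reason, "maneuvers")
  expect_error(nls_fit(c(30, -5, 100, 300), man$feno_ppb[1:4]), "positive")
})

test_that("constrained NLS respects the alveolar lower bound", {
  # noise-free c_alv = 0: unconstrained recovers 0, constrained sits at the bound
  man <- one_participant(theta = c(0, 3.5, 2.5), sigma = 0)
  fu <- nls_fit(man$flow_mls, man$feno_ppb)
  expect_true(fu$converged)
  expect_equal(unname(fu$theta_hat[1]), 0, tolerance = 1e-6)
  fc <- nls_fit(man$flow_mls, man$feno_ppb, constrained = TRUE)
  expect_true(fc$converged)
  expect_equal(unname(fc$theta_hat[1]), 0.001, tolerance = 1e-6)
  expect_gte(fc$sse, fu$sse)
  # under noise the constrained estimate never dips below the bound
  for (s in c(2, 3, 8)) {
    mn <- one_participant(theta = c(0, 3.5, 2.5), sigma = 0.15, seed = s)
    fcs <- nls_fit(mn$flow_mls, mn$feno_ppb, constrained = TRUE)
    if (fcs$converged) expect_gte(unname(fcs$theta_hat[1]), 0.001 - 1e-9)
  }
})

test_that("batched NLS agrees with stats::nls on shared data", {
  pop <- default_population()
  sim <- simulate_dataset(pop, 80, seed = 31)
  s1 <- fit_stage1(sim$maneuvers, "nls")
  grfun <- deriv(~ log(exp(lcaw) + (ca - exp(lcaw)) * exp(-exp(ldaw) / v)),
                 c("ca", "lcaw", "ldaw"), function(ca, lcaw, ldaw, v) NULL)
  agree <- 0; both <- 0; maxdiff <- 0
  for (i in seq_len(80)) {
    rows <- sim$maneuvers$participant_id == s1$participant_id[i]
    dd <- list(lf = log(sim$maneuvers$feno_ppb[rows]),
               v = sim$maneuvers$flow_mls[rows])
    st <- feno2cm:::nls_start_values(dd$v, exp(dd$lf))
    ref <- try(suppressWarnings(nls(lf ~ grfun(ca, lcaw, ldaw, v), data = dd,
                                    start = list(ca = st[1], lcaw = st[2], ldaw = st[3]))),
               silent = TRUE)
    ok_ref <- !inherits(ref, "try-error")
    if (!ok_ref) {
      ref <- try(suppressWarnings(nls(lf ~ grfun(ca, lcaw, ldaw, v), data = dd,
                                      start = list(ca = 1, lcaw = 3.5, ldaw = 2.5))),
                 silent = TRUE)
      ok_ref <- !inherits(ref, "try-error")
    }
    if (ok_ref) {
      cf <- coef(ref)
      ok_ref <- cf[1] > -50 && cf[1] < 200 && all(cf[2:3] > -5) && all(cf[2:3] < 10)
    }
    if (ok_ref == s1$converged[i]) agree <- agree + 1
    if (ok_ref && s1$converged[i]) {
      both <- both + 1
      maxdiff <- max(maxdiff, max(abs(coef(ref) - as.numeric(s1[i, 4:6]))))
    }
  }
  expect_gte(agree / 80, 0.8)
  expect_gte(both, 30)
  expect_lt(maxdiff, 1e-3)
})

test_that("flow-level averaging produces the HMA input triple", {
  man <- data.frame(
    participant_id = c(rep("A", 8), rep("B", 6)),
    flow_mls = c(30, 30, 50, 50, 100, 100, 300, 300, 30, 30, 50, 100, 100, 100),
    feno_ppb = c(40, 44, 30, 31, 10, 12, 4, 5, 20, 22, 15, 8, 9, 10))
  av <- average_by_flow_level(man)
  expect_equal(av$feno_low[av$participant_id == "A"], 42)   # mean of 40, 44
  expect_equal(av$feno_high[av$participant_id == "A"], 4.5)
  expect_true(av$complete[av$participant_id == "A"])
  # B has no 300 mL/s maneuver: non-estimable for the three-flow algorithm
  expect_false(av$complete[av$participant_id == "B"])
  s1 <- fit_stage1(man, "hma")
  expect_false(s1$converged[s1$participant_id == "B"])
  expect_match(s1$diagnostics[s1$participant_id == "B"], "missing flow level")
})

test_that("three-flow estimator solves its own forward model exactly", {
  v <- c(30, 100, 300)
  phi <- function(D, V) D / V * (1 - D / (2 * V) + D^2 / (6 * V^2))
  ca <- 1; caw <- 33.1; D <- 12.2; jp <- caw * D
  f <- c(ca + (jp / D - ca) * phi(D, v[1]),   # third-order low-flow equation
         ca + jp / v[2], ca + jp / v[3])      # high-flow linear relation
  fit <- hma_fit(v, f, tol = 1e-10)
  expect_true(fit$converged)
  expect_equal(unname(fit$theta_hat[1]), ca, tolerance = 1e-6)
  expect_equal(unname(exp(fit$theta_hat[2])), caw, tolerance = 1e-4)
  expect_equal(unname(exp(fit$theta_hat[3])), D, tolerance = 1e-4)
})

test_that("three-flow estimator on exact 2CM data is close but approximate", {
  v <- c(30, 100, 300)
  f <- feno_mean(theta_ref, v)
  fit <- hma_fit(v, f)
  expect_true(fit$converged)
  # third-order truncation error: near, but measurably different from, truth
  expect_lt(abs(fit$theta_hat[1] - 1), 0.3)
  expect_gt(abs(fit$theta_hat[1] - 1), 1e-8)
  # flat triple: no airway-alveolar gradient, degenerate
  expect_false(hma_fit(v, c(8, 8, 8))$converged)
  # rising high-flow FeNO: negative flux, non-estimable
  expect_false(hma_fit(v, c(10, 4, 6))$converged)
  expect_error(hma_fit(c(100, 30, 300), f), "increasing")
})

test_that("stage-I drivers are deterministic and batch equals single fits", {
  pop <- default_population()
  sim <- simulate_dataset(pop, 40, seed = 51)
  s1a <- fit_stage1(sim$maneuvers, "nls")
  s1b <- fit_stage1(sim$maneuvers, "nls")
  expect_identical(s1a, s1b)
  for (i in c(3, 17)) {
    rows <- sim$maneuvers$participant_id == s1a$participant_id[i]
    single <- nls_fit(sim$maneuvers$flow_mls[rows], sim$maneuvers$feno_ppb[rows])
    expect_equal(single$converged, s1a$converged[i])
    if (single$converged) {
      expect_equal(unname(single$theta_hat), as.numeric(s1a[i, 4:6]),
                   tolerance = 1e-10)
    }
  }
})

test_that("stage-I failure rates have the expected order of magnitude", {
  sim <- simulate_dataset(default_population(), 400, seed = 61)
  nls_fail <- mean(!fit_stage1(sim$maneuvers, "nls")$converged)
  hma_fail <- mean(!fit_stage1(sim$maneuvers, "hma")$converged)
  expect_gt(nls_fail, 0.10)   # material failure fraction for per-participant NLS
  expect_lt(nls_fail, 0.50)
  expect_lt(hma_fail, 0.05)   # the three-flow algorithm almost always returns
})
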