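# shared fixtures, all generated in code

theta_ref <- c(1, 3.5, 2.5)

# tiny deterministic maneuver table for one participant
one_participant <- function(theta = theta_ref, flows = rep(c(30, 50, 100, 300), 2),
                            sigma = 0, seed = 1, id = "P00001") {
  set.seed(seed)
  feno <- exp(log_feno_mean(theta, flows) + rnorm(length(flows), 0, sigma))
  data.frame(participant_id = id, flow_mls = flows, feno_ppb = feno,
             stringsAsFactors = FALSE)
}

# independent rejection sampler for the truncated MVN participant model,
# built on MASS::mvrnorm (a different stack than the package's chol sampler)
oracle_truncmvn <- function(n, mu, sigma, seed) {
  set.seed(seed)
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    cand <- MASS::mvrnorm(2 * n, mu, sigma)
    out <- rbind(out, cand[cand[, 1] >= 0, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

expect_theta_equal <- function(est, truth, tol) {
  expect_true(all(abs(est - truth) < tol),
              label = paste0("theta (", paste(signif(est, 6), collapse = ", "),
                             ") within ", tol, " of (",
                             paste(truth, collapse = ", "), ")"))
}
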