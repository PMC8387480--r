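#' Population parameters for the FeNO generating model
#'
#' Bundles the parameters of the participant-level model
#' \eqn{\theta_i \sim MVN(\alpha + \beta X_i, \Sigma_\theta)} (truncated to
#' \code{c_alv >= 0}) together with the log-scale residual standard deviation
#' of the maneuver-level observation model
#' \eqn{\log FeNO_{ij} \sim N(f(\theta_i, flow_{ij}), \sigma^2)}.
#'
#' @param alpha length-3 numeric: mean NO parameters
#'   \code{(c_alv, log_caw, log_daw)} at covariate value 0.
#' @param beta length-3 numeric: per-unit effects of a scalar covariate on
#'   each NO parameter.
#' @param sigma_theta 3x3 symmetric positive-definite covariance of the
#'   participant-level random effects.
#' @param sigma_resid residual SD of log(FeNO), > 0.
#' @return an object of class \code{"feno_population"}.
#' @seealso [default_population()], [simulate_dataset()]
#' @export
population_params <- function(alpha, beta = c(0, 0, 0), sigma_theta, sigma_resid = 0.15) {
  stopifnot(length(alpha) == 3L, length(beta) == 3L,
            is.matrix(sigma_theta), all(dim(sigma_theta) == 3L))
  if (!isTRUE(all.equal(sigma_theta, t(sigma_theta), tolerance = 1e-10))) {
    stop("`sigma_theta` must be symmetric")
  }
  ev <- eigen(sigma_theta, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("`sigma_theta` must be positive definite")
  if (!is.numeric(sigma_resid) || sigma_resid <= 0) stop("`sigma_resid` must be > 0")
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         sigma_theta = unname(sigma_theta), sigma_resid = as.numeric(sigma_resid)),
    class = "feno_population"
  )
}

#' Reference population for simulation studies
#'
#' The default generating population mirrors multiple-flow FeNO distributions
#' observed in schoolchildren cohort data: mean NO parameters
#' \code{(1, 3.5, 2.5)} for \code{(c_alv, log_caw, log_daw)}, a random-effects
#' covariance with positive \code{c_alv}/\code{log_caw} correlation and
#' negative correlations of each with \code{log_daw}, no covariate effect,
#' and residual SD 0.15 on the log-ppb scale.
#'
#' @param sigma_resid residual SD of log(FeNO); 0.15 by default (see the
#'   methods vignette for the rationale behind this value).
#' @return a \code{"feno_population"} object.
#' @export
default_population <- function(sigma_resid = 0.15) {
  sigma_theta <- matrix(c(0.44, 0.13, -0.14,
                          0.13, 0.62, -0.15,
                          -0.14, -0.15, 0.36), 3L, 3L)
  population_params(alpha = c(1, 3.5, 2.5), beta = c(0, 0, 0),
                    sigma_theta = sigma_theta, sigma_resid = sigma_resid)
}

#' Which NO parameters a simulation scenario lets the covariate affect
#'
#' Seven scenarios are used in the method-comparison study. Scenario 1 lets
#' the covariate affect all three NO parameters (equal effects); scenarios
#' 2-4 each activate exactly one parameter (\code{c_alv}, \code{log_caw},
#' \code{log_daw} respectively); scenarios 5-7 each null exactly one
#' parameter (\code{c_alv}, \code{log_caw}, \code{log_daw} respectively)
#' while the other two share the non-zero effect.
#'
#' @param scenario integer 1-7.
#' @return logical length-3 mask over \code{(c_alv, log_caw, log_daw)}:
#'   \code{TRUE} where the covariate effect varies, \code{FALSE} where it is
#'   pinned at 0.
#' @export
scenario_mask <- function(scenario) {
  masks <- list(
    c(TRUE, TRUE, TRUE),
    c(TRUE, FALSE, FALSE),
    c(FALSE, TRUE, FALSE),
    c(FALSE, FALSE, TRUE),
    c(FALSE, TRUE, TRUE),
    c(TRUE, FALSE, TRUE),
    c(TRUE, TRUE, FALSE)
  )
  if (!is.numeric(scenario) || length(scenario) != 1L || !scenario %in% 1:7) {
    stop("`scenario` must be an integer in 1..7")
  }
  masks[[scenario]]
}

#' Generating populations for one scenario sweep
#'
#' Expands a scenario and an effect-size grid into one generating population
#' per grid value: the active entries of \code{beta} (per [scenario_mask()])
#' are set to the grid value, inactive entries stay 0.
#'
#' @param scenario integer 1-7.
#' @param beta_grid effect sizes; the study design uses
#'   \code{seq(0.02, 0.2, by = 0.02)} plus a single all-zero setting shared
#'   across scenarios.
#' @param base population whose \code{alpha}, \code{sigma_theta} and
#'   \code{sigma_resid} are reused; [default_population()] by default.
#' @return named list of \code{"feno_population"} objects, names = grid
#'   values.
#' @export
scenario_settings <- function(scenario, beta_grid = seq(0.02, 0.2, by = 0.02),
                              base = default_population()) {
  mask <- scenario_mask(scenario)
  stats::setNames(lapply(beta_grid, function(b) {
    population_params(alpha = base$alpha, beta = ifelse(mask, b, 0),
                      sigma_theta = base$sigma_theta,
                      sigma_resid = base$sigma_resid)
  }), format(beta_grid))
}

#' Maneuver flow schedules
#'
#' Presets: \code{"simulation"} is the 8-maneuver design (two at each of 30,
#' 50, 100 and 300 mL/s) used by the simulation study; \code{"cohort9"} is a
#' 9-maneuver cohort protocol (three at 50 mL/s, two at each of 30, 100 and
#' 300 mL/s).
#'
#' @param preset \code{"simulation"} or \code{"cohort9"}, or a numeric vector of
#'   flows which is returned as-is (after validation).
#' @return numeric vector of flows in mL/s, one entry per maneuver.
#' @export
flow_schedule <- function(preset = "simulation") {
  if (is.numeric(preset)) {
    if (length(preset) == 0L || any(preset <= 0)) stop("flows must be strictly positive")
    return(as.numeric(preset))
  }
  switch(match.arg(preset, c("simulation", "cohort9")),
         simulation = rep(c(30, 50, 100, 300), each = 2L),
         cohort9 = c(rep(50, 3L), rep(c(30, 100, 300), each = 2L)))
}

## deterministic sub-stream seeds: one master seed per dataset, separate
## streams for X, theta and maneuver noise so e.g. changing the flow schedule
## never perturbs the theta draws.  Values stay below 2^31 - 1.
#' @keywords internal
substream_seed <- function(seed, stream) {
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  for (k in c(stream, 1)) s <- (s * 48271 + 12345 * (k + 1)) %% m
  as.integer(s)
}

#' Draw participant covariates and true NO parameters
#'
#' Covariates are iid standard normal. Each participant's NO-parameter vector
#' is drawn from \eqn{MVN(\alpha + \beta X_i, \Sigma_\theta)} with rejection
#' sampling of the whole 3-vector whenever the drawn \code{c_alv} is
#' negative (the draw is discarded and redone, which truncates the joint
#' distribution at \code{c_alv >= 0}).
#'
#' @param pop a \code{"feno_population"}.
#' @param n number of participants.
#' @param seed integer master seed.
#' @return data.frame with columns \code{participant_id}, \code{x},
#'   \code{c_alv_true}, \code{log_caw_true}, \code{log_daw_true}; the number
#'   of rejected draws is attached as attribute \code{"n_rejected"}.
#' @export
sample_participants <- function(pop, n, seed) {
  stopifnot(inherits(pop, "feno_population"), n >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  set.seed(substream_seed(seed, 1L))
  x <- stats::rnorm(n)

  set.seed(substream_seed(seed, 2L))
  R <- chol(pop$sigma_theta)
  mu <- matrix(pop$alpha, n, 3L, byrow = TRUE) + outer(x, pop$beta)
  theta <- matrix(NA_real_, n, 3L)
  pending <- seq_len(n)
  n_drawn <- 0L; n_kept <- 0L
  while (length(pending)) {
    m <- length(pending)
    z <- matrix(stats::rnorm(3L * m), m, 3L)
    cand <- mu[pending, , drop = FALSE] + z %*% R
    ok <- cand[, 1L] >= 0
    theta[pending[ok], ] <- cand[ok, , drop = FALSE]
    n_drawn <- n_drawn + m; n_kept <- n_kept + sum(ok)
    pending <- pending[!ok]
    if (n_drawn >= 10000L && n_kept / n_drawn < 0.01) {
      stop("rejection rate above 99%: the generating population places ",
           "almost all mass at c_alv < 0")
    }
  }
  out <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    x = x,
    c_alv_true = theta[, 1L],
    log_caw_true = theta[, 2L],
    log_daw_true = theta[, 3L],
    stringsAsFactors = FALSE
  )
  attr(out, "n_rejected") <- n_drawn - n_kept
  out
}

#' Simulate a multiple-flow FeNO dataset
#'
#' Generates participants via [sample_participants()] and, for every
#' scheduled maneuver, observes
#' \eqn{FeNO = \exp(f(\theta_i, flow) + \epsilon)} with
#' \eqn{\epsilon \sim N(0, \sigma^2)} iid across maneuvers.
#'
#' @inheritParams sample_participants
#' @param flows maneuver flow schedule (one entry per maneuver); see
#'   [flow_schedule()].
#' @return an object of class \code{"feno_simdata"}: a list with
#'   \code{maneuvers} (long data.frame: \code{participant_id},
#'   \code{flow_mls}, \code{feno_ppb}), \code{participants} (from
#'   [sample_participants()]), \code{pop}, \code{flows} and \code{seed}.
#' @export
simulate_dataset <- function(pop, n, flows = flow_schedule("simulation"), seed = 1L) {
  flows <- flow_schedule(flows)
  participants <- sample_participants(pop, n, seed)
  theta <- as.matrix(participants[, c("c_alv_true", "log_caw_true", "log_daw_true")])

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(substream_seed(seed, 3L))

  J <- length(flows)
  lmu <- log_feno_mean(theta, flows)            # n x J
  # the 2CM mean is strictly positive for c_alv >= 0, caw > 0; guard anyway
  n_regen <- 0L
  bad <- which(!is.finite(rowSums(lmu)))
  while (length(bad)) {
    n_regen <- n_regen + length(bad)
    redo <- sample_participants(pop, length(bad), seed + 7919L * n_regen)
    theta[bad, ] <- as.matrix(redo[, 3:5])
    participants[bad, 2:5] <- redo[, 2:5]
    lmu[bad, ] <- log_feno_mean(theta[bad, , drop = FALSE], flows)
    bad <- bad[!is.finite(rowSums(lmu[bad, , drop = FALSE]))]
  }
  eps <- matrix(stats::rnorm(n * J, 0, pop$sigma_resid), n, J)
  feno <- exp(lmu + eps)
  maneuvers <- data.frame(
    participant_id = rep(participants$participant_id, each = J),
    flow_mls = rep(flows, times = n),
    feno_ppb = as.vector(t(feno)),
    stringsAsFactors = FALSE
  )
  structure(list(maneuvers = maneuvers, participants = participants,
                 pop = pop, flows = flows, seed = seed,
                 n_regenerated = n_regen),
            class = "feno_simdata")
}

#' @export
print.feno_simdata <- function(x, ...) {
  cat("Multiple-flow FeNO dataset:", nrow(x$participants), "participants,",
      nrow(x$maneuvers), "maneuvers\n")
  cat("  flows (mL/s):", paste(x$flows, collapse = ", "), "\n")
  cat("  generating beta:", paste(format(x$pop$beta), collapse = ", "),
      " residual SD:", x$pop$sigma_resid, "\n")
  invisible(x)
}
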