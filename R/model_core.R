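#' Two-compartment model of exhaled nitric oxide
#'
#' The steady-state two-compartment model (2CM) describes the fractional
#' concentration of exhaled nitric oxide (FeNO, ppb) measured at the mouth as
#' a function of expiratory flow and three "NO parameters":
#' \deqn{FeNO(flow) = C_{aw} + (C_A - C_{aw})\, e^{-D_{aw}/flow}}
#' where \eqn{C_A} is the alveolar NO concentration (ppb), \eqn{C_{aw}} the
#' airway-tissue NO concentration (ppb) and \eqn{D_{aw}} the airway-tissue
#' diffusion capacity (pL s\eqn{^{-1}} ppb\eqn{^{-1}}).
#'
#' Throughout the package a parameter vector \code{theta} is on the
#' *estimation scale* \code{(c_alv, log_caw, log_daw)}: the alveolar
#' concentration on its natural scale (constrained non-negative where a
#' constraint applies) and the two airway parameters on the log scale, which
#' enforces their positivity and matches the multivariate-normal
#' random-effects assumption of the population models.
#'
#' @param theta numeric vector \code{c(c_alv, log_caw, log_daw)}, or an
#'   \code{n x 3} matrix with one row per participant.
#' @param flow expiratory flow in mL/s; strictly positive scalar or vector.
#' @return For a vector \code{theta}, a vector of the same length as
#'   \code{flow}; for a matrix \code{theta}, an \code{n x length(flow)}
#'   matrix.
#' @examples
#' feno_mean(c(1, 3.5, 2.5), flow = 50)
#' feno_mean(c(1, 3.5, 2.5), flow = c(30, 50, 100, 300))
#' @seealso [log_feno_mean()], [jaw_from()]
#' @export
feno_mean <- function(theta, flow) {
  if (length(flow) == 0L || any(!is.finite(flow)) || any(flow <= 0)) {
    stop("`flow` must be finite and strictly positive (mL/s)")
  }
  th <- theta_matrix(theta)
  caw <- exp(th[, 2L])
  # clamp the exponent so extreme D_aw/flow underflows cleanly to 0
  ex <- pmax(-outer(exp(th[, 3L]), flow, "/"), -745)
  out <- caw + (th[, 1L] - caw) * exp(ex)
  if (is.matrix(theta)) out else drop(out)
}

#' Log-scale mean FeNO
#'
#' Log of [feno_mean()], used as the mean of the log-transform-both-sides
#' observation models. The 2CM mean lies between \eqn{C_A} and \eqn{C_{aw}},
#' so it is positive whenever \code{c_alv > 0}; a non-positive mean (possible
#' only in the boundary case \code{c_alv = 0} at the infinite-flow limit)
#' yields the \code{-Inf} sentinel rather than an error, and callers treat
#' such parameter points as invalid.
#'
#' @inheritParams feno_mean
#' @return log-ppb values, same shape as [feno_mean()].
#' @export
log_feno_mean <- function(theta, flow) {
  m <- feno_mean(theta, flow)
  out <- suppressWarnings(log(m))
  out[m <= 0] <- -Inf
  out
}

#' Maximum airway NO flux
#'
#' The airway wall flux parameter \eqn{J'_{aw}} (pL/s) is the product
#' \eqn{C_{aw} \times D_{aw}}. It is a derived view of a \code{theta}
#' vector, never stored state; applied draw-by-draw to posterior samples of
#' \code{(log_caw, log_daw)} it yields the \eqn{J'_{aw}} posterior.
#'
#' @inheritParams feno_mean
#' @return numeric vector of \eqn{J'_{aw}} values (one per row of
#'   \code{theta}).
#' @export
jaw_from <- function(theta) {
  th <- theta_matrix(theta)
  unname(exp(th[, 2L] + th[, 3L]))
}

#' @keywords internal
theta_matrix <- function(theta) {
  if (is.matrix(theta)) {
    if (ncol(theta) != 3L) stop("`theta` matrix must have 3 columns")
    theta
  } else {
    if (length(theta) != 3L) stop("`theta` must have 3 elements (c_alv, log_caw, log_daw)")
    matrix(theta, nrow = 1L)
  }
}

#' Validate a NO-parameter vector
#'
#' Checks the invariants of the estimation-scale parameterization:
#' \code{c_alv >= 0} and finite log-scale airway parameters.
#'
#' @inheritParams feno_mean
#' @param constrained require \code{c_alv >= 0}? The data-generating model
#'   and the Bayesian fit carry this constraint; the frequentist Stage-I
#'   estimators do not.
#' @return logical vector, one per parameter vector.
#' @export
is_valid_theta <- function(theta, constrained = TRUE) {
  th <- theta_matrix(theta)
  ok <- is.finite(th[, 1L]) & is.finite(th[, 2L]) & is.finite(th[, 3L])
  if (constrained) ok <- ok & th[, 1L] >= 0
  unname(ok)
}
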