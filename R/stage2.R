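#' Stage-II ordinary least squares for covariate effects
#'
#' Regresses each estimated NO parameter on the covariate of interest in
#' three separate linear models, treating the Stage-I point estimates as
#' known outcomes. Participants whose Stage-I fit did not converge are
#' dropped. Intervals are normal-theory 95% t-intervals. This deliberately
#' does not propagate Stage-I uncertainty: that omission is the
#' characterised weakness of two-stage estimation that the unified methods
#' address, and reproducing it is part of the method comparison.
#'
#' @param estimates Stage-I results as returned by [fit_stage1()] (columns
#'   \code{participant_id}, \code{converged}, \code{c_alv_hat},
#'   \code{log_caw_hat}, \code{log_daw_hat}), or any data.frame with those
#'   columns (e.g. empirical-Bayes estimates with \code{converged = TRUE}).
#' @param covariates data.frame with \code{participant_id}, \code{x}, and
#'   any adjustment covariates.
#' @param adjusters character vector of additional covariate column names
#'   entering each regression additively.
#' @param method label recorded in the output.
#' @return data.frame with one row per NO parameter: \code{method},
#'   \code{parameter} (\code{c_alv}, \code{log_caw}, \code{log_daw}),
#'   \code{estimate}, \code{se}, \code{ci_low}, \code{ci_high},
#'   \code{n_used}.
#' @export
stage2_ols <- function(estimates, covariates, adjusters = NULL,
                       method = if (!is.null(estimates$method)) estimates$method[1L] else "stage2") {
  keep <- if (!is.null(estimates$converged)) estimates$converged else rep(TRUE, nrow(estimates))
  est <- estimates[keep, , drop = FALSE]
  if (nrow(est) < 3L) {
    stop("fewer than 3 converged Stage-I estimates for method '", method, "'")
  }
  d <- merge(est, covariates, by = "participant_id")
  if (stats::var(d$x) == 0) stop("covariate `x` has zero variance among converged participants")
  rhs <- paste(c("x", adjusters), collapse = " + ")
  cols <- c(c_alv = "c_alv_hat", log_caw = "log_caw_hat", log_daw = "log_daw_hat")
  rows <- lapply(names(cols), function(p) {
    fml <- stats::as.formula(paste(cols[[p]], "~", rhs))
    fit <- stats::lm(fml, data = d)
    sm <- summary(fit)$coefficients
    b <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
    tq <- stats::qt(0.975, df = fit$df.residual)
    data.frame(method = method, parameter = p, estimate = b, se = se,
               ci_low = b - tq * se, ci_high = b + tq * se,
               n_used = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
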