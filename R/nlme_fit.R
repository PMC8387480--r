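#' Nonlinear mixed-effects fit of the two-compartment model
#'
#' Fits the log-transform-both-sides 2CM to all participants jointly, with
#' participant-level random effects on \code{(c_alv, log_caw, log_daw)}
#' following an unstructured multivariate normal. With
#' \code{unified = FALSE} the mean NO parameters are intercept-only (the
#' Stage-I model of the two-stage NLME pipeline; covariate effects then come
#' from a separate [stage2_ols()] on the empirical-Bayes estimates). With
#' \code{unified = TRUE} the covariate enters the mean of each NO parameter,
#' so slopes and their intervals come from the single joint fit.
#'
#' Fitting uses the standard linearisation-based NLME machinery of the
#' \pkg{nlme} package. Population starting values come from medians of the
#' per-participant [nls_fit()] estimates (falling back to
#' \code{(1, 3.5, 2.5)}); slope starts are 0. NLME fitting of this model is
#' known to be fragile, so optimizer failure is reported via
#' \code{converged = FALSE} rather than raised. No non-negativity
#' constraint is placed on \code{c_alv} (only the Bayesian model and the
#' data generator carry the constraint).
#'
#' @param maneuvers long maneuver data.frame (\code{participant_id},
#'   \code{flow_mls}, \code{feno_ppb}).
#' @param covariates data.frame with \code{participant_id} and \code{x};
#'   required when \code{unified = TRUE}, used only for empirical-Bayes
#'   bookkeeping otherwise.
#' @param unified incorporate \code{x} into the NO-parameter means?
#' @param control passed to [nlme::nlmeControl()].
#' @return object of class \code{"feno_nlme"}: list with \code{converged},
#'   \code{alpha}, \code{beta} (NA unless unified), \code{effects}
#'   (data.frame of slope estimates with 95% t-intervals, unified only),
#'   \code{sigma_theta_hat}, \code{sigma_resid_hat}, \code{theta_eb}
#'   (per-participant empirical-Bayes estimates in Stage-I result layout),
#'   \code{loglik}, and the underlying \code{nlme} \code{fit}.
#' @export
nlme_fit <- function(maneuvers, covariates = NULL, unified = FALSE,
                     control = nlme::nlmeControl(maxIter = 100, msMaxIter = 200,
                                                 pnlsMaxIter = 10, returnObject = FALSE)) {
  ids <- unique(maneuvers$participant_id)
  if (length(ids) < 2L) stop("NLME requires at least 2 participants")
  if (unified && is.null(covariates)) stop("`covariates` required for the unified fit")
  d <- data.frame(id = factor(maneuvers$participant_id, levels = ids),
                  flow = maneuvers$flow_mls,
                  lfeno = log(maneuvers$feno_ppb))
  if (!is.null(covariates)) {
    d$x <- covariates$x[match(maneuvers$participant_id, covariates$participant_id)]
    if (unified && anyNA(d$x)) stop("missing covariate for some participants")
  }

  s1 <- fit_stage1(maneuvers, method = "nls")
  start_pop <- if (sum(s1$converged) >= 5L) {
    apply(s1[s1$converged, c("c_alv_hat", "log_caw_hat", "log_daw_hat")], 2, stats::median)
  } else c(1, 3.5, 2.5)
  start <- if (unified) as.vector(rbind(start_pop, 0)) else start_pop

  fixed <- if (unified) ca + lcaw + ldaw ~ x else ca + lcaw + ldaw ~ 1
  fit <- try(suppressWarnings(nlme::nlme(
    lfeno ~ log(exp(lcaw) + (ca - exp(lcaw)) * exp(-exp(ldaw) / flow)),
    fixed = fixed,
    random = ca + lcaw + ldaw ~ 1 | id,
    data = d, start = start, control = control
  )), silent = TRUE)

  out <- structure(list(converged = FALSE, unified = unified, fit = NULL,
                        alpha = rep(NA_real_, 3L), beta = rep(NA_real_, 3L),
                        effects = NULL, sigma_theta_hat = NULL,
                        sigma_resid_hat = NA_real_, theta_eb = NULL,
                        loglik = NA_real_,
                        failure = if (inherits(fit, "try-error")) conditionMessage(attr(fit, "condition")) else NULL),
                   class = "feno_nlme")
  if (inherits(fit, "try-error")) return(out)

  fe <- nlme::fixef(fit)
  pars <- c("ca", "lcaw", "ldaw")
  labs <- c(ca = "c_alv", lcaw = "log_caw", ldaw = "log_daw")
  inter <- fe[paste0(pars, if (unified) ".(Intercept)" else "")]
  if (unified) {
    tt <- summary(fit)$tTable
    sl <- paste0(pars, ".x")
    b <- tt[sl, "Value"]; se <- tt[sl, "Std.Error"]
    tq <- stats::qt(0.975, df = tt[sl, "DF"])
    out$effects <- data.frame(
      method = "u_nlme", parameter = unname(labs[pars]),
      estimate = unname(b), se = unname(se),
      ci_low = unname(b - tq * se), ci_high = unname(b + tq * se),
      n_used = length(ids), stringsAsFactors = FALSE)
    out$beta <- unname(b)
  }
  out$converged <- TRUE
  out$fit <- fit
  out$alpha <- unname(inter)
  vc <- try(as.matrix(fit$modelStruct$reStruct[[1L]]) * fit$sigma^2, silent = TRUE)
  if (!inherits(vc, "try-error") && all(is.finite(vc))) {
    out$sigma_theta_hat <- unname(vc[1:3, 1:3])
  }
  out$sigma_resid_hat <- fit$sigma
  out$loglik <- as.numeric(stats::logLik(fit))

  re <- nlme::ranef(fit)
  xs <- if (!is.null(covariates)) covariates$x[match(rownames(re), covariates$participant_id)] else rep(0, nrow(re))
  theta <- matrix(rep(unname(inter), each = nrow(re)), ncol = 3L)
  if (unified) theta <- theta + outer(xs, unname(fe[paste0(pars, ".x")]))
  theta <- theta + as.matrix(re)
  out$theta_eb <- data.frame(participant_id = rownames(re), method = "nlme_eb",
                             converged = TRUE, c_alv_hat = theta[, 1L],
                             log_caw_hat = theta[, 2L], log_daw_hat = theta[, 3L],
                             stringsAsFactors = FALSE)
  out
}

#' Empirical-Bayes NO-parameter estimate for one participant
#'
#' The posterior mode of a participant's NO parameters given their data and
#' the fitted population parameters (fixed effects plus the participant's
#' predicted random effects). For a participant absent from the fitted data
#' but present in \code{covariates}, the population mean at their covariate
#' value is returned (full shrinkage under no data).
#'
#' @param fit a converged \code{"feno_nlme"}.
#' @param participant_id one participant identifier.
#' @param covariates optional covariate table for the no-data case.
#' @return named length-3 numeric \code{(c_alv, log_caw, log_daw)}.
#' @export
empirical_bayes <- function(fit, participant_id, covariates = NULL) {
  stopifnot(inherits(fit, "feno_nlme"))
  if (!fit$converged) stop("NLME fit did not converge")
  i <- match(participant_id, fit$theta_eb$participant_id)
  if (!is.na(i)) {
    return(c(c_alv = fit$theta_eb$c_alv_hat[i],
             log_caw = fit$theta_eb$log_caw_hat[i],
             log_daw = fit$theta_eb$log_daw_hat[i]))
  }
  if (!is.null(covariates) && participant_id %in% covariates$participant_id) {
    x <- covariates$x[match(participant_id, covariates$participant_id)]
    b <- if (fit$unified) fit$beta else c(0, 0, 0)
    th <- fit$alpha + b * x
    return(c(c_alv = th[1L], log_caw = th[2L], log_daw = th[3L]))
  }
  stop("unknown participant id: ", participant_id)
}

#' @export
print.feno_nlme <- function(x, ...) {
  cat(if (x$unified) "Unified" else "Two-stage (Stage-I)",
      "nonlinear mixed-effects 2CM fit\n")
  if (!x$converged) {
    cat("  did not converge:", x$failure, "\n")
  } else {
    cat("  alpha:", paste(format(x$alpha, digits = 4), collapse = ", "), "\n")
    if (x$unified) cat("  beta: ", paste(format(x$beta, digits = 4), collapse = ", "), "\n")
    cat("  residual SD:", format(x$sigma_resid_hat, digits = 4), "\n")
  }
  invisible(x)
}
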