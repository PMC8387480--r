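## Stage-I estimators: per-participant NO-parameter estimation.
##
## Two families are implemented:
##  * nls_fit()  -- log-transform-both-sides nonlinear least squares on all
##    maneuvers, minimising sum_j (log FeNO_j - f(theta, flow_j))^2 by
##    Gauss-Newton with the relative-offset convergence criterion and
##    step halving, the classical NLS scheme.  A batched driver fits every
##    participant of a dataset simultaneously through vectorised linear
##    algebra (each participant has its own 3x3 normal-equation system,
##    solved in closed form).
##  * hma_fit()  -- the iterative third-order-approximation algorithm on
##    mean FeNO at a low/medium/high flow triple.

# log-scale 2CM mean for a batch: theta (n x 3), flow (length J) -> n x J
#' @keywords internal
fmu_log <- function(theta, flow) {
  caw <- exp(theta[, 2L])
  E <- exp(pmax(-outer(exp(theta[, 3L]), flow, "/"), -745))
  M <- caw + (theta[, 1L] - caw) * E
  out <- suppressWarnings(log(M))
  out[!is.finite(out) | M <= 0] <- NA_real_
  out
}

# Batched Gauss-Newton for the log-both-sides objective.
# y: n x J matrix of log(FeNO); flow: length-J vector; start: n x 3.
# Convergence: Bates-Watts relative-offset criterion < tol.  Failure modes
# mirror standard NLS practice: (near-)singular normal equations, step
# factor below min_factor, or iteration limit.
#' @keywords internal
gn_batch <- function(y, flow, start, constrained = FALSE,
                     maxiter = 50L, tol = 1e-5, min_factor = 1 / 1024) {
  n <- nrow(y)
  th <- start
  if (constrained) th[, 1L] <- pmax(th[, 1L], 0.001)
  active <- rep(TRUE, n)
  failed <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  iters <- rep(0L, n)

  lmu <- fmu_log(th, flow)
  sse <- rowSums((y - lmu)^2)
  bad0 <- !is.finite(sse)
  failed[bad0] <- TRUE; active[bad0] <- FALSE; reason[bad0] <- "invalid start"

  for (it in seq_len(maxiter)) {
    if (!any(active)) break
    ia <- which(active)
    iters[ia] <- it
    tha <- th[ia, , drop = FALSE]
    ca <- tha[, 1L]; caw <- exp(tha[, 2L]); dv <- outer(exp(tha[, 3L]), flow, "/")
    E <- exp(pmax(-dv, -745))
    M <- caw + (ca - caw) * E
    okM <- M > 0 & is.finite(M)
    r <- y[ia, , drop = FALSE] - suppressWarnings(log(M))
    r[!okM] <- 0
    # Jacobian of log mean wrt (c_alv, log_caw, log_daw)
    g1 <- E / M
    g2 <- caw * (1 - E) / M
    g3 <- (caw - ca) * E * dv / M
    g1[!okM] <- 0; g2[!okM] <- 0; g3[!okM] <- 0
    domain_bad <- rowSums(!okM) > 0

    a11 <- rowSums(g1 * g1); a12 <- rowSums(g1 * g2); a13 <- rowSums(g1 * g3)
    a22 <- rowSums(g2 * g2); a23 <- rowSums(g2 * g3); a33 <- rowSums(g3 * g3)
    b1 <- rowSums(g1 * r); b2 <- rowSums(g2 * r); b3 <- rowSums(g3 * r)
    det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
      a13 * (a12 * a23 - a22 * a13)
    sing <- domain_bad | !is.finite(det) | det <= 0 |
      det < 1e-10 * pmax(a11 * a22 * a33, 1e-300)
    det[sing] <- 1  # placeholder; those rows are flagged failed below
    d1 <- (b1 * (a22 * a33 - a23^2) - a12 * (b2 * a33 - a23 * b3) +
             a13 * (b2 * a23 - a22 * b3)) / det
    d2 <- (a11 * (b2 * a33 - b3 * a23) - b1 * (a12 * a33 - a23 * a13) +
             a13 * (a12 * b3 - b2 * a13)) / det
    d3 <- (a11 * (a22 * b3 - a23 * b2) - a12 * (a12 * b3 - b2 * a13) +
             b1 * (a12 * a23 - a22 * a13)) / det
    # under the box constraint the usable step is the projected one; the
    # convergence criterion must see it too, or a boundary optimum would
    # read as a failed line search
    if (constrained) d1 <- pmax(d1, 0.001 - tha[, 1L])
    # relative offset: ||P_J r|| vs residual norm at the current point
    num <- pmax(b1 * d1 + b2 * d2 + b3 * d3, 0)
    conv_now <- !sing & sqrt(num / pmax(sse[ia] - num, 1e-300)) < tol

    done <- conv_now | sing
    # step halving for the rest
    pend <- which(!done)
    fac <- rep(1, length(ia))
    while (length(pend)) {
      cand <- tha[pend, , drop = FALSE] +
        fac[pend] * cbind(d1[pend], d2[pend], d3[pend])
      if (constrained) cand[, 1L] <- pmax(cand[, 1L], 0.001)
      stry <- rowSums((y[ia[pend], , drop = FALSE] - fmu_log(cand, flow))^2)
      okdec <- is.finite(stry) & stry < sse[ia[pend]]
      acc <- pend[okdec]
      th[ia[acc], ] <- cand[okdec, , drop = FALSE]
      sse[ia[acc]] <- stry[okdec]
      pend <- pend[!okdec]
      fac[pend] <- fac[pend] / 2
      toolow <- fac[pend] < min_factor
      if (any(toolow)) {
        sing[pend[toolow]] <- TRUE
        reason[ia[pend[toolow]]] <- "step factor below minimum"
        pend <- pend[!toolow]
      }
    }
    reason[ia[sing & is.na(reason[ia])]] <- "singular gradient"
    failed[ia[sing]] <- TRUE
    active[ia[done | sing]] <- FALSE
  }
  if (any(active)) {
    failed[active] <- TRUE
    reason[active] <- "iteration limit reached"
    active[] <- FALSE
  }
  list(theta = th, converged = !failed, sse = sse, iterations = iters,
       reason = reason)
}

# Data-driven starting values from flow-level mean FeNO:
# c_alv from the two highest flow levels via FeNO*flow ~ J' + c_alv*flow,
# log_caw from log mean FeNO at the lowest flow, log_daw fixed at 2.5.
#' @keywords internal
nls_start_values <- function(flow, feno) {
  m <- tapply(feno, flow, mean)
  v <- as.numeric(names(m))
  o <- order(v)
  m <- as.numeric(m)[o]; v <- v[o]
  k <- length(v)
  ca0 <- (m[k] * v[k] - m[k - 1L] * v[k - 1L]) / (v[k] - v[k - 1L])
  c(ca0, log(m[1L]), 2.5)
}

# post-fit sanity bounds; estimates outside are treated as non-convergent
#' @keywords internal
nls_within_bounds <- function(theta, constrained = FALSE) {
  lo_ca <- if (constrained) 0.001 - 1e-9 else -50
  theta[, 1L] >= lo_ca & theta[, 1L] <= 200 &
    theta[, 2L] >= -5 & theta[, 2L] <= 10 &
    theta[, 3L] >= -5 & theta[, 3L] <= 10
}

#' Log-transform-both-sides nonlinear least squares for one participant
#'
#' Minimises \eqn{\sum_j (\log FeNO_j - f(\theta, flow_j))^2} over
#' \eqn{\theta = (c_{alv}, \log C_{aw}, \log D_{aw})} by Gauss-Newton with
#' step halving and the relative-offset stopping rule. Starting values are
#' data-driven (see Details); if the first fit fails or lands outside sanity
#' bounds, one restart from \code{(1, 3.5, 2.5)} is attempted. Failure to
#' converge is an expected outcome on small per-participant samples and is
#' reported, not raised.
#'
#' @details The default start takes \code{c_alv} from the slope of
#' \code{FeNO*flow} against \code{flow} over the two highest flow levels
#' (the high-flow linearisation of the 2CM), \code{log_caw} from the log
#' mean FeNO at the lowest flow, and \code{log_daw = 2.5}. The constrained
#' variant keeps \code{c_alv >= 0.001} by projection.
#'
#' @param flow,feno numeric vectors, one entry per maneuver (>= 4 maneuvers
#'   spanning >= 3 distinct flows).
#' @param constrained impose \code{c_alv >= 0.001}?
#' @param start optional length-3 starting value overriding the data-driven
#'   rule.
#' @return list with \code{theta_hat} (length-3, \code{NA} when not
#'   converged), \code{converged}, \code{sse}, \code{iterations},
#'   \code{reason}.
#' @export
nls_fit <- function(flow, feno, constrained = FALSE, start = NULL) {
  stopifnot(length(flow) == length(feno))
  if (any(flow <= 0) || any(feno <= 0)) stop("flow and FeNO must be strictly positive")
  if (length(unique(flow)) < 3L) {
    return(list(theta_hat = rep(NA_real_, 3L), converged = FALSE,
                sse = NA_real_, iterations = 0L,
                reason = "fewer than 3 distinct flows (structurally unidentifiable)"))
  }
  if (length(flow) < 4L) {
    return(list(theta_hat = rep(NA_real_, 3L), converged = FALSE,
                sse = NA_real_, iterations = 0L,
                reason = "fewer than 4 maneuvers"))
  }
  y <- matrix(log(feno), nrow = 1L)
  st <- matrix(if (is.null(start)) nls_start_values(flow, feno) else start, 1L)
  fit <- gn_batch(y, flow, st, constrained = constrained)
  ok <- fit$converged & nls_within_bounds(fit$theta, constrained)
  restarted <- FALSE
  if (!ok && is.null(start)) {
    restarted <- TRUE
    fit <- gn_batch(y, flow, matrix(c(1, 3.5, 2.5), 1L), constrained = constrained)
    ok <- fit$converged & nls_within_bounds(fit$theta, constrained)
  }
  reason <- if (ok) NA_character_ else {
    if (fit$converged) "estimate outside sanity bounds" else fit$reason
  }
  list(theta_hat = if (ok) drop(fit$theta) else rep(NA_real_, 3L),
       converged = ok, sse = drop(fit$sse), iterations = fit$iterations,
       restarted = restarted, reason = reason)
}

#' Mean FeNO at a low/medium/high flow triple
#'
#' Averages FeNO within each of three named flow levels (arithmetic mean on
#' the natural scale); maneuvers at any other flow are ignored. Participants
#' lacking any of the three levels are non-estimable for the three-flow
#' algorithm and are returned with \code{NA} means.
#'
#' @param maneuvers long data.frame with columns \code{participant_id},
#'   \code{flow_mls}, \code{feno_ppb}.
#' @param flows length-3 numeric, the low/medium/high target flows
#'   (default \code{c(30, 100, 300)} mL/s).
#' @return data.frame: \code{participant_id}, \code{feno_low},
#'   \code{feno_med}, \code{feno_high}, \code{complete}.
#' @export
average_by_flow_level <- function(maneuvers, flows = c(30, 100, 300)) {
  stopifnot(length(flows) == 3L, all(diff(flows) > 0))
  ids <- unique(maneuvers$participant_id)
  out <- data.frame(participant_id = ids, feno_low = NA_real_,
                    feno_med = NA_real_, feno_high = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in 1:3) {
    sel <- maneuvers$flow_mls == flows[k]
    m <- tapply(maneuvers$feno_ppb[sel], maneuvers$participant_id[sel], mean)
    out[[k + 1L]] <- as.numeric(m[match(ids, names(m))])
  }
  out$complete <- stats::complete.cases(out[, 2:4])
  out
}

# Vectorised third-order iterative algorithm.
# F: n x 3 matrix of mean FeNO at flows v = (low, med, high).
# Step 1: (c_alv, J'_aw) from the first-order high-flow linear relation
#   FeNO * V = J'_aw + c_alv * V at the medium and high flows.
# Step 2: iterate on D_aw via the third-order low-flow equation
#   C_aw = c_alv + (F_low - c_alv) / phi(D, v_low),   D <- J'_aw / C_aw,
#   phi(D, V) = D/V - D^2/(2 V^2) + D^3/(6 V^3),
# until successive D iterates agree to `tol` (relative, with an absolute
# floor of 1) or `maxiter` sweeps, returning the final iterate either way:
# the estimator always returns values when they are defined.  Triples the
# third-order model cannot fit drive D toward a degenerate boundary (tiny
# D_aw, huge C_aw); these are kept as (poor) estimates, which is what gives
# the two-stage pipeline built on this estimator its characteristic wide
# airway-parameter intervals.  Failure is reserved for non-estimable input:
# J'_aw <= 0 (FeNO not decreasing over the high flows, e.g. a flat triple)
# or a non-positive/non-finite C_aw or D_aw.
#' @keywords internal
hma_batch <- function(F, v, d_init = 10, tol = 1e-2, maxiter = 50L) {
  phi <- function(D, V) D / V * (1 - D / (2 * V) + D^2 / (6 * V^2))
  n <- nrow(F)
  ca <- (F[, 3L] * v[3L] - F[, 2L] * v[2L]) / (v[3L] - v[2L])
  jp <- (F[, 2L] - ca) * v[2L]
  usable <- rowSums(!is.finite(F)) == 0 & is.finite(jp) & jp > 0
  D <- rep(d_init, n)
  caw <- rep(NA_real_, n)
  bad <- !usable
  active <- usable
  for (k in seq_len(maxiter)) {
    if (!any(active)) break
    i <- which(active)
    cw <- ca[i] + (F[i, 1L] - ca[i]) / phi(D[i], v[1L])
    Dn <- jp[i] / cw
    invalid <- !is.finite(cw) | cw <= 0 | !is.finite(Dn) | Dn <= 0
    done <- !invalid & abs(Dn - D[i]) < tol * pmax(abs(D[i]), 1)
    D[i[!invalid]] <- Dn[!invalid]
    caw[i[!invalid]] <- cw[!invalid]
    bad[i[invalid]] <- TRUE
    active[i[invalid | done]] <- FALSE
  }
  ok <- usable & !bad & is.finite(caw) & caw > 0 & is.finite(D) & D > 0
  ok[is.na(ok)] <- FALSE
  list(theta = cbind(c_alv = ca, log_caw = suppressWarnings(log(caw)),
                     log_daw = suppressWarnings(log(D))),
       converged = ok,
       inverted_gradient = ok & caw <= ca)
}

#' Third-order iterative three-flow estimator for one participant
#'
#' Estimates the NO parameters from mean FeNO at three flows via the
#' iterative algorithm based on a third-order truncation of the exponential
#' in the 2CM. The alveolar concentration and the airway flux
#' \eqn{J'_{aw}} come from the high-flow linear relation
#' \code{FeNO*flow = Jaw + c_alv*flow} (writing \code{Jaw} for the airway
#' \code{D_aw} is then iterated through the third-order low-flow equation
#' (airway wall concentration from the low-flow FeNO at the current
#' \code{D_aw}, then the flux divided by that concentration as the next
#' \code{D_aw}) until successive iterates agree to \code{tol}, and the
#' final iterate is returned. A
#' flux \eqn{J'_{aw}}) over the medium and high flows; a
#' non-decreasing high-flow pair (negative flux, e.g. a flat triple) or a
#' non-positive \code{C_aw} or \code{D_aw} make the participant
#' non-estimable; this is flagged, not raised.
#'
#' @param flow length-3 increasing flows (mL/s).
#' @param feno length-3 mean FeNO at those flows (ppb).
#' @param d_init initial \code{D_aw} (pL/s/ppb).
#' @param tol relative agreement of successive \code{D_aw} iterates.
#' @param maxiter iteration cap; the final iterate is still returned.
#' @return list with \code{theta_hat} (\code{(c_alv, log_caw, log_daw)} or
#'   \code{NA}s) and \code{converged}.
#' @export
hma_fit <- function(flow, feno, d_init = 10, tol = 1e-2, maxiter = 50L) {
  stopifnot(length(flow) == 3L, length(feno) == 3L)
  if (any(diff(flow) <= 0)) stop("`flow` must be strictly increasing (low, medium, high)")
  if (any(feno <= 0)) stop("FeNO must be strictly positive")
  r <- hma_batch(matrix(feno, 1L), flow, d_init = d_init, tol = tol,
                 maxiter = maxiter)
  list(theta_hat = if (r$converged) drop(r$theta) else rep(NA_real_, 3L),
       converged = unname(r$converged))
}

#' Stage-I estimation for every participant of a dataset
#'
#' Batched driver running one Stage-I method over all participants of a
#' long-format maneuver table. For \code{"nls"} (and its constrained
#' variant) participants sharing an identical flow multiset are fitted
#' simultaneously by vectorised Gauss-Newton, with per-participant restarts
#' where the data-driven start fails. For \code{"hma"}, flow-level means at
#' the designated triple are formed first; participants missing a level are
#' marked non-estimable.
#'
#' @param maneuvers long data.frame (\code{participant_id}, \code{flow_mls},
#'   \code{feno_ppb}).
#' @param method \code{"nls"}, \code{"nls_constrained"}, or \code{"hma"}.
#' @param hma_flows low/medium/high triple for \code{"hma"}.
#' @return data.frame with one row per participant: \code{participant_id},
#'   \code{method}, \code{converged}, \code{c_alv_hat}, \code{log_caw_hat},
#'   \code{log_daw_hat}, \code{diagnostics}.
#' @export
fit_stage1 <- function(maneuvers, method = c("nls", "nls_constrained", "hma"),
                       hma_flows = c(30, 100, 300)) {
  method <- match.arg(method)
  ids <- unique(maneuvers$participant_id)
  n <- length(ids)
  out <- data.frame(participant_id = ids, method = method, converged = FALSE,
                    c_alv_hat = NA_real_, log_caw_hat = NA_real_,
                    log_daw_hat = NA_real_, diagnostics = NA_character_,
                    stringsAsFactors = FALSE)

  if (method == "hma") {
    av <- average_by_flow_level(maneuvers, hma_flows)
    av <- av[match(ids, av$participant_id), ]
    r <- hma_batch(as.matrix(av[, 2:4]), hma_flows)
    out$converged <- r$converged
    out[r$converged, 4:6] <- r$theta[r$converged, , drop = FALSE]
    out$diagnostics[!av$complete] <- "missing flow level"
    out$diagnostics[av$complete & !r$converged] <- "algorithm failed"
    out$diagnostics[r$inverted_gradient] <- "inverted gradient (C_aw < c_alv)"
    return(out)
  }

  constrained <- method == "nls_constrained"
  idx <- match(maneuvers$participant_id, ids)
  flows_by <- split(maneuvers$flow_mls, idx)
  feno_by <- split(maneuvers$feno_ppb, idx)
  sig <- vapply(flows_by, function(v) paste(sort(v), collapse = ","), "")
  for (s in unique(sig)) {
    members <- which(sig == s)
    fl <- sort(flows_by[[members[1L]]])
    if (length(unique(fl)) < 3L || length(fl) < 4L) {
      out$diagnostics[members] <- "too few maneuvers or flow levels"
      next
    }
    Y <- t(vapply(members, function(i) {
      o <- order(flows_by[[i]])
      log(feno_by[[i]][o])
    }, numeric(length(fl))))
    start <- t(vapply(members, function(i)
      nls_start_values(flows_by[[i]], feno_by[[i]]), numeric(3L)))
    fit <- gn_batch(Y, fl, start, constrained = constrained)
    ok <- fit$converged & nls_within_bounds(fit$theta, constrained)
    redo <- which(!ok)
    if (length(redo)) {
      fit2 <- gn_batch(Y[redo, , drop = FALSE], fl,
                       matrix(c(1, 3.5, 2.5), length(redo), 3L, byrow = TRUE),
                       constrained = constrained)
      ok2 <- fit2$converged & nls_within_bounds(fit2$theta, constrained)
      fit$theta[redo[ok2], ] <- fit2$theta[ok2, , drop = FALSE]
      out$diagnostics[members[redo]] <- ifelse(
        ok2, "restarted from fallback start",
        ifelse(fit2$converged, "estimate outside sanity bounds", fit2$reason))
      ok[redo] <- ok2
    }
    out$converged[members] <- ok
    out[members[ok], 4:6] <- fit$theta[ok, , drop = FALSE]
  }
  out
}
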