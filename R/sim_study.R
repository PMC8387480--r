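## Simulation-study harness: run estimation methods over generated datasets
## and aggregate bias, coverage, CI length, power and type-I error.

#' One simulation replicate
#'
#' Generates a dataset from \code{pop} and produces, for each requested
#' method, slope estimates with 95% intervals for the effect of the
#' covariate on each NO parameter. Method failures (Stage-I mass failure,
#' NLME non-convergence, an unconverged sampler) are recorded as data, not
#' raised.
#'
#' @param pop generating \code{"feno_population"}.
#' @param methods subset of \code{c("ts_hma", "ts_nls", "ts_nlme", "u_nlme",
#'   "u_hb")}.
#' @param n participants per dataset.
#' @param seed dataset seed.
#' @param flows maneuver schedule.
#' @param uhb_control,uhb_chains sampler protocol for \code{"u_hb"}.
#' @return data.frame with one row per method x NO parameter:
#'   effect-estimate columns plus \code{converged} (method-level),
#'   \code{beta_true} and \code{seed}.
#' @export
run_replicate <- function(pop, methods = c("ts_hma", "ts_nls"), n = 1000L,
                          seed = 1L, flows = flow_schedule("simulation"),
                          uhb_control = feno2cm::uhb_control(retained_total = 3000L),
                          uhb_chains = 3L) {
  methods <- match.arg(methods, c("ts_hma", "ts_nls", "ts_nlme", "u_nlme", "u_hb"),
                       several.ok = TRUE)
  sim <- simulate_dataset(pop, n, flows = flows, seed = seed)
  cov <- sim$participants[, c("participant_id", "x")]
  empty <- data.frame(method = NA_character_,
                      parameter = c("c_alv", "log_caw", "log_daw"),
                      estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, n_used = NA_integer_,
                      stringsAsFactors = FALSE)
  one <- function(m) {
    eff <- NULL; ok <- FALSE
    if (m == "ts_hma") {
      s1 <- fit_stage1(sim$maneuvers, method = "hma")
      eff <- try(stage2_ols(s1, cov, method = "ts_hma"), silent = TRUE)
    } else if (m == "ts_nls") {
      s1 <- fit_stage1(sim$maneuvers, method = "nls")
      eff <- try(stage2_ols(s1, cov, method = "ts_nls"), silent = TRUE)
    } else if (m == "ts_nlme") {
      f <- nlme_fit(sim$maneuvers, cov, unified = FALSE)
      eff <- if (f$converged) try(stage2_ols(f$theta_eb, cov, method = "ts_nlme"),
                                  silent = TRUE)
    } else if (m == "u_nlme") {
      f <- nlme_fit(sim$maneuvers, cov, unified = TRUE)
      eff <- if (f$converged) f$effects
    } else if (m == "u_hb") {
      f <- uhb_fit(sim$maneuvers, cov, n_chains = uhb_chains,
                   seed = substream_seed(seed, 17L), control = uhb_control)
      eff <- if (f$converged) f$effects
    }
    ok <- !is.null(eff) && !inherits(eff, "try-error")
    if (!ok) { eff <- empty; eff$method <- m }
    eff$method <- m
    eff$converged <- ok
    eff
  }
  out <- do.call(rbind, lapply(methods, one))
  out$beta_true <- pop$beta[match(out$parameter, c("c_alv", "log_caw", "log_daw"))]
  out$seed <- seed
  rownames(out) <- NULL
  out
}

#' Aggregate replicate records into performance metrics
#'
#' Computes, per (scenario, effect size, method, NO parameter): bias
#' \code{mean(estimate - truth)}, relative bias
#' \code{mean((estimate - truth)/truth)} (defined only for non-zero truth),
#' 95%-interval coverage and mean length, and the rejection rate (the
#' proportion of intervals excluding 0 — power when the truth is non-zero,
#' type-I error when it is zero). With \code{filter_all_converged = TRUE} a
#' replicate contributes only if every method requested in that replicate
#' converged on it, the conservative all-methods-converged comparison.
#'
#' @param records row-bound output of [run_replicate()] calls, optionally
#'   with \code{scenario} / \code{beta_setting} / \code{replicate} columns
#'   (added by [run_scenario()]).
#' @param filter_all_converged apply the all-methods-converged filter?
#' @return data.frame of metrics rows.
#' @export
aggregate_metrics <- function(records, filter_all_converged = TRUE) {
  if (is.null(records$scenario)) records$scenario <- 1L
  if (is.null(records$beta_setting)) records$beta_setting <- records$beta_true
  if (is.null(records$replicate)) records$replicate <- match(records$seed, unique(records$seed))
  rep_key <- interaction(records$scenario, records$beta_setting,
                         records$replicate, drop = TRUE)
  if (filter_all_converged) {
    all_ok <- tapply(records$converged, rep_key, all)
    keep <- as.logical(all_ok[match(rep_key, names(all_ok))])
    records <- records[keep, , drop = FALSE]
    if (nrow(records) == 0L) {
      stop("no replicate survives the all-methods-converged filter")
    }
  } else {
    # each method still drops only its own failed replicates
    records <- records[records$converged, , drop = FALSE]
    if (nrow(records) == 0L) stop("no converged replicate to aggregate")
  }
  grp <- list(scenario = records$scenario, beta_setting = records$beta_setting,
              method = records$method, parameter = records$parameter)
  res <- by(records, grp, function(d) {
    truth <- d$beta_true[1L]
    data.frame(
      scenario = d$scenario[1L], beta_setting = d$beta_setting[1L],
      method = d$method[1L], parameter = d$parameter[1L],
      beta_true = truth, n_replicates_used = nrow(d),
      bias = mean(d$estimate - truth),
      relative_bias = if (truth != 0) mean((d$estimate - truth) / truth) else NA_real_,
      coverage = mean(d$ci_low <= truth & truth <= d$ci_high),
      ci_length = mean(d$ci_high - d$ci_low),
      reject_rate = mean(d$ci_low > 0 | d$ci_high < 0),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), res))
  rownames(out) <- NULL
  out
}

#' Average relative bias across an effect-size grid
#'
#' Averages per-setting mean relative bias over the settings of a sweep
#' (settings first, then the average — not a pooled replicate mean), per
#' method and NO parameter. Reported in percent.
#'
#' @param metrics output of [aggregate_metrics()].
#' @return data.frame: \code{method}, \code{parameter},
#'   \code{avg_relative_bias_pct}, \code{n_settings}.
#' @export
average_relative_bias <- function(metrics) {
  m <- metrics[!is.na(metrics$relative_bias), , drop = FALSE]
  key <- interaction(m$method, m$parameter, drop = TRUE)
  out <- do.call(rbind, lapply(split(m, key), function(d) {
    data.frame(method = d$method[1L], parameter = d$parameter[1L],
               avg_relative_bias_pct = 100 * mean(d$relative_bias),
               n_settings = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Enumerate the full simulation design
#'
#' The complete study design: seven scenarios with ten effect-size settings
#' each, plus the single all-zero setting they share — 71 generating
#' configurations in total.
#'
#' @param beta_grid the non-zero effect sizes.
#' @return data.frame with \code{scenario} (0 for the shared null setting),
#'   \code{beta_setting} and the three generating effects.
#' @export
study_design <- function(beta_grid = seq(0.02, 0.2, by = 0.02)) {
  rows <- list(data.frame(scenario = 0L, beta_setting = 0,
                          beta_c_alv = 0, beta_log_caw = 0, beta_log_daw = 0))
  for (sc in 1:7) {
    mask <- scenario_mask(sc)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = sc, beta_setting = beta_grid,
      beta_c_alv = ifelse(mask[1L], beta_grid, 0),
      beta_log_caw = ifelse(mask[2L], beta_grid, 0),
      beta_log_daw = ifelse(mask[3L], beta_grid, 0))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run one scenario sweep
#'
#' Loops the scenario's effect-size grid and replicates with
#' deterministically derived seeds (any single replicate is reproducible in
#' isolation from \code{base_seed}, the setting index and the replicate
#' number).
#'
#' @param scenario integer 1-7.
#' @param methods methods to run (see [run_replicate()]).
#' @param n participants per dataset.
#' @param replicates replicates per setting.
#' @param base_seed master seed of the sweep.
#' @param beta_grid effect sizes of the sweep.
#' @param base generating population template.
#' @param ... further arguments passed to [run_replicate()].
#' @return list with \code{records} (replicate-level archive sufficient to
#'   recompute every metric) and \code{metrics}
#'   ([aggregate_metrics()] with the all-converged filter).
#' @export
run_scenario <- function(scenario, methods = c("ts_hma", "ts_nls"), n = 1000L,
                         replicates = 50L, base_seed = 1L,
                         beta_grid = seq(0.02, 0.2, by = 0.02),
                         base = default_population(), ...) {
  pops <- scenario_settings(scenario, beta_grid, base = base)
  records <- vector("list", length(pops) * replicates)
  k <- 0L
  for (s in seq_along(pops)) {
    for (r in seq_len(replicates)) {
      seed <- substream_seed(base_seed, 1000L * (100L * scenario + s) + r)
      rec <- run_replicate(pops[[s]], methods = methods, n = n, seed = seed, ...)
      rec$scenario <- scenario
      rec$beta_setting <- beta_grid[s]
      rec$replicate <- r
      k <- k + 1L
      records[[k]] <- rec
    }
  }
  records <- do.call(rbind, records)
  list(records = records,
       metrics = aggregate_metrics(records, filter_all_converged = TRUE))
}
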