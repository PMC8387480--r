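## Tabular IO and run configuration.  All tables are plain CSV; the column
## names below are part of the public contract:
##   maneuvers:  participant_id, flow_mls, feno_ppb
##   covariates: participant_id, x, [adjusters...]
##   stage1:     participant_id, method, converged, c_alv_hat, log_caw_hat,
##               log_daw_hat, diagnostics
##   effects:    method, parameter, estimate, se, ci_low, ci_high, n_used
##   posterior:  parameter, mean, sd, q2_5, q97_5, rhat

#' Read a maneuver table
#'
#' Reads and validates a long-format maneuver CSV. Rows violating the
#' maneuver invariants (non-positive flow or FeNO, unparseable numbers) are
#' rejected with line-numbered messages; participants with fewer than 3
#' distinct flows are flagged in the \code{"flagged_participants"} attribute
#' but kept (estimators decide what they can use).
#'
#' @param path CSV with columns \code{participant_id}, \code{flow_mls},
#'   \code{feno_ppb}.
#' @return validated maneuver data.frame.
#' @export
read_maneuvers <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "flow_mls", "feno_ppb")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) stop("empty maneuver file: ", path)
  d$flow_mls <- suppressWarnings(as.numeric(d$flow_mls))
  d$feno_ppb <- suppressWarnings(as.numeric(d$feno_ppb))
  bad <- which(!is.finite(d$flow_mls) | d$flow_mls <= 0 |
                 !is.finite(d$feno_ppb) | d$feno_ppb <= 0)
  if (length(bad)) {
    warning("rejected ", length(bad), " invalid row(s) (file line ",
            paste(utils::head(bad + 1L, 10L), collapse = ", "),
            if (length(bad) > 10L) ", ..." else "",
            "): flow and FeNO must be positive numbers")
    d <- d[-bad, , drop = FALSE]
    if (nrow(d) == 0L) stop("no valid rows left in ", path)
  }
  nflows <- tapply(d$flow_mls, d$participant_id, function(v) length(unique(v)))
  attr(d, "flagged_participants") <- names(nflows)[nflows < 3L]
  rownames(d) <- NULL
  d
}

#' Read a participant covariate table
#'
#' @param path CSV with columns \code{participant_id}, \code{x} and optional
#'   adjustment covariates. Columns whose names end in \code{"_true"} are
#'   generator truth and are dropped with a message (estimators never see
#'   truth).
#' @return covariate data.frame.
#' @export
read_covariates <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "x")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  truth <- grep("_true$", names(d), value = TRUE)
  if (length(truth)) {
    message("dropping generator truth column(s): ", paste(truth, collapse = ", "))
    d <- d[, setdiff(names(d), truth), drop = FALSE]
  }
  if (anyDuplicated(d$participant_id)) stop("duplicated participant_id in ", path)
  d
}

#' Write a simulated dataset to CSV
#'
#' Writes the maneuver table and a companion participant table (covariate
#' plus \code{*_true} truth columns, which [read_covariates()] strips again).
#'
#' @param sim a \code{"feno_simdata"}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the two file paths.
#' @export
write_simdata <- function(sim, dir, prefix = "feno") {
  stopifnot(inherits(sim, "feno_simdata"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_maneuvers.csv"))
  p2 <- file.path(dir, paste0(prefix, "_participants.csv"))
  utils::write.csv(sim$maneuvers, p1, row.names = FALSE)
  utils::write.csv(sim$participants, p2, row.names = FALSE)
  invisible(c(maneuvers = p1, participants = p2))
}

#' Resolve and validate a run configuration
#'
#' Fills defaults into a raw configuration (a list, or a path to a JSON or
#' YAML file) and validates the result. Resolution is idempotent:
#' re-validating a resolved configuration returns it unchanged.
#'
#' @param raw named list or path to a \code{.json}/\code{.yaml} file; an
#'   empty list yields the full default configuration.
#' @param strict reject unknown keys?
#' @return validated configuration list of class \code{"feno_config"}.
#' @export
validate_config <- function(raw = list(), strict = TRUE) {
  if (is.character(raw)) {
    raw <- if (grepl("\\.ya?ml$", raw)) yaml::read_yaml(raw)
    else jsonlite::fromJSON(raw, simplifyVector = TRUE)
  }
  stopifnot(is.list(raw))
  defaults <- list(
    seed = 1L,
    n_participants = 1000L,
    sigma_resid = 0.15,
    flow_preset = "simulation",
    methods = c("ts_hma", "ts_nls"),
    scenario = 1L,
    replicates = 50L,
    beta_grid = seq(0.02, 0.2, by = 0.02),
    chains = 3L,
    retained_total = 12000L,
    warmup = 1000L,
    max_iter = 50000L,
    out_dir = "."
  )
  unknown <- setdiff(names(raw), names(defaults))
  if (strict && length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw[intersect(names(raw), names(defaults))])
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || cfg$seed < 0 ||
      cfg$seed != floor(cfg$seed)) stop("`seed` must be a non-negative integer")
  if (cfg$sigma_resid <= 0) stop("`sigma_resid` must be > 0")
  if (!all(cfg$methods %in% c("ts_hma", "ts_nls", "ts_nlme", "u_nlme", "u_hb"))) {
    stop("unknown method in `methods`")
  }
  if (!cfg$scenario %in% 1:7) stop("`scenario` must be in 1..7")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("feno_config", "list"))
}

#' Write a reproducibility manifest
#'
#' Records the resolved configuration, seed and package version so a
#' deterministic run can be reproduced byte-for-byte.
#'
#' @param config a resolved \code{"feno_config"}.
#' @param path output JSON path.
#' @return invisibly, \code{path}.
#' @export
write_run_manifest <- function(config, path) {
  manifest <- list(
    package = "feno2cm",
    version = as.character(utils::packageVersion("feno2cm")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
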