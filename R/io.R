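# Configuration files and result serialization. Configs are YAML or JSON
# with four blocks: parameters, schedule, initial, solver (plus optional
# seed). Validation collects every violation before failing so a bad config
# is fixed in one pass.

.config_schema <- list(
  parameters = c(
    "pi", "mu", "alpha1", "alpha2", "rho1", "rho2",
    "gamma1", "gamma2", "theta", "k"
  ),
  schedule = c("phi", "T", "tau"),
  initial = c("S", "H", "I", "D", "R"),
  solver = c("dt_target", "t_end")
)

#' Read and validate a run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration describing
#' one simulation run: a `parameters` block with the ten model constants, a
#' `schedule` block (`phi`, `T`, `tau`), an `initial` block (`S,H,I,D,R`),
#' a `solver` block (`dt_target`, `t_end`) and an optional integer `seed`.
#' Unknown keys anywhere are rejected; all schema violations are reported
#' together.
#'
#' @param path Path to the configuration file.
#' @return A validated list of class `shidr_config` with elements `params`
#'   ([shidr_params()]), `schedule` ([pulse_schedule()]), `init`
#'   (state vector), `solver` (list) and `seed` (or `NULL`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(raw, where = path)
}

#' @rdname read_run_config
#' @param config A raw configuration list (as parsed from file).
#' @param where Label used in error messages.
#' @export
validate_run_config <- function(config, where = "config") {
  problems <- character(0)
  allowed_top <- c(names(.config_schema), "seed")
  extra <- setdiff(names(config), allowed_top)
  if (length(extra) > 0) {
    problems <- c(problems, sprintf(
      "unknown top-level key(s): %s", paste(extra, collapse = ", ")
    ))
  }
  for (block in names(.config_schema)) {
    keys <- .config_schema[[block]]
    blk <- config[[block]]
    if (is.null(blk)) {
      problems <- c(problems, sprintf("missing block `%s`", block))
      next
    }
    miss <- setdiff(keys, names(blk))
    if (length(miss) > 0) {
      problems <- c(problems, sprintf(
        "block `%s` missing key(s): %s", block, paste(miss, collapse = ", ")
      ))
    }
    extra <- setdiff(names(blk), keys)
    if (length(extra) > 0) {
      problems <- c(problems, sprintf(
        "block `%s` has unknown key(s): %s", block, paste(extra, collapse = ", ")
      ))
    }
    for (k in intersect(keys, names(blk))) {
      v <- blk[[k]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
        problems <- c(problems, sprintf("`%s.%s` must be a finite number", block, k))
      }
    }
  }
  # range checks only when structurally sound
  if (length(problems) == 0) {
    sb <- config$schedule
    if (sb$phi < 0 || sb$phi >= 1) {
      problems <- c(problems, sprintf(
        "`schedule.phi` must lie in [0, 1) (got %g)", sb$phi
      ))
    }
    if (sb$T <= 0) problems <- c(problems, "`schedule.T` must be > 0")
    if (sb$tau < 0) problems <- c(problems, "`schedule.tau` must be >= 0")
    if (config$solver$dt_target <= 0) {
      problems <- c(problems, "`solver.dt_target` must be > 0")
    }
    if (config$solver$t_end <= 0) problems <- c(problems, "`solver.t_end` must be > 0")
    if (any(unlist(config$initial) < 0)) {
      problems <- c(problems, "`initial` densities must be >= 0")
    }
  }
  if (length(problems) > 0) {
    stop(sprintf(
      "invalid configuration (%s):\n  - %s", where,
      paste(problems, collapse = "\n  - ")
    ), call. = FALSE)
  }
  pb <- config$parameters
  structure(
    list(
      params = shidr_params(
        pi = pb$pi, mu = pb$mu, alpha1 = pb$alpha1, alpha2 = pb$alpha2,
        rho1 = pb$rho1, rho2 = pb$rho2, gamma1 = pb$gamma1,
        gamma2 = pb$gamma2, theta = pb$theta, k = pb$k
      ),
      schedule = pulse_schedule(
        config$schedule$phi, config$schedule$T,
        config$schedule$tau
      ),
      init = shidr_state(
        config$initial$S, config$initial$H, config$initial$I,
        config$initial$D, config$initial$R
      ),
      solver = config$solver,
      seed = config$seed
    ),
    class = "shidr_config"
  )
}

#' Serialize a run configuration
#'
#' Writes a [read_run_config()]-compatible file; `read -> write -> read`
#' round-trips losslessly.
#'
#' @param config A `shidr_config` object.
#' @param path Destination path; format chosen by extension (`.json` or
#'   YAML otherwise).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "shidr_config"))
  raw <- list(
    parameters = unclass(config$params),
    schedule = list(
      phi = config$schedule$phi, T = config$schedule$period,
      tau = config$schedule$tau
    ),
    initial = as.list(config$init),
    solver = config$solver
  )
  if (!is.null(config$seed)) raw$seed <- config$seed
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

#' Run a simulation from a configuration
#'
#' @param config A `shidr_config` from [read_run_config()].
#' @return A list with `trajectory` (a `shidr_trajectory`), `thresholds`
#'   (a `shidr_thresholds`) and `report` (a `long_run_report`).
#' @export
run_from_config <- function(config) {
  stopifnot(inherits(config, "shidr_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  traj <- shidr_simulate(config$params, config$schedule,
    init = config$init,
    t_end = config$solver$t_end, dt_target = config$solver$dt_target
  )
  list(
    trajectory = traj,
    thresholds = shidr_thresholds(config$params, config$schedule),
    report = classify_long_run(traj)
  )
}

#' Write a trajectory as CSV
#'
#' Columns exactly `t, S, H, I, D, R, N, event`; RFC-4180, '.' decimal.
#'
#' @param traj A `shidr_trajectory`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "shidr_trajectory"))
  cols <- c("t", "S", "H", "I", "D", "R", "N", "event")
  readr::write_csv(dplyr::select(tibble::as_tibble(traj), dplyr::all_of(cols)), path)
  invisible(path)
}

#' Write a threshold report as JSON
#'
#' Scalar keys named after the analytical quantities (`R1`, `R2`,
#' `phi_star`, `B`, `S_star`, `F_star`, `P_floor`, the extremal constants
#' and the `phi_star_status` flag). Undefined quantities serialise as
#' `null`.
#'
#' @param x A `shidr_thresholds` object.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_thresholds_json <- function(x, path) {
  stopifnot(inherits(x, "shidr_thresholds"))
  keys <- c(
    "R1", "R2", "phi_star", "phi_star_status", "B", "S_star",
    "alpha_max", "alpha_min", "rho_min", "rho_max", "sigma_min",
    "sigma_max", "F_star", "P_floor"
  )
  jsonlite::write_json(x[keys], path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
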