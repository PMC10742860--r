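# Packaged parameter fixtures and the numerical-experiment runner.

.scheme_table <- list(
  scheme1 = list(
    alpha1 = 0.8, alpha2 = 0.9, rho1 = 0.02, rho2 = 0.03,
    gamma1 = 0.2, gamma2 = 0.5, theta = 0.5, k = 0.5, mu = 0.01, pi = 0.01,
    notes = "slow turnover (mu = 0.01); extinction regime under moderate pulsing"
  ),
  scheme2 = list(
    alpha1 = 0.8, alpha2 = 0.9, rho1 = 0.02, rho2 = 0.03,
    gamma1 = 0.09, gamma2 = 0.08, theta = 0.5, k = 0.5, mu = 0.1, pi = 0.1,
    notes = "slow resolution (small gamma); permanence regime"
  ),
  scheme3 = list(
    alpha1 = 0.8, alpha2 = 0.4, rho1 = 0.08, rho2 = 0.1,
    gamma1 = 0.8, gamma2 = 0.1, theta = 0.5, k = 0.7, mu = 0.3, pi = 0.3,
    notes = "fast turnover and resolution; extinction regime, delay sweeps"
  )
)

#' Reference initial state
#'
#' The common starting densities used by all packaged experiments:
#' `S = 0.92, H = 0.03, I = 0.02, D = 0.02, R = 0.01` (total density 1).
#'
#' @return A length-5 named state vector.
#' @export
default_initial_state <- function() {
  shidr_state(S = 0.92, H = 0.03, I = 0.02, D = 0.02, R = 0.01)
}

#' Packaged parameter schemes
#'
#' Three reference parameter sets spanning the model's qualitative regimes.
#' All three have `pi = mu`, so the carrying level `pi / mu` is 1 and the
#' total density stays exactly 1 from the reference start.
#'
#' @param name One of `"scheme1"`, `"scheme2"`, `"scheme3"`.
#' @return An object of class `shidr_scheme`: a list with `name`,
#'   `params` ([shidr_params()]), `init` (reference initial state) and
#'   `notes`.
#' @examples
#' shidr_scheme("scheme2")$params
#' @export
shidr_scheme <- function(name = c("scheme1", "scheme2", "scheme3")) {
  name <- match.arg(name)
  row <- .scheme_table[[name]]
  structure(
    list(
      name = name,
      params = shidr_params(
        pi = row$pi, mu = row$mu, alpha1 = row$alpha1, alpha2 = row$alpha2,
        rho1 = row$rho1, rho2 = row$rho2, gamma1 = row$gamma1,
        gamma2 = row$gamma2, theta = row$theta, k = row$k
      ),
      init = default_initial_state(),
      notes = row$notes
    ),
    class = "shidr_scheme"
  )
}

#' @export
print.shidr_scheme <- function(x, ...) {
  cat(sprintf("<shidr_scheme> %s — %s\n", x$name, x$notes))
  print(x$params)
  invisible(x)
}

# Experiment registry: id -> list of (scheme, phi, period, tau) settings.
.experiment_settings <- function(id) {
  base <- switch(id,
    "6.1a" = tibble::tibble(scheme = "scheme1", phi = c(0.2, 0.5), period = 2, tau = 1),
    "6.1b" = tibble::tibble(scheme = "scheme2", phi = c(0.2, 0.3), period = 2, tau = 1),
    "6.2a" = tibble::tibble(scheme = "scheme1", phi = 0.3, period = c(1, 3), tau = 1),
    "6.2b" = tibble::tibble(scheme = "scheme2", phi = 0.3, period = c(2, 4), tau = 1),
    "6.3a" = tibble::tibble(scheme = "scheme3", phi = 0.3, period = 2, tau = c(2, 4, 6, 8, 10)),
    "6.3b" = tibble::tibble(scheme = "scheme2", phi = 0.3, period = 2, tau = c(0.5, 1, 1.5)),
    "6.4" = tibble::tibble(
      scheme = "scheme1", phi = 0.2, period = 2, tau = 1,
      rho = c(0, 0.05, 0.2, 0.4, 0.6, 0.8)
    ),
    "6.5" = NULL,
    stop(sprintf("unknown experiment id '%s'", id), call. = FALSE)
  )
  base
}

#' Available packaged experiments
#'
#' @return A tibble listing each experiment id with its scheme and the
#'   quantity varied.
#' @export
shidr_experiments <- function() {
  tibble::tribble(
    ~id, ~scheme, ~varies, ~regime,
    "6.1a", "scheme1", "phi in {0.2, 0.5}", "extinction (R1 < 1)",
    "6.1b", "scheme2", "phi in {0.2, 0.3}", "permanence (R2 > 1)",
    "6.2a", "scheme1", "period in {1, 3}", "extinction (R1 < 1)",
    "6.2b", "scheme2", "period in {2, 4}", "permanence (R2 > 1)",
    "6.3a", "scheme3", "tau in {2, 4, 6, 8, 10}", "extinction (R1 < 1)",
    "6.3b", "scheme2", "tau in {0.5, 1, 1.5}", "permanence (R2 > 1)",
    "6.4", "scheme1", "rho1 = rho2 in {0, .05, .2, .4, .6, .8}", "saturation damping",
    "6.5", "scheme1", "phi, rho grids on [0, 0.4]", "threshold surfaces"
  )
}

# Default simulation horizon per scheme: the slow-turnover scheme needs a
# long window for its transients; the fast schemes settle well before 200.
.default_horizon <- function(scheme) if (scheme == "scheme1") 600 else 200

#' Run a packaged numerical experiment
#'
#' Reproduces one of the reference experiment configurations: a family of
#' simulations of the full model under a sweep of one control quantity
#' (pulse proportion, pulse period, delay, or saturation), each paired with
#' its threshold report and long-run verdict. Experiment `"6.5"` is purely
#' analytical (threshold surfaces over `phi` and `rho`) and returns a
#' [sweep_thresholds()] result.
#'
#' @param id Experiment id, see [shidr_experiments()].
#' @param t_end Optional horizon override (default: 600 for scheme 1,
#'   200 for schemes 2 and 3).
#' @param dt_target Step request for the integrator (default 0.01).
#' @param n_windows Trailing pulse periods used by the classifier.
#' @param keep_trajectories Keep the full trajectory tibbles in the result
#'   (default `TRUE`; set `FALSE` to save memory in batch runs).
#' @return For `"6.5"`, a `shidr_sweep` tibble. Otherwise a list of class
#'   `shidr_experiment` with `id`, `summary` (one row per setting: the
#'   varied values, `R1`, `R2`, `phi_star`, verdict and tail statistics,
#'   `peak_I`, `t_peak`) and `trajectories` (list of `shidr_trajectory`).
#' @examples
#' \donttest{
#' ex <- run_experiment("6.1b", t_end = 120, dt_target = 0.05)
#' ex$summary
#' }
#' @export
run_experiment <- function(id, t_end = NULL, dt_target = 0.01, n_windows = 5,
                           keep_trajectories = TRUE) {
  if (id == "6.5") {
    base <- shidr_scheme("scheme1")
    return(sweep_thresholds(base$params,
      phi_grid = seq(0, 0.4, by = 0.05),
      rho_grid = seq(0, 0.4, by = 0.05),
      period = 2, tau = 1
    ))
  }
  settings <- .experiment_settings(id)
  rows <- vector("list", nrow(settings))
  trajs <- vector("list", nrow(settings))
  for (i in seq_len(nrow(settings))) {
    st <- settings[i, ]
    sch <- shidr_scheme(st$scheme)
    p <- sch$params
    if ("rho" %in% names(st)) {
      p <- shidr_params(
        pi = p$pi, mu = p$mu, alpha1 = p$alpha1, alpha2 = p$alpha2,
        rho1 = st$rho, rho2 = st$rho, gamma1 = p$gamma1, gamma2 = p$gamma2,
        theta = p$theta, k = p$k
      )
    }
    schedule <- pulse_schedule(st$phi, st$period, st$tau)
    horizon <- if (is.null(t_end)) .default_horizon(st$scheme) else t_end
    thr <- shidr_thresholds(p, schedule)
    traj <- shidr_simulate(p, schedule,
      init = sch$init, t_end = horizon,
      dt_target = dt_target
    )
    verdict <- classify_long_run(traj, n_windows = n_windows)
    pk <- peak_infected(traj)
    rows[[i]] <- dplyr::bind_cols(
      st,
      tibble::tibble(
        t_end = horizon, R1 = thr$R1, R2 = thr$R2, phi_star = thr$phi_star
      ),
      verdict, pk
    )
    trajs[[i]] <- if (keep_trajectories) traj else NULL
  }
  structure(
    list(id = id, summary = dplyr::bind_rows(rows), trajectories = trajs),
    class = "shidr_experiment"
  )
}

#' @export
print.shidr_experiment <- function(x, ...) {
  cat(sprintf("<shidr_experiment> %s\n", x$id))
  print(x$summary)
  invisible(x)
}

#' Random admissible parameter draws
#'
#' Draws parameter sets and pulse schedules uniformly from broad admissible
#' ranges, for property-style testing of the analytical quantities. The
#' defaults cover slow-to-fast turnover (`mu`, `pi` in `[0.01, 0.5]`),
#' weak-to-strong transmission (`alpha` in `[0.05, 1]`), saturation up to
#' 0.5, resolution rates in `[0.02, 1]`, free branching fractions, pulse
#' proportions up to 0.9, periods in `[0.5, 5]` and delays up to 5.
#'
#' @param n Number of draws.
#' @param seed Optional integer seed for reproducibility.
#' @param ranges Optional named list overriding any of the default ranges;
#'   each entry is `c(lo, hi)`. Names: `pi, mu, alpha1, alpha2, rho1, rho2,
#'   gamma1, gamma2, theta, k, phi, period, tau`.
#' @return A tibble with one row per draw and one column per quantity.
#'   Use [draw_to_objects()] to materialise a row.
#' @export
random_valid_parameters <- function(n = 1, seed = NULL, ranges = NULL) {
  defaults <- list(
    pi = c(0.01, 0.5), mu = c(0.01, 0.5),
    alpha1 = c(0.05, 1), alpha2 = c(0.05, 1),
    rho1 = c(0, 0.5), rho2 = c(0, 0.5),
    gamma1 = c(0.02, 1), gamma2 = c(0.02, 1),
    theta = c(0, 1), k = c(0, 1),
    phi = c(0, 0.9), period = c(0.5, 5), tau = c(0, 5)
  )
  if (!is.null(ranges)) {
    bad <- setdiff(names(ranges), names(defaults))
    if (length(bad) > 0) {
      stop("unknown range names: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    defaults[names(ranges)] <- ranges
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- purrr::map(defaults, ~ stats::runif(n, .x[1], .x[2]))
  tibble::as_tibble(draws)
}

#' Materialise one random draw
#'
#' @param draw A one-row tibble (or row slice) from
#'   [random_valid_parameters()].
#' @return A list with `params` ([shidr_params()]) and `schedule`
#'   ([pulse_schedule()]).
#' @export
draw_to_objects <- function(draw) {
  stopifnot(nrow(draw) == 1L)
  list(
    params = shidr_params(
      pi = draw$pi, mu = draw$mu, alpha1 = draw$alpha1, alpha2 = draw$alpha2,
      rho1 = draw$rho1, rho2 = draw$rho2, gamma1 = draw$gamma1,
      gamma2 = draw$gamma2, theta = draw$theta, k = draw$k
    ),
    schedule = pulse_schedule(draw$phi, draw$period, draw$tau)
  )
}
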