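#' Classify the long-run fate of a simulated trajectory
#'
#' Decides between rumor extinction and permanence from the tail of a
#' trajectory. The spreading density `F(t) = I(t) + D(t)` is examined over
#' the final `n_windows` pulse periods (the first half of the horizon is
#' treated as burn-in and must not overlap the examination window):
#' the verdict is `"extinct"` when the window maximum of `F` stays below
#' `tol_extinct`, `"persistent"` when the window minimum stays above
#' `tol_persist`, and `"undetermined"` otherwise.
#'
#' @param traj A `shidr_trajectory` from [shidr_simulate()].
#' @param tol_extinct Extinction tolerance on `max I + D` (default `1e-6`).
#' @param tol_persist Persistence tolerance on `min I + D` (default `1e-4`).
#' @param n_windows Number of trailing pulse periods examined (default 5).
#' @return A one-row tibble of class `long_run_report` with columns
#'   `verdict`, `sup_ID_last_window`, `inf_ID_last_window`,
#'   `sup_S_distance` (distance of S to the rumor-free periodic solution
#'   over the same window), and `windows_used`.
#' @export
classify_long_run <- function(traj, tol_extinct = 1e-6, tol_persist = 1e-4,
                              n_windows = 5) {
  stopifnot(inherits(traj, "shidr_trajectory"))
  schedule <- attr(traj, "schedule")
  t_end <- max(traj$t)
  win <- n_windows * schedule$period
  if (win > t_end / 2 + 1e-9) {
    stop(sprintf(
      "horizon too short: %d windows of period %g need t_end >= %g (got %g)",
      n_windows, schedule$period, 2 * win, t_end
    ), call. = FALSE)
  }
  tail_rows <- traj[traj$t >= t_end - win - 1e-9, ]
  f <- tail_rows$I + tail_rows$D
  sup_f <- max(f)
  inf_f <- min(f)
  verdict <- if (sup_f < tol_extinct) {
    "extinct"
  } else if (inf_f > tol_persist) {
    "persistent"
  } else {
    "undetermined"
  }
  out <- tibble::tibble(
    verdict = verdict,
    sup_ID_last_window = sup_f,
    inf_ID_last_window = inf_f,
    sup_S_distance = sup_distance_to_rumor_free(traj, n_windows = n_windows),
    windows_used = n_windows
  )
  class(out) <- c("long_run_report", class(out))
  out
}

#' Distance of the susceptible class to the rumor-free periodic solution
#'
#' Supremum over the final `n_windows` pulse periods of
#' `|S(t) - S_rf(t)|`, where `S_rf` is the rumor-free periodic susceptible
#' solution evaluated at the same grid nodes with matched one-sided limits
#' at pulse instants (left rows compare against the pre-pulse level, right
#' rows against the post-pulse level). Under extinction this distance
#' vanishes; under permanence it stays bounded but need not shrink.
#'
#' @inheritParams classify_long_run
#' @return A non-negative density.
#' @export
sup_distance_to_rumor_free <- function(traj, n_windows = 5) {
  stopifnot(inherits(traj, "shidr_trajectory"))
  params <- attr(traj, "params")
  schedule <- attr(traj, "schedule")
  t_end <- max(traj$t)
  tail_rows <- traj[traj$t >= t_end - n_windows * schedule$period - 1e-9, ]
  side <- ifelse(tail_rows$event == 1L, "left", "right")
  expected <- numeric(nrow(tail_rows))
  for (s in c("left", "right")) {
    idx <- side == s
    if (any(idx)) {
      expected[idx] <- rumor_free_susceptible(
        tail_rows$t[idx], params, schedule,
        side = s
      )
    }
  }
  max(abs(tail_rows$S - expected))
}

#' Threshold surfaces over pulse proportion and saturation
#'
#' Evaluates both reproduction numbers on a grid of pulse proportions
#' `phi` and common saturation values `rho` (applied as
#' `rho1 = rho2 = rho`), holding the remaining parameters fixed. Both
#' surfaces are monotone non-increasing along each axis: stronger pulsing
#' and stronger psychological inhibition both push the thresholds down.
#'
#' @param params Baseline [shidr_params()]; its `rho1`, `rho2` are
#'   overridden by the grid.
#' @param phi_grid Pulse proportions in `[0, 1)`.
#' @param rho_grid Saturation values, `>= 0`.
#' @param period Pulse period.
#' @param tau Discrete delay.
#' @return A tibble of class `shidr_sweep` with columns
#'   `phi, rho, R1, R2`, one row per grid cell.
#' @export
sweep_thresholds <- function(params, phi_grid, rho_grid, period, tau) {
  stopifnot(inherits(params, "shidr_params"))
  grid <- tidyr::expand_grid(phi = phi_grid, rho = rho_grid)
  vals <- purrr::pmap(grid, function(phi, rho) {
    p <- shidr_params(
      pi = params$pi, mu = params$mu,
      alpha1 = params$alpha1, alpha2 = params$alpha2,
      rho1 = rho, rho2 = rho,
      gamma1 = params$gamma1, gamma2 = params$gamma2,
      theta = params$theta, k = params$k
    )
    sch <- pulse_schedule(phi, period, tau)
    tibble::tibble(
      R1 = reproduction_number_r1(p, sch),
      R2 = reproduction_number_r2(p, sch)
    )
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(vals))
  class(out) <- c("shidr_sweep", class(out))
  out
}

#' Peak of the infected (rumor-spreading) class
#'
#' @param traj A `shidr_trajectory`.
#' @return One-row tibble with `peak_I` (maximum infected density on the
#'   grid) and `t_peak` (first time it is attained).
#' @export
peak_infected <- function(traj) {
  stopifnot(nrow(traj) > 0, "I" %in% names(traj))
  i <- which.max(traj$I)
  tibble::tibble(peak_I = traj$I[i], t_peak = traj$t[i])
}
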