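#' Inter-pulse susceptible depletion level B
#'
#' The period-average-free constant
#' `B = pi * (1 - exp(-mu * period)) / (mu * (1 - (1 - phi) * exp(-mu * period)))`:
#' the left limit (value just before a pulse) of the rumor-free periodic
#' susceptible solution, and the supremum the pulsed susceptible class can
#' sustain. Without pulsing (`phi = 0`) it collapses to the carrying level
#' `pi / mu`.
#'
#' @param params A [shidr_params()] object.
#' @param schedule A [pulse_schedule()] object.
#' @return A density in `(0, pi / mu]`.
#' @export
depletion_level <- function(params, schedule) {
  stopifnot(inherits(params, "shidr_params"), inherits(schedule, "pulse_schedule"))
  E <- exp(-params$mu * schedule$period)
  params$pi * (1 - E) / (params$mu * (1 - (1 - schedule$phi) * E))
}

#' Post-pulse susceptible fixed point S*
#'
#' The value of the rumor-free periodic susceptible solution immediately
#' after each pulse: `S* = (1 - phi) * B`, the unique fixed point of the
#' period map `x -> (1 - phi) * (pi/mu + (x - pi/mu) * exp(-mu * period))`.
#'
#' @inheritParams depletion_level
#' @return A density in `(0, pi / mu]`.
#' @export
susceptible_fixed_point <- function(params, schedule) {
  (1 - schedule$phi) * depletion_level(params, schedule)
}

#' Rumor-free periodic susceptible solution
#'
#' Evaluates the T-periodic susceptible trajectory of the rumor-free regime:
#' on each inter-pulse interval the susceptible class relaxes exponentially
#' towards `pi / mu` from the post-pulse level `S*`,
#' `S(t) = pi/mu + (S* - pi/mu) * exp(-mu * (t - nT))` for `nT < t <= (n+1)T`.
#' At pulse instants the solution jumps; `side` selects which limit is
#' returned there (`"right"` gives `S*`, `"left"` gives the pre-pulse level
#' `B`).
#'
#' @param t Time(s), `>= 0`. Vectorised.
#' @inheritParams depletion_level
#' @param side `"right"` (default) or `"left"`: which one-sided limit to
#'   report when `t` falls exactly on a pulse instant.
#' @return Susceptible density at each `t`.
#' @export
rumor_free_susceptible <- function(t, params, schedule, side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(all(t >= 0))
  Tp <- schedule$period
  s_star <- susceptible_fixed_point(params, schedule)
  level <- params$pi / params$mu
  n <- floor(t / Tp + 1e-9)
  phase <- t - n * Tp
  on_pulse <- abs(phase) < 1e-9 * pmax(1, Tp)
  if (side == "left") {
    phase[on_pulse & t > 1e-12] <- Tp
  } else {
    phase[on_pulse] <- 0
  }
  level + (s_star - level) * exp(-params$mu * phase)
}

# Extremal bounding constants used by the two thresholds. The extinction
# threshold R1 bounds the dynamics from above (max alpha, min rho, min sigma);
# the permanence threshold R2 bounds from below (min alpha, max rho, max
# sigma). sigma combines exit and leaving: theta*gamma1 + mu for spreaders,
# gamma2 + mu for refuters.
threshold_constants <- function(params) {
  list(
    alpha_max = max(params$alpha1, params$alpha2),
    alpha_min = min(params$alpha1, params$alpha2),
    rho_min = min(params$rho1, params$rho2),
    rho_max = max(params$rho1, params$rho2),
    sigma_min = min(params$theta * params$gamma1 + params$mu, params$gamma2 + params$mu),
    sigma_max = max(params$theta * params$gamma1 + params$mu, params$gamma2 + params$mu)
  )
}

#' Extinction threshold R1
#'
#' The basic reproduction number controlling global attraction to the
#' rumor-free periodic solution:
#' `R1 = alpha * exp(-mu * tau) * B / ((1 + rho * B) * sigma)` with the
#' upper-bounding constants `alpha = max(alpha1, alpha2)`,
#' `rho = min(rho1, rho2)`, `sigma = min(theta*gamma1 + mu, gamma2 + mu)`
#' and `B` the pre-pulse susceptible level [depletion_level()]. When
#' `R1 < 1` the rumor dies out for every admissible start. R1 is strictly
#' decreasing in the pulse proportion `phi` and non-increasing in `tau` and
#' in the saturation factors.
#'
#' @inheritParams depletion_level
#' @return A positive dimensionless number.
#' @export
reproduction_number_r1 <- function(params, schedule) {
  cst <- threshold_constants(params)
  B <- depletion_level(params, schedule)
  cst$alpha_max * exp(-params$mu * schedule$tau) * B /
    ((1 + cst$rho_min * B) * cst$sigma_min)
}

#' Permanence threshold R2
#'
#' The lower reproduction number controlling permanence:
#' `R2 = (alpha' * exp(-mu * tau) / sigma' - rho') * S*` with the
#' lower-bounding constants `alpha' = min(alpha1, alpha2)`,
#' `rho' = max(rho1, rho2)`, `sigma' = max(theta*gamma1 + mu, gamma2 + mu)`
#' and `S*` the post-pulse susceptible level [susceptible_fixed_point()].
#' When `R2 > 1` the spreading classes `I + D` stay bounded away from zero
#' forever (the rumor is permanent). `R2 - 1` has the same sign as the
#' incidence-form quantity
#' `alpha' * exp(-mu*tau) * S* / ((1 + rho' * S*) * sigma') - 1`.
#'
#' @inheritParams depletion_level
#' @return A dimensionless number (can be negative for strong saturation).
#' @export
reproduction_number_r2 <- function(params, schedule) {
  cst <- threshold_constants(params)
  s_star <- susceptible_fixed_point(params, schedule)
  (cst$alpha_min * exp(-params$mu * schedule$tau) / cst$sigma_max - cst$rho_max) * s_star
}

#' Critical pulse proportion phi*
#'
#' The pulse proportion at which the extinction threshold crosses unity:
#' the root of `R1(phi) = 1`. Because R1 is strictly decreasing in `phi`,
#' any `phi > phi*` guarantees rumor extinction. Solved by bisection on
#' `[0, 1)`; monotonicity makes the bracket safe and the root unique.
#'
#' @param params A [shidr_params()] object.
#' @param period Pulse period (time), `> 0`.
#' @param tau Discrete delay (time), `>= 0`.
#' @param tol Absolute tolerance on `|R1(phi*) - 1|` (default `1e-10`).
#' @return A list with elements
#'   * `phi_star` — the critical proportion (`NA` when no `phi < 1` works,
#'     `0` when none is needed),
#'   * `status` — `"root"`, `"none_needed"` (already `R1(0) <= 1`), or
#'     `"unattainable"` (`R1 > 1` for every `phi < 1`),
#'   * `r1_at_root` — R1 evaluated at the returned `phi_star` (`NA` when
#'     unattainable).
#' @export
critical_pulse_rate <- function(params, period, tau, tol = 1e-10) {
  stopifnot(inherits(params, "shidr_params"), period > 0, tau >= 0)
  r1_of <- function(phi) {
    reproduction_number_r1(params, pulse_schedule(phi, period, tau))
  }
  upper <- 1 - 1e-12
  if (r1_of(0) <= 1) {
    return(list(phi_star = 0, status = "none_needed", r1_at_root = r1_of(0)))
  }
  if (r1_of(upper) > 1) {
    return(list(phi_star = NA_real_, status = "unattainable", r1_at_root = NA_real_))
  }
  lo <- 0
  hi <- upper
  # R1 decreasing: R1(lo) > 1 > R1(hi); bisect until the residual meets tol
  for (iter in seq_len(200L)) {
    mid <- 0.5 * (lo + hi)
    r <- r1_of(mid)
    if (abs(r - 1) <= tol && (hi - lo) < 1e-12) break
    if (r > 1) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-15) break
  }
  phi_star <- 0.5 * (lo + hi)
  list(phi_star = phi_star, status = "root", r1_at_root = r1_of(phi_star))
}

#' Permanence floor P
#'
#' A positive constant below which the spreading density `I + D` cannot
#' settle once the permanence threshold exceeds unity. Built from
#' `F* = (mu / alpha) * (R2 - 1)` (with `alpha = max(alpha1, alpha2)`) as
#' `P = min(F*/2, F* * exp(-sigma' * tau))`. The floor is a sufficient
#' bound from the permanence argument, not a tight one; trajectories
#' typically sit far above it.
#'
#' @inheritParams depletion_level
#' @return A list with `F_star` and `P_floor` (both `NA` when `R2 <= 1`,
#'   where no floor is asserted) and `defined` (logical).
#' @export
permanence_floor <- function(params, schedule) {
  cst <- threshold_constants(params)
  r2 <- reproduction_number_r2(params, schedule)
  if (r2 <= 1) {
    return(list(F_star = NA_real_, P_floor = NA_real_, defined = FALSE))
  }
  f_star <- params$mu / cst$alpha_max * (r2 - 1)
  p1 <- f_star * exp(-cst$sigma_max * schedule$tau)
  list(F_star = f_star, P_floor = min(f_star / 2, p1), defined = TRUE)
}

#' Full threshold report
#'
#' Computes every closed-form analytical quantity of the model for one
#' parameter set and pulse schedule: the pre- and post-pulse susceptible
#' levels `B` and `S*`, the two reproduction numbers `R1` (extinction) and
#' `R2` (permanence), the critical pulse proportion `phi*`, the permanence
#' floor, and the extremal bounding constants entering each threshold.
#'
#' @inheritParams depletion_level
#' @return An object of class `shidr_thresholds`. Use [generics::tidy()] for
#'   a long tibble of quantities or [generics::glance()] for a one-row
#'   summary.
#' @examples
#' sch <- shidr_scheme("scheme1")
#' shidr_thresholds(sch$params, pulse_schedule(0.2, 2, 1))
#' @export
shidr_thresholds <- function(params, schedule) {
  stopifnot(inherits(params, "shidr_params"), inherits(schedule, "pulse_schedule"))
  cst <- threshold_constants(params)
  phi_star <- critical_pulse_rate(params, schedule$period, schedule$tau)
  floor <- permanence_floor(params, schedule)
  structure(
    c(
      list(
        R1 = reproduction_number_r1(params, schedule),
        R2 = reproduction_number_r2(params, schedule),
        phi_star = phi_star$phi_star,
        phi_star_status = phi_star$status,
        B = depletion_level(params, schedule),
        S_star = susceptible_fixed_point(params, schedule)
      ),
      cst,
      list(
        F_star = floor$F_star,
        P_floor = floor$P_floor,
        params = params,
        schedule = schedule
      )
    ),
    class = "shidr_thresholds"
  )
}

#' @export
print.shidr_thresholds <- function(x, ...) {
  cat("<shidr_thresholds>\n")
  cat(sprintf(
    "  R1 = %.6g (%s), R2 = %.6g (%s)\n",
    x$R1, if (x$R1 < 1) "extinction guaranteed" else ">= 1",
    x$R2, if (x$R2 > 1) "permanence guaranteed" else "<= 1"
  ))
  cat(sprintf(
    "  B = %.6g, S* = %.6g, phi* = %s (%s)\n",
    x$B, x$S_star,
    if (is.na(x$phi_star)) "NA" else sprintf("%.6g", x$phi_star),
    x$phi_star_status
  ))
  if (!is.na(x$P_floor)) {
    cat(sprintf("  permanence floor P = %.6g (F* = %.6g)\n", x$P_floor, x$F_star))
  }
  invisible(x)
}
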