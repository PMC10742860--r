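#' Rate constants of the SHIDR rumor model
#'
#' Bundles the ten rate/probability constants of the susceptible-hesitant-
#' infected-refuting-recovered (SHIDR) rumor-propagation model: inflow and
#' leaving rates of the network, the two saturated contact-transmission rates
#' (rumor and truth), their psychological saturation factors, the exit rates
#' of spreaders and refuters, and the two branching fractions.
#'
#' @param pi Inflow rate of susceptibles into the network (density / time).
#' @param mu Rate at which individuals leave the network (1 / time). Must be
#'   strictly positive; it also sets the asymptotic population `pi / mu`.
#' @param alpha1 Contact transmission rate between susceptible and infected
#'   (rumor-spreading) individuals.
#' @param alpha2 Contact transmission rate between susceptible and refuting
#'   (truth-spreading) individuals.
#' @param rho1,rho2 Psychological saturation factors: incidence takes the
#'   saturated form `alpha * S * X / (1 + rho * S)`, so larger `rho` damps
#'   transmission at high susceptible density.
#' @param gamma1 Exit rate of infected individuals (towards refuting or
#'   recovered).
#' @param gamma2 Exit rate of refuting individuals (towards recovered).
#' @param theta Fraction of exiting infected individuals that recover
#'   directly (the remaining `1 - theta` become refuters); in `[0, 1]`.
#' @param k Fraction of resolving hesitants that become infected (the
#'   remaining `1 - k` become refuters); in `[0, 1]`.
#'
#' @return An object of class `shidr_params` (a validated named list).
#' @seealso [pulse_schedule()], [shidr_scheme()] for the packaged fixture
#'   parameter sets.
#' @examples
#' shidr_params(
#'   pi = 0.01, mu = 0.01, alpha1 = 0.8, alpha2 = 0.9,
#'   rho1 = 0.02, rho2 = 0.03, gamma1 = 0.2, gamma2 = 0.5,
#'   theta = 0.5, k = 0.5
#' )
#' @export
shidr_params <- function(pi, mu, alpha1, alpha2, rho1, rho2,
                         gamma1, gamma2, theta, k) {
  p <- list(
    pi = pi, mu = mu, alpha1 = alpha1, alpha2 = alpha2,
    rho1 = rho1, rho2 = rho2, gamma1 = gamma1, gamma2 = gamma2,
    theta = theta, k = k
  )
  problems <- character(0)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      problems <- c(problems, sprintf("`%s` must be a finite numeric scalar", nm))
    } else if (v < 0) {
      problems <- c(problems, sprintf("`%s` must be >= 0 (got %g)", nm, v))
    }
  }
  if (is.numeric(mu) && length(mu) == 1L && is.finite(mu) && mu <= 0) {
    problems <- c(problems, sprintf("`mu` must be > 0 (got %g)", mu))
  }
  for (nm in c("theta", "k")) {
    v <- p[[nm]]
    if (is.numeric(v) && length(v) == 1L && is.finite(v) && (v < 0 || v > 1)) {
      problems <- c(problems, sprintf("`%s` must lie in [0, 1] (got %g)", nm, v))
    }
  }
  if (length(problems) > 0) {
    stop("invalid model parameters:\n  - ", paste(problems, collapse = "\n  - "),
      call. = FALSE
    )
  }
  structure(p, class = "shidr_params")
}

#' @export
print.shidr_params <- function(x, ...) {
  cat("<shidr_params>\n")
  cat(sprintf(
    "  pi = %g, mu = %g (pi/mu = %g)\n", x$pi, x$mu, x$pi / x$mu
  ))
  cat(sprintf(
    "  alpha1 = %g, alpha2 = %g, rho1 = %g, rho2 = %g\n",
    x$alpha1, x$alpha2, x$rho1, x$rho2
  ))
  cat(sprintf(
    "  gamma1 = %g, gamma2 = %g, theta = %g, k = %g\n",
    x$gamma1, x$gamma2, x$theta, x$k
  ))
  invisible(x)
}

#' Periodic pulse-vaccination schedule
#'
#' Describes the impulsive control: at every instant `t = n * period`
#' (n = 1, 2, ...) a fraction `phi` of the susceptible class is moved
#' instantaneously to the recovered class, modelling a burst of
#' popular-science education. `tau` is the discrete delay with which
#' exposure converts into active spreading or refuting.
#'
#' @param phi Pulse proportion in `[0, 1)`: fraction of susceptibles
#'   vaccinated at each pulse.
#' @param period Pulse period (time between consecutive pulses), `> 0`.
#' @param tau Discrete delay (time), `>= 0`.
#'
#' @return An object of class `pulse_schedule`.
#' @export
pulse_schedule <- function(phi, period, tau) {
  problems <- character(0)
  chk <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      problems <<- c(problems, sprintf("`%s` must be a finite numeric scalar", nm))
      FALSE
    } else {
      TRUE
    }
  }
  if (chk(phi, "phi") && (phi < 0 || phi >= 1)) {
    problems <- c(problems, sprintf("`phi` must lie in [0, 1) (got %g)", phi))
  }
  if (chk(period, "period") && period <= 0) {
    problems <- c(problems, sprintf("`period` must be > 0 (got %g)", period))
  }
  if (chk(tau, "tau") && tau < 0) {
    problems <- c(problems, sprintf("`tau` must be >= 0 (got %g)", tau))
  }
  if (length(problems) > 0) {
    stop("invalid pulse schedule:\n  - ", paste(problems, collapse = "\n  - "),
      call. = FALSE
    )
  }
  structure(list(phi = phi, period = period, tau = tau),
    class = "pulse_schedule"
  )
}

#' @export
print.pulse_schedule <- function(x, ...) {
  cat(sprintf(
    "<pulse_schedule> phi = %g, period = %g, tau = %g\n",
    x$phi, x$period, x$tau
  ))
  invisible(x)
}

#' Compartment state vector
#'
#' A named numeric vector `(S, H, I, D, R)` of compartment densities:
#' susceptible, hesitant, infected (rumor-spreading), refuting
#' (truth-spreading), recovered.
#'
#' @param S,H,I,D,R Non-negative compartment densities.
#' @return Named numeric vector of length 5.
#' @export
shidr_state <- function(S, H, I, D, R) {
  y <- c(S = S, H = H, I = I, D = D, R = R)
  if (!all(is.finite(y))) stop("state components must be finite", call. = FALSE)
  if (any(y < 0)) stop("state components must be >= 0", call. = FALSE)
  y
}

#' Saturated incidence terms
#'
#' The model's nonlinear incidence: contacts between susceptibles and
#' spreaders (`incidence_infected`, term `alpha1 * S * I / (1 + rho1 * S)`)
#' or between susceptibles and refuters (`incidence_refuting`, term
#' `alpha2 * S * D / (1 + rho2 * S)`). The `rho` factor encodes psychological
#' inhibition: the per-contact rate saturates as `S` grows, so each term is
#' bounded above by its bilinear counterpart `alpha * S * X`.
#'
#' @param S Susceptible density (`>= 0`).
#' @param I,D Spreader / refuter density (`>= 0`).
#' @param params A [shidr_params()] object.
#' @return Non-negative flow (density / time). Vectorised over the state
#'   arguments.
#' @examples
#' p <- shidr_scheme("scheme1")$params
#' incidence_infected(S = 0.92, I = 0.02, params = p)
#' @export
incidence_infected <- function(S, I, params) {
  stopifnot(inherits(params, "shidr_params"))
  if (any(S < 0) || any(I < 0)) {
    stop("incidence requires S >= 0 and I >= 0", call. = FALSE)
  }
  params$alpha1 * S * I / (1 + params$rho1 * S)
}

#' @rdname incidence_infected
#' @export
incidence_refuting <- function(S, D, params) {
  stopifnot(inherits(params, "shidr_params"))
  if (any(S < 0) || any(D < 0)) {
    stop("incidence requires S >= 0 and D >= 0", call. = FALSE)
  }
  params$alpha2 * S * D / (1 + params$rho2 * S)
}

# Compiled-down right-hand side closure: all constants resolved once so the
# integrator's inner loop does no list lookups. `ylag` is the state at t - tau.
make_shidr_rhs <- function(params, tau) {
  pi_ <- params$pi
  mu <- params$mu
  a1 <- params$alpha1
  a2 <- params$alpha2
  r1 <- params$rho1
  r2 <- params$rho2
  g1 <- params$gamma1
  g2 <- params$gamma2
  th <- params$theta
  k <- params$k
  disc <- exp(-mu * tau) # survival factor over the delay window
  function(t, y, ylag) {
    S <- y[1L]
    inc1 <- a1 * S * y[3L] / (1 + r1 * S)
    inc2 <- a2 * S * y[4L] / (1 + r2 * S)
    Sd <- ylag[1L]
    dinc <- disc * (a1 * Sd * ylag[3L] / (1 + r1 * Sd) +
      a2 * Sd * ylag[4L] / (1 + r2 * Sd))
    c(
      pi_ - inc1 - inc2 - mu * S,
      inc1 + inc2 - dinc - mu * y[2L],
      k * dinc - (mu + g1) * y[3L],
      (1 - k) * dinc - (g2 + mu) * y[4L] + (1 - th) * g1 * y[3L],
      th * g1 * y[3L] + g2 * y[4L] - mu * y[5L]
    )
  }
}

#' Continuous-time vector field of the full SHIDR system
#'
#' Evaluates the derivative `(dS, dH, dI, dD, dR)` of the delayed SHIDR
#' system between pulses. New exposures enter the hesitant class at the
#' current saturated incidence; after a delay `tau` the surviving fraction
#' `exp(-mu * tau)` of those exposures resolves, a share `k` into the
#' infected class and `1 - k` into the refuting class. Infected individuals
#' exit at rate `gamma1` (a fraction `theta` recovering directly, the rest
#' turning refuter), refuters recover at rate `gamma2`, and every class is
#' drained at the leaving rate `mu`.
#'
#' The five components always sum to `pi - mu * N(now)`: total density obeys
#' the linear immigration-death law regardless of the rumor dynamics.
#'
#' @param now State vector `(S, H, I, D, R)` at time `t`.
#' @param delayed State vector at time `t - tau`.
#' @param params A [shidr_params()] object.
#' @param schedule A [pulse_schedule()] object (only `tau` enters the
#'   continuous dynamics).
#' @return Named numeric derivative vector of length 5.
#' @export
rhs_full <- function(now, delayed, params, schedule) {
  stopifnot(
    inherits(params, "shidr_params"), inherits(schedule, "pulse_schedule"),
    length(now) == 5L, length(delayed) == 5L
  )
  f <- make_shidr_rhs(params, schedule$tau)
  out <- f(0, as.numeric(now), as.numeric(delayed))
  names(out) <- c("S", "H", "I", "D", "R")
  out
}

#' Pulse-vaccination jump map
#'
#' The instantaneous state jump applied at each pulse instant: a fraction
#' `phi` of susceptibles is moved to the recovered class,
#' `S+ = (1 - phi) S`, `R+ = R + phi S`, with H, I, D untouched. Total
#' density N is conserved exactly.
#'
#' @param state State vector `(S, H, I, D, R)`.
#' @param phi Pulse proportion in `[0, 1)`.
#' @return The post-pulse state vector.
#' @export
apply_impulse <- function(state, phi) {
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) ||
    phi < 0 || phi >= 1) {
    stop("`phi` must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(length(state) == 5L)
  out <- state
  out[1L] <- (1 - phi) * state[1L]
  out[5L] <- state[5L] + phi * state[1L]
  out
}
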