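# Shared fixtures: scheme shortcuts and a pulsed-scalar exact solution used
# as an independent oracle for the integrator.

scheme_params <- function(name) shidr_scheme(name)$params

# Exact solution of dx/dt = pi - mu*x with x+ = (1-phi)*x at t = nT,
# computed by exact per-segment exponentials (independent of the RK4 path).
# `side` resolves which one-sided limit to return at pulse instants.
exact_pulsed_decay <- function(t, x0, pi_, mu, phi, period, side = "right") {
  level <- pi_ / mu
  vapply(seq_along(t), function(i) {
    ti <- t[i]
    n <- floor(ti / period + 1e-9)
    phase <- ti - n * period
    if (side == "left" && phase < 1e-9 && ti > 1e-12) {
      n <- n - 1
      phase <- period
    }
    x <- x0
    if (n > 0) {
      for (k in seq_len(n)) {
        x <- (1 - phi) * (level + (x - level) * exp(-mu * period))
      }
    }
    level + (x - level) * exp(-mu * phase)
  }, numeric(1))
}

# Random admissible state vectors for property loops.
random_states <- function(n, seed) {
  set.seed(seed)
  matrix(runif(5 * n, 0, 1), ncol = 5)
}
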