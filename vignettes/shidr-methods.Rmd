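---
title: "Methods: delayed impulsive rumor dynamics in shidr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delayed impulsive rumor dynamics in shidr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shidr)
```

## The model

`shidr` implements a compartmental model of rumor spreading on online
social networks with five classes: susceptible $S$ (has not met the
rumor), hesitant $H$ (has met it, still deciding), infected $I$
(actively spreading the rumor), refuting $D$ (actively spreading the
anti-rumor), and recovered $R$ (spreads neither). Between pulses the
densities obey

$$
\begin{aligned}
S' &= \pi - \frac{\alpha_1 S I}{1+\rho_1 S} - \frac{\alpha_2 S D}{1+\rho_2 S} - \mu S,\\
H' &= \frac{\alpha_1 S I}{1+\rho_1 S} + \frac{\alpha_2 S D}{1+\rho_2 S}
      - e^{-\mu\tau}\!\left[\frac{\alpha_1 S_\tau I_\tau}{1+\rho_1 S_\tau}
      + \frac{\alpha_2 S_\tau D_\tau}{1+\rho_2 S_\tau}\right] - \mu H,\\
I' &= k\,e^{-\mu\tau}S_\tau\!\left[\frac{\alpha_1 I_\tau}{1+\rho_1 S_\tau}
      + \frac{\alpha_2 D_\tau}{1+\rho_2 S_\tau}\right] - (\mu+\gamma_1) I,\\
D' &= (1-k)\,e^{-\mu\tau}S_\tau\!\left[\frac{\alpha_1 I_\tau}{1+\rho_1 S_\tau}
      + \frac{\alpha_2 D_\tau}{1+\rho_2 S_\tau}\right] - (\mu+\gamma_2) D
      + (1-\theta)\gamma_1 I,\\
R' &= \theta\gamma_1 I + \gamma_2 D - \mu R,
\end{aligned}
$$

where the subscript $\tau$ denotes evaluation at $t-\tau$. Exposure
converts into active spreading only after a processing delay $\tau$; the
factor $e^{-\mu\tau}$ is the probability of still being in the network
when the decision lands, a share $k$ of deciders start spreading the
rumor and $1-k$ the truth. The incidence is *saturated*:
$\alpha S X/(1+\rho S)$ caps the per-contact rate at high susceptible
density, with $\rho$ encoding psychological inhibition.

Periodic "impulsive vaccination" — repeated popular-science education —
acts at $t = nT$, $n \ge 1$, as the jump
$S^+ = (1-\varphi)S$, $R^+ = R + \varphi S$, leaving $H, I, D$ untouched.

Two structural identities anchor all numerics:

* the five right-hand sides sum to $\pi - \mu N$, so the total density
  obeys the linear immigration–death law $N' = \pi - \mu N$ exactly and
  tends to $\pi/\mu$;
* the jump conserves $N$.

## Analytical quantities

With $E = e^{-\mu T}$, the rumor-free regime has the $T$-periodic
susceptible solution

$$
\tilde S_e(t) = \frac{\pi}{\mu} + \left(S^* - \frac{\pi}{\mu}\right)
e^{-\mu (t - nT)}, \qquad nT < t \le (n+1)T,
$$

with post-pulse level
$S^* = \pi(1-\varphi)(1-E)\,/\,\mu(1-(1-\varphi)E)$ and pre-pulse level
$B = S^*/(1-\varphi)$. `rumor_free_susceptible()` evaluates this curve
with an explicit `side` argument for the two one-sided limits at pulse
instants.

The two thresholds bound the spreading dynamics from opposite sides:

* **Extinction**: $R_1 = \alpha e^{-\mu\tau} B / ((1+\rho B)\,\sigma)$
  with $\alpha = \max(\alpha_1,\alpha_2)$, $\rho = \min(\rho_1,\rho_2)$,
  $\sigma = \min(\theta\gamma_1+\mu,\ \gamma_2+\mu)$. When $R_1 < 1$ the
  rumor-free periodic solution is globally attractive.
* **Permanence**: $R_2 = (\alpha' e^{-\mu\tau}/\sigma' - \rho')\,S^*$
  with the opposite extremes $\alpha' = \min(\alpha_1,\alpha_2)$,
  $\rho' = \max(\rho_1,\rho_2)$,
  $\sigma' = \max(\theta\gamma_1+\mu,\ \gamma_2+\mu)$. When $R_2 > 1$
  the spreading density $I+D$ stays bounded away from zero.

$R_2$ is stated here in the form whose sign relative to 1 agrees with
the incidence-form quantity
$\alpha' e^{-\mu\tau} S^* / ((1+\rho' S^*)\,\sigma')$; that equivalence
is property-tested rather than assumed. The gap between $R_1$ and $R_2$
reflects the bounding constants, and the package verifies on $10^4$
random admissible draws that the two can never disagree in the
problematic direction ($R_1 < 1$ together with $R_2 > 1$ is impossible,
because $\alpha \ge \alpha'$, $B \ge S^*$, $\sigma \le \sigma'$ and
$x \mapsto x/(1+\rho x)$ is increasing in $x$ and decreasing in $\rho$).

**Critical pulse proportion.** $R_1$ is strictly decreasing in
$\varphi$, so $R_1(\varphi) = 1$ has at most one root $\varphi^*$ in
$[0,1)$. `critical_pulse_rate()` finds it by bisection to
$|R_1(\varphi^*) - 1| \le 10^{-10}$ rather than evaluating a closed
form: the bisection is immune to transcription ambiguity, and a closed
form re-derived from $R_1(\varphi)=1$ is used only as a test
cross-check. Degenerate cases are flagged explicitly: `"none_needed"`
when $R_1(0) \le 1$ already, `"unattainable"` when even $\varphi \to 1^-$
leaves $R_1 > 1$.

**Permanence floor.** When $R_2 > 1$ the package also reports
$F^* = (\mu/\alpha)(R_2 - 1)$ and
$P = \min(F^*/2,\ F^* e^{-\sigma'\tau})$, a positive lower bound on the
eventual spreading density coming from the permanence argument. The
floor is sufficient, not tight — simulated $I+D$ typically sits orders
of magnitude above it — so `shidr` reports $P$ but never asserts it
against trajectories.

## The integrator

All simulations use a fixed-step classical Runge–Kutta (RK4) scheme
organised by the method of steps. The step is chosen by
`resolve_step()` as the largest $dt \le dt_{\text{target}}$ dividing
both the pulse period and the delay (both treated as decimal rationals;
incommensurable pairs are rejected with instructions to pass an explicit
`dt`). Grid alignment buys two things at once:

* delayed values at node times are exact array lookups, and pulse
  instants are grid nodes, so no event detection or root-finding is
  needed;
* every discontinuity of the solution — the pulse instants and their
  $\tau$-translates, where the solution is only $C^0$ — lands on a node,
  so each RK4 step integrates a smooth segment and the classical order
  is preserved.

Delayed values at the half-step stage times fall midway between stored
nodes and are interpolated by cubic Hermite from the stored
(state, derivative) pairs; the $O(dt^4)$ interpolation error enters the
local truncation multiplied by $dt$ and does not degrade the global
fourth order. The observed error ratio when halving $dt$ is ~16 on
linear-decay, delayed, and pulsed benchmarks (the test suite checks the
ratio lies in (12, 20)).

At each pulse node both one-sided limits are recorded; trajectories
carry them as duplicated rows tagged by the `event` column
(1 = pre-pulse, 2 = post-pulse). The post-pulse value seeds the next
step, matching the right-limit convention of the jump map.

Defaults: `dt_target = 0.01`; impulses fire at $t = nT$ for $n \ge 1$
only (no pulse at $t=0$, consistent with the periodic solution's
$(nT, (n+1)T]$ convention); the history on $[-\tau, 0)$ defaults to the
constant equal to the initial state, since the reference experiments
specify only point initial values — arbitrary history functions are
accepted.

### Degenerate inputs and guards

* $\tau = 0$ reduces to a plain impulsive ODE; the delayed argument is
  the current stage state.
* $\varphi = 0$ disables the jump map entirely.
* NaN/Inf aborts integration naming the offending time.
* A checked component below $-10^{-9}$ aborts with a step-size error;
  components are never silently clipped, because clipping hides
  integrator misconfiguration.

The non-negativity guard covers $S, I, D, R$ but deliberately not $H$.
$H$ is a bookkeeping integral — the discounted incidence accumulated
over the last $\tau$ time units — and no other equation reads it. When
the user-supplied point value $H(0)$ sits below the history-consistent
value $\int_{-\tau}^0 e^{\mu s}(\text{incidence})\,ds$, the *exact*
solution of the printed $H$ equation dips slightly negative
(about $-2\times 10^{-4}$ on the slow reference scheme) while the
transient decays like $e^{-\mu t}$. That excursion is genuine model
behaviour under point initial data, not a numerical failure, so it is
reported as-is.

## Long-run classification

`classify_long_run()` inspects $F(t) = I(t)+D(t)$ over the final
`n_windows` pulse periods (default 5), requiring the window to stay
inside the second half of the horizon so that transients from the
arbitrary constant history are burned off. The verdict is `"extinct"`
when $\max F < 10^{-6}$, `"persistent"` when $\min F > 10^{-4}$, and
`"undetermined"` otherwise; both tolerances are arguments. The distance
of $S$ to $\tilde S_e$ is computed on the same window with one-sided
limits matched via the `event` tags (phase-aligned on the pulse grid,
not wall time modulo $T$, to avoid off-by-one-node artifacts).

Default horizons in `run_experiment()` are 600 time units for the
slow-turnover scheme 1 ($\mu = 0.01$: its inter-pulse relaxation and the
spreading decay rate are both of order $10^{-2}$) and 200 for schemes 2
and 3; at those horizons every reference configuration classifies
decisively — scheme 3's slowest extinction case ends with
$\max F \approx 10^{-19}$, and the persistent scheme-2 runs settle near
$F \approx 0.3$.

## The reference schemes and the random-draw generator

The three packaged schemes (`shidr_scheme()`) pin the reference
parameter table exactly, and all share $\pi = \mu$, so the carrying
level $\pi/\mu$ is 1 and the common initial state
$(0.92, 0.03, 0.02, 0.02, 0.01)$, which sums to 1, keeps $N \equiv 1$ —
a convenient built-in consistency check (the simulated $N$ must match
the closed form to $10^{-8}$; observed agreement is ~$10^{-14}$).

`random_valid_parameters()` feeds the property suites. Its default
ranges are chosen to straddle the reference regimes with a wide margin
while staying epidemiologically sensible: turnover and inflow
$\mu, \pi \in [0.01, 0.5]$ (from the slowest scheme to fast-mixing
populations), transmission $\alpha \in [0.05, 1]$, saturation
$\rho \in [0, 0.5]$ (zero recovers bilinear incidence), resolution rates
$\gamma \in [0.02, 1]$, free branching fractions $\theta, k \in [0,1]$,
pulse proportion up to 0.9, period $T \in [0.5, 5]$ and delay
$\tau \in [0, 5]$. Draws are uniform and independent; the generator
makes no attempt to emulate correlated real-world parameter estimates,
so property tests certify algebraic identities and monotonicities over
the admissible box, not calibration to any empirical network.

What the synthetic experiments do **not** capture about real rumor data:
network topology (the model is mean-field), behavioural heterogeneity,
stochastic fluctuations near extinction (densities can become
arbitrarily small without absorbing), and time-varying parameters.
Passing tests therefore certify the mathematics of this mean-field
model, not predictive accuracy for any particular platform.

## Numerical choices worth knowing

* Threshold formulas are evaluated in double precision straight from
  their closed forms; reference values in the tests were frozen from
  independent direct arithmetic at 15 digits.
* `resolve_step()` snaps times to a denominator of $10^6$ before gcd
  arithmetic; anything not representable there (e.g. $\tau = 1/3$) is
  rejected rather than silently approximated.
* Bisection for $\varphi^*$ runs on $[0, 1-10^{-12}]$; with
  monotonicity this is guaranteed to bracket.
* The tie-break in `peak_infected()` reports the *first* attainment
  time.
* Scheme constants are parsed from decimal literals exactly as printed,
  so fixture checksum tests compare with `==`-level equality.

## Known limitations

* Fixed-step only: no adaptive error control, no stiffness handling.
  The reference dynamics are non-stiff; for parameter regions with fast
  rates, choose `dt_target` accordingly (the $N$-law check is a cheap
  a-posteriori error probe).
* One discrete delay; no distributed delays.
* The permanence floor is reported, never asserted against simulation
  (it is a proof device, loose by construction).
* Bifurcation analysis (e.g. delay-induced oscillations) is out of
  scope.
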