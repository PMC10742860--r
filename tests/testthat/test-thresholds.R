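test_that("depletion level B matches its closed form and limits", {
  p1 <- scheme_params("scheme1")

  # no pulsing: collapses to the carrying level pi/mu, any period
  for (Tp in c(0.5, 2, 10)) {
    expect_equal(depletion_level(p1, pulse_schedule(0, Tp, 1)), p1$pi / p1$mu,
      tolerance = 1e-14
    )
  }

  expect_equal(depletion_level(p1, pulse_schedule(0.2, 2, 1)),
    0.0917403137705759,
    tolerance = 1e-12
  )

  # long-period limit approaches pi/mu
  expect_equal(depletion_level(p1, pulse_schedule(0.2, 5000, 1)), p1$pi / p1$mu,
    tolerance = 1e-8
  )
})

test_that("S* is (1-phi)*B and the fixed point of the pulsed period map", {
  p2 <- scheme_params("scheme2")
  expect_equal(susceptible_fixed_point(p2, pulse_schedule(0.2, 2, 1)),
    0.42031572669682,
    tolerance = 1e-12
  )
  expect_equal(
    susceptible_fixed_point(p2, pulse_schedule(0, 2, 1)),
    p2$pi / p2$mu
  )

  draws <- random_valid_parameters(30, seed = 21)
  for (i in seq_len(nrow(draws))) {
    o <- draw_to_objects(draws[i, ])
    B <- depletion_level(o$params, o$schedule)
    s_star <- susceptible_fixed_point(o$params, o$schedule)
    expect_equal(s_star, (1 - o$schedule$phi) * B, tolerance = 1e-13)
    # fixed point of x -> (1-phi)(pi/mu + (x - pi/mu) e^{-mu T})
    level <- o$params$pi / o$params$mu
    mapped <- (1 - o$schedule$phi) *
      (level + (s_star - level) * exp(-o$params$mu * o$schedule$period))
    expect_equal(mapped, s_star, tolerance = 1e-13)
  }
})

test_that("rumor-free periodic susceptible solution satisfies its defining identities", {
  draws <- random_valid_parameters(20, seed = 31)
  for (i in seq_len(nrow(draws))) {
    o <- draw_to_objects(draws[i, ])
    s_star <- susceptible_fixed_point(o$params, o$schedule)
    Tp <- o$schedule$period
    # right limit at pulse instants is S*
    expect_equal(
      rumor_free_susceptible(3 * Tp, o$params, o$schedule, side = "right"),
      s_star,
      tolerance = 1e-12
    )
    # pulsing the left limit reproduces S* (periodicity of the fixed point)
    left <- rumor_free_susceptible(4 * Tp, o$params, o$schedule, side = "left")
    expect_equal((1 - o$schedule$phi) * left, s_star, tolerance = 1e-12)
  }

  # phi = 0 collapses to the constant pi/mu
  p1 <- scheme_params("scheme1")
  sch0 <- pulse_schedule(0, 2, 1)
  tt <- seq(0, 10, by = 0.37)
  expect_equal(
    rumor_free_susceptible(tt, p1, sch0),
    rep(p1$pi / p1$mu, length(tt))
  )
})

test_that("R1 matches frozen reference values and collapses correctly", {
  p1 <- scheme_params("scheme1")
  expect_equal(reproduction_number_r1(p1, pulse_schedule(0.2, 2, 1)),
    0.741772937241543,
    tolerance = 1e-12
  )
  expect_equal(reproduction_number_r1(p1, pulse_schedule(0.5, 2, 1)),
    0.314324633109313,
    tolerance = 1e-12
  )

  # no delay, no pulsing, no saturation: alpha * pi / (mu * sigma)
  p0 <- shidr_params(
    pi = 0.02, mu = 0.05, alpha1 = 0.3, alpha2 = 0.6, rho1 = 0, rho2 = 0,
    gamma1 = 0.4, gamma2 = 0.2, theta = 0.5, k = 0.5
  )
  sigma <- min(0.5 * 0.4 + 0.05, 0.2 + 0.05)
  expect_equal(
    reproduction_number_r1(p0, pulse_schedule(0, 1, 0)),
    0.6 * (0.02 / 0.05) / sigma
  )
})

test_that("R2 matches its frozen value and the sign-equivalent incidence form", {
  p2 <- scheme_params("scheme2")
  expect_equal(reproduction_number_r2(p2, pulse_schedule(0.2, 2, 1)),
    1.6776900699958,
    tolerance = 1e-12
  )

  # rho' = 0, tau = 0 collapse: alpha' * S* / sigma'
  p0 <- shidr_params(
    pi = 0.1, mu = 0.1, alpha1 = 0.7, alpha2 = 0.9, rho1 = 0, rho2 = 0,
    gamma1 = 0.09, gamma2 = 0.08, theta = 0.5, k = 0.5
  )
  sch <- pulse_schedule(0.2, 2, 0)
  s_star <- susceptible_fixed_point(p0, sch)
  expect_equal(
    reproduction_number_r2(p0, sch),
    0.7 * s_star / max(0.5 * 0.09 + 0.1, 0.08 + 0.1)
  )

  # sign(R2 - 1) agrees with the incidence-form threshold on random draws
  draws <- random_valid_parameters(1000, seed = 77)
  for (i in seq_len(nrow(draws))) {
    o <- draw_to_objects(draws[i, ])
    r2 <- reproduction_number_r2(o$params, o$schedule)
    cst <- list(
      a = min(o$params$alpha1, o$params$alpha2),
      r = max(o$params$rho1, o$params$rho2),
      s = max(
        o$params$theta * o$params$gamma1 + o$params$mu,
        o$params$gamma2 + o$params$mu
      )
    )
    s_star <- susceptible_fixed_point(o$params, o$schedule)
    inc_form <- cst$a * exp(-o$params$mu * o$schedule$tau) * s_star /
      ((1 + cst$r * s_star) * cst$s)
    expect_true(sign(r2 - 1) == sign(inc_form - 1) || abs(r2 - 1) < 1e-12)
  }
})

test_that("phi* is the root of R1(phi) = 1, confirmed by a fine grid scan", {
  p1 <- scheme_params("scheme1")
  cp <- critical_pulse_rate(p1, period = 2, tau = 1)
  expect_identical(cp$status, "root")
  expect_gt(cp$phi_star, 0)
  expect_lt(cp$phi_star, 0.2) # R1(0.2) < 1 already
  expect_lte(abs(cp$r1_at_root - 1), 1e-10)

  # independent bracket from a fine grid scan of R1(phi)
  grid <- seq(0, 0.5, by = 1e-4)
  r1g <- vapply(
    grid,
    function(phi) reproduction_number_r1(p1, pulse_schedule(phi, 2, 1)),
    numeric(1)
  )
  lo <- grid[max(which(r1g > 1))]
  hi <- grid[min(which(r1g < 1))]
  expect_gte(cp$phi_star, lo)
  expect_lte(cp$phi_star, hi)

  # independently re-derived closed form: R1(phi)=1 iff B = sigma/(alpha e^{-mu tau} - sigma rho)
  E <- exp(-p1$mu * 2)
  sigma <- min(p1$theta * p1$gamma1 + p1$mu, p1$gamma2 + p1$mu)
  alpha <- max(p1$alpha1, p1$alpha2)
  rho <- min(p1$rho1, p1$rho2)
  B_crit <- sigma / (alpha * exp(-p1$mu * 1) - sigma * rho)
  phi_cf <- 1 - (1 - p1$pi * (1 - E) / (p1$mu * B_crit)) / E
  expect_equal(cp$phi_star, phi_cf, tolerance = 1e-9)

  # above the critical proportion, R1 < 1 on a grid
  for (phi in seq(cp$phi_star + 0.01, 0.95, by = 0.1)) {
    expect_lt(reproduction_number_r1(p1, pulse_schedule(phi, 2, 1)), 1)
  }

  # flag cases: pulsing unnecessary vs. insufficient
  weak <- shidr_params(
    pi = 0.01, mu = 0.1, alpha1 = 0.05, alpha2 = 0.05, rho1 = 0.02,
    rho2 = 0.03, gamma1 = 0.5, gamma2 = 0.5, theta = 0.5, k = 0.5
  )
  expect_identical(critical_pulse_rate(weak, 2, 1)$status, "none_needed")
  fierce <- shidr_params(
    pi = 5, mu = 0.01, alpha1 = 5, alpha2 = 5, rho1 = 0, rho2 = 0,
    gamma1 = 0.01, gamma2 = 0.01, theta = 0.5, k = 0.5
  )
  cp_f <- critical_pulse_rate(fierce, 2, 0)
  expect_identical(cp_f$status, "unattainable")
  expect_true(is.na(cp_f$phi_star))
})

test_that("permanence floor is defined exactly when R2 > 1", {
  p1 <- scheme_params("scheme1")
  fl1 <- permanence_floor(p1, pulse_schedule(0.2, 2, 1)) # R2 < 1 here
  expect_false(fl1$defined)
  expect_true(is.na(fl1$P_floor))

  p2 <- scheme_params("scheme2")
  sch <- pulse_schedule(0.2, 2, 1)
  fl2 <- permanence_floor(p2, sch)
  r2 <- reproduction_number_r2(p2, sch)
  sigma_max <- max(0.5 * 0.09 + 0.1, 0.08 + 0.1)
  f_star <- 0.1 / 0.9 * (r2 - 1)
  expect_true(fl2$defined)
  expect_equal(fl2$F_star, f_star, tolerance = 1e-13)
  expect_equal(fl2$P_floor, min(f_star / 2, f_star * exp(-sigma_max * 1)),
    tolerance = 1e-13
  )

  # tau = 0: the exponential branch dominates, floor is F*/2
  sch0 <- pulse_schedule(0.2, 2, 0)
  fl0 <- permanence_floor(p2, sch0)
  expect_equal(fl0$P_floor, fl0$F_star / 2, tolerance = 1e-13)
})

test_that("R1 is strictly decreasing in phi and both thresholds damp with rho", {
  draws <- random_valid_parameters(200, seed = 55)
  phis <- seq(0, 0.95, by = 0.05)
  for (i in seq_len(nrow(draws))) {
    o <- draw_to_objects(draws[i, ])
    r1s <- vapply(phis, function(phi) {
      reproduction_number_r1(
        o$params,
        pulse_schedule(phi, o$schedule$period, o$schedule$tau)
      )
    }, numeric(1))
    expect_true(all(diff(r1s) < 0))
  }

  # rho damping at a fixed configuration
  p1 <- scheme_params("scheme1")
  sweep <- sweep_thresholds(p1,
    phi_grid = 0.2, rho_grid = c(0, 0.1, 0.3, 0.5),
    period = 2, tau = 1
  )
  expect_true(all(diff(sweep$R1) <= 0))
  expect_true(all(diff(sweep$R2) <= 0))
})

test_that("threshold report carries consistent extremal constants and tidiers work", {
  p3 <- scheme_params("scheme3")
  sch <- pulse_schedule(0.3, 2, 2)
  thr <- shidr_thresholds(p3, sch)
  expect_equal(thr$alpha_max, 0.8)
  expect_equal(thr$alpha_min, 0.4)
  expect_equal(thr$rho_min, 0.08)
  expect_equal(thr$rho_max, 0.1)
  expect_equal(thr$sigma_min, min(0.5 * 0.8 + 0.3, 0.1 + 0.3))
  expect_equal(thr$sigma_max, max(0.5 * 0.8 + 0.3, 0.1 + 0.3))

  td <- tidy(thr)
  expect_s3_class(td, "tbl_df")
  expect_setequal(
    td$quantity,
    c(
      "R1", "R2", "phi_star", "B", "S_star", "alpha_max", "alpha_min",
      "rho_min", "rho_max", "sigma_min", "sigma_max", "F_star", "P_floor"
    )
  )
  expect_equal(td$value[td$quantity == "R1"], thr$R1)

  gl <- glance(thr)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$extinction_guaranteed)
})
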