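test_that("two-Hill elastance attains its bounds and is periodic", {
  p <- elastance_params()
  # activation vanishes at the cycle origin
  expect_equal(elastance_two_hill(0, p), p$E_min)
  # brute-force grid oracle: recompute the scaling factor independently
  tg <- seq(0, p$T, length.out = 1e5 + 1)[-(1e5 + 1)]
  g1 <- (tg / p$tau1)^p$m1
  g2 <- (tg / p$tau2)^p$m2
  shape <- (g1 / (1 + g1)) / (1 + g2)
  k_oracle <- (p$E_max - p$E_min) / max(shape)
  expect_equal(p$k, k_oracle, tolerance = 1e-9)
  E <- elastance_two_hill(tg, p)
  expect_equal(min(E), p$E_min, tolerance = 1e-6)
  expect_equal(max(E), p$E_max, tolerance = 1e-6)
  # T-periodicity
  ts <- c(0.1, 0.37, 0.6)
  expect_equal(elastance_two_hill(ts + 3 * p$T, p),
               elastance_two_hill(ts, p))
  expect_error(elastance_two_hill(NaN, p), "finite")
  expect_error(elastance_params(E_max = 0.01, E_min = 0.03), "E_max")
})

test_that("elastance bounds follow from clinical pressure-volume pairs", {
  b <- compute_elastance_bounds(7, 31, 105, 16)
  expect_equal(round(b[["E_min"]], 2), 0.03)
  expect_equal(round(b[["E_max"]], 3), 0.875)
  expect_equal(compute_elastance_bounds(0, 31, 0, 16),
               c(E_min = 0, E_max = 0))
  expect_error(compute_elastance_bounds(7, 0, 105, 16), "positive")
})

test_that("valve opening-state rate saturates at the state bounds", {
  p <- valve_params()
  expect_equal(valve_state_rate(1, p$p_open + 500, p), 0)
  expect_equal(valve_state_rate(0, p$p_open, p), 0)
  # hand arithmetic: (1 - 0.5) * 0.2 * 100
  expect_equal(valve_state_rate(0.5, 100, valve_params(p_open = 0,
                                                       K_vo = 0.2)), 10)
  # dead band between the thresholds
  expect_equal(valve_state_rate(0.7, -500, p), 0)
  # closing drive is negative and vanishes at zeta = 0
  expect_lt(valve_state_rate(0.5, -p$p_close - 200, p), 0)
  expect_equal(valve_state_rate(0, -p$p_close - 200, p), 0)
  # saturation property: explicit Euler integration stays inside [0, 1]
  set.seed(1)
  for (i in 1:20) {
    z <- stats::runif(1)
    for (s in 1:200) {
      dp <- stats::rnorm(1, 0, 3000)
      z <- z + 1e-3 * valve_state_rate(z, dp, p)
      z <- min(max(z, 0), 1)
    }
    expect_gte(z, 0)
    expect_lte(z, 1)
  }
  expect_error(valve_state_rate(1.2, 0, p), "zeta")
})

test_that("valve pressure drop follows the Bernoulli-inertance law", {
  p <- valve_params() # A_ann 60, M_st 1, rho 0.00106
  expect_equal(valve_pressure_drop(0, 0, 1, p), 0)
  # hand arithmetic: rho / (2 * 60^2) * 1e8
  expect_equal(valve_pressure_drop(1e4, 0, 1, p),
               0.00106 / (2 * 60^2) * 1e8, tolerance = 1e-12)
  # q |q| law: doubling the flow quadruples the drop
  expect_equal(valve_pressure_drop(2e4, 0, 1, p),
               4 * valve_pressure_drop(1e4, 0, 1, p))
  expect_equal(valve_pressure_drop(-1e4, 0, 1, p),
               -valve_pressure_drop(1e4, 0, 1, p))
  # sealed valve (no regurgitant area) with flow is degenerate
  sealed <- valve_params(M_rg = 0)
  expect_error(valve_pressure_drop(100, 0, 0, sealed), "degenerate")
  # optional linear K_s term
  pk <- valve_params(use_Ks = TRUE)
  expect_equal(valve_pressure_drop(1e4, 0, 1, pk) -
                 valve_pressure_drop(1e4, 0, 1, p),
               pk$rho * pk$K_s * 1e4)
})

test_that("steady Windkessel pressure matches the closed form and the ODE", {
  lpa <- windkessel_params(0.0040, 7.1974, 0.3995)
  expect_equal(windkessel_mean_pressure(0, lpa), 0)
  expect_equal(windkessel_mean_pressure(1e4, lpa), 4035)
  expect_equal(windkessel_mean_pressure(2e4, lpa),
               2 * windkessel_mean_pressure(1e4, lpa))
  off <- windkessel_params(0.1, 1, 0.2, P_distal = 500)
  expect_equal(windkessel_mean_pressure(0, off), 500)
  # dynamic oracle: integrate the 3-element Windkessel ODE under periodic
  # forcing for 20 cycles and average the inlet pressure
  q_fun <- function(t) 1e4 * (1 + 0.8 * sin(2 * pi * t / 0.8))
  rhs <- function(t, y, parms) {
    list((q_fun(t) - (y[1] - lpa$P_distal) / lpa$R_d) / lpa$C)
  }
  times <- seq(0, 20 * 0.8, by = 0.8 / 200)
  sol <- deSolve::ode(c(Pc = 0), times, rhs, NULL)
  last <- sol[, "time"] >= 19 * 0.8
  p_in <- lpa$P_distal * 0 + sol[last, "Pc"] +
    lpa$R_p * q_fun(sol[last, "time"])
  expect_equal(tmean(sol[last, "time"], p_in),
               windkessel_mean_pressure(1e4, lpa), tolerance = 5e-3)
})

test_that("tube reduction has the right values and monotonicities", {
  # endograft main body: r 5 mm, l 40 mm, E 12 MPa, h 0.22 mm
  rlc <- tube_segment_reduce(5, 40, 12e6, 0.22)
  expect_equal(rlc[["C"]], 3 * pi * 125 * 40 / (2 * 12e6 * 0.22),
               tolerance = 1e-12)
  expect_equal(rlc[["C"]], 8.9e-3, tolerance = 5e-3)
  # rigid limit
  expect_lt(tube_segment_reduce(5, 40, 1e13, 0.22)[["C"]], 1e-7)
  # r^4 law for resistance
  r1 <- tube_segment_reduce(4, 30, 1e6, 0.5)
  r2 <- tube_segment_reduce(8, 30, 1e6, 0.5)
  expect_equal(r1[["R"]] / r2[["R"]], 16)
  expect_error(tube_segment_reduce(-1, 30, 1e6, 0.5), "positive")
  # monotonicity properties over random positive inputs
  set.seed(7)
  for (i in 1:25) {
    r <- stats::runif(1, 1, 20); l <- stats::runif(1, 5, 80)
    E <- stats::runif(1, 0.5e6, 20e6); h <- stats::runif(1, 0.1, 1)
    base <- tube_segment_reduce(r, l, E, h)
    expect_lt(tube_segment_reduce(r, l, E * 1.5, h)[["C"]], base[["C"]])
    expect_lt(tube_segment_reduce(r, l, E, h * 1.5)[["C"]], base[["C"]])
    expect_lt(tube_segment_reduce(r * 1.2, l, E, h)[["R"]], base[["R"]])
    expect_true(all(base > 0))
  }
})
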