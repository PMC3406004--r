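test_that("rhs has the zero fixed point, exchange equilibrium and exact derivative values", {
  p <- ref_params()
  # zero state is a fixed point
  d0 <- pk_rhs(0, 0, p, wt())
  expect_identical(c(d0$dC1, d0$dC2), c(0, 0))
  # at C2/C1 = K_pb/K_bp with no elimination, the brain derivative vanishes
  noenz <- enzyme_kinetics("none", k_cat = 1, K_M = 1, E_conc = 0)
  C1 <- 2.5
  d <- pk_rhs(C1, C1 * p$K_pb / p$K_bp, p, noenz)
  expect_equal(d$dC2, 0, tolerance = 1e-12)
  # direct substitution: CocH3 at [E] = 0.035 uM (v_max = 199.5), C1 = 200
  d <- pk_rhs(200, 0, p, coch3())
  expect_equal(d$dC1, -(199.5 * 200 / 203.1) - 0.01898 * 200, tolerance = 1e-12)
  expect_equal(d$dC2, (11.89 / 0.3292) * 0.01898 * 200, tolerance = 1e-12)
  # exchange terms conserve amount: V_p * dC1_exchange + V_b * dC2 = 0
  d <- pk_rhs(3, 1, p, noenz)
  expect_equal(p$V_p * d$dC1 + p$V_b * d$dC2, 0, tolerance = 1e-12)
  expect_error(pk_rhs(-1, 0, p, wt()), "nonnegative")
})

test_that("simulation handles degenerate inputs and conserves mass without elimination", {
  p <- ref_params()
  noenz <- enzyme_kinetics("none", k_cat = 1, K_M = 1, E_conc = 0)
  # zero initial condition: identically zero trajectories
  tc0 <- pk_simulate(sim_spec(C1_0 = 0, t_end = 10), p, wt())
  expect_true(all(tc0$C1 == 0) && all(tc0$C2 == 0))
  # v_max = 0: total amount V_p C1 + V_b C2 constant, trajectories
  # converge to the exchange equilibrium C2/C1 = K_pb/K_bp
  tc <- pk_simulate(sim_spec(C1_0 = 2, t_end = 600), p, noenz)
  amount <- p$V_p * tc$C1 + p$V_b * tc$C2
  expect_lt(max(abs(amount - p$V_p * 2)) / (p$V_p * 2), 1e-6)
  n <- nrow(tc)
  expect_equal(tc$C2[n] / tc$C1[n], p$K_pb / p$K_bp, tolerance = 1e-4)
  expect_true(all(tc$C1 >= 0) && all(tc$C2 >= 0))
})

test_that("adaptive solution matches the fixed-step RK4 oracle within 0.5%", {
  p <- ref_params()
  cases <- list(list(enz = wt(), c0 = 5, t_end = 30),
                list(enz = coch3(), c0 = 200, t_end = 30),
                list(enz = reference_enzyme("CocE"), c0 = 50, t_end = 30))
  for (cs in cases) {
    oracle <- rk4_simulate(cs$c0, p, cs$enz, cs$t_end, dt = 0.001)
    grid <- oracle[, "t"][seq(1, nrow(oracle), by = 100)]  # every 0.1 min
    tc <- pk_simulate(sim_spec(C1_0 = cs$c0, t_end = cs$t_end), p, cs$enz,
                      times = grid)
    ref <- oracle[seq(1, nrow(oracle), by = 100), ]
    expect_lt(max(abs(tc$C1 - ref[, "C1"])) / max(ref[, "C1"]), 0.005)
    expect_lt(max(abs(tc$C2 - ref[, "C2"])) / max(ref[, "C2"]), 0.005)
  }
})

test_that("mass-balance residual stays small, including the stiff high-dose case", {
  p <- ref_params()
  noenz <- enzyme_kinetics("none", k_cat = 1, K_M = 1, E_conc = 0)
  tc <- pk_simulate(sim_spec(C1_0 = 2, t_end = 200), p, noenz)
  expect_lt(mass_balance_residual(tc)$max_rel, 1e-8)
  tc <- pk_simulate(sim_spec(C1_0 = 5, t_end = 120), p, wt())
  expect_lt(mass_balance_residual(tc)$max_rel, 1e-6)
  # stiff early phase: plasma collapses in about a minute; a fine output
  # grid keeps the trapezoidal quadrature of the elimination term accurate
  tc <- pk_simulate(sim_spec(C1_0 = 200, t_end = 60, dt = 0.001), p, coch3())
  expect_lt(mass_balance_residual(tc)$max_rel, 1e-6)
  bad <- pk_timecourse(c(0, 1), c(1, 1), c(0, 0))
  expect_error(mass_balance_residual(bad), "supplied")
})

test_that("linear-regime plasma AUC matches the closed form C1_0 K_M / V_max", {
  p <- ref_params()
  c0 <- 0.001  # far below K_M = 4.5 uM
  auc1 <- auc_infinity(sim_spec(C1_0 = c0, t_end = 60), p, wt(), "plasma")
  expect_equal(auc1, c0 * 4.5 / (4.1 * 0.035), tolerance = 0.01)
})

test_that("time courses serialise and round-trip through delimited text", {
  p <- ref_params()
  tc <- pk_simulate(sim_spec(C1_0 = 1, t_end = 5, dt = 0.5), p, wt())
  path <- tempfile(fileext = ".csv")
  write_timecourse(tc, path)
  back <- read_timecourse(path)
  expect_equal(back$t, tc$t)
  expect_equal(back$C1, tc$C1)
  expect_equal(back$C2, tc$C2)
  expect_error(pk_timecourse(c(0, 1), c(1, -0.1), c(0, 0)), "nonnegative")
  expect_error(pk_timecourse(c(1, 2), c(1, 1), c(0, 0)), "start at 0")
})

test_that("dose-based specs convert micrograms to concentration via V_p", {
  p <- ref_params()
  spec <- sim_spec(dose_ug = 11, t_end = 35)
  expect_equal(cocainePK:::initial_concentration(spec, p),
               11 / (303.35 * 11.89), tolerance = 1e-12)
  expect_error(sim_spec(C1_0 = 1, dose_ug = 1), "exactly one")
  expect_error(sim_spec(t_end = 10), "exactly one")
})
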