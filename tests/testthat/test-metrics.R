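test_that("trapezoidal AUC is exact on simple series and additive in the upper limit", {
  tc <- pk_timecourse(0:10, rep(2, 11), rep(1, 11))
  expect_identical(trapezoid_auc(tc, "plasma"), 20)
  expect_identical(trapezoid_auc(tc, "brain", t_upper = 10), 10)
  # a * exp(-k t) sampled densely converges to a/k
  a <- 3; k <- 0.5
  t <- seq(0, 60, by = 0.001)
  tce <- pk_timecourse(t, a * exp(-k * t), a * exp(-k * t))
  expect_equal(trapezoid_auc(tce, "plasma"), a / k, tolerance = 1e-4)
  # additivity: AUC(0, t1) + segment(t1, t2) = AUC(0, t2)
  seg <- trapezoid_auc(tce, "brain", 40) - trapezoid_auc(tce, "brain", 15)
  y <- a * exp(-k * t); keep <- t >= 15 & t <= 40
  manual <- sum(diff(t[keep]) * (head(y[keep], -1) + tail(y[keep], -1)) / 2)
  expect_equal(seg, manual, tolerance = 1e-12)
  # interpolated partial segment keeps monotonicity in t_upper
  expect_lt(trapezoid_auc(tce, "brain", 10.0005), trapezoid_auc(tce, "brain", 10.001))
  expect_error(trapezoid_auc(tc, "brain", t_upper = 11), "extend")
})

test_that("peak extraction refines the grid maximum and handles monotone decay", {
  # monotone-decaying plasma trace peaks at t = 0 with value C1_0
  p <- ref_params()
  tc <- pk_simulate(sim_spec(C1_0 = 5, t_end = 30), p, wt())
  pk <- tc_peak(tc, "plasma")
  expect_identical(pk$time, 0)
  expect_identical(pk$peak, 5)
  # quadratic refinement recovers an analytic parabola vertex off-grid
  t <- seq(0, 2, by = 0.25)
  y <- 1 - (t - 1.1)^2
  tcq <- pk_timecourse(t, pmax(y, 0), pmax(y, 0))
  pkq <- tc_peak(tcq, "brain")
  expect_equal(pkq$time, 1.1, tolerance = 1e-9)
  expect_equal(pkq$peak, 1, tolerance = 1e-9)
  expect_error(tc_peak(structure(data.frame(t = numeric(), C1 = numeric(),
                                            C2 = numeric()),
                                 class = c("pk_timecourse", "data.frame"))),
               "empty")
})

test_that("half-life conventions coincide for exponential decay from t = 0", {
  k <- 0.3
  t <- seq(0, 40, by = 0.001)
  tc <- pk_timecourse(t, exp(-k * t), exp(-k * t))
  expect_equal(half_life(tc, "brain", "absolute"), log(2) / k, tolerance = 1e-6)
  expect_equal(half_life(tc, "brain", "from_peak"), log(2) / k, tolerance = 1e-6)
  # horizon too short raises a range error with an extension estimate
  short <- pk_timecourse(t[t <= 1], exp(-k * t[t <= 1]), exp(-k * t[t <= 1]))
  expect_error(half_life(short, "brain"), "horizon too short")
})

test_that("brain half-life with CocH3 is nearly dose-independent at ~1.1 min", {
  p <- ref_params()
  m5 <- summary_metrics(sim_spec(C1_0 = 5, t_end = 60), p, coch3())
  expect_equal(m5$t_b_half, 1.083, tolerance = 0.02)
  hl <- vapply(c(1, 10, 100), function(d)
    summary_metrics(sim_spec(C1_0 = d, t_end = 60), p, coch3())$t_b_half,
    numeric(1))
  expect_true(all(hl > 1.0 & hl < 1.2))
})

test_that("half-life grows linearly with dose under saturating kinetics", {
  p <- ref_params()
  fit <- half_life_vs_dose(p, wt(), dose_grid = c(10, 50, 100, 150, 200))
  expect_gte(fit$r, 0.999)
  # zero-order regime: slope approaches 1/(2 v_max)
  sat <- half_life_vs_dose(p, wt(), dose_grid = c(100, 150, 200))
  expect_equal(sat$slope, 1 / (2 * wt()$v_max), tolerance = 0.01)
  expect_error(half_life_vs_dose(p, wt(), dose_grid = c(5, 5, 5)), "distinct")
  # synthetic half-lives on an exact line are recovered by the same OLS
  d <- c(1, 5, 20, 80)
  lf <- stats::lm(I(2 + 0.5 * d) ~ d)
  expect_equal(unname(coef(lf)), c(2, 0.5), tolerance = 1e-12)
})

test_that("AUC to infinity is tail-corrected and errors on non-decaying systems", {
  p <- ref_params()
  # grid-independence: halving the first-chunk density moves the result < 0.1%
  a1 <- auc_infinity(sim_spec(C1_0 = 5, t_end = 60), p, wt(), "brain")
  a2 <- auc_infinity(sim_spec(C1_0 = 5, t_end = 60, dt = 0.02), p, wt(), "brain")
  expect_equal(a1, a2, tolerance = 1e-3)
  noenz <- enzyme_kinetics("none", k_cat = 1, K_M = 1, E_conc = 0)
  expect_error(auc_infinity(sim_spec(C1_0 = 1, t_end = 10), p, noenz, "brain"),
               "diverge")
  # linear regime: AUC2/AUC1 equals K_pb/K_bp
  s <- sim_spec(C1_0 = 0.01, t_end = 60)
  r <- auc_infinity(s, p, wt(), "brain") / auc_infinity(s, p, wt(), "plasma")
  expect_equal(r, p$K_pb / p$K_bp, tolerance = 0.01)
})

test_that("brain exposure is monotone in enzyme activity and in dose", {
  p <- ref_params()
  # increasing v_max (same K_M) never increases peak, AUC or half-life
  activities <- c(0.1435, 5, 199.5)  # k_cat * [E] grid
  ms <- lapply(activities, function(v) {
    enz <- enzyme_kinetics("x", k_cat = v / 0.035, K_M = 3.1, E_conc = 0.035)
    summary_metrics(sim_spec(C1_0 = 10, t_end = 60), p, enz)
  })
  peaks <- vapply(ms, `[[`, numeric(1), "peak_C2")
  aucs <- vapply(ms, `[[`, numeric(1), "AUC2_inf")
  hls <- vapply(ms, `[[`, numeric(1), "t_b_half")
  expect_true(all(diff(peaks) < 0) && all(diff(aucs) < 0) && all(diff(hls) < 0))
  # peak and AUC strictly increase with the initial concentration
  ds <- c(1, 5, 50)
  md <- lapply(ds, function(d)
    summary_metrics(sim_spec(C1_0 = d, t_end = 60), p, coch3()))
  expect_true(all(diff(vapply(md, `[[`, numeric(1), "peak_C2")) > 0))
  expect_true(all(diff(vapply(md, `[[`, numeric(1), "AUC2_inf")) > 0))
})
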