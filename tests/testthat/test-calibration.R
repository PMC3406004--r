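test_that("noise-free tracer data with a known dose recover all four parameters", {
  fx <- reference_fixture()
  fit <- pk_fit(fx$data, dose_ug = 11, n_starts = 5, seed = 7)
  truth <- ref_truth()
  expect_lt(max(abs(coef(fit) / truth - 1)), 0.01)
  expect_true(fit$converged)
  expect_lt(fit$RMSE1, 1e-8)
  expect_lt(fit$RMSE2, 1e-8)
  expect_true(fit$auc_ratio_plausible)
})

test_that("a start at the truth returns the truth with zero residual", {
  fx <- reference_fixture()
  truth <- ref_truth()
  # geometric midpoint of these bounds IS the truth; single start
  b <- list(lower = truth / 2, upper = truth * 2)
  names(b$lower) <- names(b$upper) <- names(truth)
  fit <- pk_fit(fx$data, dose_ug = 11, bounds = b, n_starts = 1, seed = 1)
  expect_lt(max(abs(coef(fit) / truth - 1)), 1e-6)
  expect_lt(fit$RMSE1, 1e-10)
  expect_lt(fit$RMSE2, 1e-10)
})

test_that("goodness-of-fit statistics behave under exact fit and constant offset", {
  fx <- reference_fixture()
  truth <- ref_params()
  g <- goodness_of_fit(fx$data, truth, C1_0 = fx$truth$C1_0)
  expect_lt(g$RMSE1, 1e-10)
  expect_lt(g$RMSE2, 1e-10)
  expect_equal(g$r1, 1, tolerance = 1e-9)
  expect_equal(g$r2, 1, tolerance = 1e-9)
  # observations shifted by a constant: RMSE = offset, r still 1
  off <- 0.001
  shifted <- observed_dataset(
    plasma = data.frame(t = fx$data$plasma$t, value = fx$data$plasma$value + off),
    brain = data.frame(t = fx$data$brain$t, value = fx$data$brain$value + off),
    units = "abs", enzyme = fx$data$enzyme)
  g2 <- goodness_of_fit(shifted, truth, C1_0 = fx$truth$C1_0)
  expect_equal(g2$RMSE1, off, tolerance = 1e-6)
  expect_equal(g2$r1, 1, tolerance = 1e-9)
  # goodness is invariant to observation ordering (constructor sorts)
  shuf <- sample(nrow(fx$data$plasma))
  reord <- observed_dataset(fx$data$plasma[shuf, ], fx$data$brain,
                            units = "abs", enzyme = fx$data$enzyme)
  g3 <- goodness_of_fit(reord, truth, C1_0 = fx$truth$C1_0)
  expect_identical(g3$RMSE1, g$RMSE1)
})

test_that("injected noise magnitude is reflected in the RMSE at the truth", {
  truth <- ref_params()
  sigma <- 0.02
  rmse <- vapply(1:15, function(i) {
    ds <- generate_pk_dataset(truth, wt(), C1_0 = 1,
                              noise = noise_model("additive-gaussian", sigma),
                              seed = 100 + i)
    goodness_of_fit(ds$data, truth, C1_0 = 1)$RMSE1
  }, numeric(1))
  expect_equal(mean(rmse), sigma, tolerance = 0.1)
})

test_that("identical seeds reproduce identical fits bit-for-bit", {
  ds <- generate_pk_dataset(ref_params(), wt(), C1_0 = 1,
                            noise = noise_model("multiplicative-lognormal", 0.05),
                            seed = 11)
  f1 <- pk_fit(ds$data, C1_0 = 1, n_starts = 3, seed = 5)
  f2 <- pk_fit(ds$data, C1_0 = 1, n_starts = 3, seed = 5)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$ssr, f2$ssr)
})

test_that("relative-units tracer data determine the rates and the volume ratio only", {
  truth <- ref_params()
  c0 <- 11 / (303.35 * truth$V_p)
  ds <- generate_pk_dataset(truth, wt(), C1_0 = c0, units = "rel", seed = 3)
  fit <- pk_fit(ds$data, dose_ug = 11, n_starts = 6, seed = 9)
  co <- coef(fit)
  expect_equal(unname(co["K_pb"]), truth$K_pb, tolerance = 0.01)
  expect_equal(unname(co["K_bp"]), truth$K_bp, tolerance = 0.01)
  expect_equal(unname(co["V_p"] / co["V_b"]), truth$V_p / truth$V_b,
               tolerance = 0.01)
})

test_that("the identifiability probe separates recoverable from degenerate designs", {
  truth <- ref_params()
  # dose-pinned design: unique positive-orthant minimum at the truth
  pr <- identifiability_probe(truth, wt(), dose_ug = 11, n_starts = 12, seed = 2)
  expect_true(pr$unique_positive_minimum)
  expect_gt(pr$n_good, 0)
  expect_lt(max(pr$recovery_error), 0.01)
  # plasma-only schedule with fixed C1_0: V_b cannot be recovered
  pr2 <- identifiability_probe(truth, wt(), C1_0 = 0.00305,
                               schedule = list(plasma = seq(0, 35, by = 1),
                                               brain = numeric(0)),
                               n_starts = 8, seed = 2)
  expect_false(pr2$unique_positive_minimum)
  expect_true("V_b" %in% pr2$nonidentifiable)
})

test_that("dataset constructor enforces minimum design size and positivity", {
  enz <- wt()
  expect_error(observed_dataset(data.frame(t = c(0, 1, 2), value = c(1, 1, 1)),
                                data.frame(t = 0:4, value = rep(1, 5)),
                                enzyme = enz),
               "at least 4")
  expect_error(observed_dataset(data.frame(t = numeric(), value = numeric()),
                                data.frame(t = numeric(), value = numeric()),
                                enzyme = enz),
               "no observations")
  expect_error(observed_dataset(data.frame(t = 0:4, value = c(-1, 1, 1, 1, 1)),
                                data.frame(t = 0:4, value = rep(1, 5)),
                                enzyme = enz),
               "nonnegative")
})
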