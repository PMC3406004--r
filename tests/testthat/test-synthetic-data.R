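test_that("noise-free generation reproduces the model values exactly", {
  truth <- ref_params()
  sched <- seq(0, 35, by = 5)
  ds <- generate_pk_dataset(truth, wt(), C1_0 = 1, schedule = sched, seed = 1)
  tc <- pk_simulate(sim_spec(C1_0 = 1, t_end = 35, dt = 0.005), truth, wt())
  expect_equal(ds$data$plasma$value,
               approx(tc$t, tc$C1, xout = sched)$y, tolerance = 1e-8)
  expect_equal(ds$data$brain$value,
               approx(tc$t, tc$C2, xout = sched)$y, tolerance = 1e-8)
})

test_that("generation is seed-reproducible and seeds do not leak into the session RNG", {
  nm <- noise_model("multiplicative-lognormal", 0.05)
  set.seed(999); before <- runif(1)
  set.seed(999)
  d1 <- generate_pk_dataset(ref_params(), wt(), 1, noise = nm, seed = 42)
  after <- runif(1)
  d2 <- generate_pk_dataset(ref_params(), wt(), 1, noise = nm, seed = 42)
  d3 <- generate_pk_dataset(ref_params(), wt(), 1, noise = nm, seed = 43)
  expect_identical(d1$data$plasma$value, d2$data$plasma$value)
  expect_false(identical(d1$data$plasma$value, d3$data$plasma$value))
  expect_identical(before, after)  # global RNG stream untouched
})

test_that("multiplicative noise has the requested coefficient of variation", {
  # 1000 replicate observations of one time point
  ds <- generate_pk_dataset(ref_params(), wt(), C1_0 = 1,
                            schedule = list(plasma = rep(10, 1000),
                                            brain = rep(10, 4)),
                            noise = noise_model("multiplicative-lognormal", 0.05),
                            seed = 21)
  v <- ds$data$plasma$value
  cv <- sd(v) / mean(v)
  expect_gt(cv, 0.045)
  expect_lt(cv, 0.055)
})

test_that("additive noise never yields negative observations (clipped, flagged)", {
  ds <- generate_pk_dataset(ref_params(), wt(), C1_0 = 0.001,
                            noise = noise_model("additive-gaussian", 0.01),
                            seed = 5)
  expect_true(all(ds$data$plasma$value >= 0))
  expect_gt(ds$clipped, 0)
})

test_that("relative and absolute datasets differ only by the initial plasma scale", {
  truth <- ref_params()
  da <- generate_pk_dataset(truth, wt(), C1_0 = 2, units = "abs", seed = 1)
  dr <- generate_pk_dataset(truth, wt(), C1_0 = 2, units = "rel", seed = 1)
  expect_equal(da$data$plasma$value / 2, dr$data$plasma$value, tolerance = 1e-12)
  expect_equal(da$data$brain$value / 2, dr$data$brain$value, tolerance = 1e-12)
  expect_equal(dr$data$plasma$value[dr$data$plasma$t == 0], 1, tolerance = 1e-9)
})

test_that("the reference fixture matches the tracer narrative", {
  fx <- reference_fixture()
  expect_equal(fx$truth$C1_0, 11 / (303.35 * 11.89), tolerance = 1e-12)
  # brain curve peaks a few minutes after injection
  tpk <- fx$data$brain$t[which.max(fx$data$brain$value)]
  expect_gte(tpk, 4); expect_lte(tpk, 8)
  # brain/plasma exposure ratio at the truth approaches K_pb/K_bp (~1.1)
  p <- ref_params()
  spec <- sim_spec(C1_0 = fx$truth$C1_0, t_end = 35)
  r <- auc_infinity(spec, p, wt(), "brain") / auc_infinity(spec, p, wt(), "plasma")
  expect_equal(r, p$K_pb / p$K_bp, tolerance = 0.01)
  expect_equal(round(r, 1), 1.1)
})

test_that("datasets round-trip through the columnar text format", {
  ds <- generate_pk_dataset(ref_params(), wt(), C1_0 = 1,
                            schedule = list(plasma = seq(0, 35, by = 1),
                                            brain = seq(0.5, 34.5, by = 1)),
                            noise = noise_model("multiplicative-lognormal", 0.05),
                            seed = 8)
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$plasma$value, ds$data$plasma$value)
  expect_equal(back$brain$t, ds$data$brain$t)
  expect_identical(back$units, ds$data$units)
  expect_equal(back$enzyme$v_max, ds$data$enzyme$v_max)
  expect_error(generate_pk_dataset(ref_params(), wt(), 1,
                                   schedule = list(plasma = numeric(),
                                                   brain = numeric())),
               "empty")
})
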