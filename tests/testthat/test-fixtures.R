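test_that("the toy simulator hits the criteria centres at the all-ones point", {
  sim <- make_toy_simulator(toy_spec())
  bm <- sim(scaling_vector())
  centers <- cardiopop:::.crit_center_scale(
    default_criteria()[default_criteria()$stage == "calibration", ])
  for (k in seq_len(nrow(centers)))
    expect_equal(bm[[centers$biomarker[k]]], centers$center[k],
                 label = centers$biomarker[k])
  # determinism without noise
  x <- lhs_sample(5, seed = 44)
  expect_identical(sim(x), sim(x))
})

test_that("toy maps respond in physiologically sensible directions", {
  sim <- make_toy_simulator(toy_spec())
  lo <- sim(scaling_vector(gKr = 0.5))
  hi <- sim(scaling_vector(gKr = 1.5))
  expect_gt(lo$APD90, hi$APD90)  # less IKr, longer APD
})

test_that("the true plausible region is a modest, verifiable volume", {
  frac <- mean(toy_true_plausible(lhs_sample(20000, seed = 99)))
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.30)
})

test_that("observation noise is seeded and optional", {
  x <- lhs_sample(4, seed = 2)
  noisy <- make_toy_simulator(toy_spec(noise_sd = 0.1, seed = 3))
  a <- noisy(x); b <- noisy(x)
  expect_false(identical(a$APD90, b$APD90))  # fresh noise stream per call
  exact <- make_toy_simulator(toy_spec())
  expect_identical(exact(x), exact(x))
})

test_that("make_trace builds uniform multi-cycle traces with markers", {
  tr <- make_trace(trace_fixture(n_cycles = 3, dt = 1))
  expect_equal(nrow(tr), 3000)
  expect_true(all(diff(tr$time_ms) == 1))
  expect_equal(attr(tr, "stim_times"), c(0, 1000, 2000))
  expect_s3_class(tr, "cardio_trace")
})
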