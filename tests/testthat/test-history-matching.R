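test_that("Latin hypercube samples stratify each dimension", {
  pts <- lhs_sample(4, bounds = rbind(c(0, 0), c(2, 2)), seed = 3,
                    names = c("a", "b"))
  for (col in c("a", "b")) {
    strata <- cut(pts[[col]], breaks = c(0, 0.5, 1, 1.5, 2))
    expect_equal(sort(as.integer(table(strata))), rep(1L, 4))
  }
  expect_identical(lhs_sample(50, seed = 7), lhs_sample(50, seed = 7))
  big <- lhs_sample(300, seed = 1)
  expect_equal(dim(big), c(300L, 11L))
  expect_true(all(as.matrix(big) >= 0 & as.matrix(big) <= 2))
})

test_that("implausibility reproduces hand-computed cases", {
  crit <- default_criteria()
  apd90 <- crit[crit$biomarker == "APD90", ]
  expect_equal(implausibility(311, 0, apd90), 0)
  expect_equal(implausibility(360, 0, apd90), 1)
  expect_equal(implausibility(458, 0, apd90), 3)
  expect_error(implausibility(1, 0, crit[crit$biomarker == "RMP", ]),
               "implausibility mode")
})

test_that("filtering honors the strict threshold and minmax cutoffs", {
  crit <- default_criteria()
  # stub emulators returning preset biomarker values with zero variance
  stub <- function(value) structure(list(value = value),
                                    class = "preset_emulator")
  registerS3method("predict", "preset_emulator",
                   function(object, newdata, ...)
                     tibble::tibble(mean = rep(object$value, nrow(newdata)),
                                    var = 0),
                   envir = asNamespace("stats"))
  centers <- cardiopop:::.crit_center_scale(
    crit[crit$stage == "calibration", ])
  ems <- lapply(stats::setNames(centers$center, centers$biomarker), stub)
  pts <- lhs_sample(5, seed = 2)
  expect_equal(nrow(filter_points(pts, ems, crit)), 5)
  # push APD90 just past I = 3: |mean - z| = 3 sd + epsilon
  ems$APD90 <- stub(311 + 3 * 49 + 0.5)
  expect_equal(nrow(filter_points(pts, ems, crit)), 0)
  ems$APD90 <- stub(311 + 3 * 49 - 0.5)
  expect_equal(nrow(filter_points(pts, ems, crit)), 5)
  # minmax violation removes everything
  ems$CTmax <- stub(1.6)
  expect_equal(nrow(filter_points(pts, ems, crit)), 0)
})

test_that("emulator training uses only the configured window of waves", {
  sim <- make_toy_simulator(toy_spec())
  X <- lhs_sample(150, seed = 21)
  bm <- sim(X)
  training <- dplyr::bind_cols(
    tibble::tibble(wave = rep(c(1L, 2L, 3L, 4L, 5L, 6L), each = 25)), X, bm)
  # corrupt waves 1-2; a window-4 emulator at wave 6 must ignore them
  training$APD90[training$wave <= 2] <- 5000
  ems <- train_emulators(training, current_wave = 6, window = 4)
  pr <- predict(ems$APD90, X[1:20, ])
  expect_lt(max(abs(pr$mean - bm$APD90[1:20])), 100)
  expect_error(train_emulators(training[1:5, ], 1), "10 training points")
})

test_that("augmentation fills around accepted points inside the bounds", {
  pts <- lhs_sample(10, seed = 4)
  expect_identical(augment_points(pts, 5), pts)
  aug <- augment_points(pts, 500, seed = 8)
  expect_equal(nrow(aug), 500)
  expect_true(all(as.matrix(aug) >= 0 & as.matrix(aug) <= 2))
  # empirical covariance around a single central point ~ 0.05 I
  center <- tibble::as_tibble(as.data.frame(matrix(1, 1, 11,
    dimnames = list(NULL, cell_parameters()))))
  draws <- augment_points(center, 20000, seed = 12)[-1, ]
  cv <- stats::cov(as.matrix(draws))
  expect_true(all(abs(diag(cv) - 0.05) / 0.05 < 0.1))
  off <- cv[upper.tri(cv)]
  expect_lt(max(abs(off)), 0.005)
})

test_that("the convergence rule follows the 0.1% reduction and wave cap", {
  h <- tibble::tibble(wave = 1:2, candidates_in = c(2e5, 1e5),
                      candidates_surviving = c(1e5, 99999),
                      sim_accept_rate = 1, cloud_size = c(1e5, 99999))
  expect_true(has_converged(h))
  h$candidates_surviving <- c(1e5, 9e4)
  expect_false(has_converged(h))
  h_cap <- tibble::tibble(wave = 60, candidates_in = 1,
                          candidates_surviving = 1, sim_accept_rate = 1,
                          cloud_size = 1)
  expect_true(has_converged(h_cap, wave_cap = 60))
})

test_that("a small toy run is seeded-reproducible and shrinks its cloud", {
  sim <- make_toy_simulator(toy_spec())
  run <- function() {
    st <- hm_init(seed = 5, cloud_size = 2000, augment_floor = 0,
                  wave_cap = 3)
    hm_run(st, sim, n_simulators = 60, max_waves = 3)
  }
  s1 <- run(); s2 <- run()
  expect_identical(s1$history, s2$history)
  expect_identical(as.data.frame(s1$cloud), as.data.frame(s2$cloud))
  # with augmentation disabled each wave's survivors are a subset of the
  # previous cloud
  expect_true(all(diff(s1$history$candidates_surviving) <= 0) ||
                nrow(s1$history) < 2 ||
                all(s1$history$candidates_surviving <=
                      s1$history$candidates_in))
  expect_true(all(s1$history$candidates_surviving <=
                    s1$history$candidates_in))
})

test_that("the final population is calibrated against the min-max ranges", {
  sim <- make_toy_simulator(toy_spec())
  st <- hm_init(seed = 9, cloud_size = 3000, augment_floor = 500,
                wave_cap = 2)
  st <- hm_run(st, sim, n_simulators = 80, max_waves = 2)
  pop <- finalize_initial_population(st, sim, n = 150, seed = 17)
  expect_equal(nrow(pop), 150)
  crit <- default_criteria()
  acc <- pop[pop$status == "accepted", ]
  expect_gt(nrow(acc), 0)
  ok <- cardiopop:::.meets_criteria_minmax(acc, crit)
  expect_true(all(ok))
  expect_equal(attr(pop, "acceptance_rate"),
               mean(pop$status == "accepted"))
  empty <- finalize_initial_population(st, sim, n = 0)
  expect_equal(nrow(empty), 0)
})
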