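test_that("parameter summaries match direct computation", {
  ones <- stub_population(rep(1, 4))
  s <- summarize_parameters(ones)
  expect_true(all(s$mean == 1))
  expect_true(all(s$sd == 0))
  expect_true(all(s$q50 == 1))
  two <- stub_population(c(0.5, 1.5))
  g <- summarize_parameters(two)
  gna <- g[g$parameter == "gNa", ]
  expect_equal(gna$mean, 1)
  expect_equal(gna$min, 0.5)
  expect_equal(gna$max, 1.5)
  expect_error(summarize_parameters(ones[0, ]), "empty")
})

test_that("quantiles agree with a sort-based oracle", {
  x <- withr::with_seed(31, runif(1000, 0, 2))
  pop <- stub_population(x)
  s <- summarize_parameters(pop, "gNa")
  # type-7 oracle: linear interpolation of the sorted sample
  srt <- sort(x)
  oracle <- function(p) {
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    srt[lo] + (h - lo) * (srt[min(lo + 1, length(x))] - srt[lo])
  }
  expect_equal(s$q25, oracle(0.25), tolerance = 1e-12)
  expect_equal(s$q50, oracle(0.50), tolerance = 1e-12)
  expect_equal(s$q75, oracle(0.75), tolerance = 1e-12)
  expect_true(s$min <= s$q25 && s$q25 <= s$q50 && s$q50 <= s$q75 &&
                s$q75 <= s$max)
})

test_that("Pearson correlations match the covariance formula", {
  df <- withr::with_seed(5, tibble::tibble(gNa = runif(50), gCaL = runif(50)))
  df$gK1 <- df$gNa  # duplicated column
  pm <- pearson_matrix(df, c("gNa", "gCaL", "gK1"))
  R <- attr(pm, "r_matrix")
  expect_equal(R["gNa", "gK1"], 1)
  expect_equal(diag(R), c(gNa = 1, gCaL = 1, gK1 = 1))
  oracle <- sum((df$gNa - mean(df$gNa)) * (df$gCaL - mean(df$gCaL))) /
    ((50 - 1) * sd(df$gNa) * sd(df$gCaL))
  expect_equal(R["gNa", "gCaL"], oracle, tolerance = 1e-12)
  big <- withr::with_seed(6, tibble::tibble(gNa = runif(1e4),
                                            gCaL = runif(1e4)))
  expect_lt(abs(pearson_matrix(big, c("gNa", "gCaL"))$r), 0.05)
})

test_that("wasserstein_1d matches oracles and behaves as a metric", {
  expect_equal(wasserstein_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_1d(0, 1), 1)
  a <- withr::with_seed(7, rnorm(400))
  b <- withr::with_seed(8, rnorm(400, 0.5))
  expect_equal(wasserstein_1d(a, b), mean(abs(sort(a) - sort(b))),
               tolerance = 1e-12)
  # metric properties on random triples (equal sizes)
  for (k in 1:5) {
    s <- withr::with_seed(100 + k, list(x = rnorm(60), y = rnorm(60, 1),
                                        z = rexp(60)))
    expect_equal(wasserstein_1d(s$x, s$y), wasserstein_1d(s$y, s$x))
    expect_lte(wasserstein_1d(s$x, s$z),
               wasserstein_1d(s$x, s$y) + wasserstein_1d(s$y, s$z) + 1e-12)
  }
})

test_that("classification recovers separable and null structure", {
  sep <- tibble::tibble(x = c(rnorm(100, 0), rnorm(100, 10)),
                        rejected = rep(c(FALSE, TRUE), each = 100))
  cr <- suppressWarnings(classify_rejection(sep, "rejected", "x"))
  expect_equal(cr$accuracy, 1)
  expect_equal(cr$auc, 1)
  null <- withr::with_seed(9, tibble::tibble(
    x = rnorm(1000), rejected = rep(c(FALSE, TRUE), 500)))
  cr0 <- classify_rejection(null, "rejected", "x")
  expect_lt(abs(cr0$auc - 0.5), 0.05)
  expect_error(classify_rejection(tibble::tibble(x = 1:5, rejected = TRUE),
                                  "rejected", "x"), "both classes")
})

test_that("the Youden threshold recovers a rejection breakpoint near 1.2", {
  df <- withr::with_seed(13, {
    x <- runif(2000, 0, 2)
    tibble::tibble(Vmaxup = x,
                   rejected = runif(2000) < stats::plogis(8 * (x - 1.2)))
  })
  cr <- classify_rejection(df, "rejected", "Vmaxup")
  expect_lt(abs(cr$threshold - 1.2), 0.1)
  expect_gt(cr$odds_ratio$or, 1)
})

test_that("odds ratios follow ad/bc with the zero-cell correction", {
  o <- odds_ratio(rbind(c(20, 5), c(10, 20)))
  expect_equal(o$or, 8)
  expect_false(o$corrected)
  expect_true(o$ci[1] < 8 && 8 < o$ci[2])
  expect_equal(odds_ratio(rbind(c(10, 10), c(10, 10)))$or, 1)
  oz <- odds_ratio(rbind(c(5, 0), c(3, 7)))
  expect_true(is.finite(oz$or))
  expect_true(oz$corrected)
})

test_that("sensitivity at factor 1 reports exactly zero change", {
  cfg <- quick_config(8)
  tab <- sensitivity_analysis(parameters = "gKr", factors = 1,
                              biomarkers = c("APD90", "dVdtmax"),
                              config = cfg)
  expect_equal(tab$APD90, 0)
  expect_equal(tab$dVdtmax, 0)
})
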