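smooth_training <- function(n = 120, seed = 42) {
  X <- lhs_sample(n, seed = seed)
  y <- with(X, 300 - 60 * (gKr - 1) + 25 * (gCaL - 1) - 10 * (gKs - 1) +
              8 * (gCaL - 1) * (PNaK - 1))
  list(X = as.matrix(X), y = y)
}

test_that("the GP interpolates its training data within 3 posterior SDs", {
  tr <- smooth_training(80)
  g <- gp_fit(tr$X, tr$y)
  pr <- predict(g, tr$X)
  tol <- 3 * sqrt(pr$var + g$nugget * g$sd_y^2) + 1e-6
  expect_true(all(abs(pr$mean - tr$y) <= tol))
  expect_true(all(pr$var >= 0))
})

test_that("GP fitting is reproducible under a fixed seed", {
  tr <- smooth_training(60)
  g1 <- gp_fit(tr$X, tr$y, seed = 5L)
  g2 <- gp_fit(tr$X, tr$y, seed = 5L)
  expect_identical(predict(g1, tr$X[1:10, ]), predict(g2, tr$X[1:10, ]))
})

test_that("predictions match the closed-form GP equations", {
  # independent route: direct matrix algebra with the fitted hyperparameters
  tr <- smooth_training(40)
  g <- gp_fit(tr$X, tr$y)
  Xs <- g$Xs
  Xn <- as.matrix(lhs_sample(7, seed = 9))
  Xns <- Xn / 2
  K <- g$s2 * exp(-0.5 * as.matrix(stats::dist(Xs))^2 / g$ell^2)
  diag(K) <- diag(K) + g$nugget + 1e-10
  ks <- g$s2 * exp(-0.5 * outer(rowSums(Xns^2), rowSums(Xs^2), `+`) /
                     g$ell^2 + (Xns %*% t(Xs)) / g$ell^2)
  ys <- (tr$y - g$mu_y) / g$sd_y
  mu <- as.numeric(ks %*% solve(K, ys)) * g$sd_y + g$mu_y
  vv <- (g$s2 + g$nugget - diag(ks %*% solve(K, t(ks)))) * g$sd_y^2
  pr <- predict(g, Xn)
  expect_equal(pr$mean, mu, tolerance = 1e-8)
  expect_equal(pr$var, pmax(vv, 0), tolerance = 1e-5)
})

test_that("leave-one-out accuracy is high on smooth toy biomarkers", {
  sim <- make_toy_simulator(toy_spec())
  X <- lhs_sample(200, seed = 11)
  bm <- sim(X)
  for (b in c("APD90", "CTmax", "CTD80")) {
    g <- gp_fit(as.matrix(X), bm[[b]])
    expect_gt(g$loo_r2, 0.95, label = paste("LOO R2 for", b))
  }
})

test_that("a GP needs at least 10 training points", {
  tr <- smooth_training(9)
  expect_error(gp_fit(tr$X, tr$y), "10 training points")
})

test_that("tidy and glance expose hyperparameters and diagnostics", {
  tr <- smooth_training(40)
  g <- gp_fit(tr$X, tr$y)
  td <- generics::tidy(g)
  expect_setequal(td$term, c("lengthscale", "signal_variance", "nugget"))
  gl <- generics::glance(g)
  expect_true(all(c("loo_rmse", "loo_r2", "n") %in% names(gl)))
})
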