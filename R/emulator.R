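#' Gaussian-process regression emulator
#'
#' A per-biomarker emulator with a radial-basis-function (squared-exponential)
#' kernel: inputs are scaled to the unit cube via the sampling bounds, outputs
#' are centred and scaled, and the kernel hyperparameters (lengthscale, signal
#' variance, nugget) are fitted by marginal-likelihood optimization with a few
#' seeded restarts.  The predictive mean and variance feed the implausibility
#' measure of history matching.
#'
#' @param X Matrix or data frame of training inputs (n x d).
#' @param y Numeric vector of training outputs.
#' @param bounds 2 x d matrix (rows: lower, upper) used to standardize the
#'   inputs; defaults to \[0, 2\] per dimension.
#' @param n_restarts Number of optimizer restarts.
#' @param seed Seed controlling the restart starting points.
#' @return An object of class `gp_emulator`.
#' @export
gp_fit <- function(X, y, bounds = NULL, n_restarts = 3, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  if (n < 10) abort("at least 10 training points are required")
  if (is.null(bounds)) bounds <- rbind(rep(0, d), rep(2, d))
  Xs <- sweep(sweep(X, 2, bounds[1, ]), 2, bounds[2, ] - bounds[1, ], `/`)
  mu_y <- mean(y); sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  ys <- (y - mu_y) / sd_y

  D2 <- as.matrix(stats::dist(Xs))^2
  # negative log marginal likelihood with analytic gradient in
  # (log ell, log s2, log nug); value and gradient share one factorization
  cache <- new.env(parent = emptyenv())
  nll_full <- function(par) {
    key <- paste(par, collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    ell <- exp(par[1]); s2 <- exp(par[2]); nug <- exp(par[3])
    C <- exp(-0.5 * D2 / ell^2)
    K <- s2 * C
    diag(K) <- diag(K) + nug + 1e-10
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) {
      cache$key <- key
      cache$val <- list(value = 1e10, grad = c(0, 0, 0))
      return(cache$val)
    }
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    val <- as.numeric(0.5 * sum(ys * alpha) + sum(log(diag(ch))) +
                        0.5 * n * log(2 * pi))
    Kinv <- chol2inv(ch)
    A <- Kinv - tcrossprod(alpha)  # dL/dK = A/2 in trace sense
    dK_ell <- (s2 * C) * (D2 / ell^2)
    g_ell <- 0.5 * sum(A * dK_ell)
    g_s2 <- 0.5 * sum(A * (s2 * C))
    g_nug <- 0.5 * nug * sum(diag(A))
    cache$key <- key
    cache$val <- list(value = val, grad = c(g_ell, g_s2, g_nug))
    cache$val
  }
  starts <- withr::with_seed(seed, {
    cbind(log(stats::runif(n_restarts, 0.2, 1.5)),
          log(stats::runif(n_restarts, 0.5, 2)),
          log(stats::runif(n_restarts, 1e-6, 1e-3)))
  })
  starts[1, ] <- log(c(0.5, 1, 1e-4))
  best <- NULL
  for (k in seq_len(n_restarts)) {
    fit <- tryCatch(
      stats::optim(starts[k, ], function(p) nll_full(p)$value,
                   function(p) nll_full(p)$grad, method = "L-BFGS-B",
                   lower = log(c(1e-2, 1e-4, 1e-9)),
                   upper = log(c(10, 1e3, 1)),
                   control = list(maxit = 60)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("GP hyperparameter optimization failed")
  par <- best$par
  ell <- exp(par[1]); s2 <- exp(par[2]); nug <- exp(par[3])
  K <- s2 * exp(-0.5 * D2 / ell^2)
  diag(K) <- diag(K) + nug + 1e-10
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  Kinv <- chol2inv(ch)
  # leave-one-out diagnostics from the precision matrix
  loo_mean <- ys - alpha / diag(Kinv)
  loo_rmse <- sqrt(mean((loo_mean - ys)^2)) * sd_y
  loo_r2 <- 1 - mean((loo_mean - ys)^2) / mean((ys - mean(ys))^2)
  structure(list(Xs = Xs, bounds = bounds, mu_y = mu_y, sd_y = sd_y,
                 ell = ell, s2 = s2, nugget = nug,
                 chol = ch, alpha = alpha, Kinv = Kinv,
                 nll = best$value, loo_rmse = loo_rmse, loo_r2 = loo_r2,
                 n = n, d = d),
            class = "gp_emulator")
}

#' Predict from a GP emulator
#'
#' @param object A `gp_emulator`.
#' @param newdata Matrix or data frame of inputs.
#' @param ... Unused.
#' @return Tibble with columns `mean` and `var` (predictive variance,
#'   including the fitted nugget), on the original output scale.
#' @export
predict.gp_emulator <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  storage.mode(Xn) <- "double"
  b <- object$bounds
  Xn <- sweep(sweep(Xn, 2, b[1, ]), 2, b[2, ] - b[1, ], `/`)
  m <- nrow(Xn)
  chunk <- max(1L, floor(2e7 / object$n))
  means <- numeric(m); vars <- numeric(m)
  for (i0 in seq(1L, m, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, m)
    # cross-kernel via squared distances
    cross <- outer(rowSums(Xn[idx, , drop = FALSE]^2), rowSums(object$Xs^2),
                   `+`) - 2 * Xn[idx, , drop = FALSE] %*% t(object$Xs)
    cross[cross < 0] <- 0
    Ks <- object$s2 * exp(-0.5 * cross / object$ell^2)
    means[idx] <- as.numeric(Ks %*% object$alpha)
    v <- object$s2 + object$nugget - rowSums((Ks %*% object$Kinv) * Ks)
    vars[idx] <- pmax(v, 0)
  }
  tibble::tibble(mean = means * object$sd_y + object$mu_y,
                 var = vars * object$sd_y^2)
}

#' @export
print.gp_emulator <- function(x, ...) {
  cat(sprintf(
    "GP emulator: n = %d, d = %d; lengthscale %.3f, signal var %.3f, nugget %.2e\n",
    x$n, x$d, x$ell, x$s2, x$nugget))
  cat(sprintf("leave-one-out RMSE %.4g (R^2 %.3f)\n", x$loo_rmse, x$loo_r2))
  invisible(x)
}

#' Tidy a GP emulator
#' @param x A `gp_emulator`.
#' @param ... Unused.
#' @return One row per hyperparameter with `term` and `estimate`.
#' @exportS3Method generics::tidy
tidy.gp_emulator <- function(x, ...) {
  tibble::tibble(term = c("lengthscale", "signal_variance", "nugget"),
                 estimate = c(x$ell, x$s2, x$nugget))
}

#' Glance at a GP emulator
#' @param x A `gp_emulator`.
#' @param ... Unused.
#' @return One-row tibble with fit diagnostics.
#' @exportS3Method generics::glance
glance.gp_emulator <- function(x, ...) {
  tibble::tibble(n = x$n, d = x$d, neg_log_lik = x$nll,
                 loo_rmse = x$loo_rmse, loo_r2 = x$loo_r2)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
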