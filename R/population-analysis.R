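#' Parameter summary over a model set
#'
#' Column-wise moments and order statistics of the scaling factors.
#'
#' @param model_set Tibble containing the scaling-factor columns.
#' @param parameters Columns to summarize (default the 11 model parameters
#'   present).
#' @return Tibble with one row per parameter: `parameter`, `mean`, `sd`,
#'   `min`, `q25`, `q50`, `q75`, `max`.
#' @export
summarize_parameters <- function(model_set, parameters = NULL) {
  if (!nrow(model_set)) abort("empty model set")
  if (is.null(parameters))
    parameters <- intersect(.param_names, colnames(model_set))
  rows <- lapply(parameters, function(p) {
    x <- model_set[[p]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    tibble::tibble(parameter = p, mean = mean(x), sd = stats::sd(x),
                   min = min(x), q25 = q[1], q50 = q[2], q75 = q[3],
                   max = max(x))
  })
  dplyr::bind_rows(rows)
}

#' Pairwise Pearson correlations with p-values
#'
#' @param model_set Tibble containing the columns to correlate.
#' @param parameters Columns (default the scaling factors present).
#' @return Tibble `param1`, `param2`, `r`, `p` (upper triangle), with
#'   attributes `"r_matrix"` and `"p_matrix"` (symmetric, unit diagonal).
#' @export
pearson_matrix <- function(model_set, parameters = NULL) {
  if (is.null(parameters))
    parameters <- intersect(.param_names, colnames(model_set))
  if (nrow(model_set) < 3) abort("at least 3 models are required")
  d <- length(parameters)
  R <- diag(1, d); P <- diag(0, d)
  dimnames(R) <- dimnames(P) <- list(parameters, parameters)
  rows <- list()
  for (i in seq_len(d - 1)) for (j in seq(i + 1, d)) {
    ct <- stats::cor.test(model_set[[parameters[i]]],
                          model_set[[parameters[j]]], method = "pearson")
    R[i, j] <- R[j, i] <- unname(ct$estimate)
    P[i, j] <- P[j, i] <- ct$p.value
    rows[[length(rows) + 1L]] <- tibble::tibble(
      param1 = parameters[i], param2 = parameters[j],
      r = unname(ct$estimate), p = ct$p.value)
  }
  structure(dplyr::bind_rows(rows), r_matrix = R, p_matrix = P)
}

#' One-dimensional Wasserstein (earth-mover) distance
#'
#' Exact 1-D earth-mover distance between the empirical distributions of two
#' samples, computed as the area between their empirical CDFs.  For samples
#' of equal size this equals the mean absolute difference of the sorted
#' samples.
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @return Non-negative distance.
#' @export
wasserstein_1d <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) abort("samples must be non-empty")
  z <- sort(c(sample_a, sample_b))
  if (length(z) == 1) return(0)
  dz <- diff(z)
  grid <- z[-length(z)]
  fa <- stats::ecdf(sample_a)(grid)
  fb <- stats::ecdf(sample_b)(grid)
  sum(abs(fa - fb) * dz)
}

#' Logistic accept/reject classifier
#'
#' Fits a logistic regression of the rejection label on the given features,
#' evaluated by seeded stratified k-fold cross-validation; for a single
#' feature, also reports the decision threshold maximizing Youden's index on
#' the pooled cross-validated ROC curve.
#'
#' @param data Tibble with the feature columns and the label.
#' @param label Name of a logical/0-1 column (TRUE/1 = rejected).
#' @param features Feature column names (one for the uniparametric case).
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param or_threshold Optional feature threshold at which a 2x2
#'   accepted-versus-below-threshold table and odds ratio are reported
#'   (uniparametric case only; defaults to the Youden threshold).
#' @return A `classifier_report` list: `accuracy`, `auc`, `sensitivity`,
#'   `specificity`, `threshold` (uniparametric), `odds_ratio` (with CI),
#'   `coefficients`, `folds`.
#' @export
classify_rejection <- function(data, label = "rejected", features,
                               k = 5, seed = 1L, or_threshold = NULL) {
  y <- as.integer(as.logical(data[[label]]))
  if (length(unique(y)) < 2) abort("both classes must be present")
  X <- data[, features, drop = FALSE]
  df <- dplyr::bind_cols(tibble::tibble(.y = y), X)
  folds <- withr::with_seed(seed, {
    f <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  prob <- numeric(length(y))
  fml <- stats::as.formula(paste(".y ~", paste(features, collapse = " + ")))
  for (fold in seq_len(k)) {
    fit <- stats::glm(fml, family = stats::binomial(), data = df[folds != fold, ])
    prob[folds == fold] <- stats::predict(fit, newdata = df[folds == fold, ],
                                          type = "response")
  }
  pred <- as.integer(prob >= 0.5)
  acc <- mean(pred == y)
  sens <- sum(pred == 1 & y == 1) / sum(y == 1)
  spec <- sum(pred == 0 & y == 0) / sum(y == 0)
  roc <- pROC::roc(response = y, predictor = prob, quiet = TRUE,
                   direction = "<", levels = c(0, 1))
  auc <- as.numeric(pROC::auc(roc))
  thr <- NULL; orr <- NULL
  if (length(features) == 1) {
    x <- data[[features]]
    roc_x <- pROC::roc(response = y, predictor = x, quiet = TRUE)
    cth <- pROC::coords(roc_x, "best", best.method = "youden",
                        transpose = FALSE)
    thr <- as.numeric(cth$threshold[1])
    at <- or_threshold %||% thr
    accepted <- y == 0
    below <- x < at
    tab <- matrix(c(sum(accepted & below), sum(accepted & !below),
                    sum(!accepted & below), sum(!accepted & !below)),
                  2, byrow = TRUE)
    orr <- odds_ratio(tab)
    orr$threshold <- at
  }
  full <- stats::glm(fml, family = stats::binomial(), data = df)
  structure(list(features = features, accuracy = acc, auc = auc,
                 sensitivity = sens, specificity = spec, threshold = thr,
                 odds_ratio = orr,
                 coefficients = stats::coef(full), folds = folds,
                 n = length(y), k = k, seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "logistic classifier on %s: accuracy %.3f, AUC %.3f, sens %.3f, spec %.3f\n",
    paste(x$features, collapse = " + "), x$accuracy, x$auc, x$sensitivity,
    x$specificity))
  if (!is.null(x$threshold))
    cat(sprintf("Youden threshold: %.3f\n", x$threshold))
  if (!is.null(x$odds_ratio))
    cat(sprintf("odds ratio (accepted | feature < %.3f): %.2f [%.2f, %.2f]\n",
                x$odds_ratio$threshold, x$odds_ratio$or, x$odds_ratio$ci[1],
                x$odds_ratio$ci[2]))
  invisible(x)
}

#' Tidy a classifier report
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.classifier_report <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' Glance at a classifier report
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.classifier_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, auc = x$auc,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 threshold = x$threshold %||% NA_real_, n = x$n, k = x$k)
}

#' Odds ratio of a 2 x 2 table
#'
#' `OR = ad / bc` with the Haldane-Anscombe 0.5 correction when any cell is
#' zero, and a Woolf log-normal 95% confidence interval.
#'
#' @param table_2x2 2 x 2 matrix `rbind(c(a, b), c(c, d))` of non-negative
#'   counts.
#' @return List with `or`, `ci` (length-2), `corrected` (logical).
#' @export
odds_ratio <- function(table_2x2) {
  stopifnot(all(dim(table_2x2) == c(2, 2)), all(table_2x2 >= 0))
  t2 <- table_2x2
  corrected <- any(t2 == 0)
  if (corrected) t2 <- t2 + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se <- sqrt(sum(1 / t2))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(or = or, ci = ci, corrected = corrected)
}

#' Uniparametric sensitivity analysis
#'
#' Scales one parameter at a time (default 0.5x and 2x), reruns the model to
#' steady state, and reports the percent change of each biomarker relative to
#' the baseline run.
#'
#' @param scaling Baseline scaling vector.
#' @param parameters Parameters to perturb.
#' @param factors Scaling factors applied to each parameter.
#' @param biomarkers Biomarker columns to report.
#' @param config A [sim_config()].
#' @return Tibble `parameter`, `factor`, one column per biomarker
#'   (percent change), plus `flags`.
#' @export
sensitivity_analysis <- function(scaling = scaling_vector(),
                                 parameters = .param_names,
                                 factors = c(0.5, 2),
                                 biomarkers = c("RMP", "Vpeak", "dVdtmax",
                                                "APD90"),
                                 config = sim_config()) {
  base <- extract_biomarkers(simulate_cell(scaling, config = config))
  rows <- list()
  for (p in parameters) for (f in factors) {
    sc <- scaling
    sc[[p]] <- sc[[p]] * f
    bm <- extract_biomarkers(simulate_cell(sc, config = config))
    row <- tibble::tibble(parameter = p, factor = f)
    for (b in biomarkers)
      row[[b]] <- 100 * (bm[[b]] - base[[b]]) / base[[b]]
    row$flags <- bm$flags
    rows[[length(rows) + 1L]] <- row
  }
  structure(dplyr::bind_rows(rows), baseline = base)
}
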