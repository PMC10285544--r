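#' @importFrom dplyr bind_cols slice_sample
NULL

#' Latin hypercube sample of the parameter space
#'
#' Maximin Latin hypercube sampling (one point per stratum per dimension);
#' large requests fall back to a plain (random) Latin hypercube for speed.
#'
#' @param n_points Number of points.
#' @param bounds 2 x d matrix (rows: lower, upper); default \[0, 2\] for the
#'   11 cell-model parameters.
#' @param seed Integer seed; identical seeds give identical point sets.
#' @param names Column names (default the 11 scaling-factor names).
#' @return Tibble of `n_points` rows.
#' @export
lhs_sample <- function(n_points, bounds = NULL, seed = 1L, names = NULL) {
  stopifnot(n_points >= 1)
  if (is.null(bounds)) bounds <- rbind(rep(0, 11), rep(2, 11))
  d <- ncol(bounds)
  if (is.null(names))
    names <- if (d == 11) .param_names else paste0("x", seq_len(d))
  U <- withr::with_seed(seed, {
    if (n_points <= 1000) lhs::maximinLHS(n_points, d)
    else lhs::randomLHS(n_points, d)
  })
  X <- sweep(sweep(U, 2, bounds[2, ] - bounds[1, ], `*`), 2, bounds[1, ], `+`)
  colnames(X) <- names
  tibble::as_tibble(as.data.frame(X))
}

#' Implausibility measure
#'
#' `I(x) = |E[f(x)] - z| / sqrt(Var[f(x)] + Var(e))`, the standardized
#' distance between the emulator's predicted biomarker and the experimental
#' mean, accounting for both the emulator's predictive variance and the
#' experimental variance.
#'
#' @param pred_mean,pred_var Emulator predictive mean and variance (vectors).
#' @param criterion One row of a criteria table in implausibility mode.
#' @return Non-negative implausibility values.
#' @export
implausibility <- function(pred_mean, pred_var, criterion) {
  if (criterion$mode != "implausibility")
    abort("criterion must be in implausibility mode")
  denom <- pred_var + criterion$sd^2
  if (any(denom <= 0)) abort("degenerate criterion: zero total variance")
  abs(pred_mean - criterion$mean) / sqrt(denom)
}

#' Filter candidate points by emulated implausibility
#'
#' A point survives iff its maximal implausibility over all
#' implausibility-mode criteria is at most `threshold` (strict rejection
#' above it) and every minmax-mode criterion's predicted mean lies inside
#' its range.
#'
#' @param points Tibble of candidate points.
#' @param emulators Named list of `gp_emulator`s (one per criterion
#'   biomarker).
#' @param criteria Criteria table (calibration stage rows are used).
#' @param threshold Implausibility threshold (3, after the 3-sigma rule).
#' @return The surviving subset of `points`, with attribute `"max_I"` holding
#'   each input point's maximal implausibility.
#' @export
filter_points <- function(points, emulators, criteria, threshold = 3) {
  crit <- criteria[criteria$stage == "calibration", ]
  # evaluate implausibility-mode criteria first and drop points as soon as
  # one criterion rules them out, so later emulators see fewer points
  crit <- crit[order(crit$mode != "implausibility"), ]
  keep <- rep(TRUE, nrow(points))
  max_i <- rep(0, nrow(points))
  pmat <- points[, .hm_param_names(points), drop = FALSE]
  for (k in seq_len(nrow(crit))) {
    cr <- crit[k, ]
    em <- emulators[[cr$biomarker]]
    if (is.null(em)) abort(paste("no emulator for", cr$biomarker))
    idx <- which(keep)
    if (!length(idx)) break
    pr <- predict(em, pmat[idx, , drop = FALSE])
    if (cr$mode == "implausibility") {
      I <- implausibility(pr$mean, pr$var, cr)
      max_i[idx] <- pmax(max_i[idx], I)
      keep[idx] <- I <= threshold
    } else {
      keep[idx] <- pr$mean >= cr$min & pr$mean <= cr$max
    }
  }
  out <- points[keep, , drop = FALSE]
  attr(out, "max_I") <- max_i
  out
}

.hm_param_names <- function(points) {
  intersect(c(.param_names, colnames(points)), colnames(points))
}

#' Train per-biomarker emulators on recent waves
#'
#' One independent GP per calibrated biomarker, trained on the accepted
#' simulator results of up to `window` preceding waves (including the current
#' one).
#'
#' @param training Tibble with a `wave` column, the parameter columns and one
#'   column per biomarker.
#' @param current_wave Current wave index.
#' @param criteria Criteria table.
#' @param window Number of most recent waves used.
#' @param bounds Sampling bounds for input standardization.
#' @param seed Seed for hyperparameter restarts.
#' @return Named list of `gp_emulator`s with attribute `"diagnostics"`
#'   (leave-one-out RMSE per biomarker).
#' @export
train_emulators <- function(training, current_wave, criteria = default_criteria(),
                            window = 4, bounds = NULL, seed = 1L) {
  crit <- criteria[criteria$stage == "calibration", ]
  use <- training[training$wave > current_wave - window &
                    training$wave <= current_wave, , drop = FALSE]
  if (nrow(use) < 10) abort("fewer than 10 training points in the window")
  X <- as.matrix(use[, intersect(.param_names, colnames(use)), drop = FALSE])
  ems <- list()
  diags <- numeric()
  for (bm in crit$biomarker) {
    if (!bm %in% colnames(use)) abort(paste("training set lacks", bm))
    ems[[bm]] <- gp_fit(X, use[[bm]], bounds = bounds, seed = seed)
    diags[bm] <- ems[[bm]]$loo_rmse
  }
  attr(ems, "diagnostics") <- diags
  ems
}

#' Augment a point cloud around accepted points
#'
#' Draws from a multivariate normal centred at randomly chosen accepted
#' points with covariance `0.05 * I`; whole draws falling outside the bounds
#' are redrawn.
#'
#' @param accepted_points Tibble of accepted points (non-empty).
#' @param target Desired total number of points; if already reached, the
#'   input is returned unchanged.
#' @param seed Integer seed.
#' @param bounds 2 x d bounds matrix (default \[0, 2\]^d).
#' @param var Per-dimension variance of the proposal (0.05).
#' @return Tibble with at least `target` rows (input rows first).
#' @export
augment_points <- function(accepted_points, target, seed = 1L, bounds = NULL,
                           var = 0.05) {
  n0 <- nrow(accepted_points)
  if (n0 < 1) abort("accepted_points must be non-empty")
  if (n0 >= target) return(accepted_points)
  d <- ncol(accepted_points)
  if (is.null(bounds)) bounds <- rbind(rep(0, d), rep(2, d))
  X <- as.matrix(accepted_points)
  need <- target - n0
  sd1 <- sqrt(var)
  new_pts <- withr::with_seed(seed, {
    out <- matrix(NA_real_, need, d)
    filled <- 0L
    while (filled < need) {
      m <- (need - filled) * 2L
      centers <- X[sample.int(n0, m, replace = TRUE), , drop = FALSE]
      draws <- centers + matrix(stats::rnorm(m * d, sd = sd1), m, d)
      ok <- rowSums(sweep(draws, 2, bounds[1, ], `<`) |
                      sweep(draws, 2, bounds[2, ], `>`)) == 0
      draws <- draws[ok, , drop = FALSE]
      take <- min(nrow(draws), need - filled)
      if (take > 0) {
        out[filled + seq_len(take), ] <- draws[seq_len(take), , drop = FALSE]
        filled <- filled + take
      }
    }
    out
  })
  colnames(new_pts) <- colnames(X)
  dplyr::bind_rows(accepted_points, tibble::as_tibble(as.data.frame(new_pts)))
}

# does a row of simulated biomarkers meet all calibration criteria?
.meets_criteria <- function(bm, criteria, threshold = 3) {
  crit <- criteria[criteria$stage == "calibration", ]
  ok <- rep(TRUE, nrow(bm))
  for (k in seq_len(nrow(crit))) {
    v <- bm[[crit$biomarker[k]]]
    if (is.null(v)) abort(paste("biomarkers lack", crit$biomarker[k]))
    ok_k <- if (crit$mode[k] == "implausibility") {
      abs(v - crit$mean[k]) / crit$sd[k] <= threshold
    } else {
      v >= crit$min[k] & v <= crit$max[k]
    }
    ok_k[is.na(ok_k)] <- FALSE
    ok <- ok & ok_k
  }
  ok
}

#' Initialize a history-matching run
#'
#' @param seed Master seed; every random draw in the run derives from it.
#' @param cloud_size Size of the wave-1 candidate cloud.
#' @param augment_floor Minimum candidate-cloud size; smaller surviving sets
#'   are augmented back to this size.
#' @param threshold Implausibility threshold.
#' @param window Emulator training window (waves).
#' @param wave_cap Maximum number of waves.
#' @param bounds 2 x 11 sampling bounds.
#' @return A `wave_state` list.
#' @export
hm_init <- function(seed = 1L, cloud_size = 1e6, augment_floor = 1e5,
                    threshold = 3, window = 4, wave_cap = 60,
                    bounds = NULL) {
  if (is.null(bounds)) bounds <- rbind(rep(0, 11), rep(2, 11))
  structure(list(wave = 0L, seed = as.integer(seed),
                 cloud = NULL, training = NULL, emulators = NULL,
                 cloud_size = cloud_size, augment_floor = augment_floor,
                 threshold = threshold, window = window, wave_cap = wave_cap,
                 bounds = bounds,
                 history = tibble::tibble(wave = integer(),
                                          candidates_in = integer(),
                                          candidates_surviving = integer(),
                                          sim_accept_rate = double(),
                                          cloud_size = integer())),
            class = "wave_state")
}

#' Run one history-matching wave
#'
#' Samples simulator points (Latin hypercube on wave 1, uniform draws from
#' the NROY cloud afterwards), runs the simulator, drops abnormal runs,
#' retrains the emulators on up to `window` recent waves, evaluates them on
#' the candidate cloud (a fresh Latin hypercube cloud on wave 1, the
#' surviving cloud afterwards), filters by implausibility, and augments the
#' cloud if it falls below the floor.
#'
#' @param state A `wave_state` from [hm_init()] or a previous wave.
#' @param simulator Function mapping a data frame of points to a tibble of
#'   biomarkers with attribute `"abnormal"` (see [make_toy_simulator()] and
#'   [cell_simulator()]).
#' @param criteria Criteria table.
#' @param n_simulators Simulator runs per wave.
#' @return The updated `wave_state`; an empty NROY set terminates with
#'   status `"empty NROY"` in the state.
#' @export
run_wave <- function(state, simulator, criteria = default_criteria(),
                     n_simulators = 300) {
  stopifnot(inherits(state, "wave_state"))
  wave <- state$wave + 1L
  seed_w <- state$seed + 1000L * wave
  pnames <- colnames(state$bounds) %||% .param_names
  # --- sample simulator points ---
  if (wave == 1L) {
    sim_pts <- lhs_sample(n_simulators, state$bounds, seed = seed_w,
                          names = pnames)
  } else {
    sim_pts <- withr::with_seed(seed_w, {
      state$cloud[sample.int(nrow(state$cloud),
                             min(n_simulators, nrow(state$cloud))), ,
                  drop = FALSE]
    })
  }
  # --- run simulators ---
  bm <- simulator(sim_pts)
  abnormal <- attr(bm, "abnormal") %||% rep(FALSE, nrow(bm))
  valid <- !abnormal & stats::complete.cases(bm)
  accept <- .meets_criteria(bm, criteria, state$threshold) & valid
  train_new <- dplyr::bind_cols(tibble::tibble(wave = wave),
                                sim_pts[valid, , drop = FALSE],
                                bm[valid, , drop = FALSE])
  state$training <- dplyr::bind_rows(state$training, train_new)
  # --- retrain emulators ---
  state$emulators <- train_emulators(state$training, wave, criteria,
                                     window = state$window,
                                     bounds = state$bounds,
                                     seed = state$seed)
  # --- candidate cloud ---
  cloud <- if (wave == 1L) {
    lhs_sample(state$cloud_size, state$bounds, seed = seed_w + 1L,
               names = pnames)
  } else {
    state$cloud
  }
  surv <- filter_points(cloud, state$emulators, criteria, state$threshold)
  n_in <- nrow(cloud); n_surv <- nrow(surv)
  if (n_surv == 0) {
    state$status <- "empty NROY"
    state$wave <- wave
    return(state)
  }
  if (n_surv < state$augment_floor)
    surv <- augment_points(surv, state$augment_floor, seed = seed_w + 2L,
                           bounds = state$bounds)
  state$cloud <- surv
  state$wave <- wave
  state$status <- "ok"
  state$history <- dplyr::bind_rows(state$history, tibble::tibble(
    wave = wave, candidates_in = n_in, candidates_surviving = n_surv,
    sim_accept_rate = mean(accept), cloud_size = nrow(surv)))
  state
}

#' Convergence rule for a history-matching run
#'
#' @param state A `wave_state` (or its `history` tibble).
#' @param tol Relative reduction of the surviving-cloud size below which the
#'   run has converged (0.1%).
#' @param wave_cap Hard cap on the number of waves (the run converges at the
#'   cap regardless).
#' @return Logical.
#' @export
has_converged <- function(state, tol = 0.001, wave_cap = 60) {
  hist <- if (inherits(state, "wave_state")) state$history else state
  if (nrow(hist) >= 1 && hist$wave[nrow(hist)] >= wave_cap) return(TRUE)
  if (nrow(hist) < 2) return(FALSE)
  s <- utils::tail(hist$candidates_surviving, 2)
  abs(s[2] - s[1]) / max(s[1], 1) < tol
}

#' Drive a history-matching run to convergence
#'
#' @inheritParams run_wave
#' @param state A `wave_state` from [hm_init()].
#' @param max_waves Optional override of the state's wave cap.
#' @param verbose Print per-wave progress.
#' @return The final `wave_state`.
#' @export
hm_run <- function(state, simulator, criteria = default_criteria(),
                   n_simulators = 300, max_waves = NULL, verbose = FALSE) {
  cap <- max_waves %||% state$wave_cap
  repeat {
    state <- run_wave(state, simulator, criteria, n_simulators)
    if (verbose) {
      h <- utils::tail(state$history, 1)
      message(sprintf(
        "wave %d: %d/%d candidates survive, simulator acceptance %.2f",
        h$wave, h$candidates_surviving, h$candidates_in, h$sim_accept_rate))
    }
    if (!identical(state$status, "ok")) break
    if (has_converged(state, wave_cap = cap)) break
  }
  state
}

#' Draw and calibrate the initial population
#'
#' Samples `n` parameter vectors from the converged NROY cloud, runs the
#' simulator for each, and rejects models whose biomarkers fall outside the
#' min-max ranges of the criteria or that exhibit abnormalities.
#'
#' @param state A converged `wave_state` (its cloud is sampled), or a tibble
#'   of NROY points.
#' @param simulator Simulator function (as in [run_wave()]).
#' @param n Number of models to draw.
#' @param criteria Criteria table.
#' @param seed Integer seed.
#' @return A population tibble: `model_id`, the scaling-factor columns, the
#'   biomarker columns, `abnormal` and `status`
#'   (`"accepted"` / `"rejected:biomarker_range"` / `"rejected:abnormality"`),
#'   with attribute `"acceptance_rate"`.
#' @export
finalize_initial_population <- function(state, simulator, n = 1000,
                                        criteria = default_criteria(),
                                        seed = 1L) {
  cloud <- if (inherits(state, "wave_state")) state$cloud else state
  if (n == 0)
    return(structure(tibble::tibble(), acceptance_rate = NA_real_))
  pts <- withr::with_seed(seed, {
    cloud[sample.int(nrow(cloud), n, replace = n > nrow(cloud)), ,
          drop = FALSE]
  })
  bm <- simulator(pts)
  abnormal <- attr(bm, "abnormal") %||% rep(FALSE, nrow(bm))
  in_range <- .meets_criteria_minmax(bm, criteria)
  status <- ifelse(abnormal, "rejected:abnormality",
                   ifelse(in_range, "accepted", "rejected:biomarker_range"))
  pop <- dplyr::bind_cols(tibble::tibble(model_id = seq_len(n)), pts, bm,
                          tibble::tibble(abnormal = abnormal,
                                         status = status))
  structure(pop, acceptance_rate = mean(status == "accepted"))
}

# final-population calibration: min-max ranges only (all criteria rows carry
# printed min/max)
.meets_criteria_minmax <- function(bm, criteria) {
  crit <- criteria[criteria$stage == "calibration", ]
  ok <- rep(TRUE, nrow(bm))
  for (k in seq_len(nrow(crit))) {
    v <- bm[[crit$biomarker[k]]]
    ok_k <- v >= crit$min[k] & v <= crit$max[k]
    ok_k[is.na(ok_k)] <- FALSE
    ok <- ok & ok_k
  }
  ok
}

#' Cell-model simulator for history matching
#'
#' Wraps the electro-mechanical cell model into the simulator interface used
#' by [run_wave()]: each point is run to steady state at the reference
#' isometric protocol, biomarkers are extracted from the last cycle and the
#' last two cycles are screened for excitation abnormalities.
#'
#' @param config A [sim_config()].
#' @param protocol A [mech_protocol()] (reference: isometric at 0.93 L_max).
#' @param abn_config An [abnormality_config()].
#' @return A simulator function.
#' @export
cell_simulator <- function(config = sim_config(),
                           protocol = mech_protocol(),
                           abn_config = abnormality_config()) {
  function(points) {
    pts <- if (is.data.frame(points)) points else
      tibble::as_tibble(as.data.frame(matrix(points, nrow = 1,
                                             dimnames = list(NULL, .param_names))))
    res <- lapply(seq_len(nrow(pts)), function(i) {
      sc <- scaling_vector(.values = pts[i, , drop = FALSE])
      tr <- simulate_cell(sc, protocol, config)
      if (attr(tr, "status") != "ok")
        return(list(bm = NULL, abnormal = TRUE))
      bm <- extract_biomarkers(tr)
      ap <- detect_ap_abnormalities(tr, abn_config)
      co <- detect_contraction_abnormalities(tr, "isometric", abn_config)
      list(bm = bm, abnormal = any_abnormal(ap) || any_abnormal(co) ||
             nchar(bm$flags) > 0)
    })
    bms <- lapply(res, function(r) {
      if (is.null(r$bm)) {
        empty <- extract_biomarkers(make_trace(trace_fixture()))
        empty[1, ] <- NA
        empty$flags <- "integration_failed"
        empty
      } else r$bm
    })
    out <- dplyr::bind_rows(bms)
    attr(out, "abnormal") <- vapply(res, function(r) isTRUE(r$abnormal), TRUE)
    out
  }
}
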