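# ---------------------------------------------------------------------------
# Analytic trace fixtures: piecewise-linear / raised-cosine channel builders
# with closed-form biomarker geometry, used to test extraction and detection
# without the ODE model.
# ---------------------------------------------------------------------------

#' Piecewise-linear channel description
#'
#' @param time,value Breakpoint vectors (ms, signal units); the signal holds
#'   the first/last value outside the breakpoints and interpolates linearly
#'   between them.
#' @return A channel description for [trace_fixture()].
#' @export
fx_linear <- function(time, value) {
  stopifnot(length(time) == length(value), !is.unsorted(time))
  structure(list(time = time, value = value), class = "fx_linear")
}

#' Raised-cosine bump channel description
#'
#' One or more raised-cosine bumps on a constant baseline:
#' `baseline + sum_k amp_k/2 * (1 + cos(pi * (t - center_k)/halfwidth_k))`
#' for `|t - center_k| <= halfwidth_k`.
#'
#' @param baseline Constant baseline level.
#' @param center,halfwidth,amplitude Vectors describing each bump (ms, ms,
#'   signal units).
#' @return A channel description for [trace_fixture()].
#' @export
fx_cosine <- function(baseline, center, halfwidth, amplitude) {
  stopifnot(length(center) == length(halfwidth),
            length(center) == length(amplitude), all(halfwidth > 0))
  structure(list(baseline = baseline, center = center,
                 halfwidth = halfwidth, amplitude = amplitude),
            class = "fx_cosine")
}

#' Constant channel description
#' @param value Constant level.
#' @return A channel description for [trace_fixture()].
#' @export
fx_const <- function(value) structure(list(value = value), class = "fx_const")

.fx_eval <- function(ch, tt) {
  if (inherits(ch, "fx_const")) return(rep(ch$value, length(tt)))
  if (inherits(ch, "fx_linear"))
    return(stats::approx(ch$time, ch$value, xout = tt, rule = 2)$y)
  if (inherits(ch, "fx_cosine")) {
    y <- rep(ch$baseline, length(tt))
    for (k in seq_along(ch$center)) {
      u <- (tt - ch$center[k]) / ch$halfwidth[k]
      inside <- abs(u) <= 1
      y[inside] <- y[inside] +
        ch$amplitude[k] / 2 * (1 + cos(pi * u[inside]))
    }
    return(y)
  }
  abort("unknown channel description")
}

#' Analytic trace fixture specification
#'
#' @param V,Cai,force,length Channel descriptions ([fx_linear()],
#'   [fx_cosine()], [fx_const()]) for membrane potential (mV), cytosolic Ca2+
#'   (uM), normalized active force and cell length (fraction of L_max).  Each
#'   may also be a list of per-cycle descriptions (recycled), e.g. to build
#'   alternans fixtures.
#' @param cycle_ms Cycle length in ms.
#' @param dt Sampling step in ms.
#' @param n_cycles Number of cycles.
#' @return A list of class `trace_fixture`.
#' @export
trace_fixture <- function(V = fx_const(-85), Cai = fx_const(0.1),
                          force = fx_const(0), length = fx_const(0.93),
                          cycle_ms = 1000, dt = 0.5, n_cycles = 1) {
  structure(list(V = V, Cai = Cai, force = force, length = length,
                 cycle_ms = cycle_ms, dt = dt, n_cycles = n_cycles),
            class = "trace_fixture")
}

#' Build a trace from an analytic fixture specification
#'
#' @param spec A [trace_fixture()].
#' @return A `cardio_trace` tibble with stimulus markers at the cycle starts;
#'   biomarkers of the generated trace follow from the segment geometry in
#'   closed form.
#' @export
make_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_fixture"))
  per_cycle <- function(ch, cyc) {
    if (is.list(ch) && !inherits(ch, c("fx_const", "fx_linear", "fx_cosine")))
      ch[[(cyc - 1L) %% length(ch) + 1L]] else ch
  }
  tt <- seq(0, spec$cycle_ms - spec$dt, by = spec$dt)
  rows <- lapply(seq_len(spec$n_cycles), function(cyc) {
    tibble::tibble(
      time_ms = tt + (cyc - 1) * spec$cycle_ms,
      V_mV = .fx_eval(per_cycle(spec$V, cyc), tt),
      Cai_uM = .fx_eval(per_cycle(spec$Cai, cyc), tt),
      F_active = .fx_eval(per_cycle(spec$force, cyc), tt),
      L_frac = .fx_eval(per_cycle(spec$length, cyc), tt),
      cycle = cyc
    )
  })
  out <- dplyr::bind_rows(rows)
  out$F_total <- out$F_active + .f_pe(out$L_frac) / .f_ref_peak
  out <- out[, c("time_ms", "V_mV", "Cai_uM", "F_active", "F_total",
                 "L_frac", "cycle")]
  structure(out, status = "ok",
            stim_times = (seq_len(spec$n_cycles) - 1) * spec$cycle_ms,
            cycle_summary = NULL, protocol = NULL, config = NULL,
            class = c("cardio_trace", class(tibble::tibble())))
}

# ---------------------------------------------------------------------------
# Toy simulator: smooth analytic maps from the 11-D scaling space to the
# calibrated biomarkers, with a known ground-truth plausible region.
# ---------------------------------------------------------------------------

# frozen coefficient table: per biomarker a sparse weight vector over the 11
# parameters, one quadratic cross term, all on the standardized scale
# g_n(x) = sum_j w_nj (x_j - 1) + q_n (x_a - 1)(x_b - 1);
# the biomarker value is center_n + scale_n * g_n(x).
.toy_gain <- 2.6  # frozen global coefficient gain; sets the plausible volume

.toy_weights <- function() {
  w <- matrix(0, nrow = 10, ncol = 11,
              dimnames = list(c("RMP", "APD20", "APD50", "APD90", "Tri9040",
                                "CTmin", "CTmax", "CaTTP", "CTD50", "CTD80"),
                              .param_names))
  w["RMP", c("gK1", "PNaK", "gNa")] <- c(-1.1, -0.6, 0.4)
  w["APD20", c("gCaL", "gKr", "gKs")] <- c(1.3, -1.1, -0.7)
  w["APD50", c("gCaL", "gKr", "gK1")] <- c(1.3, -1.3, -0.6)
  w["APD90", c("gKr", "gKs", "gCaL", "gK1")] <- c(-1.6, -0.9, 0.9, -0.6)
  w["Tri9040", c("gKr", "gK1", "ks")] <- c(-1.3, -0.9, 0.6)
  w["CTmin", c("Vmaxup", "KNaCa", "gCaL")] <- c(-1.3, -0.9, 0.7)
  w["CTmax", c("ks", "Vmaxup", "gCaL", "kom")] <- c(1.1, 0.9, 1.1, -0.6)
  w["CaTTP", c("ks", "kim", "gCaL")] <- c(-1.1, 0.6, -0.5)
  w["CTD50", c("Vmaxup", "ks", "KNaCa")] <- c(-1.3, 0.6, -0.6)
  w["CTD80", c("Vmaxup", "KNaCa", "gCaL")] <- c(-1.5, -0.7, 0.6)
  w * .toy_gain
}

.toy_quad <- function() {
  tibble::tibble(
    biomarker = c("APD90", "CTmax", "CTD80"),
    a = c("gCaL", "gCaL", "Vmaxup"),
    b = c("PNaK", "PNaK", "KNaCa"),
    q = c(0.5, 0.5, 0.4) * .toy_gain
  )
}

#' Toy simulator specification
#'
#' @param criteria Calibration criteria table (see [default_criteria()]);
#'   the toy maps are centred so the all-ones point hits every criterion's
#'   centre (experimental mean, or min-max midpoint).
#' @param noise_sd Optional observation noise, as a fraction of each
#'   biomarker's scale (0 gives exact closed-form biomarkers).
#' @param seed Seed for the observation noise stream.
#' @return A list of class `toy_spec`.
#' @export
toy_spec <- function(criteria = default_criteria(), noise_sd = 0, seed = 1L) {
  crit <- criteria[criteria$stage == "calibration", ]
  structure(list(criteria = crit, noise_sd = noise_sd, seed = seed),
            class = "toy_spec")
}

# centre and scale of each criterion used by the toy maps
.crit_center_scale <- function(crit) {
  center <- ifelse(crit$mode == "implausibility", crit$mean,
                   (crit$min + crit$max) / 2)
  scale <- ifelse(crit$mode == "implausibility", crit$sd,
                  (crit$max - crit$min) / 6)
  tibble::tibble(biomarker = crit$biomarker, center = center, scale = scale)
}

#' Build the toy simulator
#'
#' Returns a drop-in replacement for the ODE simulator in history matching:
#' a deterministic callable mapping an 11-parameter scaling vector (or a data
#' frame of them) to the calibrated biomarkers through smooth affine + mild
#' quadratic maps with frozen coefficients.  The true plausible region (all
#' biomarkers within the criteria) is computable by brute-force evaluation.
#'
#' @param spec A [toy_spec()].
#' @return A function: `f(x)` with `x` a scaling vector or data frame of
#'   scaling vectors; returns a tibble (one row per point) of biomarker
#'   values, with attribute `"abnormal"` (all `FALSE`; the toy has no
#'   excitation abnormalities).
#' @export
make_toy_simulator <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  W <- .toy_weights()
  Q <- .toy_quad()
  cs <- .crit_center_scale(spec$criteria)
  W <- W[cs$biomarker, , drop = FALSE]
  noise_sd <- spec$noise_sd
  seed <- spec$seed
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  function(x) {
    X <- if (is.data.frame(x)) as.matrix(x[, .param_names, drop = FALSE])
         else matrix(scaling_vector(.values = x), nrow = 1,
                     dimnames = list(NULL, .param_names))
    D <- X - 1
    G <- D %*% t(W)
    for (k in seq_len(nrow(Q))) {
      G[, Q$biomarker[k]] <- G[, Q$biomarker[k]] +
        Q$q[k] * D[, Q$a[k]] * D[, Q$b[k]]
    }
    vals <- sweep(sweep(G, 2, cs$scale, `*`), 2, cs$center, `+`)
    if (noise_sd > 0) {
      counter$i <- counter$i + 1L
      noise <- withr::with_seed(seed + counter$i, {
        matrix(stats::rnorm(length(vals)), nrow(vals))
      })
      vals <- vals + noise * noise_sd *
        matrix(cs$scale, nrow(vals), ncol(vals), byrow = TRUE)
    }
    out <- tibble::as_tibble(as.data.frame(vals))
    attr(out, "abnormal") <- rep(FALSE, nrow(out))
    out
  }
}

#' Ground-truth plausibility of points under the toy maps
#'
#' Brute-force evaluation of the noise-free toy maps against the criteria:
#' a point is truly plausible iff every implausibility-mode biomarker lies
#' within 3 experimental standard deviations of its mean and every minmax-mode
#' biomarker lies inside its range.
#'
#' @param points Data frame of scaling vectors.
#' @param spec A [toy_spec()].
#' @return Logical vector, one entry per point.
#' @export
toy_true_plausible <- function(points, spec = toy_spec()) {
  spec_exact <- spec
  spec_exact$noise_sd <- 0
  bm <- make_toy_simulator(spec_exact)(points)
  crit <- spec$criteria
  ok <- rep(TRUE, nrow(bm))
  for (k in seq_len(nrow(crit))) {
    v <- bm[[crit$biomarker[k]]]
    ok <- ok & if (crit$mode[k] == "implausibility") {
      abs(v - crit$mean[k]) / crit$sd[k] <= 3
    } else {
      v >= crit$min[k] & v <= crit$max[k]
    }
  }
  ok
}
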