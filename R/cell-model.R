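#' @useDynLib cardiopop
#' @importFrom deSolve lsoda lsodar
#' @import tibble
#' @importFrom rlang abort warn %||%
NULL

# Names and order of the 11 scalable parameters of the cell model.
.param_names <- c("gNa", "gCaL", "gK1", "gKs", "gKr",
                  "Vmaxup", "KNaCa", "PNaK", "ks", "kim", "kom")

#' Scalable parameter names of the cell model
#'
#' The eleven ionic / calcium-handling parameters that are varied when building
#' a population: maximal conductances of the fast Na+ current (gNa), L-type
#' Ca2+ current (gCaL), inward-rectifier (gK1), slow and rapid delayed
#' rectifiers (gKs, gKr); maximal SERCA uptake rate (Vmaxup); maximal
#' Na+/Ca2+-exchanger current (KNaCa); maximal Na+/K+-pump current (PNaK); and
#' the ryanodine-receptor release scale (ks) plus two Markov-gate rate
#' constants (kim, kom).
#'
#' @return Character vector of length 11.
#' @export
cell_parameters <- function() .param_names

#' Build a scaling vector
#'
#' A scaling vector holds one dimensionless multiplicative factor per scalable
#' model parameter; the all-ones vector reproduces the reference model.
#'
#' @param ... Named factors (subset of [cell_parameters()]); unnamed defaults
#'   stay at 1.
#' @param .values Optionally a named numeric vector / list / one-row data frame
#'   giving the factors directly.
#' @return Named numeric vector of length 11 in canonical order.
#' @examples
#' scaling_vector()             # reference model
#' scaling_vector(gKr = 0.5)    # half the rapid delayed-rectifier conductance
#' @export
scaling_vector <- function(..., .values = NULL) {
  out <- stats::setNames(rep(1, length(.param_names)), .param_names)
  vals <- if (!is.null(.values)) .values else list(...)
  if (is.data.frame(vals)) {
    stopifnot(nrow(vals) == 1L)
    vals <- as.list(vals[intersect(names(vals), .param_names)])
  }
  vals <- unlist(vals)
  if (length(vals)) {
    bad <- setdiff(names(vals), .param_names)
    if (length(bad)) abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    out[names(vals)] <- as.numeric(vals)
  }
  if (any(!is.finite(out)) || any(out < 0))
    abort("scaling factors must be finite and non-negative")
  out
}

#' Build a drug block vector
#'
#' Per-channel remaining-conductance fractions applied multiplicatively on top
#' of a scaling vector; 1 for every channel means drug-free.
#'
#' @param INa,ICaL,IKr,IKs Remaining conductance fraction in \[0, 1\].
#' @return Named numeric vector of length 4.
#' @export
drug_block <- function(INa = 1, ICaL = 1, IKr = 1, IKs = 1) {
  out <- c(INa = INa, ICaL = ICaL, IKr = IKr, IKs = IKs)
  if (any(!is.finite(out)) || any(out < 0) || any(out > 1))
    abort("block factors must lie in [0, 1]")
  out
}

#' Mechanical protocol
#'
#' @param mode `"isometric"` (fixed cell length) or `"afterloaded"` (first
#'   isotonic twitch against a constant load after a steady-state isometric
#'   run).
#' @param initial_length Initial cell length as a fraction of L_max (the length
#'   of maximal force development, sarcomere length 2.23 um); the reference
#'   protocol uses 0.93.
#' @param afterload For afterloaded mode only: the load as a fraction of the
#'   model's own peak isometric active force F_max.
#' @return A list of class `mech_protocol`.
#' @export
mech_protocol <- function(mode = c("isometric", "afterloaded"),
                          initial_length = 0.93, afterload = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(initial_length) || initial_length < 0.75 || initial_length > 1)
    abort("initial_length must be a fraction of L_max in [0.75, 1]")
  if (mode == "afterloaded") {
    if (is.null(afterload) || afterload <= 0)
      abort("afterloaded mode requires a positive afterload fraction")
  } else if (!is.null(afterload)) {
    abort("afterload is only meaningful in afterloaded mode")
  }
  structure(list(mode = mode, initial_length = initial_length,
                 afterload = afterload), class = "mech_protocol")
}

#' Simulation configuration
#'
#' @param hz Pacing frequency in Hz.
#' @param n_cycles Number of paced cycles (the reference protocol uses 200 to
#'   reach steady state).
#' @param dt Output sampling step in ms for the returned cycles; must divide
#'   the cycle length.
#' @param stim_amp Stimulus amplitude in pA/pF (negative = depolarizing);
#'   about twice the diastolic threshold of the reference model.
#' @param stim_dur Stimulus duration in ms.
#' @param rtol,atol Solver relative/absolute tolerances.
#' @param ss_tol Relative steady-state tolerance on per-cycle summaries.
#' @param keep_cycles How many final cycles to return at full resolution.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(hz = 1, n_cycles = 200, dt = 0.5, stim_amp = -52,
                       stim_dur = 1, rtol = 1e-6, atol = 1e-8,
                       ss_tol = 0.01, keep_cycles = 2) {
  if (n_cycles < 2) abort("n_cycles must be at least 2")
  cl <- 1000 / hz
  if (abs(cl / dt - round(cl / dt)) > 1e-9)
    abort("sampling step must divide the cycle length")
  if (rtol <= 0 || atol <= 0) abort("solver tolerances must be positive")
  structure(list(hz = hz, n_cycles = n_cycles, dt = dt, stim_amp = stim_amp,
                 stim_dur = stim_dur, rtol = rtol, atol = atol,
                 ss_tol = ss_tol, keep_cycles = keep_cycles),
            class = "sim_config")
}

# ---------------------------------------------------------------------------
# Reference constants (frozen after one-off tuning of the all-ones model to
# the packaged calibration ranges).  Shipped as JSON in inst/extdata.
# ---------------------------------------------------------------------------

.mech_constants <- list(
  beta_se = 0.2,    # series-elastic scale (force units)
  alpha_se = 60,    # series-elastic stiffness (per L_max fraction)
  beta_pe = 0.03,   # parallel-elastic scale
  alpha_pe = 15,    # parallel-elastic stiffness
  L_pe0 = 0.80,     # parallel-elastic slack length (L_max fraction)
  F_xb = 2.0,       # force per unit attached cross-bridge fraction
  v_h = 1e-3,       # force-velocity scale (L_max fraction per ms)
  a_h = 0.25,       # Hill curvature of the force-velocity relation
  eps_f = 1e-3,     # regularization of the force ratio at N ~ 0
  k_p = 0.0025,      # cross-bridge attachment rate (per ms)
  k_m = 0.03,      # cross-bridge detachment rate (per ms)
  c_v = 3,          # velocity sensitivity of detachment
  s_ov = 15,        # steepness of the length (overlap) dependence
  l_half = 0.78,    # half-activation length of the overlap function
  a_on = 150,        # CaTnC on-rate (per mM per ms)
  a_off = 0.21,     # CaTnC off-rate (per ms)
  k_coop = 3.3,       # cooperative slowing of CaTnC decay by Xb and CaTnC
  c_bb = 1,         # weight of CaTnC self-cooperativity
  B_tot = 0.07,     # total troponin-C concentration (mM)
  b_50 = 0.40,      # half-activation CaTnC fraction for Xb recruitment
  n_hill = 3,       # steepness of Xb Ca-activation
  Gto = 0.073,      # transient-outward conductance (nS/pF)
  GKs_base = 0.392, # slow delayed-rectifier conductance (nS/pF)
  ks_base = 0.08,   # RyR release scale (per ms)
  kim_base = 0.01, # RyR Markov I->O / RI->R rate (per ms)
  kom_base = 0.6,  # RyR Markov O->R / I->RI rate (per ms)
  k1_prime = 1.1,  # RyR activation rate constant (per mM^2 per ms)
  k2_prime = 0.04  # RyR inactivation rate constant (per mM per ms)
)

# Peak isometric active force of the reference (all-ones) model at 0.93 L_max
# in raw model units; all reported forces are normalized by this value.
.f_ref_peak <- 0.1247123560  # raw units; 200 cycles, 1 Hz, 0.93 L_max

.state_names <- c("V", "m", "h", "j", "d", "f", "f2", "fcass", "r", "s",
                  "xs", "xr1", "xr2", "Nai", "Ki", "Cai", "Cass", "Casr",
                  "O", "I", "RI", "B", "N", "lc")

# initial resting state at a given cell length
.init_state <- function(L) {
  mc <- .mech_constants
  strain0 <- log1p(mc$eps_f / mc$beta_se) / mc$alpha_se
  stats::setNames(c(
    -86.2, 0.0017, 0.75, 0.75, 3.3e-5, 1, 1, 1, 0, 1,
    0.0087, 0.0021, 0.43, 7.67, 138.3, 7e-5, 7e-5, 1.3,
    0, 0, 0, 0.002, 0.002, L - strain0
  ), .state_names)
}

# assemble the full parameter vector for the compiled model
.cell_parms <- function(scaling, block = NULL, stim_on = 0, mode = 0,
                        L_cell = 0.93, F_clamp = 0, block_ca = 0,
                        config = sim_config()) {
  sc <- scaling_vector(.values = scaling)
  if (!is.null(block)) {
    b <- drug_block()
    b[names(block)] <- block
    sc["gNa"]  <- sc["gNa"]  * b[["INa"]]
    sc["gCaL"] <- sc["gCaL"] * b[["ICaL"]]
    sc["gKr"]  <- sc["gKr"]  * b[["IKr"]]
    sc["gKs"]  <- sc["gKs"]  * b[["IKs"]]
  }
  mc <- .mech_constants
  c(unname(sc),
    config$stim_amp, stim_on, mode, L_cell, F_clamp, block_ca,
    mc$beta_se, mc$alpha_se, mc$beta_pe, mc$alpha_pe, mc$L_pe0,
    mc$F_xb, mc$v_h, mc$a_h, mc$eps_f,
    mc$k_p, mc$k_m, mc$c_v, mc$s_ov, mc$l_half,
    mc$a_on, mc$a_off, mc$k_coop, mc$c_bb, mc$B_tot, mc$b_50, mc$n_hill,
    mc$Gto, mc$GKs_base, mc$ks_base, mc$kim_base, mc$kom_base,
    mc$k1_prime, mc$k2_prime)
}

# parallel-elastic force (R mirror of the compiled formula)
.f_pe <- function(L) {
  mc <- .mech_constants
  s <- L - mc$L_pe0
  ifelse(s > 0, mc$beta_pe * expm1(mc$alpha_pe * s), 0)
}

.yout_names <- c("F_active", "F_total", "L", "v_ce")

# one integration segment through the compiled model; returns the deSolve
# matrix (columns: time, states, global outputs)
.integrate <- function(state, times, parms, config, root = NULL) {
  if (is.null(root)) {
    deSolve::lsoda(y = state, times = times, func = "cell_derivs",
                   parms = parms, dllname = "cardiopop",
                   initfunc = "cell_initmod", nout = 4L,
                   outnames = .yout_names,
                   rtol = config$rtol, atol = config$atol, maxsteps = 20000)
  } else {
    deSolve::lsodar(y = state, times = times, func = "cell_derivs",
                    parms = parms, dllname = "cardiopop",
                    initfunc = "cell_initmod", nout = 4L,
                    outnames = .yout_names, rootfunc = root, nroot = 1L,
                    rtol = config$rtol, atol = config$atol, maxsteps = 20000)
  }
}

# integrate one paced cycle (stimulus segment then free segment) on an output
# grid with step `out_dt`; returns list(mat, state)
.run_cycle <- function(state, parms_stim, parms_free, cl, out_dt, config) {
  sd <- config$stim_dur
  t1 <- seq(0, sd, by = min(out_dt, sd))
  m1 <- .integrate(state, t1, parms_stim, config)
  s1 <- m1[nrow(m1), 1 + seq_along(.state_names)]
  grid2 <- seq(ceiling(sd / out_dt) * out_dt, cl, by = out_dt)
  t2 <- unique(c(sd, grid2))
  m2 <- .integrate(s1, t2, parms_free, config)
  mat <- rbind(m1[-nrow(m1), , drop = FALSE], m2)
  attr(mat, "istate") <- pmin(attr(m1, "istate"), attr(m2, "istate"))
  list(mat = mat, state = m2[nrow(m2), 1 + seq_along(.state_names)])
}

.cycle_summary <- function(mat, cl) {
  tt <- mat[, "time"]; V <- mat[, "V"]
  dv <- diff(V) / diff(tt)
  i_act <- which.max(dv)
  vpk <- max(V); rmp <- V[1]
  v90 <- vpk - 0.9 * (vpk - rmp)
  post <- which(tt > tt[which.max(V)] & V <= v90)
  apd90 <- if (length(post)) tt[min(post)] - tt[i_act] else NA_real_
  c(peak_V = vpk, apd90 = apd90,
    peak_F = max(mat[, "F_active"]), peak_Cai = max(mat[, "Cai"]),
    min_Cai = min(mat[, "Cai"]))
}

.has_failed <- function(mat) {
  if (any(!is.finite(mat))) return(TRUE)
  ist <- attr(mat, "istate")
  !is.null(ist) && is.finite(ist[1]) && ist[1] < 0
}

.trace_failed <- function(reason, protocol, config) {
  structure(tibble::tibble(time_ms = numeric(), V_mV = numeric(),
                           Cai_uM = numeric(), F_active = numeric(),
                           F_total = numeric(), L_frac = numeric(),
                           cycle = integer()),
            status = "integration_failed", detail = reason,
            protocol = protocol, config = config,
            class = c("cardio_trace", class(tibble::tibble())))
}

.assemble_trace <- function(mats, cycles, stim_times, summaries, protocol,
                            config, state, status = "ok", phase = NULL) {
  df <- do.call(rbind, mats)
  out <- tibble::tibble(
    time_ms = df[, "time"],
    V_mV = df[, "V"],
    Cai_uM = df[, "Cai"] * 1000,
    F_active = df[, "F_active"] / .f_ref_peak,
    F_total = df[, "F_total"] / .f_ref_peak,
    L_frac = df[, "L"],
    cycle = rep(cycles, vapply(mats, nrow, 1L))
  )
  if (!is.null(phase)) out$phase <- phase
  structure(out,
            status = status,
            stim_times = stim_times,
            cycle_summary = summaries,
            protocol = protocol, config = config,
            final_state = state,
            class = c("cardio_trace", class(tibble::tibble())))
}

#' Simulate a paced cell
#'
#' Runs the electro-mechanical cell model for `config$n_cycles` paced cycles at
#' the protocol's mechanical boundary condition and returns the last
#' `config$keep_cycles` cycles sampled at `config$dt`, together with per-cycle
#' scalar summaries for all cycles (attribute `"cycle_summary"`).
#' Identical inputs give bit-identical traces.
#'
#' @param scaling Scaling vector (see [scaling_vector()]); anything coercible.
#' @param protocol A [mech_protocol()]; afterloaded protocols should normally
#'   go through [afterloaded_twitch()].
#' @param config A [sim_config()].
#' @param block Optional [drug_block()] applied on top of the scaling.
#' @param block_ca_fluxes Zero all sarcolemmal Ca2+ fluxes (conservation
#'   checks only).
#' @return A `cardio_trace` tibble with columns `time_ms`, `V_mV`, `Cai_uM`,
#'   `F_active`, `F_total` (normalized to the reference model's peak isometric
#'   force at 0.93 L_max), `L_frac` and `cycle`; solver failure yields an empty
#'   trace with attribute `status = "integration_failed"` rather than an error.
#' @export
simulate_cell <- function(scaling = scaling_vector(),
                          protocol = mech_protocol(),
                          config = sim_config(), block = NULL,
                          block_ca_fluxes = FALSE) {
  stopifnot(inherits(protocol, "mech_protocol"), inherits(config, "sim_config"))
  if (protocol$mode == "afterloaded")
    return(afterloaded_twitch(scaling, protocol$afterload, config, block,
                              initial_length = protocol$initial_length))
  cl <- 1000 / config$hz
  L <- protocol$initial_length
  pf <- .cell_parms(scaling, block, stim_on = 0, mode = 0, L_cell = L,
                    block_ca = as.numeric(block_ca_fluxes), config = config)
  ps <- pf; ps[13] <- 1  # stim_on slot (1-based index 13 = STIM_ON)
  state <- .init_state(L)
  nk <- min(config$keep_cycles, config$n_cycles)
  burn_dt <- 1
  summaries <- matrix(NA_real_, config$n_cycles, 5)
  mats <- list(); cycles <- integer()
  for (cyc in seq_len(config$n_cycles)) {
    keep <- cyc > config$n_cycles - nk
    res <- tryCatch(
      .run_cycle(state, ps, pf, cl, if (keep) config$dt else burn_dt, config),
      warning = function(w) w, error = function(e) e)
    if (inherits(res, "condition") || .has_failed(res$mat))
      return(.trace_failed(conditionMessage2(res), protocol, config))
    summaries[cyc, ] <- .cycle_summary(res$mat, cl)
    if (keep) {
      m <- res$mat
      m[, "time"] <- m[, "time"] + (cyc - 1) * cl
      if (length(mats)) m <- m[-1, , drop = FALSE]  # drop duplicated boundary
      mats[[length(mats) + 1L]] <- m
      cycles <- c(cycles, cyc)
    }
    state <- res$state
  }
  colnames(summaries) <- c("peak_V", "apd90", "peak_F", "peak_Cai", "min_Cai")
  summ <- tibble::as_tibble(summaries)
  summ$cycle <- seq_len(config$n_cycles)
  summ$peak_F <- summ$peak_F / .f_ref_peak
  .assemble_trace(mats, cycles, stim_times = (seq_len(config$n_cycles) - 1) * cl,
                  summaries = summ, protocol = protocol, config = config,
                  state = state)
}

conditionMessage2 <- function(x) {
  if (inherits(x, "condition")) conditionMessage(x) else "non-finite state"
}

#' Peak isometric force at steady state
#'
#' Maximum active force over the last cycle of a steady-state isometric run,
#' normalized to the reference model's peak isometric force at 0.93 L_max.
#'
#' @inheritParams simulate_cell
#' @param initial_length Cell length as a fraction of L_max.
#' @return A single normalized force; `NA` with attribute `status` on solver
#'   failure.
#' @export
peak_isometric_force <- function(scaling = scaling_vector(),
                                 initial_length = 0.93,
                                 config = sim_config(), block = NULL) {
  tr <- simulate_cell(scaling, mech_protocol("isometric", initial_length),
                      config, block)
  if (attr(tr, "status") != "ok")
    return(structure(NA_real_, status = attr(tr, "status")))
  max(tr$F_active[tr$cycle == max(tr$cycle)])
}

#' First afterloaded (isotonic) twitch
#'
#' After a steady-state isometric run at `initial_length`, the first twitch of
#' the next cycle is simulated against a constant load: the cell is isometric
#' while active force is below the afterload, shortens at constant total force
#' once the load is reached, and returns to isometric contraction when it
#' re-lengthens to the initial length.
#'
#' @inheritParams simulate_cell
#' @param afterload_fraction Load as a fraction of the model's peak isometric
#'   active force F_max at `initial_length`.
#' @param initial_length Preload length (fraction of L_max), default 0.93.
#' @param isometric_trace Optionally a precomputed steady-state isometric trace
#'   (from [simulate_cell()]) to reuse its final state and F_max.
#' @return A `cardio_trace` tibble of the afterloaded cycle (with a `phase`
#'   column: "isometric", "isotonic", "relaxation"); attribute `F_max` carries
#'   the normalized peak isometric force.  An afterload at or above F_max gives
#'   a fully isometric twitch flagged `"never_lifted"`.
#' @export
afterloaded_twitch <- function(scaling = scaling_vector(),
                               afterload_fraction = 0.5,
                               config = sim_config(), block = NULL,
                               initial_length = 0.93,
                               isometric_trace = NULL) {
  if (afterload_fraction <= 0) abort("afterload fraction must be positive")
  if (is.null(isometric_trace)) {
    isometric_trace <- simulate_cell(scaling,
                                     mech_protocol("isometric", initial_length),
                                     config, block)
  }
  if (attr(isometric_trace, "status") != "ok") return(isometric_trace)
  L <- initial_length
  cl <- 1000 / config$hz
  fmax_norm <- max(isometric_trace$F_active[
    isometric_trace$cycle == max(isometric_trace$cycle)])
  fmax_raw <- fmax_norm * .f_ref_peak
  f_after_raw <- afterload_fraction * fmax_raw
  f_clamp <- f_after_raw + .f_pe(L)
  state <- attr(isometric_trace, "final_state")

  p_iso  <- .cell_parms(scaling, block, stim_on = 0, mode = 0, L_cell = L,
                        F_clamp = f_clamp, config = config)
  p_stim <- p_iso; p_stim[13] <- 1
  p_ton  <- .cell_parms(scaling, block, stim_on = 0, mode = 1, L_cell = L,
                        F_clamp = f_clamp, config = config)
  dt <- config$dt
  grid <- function(a, b) {
    g <- seq(ceiling(a / dt) * dt, b, by = dt)
    unique(c(a, g[g > a + 1e-12], b))
  }
  mats <- list(); phases <- character()
  run <- function(state, times, parms, root = NULL) {
    tryCatch(.integrate(state, times, parms, config, root),
             warning = function(w) w, error = function(e) e)
  }
  # stimulus segment (isometric)
  m <- run(state, grid(0, config$stim_dur), p_stim)
  if (inherits(m, "condition") || .has_failed(m))
    return(.trace_failed(conditionMessage2(m), mech_protocol("afterloaded", L,
                         afterload_fraction), config))
  mats[[1]] <- m[-nrow(m), , drop = FALSE]; phases[1] <- "isometric"
  state <- m[nrow(m), 1 + seq_along(.state_names)]
  t0 <- config$stim_dur
  status <- "ok"
  if (afterload_fraction >= 1) {
    status <- "never_lifted"
    m <- run(state, grid(t0, cl), p_iso)
    if (inherits(m, "condition") || .has_failed(m))
      return(.trace_failed(conditionMessage2(m),
                           mech_protocol("afterloaded", L, afterload_fraction),
                           config))
    mats[[2]] <- m; phases[2] <- "isometric"
  } else {
    # isometric rise with a root on (active force - afterload)
    m <- run(state, grid(t0, cl), p_iso, root = "cell_root_force")
    if (inherits(m, "condition") || .has_failed(m))
      return(.trace_failed(conditionMessage2(m),
                           mech_protocol("afterloaded", L, afterload_fraction),
                           config))
    t_lift <- m[nrow(m), "time"]
    mats[[2]] <- m; phases[2] <- "isometric"
    state <- m[nrow(m), 1 + seq_along(.state_names)]
    if (t_lift >= cl - 1e-9) {
      status <- "never_lifted"
    } else {
      # isotonic shortening: short hysteresis burn, then a root on re-lengthening
      t_burn <- min(t_lift + 1, cl)
      m <- run(state, unique(c(t_lift, t_burn)), p_ton)
      if (inherits(m, "condition") || .has_failed(m))
        return(.trace_failed(conditionMessage2(m),
                             mech_protocol("afterloaded", L, afterload_fraction),
                             config))
      mats[[3]] <- m[-1, , drop = FALSE]; phases[3] <- "isotonic"
      state <- m[nrow(m), 1 + seq_along(.state_names)]
      if (t_burn < cl) {
        m <- run(state, grid(t_burn, cl), p_ton, root = "cell_root_len")
        if (inherits(m, "condition") || .has_failed(m))
          return(.trace_failed(conditionMessage2(m),
                               mech_protocol("afterloaded", L, afterload_fraction),
                               config))
        t_back <- m[nrow(m), "time"]
        mats[[4]] <- m[-1, , drop = FALSE]; phases[4] <- "isotonic"
        state <- m[nrow(m), 1 + seq_along(.state_names)]
        state["lc"] <- min(state[["lc"]], L)  # re-clamp at initial length
        if (t_back < cl - 1e-9) {
          m <- run(state, grid(t_back, cl), p_iso)
          if (inherits(m, "condition") || .has_failed(m))
            return(.trace_failed(conditionMessage2(m),
                                 mech_protocol("afterloaded", L,
                                               afterload_fraction), config))
          mats[[5]] <- m[-1, , drop = FALSE]; phases[5] <- "relaxation"
        }
      }
    }
  }
  # resample phase joins onto the uniform output grid
  final_state <- mats[[length(mats)]][nrow(mats[[length(mats)]]),
                                      1 + seq_along(.state_names)]
  starts <- vapply(mats, function(m) m[1, "time"], 1)
  full <- do.call(rbind, mats)
  keep <- !duplicated(full[, "time"])
  full <- full[keep, , drop = FALSE]
  tgrid <- seq(0, cl, by = dt)
  res <- vapply(colnames(full)[-1], function(cn)
    stats::approx(full[, "time"], full[, cn], xout = tgrid, rule = 2)$y,
    numeric(length(tgrid)))
  phase_grid <- phases[pmax(1, findInterval(tgrid, starts))]
  tr <- .assemble_trace(list(cbind(time = tgrid, res)), 1L,
                        stim_times = 0, summaries = NULL,
                        protocol = mech_protocol("afterloaded", L,
                                                 afterload_fraction),
                        config = config, state = final_state,
                        status = status, phase = phase_grid)
  tr$cycle <- 1L
  attr(tr, "F_max") <- fmax_norm
  tr
}
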