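#' Abnormality detection thresholds
#'
#' The abnormality classes follow the usual reading of excitation and
#' contraction disturbances in paced cardiomyocytes; the numeric thresholds
#' are package defaults (frozen for calibration runs) since the classes are
#' conventionally named but not operationally standardized.
#'
#' @param ead_mV Minimum amplitude of a secondary depolarization during
#'   repolarization to count as an early afterdepolarization (EAD); the
#'   default sits above the few-mV dome rise of a normal spike-notch-dome
#'   AP morphology.
#' @param ead_ms Minimum sustained duration of positive dV/dt for an EAD.
#' @param dad_mV Minimum rise above the running diastolic baseline for a
#'   delayed afterdepolarization (DAD).
#' @param alternans_ms APD90 difference between consecutive cycles flagged as
#'   alternans.
#' @param premature_mV Upstroke threshold crossed outside a stimulus window
#'   for a premature AP.
#' @param prominence_frac Relative prominence of a secondary twitch peak for a
#'   double-peak contraction.
#' @param spontaneous_frac Relative prominence of a secondary Ca2+ peak for
#'   spontaneous SR Ca2+ release.
#' @param failed_contraction_frac Isotonic shortening amplitude below which a
#'   contraction counts as failed (fraction of initial length).
#' @param stim_latency_ms Post-stimulus window within which an upstroke is
#'   attributed to pacing.
#' @return A list of class `abnormality_config`.
#' @export
abnormality_config <- function(ead_mV = 5, ead_ms = 5, dad_mV = 2,
                               alternans_ms = 5, premature_mV = -20,
                               prominence_frac = 0.10,
                               spontaneous_frac = 0.05,
                               failed_contraction_frac = 0.01,
                               stim_latency_ms = 10) {
  structure(as.list(environment()), class = "abnormality_config")
}

.flag_names <- c("EAD", "DAD", "premature_AP", "failed_repolarization",
                 "APD_alternans", "double_peak_contraction",
                 "failed_contraction", "spontaneous_Ca_release")

.new_flags <- function() {
  structure(stats::setNames(as.list(rep(FALSE, length(.flag_names))),
                            .flag_names),
            detail = character(), class = "abnormality_flags")
}

.set_flag <- function(fl, name, detail) {
  fl[[name]] <- TRUE
  attr(fl, "detail") <- c(attr(fl, "detail"),
                          stats::setNames(detail, name))
  fl
}

#' @export
print.abnormality_flags <- function(x, ...) {
  on <- names(which(unlist(x)))
  if (!length(on)) cat("no abnormalities\n")
  else cat("abnormal:", paste(on, collapse = ", "), "\n")
  invisible(x)
}

#' Any abnormality flag set?
#' @param flags An `abnormality_flags` object.
#' @return Logical scalar.
#' @export
any_abnormal <- function(flags) any(unlist(flags))

# local maxima of y with prominence above `prom`; returns indices
.peaks <- function(y, prom) {
  n <- length(y)
  if (n < 3) return(integer())
  d <- diff(y)
  # indices where slope changes + to - (flat tops take the first sample)
  up <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  keep <- vapply(up, function(i) {
    # prominence: drop to the highest of the lowest points separating i from
    # a higher value (or the signal edge)
    left <- y[seq_len(i - 1)]
    right <- y[seq(i + 1, n)]
    higher_l <- which(left >= y[i])
    higher_r <- which(right >= y[i]) + i
    base_l <- min(y[seq(if (length(higher_l)) max(higher_l) else 1, i)])
    base_r <- min(y[seq(i, if (length(higher_r)) min(higher_r) else n)])
    y[i] - max(base_l, base_r) >= prom
  }, TRUE)
  up[keep]
}

# analyse one cycle of V; returns list of flags found + apd90
.analyse_ap_cycle <- function(tt, V, cfg) {
  out <- list(flags = character(), detail = character(), apd90 = NA_real_)
  rmp <- .rmp(tt, V)
  i_pk <- which.max(V)
  amp <- V[i_pk] - min(V)
  if (amp < 30) return(out)  # handled as failed excitation by the caller
  v10 <- V[i_pk] - 0.1 * amp
  v90 <- V[i_pk] - 0.9 * amp
  t10 <- .cross_down(tt, V, v10, i0 = i_pk)
  t90 <- .cross_down(tt, V, v90, i0 = i_pk)
  dv <- diff(V) / diff(tt)
  i_act <- which.max(dv)
  if (is.na(t90)) {
    out$flags <- c(out$flags, "failed_repolarization")
    out$detail <- c(out$detail, failed_repolarization =
                      "V never reached 90% repolarization before next stimulus")
  } else {
    out$apd90 <- t90 - tt[i_act]
  }
  # EAD: sustained positive dV/dt between 10% and 90% repolarization
  if (!is.na(t10)) {
    t_end <- if (is.na(t90)) max(tt) else t90
    win <- which(tt > t10 & tt <= t_end)
    if (length(win) > 2) {
      pos <- dv[win[-length(win)]] > 0
      r <- rle(pos)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        i0 <- win[starts[k]]; i1 <- win[min(ends[k] + 1, length(win))]
        dur <- tt[i1] - tt[i0]
        rise <- max(V[i0:i1]) - V[i0]
        if (dur >= cfg$ead_ms && rise >= cfg$ead_mV) {
          out$flags <- c(out$flags, "EAD")
          out$detail <- c(out$detail, EAD = sprintf(
            "secondary rise of %.1f mV over %.1f ms at t=%.1f ms", rise, dur,
            tt[i0]))
          break
        }
      }
    }
  }
  # DAD: rise above the running diastolic baseline after 90% repolarization
  if (!is.na(t90)) {
    win <- which(tt > t90)
    if (length(win) > 2) {
      base <- cummin(V[win])
      rise <- V[win] - base
      if (any(rise >= cfg$dad_mV)) {
        i <- win[which(rise >= cfg$dad_mV)[1]]
        out$flags <- c(out$flags, "DAD")
        out$detail <- c(out$detail, DAD = sprintf(
          "diastolic rise of %.1f mV at t=%.1f ms", max(rise), tt[i]))
      }
    }
  }
  # premature AP: a second upward crossing of the upstroke threshold within
  # one paced cycle (the first is the paced upstroke); crossings inside the
  # stimulus latency window are attributed to pacing
  cross <- which(V[-1] >= cfg$premature_mV & V[-length(V)] < cfg$premature_mV)
  late <- cross[-1]
  late <- late[tt[late] > cfg$stim_latency_ms]
  if (length(late)) {
    out$flags <- c(out$flags, "premature_AP")
    out$detail <- c(out$detail, premature_AP = sprintf(
      "upstroke crossing %g mV at t=%.1f ms", cfg$premature_mV,
      tt[late[1]]))
  }
  out
}

#' Detect action-potential abnormalities
#'
#' Examines the last two paced cycles of a trace for early and delayed
#' afterdepolarizations, premature APs, failed repolarization, and APD
#' alternans.  Detectors are pure functions of the trace.
#'
#' @param trace A `cardio_trace` holding at least the last 2 paced cycles
#'   (a single-cycle trace skips the alternans check).
#' @param config An [abnormality_config()].
#' @return An `abnormality_flags` object (named logicals plus a `detail`
#'   attribute).  A trace with no AP returns `failed_excitation` status in the
#'   detail rather than an error.
#' @export
detect_ap_abnormalities <- function(trace, config = abnormality_config()) {
  fl <- .new_flags()
  if (!nrow(trace)) return(.set_flag(fl, "failed_repolarization",
                                     "integration failed"))
  cycles <- sort(unique(trace$cycle))
  apd90s <- c()
  for (cy in utils::tail(cycles, 2)) {
    cyc <- trace[trace$cycle == cy, , drop = FALSE]
    tt <- cyc$time_ms - cyc$time_ms[1]
    V <- cyc$V_mV
    if (max(V) - min(V) < 30) {
      attr(fl, "detail") <- c(attr(fl, "detail"),
                              failed_excitation = "no AP in cycle")
      next
    }
    res <- .analyse_ap_cycle(tt, V, config)
    for (k in seq_along(res$flags))
      fl <- .set_flag(fl, res$flags[k], res$detail[k])
    apd90s <- c(apd90s, res$apd90)
  }
  if (length(apd90s) == 2 && all(!is.na(apd90s)) &&
      abs(diff(apd90s)) > config$alternans_ms) {
    fl <- .set_flag(fl, "APD_alternans", sprintf(
      "APD90 %.1f vs %.1f ms on consecutive cycles", apd90s[1], apd90s[2]))
  }
  fl
}

#' Detect contraction abnormalities
#'
#' Flags double-peak contractions (two or more local maxima of the twitch
#' signal with prominence of at least 10% of the twitch amplitude within one
#' cycle), failed contractions (isotonic shortening amplitude below 1% of the
#' initial length, afterloaded mode only) and spontaneous SR Ca2+ release
#' (a secondary Ca2+ peak during decay or diastole).
#'
#' @param trace A `cardio_trace`.
#' @param mode `"isometric"` (twitch signal = active force) or `"afterloaded"`
#'   (twitch signal = shortening).
#' @param config An [abnormality_config()].
#' @return An `abnormality_flags` object.
#' @export
detect_contraction_abnormalities <- function(trace,
                                             mode = c("isometric",
                                                      "afterloaded"),
                                             config = abnormality_config()) {
  mode <- match.arg(mode)
  fl <- .new_flags()
  if (!nrow(trace)) return(.set_flag(fl, "failed_contraction",
                                     "integration failed"))
  cyc <- .final_cycle(trace)
  sig <- if (mode == "isometric") cyc$F_active else (cyc$L_frac[1] - cyc$L_frac)
  amp <- max(sig) - min(sig)
  if (amp > 0) {
    pk <- .peaks(sig, prom = config$prominence_frac * amp)
    if (length(pk) >= 2)
      fl <- .set_flag(fl, "double_peak_contraction", sprintf(
        "%d twitch peaks with prominence >= %g%% of amplitude", length(pk),
        100 * config$prominence_frac))
  }
  if (mode == "afterloaded") {
    sm <- shortening_metrics(trace)
    if (sm$amplitude < config$failed_contraction_frac)
      fl <- .set_flag(fl, "failed_contraction", sprintf(
        "shortening amplitude %.4f below %.2f%%", sm$amplitude,
        100 * config$failed_contraction_frac))
  }
  ca <- cyc$Cai_uM
  ca_amp <- max(ca) - min(ca)
  if (ca_amp > 0.02) {
    pk <- .peaks(ca, prom = config$spontaneous_frac * ca_amp)
    if (length(pk) >= 2)
      fl <- .set_flag(fl, "spontaneous_Ca_release", sprintf(
        "%d Ca2+ peaks with prominence >= %g%% of amplitude", length(pk),
        100 * config$spontaneous_frac))
  }
  fl
}

#' Steady-state check on per-cycle summaries
#'
#' @param summaries Tibble of per-cycle summaries (attribute `cycle_summary`
#'   of a trace) with columns `apd90`, `peak_Cai`, `peak_F`.
#' @param tolerance Maximum relative change between the last two cycles.
#' @return `TRUE` iff APD90, peak Ca2+ and peak force each changed by less
#'   than `tolerance` between the last two cycles.
#' @export
check_steady_state <- function(summaries, tolerance = 0.01) {
  stopifnot(nrow(summaries) >= 2)
  last2 <- utils::tail(summaries, 2)
  rel <- function(x) {
    if (any(is.na(x))) return(Inf)
    abs(diff(x)) / max(abs(x[1]), 1e-12)
  }
  all(c(rel(last2$apd90), rel(last2$peak_Cai), rel(last2$peak_F)) < tolerance)
}
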