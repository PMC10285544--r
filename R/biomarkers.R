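#' @importFrom dplyr filter mutate select arrange bind_rows
NULL

# linear-interpolated first downward crossing of `level` in y(t) after index i0;
# ties broken toward the earlier time
.cross_down <- function(tt, y, level, i0 = 1L) {
  idx <- which(y[-1] <= level & seq_along(y)[-1] > i0)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]  # y[i] > level >= y[i + 1] (first such)
  if (y[i] <= level) return(tt[i])
  tt[i] + (tt[i + 1] - tt[i]) * (y[i] - level) / (y[i] - y[i + 1])
}

# extract the rows of the final complete cycle, time re-based to cycle start
.final_cycle <- function(trace) {
  stopifnot(nrow(trace) > 0)
  cyc <- trace[trace$cycle == max(trace$cycle), , drop = FALSE]
  dt <- diff(cyc$time_ms)
  if (any(abs(dt - dt[1]) > 1e-8)) abort("trace timebase is not uniform")
  cyc$time_ms <- cyc$time_ms - cyc$time_ms[1]
  cyc
}

# onset of a twitch-like signal: last attainment of the pre-peak minimum
.onset_time <- function(tt, y, i_peak, tol_frac = 1e-6) {
  pre <- seq_len(i_peak)
  ymin <- min(y[pre])
  tol <- tol_frac * (y[i_peak] - ymin) + 1e-12
  tt[max(which(y[pre] <= ymin + tol))]
}

#' Action potential duration
#'
#' Interval from activation time (time of maximal upstroke velocity in the
#' final cycle) to the first post-peak time at which the membrane potential
#' has repolarized by `fraction` of the AP amplitude, with linear interpolation
#' between samples.
#'
#' @param trace A `cardio_trace` (see [simulate_cell()]).
#' @param fraction Repolarization fraction in \[0, 1\] (0.9 gives APD90).
#' @return Duration in ms; `NA` with a `failed_repolarization` note if the AP
#'   never repolarizes to the level within the cycle.
#' @export
apd <- function(trace, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  cyc <- .final_cycle(trace)
  tt <- cyc$time_ms; V <- cyc$V_mV
  rmp <- .rmp(tt, V)
  i_pk <- which.max(V)
  dv <- diff(V) / diff(tt)
  i_act <- which.max(dv)
  level <- V[i_pk] - fraction * (V[i_pk] - rmp)
  t_cross <- .cross_down(tt, V, level, i0 = i_pk)
  if (is.na(t_cross)) return(NA_real_)
  t_cross - tt[i_act]
}

# RMP convention: minimum V over the 50 ms preceding the next stimulus
# (i.e. the final 50 ms of the cycle)
.rmp <- function(tt, V) {
  min(V[tt >= max(tt) - 50])
}

#' Shortening metrics of an afterloaded twitch
#'
#' @param trace A `cardio_trace` from [afterloaded_twitch()] (an isometric
#'   trace yields zero amplitude and velocity).
#' @return Named list with `amplitude` (fractional shortening of the initial
#'   length) and `max_velocity` (maximum of -dL/dt over the shortening phase,
#'   in L_max/s; central differences on the sampled trace).
#' @export
shortening_metrics <- function(trace) {
  cyc <- .final_cycle(trace)
  L <- cyc$L_frac; tt <- cyc$time_ms
  L0 <- L[1]
  amp <- (L0 - min(L)) / L0
  if (amp <= 0) return(list(amplitude = 0, max_velocity = 0))
  n <- length(L)
  v <- c(NA, (L[-(1:2)] - L[1:(n - 2)]) / (tt[-(1:2)] - tt[1:(n - 2)]), NA)
  vmax <- max(-v, na.rm = TRUE) * 1000  # per ms -> per s
  list(amplitude = amp, max_velocity = max(vmax, 0))
}

#' Extract the biomarker set from a trace
#'
#' Computes, on the final complete cycle, the action-potential biomarkers
#' (RMP, Vpeak, dV/dt_max, APD20/40/50/90, triangulation Tri9040 =
#' APD90 - APD40), the Ca2+-transient biomarkers (diastolic CTmin and peak
#' CTmax in uM, time-to-peak CaTTP, decay durations CTD50/CTD80), the
#' isometric-force biomarkers (time-to-peak FTTP, time from peak to 90% decay
#' FTTr, twitch duration FTD, diastolic FTd and peak FTpeak normalized force)
#' and, for afterloaded traces, the shortening metrics.  Signals without an
#' event set a flag instead of a number.
#'
#' Conventions: APDxx are measured from activation time (maximal dV/dt); RMP
#' is the minimum V over the 50 ms preceding the next stimulus; CaTTP, CTDxx,
#' FTTP and FTTr are measured from the onset of the respective transient (last
#' attainment of the pre-peak diastolic minimum); CTDxx run to xx% decay from
#' peak toward CTmin; FTD is the interval during which force exceeds the
#' diastolic level by more than 5% of the twitch amplitude.
#'
#' @param trace A `cardio_trace` with at least one complete paced cycle.
#' @return One-row tibble with the biomarker columns and a `flags` column
#'   (comma-separated flag names, empty if none).
#' @export
extract_biomarkers <- function(trace) {
  if (!nrow(trace)) abort("empty trace (integration may have failed)")
  cyc <- .final_cycle(trace)
  tt <- cyc$time_ms
  flags <- character()
  out <- list()

  # --- action potential ---
  V <- cyc$V_mV
  rmp <- .rmp(tt, V)
  i_pk <- which.max(V)
  vpeak <- V[i_pk]
  out$RMP <- rmp
  if (vpeak - min(V) < 30) {
    flags <- c(flags, "no_AP")
    out[c("Vpeak", "dVdtmax", "APD20", "APD40", "APD50", "APD90",
          "Tri9040")] <- NA_real_
  } else {
    dv <- diff(V) / diff(tt)
    i_act <- which.max(dv)
    out$Vpeak <- vpeak
    out$dVdtmax <- max(dv)
    apdxx <- function(fr) {
      lv <- vpeak - fr * (vpeak - rmp)
      tc <- .cross_down(tt, V, lv, i0 = i_pk)
      if (is.na(tc)) NA_real_ else tc - tt[i_act]
    }
    out$APD20 <- apdxx(0.2); out$APD40 <- apdxx(0.4)
    out$APD50 <- apdxx(0.5); out$APD90 <- apdxx(0.9)
    if (is.na(out$APD90)) flags <- c(flags, "failed_repolarization")
    out$Tri9040 <- out$APD90 - out$APD40
  }

  # --- Ca2+ transient ---
  ca <- cyc$Cai_uM
  ctmin <- min(ca); ctmax <- max(ca)
  out$CTmin <- ctmin; out$CTmax <- ctmax
  if (ctmax - ctmin < 0.02) {
    flags <- c(flags, "no_transient")
    out[c("CaTTP", "CTD50", "CTD80")] <- NA_real_
  } else {
    i_cp <- which.max(ca)
    t_on <- .onset_time(tt, ca, i_cp)
    out$CaTTP <- tt[i_cp] - t_on
    ctd <- function(fr) {
      lv <- ctmax - fr * (ctmax - ctmin)
      tc <- .cross_down(tt, ca, lv, i0 = i_cp)
      if (is.na(tc)) NA_real_ else tc - t_on
    }
    out$CTD50 <- ctd(0.5); out$CTD80 <- ctd(0.8)
  }

  # --- isometric force twitch ---
  fa <- cyc$F_active
  i_fp <- which.max(fa)
  fd <- min(fa[seq_len(i_fp)])
  famp <- fa[i_fp] - fd
  out$FTd <- fd; out$FTpeak <- fa[i_fp]
  if (famp < 0.01) {
    flags <- c(flags, "no_twitch")
    out[c("FTTP", "FTTr", "FTD")] <- NA_real_
  } else {
    t_on <- .onset_time(tt, fa, i_fp)
    out$FTTP <- tt[i_fp] - t_on
    lv90 <- fa[i_fp] - 0.9 * famp
    t90 <- .cross_down(tt, fa, lv90, i0 = i_fp)
    out$FTTr <- if (is.na(t90)) NA_real_ else t90 - tt[i_fp]
    lv5 <- fd + 0.05 * famp
    t_up <- .cross_up(tt, fa, lv5, before = i_fp)
    t_dn <- .cross_down(tt, fa, lv5, i0 = i_fp)
    out$FTD <- if (is.na(t_up) || is.na(t_dn)) NA_real_ else t_dn - t_up
  }

  # --- shortening (afterloaded traces) ---
  sm <- shortening_metrics(trace)
  out$shortening_amplitude <- sm$amplitude
  out$max_shortening_velocity <- sm$max_velocity

  out$flags <- paste(flags, collapse = ",")
  res <- tibble::as_tibble(out[!vapply(out, is.null, TRUE)])
  attr(res, "flags") <- flags
  res
}

# linear-interpolated last upward crossing of `level` before index `before`
.cross_up <- function(tt, y, level, before) {
  idx <- which(y[-1] >= level & seq_along(y)[-1] <= before)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]  # y[i] < level <= y[i+1]
  if (y[i] >= level) return(tt[i])
  tt[i] + (tt[i + 1] - tt[i]) * (level - y[i]) / (y[i + 1] - y[i])
}
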