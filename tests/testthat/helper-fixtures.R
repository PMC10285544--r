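# Shared analytic fixtures and stub backends used across the suite.

# linear-ramp AP: rest -85 mV, instantaneous step to +35 mV at 100 ms,
# linear decline back to -85 mV at 400 ms, flat afterwards.
ramp_ap_fixture <- function(dt = 0.5) {
  trace_fixture(
    V = fx_linear(c(0, 100, 100 + 1e-9, 400), c(-85, -85, 35, -85)),
    Cai = fx_cosine(0.1, 300, 250, 1),
    dt = dt)
}

# linear force ramp: 0 before 50 ms, rise to 1 at 350 ms, fall to 0 at 650 ms
ramp_force_fixture <- function(dt = 0.5) {
  trace_fixture(force = fx_linear(c(0, 50, 350, 650), c(0, 0, 1, 0)),
                dt = dt)
}

# physiologically-shaped clean cycle from raised cosines (no abnormality)
clean_cycle_fixture <- function(ap_amp = 120, ap_halfwidth = 180,
                                ca_amp = 1, f_amp = 1, n_cycles = 2,
                                dt = 1) {
  trace_fixture(
    V = fx_cosine(-85, 10 + ap_halfwidth, ap_halfwidth, ap_amp),
    Cai = fx_cosine(0.08, 160, 150, ca_amp),
    force = fx_cosine(0.02, 300, 250, f_amp),
    n_cycles = n_cycles, dt = dt)
}

# a fast reduced-cycle configuration for unit tests of the ODE model
quick_config <- function(n_cycles = 5, ...) {
  sim_config(n_cycles = n_cycles, ...)
}

# stub mechanical backend: behaviour keyed on the gNa scaling factor
# (used to rig one model per failure mode)
#   1.00 -> reference-like, passes everything
#   0.11 -> FTTP too long (force-biomarker stage)
#   0.12 -> EAD at 0.80 L_max (preload stage)
#   0.13 -> non-monotone L-F (LF stage)
#   0.14 -> EAD at afterload 0.25 (afterload stage)
#   0.15 -> non-monotone F-V (afterload stage)
stub_backend <- function() {
  ok_flags <- cardiopop:::.new_flags()
  bad_ead <- cardiopop:::.set_flag(cardiopop:::.new_flags(), "EAD", "rigged")
  bm_ok <- tibble::tibble(FTTP = 275, FTTr = 301, FTD = 501)
  bm_slow <- tibble::tibble(FTTP = 400, FTTr = 301, FTD = 501)
  function(scaling, what = c("isometric", "afterloaded"), arg) {
    what <- match.arg(what)
    key <- round(scaling[["gNa"]], 2)
    if (what == "isometric") {
      pf <- switch(as.character(key),
        "0.13" = c("0.8" = 0.30, "0.85" = 0.30, "0.9" = 0.45,
                   "0.93" = 0.5)[[as.character(arg)]],
        0.5 * arg / 0.93)
      list(status = "ok",
           biomarkers = if (key == 0.11) bm_slow else bm_ok,
           ap_flags = if (key == 0.12 && arg == 0.80) bad_ead else ok_flags,
           contr_flags = ok_flags,
           peak_force = pf)
    } else {
      vel <- switch(as.character(key),
                    "0.15" = c("0.25" = 2.0, "0.5" = 2.2, "0.75" = 1.0),
                    c("0.25" = 2.0, "0.5" = 1.2, "0.75" = 0.6))
      list(status = "ok",
           ap_flags = if (key == 0.14 && arg == 0.25) bad_ead else ok_flags,
           contr_flags = ok_flags,
           shortening = list(amplitude = 0.05,
                             max_velocity = vel[[as.character(arg)]]),
           peak_force = 0.5)
    }
  }
}

# minimal population tibble from a named list of gNa keys
stub_population <- function(keys) {
  n <- length(keys)
  pop <- tibble::as_tibble(as.data.frame(matrix(1, n, 11,
    dimnames = list(NULL, cell_parameters()))))
  pop$gNa <- keys
  dplyr::bind_cols(tibble::tibble(model_id = seq_len(n)), pop,
                   tibble::tibble(status = "accepted"))
}
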