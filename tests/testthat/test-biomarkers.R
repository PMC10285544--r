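test_that("linear-ramp AP yields closed-form durations", {
  dt <- 0.5
  tr <- make_trace(ramp_ap_fixture(dt))
  bm <- extract_biomarkers(tr)
  # amplitude 120 mV over a 300 ms linear decline: APDxx = xx% of the ramp
  expect_equal(bm$RMP, -85)
  expect_equal(bm$Vpeak, 35, tolerance = 0.02)  # peak between samples
  expect_lt(abs(bm$APD90 - 270), dt)
  expect_lt(abs(bm$APD50 - 150), dt)
  expect_lt(abs(bm$APD40 - 120), dt)
  expect_lt(abs(bm$Tri9040 - 150), 2 * dt)
  expect_lt(abs(apd(tr, 0.9) - 270), dt)
  expect_lte(abs(apd(tr, 0)), dt)  # peak is the reference
})

test_that("apd is stable under halving the sampling step", {
  a1 <- apd(make_trace(ramp_ap_fixture(0.5)), 0.9)
  a2 <- apd(make_trace(ramp_ap_fixture(0.25)), 0.9)
  expect_lt(abs(a1 - a2), 0.5)
})

test_that("constant membrane potential flags no_AP", {
  tr <- make_trace(trace_fixture(V = fx_const(-85)))
  bm <- extract_biomarkers(tr)
  expect_match(bm$flags, "no_AP")
  expect_true(is.na(bm$APD90))
  expect_true(is.na(bm$Vpeak))
})

test_that("force-ramp twitch yields closed-form FTTP and FTTr", {
  bm <- extract_biomarkers(make_trace(ramp_force_fixture(0.5)))
  expect_lt(abs(bm$FTTP - 300), 0.5)
  expect_lt(abs(bm$FTTr - 270), 0.5)
})

test_that("shortening metrics follow trace geometry", {
  # constant length
  sm0 <- shortening_metrics(make_trace(trace_fixture()))
  expect_equal(sm0$amplitude, 0)
  expect_equal(sm0$max_velocity, 0)
  # 0.93 flat, linear drop to 0.837 over 100 ms, linear recovery
  tr <- make_trace(trace_fixture(
    length = fx_linear(c(0, 200, 300, 500), c(0.93, 0.93, 0.837, 0.93))))
  sm <- shortening_metrics(tr)
  expect_equal(sm$amplitude, 0.1, tolerance = 1e-6)
  expect_equal(sm$max_velocity, 0.93, tolerance = 0.01)
  # 0.5% drop fixture
  tr2 <- make_trace(trace_fixture(
    length = fx_linear(c(0, 200, 300, 500),
                       c(0.93, 0.93, 0.93 * 0.995, 0.93))))
  expect_equal(shortening_metrics(tr2)$amplitude, 0.005, tolerance = 1e-6)
})

test_that("biomarker ordering invariants hold on random clean fixtures", {
  for (k in 1:25) {
    par <- withr::with_seed(1000 + k, {
      list(amp = runif(1, 80, 130), hw = runif(1, 120, 220),
           ca = runif(1, 0.5, 1.4), f = runif(1, 0.3, 1.2))
    })
    bm <- extract_biomarkers(make_trace(clean_cycle_fixture(
      ap_amp = par$amp, ap_halfwidth = par$hw, ca_amp = par$ca,
      f_amp = par$f, dt = 0.5, n_cycles = 1)))
    expect_true(bm$APD20 <= bm$APD40)
    expect_true(bm$APD40 <= bm$APD50)
    expect_true(bm$APD50 <= bm$APD90)
    expect_gte(bm$Tri9040, 0)
    expect_lt(bm$CTmin, bm$CTmax)
    expect_lt(bm$FTd, bm$FTpeak)
    expect_true(all(c(bm$APD90, bm$CaTTP, bm$CTD50, bm$CTD80, bm$FTTP,
                      bm$FTD) > 0))
  }
})

test_that("duration biomarkers are resolution-robust", {
  b1 <- extract_biomarkers(make_trace(clean_cycle_fixture(dt = 1,
                                                          n_cycles = 1)))
  b2 <- extract_biomarkers(make_trace(clean_cycle_fixture(dt = 0.5,
                                                          n_cycles = 1)))
  for (nm in c("APD20", "APD50", "APD90", "CaTTP", "CTD50", "CTD80",
               "FTTP", "FTTr", "FTD"))
    expect_lt(abs(b1[[nm]] - b2[[nm]]), 1, label = nm)
})
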