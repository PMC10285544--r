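# EAD fixture: clean AP with a raised-cosine bump injected during
# repolarization
ead_fixture <- function(bump_mV = 15, bump_ms = 20, n_cycles = 2) {
  base <- clean_cycle_fixture(n_cycles = n_cycles, dt = 0.5)
  base$V <- fx_cosine(-85, c(190, 280), c(180, bump_ms / 2),
                      c(120, bump_mV))
  base
}

test_that("clean fixture cycles raise no abnormality flags", {
  tr <- make_trace(clean_cycle_fixture(dt = 0.5))
  expect_false(any_abnormal(detect_ap_abnormalities(tr)))
  expect_false(any_abnormal(detect_contraction_abnormalities(tr,
                                                             "isometric")))
})

test_that("an injected repolarization bump is detected as an EAD", {
  fl <- detect_ap_abnormalities(make_trace(ead_fixture(15, 20)))
  expect_true(fl$EAD)
  # monotone severity: enlarging the bump never clears the flag
  for (amp in c(20, 30, 45)) {
    expect_true(detect_ap_abnormalities(make_trace(ead_fixture(amp, 20)))$EAD)
  }
})

test_that("sub-threshold bumps do not trigger the EAD detector", {
  fl <- detect_ap_abnormalities(make_trace(ead_fixture(0.5, 20)))
  expect_false(fl$EAD)
})

test_that("diastolic rises are detected as DADs", {
  base <- clean_cycle_fixture(dt = 0.5)
  base$V <- fx_cosine(-85, c(190, 700), c(180, 40), c(120, 10))
  fl <- detect_ap_abnormalities(make_trace(base))
  expect_true(fl$DAD)
  expect_false(fl$premature_AP)
})

test_that("a full diastolic upstroke is a premature AP", {
  base <- clean_cycle_fixture(dt = 0.5)
  base$V <- fx_cosine(-85, c(190, 700), c(180, 120), c(120, 115))
  fl <- detect_ap_abnormalities(make_trace(base))
  expect_true(fl$premature_AP)
})

test_that("failed repolarization is flagged when V never reaches 90%", {
  base <- trace_fixture(V = fx_linear(c(0, 10, 11, 1000),
                                      c(-85, -85, 35, 10)), dt = 0.5)
  fl <- detect_ap_abnormalities(make_trace(base))
  expect_true(fl$failed_repolarization)
})

test_that("APD90 alternans across consecutive cycles is flagged", {
  two_apd <- function(apd_a, apd_b) {
    # linear-decline APs whose APD90 is 90% of the declining ramp
    mkv <- function(apd) fx_linear(c(0, 100, 100 + 1e-9, 100 + apd / 0.9),
                                   c(-85, -85, 35, -85))
    make_trace(trace_fixture(V = list(mkv(apd_a), mkv(apd_b)),
                             n_cycles = 2, dt = 0.5))
  }
  expect_true(detect_ap_abnormalities(two_apd(300, 330))$APD_alternans)
  expect_false(detect_ap_abnormalities(two_apd(300, 303))$APD_alternans)
})

test_that("double-peak contractions are detected by prominence", {
  single <- make_trace(trace_fixture(force = fx_cosine(0, 300, 250, 1)))
  expect_false(
    detect_contraction_abnormalities(single, "isometric")$double_peak_contraction)
  dbl <- make_trace(trace_fixture(
    force = fx_cosine(0, c(200, 500), c(120, 120), c(1, 1))))
  expect_true(
    detect_contraction_abnormalities(dbl, "isometric")$double_peak_contraction)
})

test_that("shortening below 1% is a failed contraction", {
  tr <- make_trace(trace_fixture(
    length = fx_linear(c(0, 200, 300, 500),
                       c(0.93, 0.93, 0.93 * 0.995, 0.93))))
  fl <- detect_contraction_abnormalities(tr, "afterloaded")
  expect_true(fl$failed_contraction)
})

test_that("secondary Ca2+ peaks flag spontaneous SR release", {
  tr <- make_trace(trace_fixture(
    Cai = fx_cosine(0.08, c(160, 700), c(150, 60), c(1, 0.15))))
  fl <- detect_contraction_abnormalities(tr, "isometric")
  expect_true(fl$spontaneous_Ca_release)
})

test_that("steady-state check compares the last two cycles", {
  s_ok <- tibble::tibble(apd90 = c(300, 300), peak_Cai = c(1, 1),
                         peak_F = c(0.5, 0.5))
  expect_true(check_steady_state(s_ok))
  s_bad <- tibble::tibble(apd90 = c(300, 300), peak_Cai = c(1, 1),
                          peak_F = c(1.0, 0.9))
  expect_false(check_steady_state(s_bad))
  s_alt <- tibble::tibble(apd90 = c(300, 330), peak_Cai = c(1, 1),
                          peak_F = c(0.5, 0.5))
  expect_false(check_steady_state(s_alt))
})

test_that("clean raised-cosine twitches never false-positive", {
  n_bad <- 0L
  for (k in 1:1000) {
    par <- withr::with_seed(k, {
      list(amp = runif(1, 80, 130), hw = runif(1, 100, 230),
           ca = runif(1, 0.4, 1.4), f = runif(1, 0.2, 1.2))
    })
    tr <- make_trace(clean_cycle_fixture(ap_amp = par$amp,
                                         ap_halfwidth = par$hw,
                                         ca_amp = par$ca, f_amp = par$f,
                                         n_cycles = 1, dt = 1))
    if (any_abnormal(detect_ap_abnormalities(tr)) ||
        any_abnormal(detect_contraction_abnormalities(tr, "isometric")))
      n_bad <- n_bad + 1L
  }
  expect_identical(n_bad, 0L)
})
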