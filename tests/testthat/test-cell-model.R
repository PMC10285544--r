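test_that("scaling vectors validate and default to the reference model", {
  sv <- scaling_vector()
  expect_named(sv, cell_parameters())
  expect_true(all(sv == 1))
  expect_equal(scaling_vector(gKr = 0.5)[["gKr"]], 0.5)
  expect_error(scaling_vector(bogus = 1), "unknown parameter")
  expect_error(scaling_vector(gNa = -1), "non-negative")
  expect_error(drug_block(IKr = 1.5), "0, 1")
  expect_error(mech_protocol("afterloaded"), "afterload")
  expect_error(sim_config(dt = 0.3), "divide")
})

test_that("simulation is deterministic and respects the isometric clamp", {
  cfg <- quick_config(5)
  t1 <- simulate_cell(config = cfg)
  t2 <- simulate_cell(config = cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_true(all(t1$L_frac == 0.93))
  # uniform, strictly increasing timebase
  expect_true(all(diff(t1$time_ms) > 0))
  expect_lt(max(abs(diff(t1$time_ms) - cfg$dt)), 1e-9)
  # per-cycle summaries for all cycles
  expect_equal(nrow(attr(t1, "cycle_summary")), 5)
})

test_that("an unstimulated cell stays at rest", {
  tr <- simulate_cell(config = quick_config(3, stim_amp = 0))
  v <- tr$V_mV[tr$cycle == max(tr$cycle)]
  expect_lt(max(v) - min(v), 5)
  expect_match(extract_biomarkers(tr)$flags, "no_AP")
})

test_that("removing IKr prolongs the action potential", {
  cfg <- quick_config(40)
  apd_ref <- tail(attr(simulate_cell(config = cfg), "cycle_summary")$apd90, 1)
  apd_blk <- tail(attr(simulate_cell(scaling_vector(gKr = 0), config = cfg),
                       "cycle_summary")$apd90, 1)
  expect_gt(apd_blk, apd_ref)
})

test_that("total cell calcium is conserved with frozen sarcolemmal fluxes", {
  cfg <- quick_config(30)
  tr <- simulate_cell(config = cfg)
  st <- attr(tr, "final_state")
  p <- cardiopop:::.cell_parms(scaling_vector(), config = cfg, block_ca = 1)
  ps <- p; ps[13] <- 1
  m <- cardiopop:::.run_cycle(st, ps, p, 1000, 1, cfg)$mat
  Vc <- 0.016404; Vsr <- 0.001094; Vss <- 5.468e-5
  total <- function(i) {
    cai <- m[i, "Cai"]; cass <- m[i, "Cass"]; casr <- m[i, "Casr"]
    Vc * (cai + 0.35 * cai / (cai + 0.001) + m[i, "B"]) +
      Vss * (cass + 0.4 * cass / (cass + 2.5e-4)) +
      Vsr * (casr + 5 * casr / (casr + 0.3))
  }
  tots <- vapply(seq(1, nrow(m), by = 25), total, 1.0)
  expect_lt((max(tots) - min(tots)) / mean(tots), 1e-8)
})

test_that("mechano-calcium feedback links length to the Ca2+ transient", {
  cfg <- quick_config(150)
  ca93 <- max(simulate_cell(protocol = mech_protocol("isometric", 0.93),
                            config = cfg)$Cai_uM)
  ca80 <- max(simulate_cell(protocol = mech_protocol("isometric", 0.80),
                            config = cfg)$Cai_uM)
  expect_gt(abs(ca80 - ca93), 0.002)
  expect_gt(ca80, ca93)  # reduced preload raises the transient
})

test_that("afterloaded twitches clamp force and restore length", {
  cfg <- quick_config(40)
  iso <- simulate_cell(config = cfg)
  tw <- afterloaded_twitch(afterload_fraction = 0.5, config = cfg,
                           isometric_trace = iso)
  expect_equal(attr(tw, "status"), "ok")
  iso_phase <- tw[tw$phase == "isotonic", ]
  expect_gt(nrow(iso_phase), 5)
  # total force constant at the clamp during the isotonic phase
  clamp <- iso_phase$F_total[2]
  expect_lt(max(abs(iso_phase$F_total[-1] - clamp)) / clamp, 1e-4)
  # cell shortens and re-lengthens to the initial length
  expect_lt(min(tw$L_frac), 0.93)
  expect_equal(tail(tw$L_frac, 1), 0.93, tolerance = 1e-6)
  # determinism
  tw2 <- afterloaded_twitch(afterload_fraction = 0.5, config = cfg,
                            isometric_trace = iso)
  expect_identical(as.data.frame(tw), as.data.frame(tw2))
})

test_that("a load at or above peak force never lifts", {
  cfg <- quick_config(40)
  iso <- simulate_cell(config = cfg)
  tw <- afterloaded_twitch(afterload_fraction = 1.0, config = cfg,
                           isometric_trace = iso)
  expect_equal(attr(tw, "status"), "never_lifted")
  expect_true(all(tw$L_frac == 0.93))
})

test_that("peak isometric force is reproducible and self-normalizing", {
  cfg <- quick_config(30)
  f1 <- peak_isometric_force(config = cfg)
  f2 <- peak_isometric_force(config = cfg)
  expect_identical(f1, f2)
  expect_gt(f1, 0)
})

test_that("solver failure yields a flagged empty trace, not an error", {
  cfg <- sim_config(n_cycles = 2, rtol = 1e-13, atol = 1e-16)
  tr <- suppressWarnings(simulate_cell(config = cfg))
  if (attr(tr, "status") != "ok") {
    expect_identical(attr(tr, "status"), "integration_failed")
    expect_equal(nrow(tr), 0)
  } else {
    succeed("solver coped with extreme tolerances")
  }
})
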