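test_that("each rigged model is rejected at its own stage", {
  pop <- stub_population(c(1.00, 0.11, 0.12, 0.13, 0.14, 0.15))
  res <- run_mechanical_calibration(pop, backend = stub_backend())
  st <- res$population$status
  expect_equal(st[1], "accepted")
  expect_equal(st[2], "rejected:mech:force_biomarkers")
  expect_equal(st[3], "rejected:mech:preload")
  expect_equal(st[4], "rejected:mech:LF_curve")
  expect_equal(st[5], "rejected:mech:afterload")
  expect_equal(st[6], "rejected:mech:afterload")
  # conservation: accepted + per-stage rejections = input
  expect_equal(nrow(res$accepted) + sum(res$summary$rejected), nrow(pop))
  # rejected models never re-enter later stages
  expect_false(0.11 %in% round(res$reports$preload$model_id, 2))
})

test_that("force-biomarker screening applies the packaged ranges", {
  pop <- stub_population(c(1.00, 0.11))
  rep1 <- stage_force_biomarkers(pop, stub_backend())
  expect_equal(rep1$decision, c("kept", "rejected"))
  expect_match(rep1$reason[2], "FTTP")
  empty <- stage_force_biomarkers(pop[0, ], stub_backend())
  expect_equal(nrow(empty), 0)
})

test_that("the length-force stage requires a strict increase", {
  ok <- tibble::tibble(model_id = 1L, length = c(0.8, 0.85, 0.9),
                       peak_force = c(0.20, 0.30, 0.40))
  pop <- stub_population(1.00)
  rep_ok <- stage_lf_curve(pop, stub_backend(), ok)
  expect_equal(rep_ok$decision, "kept")
  dec <- ok; dec$peak_force <- c(0.45, 0.40, 0.35)
  expect_equal(stage_lf_curve(pop, stub_backend(), dec)$decision, "rejected")
  tie <- ok; tie$peak_force <- c(0.25, 0.25, 0.40)  # tie counts as failure
  expect_equal(stage_lf_curve(pop, stub_backend(), tie)$decision, "rejected")
})

test_that("the afterload stage rejects non-monotone force-velocity", {
  pop <- stub_population(0.15)
  rep4 <- stage_afterload(pop, stub_backend())
  expect_equal(rep4$decision, "rejected")
  expect_match(rep4$reason[1], "force-velocity")
  fv <- attr(rep4, "fv_curves")
  expect_equal(nrow(fv), 3)
})

test_that("an empty preload length list is a no-op", {
  pop <- stub_population(1.00)
  rep2 <- stage_preload(pop, stub_backend(), lengths = numeric())
  expect_equal(rep2$decision, "kept")
})
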