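test_that("the pore-block factor has its analytic limits", {
  expect_equal(block_factor(0, 1, 2), 1)
  for (h in c(0.5, 1, 1.56, 3))
    expect_equal(block_factor(5, 5, h), 0.5)
  # Verapamil ICaL at 0.27 uM (3x EFTPCmax): direct formula evaluation
  expect_equal(block_factor(0.27, 0.2, 0.80), 0.4403, tolerance = 1e-3)
  # monotone decreasing, continuous, limits 1 and 0
  cc <- 10^seq(-4, 4, length.out = 100)
  f <- block_factor(cc, 0.5, 1.3)
  expect_true(all(diff(f) < 0))
  expect_lt(f[100], 1e-3)
  expect_gt(f[1], 1 - 1e-3)
  expect_error(block_factor(-1, 1, 1), "non-negative")
})

test_that("drug specs map concentrations to block vectors", {
  dof <- drug_spec("Dofetilide")
  expect_true(all(apply_drug(dof, multiplier = 0) == 1))
  b <- apply_drug(dof, concentration = 0.013)
  expect_equal(b[["IKr"]], 0.5)
  expect_gt(b[["ICaL"]], 0.99)   # 0.013 uM << IC50 of 201 uM
  # channel-wise monotone in the multiplier
  mats <- sapply(c(0.1, 1, 10, 100),
                 function(m) apply_drug(dof, multiplier = m))
  expect_true(all(apply(mats, 1, function(r) all(diff(r) <= 0))))
  # Verapamil has no IKs block
  ver <- drug_spec("Verapamil")
  expect_equal(apply_drug(ver, multiplier = 100)[["IKs"]], 1)
  # a non-positive EFTPCmax demands an absolute concentration
  broken <- ver
  attr(broken, "eftpc_uM") <- 0
  expect_error(apply_drug(broken, multiplier = 1), "absolute concentration")
  expect_error(drug_spec("NoSuchDrug"), "unknown drug")
})

test_that("drug tables round-trip losslessly through CSV", {
  tb <- default_drugs()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tb, path)
  expect_equal(as.data.frame(read_drug_table(path)), as.data.frame(tb))
})
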