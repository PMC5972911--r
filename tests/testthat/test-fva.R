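test_that("on a unique path every flux range collapses at fraction 1", {
  chain <- generate_linear_chain(2)
  fva <- flux_variability(chain, "EX_out", fraction = 1,
                          fixed_fluxes = c(EX_in = -10))
  expect_true(all(abs(fva$max - fva$min) < 1e-7))
  expect_equal(fva$min[fva$reaction == "EX_out"], 10, tolerance = 1e-7)
})

test_that("two parallel identical routes show the full alternate range", {
  m <- parallel_routes_model()
  fva <- flux_variability(m, "EX_out", fraction = 1,
                          fixed_fluxes = c(EX_in = -10))
  for (r in c("R1a", "R1b")) {
    expect_equal(fva$min[fva$reaction == r], 0, tolerance = 1e-7)
    expect_equal(fva$max[fva$reaction == r], 10, tolerance = 1e-7)
  }
  expect_equal(fva$min[fva$reaction == "EX_out"], 10, tolerance = 1e-7)
  expect_equal(fva$max[fva$reaction == "EX_out"], 10, tolerance = 1e-7)
})

test_that("the NOG glycerol P3HB drain is pinned at 7.5 across optima", {
  res <- all_scenarios()[[6]] # glycerol, NOG
  fva <- flux_variability(res$model, "EX_phb_e", fraction = 1,
                          reactions = "EX_phb_e",
                          fixed_fluxes = res$fixed_fluxes)
  expect_equal(fva$min, 7.5, tolerance = 1e-6)
  expect_equal(fva$max, 7.5, tolerance = 1e-6)
})

test_that("invalid fractions and infeasible bases are rejected", {
  chain <- generate_linear_chain(1)
  expect_error(flux_variability(chain, "EX_out", fraction = 0), "in \\(0, 1\\]")
  expect_error(flux_variability(chain, "EX_out", fraction = 1.2),
               "in \\(0, 1\\]")
  bad <- generate_linear_chain(2, conversion_ubs = c(3, 1000))
  expect_error(flux_variability(bad, "EX_out", fraction = 1,
                                fixed_fluxes = c(EX_in = -10)),
               "status: infeasible")
})
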