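test_that("carbon_yield implements the mole-carbon ratio", {
  expect_equal(carbon_yield(8.33, 10, 4, 5), 0.6664)
  expect_equal(carbon_yield(7.5, 10, 4, 3), 1)
  expect_equal(carbon_yield(0, 10, 4, 5), 0)
  expect_error(carbon_yield(1, 0, 4, 5), "substrate rate is zero")
  expect_error(carbon_yield(-1, 10, 4, 5), "non-negative")
  expect_error(carbon_yield(1, 10, 0, 5), ">= 1")
})

test_that("scenario construction validates its inputs", {
  s <- scenario("xylose", uptake_rate = 10, nog = TRUE)
  expect_equal(s$exchange, "EX_xyl__D_e")
  expect_equal(s$substrate_carbons, 5L)
  expect_error(scenario("sucrose"), "should be one of")
  expect_error(scenario("xylose", uptake_rate = -1), "non-negative")
})

test_that("theoretical maxima land on the published optima", {
  res <- all_scenarios() # glc, xyl, gly baseline; glc, xyl, gly NOG
  rates <- vapply(res, `[[`, 0, "product_rate")
  yields <- vapply(res, `[[`, 0, "carbon_yield")
  expect_equal(rates, c(10, 25 / 3, 5, 40 / 3, 100 / 9, 7.5),
               tolerance = 1e-6)
  expect_equal(yields, c(2/3, 2/3, 2/3, 8/9, 8/9, 1), tolerance = 1e-6)
})

test_that("the yield identity and carbon conservation hold at every optimum", {
  for (r in all_scenarios()) {
    expect_equal(r$carbon_yield,
                 r$product_rate * 4 / (10 * r$scenario$substrate_carbons),
                 tolerance = 1e-12)
    expect_gte(r$carbon_yield, 0)
    expect_lte(r$carbon_yield, 1 + 1e-9)
    # substrate carbon in = product carbon + CO2 out; acetate stays zero
    expect_equal(10 * r$scenario$substrate_carbons,
                 4 * r$product_rate + r$co2_rate, tolerance = 1e-6)
    expect_equal(unname(r$solution$fluxes["EX_ac_e"]), 0, tolerance = 1e-7)
    expect_equal(unname(r$solution$fluxes["EX_phb_e"]), r$product_rate)
  }
})

test_that("the baseline yield ceiling is uniform across substrates", {
  base <- all_scenarios()[1:3]
  yields <- vapply(base, `[[`, 0, "carbon_yield")
  expect_equal(yields, rep(2/3, 3), tolerance = 1e-9)
})

test_that("the NOG optimum dominates the baseline for every substrate", {
  res <- all_scenarios()
  for (i in 1:3) {
    expect_gte(res[[i + 3]]$product_rate, res[[i]]$product_rate - 1e-9)
    expect_gte(res[[i + 3]]$carbon_yield, res[[i]]$carbon_yield - 1e-9)
  }
  expect_equal(res[[6]]$carbon_yield, 1, tolerance = 1e-9)
})

test_that("zero uptake gives zero production", {
  r <- theoretical_max_production(core_model(),
                                  scenario("xylose", uptake_rate = 0))
  expect_equal(r$product_rate, 0, tolerance = 1e-9)
  expect_true(is.na(r$carbon_yield))
})

test_that("an unbalanced base model is rejected", {
  m <- core_model()
  i <- with(m$stoichiometry, reaction == "PDH" & metabolite == "co2_c")
  m$stoichiometry$coefficient[i] <- 2
  expect_error(theoretical_max_production(m, scenario("xylose")),
               "fails carbon-balance.*PDH")
})

test_that("other carbon sources are closed to uptake in a scenario", {
  r <- theoretical_max_production(core_model(), scenario("glycerol"))
  expect_equal(unname(r$solution$fluxes[c("EX_glc__D_e", "EX_xyl__D_e")]),
               c(0, 0), tolerance = 1e-9)
})

test_that("the flux report pins carbon loss on pyruvate decarboxylation", {
  res <- all_scenarios()
  base_xyl <- res[[2]]
  rep <- flux_report(base_xyl, pathway_order = c("PDH", "GND", "EX_co2_e",
                                                 "EX_phb_e"))
  co2 <- rep$flux[rep$reaction == "EX_co2_e"]
  pdh <- rep$flux[rep$reaction == "PDH"]
  # CO2 release equals the PDH flux: the oxidative PPP contributes nothing
  expect_equal(co2, pdh, tolerance = 1e-6)
  expect_equal(rep$flux[rep$reaction == "GND"], 0, tolerance = 1e-6)
  expect_true(rep$unique[rep$reaction == "EX_co2_e"])
  expect_true(rep$unique[rep$reaction == "EX_phb_e"])

  nog_gly <- res[[6]]
  rep2 <- flux_report(nog_gly, pathway_order = c("EX_co2_e", "EX_phb_e"))
  expect_equal(rep2$flux[rep2$reaction == "EX_co2_e"], 0, tolerance = 1e-6)
})

test_that("the default flux report is sorted by subsystem and keeps CO2", {
  rep <- flux_report(all_scenarios()[[3]])
  expect_true("EX_co2_e" %in% rep$reaction)
  expect_true(all(abs(rep$flux[!rep$reaction %in% "EX_co2_e"]) > 1e-6))
  sub <- rep$subsystem[rep$subsystem != "exchange"]
  expect_true(!is.unsorted(sub))
  expect_error(flux_report(all_scenarios()[[3]], pathway_order = "zz"),
               "unknown reaction")
})
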