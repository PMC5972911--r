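test_that("a fixed uptake propagates through a linear chain", {
  chain <- generate_linear_chain(2)
  sol <- solve_fba(chain, "EX_out", fixed_fluxes = c(EX_in = -10))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes[c("R1", "R2")]), c(10, 10),
               tolerance = 1e-9)
})

test_that("a bottleneck bound caps the optimum when uptake is a bound", {
  chain <- generate_linear_chain(5, uptake_bound = 10,
                                 conversion_ubs = c(1000, 1000, 3, 1000, 1000))
  sol <- solve_fba(chain, "EX_out")
  expect_equal(sol$objective_value, 3, tolerance = 1e-9)
})

test_that("a fixed uptake conflicting with a bottleneck is infeasible", {
  chain <- generate_linear_chain(5, conversion_ubs = c(1000, 1000, 3, 1000,
                                                       1000))
  sol <- solve_fba(chain, "EX_out", fixed_fluxes = c(EX_in = -10))
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
})

test_that("an uncapped objective is reported as unbounded, not a number", {
  chain <- generate_linear_chain(1)
  chain <- set_bounds(chain, "EX_in", lower = -Inf)
  chain <- set_bounds(chain, "R1", upper = Inf)
  chain <- set_bounds(chain, "EX_out", upper = Inf)
  sol <- solve_fba(chain, "EX_out")
  expect_equal(sol$status, "unbounded")
  expect_true(is.na(sol$objective_value))
})

test_that("argument validation catches bad objectives and fixed fluxes", {
  chain <- generate_linear_chain(1)
  expect_error(solve_fba(chain, "nope"), "unknown objective")
  expect_error(solve_fba(chain, "EX_out", fixed_fluxes = c(zz = 1)),
               "unknown reaction")
  expect_error(solve_fba(chain, "EX_out", fixed_fluxes = c(EX_in = -99)),
               "outside declared bounds")
  expect_error(solve_fba(chain, "EX_out", fixed_fluxes = 5), "named")
})

test_that("minimization works and respects the zero lower bound", {
  chain <- generate_linear_chain(2)
  sol <- solve_fba(chain, "EX_out", maximize = FALSE)
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("optimal solutions satisfy steady state and bounds", {
  cases <- list(generate_linear_chain(3),
                parallel_routes_model(),
                generate_planted_network(3, 4, 6, seed = 11)$model)
  for (m in cases) {
    sol <- solve_fba(m, m$objective_candidates[1])
    expect_equal(sol$status, "optimal")
    S <- stoich_matrix(m)
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-7)
    b <- m$reactions
    expect_true(all(sol$fluxes >= b$lower_bound - 1e-7))
    expect_true(all(sol$fluxes <= b$upper_bound + 1e-7))
  }
})

test_that("the curated-model LP is homogeneous in the uptake rate", {
  m <- core_model()
  combos <- expand.grid(substrate = c("xylose", "glycerol"),
                        nog = c(FALSE, TRUE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    base <- theoretical_max_production(
      m, scenario(combos$substrate[i], uptake_rate = 10,
                  nog = combos$nog[i]))
    for (k in c(0.5, 2)) {
      scaled <- theoretical_max_production(
        m, scenario(combos$substrate[i], uptake_rate = 10 * k,
                    nog = combos$nog[i]))
      expect_equal(scaled$product_rate, k * base$product_rate,
                   tolerance = 1e-7)
      expect_equal(scaled$carbon_yield, base$carbon_yield,
                   tolerance = 1e-9)
    }
  }
})
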