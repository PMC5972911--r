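test_that("measured titers convert to the published carbon yields", {
  # 2.99 g/L P3HB from 10 g/L glycerol, fully consumed
  y <- experimental_carbon_yield(2.99, 10, 92.09, 3)
  expect_equal(round(y, 2), 0.43)
  # exact hand arithmetic: 0.4 mol C product / 0.6 mol C substrate
  y2 <- experimental_carbon_yield(8.609, 18.016, 180.16, 6)
  expect_equal(y2, 2 / 3, tolerance = 1e-10)
  expect_equal(experimental_carbon_yield(0, 10, 92.09, 3), 0)
})

test_that("the yield is scale-invariant and additive over substrates", {
  base <- experimental_carbon_yield(2.99, 10, 92.09, 3)
  for (k in c(0.25, 3, 10)) {
    expect_equal(experimental_carbon_yield(2.99 * k, 10 * k, 92.09, 3),
                 base, tolerance = 1e-12)
  }
  split <- experimental_carbon_yield(2.99, c(5, 5), c(92.09, 92.09), c(3, 3))
  expect_equal(split, base, tolerance = 1e-12)
  mixed <- experimental_carbon_yield(1.5, c(10, 5), c(180.16, 150.13),
                                     c(6, 5))
  manual <- (1.5 / 86.09 * 4) / (10 / 180.16 * 6 + 5 / 150.13 * 5)
  expect_equal(mixed, manual, tolerance = 1e-12)
})

test_that("yield calculator rejects degenerate inputs", {
  expect_error(experimental_carbon_yield(1, numeric(0), 92.09, 3),
               "at least one substrate")
  expect_error(experimental_carbon_yield(1, 0, 92.09, 3),
               "substrate carbon is zero")
  expect_error(experimental_carbon_yield(-1, 10, 92.09, 3), "non-negative")
  expect_error(experimental_carbon_yield(1, 10, 0, 3), "positive")
})

test_that("relative yield increases match the published percentages", {
  expect_equal(round(relative_yield_increase(0.19, 0.24), 1), 26.3)
  expect_equal(round(relative_yield_increase(0.30, 0.43), 1), 43.3)
  expect_equal(relative_yield_increase(0.37, 0.37), 0)
  expect_error(relative_yield_increase(0, 0.4), "positive")
})

test_that("forward and reverse relative increases are reciprocal", {
  for (pair in list(c(0.19, 0.24), c(0.3, 0.43), c(0.21, 0.31))) {
    r1 <- relative_yield_increase(pair[1], pair[2])
    r2 <- relative_yield_increase(pair[2], pair[1])
    expect_equal((1 + r1 / 100) * (1 + r2 / 100), 1, tolerance = 1e-12)
  }
})

test_that("polymer content is a weight fraction of the dry biomass", {
  expect_equal(phb_content(1, 4), 25)
  expect_equal(phb_content(0, 3), 0)
  # consistency check: a 30.95 wt% content at 2.31 g/L implies 7.464 g/L CDW
  expect_equal(phb_content(2.31, 7.464), 30.95, tolerance = 0.01)
  expect_error(phb_content(5, 4), "exceeds cell dry weight")
  expect_error(phb_content(1, 0), "positive")
})
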