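test_that("formula parsing yields element counts and rejects garbage", {
  expect_equal(parse_formula("C4H6O2"), c(C = 4L, H = 6L, O = 2L))
  expect_equal(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_equal(parse_formula("C23H34N7O17P3S"),
               c(C = 23L, H = 34L, N = 7L, O = 17L, P = 3L, S = 1L))
  expect_equal(parse_formula("HO4P"), c(H = 1L, O = 4L, P = 1L))
  expect_equal(element_count(c("C6H12O6", "H2O", "CO2")), c(6L, 0L, 1L))
  expect_error(parse_formula("C6H"), NA) # trailing implicit 1 is legal
  expect_error(parse_formula("6CH"), "cannot parse")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula(NA_character_), "non-empty")
})

test_that("model constructor enforces structural invariants", {
  mets <- data.frame(id = c("a", "b"), name = c("a", "b"), formula = "C",
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_a", "R1"), name = c("in", "conv"),
                     lower_bound = c(-10, 0), upper_bound = c(0, 10),
                     subsystem = "x", is_exchange = c(TRUE, FALSE),
                     stringsAsFactors = FALSE)
  st <- data.frame(reaction = c("EX_a", "R1", "R1"),
                   metabolite = c("a", "a", "b"),
                   coefficient = c(-1, -1, 1), stringsAsFactors = FALSE)
  expect_s3_class(stoich_model(mets, rxns, st), "stoich_model")

  dup_m <- mets; dup_m$id <- c("a", "a")
  expect_error(stoich_model(dup_m, rxns, st), "duplicate metabolite id")
  dup_r <- rxns; dup_r$id <- c("R1", "R1")
  expect_error(stoich_model(mets, dup_r, st), "duplicate reaction id")
  bad_ref <- st; bad_ref$metabolite[1] <- "zz"
  expect_error(stoich_model(mets, rxns, bad_ref), "unknown metabolite: zz")
  zero <- st; zero$coefficient[2] <- 0
  expect_error(stoich_model(mets, rxns, zero), "zero stoichiometric")
  expect_error(stoich_model(mets, rxns, st[-1, ]),
               "no metabolites.*EX_a|all-zero")
  flip <- rxns; flip$lower_bound[2] <- 20
  expect_error(stoich_model(mets, flip, st), "lower_bound > upper_bound")
})

test_that("stoichiometric matrix and bound edits are consistent", {
  m <- generate_linear_chain(2)
  S <- stoich_matrix(m)
  expect_equal(dim(S), c(3L, 4L))
  expect_equal(unname(colSums(S != 0)), c(1, 2, 2, 1))
  # every internal column is carbon-neutral given unit-carbon species
  expect_equal(unname(colSums(S[, c("R1", "R2")])), c(0, 0))
  m2 <- set_bounds(m, "R1", upper = 3)
  expect_equal(m2$reactions$upper_bound[m2$reactions$id == "R1"], 3)
  expect_error(set_bounds(m, "R1", lower = 5, upper = 2), "lower_bound >")
  expect_error(set_bounds(m, "nope", upper = 1), "unknown reaction")
})

test_that("carbon counts come from formulas", {
  m <- core_model()
  cc <- carbon_counts(m)
  expect_equal(unname(cc[c("glc__D_e", "xyl__D_e", "glyc_e", "phb_c")]),
               c(6L, 5L, 3L, 4L))
})
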