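test_that("the NOG knock-in adds exactly the two phosphoketolases", {
  base <- core_model()
  nog <- knock_in_nog(base)
  expect_equal(nrow(nog$reactions), nrow(base$reactions) + 2L)
  expect_setequal(setdiff(nog$reactions$id, base$reactions$id),
                  c("FPK", "XPK"))
  expect_equal(sum(base$reactions$subsystem == "NOG"), 0L)
  expect_equal(sum(nog$reactions$subsystem == "NOG"), 2L)
  # F6P + Pi -> E4P + AcP + H2O and X5P + Pi -> G3P + AcP + H2O
  fpk <- nog$stoichiometry[nog$stoichiometry$reaction == "FPK", ]
  expect_setequal(fpk$metabolite[fpk$coefficient < 0], c("f6p_c", "pi_c"))
  expect_setequal(fpk$metabolite[fpk$coefficient > 0],
                  c("e4p_c", "actp_c", "h2o_c"))
  xpk <- nog$stoichiometry[nog$stoichiometry$reaction == "XPK", ]
  expect_setequal(xpk$metabolite[xpk$coefficient < 0],
                  c("xu5p__D_c", "pi_c"))
  expect_setequal(xpk$metabolite[xpk$coefficient > 0],
                  c("g3p_c", "actp_c", "h2o_c"))
})

test_that("both knock-in reactions are balanced for all checked elements", {
  rep <- validate_elemental_balance(knock_in_nog(core_model()))
  expect_true(rep$pass)
  expect_true(all(rep$imbalance[c("FPK", "XPK"), ] == 0))
})

test_that("the knock-in changes no existing coefficient or bound", {
  base <- core_model()
  before <- list(r = base$reactions, s = base$stoichiometry)
  nog <- knock_in_nog(base)
  # the input model is untouched
  expect_identical(base$reactions, before$r)
  expect_identical(base$stoichiometry, before$s)
  # pre-existing rows are identical in the extended model
  expect_identical(nog$reactions[seq_len(nrow(before$r)), ], before$r)
  expect_identical(nog$stoichiometry[seq_len(nrow(before$s)), ], before$s)
})

test_that("a duplicate knock-in is an error", {
  nog <- knock_in_nog(core_model())
  expect_error(knock_in_nog(nog), "already contains the NOG")
})

test_that("the knock-in requires and activates fructose-1,6-bisphosphatase", {
  m <- core_model()
  closed <- set_bounds(m, "FBP", upper = 0)
  opened <- knock_in_nog(closed)
  expect_gt(opened$reactions$upper_bound[opened$reactions$id == "FBP"], 0)

  no_fbp <- m
  keep <- no_fbp$reactions$id != "FBP"
  no_fbp$reactions <- no_fbp$reactions[keep, ]
  no_fbp$stoichiometry <-
    no_fbp$stoichiometry[no_fbp$stoichiometry$reaction != "FBP", ]
  expect_error(knock_in_nog(no_fbp), "lacks fructose-1,6-bisphosphatase")
})
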