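test_that("packaged model round-trips byte-for-byte and field-for-field", {
  path <- system.file("extdata", "ecoli_phb_core.tsv", package = "phbflux")
  m <- read_model(path)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, tmp)
  expect_identical(readLines(tmp), readLines(path))
  expect_identical(read_model(tmp), m)
})

test_that("generated fixtures round-trip through the native format", {
  for (seed in c(1, 2, 3)) {
    g <- generate_planted_network(3, 3, 7.5, seed = seed)
    tmp <- withr::local_tempfile(fileext = ".tsv")
    write_model(g$model, tmp)
    expect_identical(read_model(tmp), g$model)
  }
})

test_that("the packaged file header counts match its body", {
  path <- system.file("extdata", "ecoli_phb_core.tsv", package = "phbflux")
  lines <- readLines(path)
  n_rxn <- as.integer(sub("# reactions: ", "",
                          grep("^# reactions:", lines, value = TRUE)))
  m <- read_model(path)
  expect_equal(nrow(m$reactions), n_rxn)
  # a tampered header count is rejected
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sub("^# reactions: .*", "# reactions: 3", lines), tmp)
  expect_error(read_model(tmp), "declares 3 reactions")
})

test_that("parse errors name the offending reaction or line", {
  m <- generate_linear_chain(1)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, tmp)
  lines <- readLines(tmp)

  dup <- sub("^R1\t", "EX_in\t", lines)
  dup <- sub("# reactions: 3", "# reactions: 3", dup)
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(dup, tmp2)
  expect_error(read_model(tmp2), "duplicate reaction id: EX_in")

  noarrow <- sub("s0 -> s1", "s0 s1", lines)
  writeLines(noarrow, tmp2)
  expect_error(read_model(tmp2), "reaction R1.*arrow")

  badnum <- sub("s0 -> s1\t0\t1000", "s0 -> s1\tzero\t1000", lines)
  writeLines(badnum, tmp2)
  expect_error(read_model(tmp2), "non-numeric bounds")

  expect_error(read_model("/nonexistent/file.tsv"), "does not exist")
})

test_that("SBML import agrees with the native representation", {
  tmp <- withr::local_tempfile(fileext = ".xml")
  write_chain_sbml(tmp)
  m <- read_model(tmp, format = "sbml")
  expect_equal(nrow(m$metabolites), 2L)
  expect_equal(nrow(m$reactions), 3L)
  expect_true(all(m$reactions$is_exchange == c(TRUE, FALSE, TRUE)))
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_in"], -10)
  expect_true(validate_elemental_balance(m, "C")$pass)
  sol <- solve_fba(m, "EX_out")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
})
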