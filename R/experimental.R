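# Experimental carbon-yield arithmetic: converting measured P3HB titers
# and consumed substrate masses into mole-carbon yields, relative yield
# improvements, and polymer content.
#
# The yield basis is moles of carbon in the polymer repeat unit (C4H6O2,
# 86.09 g/mol) over moles of carbon in the consumed substrates; this is
# the basis on which titer and consumption measurements reproduce the
# published yields.

#' Carbon yield from measured concentrations
#'
#' `(titer / unit mass * product carbons) / sum(consumed / molar mass *
#' carbons)`, i.e. mol carbon in product per mol carbon in consumed
#' substrate.  Multiple substrates contribute additively to the
#' denominator.
#'
#' @param product_g_l P3HB titer, g/L.
#' @param substrate_g_l Numeric vector of consumed substrate masses, g/L.
#' @param substrate_molar_mass Molar masses, g/mol (recycled).
#' @param substrate_carbons Carbon atoms per substrate molecule (recycled).
#' @param product_unit_mass Molar mass of the polymer repeat unit, g/mol.
#' @param product_carbons Carbon atoms per repeat unit.
#' @return Dimensionless carbon-yield fraction.
#' @examples
#' # 2.99 g/L P3HB from 10 g/L glycerol, fully consumed
#' experimental_carbon_yield(2.99, 10, 92.09, 3)
#' @export
experimental_carbon_yield <- function(product_g_l, substrate_g_l,
                                      substrate_molar_mass,
                                      substrate_carbons,
                                      product_unit_mass = 86.09,
                                      product_carbons = 4) {
  if (length(product_g_l) != 1L || is.na(product_g_l) || product_g_l < 0) {
    stop("product_g_l must be a single non-negative number")
  }
  if (!length(substrate_g_l)) stop("at least one substrate is required")
  if (any(substrate_g_l < 0)) stop("substrate masses must be non-negative")
  if (any(substrate_molar_mass <= 0) || product_unit_mass <= 0) {
    stop("molar masses must be positive")
  }
  if (any(substrate_carbons < 1) || product_carbons < 1) {
    stop("carbon counts must be >= 1")
  }
  substrate_molar_mass <- rep_len(substrate_molar_mass, length(substrate_g_l))
  substrate_carbons <- rep_len(substrate_carbons, length(substrate_g_l))
  denom <- sum(substrate_g_l / substrate_molar_mass * substrate_carbons)
  if (denom == 0) {
    stop("carbon yield undefined: total substrate carbon is zero")
  }
  (product_g_l / product_unit_mass * product_carbons) / denom
}

#' Relative yield increase in percent
#'
#' `(engineered / control - 1) * 100`.
#'
#' @param control_yield Yield of the control strain (> 0).
#' @param engineered_yield Yield of the engineered strain (>= 0).
#' @return Percent increase (negative for a decrease).
#' @examples
#' relative_yield_increase(0.19, 0.24) # ~26.3
#' @export
relative_yield_increase <- function(control_yield, engineered_yield) {
  if (any(control_yield <= 0)) {
    stop("control yield must be positive")
  }
  if (any(engineered_yield < 0)) stop("engineered yield must be non-negative")
  (engineered_yield / control_yield - 1) * 100
}

#' Intracellular polymer content in weight percent
#'
#' @param product_titer P3HB concentration, g/L.
#' @param cell_dry_weight Cell dry weight, g/L (> 0); must be at least the
#'   titer, since the polymer is part of the biomass.
#' @return Content in wt%.
#' @export
phb_content <- function(product_titer, cell_dry_weight) {
  if (any(cell_dry_weight <= 0)) stop("cell dry weight must be positive")
  if (any(product_titer < 0)) stop("product titer must be non-negative")
  if (any(product_titer > cell_dry_weight)) {
    stop("product titer exceeds cell dry weight")
  }
  product_titer / cell_dry_weight * 100
}

#' Read a measurement table
#'
#' Tab-separated table with columns `sample`, `group`, `role`
#' (`control` or `engineered`), `phb_g_l`, optionally `cdw_g_l`, and one
#' column per consumed substrate (`glucose_g_l`, `xylose_g_l`,
#' `glycerol_g_l`).
#'
#' @param path Path to the TSV file.
#' @return A data.frame of measurements.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement table does not exist: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample", "group", "role", "phb_g_l")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("measurement table lacks columns: ", paste(missing, collapse = ", "))
  }
  sub_cols <- intersect(paste0(SUBSTRATE_INFO$substrate, "_g_l"), names(df))
  if (!length(sub_cols) && nrow(df)) {
    stop("measurement table has no substrate column (e.g. glycerol_g_l)")
  }
  df
}

#' Packaged example measurement table
#'
#' Loads the shipped glycerol shake-flask example
#' (`inst/extdata/glycerol_yields_synthetic.tsv`).  The engineered-strain
#' titer is a published value; the control titer is synthetic,
#' back-calculated from the published control yield, and the file says so.
#'
#' @return A data.frame of measurements.
#' @export
example_measurements <- function() {
  read_measurements(system.file("extdata", "glycerol_yields_synthetic.tsv",
                                package = "phbflux", mustWork = TRUE))
}
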