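# Scenario analysis: theoretical maximum P3HB production per substrate,
# with and without the NOG knock-in.
#
# Convention: the substrate exchange flux is fixed (an equality, not a
# bound) to -uptake_rate, matching a stated consumption rate of
# 10 mmol gDCW-1 h-1; all other carbon-source exchanges are closed to
# uptake; the P3HB monomer drain is maximized with zero biomass and zero
# ATP maintenance.  The carbon yield is the mole-carbon ratio
# product_rate * 4 / (uptake_rate * substrate carbons), with 4 the carbon
# count of the C4H6O2 monomer unit.

SUBSTRATE_INFO <- data.frame(
  substrate = c("glucose", "xylose", "glycerol"),
  exchange = c("EX_glc__D_e", "EX_xyl__D_e", "EX_glyc_e"),
  metabolite = c("glc__D_e", "xyl__D_e", "glyc_e"),
  carbons = c(6L, 5L, 3L),
  molar_mass = c(180.16, 150.13, 92.09),
  stringsAsFactors = FALSE)

PHB_MONOMER_CARBONS <- 4L
PHB_MONOMER_MASS <- 86.09 # g/mol of the C4H6O2 repeat unit

#' Define a production scenario
#'
#' @param substrate One of `"glucose"`, `"xylose"`, `"glycerol"`.
#' @param uptake_rate Fixed substrate consumption rate, mmol gDCW-1 h-1
#'   (the convention used throughout is 10).
#' @param nog Apply the NOG phosphoketolase knock-in?
#' @param objective Reaction id of the P3HB monomer drain.
#' @return Object of class `phb_scenario`.
#' @export
scenario <- function(substrate = c("glucose", "xylose", "glycerol"),
                     uptake_rate = 10, nog = FALSE,
                     objective = "EX_phb_e") {
  substrate <- match.arg(substrate)
  if (!is.numeric(uptake_rate) || length(uptake_rate) != 1L ||
      is.na(uptake_rate) || uptake_rate < 0) {
    stop("uptake_rate must be a single non-negative number")
  }
  info <- SUBSTRATE_INFO[SUBSTRATE_INFO$substrate == substrate, ]
  structure(list(substrate = substrate, uptake_rate = uptake_rate,
                 nog = isTRUE(nog), objective = objective,
                 exchange = info$exchange, metabolite = info$metabolite,
                 substrate_carbons = info$carbons),
            class = "phb_scenario")
}

#' @export
print.phb_scenario <- function(x, ...) {
  cat(sprintf("<phb_scenario> %s, uptake %g mmol/gDCW/h, NOG %s, objective %s\n",
              x$substrate, x$uptake_rate, if (x$nog) "on" else "off",
              x$objective))
  invisible(x)
}

#' Carbon yield from molar rates
#'
#' `(product_rate * product_carbons) / (substrate_rate * substrate_carbons)`:
#' the fraction of consumed substrate carbon recovered in the product.
#'
#' @param product_rate,substrate_rate Non-negative molar rates
#'   (`substrate_rate > 0`).
#' @param product_carbons,substrate_carbons Carbon atoms per molecule
#'   (>= 1).
#' @return Dimensionless fraction.
#' @examples
#' carbon_yield(8.33, 10, 4, 5) # xylose at the baseline optimum, ~0.667
#' @export
carbon_yield <- function(product_rate, substrate_rate, product_carbons = 4,
                         substrate_carbons) {
  if (any(product_rate < 0) || any(substrate_rate < 0)) {
    stop("rates must be non-negative")
  }
  if (any(substrate_rate == 0)) {
    stop("carbon yield undefined: substrate rate is zero")
  }
  if (any(product_carbons < 1) || any(substrate_carbons < 1)) {
    stop("carbon counts must be >= 1")
  }
  (product_rate * product_carbons) / (substrate_rate * substrate_carbons)
}

#' Theoretical maximum P3HB production for a scenario
#'
#' Applies the NOG knock-in when the scenario requests it, fixes the
#' substrate exchange to the scenario uptake rate, closes the other
#' carbon-source exchanges to uptake, and maximizes the P3HB monomer
#' drain by FBA.
#'
#' @param base_model The baseline (no-NOG) curated model; it must pass
#'   elemental-balance validation.
#' @param scen A `phb_scenario`.
#' @return Object of class `yield_result`: list with `scenario`,
#'   `product_rate`, `carbon_yield`, `co2_rate`, `solution` (the
#'   `fba_solution`), and the solved `model` with its `fixed_fluxes`.
#' @export
theoretical_max_production <- function(base_model, scen) {
  if (!inherits(scen, "phb_scenario")) stop("scen must be a phb_scenario")
  bal <- validate_elemental_balance(base_model, "C")
  if (!bal$pass) {
    stop("base model fails carbon-balance validation; offending reactions: ",
         paste(bal$failed, collapse = ", "))
  }
  i <- match(scen$metabolite, base_model$metabolites$id)
  if (is.na(i)) stop("model lacks substrate metabolite ", scen$metabolite)
  nC <- element_count(base_model$metabolites$formula[i], "C")
  if (nC != scen$substrate_carbons) {
    stop(sprintf("substrate %s has %d carbons in the model, expected %d",
                 scen$substrate, nC, scen$substrate_carbons))
  }
  model <- if (scen$nog) knock_in_nog(base_model) else base_model
  # close the other carbon-source exchanges to uptake
  others <- setdiff(SUBSTRATE_INFO$exchange, scen$exchange)
  for (ex in intersect(others, model$reactions$id)) {
    j <- match(ex, model$reactions$id)
    model$reactions$lower_bound[j] <- max(0, model$reactions$lower_bound[j])
  }
  fixed <- stats::setNames(-scen$uptake_rate, scen$exchange)
  sol <- solve_fba(model, scen$objective, fixed_fluxes = fixed)
  if (sol$status != "optimal") {
    stop(sprintf("scenario %s%s is not solvable: status %s", scen$substrate,
                 if (scen$nog) "+NOG" else "", sol$status))
  }
  rate <- unname(sol$fluxes[scen$objective])
  yield <- if (scen$uptake_rate > 0) {
    carbon_yield(rate, scen$uptake_rate, PHB_MONOMER_CARBONS,
                 scen$substrate_carbons)
  } else NA_real_
  structure(list(scenario = scen, product_rate = rate,
                 carbon_yield = yield,
                 co2_rate = unname(sol$fluxes["EX_co2_e"]),
                 solution = sol, model = model, fixed_fluxes = fixed),
            class = "yield_result")
}

#' @export
print.yield_result <- function(x, ...) {
  cat(sprintf("<yield_result> %s%s, uptake %g: P3HB rate %.2f mmol/gDCW/h",
              x$scenario$substrate, if (x$scenario$nog) "+NOG" else "",
              x$scenario$uptake_rate, x$product_rate))
  if (!is.na(x$carbon_yield)) {
    cat(sprintf(", carbon yield %.1f%%", 100 * x$carbon_yield))
  }
  cat("\n")
  invisible(x)
}

#' Flux report for an optimal scenario solution
#'
#' Tabulates the flux of each reported reaction together with its flux
#' range at the optimal objective level (flux variability at fraction 1),
#' flagging fluxes that are not unique across alternate optima.  The CO2
#' exchange flux is always included.
#'
#' @param result A `yield_result` with an optimal solution.
#' @param pathway_order Reaction ids to report, in order.  Empty (default)
#'   reports every reaction carrying flux, sorted by subsystem.
#' @param tol Fluxes and range widths below `tol` are treated as zero.
#' @return A data.frame with columns `reaction`, `name`, `subsystem`,
#'   `flux`, `min`, `max`, `unique`.
#' @export
flux_report <- function(result, pathway_order = character(), tol = 1e-6) {
  if (!inherits(result, "yield_result")) stop("result must be a yield_result")
  if (result$solution$status != "optimal") {
    stop("flux report requires an optimal solution; status: ",
         result$solution$status)
  }
  model <- result$model
  fl <- result$solution$fluxes
  if (length(pathway_order)) {
    unknown <- setdiff(pathway_order, model$reactions$id)
    if (length(unknown)) {
      stop("unknown reaction in pathway_order: ",
           paste(unknown, collapse = ", "))
    }
    ids <- pathway_order
  } else {
    ids <- model$reactions$id[abs(fl[model$reactions$id]) > tol]
    sub <- model$reactions$subsystem[match(ids, model$reactions$id)]
    ids <- ids[order(sub, ids)]
  }
  ids <- union(ids, "EX_co2_e")
  fva <- flux_variability(model, result$scenario$objective, fraction = 1,
                          reactions = ids,
                          fixed_fluxes = result$fixed_fluxes)
  j <- match(ids, model$reactions$id)
  out <- data.frame(
    reaction = ids,
    name = model$reactions$name[j],
    subsystem = model$reactions$subsystem[j],
    flux = unname(fl[ids]),
    min = fva$min[match(ids, fva$reaction)],
    max = fva$max[match(ids, fva$reaction)],
    stringsAsFactors = FALSE)
  out$unique <- (out$max - out$min) <= tol
  out
}
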