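# Pipeline entry points: run every substrate x NOG scenario and summarize,
# and turn a measurement table into a yield table with control/engineered
# comparisons.  All rounding to the reported precision (two decimals for
# rates and yields, one decimal for percents) happens here, in the
# reporting layer; upstream values are never rounded.

#' Run substrate x NOG scenarios and summarize
#'
#' @param model Baseline curated model (default: the packaged core model).
#' @param substrates Substrates to analyse.
#' @param nog Logical vector of NOG states to analyse.
#' @param uptake_rate Fixed substrate consumption rate, mmol gDCW-1 h-1.
#' @param out_dir Optional directory; when given, writes `scenarios.tsv`
#'   and one `fluxes_<substrate>_<nog>.tsv` report per scenario.
#' @return A data.frame with one row per scenario: raw `product_rate`,
#'   `carbon_yield` and `co2_rate`, plus reporting-precision columns
#'   `rate` (2 dp) and `yield_pct` (1 dp).
#' @export
run_scenarios <- function(model = ecoli_phb_core(),
                          substrates = c("glucose", "xylose", "glycerol"),
                          nog = c(FALSE, TRUE), uptake_rate = 10,
                          out_dir = NULL) {
  bad <- setdiff(substrates, SUBSTRATE_INFO$substrate)
  if (length(bad)) {
    stop("unknown substrate: ", paste(bad, collapse = ", "),
         " (expected glucose, xylose or glycerol)")
  }
  grid <- expand.grid(substrate = substrates, nog = nog,
                      stringsAsFactors = FALSE)
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    scen <- scenario(grid$substrate[i], uptake_rate = uptake_rate,
                     nog = grid$nog[i])
    results[[i]] <- theoretical_max_production(model, scen)
  }
  out <- data.frame(
    substrate = grid$substrate,
    nog = grid$nog,
    uptake_rate = uptake_rate,
    product_rate = vapply(results, `[[`, 0, "product_rate"),
    carbon_yield = vapply(results, `[[`, 0, "carbon_yield"),
    co2_rate = vapply(results, `[[`, 0, "co2_rate"),
    stringsAsFactors = FALSE)
  out$rate <- round(out$product_rate, 2)
  out$yield_pct <- round(100 * out$carbon_yield, 1)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(out, file.path(out_dir, "scenarios.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (i in seq_len(nrow(grid))) {
      rep_i <- flux_report(results[[i]])
      rep_i$flux <- round(rep_i$flux, 4)
      rep_i$min <- round(rep_i$min, 4)
      rep_i$max <- round(rep_i$max, 4)
      utils::write.table(
        rep_i,
        file.path(out_dir, sprintf("fluxes_%s_%s.tsv", grid$substrate[i],
                                   if (grid$nog[i]) "nog" else "base")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' Yield table from a measurement table
#'
#' Computes the carbon yield of each measured sample and, within each
#' `group`, the percent increase of every engineered sample over the
#' group's control.  Yields are reported to two decimals and percent
#' increases to one decimal, and the increase is computed from the
#' two-decimal yields (the precision at which such yields are quoted).
#'
#' @param measurements A data.frame as returned by [read_measurements()],
#'   or a path to such a table.
#' @param out_file Optional TSV output path.
#' @return A data.frame with columns `sample`, `group`, `role`, `yield`
#'   (2 dp), `content_wt_pct` (when `cdw_g_l` is present), and
#'   `increase_pct` (1 dp, engineered rows of groups with a control).
#' @export
run_exp_yields <- function(measurements, out_file = NULL) {
  if (is.character(measurements)) {
    measurements <- read_measurements(measurements)
  }
  if (!nrow(measurements)) {
    warning("empty measurement table; returning empty yield table")
    return(data.frame(sample = character(), group = character(),
                      role = character(), yield = numeric(),
                      increase_pct = numeric(), stringsAsFactors = FALSE))
  }
  sub_cols <- intersect(paste0(SUBSTRATE_INFO$substrate, "_g_l"),
                        names(measurements))
  if (!length(sub_cols)) {
    stop("measurement table has no substrate column (e.g. glycerol_g_l)")
  }
  info <- SUBSTRATE_INFO[match(sub(("_g_l"), "", sub_cols),
                               SUBSTRATE_INFO$substrate), ]
  yields <- vapply(seq_len(nrow(measurements)), function(i) {
    cons <- as.numeric(measurements[i, sub_cols])
    cons[is.na(cons)] <- 0
    experimental_carbon_yield(measurements$phb_g_l[i], cons,
                              info$molar_mass, info$carbons)
  }, numeric(1))
  out <- data.frame(sample = measurements$sample,
                    group = measurements$group,
                    role = measurements$role,
                    yield = round(yields, 2),
                    stringsAsFactors = FALSE)
  if ("cdw_g_l" %in% names(measurements)) {
    out$content_wt_pct <- round(phb_content(measurements$phb_g_l,
                                            measurements$cdw_g_l), 2)
  }
  out$increase_pct <- NA_real_
  for (g in unique(out$group)) {
    rows <- out$group == g
    ctrl <- which(rows & out$role == "control")
    eng <- which(rows & out$role == "engineered")
    if (length(eng) && !length(ctrl)) {
      stop("group '", g, "' has engineered samples but no control")
    }
    if (length(ctrl) > 1L) {
      stop("group '", g, "' has more than one control sample")
    }
    if (length(ctrl) && length(eng)) {
      out$increase_pct[eng] <- round(
        relative_yield_increase(out$yield[ctrl], out$yield[eng]), 1)
    }
  }
  if (all(is.na(out$increase_pct))) out$increase_pct <- NULL
  if (!is.null(out_file)) {
    utils::write.table(out, out_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
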