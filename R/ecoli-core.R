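# Curated E. coli central-carbon core model with the P3HB synthesis
# pathway, built programmatically.  The packaged file
# inst/extdata/ecoli_phb_core.tsv is the serialization of
# build_ecoli_core() with default settings.
#
# Scope: glucose PTS uptake; xylose proton symport + isomerase +
# xylulokinase; glycerol facilitated diffusion with both assimilation
# routes (glpK/glpD to the quinone pool, and gldA dehydrogenase to DHA with
# PEP-dependent dihydroxyacetone kinase and fructose-6-phosphate aldolase
# as DHA entry points); Embden-Meyerhof glycolysis with
# fructose-1,6-bisphosphatase; the full oxidative and non-oxidative
# pentose-phosphate pathway; pyruvate dehydrogenase; the TCA cycle with PEP
# carboxylase anaplerosis; the acetyl-phosphate node (reversible
# phosphotransacetylase, acetate kinase); the phaA/phaB/phaC P3HB pathway
# ending in a monomer drain; a transhydrogenase; and respiration lumped to
# one reaction per electron donor with a configurable P/O ratio.
#
# Metabolite formulas follow the usual ionized-species conventions of
# constraint-based E. coli reconstructions (e.g. glucose 6-phosphate
# C6H11O9P), with explicit protons where deprotonation requires them, so
# that every internal reaction balances for C, H, O, N, P and S.
# Transport steps are modelled without an explicit proton-motive-force
# budget: periplasmic and cytosolic protons interconvert freely and
# respiration is lumped directly to ATP, so symport stoichiometry is
# carried but not energetically charged.

#' Build the curated E. coli P3HB core model
#'
#' Constructs the model in code.  `po_nadh` and `po_quinol` set the ATP
#' yield per NADH or quinol oxidized in the lumped respiratory reactions;
#' `atp_maintenance` sets the lower bound of the ATP maintenance drain
#' (0 for theoretical-maximum analyses).
#'
#' @param po_nadh P/O ratio for NADH oxidation (mol ATP per mol NADH).
#' @param po_quinol P/O ratio for quinol oxidation.
#' @param atp_maintenance Non-growth ATP maintenance flux, mmol gDCW-1 h-1.
#' @return A `stoich_model` with 61 metabolites and 66 reactions.
#' @seealso [ecoli_phb_core()] for the packaged serialization,
#'   [knock_in_nog()] for the phosphoketolase extension.
#' @export
build_ecoli_core <- function(po_nadh = 2.5, po_quinol = 1.5,
                             atp_maintenance = 0) {
  stopifnot(po_nadh >= 0, po_quinol >= 0, atp_maintenance >= 0)
  M <- function(id, name, formula, compartment = "c") {
    data.frame(id = id, name = name, formula = formula,
               compartment = compartment, stringsAsFactors = FALSE)
  }
  metabolites <- rbind(
    # glycolysis / gluconeogenesis
    M("g6p_c", "D-glucose 6-phosphate", "C6H11O9P"),
    M("f6p_c", "D-fructose 6-phosphate", "C6H11O9P"),
    M("fdp_c", "D-fructose 1,6-bisphosphate", "C6H10O12P2"),
    M("dhap_c", "dihydroxyacetone phosphate", "C3H5O6P"),
    M("g3p_c", "glyceraldehyde 3-phosphate", "C3H5O6P"),
    M("13dpg_c", "3-phospho-D-glyceroyl phosphate", "C3H4O10P2"),
    M("3pg_c", "3-phospho-D-glycerate", "C3H4O7P"),
    M("2pg_c", "2-phospho-D-glycerate", "C3H4O7P"),
    M("pep_c", "phosphoenolpyruvate", "C3H2O6P"),
    M("pyr_c", "pyruvate", "C3H3O3"),
    # pentose phosphate pathway
    M("6pgl_c", "6-phospho-D-glucono-1,5-lactone", "C6H9O9P"),
    M("6pgc_c", "6-phospho-D-gluconate", "C6H10O10P"),
    M("ru5p__D_c", "D-ribulose 5-phosphate", "C5H9O8P"),
    M("r5p_c", "D-ribose 5-phosphate", "C5H9O8P"),
    M("xu5p__D_c", "D-xylulose 5-phosphate", "C5H9O8P"),
    M("s7p_c", "sedoheptulose 7-phosphate", "C7H13O10P"),
    M("e4p_c", "D-erythrose 4-phosphate", "C4H7O7P"),
    # xylose assimilation
    M("xyl__D_c", "D-xylose", "C5H10O5"),
    M("xylu__D_c", "D-xylulose", "C5H10O5"),
    # glycerol assimilation
    M("glyc_c", "glycerol", "C3H8O3"),
    M("glyc3p_c", "sn-glycerol 3-phosphate", "C3H7O6P"),
    M("dha_c", "dihydroxyacetone", "C3H6O3"),
    # acetyl-CoA / acetyl-phosphate node and P3HB pathway
    M("accoa_c", "acetyl-CoA", "C23H34N7O17P3S"),
    M("coa_c", "coenzyme A", "C21H32N7O16P3S"),
    M("actp_c", "acetyl phosphate", "C2H3O5P"),
    M("ac_c", "acetate", "C2H3O2"),
    M("aacoa_c", "acetoacetyl-CoA", "C25H36N7O18P3S"),
    M("3hbcoa_c", "(R)-3-hydroxybutyryl-CoA", "C25H38N7O18P3S"),
    M("phb_c", "P3HB monomer unit", "C4H6O2"),
    # TCA cycle
    M("cit_c", "citrate", "C6H5O7"),
    M("icit_c", "isocitrate", "C6H5O7"),
    M("akg_c", "2-oxoglutarate", "C5H4O5"),
    M("succoa_c", "succinyl-CoA", "C25H35N7O19P3S"),
    M("succ_c", "succinate", "C4H4O4"),
    M("fum_c", "fumarate", "C4H2O4"),
    M("mal__L_c", "L-malate", "C4H4O5"),
    M("oaa_c", "oxaloacetate", "C4H2O5"),
    # cofactors and small molecules
    M("nad_c", "NAD+", "C21H26N7O14P2"),
    M("nadh_c", "NADH", "C21H27N7O14P2"),
    M("nadp_c", "NADP+", "C21H25N7O17P3"),
    M("nadph_c", "NADPH", "C21H26N7O17P3"),
    M("atp_c", "ATP", "C10H12N5O13P3"),
    M("adp_c", "ADP", "C10H12N5O10P2"),
    M("amp_c", "AMP", "C10H12N5O7P"),
    M("pi_c", "phosphate", "HO4P"),
    M("q8_c", "ubiquinone-8", "C49H74O4"),
    M("q8h2_c", "ubiquinol-8", "C49H76O4"),
    M("h2o_c", "water", "H2O"),
    M("h_c", "proton", "H"),
    M("co2_c", "carbon dioxide", "CO2"),
    M("o2_c", "oxygen", "O2"),
    # extracellular species
    M("glc__D_e", "D-glucose", "C6H12O6", "e"),
    M("xyl__D_e", "D-xylose", "C5H10O5", "e"),
    M("glyc_e", "glycerol", "C3H8O3", "e"),
    M("o2_e", "oxygen", "O2", "e"),
    M("co2_e", "carbon dioxide", "CO2", "e"),
    M("h2o_e", "water", "H2O", "e"),
    M("pi_e", "phosphate", "HO4P", "e"),
    M("h_e", "proton", "H", "e"),
    M("ac_e", "acetate", "C2H3O2", "e"),
    M("phb_e", "P3HB monomer unit", "C4H6O2", "e")
  )

  rxn <- list()
  R <- function(id, name, eq, lb, ub, sub) {
    list(id = id, name = name, eq = eq, lb = lb, ub = ub, sub = sub)
  }
  U <- 1000 # default flux cap, mmol gDCW-1 h-1
  rxns <- list(
    # --- exchanges (one-sided; positive flux = export) ---------------------
    R("EX_glc__D_e", "glucose exchange", "glc__D_e <->", -U, U, "exchange"),
    R("EX_xyl__D_e", "xylose exchange", "xyl__D_e <->", -U, U, "exchange"),
    R("EX_glyc_e", "glycerol exchange", "glyc_e <->", -U, U, "exchange"),
    R("EX_o2_e", "oxygen exchange", "o2_e <->", -U, U, "exchange"),
    R("EX_co2_e", "carbon dioxide exchange", "co2_e ->", 0, U, "exchange"),
    R("EX_h2o_e", "water exchange", "h2o_e <->", -U, U, "exchange"),
    R("EX_pi_e", "phosphate exchange", "pi_e <->", -U, U, "exchange"),
    R("EX_h_e", "proton exchange", "h_e <->", -U, U, "exchange"),
    R("EX_ac_e", "acetate exchange", "ac_e ->", 0, U, "exchange"),
    R("EX_phb_e", "P3HB monomer drain", "phb_e ->", 0, U, "exchange"),
    # --- transport ---------------------------------------------------------
    R("GLCpts", "glucose PTS", "glc__D_e + pep_c -> g6p_c + pyr_c",
      0, U, "transport"),
    R("XYLt2", "xylose proton symport",
      "h_e + xyl__D_e -> h_c + xyl__D_c", 0, U, "transport"),
    R("GLYCt", "glycerol facilitated diffusion", "glyc_e <-> glyc_c",
      -U, U, "transport"),
    R("O2t", "oxygen diffusion", "o2_e <-> o2_c", -U, U, "transport"),
    R("CO2t", "carbon dioxide diffusion", "co2_c <-> co2_e", -U, U,
      "transport"),
    R("H2Ot", "water diffusion", "h2o_c <-> h2o_e", -U, U, "transport"),
    R("PIt", "phosphate transport", "pi_e <-> pi_c", -U, U, "transport"),
    R("Ht", "proton diffusion", "h_e <-> h_c", -U, U, "transport"),
    R("ACt", "acetate export", "ac_c <-> ac_e", -U, U, "transport"),
    R("PHBt", "P3HB monomer export", "phb_c -> phb_e", 0, U, "transport"),
    # --- glycolysis / gluconeogenesis --------------------------------------
    R("PGI", "glucose-6-phosphate isomerase", "g6p_c <-> f6p_c", -U, U,
      "glycolysis"),
    R("PFK", "phosphofructokinase",
      "atp_c + f6p_c -> adp_c + fdp_c + h_c", 0, U, "glycolysis"),
    R("FBP", "fructose-1,6-bisphosphatase",
      "fdp_c + h2o_c -> f6p_c + pi_c", 0, U, "glycolysis"),
    R("FBA", "fructose-bisphosphate aldolase", "fdp_c <-> dhap_c + g3p_c",
      -U, U, "glycolysis"),
    R("TPI", "triose-phosphate isomerase", "dhap_c <-> g3p_c", -U, U,
      "glycolysis"),
    R("GAPD", "glyceraldehyde-3-phosphate dehydrogenase",
      "g3p_c + nad_c + pi_c <-> 13dpg_c + h_c + nadh_c", -U, U,
      "glycolysis"),
    R("PGK", "phosphoglycerate kinase", "13dpg_c + adp_c <-> 3pg_c + atp_c",
      -U, U, "glycolysis"),
    R("PGM", "phosphoglycerate mutase", "3pg_c <-> 2pg_c", -U, U,
      "glycolysis"),
    R("ENO", "enolase", "2pg_c <-> h2o_c + pep_c", -U, U, "glycolysis"),
    R("PYK", "pyruvate kinase", "adp_c + h_c + pep_c -> atp_c + pyr_c",
      0, U, "glycolysis"),
    R("PPS", "phosphoenolpyruvate synthase",
      "atp_c + h2o_c + pyr_c -> amp_c + 2 h_c + pep_c + pi_c", 0, U,
      "glycolysis"),
    R("ADK1", "adenylate kinase", "amp_c + atp_c <-> 2 adp_c", -U, U,
      "energy"),
    # --- pentose phosphate pathway -----------------------------------------
    R("G6PDH2", "glucose-6-phosphate dehydrogenase",
      "g6p_c + nadp_c -> 6pgl_c + h_c + nadph_c", 0, U, "PPP"),
    R("PGL", "6-phosphogluconolactonase", "6pgl_c + h2o_c -> 6pgc_c + h_c",
      0, U, "PPP"),
    R("GND", "6-phosphogluconate dehydrogenase",
      "6pgc_c + nadp_c -> co2_c + nadph_c + ru5p__D_c", 0, U, "PPP"),
    R("RPI", "ribose-5-phosphate isomerase", "r5p_c <-> ru5p__D_c", -U, U,
      "PPP"),
    R("RPE", "ribulose-5-phosphate 3-epimerase",
      "ru5p__D_c <-> xu5p__D_c", -U, U, "PPP"),
    R("TKT1", "transketolase 1", "r5p_c + xu5p__D_c <-> g3p_c + s7p_c",
      -U, U, "PPP"),
    R("TKT2", "transketolase 2", "e4p_c + xu5p__D_c <-> f6p_c + g3p_c",
      -U, U, "PPP"),
    R("TALA", "transaldolase", "g3p_c + s7p_c <-> e4p_c + f6p_c", -U, U,
      "PPP"),
    # --- xylose assimilation -----------------------------------------------
    R("XYLI1", "xylose isomerase", "xyl__D_c <-> xylu__D_c", -U, U,
      "xylose"),
    R("XYLK", "xylulokinase",
      "atp_c + xylu__D_c -> adp_c + h_c + xu5p__D_c", 0, U, "xylose"),
    # --- glycerol assimilation ---------------------------------------------
    R("GLYK", "glycerol kinase",
      "atp_c + glyc_c -> adp_c + glyc3p_c + h_c", 0, U, "glycerol"),
    R("G3PD5", "glycerol-3-phosphate dehydrogenase (quinone)",
      "glyc3p_c + q8_c -> dhap_c + q8h2_c", 0, U, "glycerol"),
    R("GLYCDx", "glycerol dehydrogenase",
      "glyc_c + nad_c <-> dha_c + h_c + nadh_c", -U, U, "glycerol"),
    R("DHAPT", "dihydroxyacetone kinase (PEP)",
      "dha_c + pep_c -> dhap_c + pyr_c", 0, U, "glycerol"),
    R("F6PA", "fructose-6-phosphate aldolase",
      "f6p_c <-> dha_c + g3p_c", -U, U, "glycerol"),
    # --- pyruvate dehydrogenase and acetyl-phosphate node ------------------
    R("PDH", "pyruvate dehydrogenase",
      "coa_c + nad_c + pyr_c -> accoa_c + co2_c + nadh_c", 0, U,
      "pyruvate"),
    R("PTAr", "phosphotransacetylase", "accoa_c + pi_c <-> actp_c + coa_c",
      -U, U, "acetate"),
    R("ACKr", "acetate kinase", "ac_c + atp_c <-> actp_c + adp_c", -U, U,
      "acetate"),
    # --- P3HB synthesis ----------------------------------------------------
    R("PHAA", "acetyl-CoA acetyltransferase (phaA)",
      "2 accoa_c <-> aacoa_c + coa_c", -U, U, "PHB"),
    R("PHAB", "acetoacetyl-CoA reductase (phaB)",
      "aacoa_c + h_c + nadph_c -> 3hbcoa_c + nadp_c", 0, U, "PHB"),
    R("PHAC", "PHA synthase monomer drain (phaC)",
      "3hbcoa_c -> coa_c + phb_c", 0, U, "PHB"),
    # --- TCA cycle and anaplerosis -----------------------------------------
    R("CS", "citrate synthase",
      "accoa_c + h2o_c + oaa_c -> cit_c + coa_c + h_c", 0, U, "TCA"),
    R("ACONT", "aconitase", "cit_c <-> icit_c", -U, U, "TCA"),
    R("ICDHy", "isocitrate dehydrogenase (NADP)",
      "icit_c + nadp_c -> akg_c + co2_c + nadph_c", 0, U, "TCA"),
    R("AKGDH", "2-oxoglutarate dehydrogenase",
      "akg_c + coa_c + nad_c -> co2_c + nadh_c + succoa_c", 0, U, "TCA"),
    R("SUCOAS", "succinyl-CoA synthetase",
      "adp_c + pi_c + succoa_c <-> atp_c + coa_c + succ_c", -U, U, "TCA"),
    R("SUCDi", "succinate dehydrogenase", "q8_c + succ_c -> fum_c + q8h2_c",
      0, U, "TCA"),
    R("FUM", "fumarase", "fum_c + h2o_c <-> mal__L_c", -U, U, "TCA"),
    R("MDH", "malate dehydrogenase",
      "mal__L_c + nad_c <-> h_c + nadh_c + oaa_c", -U, U, "TCA"),
    R("PPC", "PEP carboxylase",
      "co2_c + h2o_c + pep_c -> h_c + oaa_c + pi_c", 0, U, "anaplerosis"),
    # --- energy metabolism -------------------------------------------------
    R("NADHOR", "NADH oxidation lumped to ATP synthesis",
      sprintf(paste("%s adp_c + %s h_c + nadh_c + 0.5 o2_c + %s pi_c ->",
                    "%s atp_c + %s h2o_c + nad_c"),
              fmt_num(po_nadh), fmt_num(po_nadh + 1), fmt_num(po_nadh),
              fmt_num(po_nadh), fmt_num(po_nadh + 1)),
      0, U, "oxphos"),
    R("QUINOR", "ubiquinol oxidation lumped to ATP synthesis",
      sprintf(paste("%s adp_c + %s h_c + 0.5 o2_c + %s pi_c + q8h2_c ->",
                    "%s atp_c + %s h2o_c + q8_c"),
              fmt_num(po_quinol), fmt_num(po_quinol), fmt_num(po_quinol),
              fmt_num(po_quinol), fmt_num(po_quinol + 1)),
      0, U, "oxphos"),
    R("THD", "transhydrogenase (uncoupled lump)",
      "nadh_c + nadp_c <-> nad_c + nadph_c", -U, U, "energy"),
    R("ATPM", "ATP maintenance drain",
      "atp_c + h2o_c -> adp_c + h_c + pi_c", atp_maintenance, U, "energy")
  )

  reactions <- do.call(rbind, lapply(rxns, function(r) {
    eq <- parse_equation(r$eq, r$id)
    data.frame(id = r$id, name = r$name, lower_bound = r$lb,
               upper_bound = r$ub, subsystem = r$sub,
               is_exchange = eq$one_sided, stringsAsFactors = FALSE)
  }))
  stoich <- do.call(rbind, lapply(rxns, function(r) {
    eq <- parse_equation(r$eq, r$id)
    data.frame(reaction = r$id, metabolite = names(eq$stoich),
               coefficient = as.numeric(eq$stoich), stringsAsFactors = FALSE)
  }))

  stoich_model(
    metabolites, reactions, stoich,
    objective_candidates = "EX_phb_e",
    name = "ecoli_phb_core",
    version = sprintf("1.0 (P/O NADH %s, quinol %s, maintenance %s)",
                      fmt_num(po_nadh), fmt_num(po_quinol),
                      fmt_num(atp_maintenance)))
}

#' Load the packaged curated core model
#'
#' Reads `inst/extdata/ecoli_phb_core.tsv`, the serialization of
#' [build_ecoli_core()] with default settings (the format of record).
#'
#' @return A `stoich_model`.
#' @export
ecoli_phb_core <- function() {
  path <- system.file("extdata", "ecoli_phb_core.tsv", package = "phbflux",
                      mustWork = TRUE)
  read_model(path, format = "table")
}

#' Knock the non-oxidative glycolysis (NOG) pathway into a model
#'
#' Adds the two phosphoketolase reactions that define the NOG design:
#' F6P phosphoketolase (`FPK`: f6p + pi -> e4p + acetyl phosphate + h2o)
#' and X5P phosphoketolase (`XPK`: xu5p + pi -> g3p + acetyl phosphate +
#' h2o), and ensures the native fructose-1,6-bisphosphatase (`FBP`) is
#' present with an open forward bound, since the NOG cycle requires it to
#' return triose phosphates to the hexose pool.  The input model is not
#' modified.
#'
#' @param model A `stoich_model` without phosphoketolase reactions.
#' @return A new model with exactly two added reactions (subsystem
#'   `"NOG"`); all pre-existing coefficients and bounds are untouched
#'   except a closed `FBP` upper bound, which is opened.
#' @export
knock_in_nog <- function(model) {
  validate_model(model)
  present <- intersect(c("FPK", "XPK"), model$reactions$id)
  if (length(present) || any(model$reactions$subsystem == "NOG")) {
    stop("model already contains the NOG phosphoketolase knock-in")
  }
  need <- c("f6p_c", "xu5p__D_c", "e4p_c", "g3p_c", "actp_c", "pi_c",
            "h2o_c")
  missing <- setdiff(need, model$metabolites$id)
  if (length(missing)) {
    stop("model lacks metabolites required for the NOG knock-in: ",
         paste(missing, collapse = ", "))
  }
  i <- match("FBP", model$reactions$id)
  if (is.na(i)) {
    stop("model lacks fructose-1,6-bisphosphatase (FBP), required by NOG")
  }
  if (model$reactions$upper_bound[i] <= 0) {
    model <- set_bounds(model, "FBP", upper = 1000)
  }
  model <- add_reaction(
    model, "FPK", "fructose-6-phosphate phosphoketolase (fxpk)",
    c(f6p_c = -1, pi_c = -1, e4p_c = 1, actp_c = 1, h2o_c = 1),
    0, 1000, subsystem = "NOG")
  model <- add_reaction(
    model, "XPK", "xylulose-5-phosphate phosphoketolase (fxpk)",
    c(xu5p__D_c = -1, pi_c = -1, g3p_c = 1, actp_c = 1, h2o_c = 1),
    0, 1000, subsystem = "NOG")
  validate_model(model)
  model
}
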