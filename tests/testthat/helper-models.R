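# Shared fixtures, all built in code.

# the packaged curated model, loaded once per test run
core_model <- function() {
  env <- globalenv()
  if (is.null(env$.phbflux_core)) {
    env$.phbflux_core <- ecoli_phb_core()
  }
  env$.phbflux_core
}

# chain with two parallel identical conversions, for alternate-optima tests
parallel_routes_model <- function() {
  mets <- data.frame(id = c("a", "b"), name = c("a", "b"), formula = "C",
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_in", "R1a", "R1b", "EX_out"),
    name = c("uptake", "route a", "route b", "export"),
    lower_bound = c(-10, 0, 0, 0), upper_bound = c(0, 1000, 1000, 1000),
    subsystem = c("exchange", "chain", "chain", "exchange"),
    is_exchange = c(TRUE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  st <- data.frame(
    reaction = c("EX_in", "R1a", "R1a", "R1b", "R1b", "EX_out"),
    metabolite = c("a", "a", "b", "a", "b", "b"),
    coefficient = c(-1, -1, 1, -1, 1, -1), stringsAsFactors = FALSE)
  stoich_model(mets, rxns, st, objective_candidates = "EX_out",
               name = "parallel", version = "1")
}

# minimal SBML serialization of a linear chain, written to a temp file
write_chain_sbml <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '      level="3" version="1" fbc:required="false">',
    '  <model id="chain" name="chain">',
    '    <listOfParameters>',
    '      <parameter id="lb_up" value="-10" constant="true"/>',
    '      <parameter id="lb_0" value="0" constant="true"/>',
    '      <parameter id="ub_def" value="1000" constant="true"/>',
    '    </listOfParameters>',
    '    <listOfSpecies>',
    '      <species id="s0" compartment="c" fbc:chemicalFormula="C"/>',
    '      <species id="s1" compartment="c" fbc:chemicalFormula="C"/>',
    '    </listOfSpecies>',
    '    <listOfReactions>',
    '      <reaction id="EX_in" reversible="true"',
    '                fbc:lowerFluxBound="lb_up" fbc:upperFluxBound="lb_0">',
    '        <listOfReactants>',
    '          <speciesReference species="s0" stoichiometry="1"/>',
    '        </listOfReactants>',
    '      </reaction>',
    '      <reaction id="R1" reversible="false"',
    '                fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_def">',
    '        <listOfReactants>',
    '          <speciesReference species="s0" stoichiometry="1"/>',
    '        </listOfReactants>',
    '        <listOfProducts>',
    '          <speciesReference species="s1" stoichiometry="1"/>',
    '        </listOfProducts>',
    '      </reaction>',
    '      <reaction id="EX_out" reversible="false"',
    '                fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_def">',
    '        <listOfReactants>',
    '          <speciesReference species="s1" stoichiometry="1"/>',
    '        </listOfReactants>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>'), path)
  path
}

# run all substrate x NOG scenarios on the packaged model, once per run
all_scenarios <- function() {
  env <- globalenv()
  if (is.null(env$.phbflux_scen)) {
    m <- core_model()
    grid <- expand.grid(substrate = c("glucose", "xylose", "glycerol"),
                        nog = c(FALSE, TRUE), stringsAsFactors = FALSE)
    env$.phbflux_scen <- lapply(seq_len(nrow(grid)), function(i) {
      theoretical_max_production(
        m, scenario(grid$substrate[i], uptake_rate = 10, nog = grid$nog[i]))
    })
  }
  env$.phbflux_scen
}
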