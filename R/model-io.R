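# Model file I/O.
#
# Native format of record: a tab-separated plain-text file with two
# sections.  Header comment lines record name, version, section sizes and
# objective candidates; the [metabolites] section lists id, name, formula,
# compartment; the [reactions] section lists id, name, an equation string,
# bounds and subsystem.  Equations use "->" / "<->" arrows and "+"-joined
# "coef met" terms; exchange reactions are written one-sided
# ("xyl__D_e <->").  Reversibility is carried by the bounds; the arrow is
# cosmetic.  An SBML Level 3 (fbc) importer is provided as a convenience.

fmt_num <- function(x) {
  # 17 significant digits: doubles survive the write/read round trip exactly
  format(x, digits = 17, trim = TRUE, scientific = FALSE)
}

# internal: equation string for one reaction
format_equation <- function(model, rxn_id) {
  st <- reaction_stoich(model, rxn_id)
  term <- function(coefs) {
    paste(vapply(seq_along(coefs), function(i) {
      cf <- abs(coefs[i])
      if (cf == 1) names(coefs)[i] else paste(fmt_num(cf), names(coefs)[i])
    }, character(1)), collapse = " + ")
  }
  lhs <- st[st < 0]
  rhs <- st[st > 0]
  i <- match(rxn_id, model$reactions$id)
  arrow <- if (model$reactions$lower_bound[i] < 0) "<->" else "->"
  paste(term(lhs), arrow, term(rhs))
}

# internal: parse "2 a + b -> c" into a named coefficient vector
parse_equation <- function(eq, rxn_id = "?") {
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->" else if
    (grepl("->", eq, fixed = TRUE)) "->" else
    stop(sprintf("reaction %s: equation has no '->' or '<->' arrow: '%s'",
                 rxn_id, eq))
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) {
    stop(sprintf("reaction %s: malformed equation '%s'", rxn_id, eq))
  }
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(side, " + ", fixed = TRUE)[[1]])
    coefs <- numeric(length(terms))
    mets <- character(length(terms))
    for (i in seq_along(terms)) {
      parts <- strsplit(terms[i], "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        coefs[i] <- 1
        mets[i] <- parts
      } else if (length(parts) == 2L) {
        cf <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(cf)) {
          stop(sprintf("reaction %s: cannot parse coefficient in term '%s'",
                       rxn_id, terms[i]))
        }
        coefs[i] <- cf
        mets[i] <- parts[2]
      } else {
        stop(sprintf("reaction %s: cannot parse term '%s'", rxn_id, terms[i]))
      }
    }
    stats::setNames(sign * coefs, mets)
  }
  out <- c(parse_side(sides[1], -1), parse_side(sides[2], +1))
  if (!length(out)) {
    stop(sprintf("reaction %s: equation has no metabolites", rxn_id))
  }
  dup <- names(out)[duplicated(names(out))]
  if (length(dup)) {
    stop(sprintf("reaction %s: metabolite appears twice in equation: %s",
                 rxn_id, paste(dup, collapse = ", ")))
  }
  list(stoich = out, one_sided = !nzchar(trimws(sides[1])) ||
         !nzchar(trimws(sides[2])))
}

#' Write a model in the native table format
#'
#' @param model A `stoich_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(model, path) {
  validate_model(model)
  lines <- c(
    sprintf("# model: %s", model$name),
    sprintf("# version: %s", model$version),
    sprintf("# metabolites: %d", nrow(model$metabolites)),
    sprintf("# reactions: %d", nrow(model$reactions)),
    sprintf("# objective_candidates: %s",
            paste(model$objective_candidates, collapse = ",")),
    "[metabolites]",
    "id\tname\tformula\tcompartment",
    sprintf("%s\t%s\t%s\t%s", model$metabolites$id, model$metabolites$name,
            model$metabolites$formula, model$metabolites$compartment),
    "[reactions]",
    "id\tname\tequation\tlower_bound\tupper_bound\tsubsystem",
    vapply(seq_len(nrow(model$reactions)), function(i) {
      id <- model$reactions$id[i]
      sprintf("%s\t%s\t%s\t%s\t%s\t%s", id, model$reactions$name[i],
              format_equation(model, id),
              fmt_num(model$reactions$lower_bound[i]),
              fmt_num(model$reactions$upper_bound[i]),
              model$reactions$subsystem[i])
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a model file
#'
#' Reads either the package's native tab-separated format (the format of
#' record, see [write_model()]) or a minimal SBML Level 3 document with the
#' `fbc` flux-bound extension.
#'
#' @param path Path to the model file.
#' @param format `"table"` (native) or `"sbml"`.
#' @return A `stoich_model`.
#' @export
read_model <- function(path, format = c("table", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file does not exist: ", path)
  switch(format, table = read_model_table(path), sbml = read_sbml(path))
}

read_model_table <- function(path) {
  lines <- readLines(path)
  header <- function(key, required = TRUE) {
    pat <- paste0("^# ", key, ": ?")
    hit <- grep(pat, lines, value = TRUE)
    if (!length(hit)) {
      if (required) stop("missing header line '# ", key, ":' in ", path)
      return(NA_character_)
    }
    sub(pat, "", hit[1])
  }
  name <- header("model")
  version <- header("version")
  n_met <- as.integer(header("metabolites"))
  n_rxn <- as.integer(header("reactions"))
  obj <- header("objective_candidates")
  obj <- if (is.na(obj) || !nzchar(obj)) character() else
    strsplit(obj, ",", fixed = TRUE)[[1]]

  sec_met <- which(lines == "[metabolites]")
  sec_rxn <- which(lines == "[reactions]")
  if (length(sec_met) != 1L || length(sec_rxn) != 1L || sec_met > sec_rxn) {
    stop("model file must contain one [metabolites] and one [reactions] ",
         "section, in that order: ", path)
  }
  body <- function(from, to) {
    blk <- lines[seq(from, to)]
    blk <- blk[!grepl("^#", blk) & nzchar(trimws(blk))]
    if (length(blk) < 1L) stop("empty section in model file: ", path)
    blk
  }
  met_lines <- body(sec_met + 1L, sec_rxn - 1L)
  rxn_lines <- body(sec_rxn + 1L, length(lines))

  split_cols <- function(ln, n, what, lineno) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != n) {
      stop(sprintf("line %d: expected %d tab-separated fields in %s row, got %d",
                   lineno, n, what, length(parts)))
    }
    parts
  }
  met_header <- strsplit(met_lines[1], "\t")[[1]]
  if (!identical(met_header, c("id", "name", "formula", "compartment"))) {
    stop("unexpected metabolite column header in ", path)
  }
  met_rows <- lapply(seq_along(met_lines[-1]), function(i) {
    split_cols(met_lines[-1][i], 4L, "metabolite", i)
  })
  metabolites <- data.frame(
    id = vapply(met_rows, `[`, "", 1), name = vapply(met_rows, `[`, "", 2),
    formula = vapply(met_rows, `[`, "", 3),
    compartment = vapply(met_rows, `[`, "", 4), stringsAsFactors = FALSE)

  rxn_header <- strsplit(rxn_lines[1], "\t")[[1]]
  if (!identical(rxn_header, c("id", "name", "equation", "lower_bound",
                               "upper_bound", "subsystem"))) {
    stop("unexpected reaction column header in ", path)
  }
  rxn_rows <- lapply(seq_along(rxn_lines[-1]), function(i) {
    split_cols(rxn_lines[-1][i], 6L, "reaction", i)
  })
  st <- list()
  reactions <- data.frame(
    id = character(), name = character(), lower_bound = numeric(),
    upper_bound = numeric(), subsystem = character(),
    is_exchange = logical(), stringsAsFactors = FALSE)
  for (row in rxn_rows) {
    id <- row[1]
    eq <- parse_equation(row[3], id)
    lb <- suppressWarnings(as.numeric(row[4]))
    ub <- suppressWarnings(as.numeric(row[5]))
    if (is.na(lb) || is.na(ub)) {
      stop(sprintf("reaction %s: non-numeric bounds '%s'/'%s'",
                   id, row[4], row[5]))
    }
    reactions <- rbind(reactions, data.frame(
      id = id, name = row[2], lower_bound = lb, upper_bound = ub,
      subsystem = row[6], is_exchange = eq$one_sided,
      stringsAsFactors = FALSE))
    st[[id]] <- data.frame(reaction = id, metabolite = names(eq$stoich),
                           coefficient = as.numeric(eq$stoich),
                           stringsAsFactors = FALSE)
  }
  if (!is.na(n_met) && n_met != nrow(metabolites)) {
    stop(sprintf("header declares %d metabolites but file has %d",
                 n_met, nrow(metabolites)))
  }
  if (!is.na(n_rxn) && n_rxn != nrow(reactions)) {
    stop(sprintf("header declares %d reactions but file has %d",
                 n_rxn, nrow(reactions)))
  }
  stoich_model(metabolites, reactions, do.call(rbind, st),
               objective_candidates = obj, name = name, version = version)
}

#' Import a minimal SBML Level 3 model
#'
#' Reads species (with `fbc:chemicalFormula`), reactions, stoichiometry
#' and fbc flux bounds from an SBML L3 document.  Exchange reactions are
#' recognised by a one-sided equation or an `EX_` id prefix.  This importer
#' covers the subset of SBML needed to exchange small constraint-based
#' models; the native table format is the format of record.
#'
#' @param path Path to an SBML file.
#' @return A `stoich_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[["d1"]],
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) stop("no <model> element in ", path)

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("no species in SBML file ", path)
  metabolites <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns = ns),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("no reactions in SBML file ", path)
  st <- list()
  rxns <- data.frame(
    id = character(), name = character(), lower_bound = numeric(),
    upper_bound = numeric(), subsystem = character(),
    is_exchange = logical(), stringsAsFactors = FALSE)
  for (node in rx) {
    id <- xml2::xml_attr(node, "id")
    nm <- xml2::xml_attr(node, "name")
    if (is.na(nm)) nm <- id
    refs <- function(xp, sign) {
      sr <- xml2::xml_find_all(node, xp, ns)
      if (!length(sr)) return(NULL)
      data.frame(reaction = id,
                 metabolite = xml2::xml_attr(sr, "species"),
                 coefficient = sign * as.numeric(
                   ifelse(is.na(xml2::xml_attr(sr, "stoichiometry")), "1",
                          xml2::xml_attr(sr, "stoichiometry"))),
                 stringsAsFactors = FALSE)
    }
    rows <- rbind(refs("./s:listOfReactants/s:speciesReference", -1),
                  refs("./s:listOfProducts/s:speciesReference", +1))
    if (is.null(rows)) stop("reaction ", id, " has no metabolites in ", path)
    lb_ref <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns = ns)
    ub_ref <- xml2::xml_attr(node, "fbc:upperFluxBound", ns = ns)
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_val)) par_val[[lb_ref]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_val)) par_val[[ub_ref]]
          else 1000
    one_sided <- !any(rows$coefficient < 0) || !any(rows$coefficient > 0)
    rxns <- rbind(rxns, data.frame(
      id = id, name = nm, lower_bound = lb, upper_bound = ub,
      subsystem = "", is_exchange = one_sided || startsWith(id, "EX_"),
      stringsAsFactors = FALSE))
    st[[id]] <- rows
  }
  nm <- xml2::xml_attr(model_node, "name")
  if (is.na(nm)) nm <- xml2::xml_attr(model_node, "id")
  stoich_model(metabolites, rxns, do.call(rbind, st),
               name = if (is.na(nm)) "sbml model" else nm, version = "1")
}
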