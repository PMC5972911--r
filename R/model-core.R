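# Core data structures: metabolites, reactions, stoichiometric models.
#
# A model is a plain list with class "stoich_model":
#   metabolites     data.frame(id, name, formula, compartment)
#   reactions       data.frame(id, name, lower_bound, upper_bound,
#                              subsystem, is_exchange)
#   stoichiometry   data.frame(reaction, metabolite, coefficient), long form;
#                   negative coefficient = consumed, positive = produced
#   objective_candidates  character vector of reaction ids
#   name, version   metadata strings
#
# Fluxes are in mmol gDCW^-1 h^-1 throughout.

#' Parse an elemental formula string
#'
#' Parses a Hill-style formula such as `"C6H11O9P"` into a named integer
#' vector of element counts.  Counts must be non-negative integers; an
#' omitted count means 1.
#'
#' @param formula A single formula string (e.g. `"C4H6O2"`).
#' @return Named integer vector, one entry per element symbol.
#' @examples
#' parse_formula("C4H6O2")
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L || is.na(formula) || !nzchar(formula)) {
    stop("formula must be a single non-empty string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop(sprintf("cannot parse formula '%s'", formula))
  }
  elem <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Za-z]+", "", toks)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  out <- tapply(cnt, elem, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Number of atoms of one element in a formula
#'
#' @param formula Formula string or vector of formula strings.
#' @param element Element symbol, default `"C"`.
#' @return Integer vector of counts (0 when the element is absent).
#' @export
element_count <- function(formula, element = "C") {
  vapply(formula, function(f) {
    counts <- parse_formula(f)
    if (element %in% names(counts)) counts[[element]] else 0L
  }, integer(1), USE.NAMES = FALSE)
}

#' Construct a stoichiometric model
#'
#' Low-level constructor used by the file readers and network generators.
#' Checks all structural invariants: unique ids, resolvable metabolite
#' references, non-zero coefficients, at least one metabolite per reaction
#' and ordered bounds.
#'
#' @param metabolites data.frame with columns `id`, `name`, `formula`,
#'   `compartment`.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `subsystem`, `is_exchange`.
#' @param stoichiometry data.frame with columns `reaction`, `metabolite`,
#'   `coefficient` (negative = consumed).
#' @param objective_candidates Character vector of reaction ids that are
#'   sensible FBA objectives.
#' @param name,version Metadata strings.
#' @return Object of class `stoich_model`.
#' @export
stoich_model <- function(metabolites, reactions, stoichiometry,
                         objective_candidates = character(),
                         name = "model", version = "1") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stoichiometry <- as.data.frame(stoichiometry, stringsAsFactors = FALSE)
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  rownames(stoichiometry) <- NULL
  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry,
         objective_candidates = objective_candidates,
         name = name, version = version),
    class = "stoich_model")
  validate_model(model)
  model
}

#' Validate the structural invariants of a model
#'
#' Stops with an informative error on the first violated invariant:
#' duplicate metabolite or reaction ids, stoichiometry rows referencing
#' unknown ids, zero coefficients, reactions with no metabolites, or
#' `lower_bound > upper_bound`.
#'
#' @param model A `stoich_model`.
#' @return The model, invisibly.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  st <- model$stoichiometry
  need_m <- c("id", "name", "formula", "compartment")
  need_r <- c("id", "name", "lower_bound", "upper_bound", "subsystem",
              "is_exchange")
  if (!all(need_m %in% names(mets))) {
    stop("metabolite table must have columns: ", paste(need_m, collapse = ", "))
  }
  if (!all(need_r %in% names(rxns))) {
    stop("reaction table must have columns: ", paste(need_r, collapse = ", "))
  }
  dup <- mets$id[duplicated(mets$id)]
  if (length(dup)) stop("duplicate metabolite id: ", paste(unique(dup), collapse = ", "))
  dup <- rxns$id[duplicated(rxns$id)]
  if (length(dup)) stop("duplicate reaction id: ", paste(unique(dup), collapse = ", "))
  unknown <- setdiff(st$metabolite, mets$id)
  if (length(unknown)) {
    stop("stoichiometry references unknown metabolite: ",
         paste(unknown, collapse = ", "))
  }
  unknown <- setdiff(st$reaction, rxns$id)
  if (length(unknown)) {
    stop("stoichiometry references unknown reaction: ",
         paste(unknown, collapse = ", "))
  }
  if (any(st$coefficient == 0)) {
    bad <- unique(st$reaction[st$coefficient == 0])
    stop("zero stoichiometric coefficient in reaction: ",
         paste(bad, collapse = ", "))
  }
  empty <- setdiff(rxns$id, unique(st$reaction))
  if (length(empty)) {
    stop("reaction with no metabolites (all-zero column): ",
         paste(empty, collapse = ", "))
  }
  bad <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  if (length(bad)) {
    stop("lower_bound > upper_bound for reaction: ", paste(bad, collapse = ", "))
  }
  dupst <- duplicated(st[, c("reaction", "metabolite")])
  if (any(dupst)) {
    stop("duplicate stoichiometry entry for reaction: ",
         paste(unique(st$reaction[dupst]), collapse = ", "))
  }
  unknown <- setdiff(model$objective_candidates, rxns$id)
  if (length(unknown)) {
    stop("objective candidate is not a reaction: ", paste(unknown, collapse = ", "))
  }
  invisible(model)
}

#' Stoichiometric (constraint) matrix of a model
#'
#' Rows are metabolites, columns are reactions; entry (i, j) is the signed
#' coefficient of metabolite i in reaction j.  The model sizes here are
#' small (tens of reactions), so a dense base matrix is used.
#'
#' @param model A `stoich_model`.
#' @return Numeric matrix with metabolite ids as rownames and reaction ids
#'   as colnames.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  S[cbind(model$stoichiometry$metabolite, model$stoichiometry$reaction)] <-
    model$stoichiometry$coefficient
  S
}

#' Carbon count of each metabolite in a model
#'
#' @param model A `stoich_model`.
#' @return Named integer vector of carbon atoms per metabolite id.
#' @export
carbon_counts <- function(model) {
  stats::setNames(element_count(model$metabolites$formula, "C"),
                  model$metabolites$id)
}

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("<stoich_model> %s (version %s)\n", x$name, x$version))
  cat(sprintf("  metabolites: %d\n", nrow(x$metabolites)))
  cat(sprintf("  reactions:   %d (%d exchange)\n", nrow(x$reactions),
              sum(x$reactions$is_exchange)))
  if (length(x$objective_candidates)) {
    cat("  objective candidates:", paste(x$objective_candidates, collapse = ", "),
        "\n")
  }
  invisible(x)
}

# internal: named stoichiometry vector of one reaction
reaction_stoich <- function(model, rxn_id) {
  rows <- model$stoichiometry$reaction == rxn_id
  stats::setNames(model$stoichiometry$coefficient[rows],
                  model$stoichiometry$metabolite[rows])
}

# internal: bounds as named vectors
model_bounds <- function(model) {
  list(lb = stats::setNames(model$reactions$lower_bound, model$reactions$id),
       ub = stats::setNames(model$reactions$upper_bound, model$reactions$id))
}

#' Set flux bounds on a reaction
#'
#' @param model A `stoich_model`.
#' @param reaction Reaction id.
#' @param lower,upper New bounds; `NULL` leaves the bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction, lower = NULL, upper = NULL) {
  i <- match(reaction, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", reaction)
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  if (model$reactions$lower_bound[i] > model$reactions$upper_bound[i]) {
    stop("lower_bound > upper_bound for reaction: ", reaction)
  }
  model
}

# internal: add one reaction to a model from a named stoichiometry vector
add_reaction <- function(model, id, name, stoich, lower, upper,
                         subsystem = "", is_exchange = FALSE) {
  if (id %in% model$reactions$id) stop("duplicate reaction id: ", id)
  unknown <- setdiff(names(stoich), model$metabolites$id)
  if (length(unknown)) {
    stop("reaction ", id, " references unknown metabolite: ",
         paste(unknown, collapse = ", "))
  }
  model$reactions <- rbind(model$reactions, data.frame(
    id = id, name = name, lower_bound = lower, upper_bound = upper,
    subsystem = subsystem, is_exchange = is_exchange,
    stringsAsFactors = FALSE))
  model$stoichiometry <- rbind(model$stoichiometry, data.frame(
    reaction = id, metabolite = names(stoich),
    coefficient = as.numeric(stoich), stringsAsFactors = FALSE))
  rownames(model$reactions) <- NULL
  rownames(model$stoichiometry) <- NULL
  model
}
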