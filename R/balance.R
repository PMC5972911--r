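# Elemental-balance validation.
#
# Every internal (non-exchange) reaction of a mass-balanced model must
# conserve each chemical element; exchange reactions move matter across the
# system boundary and are exempt.  Carbon conservation of every internal
# reaction is what makes the carbon-yield arithmetic exact: at steady state
# the only way carbon can leave the network is through an exchange flux,
# so CO2 release fully accounts for the gap between substrate carbon and
# product carbon.

#' Validate elemental balance of all internal reactions
#'
#' For each non-exchange reaction, computes the signed imbalance
#' `sum(coefficient * atom count)` for each requested element.  A reaction
#' passes when all imbalances are zero; exchange reactions are listed as
#' exempt.
#'
#' @param model A `stoich_model`.
#' @param elements Character vector of element symbols to check.
#' @return A `balance_report`: list with `imbalance` (matrix, internal
#'   reactions x elements), `exempt` (exchange reaction ids), `pass`
#'   (logical), and `failed` (ids of unbalanced reactions).
#' @examples
#' m <- generate_linear_chain(2)
#' validate_elemental_balance(m, "C")$pass
#' @export
validate_elemental_balance <- function(model,
                                       elements = c("C", "H", "O", "N", "P", "S")) {
  validate_model(model)
  used <- unique(model$stoichiometry$metabolite)
  mets <- model$metabolites[model$metabolites$id %in% used, ]
  bad <- mets$id[is.na(mets$formula) | !nzchar(mets$formula)]
  if (length(bad)) {
    stop("metabolite with missing formula: ", paste(bad, collapse = ", "))
  }
  E <- matrix(0, nrow(model$metabolites), length(elements),
              dimnames = list(model$metabolites$id, elements))
  for (el in elements) {
    E[, el] <- element_count(model$metabolites$formula, el)
  }
  S <- stoich_matrix(model)
  internal <- model$reactions$id[!model$reactions$is_exchange]
  exempt <- model$reactions$id[model$reactions$is_exchange]
  imbalance <- t(S[, internal, drop = FALSE]) %*% E
  # coefficients are rationals entered as decimals; treat < 1e-9 as zero
  imbalance[abs(imbalance) < 1e-9] <- 0
  failed <- rownames(imbalance)[rowSums(abs(imbalance)) > 0]
  structure(list(imbalance = imbalance, exempt = exempt,
                 pass = length(failed) == 0L, failed = failed,
                 elements = elements),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> elements %s: %s\n",
              paste(x$elements, collapse = ","),
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  internal reactions checked: %d, exchange (exempt): %d\n",
              nrow(x$imbalance), length(x$exempt)))
  if (!x$pass) {
    cat("  unbalanced reactions:\n")
    bad <- x$imbalance[x$failed, , drop = FALSE]
    for (i in seq_len(nrow(bad))) {
      nz <- bad[i, bad[i, ] != 0, drop = TRUE]
      cat(sprintf("    %s: %s\n", rownames(bad)[i],
                  paste(sprintf("%s %+g", names(nz), nz), collapse = ", ")))
    }
  }
  invisible(x)
}
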