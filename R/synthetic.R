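# Generators for small mass-balanced stoichiometric test networks.
#
# These fixtures exercise the LP engine independently of the curated
# biological model: linear chains with known throughput, and randomized
# networks with a planted, provably attainable optimum.  All generated
# species carry formula "C" (one carbon) and all conversions are 1:1, so
# every fixture passes carbon-balance validation by construction.

# internal: run code with a private RNG stream seeded by `seed`
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a linear-chain test network
#'
#' Builds `uptake exchange -> s0 -> s1 -> ... -> sn -> product exchange`
#' with `n_intermediates` conversion steps.  Every species has formula
#' `"C"`, so the chain is carbon-balanced, and the maximum product flux
#' equals the uptake bound (or the tightest conversion bound).
#'
#' @param n_intermediates Number of chain conversion reactions (>= 1).
#' @param uptake_bound Maximum uptake flux of the substrate exchange.
#' @param conversion_ubs Optional numeric vector of upper bounds for the
#'   conversion reactions (recycled to length `n_intermediates`).
#' @return A `stoich_model` with reactions `EX_in`, `R1..Rn`, `EX_out`.
#' @export
generate_linear_chain <- function(n_intermediates, uptake_bound = 10,
                                  conversion_ubs = NULL) {
  if (!is.numeric(n_intermediates) || length(n_intermediates) != 1L ||
      n_intermediates < 1 || n_intermediates != round(n_intermediates)) {
    stop("n_intermediates must be an integer >= 1")
  }
  n <- as.integer(n_intermediates)
  if (is.null(conversion_ubs)) conversion_ubs <- 1000
  conversion_ubs <- rep_len(conversion_ubs, n)
  species <- paste0("s", 0:n)
  metabolites <- data.frame(
    id = species, name = species, formula = "C", compartment = "c",
    stringsAsFactors = FALSE)
  reactions <- data.frame(
    id = c("EX_in", paste0("R", seq_len(n)), "EX_out"),
    name = c("substrate exchange", paste("conversion", seq_len(n)),
             "product exchange"),
    lower_bound = c(-uptake_bound, rep(0, n), 0),
    upper_bound = c(0, conversion_ubs, 1000),
    subsystem = c("exchange", rep("chain", n), "exchange"),
    is_exchange = c(TRUE, rep(FALSE, n), TRUE),
    stringsAsFactors = FALSE)
  stoich <- rbind(
    data.frame(reaction = "EX_in", metabolite = "s0", coefficient = -1,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(reaction = paste0("R", i),
                 metabolite = c(species[i], species[i + 1]),
                 coefficient = c(-1, 1), stringsAsFactors = FALSE)
    })),
    data.frame(reaction = "EX_out", metabolite = species[n + 1],
               coefficient = -1, stringsAsFactors = FALSE))
  stoich_model(metabolites, reactions, stoich,
               objective_candidates = "EX_out",
               name = sprintf("linear_chain_%d", n), version = "1")
}

#' Generate a random network with a planted optimum
#'
#' Builds a linear core path whose single bottleneck bound equals
#' `planted_optimum`, then adds `n_decoy_reactions` random carbon-balanced
#' side reactions that provably cannot raise the optimum: either edges
#' that do not cross the bottleneck cut in the forward direction
#' (recirculating or same-side shortcuts) or reversible links to a
#' dead-end metabolite whose steady-state flux is forced to zero.  The
#' maximum flux of `EX_out` therefore equals `planted_optimum` exactly.
#'
#' @param n_intermediates Core chain length (>= 1).
#' @param n_decoy_reactions Number of decoy reactions to add (>= 0).
#' @param planted_optimum The planted maximum product flux (> 0).
#' @param seed Integer seed; identical seeds give identical models.
#' @return List with elements `model` (a `stoich_model`) and
#'   `planted_optimum`.
#' @export
generate_planted_network <- function(n_intermediates = 3,
                                     n_decoy_reactions = 3,
                                     planted_optimum = 10, seed = 1) {
  if (planted_optimum <= 0) stop("planted_optimum must be > 0")
  if (n_decoy_reactions < 0) stop("n_decoy_reactions must be >= 0")
  n <- as.integer(n_intermediates)
  with_seed(seed, {
    uptake <- planted_optimum * stats::runif(1, 1.5, 3)
    wide <- planted_optimum * stats::runif(n, 2, 4)
    k <- sample.int(n, 1) # bottleneck conversion index
    ubs <- wide
    ubs[k] <- planted_optimum
    model <- generate_linear_chain(n, uptake_bound = uptake,
                                   conversion_ubs = ubs)
    n_dead <- 0L
    for (d in seq_len(n_decoy_reactions)) {
      if (stats::runif(1) < 0.5) {
        # edge s_i -> s_j that must not cross the cut {s_(k-1) | s_k}
        # forward, i.e. not (i < k and j >= k)
        repeat {
          ij <- sample(0:n, 2)
          if (!(ij[1] < k && ij[2] >= k)) break
        }
        model <- add_reaction(
          model, sprintf("DEC%d", d), sprintf("decoy edge s%d to s%d",
                                              ij[1], ij[2]),
          stats::setNames(c(-1, 1), paste0("s", ij)),
          0, planted_optimum * stats::runif(1, 0.5, 2.5),
          subsystem = "decoy")
      } else {
        # reversible link to a fresh dead-end species: flux forced to 0
        n_dead <- n_dead + 1L
        dead <- sprintf("d%d", n_dead)
        model$metabolites <- rbind(model$metabolites, data.frame(
          id = dead, name = dead, formula = "C", compartment = "c",
          stringsAsFactors = FALSE))
        src <- sample(0:n, 1)
        cap <- planted_optimum * stats::runif(1, 0.2, 1)
        model <- add_reaction(
          model, sprintf("DEC%d", d), sprintf("decoy dead end s%d", src),
          stats::setNames(c(-1, 1), c(paste0("s", src), dead)),
          -cap, cap, subsystem = "decoy")
      }
    }
    model$name <- sprintf("planted_%d_%d_seed%d", n, n_decoy_reactions,
                          as.integer(seed))
    validate_model(model)
    list(model = model, planted_optimum = planted_optimum)
  })
}
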