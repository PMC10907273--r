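#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

# Canonical species ordering. Vectors, tables and CSV columns all follow it,
# so outputs are reproducible byte-for-byte.
ENZYME_FORMS <- c(
  "E", "E.ADP", "E.BPG", "E.ADP.BPG", "E.ATP",
  "E.PG", "E.ATP.PG", "E.TZ", "E.TZ.BPG", "E.TZ.PG"
)
FREE_LIGANDS <- c("ADP", "BPG", "ATP", "PG", "TZ")
ALL_SPECIES <- c(ENZYME_FORMS, FREE_LIGANDS)

# Species whose totals are conserved by the un-clamped dynamics.
ADENINE_SPECIES <- c("ADP", "ATP", "E.ADP", "E.ADP.BPG", "E.ATP", "E.ATP.PG")
TZ_SPECIES <- c("TZ", "E.TZ", "E.TZ.BPG", "E.TZ.PG")
TZ_BOUND_FORMS <- c("E.TZ", "E.TZ.BPG", "E.TZ.PG")

#' Species of the PGK1 reaction network
#'
#' @param clamped Character vector of species held constant during
#'   integration. The default clamps 1,3-BPG only, matching the in vitro
#'   protocol where 1,3-BPG is buffered at 80 uM by an upstream reaction.
#' @return A tibble with columns `name`, `role` (enzyme-form or free-ligand)
#'   and `clamped`.
#' @export
pgk_species <- function(clamped = "BPG") {
  bad <- setdiff(clamped, ALL_SPECIES)
  if (length(bad)) {
    stop("unknown species in 'clamped': ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    name = ALL_SPECIES,
    role = rep(c("enzyme-form", "free-ligand"),
               c(length(ENZYME_FORMS), length(FREE_LIGANDS))),
    clamped = ALL_SPECIES %in% clamped
  )
}

# Reaction topology: each reversible reaction converts one enzyme form into
# another, consuming at most one free ligand. `kf_ref`/`kr_ref` name the rate
# parameter; `eta_f` marks terazosin edges whose on-rate is scaled by eta.
reaction_table <- function() {
  tibble::tribble(
    ~id,   ~form_in,    ~ligand, ~form_out,   ~kf_ref,   ~kr_ref,   ~eta_f,
    "R1",  "E",         "ADP",   "E.ADP",     "a_plus",  "a_minus", FALSE,
    "R2",  "E",         "BPG",   "E.BPG",     "c_plus",  "c_minus", FALSE,
    "R3",  "E.ADP",     "BPG",   "E.ADP.BPG", "b_plus",  "b_minus", FALSE,
    "R4",  "E.BPG",     "ADP",   "E.ADP.BPG", "d_plus",  "d_minus", FALSE,
    "R5",  "E.ADP.BPG", NA,      "E.ATP.PG",  "k_plus",  "k_minus", FALSE,
    "R6",  "E",         "ATP",   "E.ATP",     "a_plus",  "a_minus", FALSE,
    "R7",  "E",         "PG",    "E.PG",      "c_plus",  "c_minus", FALSE,
    "R8",  "E.ATP",     "PG",    "E.ATP.PG",  "b_plus",  "b_minus", FALSE,
    "R9",  "E.PG",      "ATP",   "E.ATP.PG",  "d_plus",  "d_minus", FALSE,
    "R10", "E",         "TZ",    "E.TZ",      "a_plus",  "a_minus", TRUE,
    "R11", "E.BPG",     "TZ",    "E.TZ.BPG",  "d_plus",  "d_minus", TRUE,
    "R12", "E.PG",      "TZ",    "E.TZ.PG",   "d_plus",  "d_minus", TRUE,
    "R13", "E.TZ",      "BPG",   "E.TZ.BPG",  "b_plus",  "b_minus", FALSE,
    "R14", "E.TZ",      "PG",    "E.TZ.PG",   "b_plus",  "b_minus", FALSE
  )
}

#' Build the canonical terazosin-PGK1 reaction network
#'
#' Assembles the 15-species, 14-reversible-reaction mass-action network: two
#' random-order binding diamonds (substrates ADP + 1,3-BPG on one side,
#' products ATP + 3-PG on the other) joined by the reversible phosphotransfer
#' step, plus three terazosin-bound forms (`E.TZ`, `E.TZ.BPG`, `E.TZ.PG`)
#' reached by terazosin binding the free nucleotide pocket. Terazosin
#' association uses `eta * a_plus` on free enzyme and `eta * d_plus` on
#' phosphoglycerate-occupied enzyme, mirroring the nucleotide edges it
#' competes with; its dissociation reuses `a_minus`/`d_minus`.
#' Phosphoglycerate binding to the terazosin-occupied enzyme uses `b_plus` /
#' `b_minus`, the same constants as binding to a nucleotide-occupied enzyme.
#'
#' Note the default constants do not satisfy thermodynamic detailed balance
#' around the substrate diamond (`a+b+/a-b- != c+d+/c-d-`); they are kept as
#' measured and no cycle-consistency correction is applied.
#'
#' @param params A [rate_parameters()] object.
#' @param include_tz If `FALSE`, build the 7-form terazosin-free subnetwork
#'   (reactions R1-R9 only); useful for reduction checks.
#' @param clamped Species held constant during integration (default `"BPG"`).
#' @return A `pgk_network` object: a list with `species` and `reactions`
#'   tibbles, the `params`, and a precomputed stoichiometry matrix.
#' @examples
#' net <- pgk_network()
#' net$reactions[, c("id", "label", "kf", "kr")]
#' @export
pgk_network <- function(params = rate_parameters(), include_tz = TRUE,
                        clamped = "BPG") {
  if (!inherits(params, "rate_parameters")) {
    params <- do.call(rate_parameters, as.list(params))
  }
  validate_rate_parameters(params)

  rx <- reaction_table()
  if (!include_tz) rx <- rx[1:9, ]

  rx$kf <- purrr::map2_dbl(rx$kf_ref, rx$eta_f,
                           ~ params[[.x]] * if (.y) params$eta else 1)
  rx$kr <- purrr::map_dbl(rx$kr_ref, ~ params[[.x]])
  rx$label <- ifelse(
    is.na(rx$ligand),
    paste0(rx$form_in, " <-> ", rx$form_out),
    paste0(rx$form_in, " + ", rx$ligand, " <-> ", rx$form_out)
  )

  species <- pgk_species(clamped)
  if (!include_tz) {
    species <- species[!species$name %in% c(TZ_BOUND_FORMS, "TZ"), ]
  }

  net <- structure(
    list(species = species, reactions = rx, params = params),
    class = "pgk_network"
  )
  net$stoich <- stoichiometry_matrix(net)
  net
}

# Species-by-reaction stoichiometry matrix (net change of each species per
# unit of forward reaction progress).
stoichiometry_matrix <- function(network) {
  sp <- network$species$name
  rx <- network$reactions
  N <- matrix(0, nrow = length(sp), ncol = nrow(rx),
              dimnames = list(sp, rx$id))
  for (j in seq_len(nrow(rx))) {
    N[rx$form_in[j], j] <- N[rx$form_in[j], j] - 1
    if (!is.na(rx$ligand[j])) N[rx$ligand[j], j] <- N[rx$ligand[j], j] - 1
    N[rx$form_out[j], j] <- N[rx$form_out[j], j] + 1
  }
  N
}

#' @export
print.pgk_network <- function(x, ...) {
  cat(sprintf("<pgk_network> %d species (%d enzyme forms), %d reversible reactions\n",
              nrow(x$species), sum(x$species$role == "enzyme-form"),
              nrow(x$reactions)))
  cl <- x$species$name[x$species$clamped]
  cat("  clamped:", if (length(cl)) paste(cl, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Change which species are clamped
#'
#' Clamped species keep a fixed concentration during integration; their time
#' derivative is forced to zero. Clamping every free ligand makes the
#' enzyme-form subsystem linear, which is how the steady-state
#' [enzyme_steady_state()] cross-check operates.
#'
#' @param network A `pgk_network`.
#' @param clamped Character vector of species names (may be empty).
#' @return The network with updated clamping flags.
#' @export
set_clamped <- function(network, clamped) {
  stopifnot(inherits(network, "pgk_network"))
  bad <- setdiff(clamped, network$species$name)
  if (length(bad)) {
    stop("unknown species in 'clamped': ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  network$species$clamped <- network$species$name %in% clamped
  network
}

# Validate and order a state vector against the network species; enforces
# non-negativity with a small underflow allowance for integrator output.
check_state <- function(network, state, clip = 0) {
  sp <- network$species$name
  if (is.null(names(state))) {
    if (length(state) != length(sp)) {
      stop("state must have length ", length(sp), call. = FALSE)
    }
    names(state) <- sp
  } else {
    missing <- setdiff(sp, names(state))
    if (length(missing)) {
      stop("state is missing species: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    state <- state[sp]
  }
  if (any(!is.finite(state))) stop("state contains non-finite values", call. = FALSE)
  neg <- state < 0
  if (any(state < -clip)) {
    stop("negative concentration(s): ",
         paste(names(state)[state < -clip], collapse = ", "), call. = FALSE)
  }
  state[neg] <- 0
  state
}

# Net rate of progress of each reaction (uM/s), forward direction positive.
reaction_net_rates <- function(network, state) {
  rx <- network$reactions
  fwd <- state[rx$form_in] * ifelse(is.na(rx$ligand), 1, state[rx$ligand])
  setNames(rx$kf * fwd - rx$kr * state[rx$form_out], rx$id)
}

#' Mass-action time derivative of the network state
#'
#' Evaluates the right-hand side of the ODE system: for each reversible
#' reaction the net rate is `kf * [form_in] * [ligand] - kr * [form_out]`,
#' and species derivatives are the stoichiometry-weighted sums of these
#' rates. Clamped species have derivative exactly zero.
#'
#' @param network A `pgk_network`.
#' @param state Named (or canonically ordered) non-negative concentration
#'   vector in micromolar.
#' @return Named derivative vector in micromolar per second.
#' @examples
#' net <- pgk_network()
#' st <- state_vector(net, E = 0.04, ADP = 1000)
#' mass_action_rhs(net, st)[["E.ADP"]] # a+ * [E] * [ADP] = 244
#' @export
mass_action_rhs <- function(network, state) {
  state <- check_state(network, state)
  v <- reaction_net_rates(network, state)
  d <- drop(network$stoich %*% v)
  d[network$species$clamped] <- 0
  d
}

#' Construct a state vector in canonical species order
#'
#' @param network A `pgk_network`.
#' @param ... Named concentrations in micromolar; unnamed species default to 0.
#' @return Named numeric vector over the network's species.
#' @export
state_vector <- function(network, ...) {
  vals <- c(...)
  st <- setNames(numeric(nrow(network$species)), network$species$name)
  if (length(vals)) {
    bad <- setdiff(names(vals), names(st))
    if (length(bad)) {
      stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    st[names(vals)] <- vals
  }
  st
}

#' Rate matrix of the enzyme-form subsystem at fixed ligand concentrations
#'
#' When every free ligand is clamped, the enzyme forms evolve linearly:
#' `d e / dt = M e`. This returns the generator matrix `M` (columns sum to
#' zero), whose null space is the stationary enzyme distribution.
#'
#' @param network A `pgk_network`.
#' @param ligands Named vector of clamped ligand concentrations in micromolar
#'   (all free ligands of the network must be present).
#' @return Square matrix over the network's enzyme forms.
#' @export
enzyme_rate_matrix <- function(network, ligands) {
  forms <- network$species$name[network$species$role == "enzyme-form"]
  lig <- network$species$name[network$species$role == "free-ligand"]
  missing <- setdiff(lig, names(ligands))
  if (length(missing)) {
    stop("ligand concentrations missing for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  M <- matrix(0, length(forms), length(forms), dimnames = list(forms, forms))
  rx <- network$reactions
  for (j in seq_len(nrow(rx))) {
    kon <- rx$kf[j] * if (is.na(rx$ligand[j])) 1 else ligands[[rx$ligand[j]]]
    i <- rx$form_in[j]; o <- rx$form_out[j]
    M[o, i] <- M[o, i] + kon
    M[i, i] <- M[i, i] - kon
    M[i, o] <- M[i, o] + rx$kr[j]
    M[o, o] <- M[o, o] - rx$kr[j]
  }
  M
}

#' Stationary enzyme-form distribution at fixed ligand concentrations
#'
#' Solves the null space of [enzyme_rate_matrix()] by singular value
#' decomposition and normalises to unit total. This is a closed-form
#' linear-algebra route to the long-time enzyme distribution, independent of
#' the ODE integrator.
#'
#' @inheritParams enzyme_rate_matrix
#' @return Named vector of enzyme-form fractions summing to one.
#' @export
enzyme_steady_state <- function(network, ligands) {
  M <- enzyme_rate_matrix(network, ligands)
  sv <- svd(M)
  v <- sv$v[, ncol(M)]
  v <- v / sum(v)
  if (any(v < -1e-10)) {
    stop("null-space solution is not a distribution; rate matrix may be reducible",
         call. = FALSE)
  }
  setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(M))
}

#' Export a network description as JSON
#'
#' Writes a plain JSON description (species with roles and clamping flags,
#' reactions with rate-parameter references and resolved values, parameter
#' set) for inspection and round-trip testing.
#'
#' @param network A `pgk_network`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
network_to_json <- function(network, path = NULL) {
  desc <- list(
    species = network$species,
    reactions = network$reactions[, c("id", "label", "form_in", "ligand",
                                      "form_out", "kf_ref", "kr_ref",
                                      "eta_f", "kf", "kr")],
    parameters = unclass(network$params)
  )
  js <- jsonlite::toJSON(desc, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
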