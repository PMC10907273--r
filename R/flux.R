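#' Net flux of each reversible interaction
#'
#' The net flux of an interaction is its forward minus reverse mass-action
#' rate, e.g. `a+ [E][ADP] - a- [E.ADP]` for nucleotide binding to free
#' enzyme. Positive values flow in the direction the reaction is written
#' (towards the more-liganded form; for phosphotransfer, towards products).
#'
#' @param network A [pgk_network()].
#' @param state Named concentration vector in micromolar (e.g. the final row
#'   of a [simulate_pgk()] trajectory).
#' @param tz_uM Optional terazosin label for the rows (defaults to the free
#'   TZ concentration in `state`, if present).
#' @return A tibble with one row per reaction: `reaction`, `label`, `tz_uM`,
#'   `net_flux_uM_s`.
#' @examples
#' net <- pgk_network()
#' st <- final_states(net, sim_config(tz = 0.05))
#' net_fluxes(net, st)
#' @export
net_fluxes <- function(network, state, tz_uM = NULL) {
  state <- check_state(network, state)
  if (is.null(tz_uM)) {
    tz_uM <- if ("TZ" %in% names(state)) unname(state[["TZ"]]) else NA_real_
  }
  v <- reaction_net_rates(network, state)
  tibble::tibble(
    reaction = network$reactions$id,
    label = network$reactions$label,
    tz_uM = tz_uM,
    net_flux_uM_s = unname(v)
  )
}

# Convenience: final state at t_end for one scenario.
#' Final simulated state under a protocol
#'
#' Runs [simulate_pgk()] and returns the state at `t_end` as a named vector.
#'
#' @inheritParams simulate_pgk
#' @return Named concentration vector (uM).
#' @export
final_states <- function(network, config = sim_config()) {
  final_state(simulate_pgk(network, config))
}

#' Net-flux table across a terazosin grid
#'
#' Simulates each terazosin concentration in `config$tz_grid` under an
#' otherwise identical protocol and evaluates every reaction's net flux at
#' `t_end`, mirroring a per-interaction flux table with one column block per
#' terazosin concentration.
#'
#' @inheritParams simulate_pgk
#' @return A long tibble: `reaction`, `label`, `tz_uM` (nominal initial
#'   concentration), `net_flux_uM_s`.
#' @export
flux_table <- function(network, config = sim_config()) {
  purrr::map_dfr(config$tz_grid, function(tz) {
    cfg <- config
    cfg$tz <- tz
    st <- final_states(network, cfg)
    net_fluxes(network, st, tz_uM = tz)
  })
}

# Baseline denominators below this (uM) make percent change meaningless.
PCT_BASELINE_FLOOR <- 1e-15

#' Enzyme-form occupancy and change relative to the terazosin-free baseline
#'
#' Computes the fraction of total enzyme in each configuration at the end of
#' a trajectory. Terazosin-free forms are additionally reported as percent
#' change relative to the matching baseline run without terazosin;
#' terazosin-bound forms (whose baseline is zero) are reported as percent of
#' total enzyme instead.
#'
#' @param network A [pgk_network()].
#' @param trajectory Trajectory at the terazosin concentration of interest.
#' @param baseline Trajectory from the identical protocol with `tz = 0`.
#' @return An `occupancy_table` tibble: `form`, `concentration_uM`,
#'   `fraction`, `percent_change` (NA for terazosin-bound forms, and NA when
#'   the baseline concentration is below 1e-15 uM), `percent_of_enzyme`
#'   (terazosin-bound forms only).
#' @examples
#' net <- pgk_network()
#' base <- simulate_pgk(net, sim_config(tz = 0))
#' high <- simulate_pgk(net, sim_config(tz = 25))
#' occupancy(net, high, base)
#' @export
occupancy <- function(network, trajectory, baseline) {
  stopifnot(inherits(trajectory, "pgk_trajectory"),
            inherits(baseline, "pgk_trajectory"))
  cfg_b <- attr(baseline, "config")
  if (!is.null(cfg_b) && cfg_b$tz != 0) {
    stop("baseline trajectory must have tz = 0", call. = FALSE)
  }
  t1 <- max(trajectory$time); t0 <- max(baseline$time)
  if (abs(t1 - t0) > 1e-9) {
    stop("trajectory and baseline must be evaluated at the same time",
         call. = FALSE)
  }
  st <- final_state(trajectory)
  st0 <- final_state(baseline)
  forms <- network$species$name[network$species$role == "enzyme-form"]
  conc <- st[forms]
  total <- sum(conc)
  if (total <= 0) stop("no enzyme present in trajectory", call. = FALSE)
  frac <- conc / total
  is_tz <- forms %in% TZ_BOUND_FORMS
  base_conc <- st0[forms]
  pct_change <- ifelse(
    is_tz | base_conc < PCT_BASELINE_FLOOR,
    NA_real_,
    100 * (conc - base_conc) / base_conc
  )
  out <- tibble::tibble(
    form = forms,
    concentration_uM = unname(conc),
    fraction = unname(frac),
    percent_change = unname(pct_change),
    percent_of_enzyme = ifelse(is_tz, 100 * unname(frac), NA_real_)
  )
  structure(out, class = c("occupancy_table", class(out)),
            time = t1, total_enzyme = total)
}

#' Occupancy table across a terazosin grid
#'
#' Runs [occupancy()] for every non-zero terazosin concentration in
#' `config$tz_grid` against the shared terazosin-free baseline.
#'
#' @inheritParams simulate_pgk
#' @return A long tibble with an added `tz_uM` column.
#' @export
occupancy_table <- function(network, config = sim_config()) {
  cfg0 <- config
  cfg0$tz <- 0
  base <- simulate_pgk(network, cfg0)
  purrr::map_dfr(setdiff(config$tz_grid, 0), function(tz) {
    cfg <- config
    cfg$tz <- tz
    occ <- occupancy(network, simulate_pgk(network, cfg), base)
    dplyr::mutate(tibble::as_tibble(occ), tz_uM = tz, .before = 1)
  })
}
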