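#' Simulation protocol configuration
#'
#' Bundles initial conditions, integration horizon and solver tolerances.
#' Defaults reproduce the in vitro protocol the model was built around:
#' 0.04 uM free PGK1, 1 mM ADP, 1,3-BPG clamped at 80 uM, no products, and
#' product formation read out at 1 min -- a quasi-equilibrium time at which
#' the production rate has reached and still holds its maximum.
#'
#' @param t_end Integration horizon in seconds (default 60).
#' @param enzyme_total Total PGK1 in micromolar, supplied as free enzyme.
#' @param adp,bpg,atp,pg,tz Initial free-ligand concentrations in micromolar.
#' @param tz_grid Terazosin concentrations (uM) for dose-response runs; must
#'   contain 0, the baseline. Default: 0, 2.5 nM, 25 nM, 50 nM, 0.25 uM,
#'   0.5 uM, 2.5 uM, 25 uM.
#' @param rtol,atol Relative / absolute solver tolerances. The tight defaults
#'   keep conservation drift far below reporting precision.
#' @param rate_window Time window (seconds) over which early-time production
#'   slopes are measured for apparent-Km prediction: after the binding
#'   transient, before substrate depletion.
#' @return A `sim_config` object.
#' @export
sim_config <- function(t_end = 60, enzyme_total = 0.04,
                       adp = 1000, bpg = 80, atp = 0, pg = 0, tz = 0,
                       tz_grid = c(0, 0.0025, 0.025, 0.05, 0.25, 0.5, 2.5, 25),
                       rtol = 1e-9, atol = 1e-12,
                       rate_window = c(0.5, 2)) {
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0) {
    stop("t_end must be a single positive number", call. = FALSE)
  }
  conc <- c(enzyme_total = enzyme_total, adp = adp, bpg = bpg,
            atp = atp, pg = pg, tz = tz)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("initial concentrations must be finite and non-negative",
         call. = FALSE)
  }
  if (any(tz_grid < 0)) stop("tz_grid must be non-negative", call. = FALSE)
  if (!any(tz_grid == 0)) {
    stop("tz_grid must contain 0 (the no-terazosin baseline)", call. = FALSE)
  }
  if (length(rate_window) != 2L || rate_window[1] >= rate_window[2]) {
    stop("rate_window must be an increasing pair of times", call. = FALSE)
  }
  structure(
    list(t_end = t_end, enzyme_total = enzyme_total,
         adp = adp, bpg = bpg, atp = atp, pg = pg, tz = tz,
         tz_grid = tz_grid, rtol = rtol, atol = atol,
         rate_window = rate_window),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  t_end %g s, E %g uM, ADP %g uM, BPG %g uM (clamped by default),\n",
              x$t_end, x$enzyme_total, x$adp, x$bpg))
  cat(sprintf("  ATP %g uM, 3-PG %g uM, TZ %g uM\n", x$atp, x$pg, x$tz))
  cat(sprintf("  tz_grid (uM): %s\n", paste(x$tz_grid, collapse = ", ")))
  cat(sprintf("  rtol %g, atol %g uM\n", x$rtol, x$atol))
  invisible(x)
}

# Initial state vector implied by a sim_config: all enzyme starts free.
initial_state <- function(network, config) {
  vals <- c(E = config$enzyme_total, ADP = config$adp, BPG = config$bpg,
            ATP = config$atp, PG = config$pg, TZ = config$tz)
  vals <- vals[names(vals) %in% network$species$name]
  do.call(state_vector, c(list(network), as.list(vals)))
}

# Integrator output tolerance: magnitudes below this are treated as solver
# underflow and clipped to zero; larger negatives are an error.
NEG_CLIP <- 1e-12

#' Integrate the PGK1 network
#'
#' Runs the stiff ODE solver (`deSolve::lsoda`) on the mass-action system.
#' Clamped species are held at their initial concentration. Tiny negative
#' excursions from the integrator (|x| < 1e-12 uM) are clipped to zero;
#' anything larger raises an error rather than propagating silently.
#'
#' @param network A [pgk_network()].
#' @param config A [sim_config()].
#' @param times Optional output time grid (seconds); defaults to
#'   `c(0, t_end)`. Dense grids are only needed when the transient itself is
#'   analysed.
#' @param init Optional named state vector (uM) overriding the
#'   config-derived initial condition.
#' @return A `pgk_trajectory`: a tibble with a `time` column and one column
#'   per species, with the network and config attached as attributes.
#' @examples
#' traj <- simulate_pgk(pgk_network(), sim_config(tz = 0.05))
#' atp_production(traj)
#' @export
simulate_pgk <- function(network, config = sim_config(), times = NULL,
                         init = NULL) {
  stopifnot(inherits(network, "pgk_network"))
  if (!inherits(config, "sim_config")) stop("config must be a sim_config",
                                            call. = FALSE)
  y0 <- if (is.null(init)) initial_state(network, config)
        else check_state(network, init)
  if (is.null(times)) times <- c(0, config$t_end)
  if (max(times) != config$t_end) {
    stop("times must end at config$t_end", call. = FALSE)
  }

  rhs <- make_rhs(network)
  out <- deSolve::lsoda(y = y0, times = times, func = rhs, parms = NULL,
                        rtol = config$rtol, atol = config$atol,
                        maxsteps = 100000L)
  diagn <- attributes(out)$istate
  if (!is.null(diagn) && diagn[1] < 0) {
    stop("ODE solver failed (istate = ", diagn[1], ") at TZ = ", config$tz,
         " uM; see deSolve diagnostics", call. = FALSE)
  }
  if (abs(out[nrow(out), 1] - max(times)) > 1e-9 || nrow(out) < length(times)) {
    stop("ODE solver stopped early at t = ", out[nrow(out), 1],
         " s (of ", max(times), " s) at TZ = ", config$tz, " uM",
         call. = FALSE)
  }
  states <- out[, -1, drop = FALSE]
  if (any(!is.finite(states))) {
    stop("ODE solution contains non-finite values at TZ = ", config$tz,
         " uM", call. = FALSE)
  }
  if (any(states < -NEG_CLIP)) {
    stop("ODE solution went negative beyond clip tolerance (min = ",
         format(min(states)), " uM)", call. = FALSE)
  }
  states[states < 0] <- 0

  traj <- tibble::as_tibble(as.data.frame(cbind(time = out[, 1], states)))
  structure(traj, class = c("pgk_trajectory", class(traj)),
            network = network, config = config)
}

# Vectorised right-hand side for deSolve, closed over precomputed indices.
make_rhs <- function(network) {
  rx <- network$reactions
  i_in <- match(rx$form_in, network$species$name)
  i_out <- match(rx$form_out, network$species$name)
  has_lig <- !is.na(rx$ligand)
  i_lig <- match(rx$ligand, network$species$name)
  kf <- rx$kf; kr <- rx$kr
  N <- network$stoich
  clamped <- network$species$clamped

  function(t, y, parms) {
    lig <- rep(1, length(kf))
    lig[has_lig] <- y[i_lig[has_lig]]
    v <- kf * y[i_in] * lig - kr * y[i_out]
    d <- N %*% v
    d[clamped] <- 0
    list(d)
  }
}

# Last state of a trajectory as a named vector.
final_state <- function(trajectory) {
  stopifnot(inherits(trajectory, "pgk_trajectory"))
  st <- as.matrix(trajectory[nrow(trajectory), -1, drop = FALSE])[1, ]
  st
}

#' ATP production of a simulated trajectory
#'
#' The default readout is the total adenine-triphosphate pool -- free ATP
#' plus the enzyme-bound forms `E.ATP` and `E.ATP.PG` -- at the final time.
#' Under the quasi-equilibrium protocol the production rate is near its
#' maximum throughout, so the pool at 60 s is approximately rate x 60 s.
#' `kind = "rate"` instead returns the instantaneous pool growth rate at the
#' final time (the net phosphotransfer rate), for sensitivity checks.
#'
#' @param trajectory A `pgk_trajectory` from [simulate_pgk()].
#' @param kind `"pool"` (default, uM) or `"rate"` (uM/s).
#' @return A single number.
#' @export
atp_production <- function(trajectory, kind = c("pool", "rate")) {
  kind <- match.arg(kind)
  st <- final_state(trajectory)
  pool_members <- intersect(c("ATP", "E.ATP", "E.ATP.PG"), names(st))
  if (kind == "pool") return(sum(st[pool_members]))
  net <- attr(trajectory, "network")
  v <- reaction_net_rates(net, check_state(net, st))
  unname(v["R5"])
}

#' Terazosin dose-response of ATP production
#'
#' Runs one simulation per terazosin concentration in `config$tz_grid`,
#' identical otherwise, and reports ATP production relative to the
#' terazosin-free baseline. With the default parameters the response is
#' biphasic: stimulation peaks near 50 nM and high concentrations inhibit.
#'
#' @inheritParams simulate_pgk
#' @param kind Production readout passed to [atp_production()].
#' @return A `tz_dose_response` tibble with columns `tz_uM`, `atp_uM` and
#'   `percent_change` (exactly 0 at the baseline row).
#' @examples
#' \donttest{
#' dose_response(pgk_network())
#' }
#' @export
dose_response <- function(network, config = sim_config(),
                          kind = c("pool", "rate")) {
  kind <- match.arg(kind)
  res <- purrr::map_dbl(config$tz_grid, function(tz) {
    cfg <- config
    cfg$tz <- tz
    atp_production(simulate_pgk(network, cfg), kind = kind)
  })
  baseline <- res[match(0, config$tz_grid)]
  out <- tibble::tibble(
    tz_uM = config$tz_grid,
    atp_uM = res,
    percent_change = ifelse(config$tz_grid == 0, 0,
                            100 * (res - baseline) / baseline)
  )
  structure(out, class = c("tz_dose_response", class(out)), config = config)
}

# Early-time ATP production rate (uM/s): least-squares slope of the total
# ATP pool over the configured rate window.
initial_production_rate <- function(network, config) {
  win <- config$rate_window
  cfg <- config
  cfg$t_end <- win[2]
  times <- unique(sort(c(0, seq(win[1], win[2], length.out = 25))))
  traj <- simulate_pgk(network, cfg, times = times)
  pool_members <- intersect(c("ATP", "E.ATP", "E.ATP.PG"), names(traj))
  keep <- traj$time >= win[1]
  pool <- rowSums(traj[keep, pool_members, drop = FALSE])
  unname(stats::coef(stats::lm(pool ~ traj$time[keep]))[2])
}

#' Model-predicted apparent Michaelis constant under terazosin
#'
#' Emulates the initial-rate enzyme assay on the kinetic model: for each ADP
#' concentration the early-time ATP production rate is measured at a fixed
#' terazosin concentration, and the rate-vs-ADP curve is fit to the
#' Michaelis-Menten form. A competitive inhibitor leaves the fitted maximal
#' rate nearly unchanged while inflating the apparent Km.
#'
#' @param network A [pgk_network()].
#' @param tz Terazosin concentration in micromolar.
#' @param adp_grid ADP concentrations (uM) spanning at least a decade around
#'   the apparent Km.
#' @param config Base [sim_config()]; its `rate_window` sets the slope window.
#' @return A one-row tibble with `tz_uM`, `km_uM`, `vmax_uM_s`; the full
#'   [fit_mm()] object is attached as attribute `"fit"`.
#' @export
predict_apparent_km <- function(network, tz,
                                adp_grid = c(100, 250, 500, 1000, 2500,
                                             5000, 10000, 25000),
                                config = sim_config()) {
  if (max(adp_grid) / min(adp_grid) < 10) {
    stop("adp_grid must span at least one decade", call. = FALSE)
  }
  rates <- purrr::map_dbl(adp_grid, function(adp) {
    cfg <- config
    cfg$adp <- adp
    cfg$tz <- tz
    initial_production_rate(network, cfg)
  })
  fit <- fit_mm(tibble::tibble(substrate = adp_grid, rate = rates))
  est <- generics::tidy(fit)
  out <- tibble::tibble(
    tz_uM = tz,
    km_uM = est$estimate[est$term == "km"],
    vmax_uM_s = est$estimate[est$term == "vmax"]
  )
  attr(out, "fit") <- fit
  out
}
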