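#' Default dissociation-rate grid for the c-/b- sweep
#'
#' Log-spaced `c_minus` values spanning a `c-/b-` ratio of 0.005 to 1.2 at
#' the default `b_minus` of 160 per second, bracketing both the stimulatory
#' regime (ratio near zero) and the inhibitory regime (ratio near one), with
#' the measured value (14/160 = 0.0875) inside the range.
#'
#' @param n Number of grid points (default 25).
#' @param ratio_range Range of `c-/b-` ratios to span.
#' @param b_minus Fixed `b_minus` (per second).
#' @return Numeric vector of `c_minus` values (per second).
#' @export
default_cminus_grid <- function(n = 25, ratio_range = c(0.005, 1.2),
                                b_minus = 160) {
  exp(seq(log(ratio_range[1] * b_minus), log(ratio_range[2] * b_minus),
          length.out = n))
}

#' Sweep a rate parameter against the terazosin grid
#'
#' For each parameter value, rebuilds the network, simulates the
#' terazosin-free baseline and every terazosin concentration in `tz_grid`
#' under an otherwise identical protocol, and reports the ratio of ATP
#' production with terazosin to production without it. Because the baseline
#' itself depends on the swept parameter, a fresh baseline is simulated at
#' every parameter value. A solver failure at one grid point is recorded as
#' a missing ratio with its diagnostic message; the sweep continues.
#'
#' @param param Name of the rate parameter to sweep (one of the
#'   [rate_parameters()] fields, e.g. `"c_minus"`).
#' @param values Parameter values to visit.
#' @param tz_grid Terazosin concentrations (uM); a 0 entry yields ratio 1.
#' @param config Base [sim_config()].
#' @param params Template parameter set that the sweep modifies.
#' @return A `tz_sweep` tibble: `param`, `value`, `tz_uM`, `atp_uM`,
#'   `atp0_uM`, `ratio`, `note` (solver diagnostics for failed cells).
#' @examples
#' \donttest{
#' sw <- sweep_parameter("c_minus", default_cminus_grid(n = 5),
#'                       tz_grid = c(0.05, 25))
#' classify_stimulation(sw)
#' }
#' @export
sweep_parameter <- function(param, values,
                            tz_grid = c(0.0025, 0.025, 0.05, 0.25, 0.5, 2.5, 25),
                            config = sim_config(),
                            params = rate_parameters()) {
  if (!param %in% names(unclass(params))) {
    stop("unknown rate parameter: ", param, call. = FALSE)
  }
  if (!length(values) || !length(tz_grid)) {
    stop("values and tz_grid must be non-empty", call. = FALSE)
  }
  cell <- function(net, tz) {
    cfg <- config
    cfg$tz <- tz
    tryCatch(
      list(atp = atp_production(simulate_pgk(net, cfg)), note = NA_character_),
      error = function(e) list(atp = NA_real_, note = conditionMessage(e))
    )
  }
  out <- purrr::map_dfr(values, function(val) {
    p <- update_rate_parameters(params, setNames(list(val), param))
    net <- pgk_network(p)
    base <- cell(net, 0)
    purrr::map_dfr(tz_grid, function(tz) {
      res <- if (tz == 0) base else cell(net, tz)
      tibble::tibble(
        param = param, value = val, tz_uM = tz,
        atp_uM = res$atp, atp0_uM = base$atp,
        ratio = if (tz == 0) 1 else res$atp / base$atp,
        note = res$note
      )
    })
  })
  structure(out, class = c("tz_sweep", class(out)), config = config)
}

#' Classify sweep cells as stimulation, neutral or inhibition
#'
#' Labels each (parameter value, terazosin) cell of a sweep by comparing its
#' production ratio to one: stimulation above `1 + epsilon`, inhibition
#' below `1 - epsilon`, neutral within the band. The classification is a
#' pure per-cell function of the ratio, so it is invariant to the ordering
#' of the grid axes.
#'
#' @param sweep A `tz_sweep` from [sweep_parameter()].
#' @param epsilon Half-width of the neutral band (default 0.01).
#' @return The sweep with an added `classification` column (factor with
#'   levels inhibition, neutral, stimulation; NA for failed cells).
#' @export
classify_stimulation <- function(sweep, epsilon = 0.01) {
  stopifnot(is.numeric(epsilon), epsilon >= 0)
  cls <- dplyr::case_when(
    is.na(sweep$ratio) ~ NA_character_,
    sweep$ratio > 1 + epsilon ~ "stimulation",
    sweep$ratio < 1 - epsilon ~ "inhibition",
    TRUE ~ "neutral"
  )
  sweep$classification <- factor(cls, levels = c("inhibition", "neutral",
                                                 "stimulation"))
  sweep
}
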