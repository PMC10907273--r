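# Shared fixtures. The default network/protocol is cheap to build; the full
# dose-response is simulated once and reused across files.
default_net <- pgk_network()

cached_dose_response <- local({
  dr <- NULL
  function() {
    if (is.null(dr)) dr <<- dose_response(default_net)
    dr
  }
})

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# Random ligand concentrations (uM) on log scales typical of the protocol.
random_ligands <- function() {
  c(ADP = exp(stats::runif(1, log(10), log(5000))),
    BPG = exp(stats::runif(1, log(1), log(500))),
    ATP = exp(stats::runif(1, log(1), log(2000))),
    PG  = exp(stats::runif(1, log(1), log(500))),
    TZ  = exp(stats::runif(1, log(1e-3), log(25))))
}

# Rate parameters jittered around the defaults by up to e^+-1.
random_params <- function() {
  base <- unclass(rate_parameters())
  do.call(rate_parameters,
          lapply(base, function(v) v * exp(stats::runif(1, -1, 1))))
}

# Independent tally of a form's incident net fluxes, built from the
# documented reaction wiring rather than the package's stoichiometry matrix.
incident_flux_sum <- function(form, fluxes) {
  wiring <- list(
    R1 = c("E", "E.ADP"), R2 = c("E", "E.BPG"),
    R3 = c("E.ADP", "E.ADP.BPG"), R4 = c("E.BPG", "E.ADP.BPG"),
    R5 = c("E.ADP.BPG", "E.ATP.PG"), R6 = c("E", "E.ATP"),
    R7 = c("E", "E.PG"), R8 = c("E.ATP", "E.ATP.PG"),
    R9 = c("E.PG", "E.ATP.PG"), R10 = c("E", "E.TZ"),
    R11 = c("E.BPG", "E.TZ.BPG"), R12 = c("E.PG", "E.TZ.PG"),
    R13 = c("E.TZ", "E.TZ.BPG"), R14 = c("E.TZ", "E.TZ.PG")
  )
  total <- 0
  for (id in names(wiring)) {
    v <- fluxes$net_flux_uM_s[fluxes$reaction == id]
    if (wiring[[id]][1] == form) total <- total - v
    if (wiring[[id]][2] == form) total <- total + v
  }
  total
}
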