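test_that("substrate-only start produces monotone ATP accumulation", {
  times <- seq(0, 60, length.out = 61)
  traj <- simulate_pgk(default_net, sim_config(tz = 0), times = times)
  pool <- rowSums(traj[, c("ATP", "E.ATP", "E.ATP.PG")])
  after <- traj$time >= 1 # past the binding transient
  expect_true(all(diff(pool[after]) > 0))
  expect_gt(atp_production(traj), 0)
})

test_that("no enzyme means no catalysis", {
  traj <- simulate_pgk(default_net, sim_config(enzyme_total = 0, tz = 0.05))
  forms <- c("E", "E.ADP", "E.BPG", "E.ADP.BPG", "E.ATP", "E.PG",
             "E.ATP.PG", "E.TZ", "E.TZ.BPG", "E.TZ.PG")
  expect_true(all(as.matrix(traj[, forms]) == 0))
  expect_equal(atp_production(traj), 0)
})

test_that("ATP pool equals the time integral of the phosphotransfer flux", {
  times <- seq(0, 60, length.out = 601)
  traj <- simulate_pgk(default_net, sim_config(tz = 0), times = times)
  v5 <- apply(as.matrix(traj[, -1]), 1, function(s) {
    net_fluxes(default_net, s)$net_flux_uM_s[5]
  })
  integral <- sum(diff(times) * (head(v5, -1) + tail(v5, -1)) / 2)
  expect_lt(rel_err(integral, atp_production(traj)), 5e-3)
})

test_that("production is near-linear in time under quasi-equilibrium", {
  full <- atp_production(simulate_pgk(default_net, sim_config(t_end = 60)))
  half <- atp_production(simulate_pgk(default_net, sim_config(t_end = 30)))
  expect_lt(abs(half / full - 0.5), 0.05)
})

test_that("identical configs give bit-identical trajectories", {
  cfg <- sim_config(tz = 0.05)
  t1 <- simulate_pgk(default_net, cfg)
  t2 <- simulate_pgk(default_net, cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("clamped-ligand simulations reach the null-space steady state", {
  net <- set_clamped(default_net, c("ADP", "BPG", "ATP", "PG", "TZ"))
  set.seed(7)
  for (i in 1:3) {
    lig <- random_ligands()
    oracle <- enzyme_steady_state(net, lig)
    cfg <- sim_config(t_end = 2000, adp = lig[["ADP"]], bpg = lig[["BPG"]],
                      atp = lig[["ATP"]], pg = lig[["PG"]], tz = lig[["TZ"]],
                      rtol = 1e-11, atol = 1e-16)
    st <- final_states(net, cfg)
    frac <- st[names(oracle)] / sum(st[names(oracle)])
    expect_lt(max(abs(frac - oracle) / oracle), 1e-6)
  }
})

test_that("solver tolerances beyond default do not move the answer", {
  loose <- atp_production(simulate_pgk(default_net, sim_config(tz = 0.05)))
  tight <- atp_production(simulate_pgk(
    default_net, sim_config(tz = 0.05, rtol = 1e-11, atol = 1e-14)))
  expect_lt(rel_err(loose, tight), 1e-3)
})

test_that("dose response is computed against the zero-terazosin baseline", {
  dr <- cached_dose_response()
  expect_equal(nrow(dr), 8)
  expect_identical(dr$percent_change[dr$tz_uM == 0], 0)
  expect_equal(dr$percent_change,
               100 * (dr$atp_uM - dr$atp_uM[dr$tz_uM == 0]) /
                 dr$atp_uM[dr$tz_uM == 0])

  flat <- dose_response(default_net, sim_config(tz_grid = 0))
  expect_identical(flat$percent_change, 0)
})

test_that("config validation catches bad protocols", {
  expect_error(sim_config(t_end = 0), "t_end")
  expect_error(sim_config(adp = -1), "non-negative")
  expect_error(sim_config(tz_grid = c(0.05, 25)), "baseline")
  expect_error(simulate_pgk(default_net, sim_config(), times = c(0, 30)),
               "t_end")
})

test_that("apparent Km scales as a competitive mechanism should", {
  grid <- c(20, 50, 150, 400, 1200, 4000, 12000, 40000)
  k0 <- predict_apparent_km(default_net, tz = 0, adp_grid = grid)
  k1 <- predict_apparent_km(default_net, tz = 0.5, adp_grid = grid)
  expect_gt(k1$km_uM, k0$km_uM)

  # noiseless fit: Vmax close to the rate at saturating ADP
  cfg_sat <- sim_config(adp = max(grid))
  sat_rate <- tzpgk:::initial_production_rate(default_net, cfg_sat)
  expect_lt(rel_err(k0$vmax_uM_s, sat_rate), 0.05)

  # doubling enzyme doubles Vmax and leaves Km unchanged (small residual
  # nonlinearity from product rebinding, which also scales with enzyme)
  k2 <- predict_apparent_km(default_net, tz = 0, adp_grid = grid,
                            config = sim_config(enzyme_total = 0.08))
  expect_lt(rel_err(k2$vmax_uM_s, 2 * k0$vmax_uM_s), 0.02)
  expect_lt(rel_err(k2$km_uM, k0$km_uM), 0.01)
})
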