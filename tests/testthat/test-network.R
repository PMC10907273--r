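test_that("canonical network has the documented topology and rate wiring", {
  net <- default_net
  expect_equal(nrow(net$species), 15)
  expect_equal(sum(net$species$role == "enzyme-form"), 10)
  expect_equal(nrow(net$reactions), 14)
  expect_true(all(net$species$clamped == (net$species$name == "BPG")))

  # every rate-constant pair drives at least one reaction
  refs <- c(net$reactions$kf_ref, net$reactions$kr_ref)
  for (p in c("a_plus", "a_minus", "b_plus", "b_minus", "c_plus", "c_minus",
              "d_plus", "d_minus", "k_plus", "k_minus")) {
    expect_true(p %in% refs, info = p)
  }

  # 3-PG release from E.TZ.PG reuses b-, the fast phosphoglycerate off-rate
  expect_equal(net$reactions$kr[net$reactions$id == "R14"], 160)
  # terazosin association edges carry the eta multiplier
  expect_equal(net$reactions$kf[net$reactions$id == "R10"], 562 * 6.1)
  expect_equal(net$reactions$kf[net$reactions$id == "R11"], 562 * 4.1)

  # published default rate constants
  p <- rate_parameters()
  expect_equal(unclass(p)[c("a_plus", "a_minus", "b_plus", "b_minus",
                            "c_plus", "c_minus", "d_plus", "d_minus",
                            "k_plus", "k_minus", "eta")],
               list(a_plus = 6.1, a_minus = 38, b_plus = 170, b_minus = 160,
                    c_plus = 450, c_minus = 14, d_plus = 4.1, d_minus = 270,
                    k_plus = 5, k_minus = 5, eta = 562))
})

test_that("eta = 0 disconnects the terazosin-bound forms", {
  net0 <- pgk_network(rate_parameters(eta = 0))
  tz_rx <- net0$reactions$id %in% c("R10", "R11", "R12")
  expect_true(all(net0$reactions$kf[tz_rx] == 0))
  # from a terazosin-free start the TZ-bound forms stay exactly zero
  traj <- simulate_pgk(net0, sim_config(tz = 0.05))
  expect_true(all(as.matrix(traj[, c("E.TZ", "E.TZ.BPG", "E.TZ.PG")]) == 0))
})

test_that("parameter validation rejects invalid values", {
  expect_error(rate_parameters(a_plus = -1), "a_plus")
  expect_error(rate_parameters(eta = NaN), "eta")
  expect_error(pgk_network(clamped = "XYZ"), "unknown species")
  expect_error(mass_action_rhs(default_net,
                               state_vector(default_net, E = -0.1)),
               "negative")
})

test_that("mass-action derivatives match hand-evaluated rates", {
  net <- default_net

  # free enzyme with nothing to bind is a fixed point
  d0 <- mass_action_rhs(net, state_vector(net, E = 0.04))
  expect_true(all(d0 == 0))

  # single active term: a+ [E][ADP] = 6.1 * 0.04 * 1000 = 244 uM/s
  st <- state_vector(net, E = 0.04, ADP = 1000)
  d <- mass_action_rhs(net, st)
  expect_equal(d[["E.ADP"]], 244)
  expect_equal(d[["E"]], -244)

  # detailed balance of one reversible edge: [E.ADP] = (a+/a-)[E][ADP]
  st_eq <- state_vector(net, E = 0.01, ADP = 200,
                        E.ADP = (6.1 / 38) * 0.01 * 200)
  expect_equal(max(abs(mass_action_rhs(net, st_eq))), 0)
})

test_that("derivatives respect clamping and conservation at random states", {
  set.seed(42)
  for (i in 1:25) {
    st <- state_vector(default_net)
    st[] <- stats::runif(length(st), 0, 100)
    d <- mass_action_rhs(default_net, st)
    expect_identical(d[["BPG"]], 0) # clamped
    forms <- c("E", "E.ADP", "E.BPG", "E.ADP.BPG", "E.ATP", "E.PG",
               "E.ATP.PG", "E.TZ", "E.TZ.BPG", "E.TZ.PG")
    expect_lt(abs(sum(d[forms])), 1e-10 * max(abs(d)))
    adenine <- c("ADP", "ATP", "E.ADP", "E.ADP.BPG", "E.ATP", "E.ATP.PG")
    expect_lt(abs(sum(d[adenine])), 1e-10 * max(abs(d)))
    tz <- c("TZ", "E.TZ", "E.TZ.BPG", "E.TZ.PG")
    expect_lt(abs(sum(d[tz])), 1e-10 * max(abs(d)))
  }
})

test_that("terazosin-free dynamics reduce to the 7-form subnetwork", {
  net7 <- pgk_network(include_tz = FALSE)
  expect_equal(nrow(net7$reactions), 9)
  times <- seq(0, 60, length.out = 7)
  cfg <- sim_config(tz = 0)
  full <- simulate_pgk(default_net, cfg, times = times)
  red <- simulate_pgk(net7, cfg, times = times)
  shared <- names(red)
  expect_equal(as.matrix(as.data.frame(full)[, shared]),
               as.matrix(as.data.frame(red)[, shared]),
               tolerance = 1e-8)
})

test_that("network JSON export round-trips the full description", {
  path <- withr::local_tempfile(fileext = ".json")
  network_to_json(default_net, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$species$name, default_net$species$name)
  expect_equal(back$reactions$id, default_net$reactions$id)
  expect_equal(back$reactions$kf, default_net$reactions$kf)
  expect_equal(unlist(back$parameters), unlist(unclass(default_net$params)))
})
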