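test_that("rest is a fixed point for both fiber types", {
  f <- fix_myel(10, 7)
  r <- simulate_fiber(f, config = sim_config(dt = 0.002, t_sim = 5))
  expect_lt(max(abs(r$V - f$v_rest)), 1)
  u <- fix_unmyel()
  ru <- simulate_fiber(u, config = sim_config(dt = 0.005, t_sim = 5))
  expect_lt(max(abs(ru$V - u$v_rest)), 1)
})

test_that("a suprathreshold clamp elicits a distally propagating AP", {
  f <- fix_myel(10, 11)
  r <- simulate_fiber(f, clamps = list(fix_test_clamp()),
                      config = sim_config(dt = 0.002, t_sim = 2))
  nodes <- which(f$comp$label == "node")
  distal <- nodes[length(nodes)]
  expect_gt(max(r$V[distal, ]), 0)    # AP observed at the most distal node
  det <- detect_propagating_ap(r, f$comp$x[distal])
  expect_true(det$detected)
  expect_gt(det$t_cross, 0.1)
})

test_that("compartment-summed membrane current balances the injected current", {
  # Kirchhoff oracle on a 3-compartment toy fiber
  f <- unmyelinated_fiber(1, 100, n_compartments = 3L)
  stim <- make_pulse(0.2, 0.001, 1)
  r <- simulate_fiber(f, clamps = list(clamp_current(2L, stim)),
                      config = sim_config(dt = 0.001, t_sim = 2,
                                          record_imem = TRUE))
  inj <- stim_eval(stim, r$time)
  total <- colSums(r$imem)
  on <- inj != 0
  expect_lt(max(abs(total[on] - inj[on]) / abs(inj[on])), 0.001)
  # and on a myelinated fiber (double cable)
  fm <- fix_myel(10, 5)
  stim2 <- make_pulse(0.2, 0.002, 0.5)
  rm <- simulate_fiber(fm, clamps = list(clamp_current(1L, stim2)),
                       config = sim_config(dt = 0.001, t_sim = 1,
                                           record_imem = TRUE))
  inj2 <- stim_eval(stim2, rm$time)
  tot2 <- colSums(rm$imem)
  on2 <- inj2 != 0
  expect_lt(max(abs(tot2[on2] - inj2[on2]) / abs(inj2[on2])), 0.001)
})

test_that("conduction velocity increases with myelinated diameter", {
  vel <- vapply(c(5.7, 10, 16), function(d) {
    f <- myelinated_fiber(d, n_nodes = 15L)
    r <- simulate_fiber(f, clamps = list(fix_test_clamp()),
                        config = sim_config(dt = 0.002, t_sim = 3))
    nx <- node_positions(f)
    conduction_velocity(r, nx[5L], nx[12L])
  }, numeric(1L))
  expect_true(all(diff(vel) > 0))
  expect_gt(vel[2L], 30)   # 10 um fiber in the tens of m/s
})

test_that("myelinated conduction is far faster than unmyelinated", {
  f <- myelinated_fiber(10, n_nodes = 11L)
  rm <- simulate_fiber(f, clamps = list(fix_test_clamp()),
                       config = sim_config(dt = 0.002, t_sim = 2))
  nx <- node_positions(f)
  vm <- conduction_velocity(rm, nx[3L], nx[9L])
  u <- unmyelinated_fiber(1, 3000)
  ru <- simulate_fiber(u, clamps = list(clamp_current(1L, make_pulse(0.1, 0.005, 1))),
                       config = sim_config(dt = 0.005, t_sim = 15))
  vu <- conduction_velocity(ru, 800, 2500)
  expect_gt(vm / vu, 10)
})

test_that("velocity measurement rejects degenerate positions", {
  f <- fix_myel(10, 7)
  r <- simulate_fiber(f, clamps = list(fix_test_clamp()),
                      config = sim_config(dt = 0.002, t_sim = 2))
  nx <- node_positions(f)
  expect_error(conduction_velocity(r, nx[3L], nx[3L]), "same compartment")
  r0 <- simulate_fiber(f, config = sim_config(dt = 0.002, t_sim = 1))
  expect_error(conduction_velocity(r0, nx[1L], nx[5L]),
               "no action potential")
})

test_that("shifting all stimuli in time shifts the crossings equally", {
  f <- fix_myel(10, 9)
  nx <- node_positions(f)
  run <- function(t0) {
    r <- simulate_fiber(f, clamps = list(fix_test_clamp(t0 = t0)),
                        config = sim_config(dt = 0.002, t_sim = 2.5))
    detect_propagating_ap(r, nx[8L])$t_cross
  }
  t1 <- run(0.1); t2 <- run(0.6)
  expect_equal(t2 - t1, 0.5, tolerance = 0.01)
})

test_that("a centered clamp produces mirror-symmetric voltages", {
  f <- unmyelinated_fiber(1, 1000, n_compartments = 21L)
  r <- simulate_fiber(f, clamps = list(clamp_current(11L, make_pulse(0.1, 0.002, 0.5))),
                      config = sim_config(dt = 0.005, t_sim = 3))
  expect_equal(r$V[1:10, ], r$V[21:12, ], tolerance = 1e-9)
})

test_that("voltage clamp pins the commanded compartment", {
  f <- fix_unmyel(1, 500)
  cmd <- stimulus(c(0, 1), c(-20, -20))
  r <- simulate_fiber(f, clamps = list(clamp_voltage(1L, cmd)),
                      config = sim_config(dt = 0.01, t_sim = 2))
  expect_equal(r$V[1L, ncol(r$V)], -20, tolerance = 1e-6)
})

test_that("threshold estimates are insensitive to halving dt", {
  f <- myelinated_fiber(10, n_nodes = 9L)
  el <- point_source(node_positions(f)[5L], 500, 0)
  mat <- material(0.2)
  wf <- make_pulse(0.1, -1, 0.1)
  th <- function(dt) activation_threshold(
    f, el, mat, wf, config = sim_config(dt = dt, t_sim = 2),
    spec = threshold_spec(lower = 20, upper = 400, tol = 0.001))$threshold
  expect_rel(th(0.002), th(0.001), 0.02)
})
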