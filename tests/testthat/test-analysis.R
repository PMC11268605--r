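test_that("AP detection distinguishes rest, clamp site and distal arrival", {
  f <- fix_myel(10, 11)
  r0 <- simulate_fiber(f, config = sim_config(dt = 0.002, t_sim = 2))
  expect_false(detect_propagating_ap(r0, f$length / 2)$detected)

  r <- simulate_fiber(f, clamps = list(fix_test_clamp()),
                      config = sim_config(dt = 0.002, t_sim = 2))
  near <- detect_propagating_ap(r, 0)
  far <- detect_propagating_ap(r, f$length)
  expect_true(near$detected && far$detected)
  expect_gt(far$t_cross, near$t_cross)     # causality
})

test_that("bisection honours its tolerance contract and bracket invariance", {
  # analytic response with known threshold 123.4
  resp <- function(a) a >= 123.4
  s1 <- threshold_search(resp, threshold_spec(lower = 1, upper = 1000,
                                              tol = 0.001))
  expect_lte((s1$threshold - s1$lower) / s1$lower, 0.001)
  expect_gte(s1$threshold, 123.4)
  expect_rel(s1$threshold, 123.4, 0.002)
  # different valid starting bracket -> same threshold within tolerance
  s2 <- threshold_search(resp, threshold_spec(lower = 100, upper = 200,
                                              tol = 0.001))
  expect_rel(s2$threshold, s1$threshold, 0.002)
  # automatic expansion when the bracket misses
  s3 <- threshold_search(resp, threshold_spec(lower = 1, upper = 2,
                                              tol = 0.001))
  expect_rel(s3$threshold, 123.4, 0.002)
  expect_error(threshold_search(function(a) FALSE,
                                threshold_spec(max_expand = 3L)),
               "no response")
})

test_that("activation threshold decreases with fiber diameter", {
  mat <- material(0.2)
  wf <- make_pulse(0.1, -1, 0.1)
  th <- vapply(c(5.7, 10, 16), function(d) {
    f <- myelinated_fiber(d, n_nodes = 9L)
    el <- point_source(node_positions(f)[5L], 1000, 0)
    activation_threshold(f, el, mat, wf,
                         config = sim_config(dt = 0.002, t_sim = 2),
                         spec = threshold_spec(lower = 50, upper = 1000,
                                               tol = 0.001))$threshold
  }, numeric(1L))
  expect_true(all(diff(th) < 0))
})

test_that("activation threshold decreases with pulse width", {
  f <- myelinated_fiber(10, n_nodes = 9L)
  el <- point_source(node_positions(f)[5L], 1000, 0)
  mat <- material(0.2)
  th <- vapply(c(0.01, 0.05, 0.1), function(w) {
    activation_threshold(f, el, mat, make_pulse(0.1, -1, w),
                         config = sim_config(dt = 0.002, t_sim = 2),
                         spec = threshold_spec(lower = 50, upper = 1200,
                                               tol = 0.001))$threshold
  }, numeric(1L))
  expect_true(all(diff(th) < 0))     # strength-duration property
})

test_that("thresholds are deterministic across repeat runs", {
  f <- myelinated_fiber(10, n_nodes = 7L)
  el <- point_source(node_positions(f)[4L], 800, 0)
  run <- function() activation_threshold(
    f, el, material(0.2), make_pulse(0.1, -1, 0.05),
    config = sim_config(dt = 0.002, t_sim = 2),
    spec = threshold_spec(lower = 50, upper = 800, tol = 0.001))$threshold
  expect_identical(run(), run())
})

test_that("amplitude-latency fit recovers a constructed power law", {
  tt <- seq(0, 5, by = 0.005)
  lats <- c(0.5, 0.8, 1.2, 1.7, 2.3, 3.0)
  amps <- 4 * lats^(-2)
  pot <- t(vapply(seq_along(lats), function(i) {
    amps[i] * exp(-((tt - lats[i]) / 0.05)^2)
  }, numeric(length(tt))))
  ec <- list(time = tt, potential = pot)
  fit <- amplitude_latency_fit(ec, exclude_first = FALSE)
  expect_equal(fit$slope, -2, tolerance = 1e-6)
  # slope invariant to uniform amplitude scaling
  ec2 <- list(time = tt, potential = 37 * pot)
  expect_equal(amplitude_latency_fit(ec2, exclude_first = FALSE)$slope,
               fit$slope, tolerance = 1e-9)
  # excluding the first point drops it from the fit but not the table
  fit2 <- amplitude_latency_fit(ec, exclude_first = TRUE)
  expect_equal(nrow(fit2$points), length(lats))
})

test_that("recruitment endpoints and the width shift are physical", {
  pop <- axon_packing(create_axon_population(12, 1, seed = 21), seed = 21)
  fasc <- fascicle(pop, length = 6000)
  el <- point_source(3000, 150, 0)
  mat <- material(0.2)
  curve <- recruitment_curve(
    fasc, el, mat, sweep = c(0.5, 30, 80, 200, 500),
    waveform = make_pulse(0.1, -1, 0.05),
    config = sim_config(dt = 0.002, t_sim = 2))
  expect_equal(curve$recruited[1L], 0)            # ~zero amplitude
  expect_equal(curve$recruited[nrow(curve)], 1)   # far above max threshold
  expect_true(all(diff(curve$recruited) >= 0))    # monotone recruitment

  # halving pulse width shifts the curve toward higher amplitudes
  curve2 <- recruitment_curve(
    fasc, el, mat, sweep = c(0.5, 30, 80, 200, 500),
    waveform = make_pulse(0.1, -1, 0.025),
    config = sim_config(dt = 0.002, t_sim = 2))
  expect_true(all(curve2$recruited <= curve$recruited))
  expect_lt(sum(curve2$recruited), sum(curve$recruited))
})
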