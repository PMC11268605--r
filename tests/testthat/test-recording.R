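test_that("PSA recorder footprint equals the field-side footprint", {
  mat <- material(c(0.57, 0.085, 0.085))
  pt <- c(100, 250, -40); comp <- c(900, 10, 25)
  expect_equal(recorder_footprint_psa(pt, comp, mat),
               psa_footprint(comp, pt, mat))
  # isotropic closed form at 1 mm
  expect_equal(recorder_footprint_psa(c(0, 0, 0), c(1000, 0, 0),
                                      material(0.2)),
               1 / (4 * pi * 0.2 * 1e-3), tolerance = 1e-12)
})

test_that("LSA matches PSA quadrature and its far-field limit", {
  mat <- material(0.2)
  quad <- function(point, x0, x1, y, z) {
    stats::integrate(function(s) vapply(s, function(si)
      psa_footprint(c(si, y, z), point, mat), numeric(1L)),
      x0, x1, rel.tol = 1e-10)$value / (x1 - x0)
  }
  cases <- list(
    list(p = c(500, 300, 0), x0 = 0, x1 = 100),    # beyond the end
    list(p = c(50, 300, 0), x0 = 0, x1 = 100),     # over the segment
    list(p = c(-200, 150, 80), x0 = 0, x1 = 60))
  for (cs in cases) {
    lsa <- recorder_footprint_lsa(cs$p, cs$x0, cs$x1, 0, 0, mat)
    expect_rel(lsa, quad(cs$p, cs$x0, cs$x1, 0, 0), 0.005)
  }
  # dl -> 0: equals PSA at the midpoint within 0.1% when r > 100 dl
  lsa <- recorder_footprint_lsa(c(2000, 1500, 0), 0, 10, 0, 0, mat)
  psa <- psa_footprint(c(5, 0, 0), c(2000, 1500, 0), mat)
  expect_rel(lsa, psa, 0.001)
  # dimensional scaling: doubling all lengths halves the footprint
  a <- recorder_footprint_lsa(c(300, 120, 0), 0, 50, 0, 0, mat)
  b <- recorder_footprint_lsa(c(600, 240, 0), 0, 100, 0, 0, mat)
  expect_equal(b, a / 2, tolerance = 1e-12)
})

test_that("LSA requires an isotropic material and off-axis points", {
  expect_error(recorder(c(0, 100, 0), material(c(0.5, 0.1, 0.1)),
                        method = "LSA"), "isotropic")
  expect_error(recorder_footprint_lsa(c(50, 0, 0), 0, 100, 0, 0,
                                      material(0.2)), "singularity")
})

test_that("eCAP is a linear superposition of per-fiber contributions", {
  cfg <- sim_config(dt = 0.002, t_sim = 1.5, record_imem = TRUE)
  f1 <- myelinated_fiber(10, n_nodes = 7L, y = 30)
  f2 <- myelinated_fiber(5.7, n_nodes = 9L, y = -40)
  r1 <- simulate_fiber(f1, clamps = list(fix_test_clamp()), config = cfg)
  r2 <- simulate_fiber(f2, clamps = list(fix_test_clamp()), config = cfg)
  rec <- recorder(rbind(c(2000, 150, 0), c(4000, 150, 0)))
  eboth <- compute_ecap(list(r1, r2), rec)
  e1 <- compute_ecap(r1, rec)
  e2 <- compute_ecap(r2, rec)
  expect_equal(eboth$potential, e1$potential + e2$potential)
})

test_that("doubling membrane currents doubles the recorded potential", {
  f <- myelinated_fiber(10, n_nodes = 7L)
  r <- simulate_fiber(f, clamps = list(fix_test_clamp()),
                      config = sim_config(dt = 0.002, t_sim = 1.5,
                                          record_imem = TRUE))
  rec <- recorder(c(3000, 200, 0))
  e1 <- compute_ecap(r, rec)
  r2 <- r; r2$imem <- 2 * r$imem
  e2 <- compute_ecap(r2, rec)
  expect_equal(e2$potential, 2 * e1$potential)
})

test_that("opposite equidistant current sources cancel at the recorder", {
  # constructed two-compartment current pattern, symmetric about the point
  f <- unmyelinated_fiber(1, 1000, n_compartments = 11L)
  r <- simulate_fiber(f, config = sim_config(dt = 0.01, t_sim = 0.1,
                                             record_imem = TRUE))
  r$imem[] <- 0
  r$imem[3L, ] <- 1; r$imem[9L, ] <- -1     # symmetric about x = 500
  rec <- recorder(c(500, 100, 0))
  e <- compute_ecap(r, rec)
  expect_lt(max(abs(e$potential)), 1e-12)
  # a single constant source gives footprint x current, constant in time
  r$imem[] <- 0; r$imem[3L, ] <- 2
  fp <- recorder_footprints(rec, f)
  e1 <- compute_ecap(r, rec)
  expect_equal(unname(e1$potential[1L, ]),
               rep(2 * fp[1L, 3L] / 1000, length(r$time)))
})

test_that("eCAP peak amplitude decreases with recorder distance", {
  f <- myelinated_fiber(10, n_nodes = 11L)
  r <- simulate_fiber(f, clamps = list(fix_test_clamp()),
                      config = sim_config(dt = 0.002, t_sim = 2,
                                          record_imem = TRUE))
  mid <- f$length / 2
  rr <- c(100, 300, 900)
  peaks <- vapply(rr, function(d) {
    e <- compute_ecap(r, recorder(c(mid, d, 0)))
    max(abs(e$potential))
  }, numeric(1L))
  expect_true(all(diff(peaks) < 0))
})

test_that("peak latency along the fiber is consistent with velocity", {
  f <- myelinated_fiber(10, n_nodes = 15L)
  r <- simulate_fiber(f, clamps = list(fix_test_clamp()),
                      config = sim_config(dt = 0.002, t_sim = 3,
                                          record_imem = TRUE))
  nx <- node_positions(f)
  v <- conduction_velocity(r, nx[4L], nx[12L])
  xs <- seq(4000, 12000, by = 2000)
  rec <- recorder(cbind(xs, 300, 0))
  e <- compute_ecap(r, rec)
  # track the main negative deflection of the traveling wave (its largest
  # lobe can alternate between phases; the negative lobe is single-phase)
  lat <- apply(e$potential, 1L, function(p) e$time[which.min(p)])
  fit <- stats::lm(lat ~ xs)
  v_lat <- 1 / stats::coef(fit)[[2L]] / 1000    # um/ms -> m/s
  expect_rel(v_lat, v, 0.05)
})

test_that("stimulation artifact superposes onto the recording", {
  f <- myelinated_fiber(10, n_nodes = 7L)
  r <- simulate_fiber(f, config = sim_config(dt = 0.002, t_sim = 1,
                                             record_imem = TRUE))
  el <- point_source(f$length / 2, 2000, 0)
  ctx <- extracellular_context(
    material(0.2), list(list(electrode = el, stim = make_pulse(0.2, -100, 0.3))))
  rec <- recorder(c(1000, 400, 0))
  e0 <- compute_ecap(r, rec)
  e1 <- compute_ecap(r, rec, artifact_context = ctx)
  expect_equal(e1$potential - e0$potential,
               field_at(rec$points, r$time, ctx))
})
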