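test_that("HH rates reproduce the canonical steady states at rest", {
  r <- hh_rates(-65)
  expect_equal(r$minf, 0.0529, tolerance = 0.01)
  expect_equal(r$hinf, 0.5961, tolerance = 0.01)
  expect_equal(r$ninf, 0.3177, tolerance = 0.01)
})

test_that("gate steady states saturate and stay in [0, 1]", {
  expect_gt(hh_rates(80)$minf, 0.99)
  vv <- seq(-120, 80, by = 1)
  r <- hh_rates(vv)
  for (g in list(r$minf, r$hinf, r$ninf)) {
    expect_true(all(g >= 0 & g <= 1))
  }
  rm <- mrg_rates(vv)
  for (g in list(rm$minf, rm$hinf, rm$mpinf, rm$sinf))
    expect_true(all(g >= 0 & g <= 1))
  # singular points of the rate expressions are handled
  expect_true(is.finite(hh_rates(-40)$am))
  expect_true(is.finite(mrg_rates(-20.4)$am))
})

test_that("morphology interpolation passes through the published table", {
  # published double-cable geometry rows (diameter, node-node spacing,
  # axon diameter, node diameter, juxtaparanode length, lamellae)
  tab <- data.frame(
    fiber = c(5.7, 7.3, 8.7, 10, 11.5, 12.8, 14, 15, 16),
    deltax = c(500, 750, 1000, 1150, 1250, 1350, 1400, 1450, 1500),
    axon_d = c(3.4, 4.6, 5.8, 6.9, 8.1, 8.8, 9.2, 10.4, 10.9),
    node_d = c(1.9, 2.4, 2.8, 3.3, 3.7, 4.2, 4.7, 5.0, 5.5),
    flut_l = c(35, 38, 40, 46, 50, 54, 56, 58, 60),
    nl = c(80, 100, 110, 120, 130, 135, 140, 145, 150))
  for (i in seq_len(nrow(tab))) {
    m <- mrg_morphology(tab$fiber[i])
    expect_rel(m$internode_length, tab$deltax[i], 0.01)
    expect_rel(m$axon_diameter, tab$axon_d[i], 0.01)
    expect_rel(m$node_diameter, tab$node_d[i], 0.01)
    expect_rel(m$flut_length, tab$flut_l[i], 0.01)
    expect_rel(m$n_lamellae, tab$nl[i], 0.01)
  }
})

test_that("morphology stays positive over the whole domain", {
  for (d in seq(1, 20, by = 0.25)) {
    m <- mrg_morphology(d)
    expect_true(all(unlist(m) > 0), info = paste("diameter", d))
  }
  expect_error(mrg_morphology(0.5), "1, 20")
  expect_error(mrg_morphology(25), "1, 20")
})

test_that("internode length and axon diameter increase with fiber diameter", {
  dd <- seq(2, 20, by = 0.5)
  deltax <- vapply(dd, function(d) mrg_morphology(d)$internode_length,
                   numeric(1L))
  axon <- vapply(dd, function(d) mrg_morphology(d)$axon_diameter, numeric(1L))
  expect_true(all(diff(deltax) > 0))
  expect_true(all(diff(axon) > 0))
})

test_that("section lengths between nodes sum to the internodal gap", {
  for (d in c(1.5, 5.7, 10, 16, 19)) {
    m <- mrg_morphology(d)
    span <- 2 * m$mysa_length + 2 * m$flut_length + 6 * m$stin_length
    expect_equal(span, m$internode_length - m$node_length, tolerance = 1e-9)
  }
})

test_that("membrane currents balance at rest and respond to depolarization", {
  f <- fix_unmyel()
  v0 <- rep(f$v_rest, nrow(f$comp))
  ic <- membrane_currents(f, v0)
  expect_lt(max(abs(ic$i_ion)), 1e-8)   # rest: net ionic current ~ 0
  # all conductances zero -> no current
  f0 <- f
  f0$membrane$gna <- f0$membrane$gk <- f0$membrane$gl <- 0
  expect_equal(membrane_currents(f0, v0)$i_ion, rep(0, nrow(f$comp)))
  # depolarize to 0 mV with h frozen at rest: inward (negative) Na current
  r <- hh_rates(f$v_rest)
  rd <- hh_rates(0)
  g <- list(m = rep(rd$minf, nrow(f$comp)), h = rep(r$hinf, nrow(f$comp)),
            n = rep(r$ninf, nrow(f$comp)))
  fna <- f
  fna$membrane$gk <- 0; fna$membrane$gl <- 0
  expect_lt(membrane_currents(fna, rep(0, nrow(f$comp)), gates = g)$i_ion[1L],
            0)
})

test_that("myelinated fiber geometry follows the node/internode sequence", {
  f <- fix_myel(10, 11)
  labs <- f$comp$label
  expect_equal(sum(labs == "node"), 11L)
  expect_equal(labs[1:12],
               c("node", "mysa", "flut", rep("stin", 6), "flut", "mysa",
                 "node"))
  expect_equal(nrow(f$comp), 11L + 10L * 10L)
  # node spacing equals the interpolated internodal gap
  nx <- node_positions(f)
  expect_equal(diff(nx), rep(mrg_morphology(10)$internode_length, 10L),
               tolerance = 1e-9)
})

test_that("fiber definitions round-trip through JSON", {
  f <- myelinated_fiber(8.7, y = 30, z = -12, length = 9000)
  f2 <- fiber_from_json(fiber_to_json(f))
  expect_equal(f2$diameter, 8.7)
  expect_equal(f2$y, 30)
  expect_equal(f2$n_nodes, f$n_nodes)
})
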