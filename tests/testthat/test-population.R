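test_that("population generation respects type fractions and determinism", {
  p <- create_axon_population(100, 1, seed = 5)
  expect_true(all(p$type == "myelinated"))
  p0 <- create_axon_population(100, 0, seed = 5)
  expect_true(all(p0$type == "unmyelinated"))
  expect_identical(create_axon_population(50, 0.4, seed = 9),
                   create_axon_population(50, 0.4, seed = 9))
  expect_error(create_axon_population(
    10, 0.5, diameter_stats = list(myelinated = "nope",
                                   unmyelinated = "sciatic_unmyelinated"),
    seed = 1), "unknown diameter distribution")
})

test_that("truncated lognormal sampling matches the analytic mean", {
  spec <- list(name = "trunc_lognormal", meanlog = log(4), sdlog = 0.5,
               min = 1, max = 16)
  p <- create_axon_population(10000, 1,
                              diameter_stats = list(myelinated = spec),
                              seed = 11)
  mu <- trunc_lognormal_mean(log(4), 0.5, 1, 16)
  sem <- stats::sd(p$diameter) / sqrt(nrow(p))
  expect_lt(abs(mean(p$diameter) - mu), 3 * sem)
  expect_true(all(p$diameter >= 1 & p$diameter <= 16))
})

test_that("a single axon packs to the origin", {
  p <- create_axon_population(1, 1, seed = 1)
  p <- axon_packing(p, seed = 1)
  expect_lt(sqrt(p$y^2 + p$z^2), 0.5)
  expect_equal(attr(p, "fitted_radius"), sqrt(p$y^2 + p$z^2) + p$diameter / 2)
})

test_that("two equal axons settle in contact symmetrically about the origin", {
  p <- create_axon_population(2, 1, seed = 1)
  p$diameter <- c(4, 4)
  gap <- 0.5
  p <- axon_packing(p, delta_gap = gap, seed = 1)
  d <- sqrt(diff(p$y)^2 + diff(p$z)^2)
  expect_rel(d, 4 + gap, 0.05)                    # force-balance distance
  expect_lt(sqrt(mean(p$y)^2 + mean(p$z)^2), 1.5) # pair centered
})

test_that("packing leaves no overlaps, preserves diameters, reproduces", {
  pop <- create_axon_population(150, 0.5, seed = 3)
  packed <- axon_packing(pop, seed = 3)
  expect_equal(count_overlaps(packed), 0L)
  expect_identical(sort(packed$diameter), sort(pop$diameter))
  packed2 <- axon_packing(pop, seed = 3)
  expect_identical(packed$y, packed2$y)           # bit-reproducible
  expect_identical(packed$z, packed2$z)
  # packing density below 1: fitted radius above the equal-area radius
  r_eq <- sqrt(sum((packed$diameter / 2)^2))
  expect_gt(attr(packed, "fitted_radius"), r_eq)
})

test_that("packing respects a minimal inter-fiber gap", {
  pop <- create_axon_population(40, 1, seed = 2)
  packed <- axon_packing(pop, delta_gap = 1, seed = 2)
  expect_equal(count_overlaps(packed, delta_gap = 1), 0L)
})

test_that("population operations behave literally", {
  pop <- axon_packing(create_axon_population(60, 0.5, seed = 4), seed = 4)
  f <- filter_by_diameter(pop, min = 2)
  expect_true(all(f$diameter >= 2))

  disk <- c(pop$y[1L], pop$z[1L])
  r2 <- remove_overlapping_with_disk(pop, disk, 5)
  dd <- sqrt((r2$y - disk[1L])^2 + (r2$z - disk[2L])^2)
  expect_true(all(dd >= 5 + r2$diameter / 2))
  expect_lt(nrow(r2), nrow(pop))

  t2 <- translate_population(translate_population(pop, 10, -3), -10, 3)
  expect_equal(t2$y, pop$y)
  r360 <- rotate_population(pop, 360)
  expect_equal(r360$y, pop$y, tolerance = 1e-9)
  expect_equal(r360$z, pop$z, tolerance = 1e-9)
})

test_that("fascicle and nerve enforce their geometric invariants", {
  pop <- axon_packing(create_axon_population(20, 1, seed = 6), seed = 6)
  fa <- fascicle(pop, length = 5000)
  rr <- sqrt(pop$y^2 + pop$z^2) + pop$diameter / 2
  expect_gte(fa$radius, max(rr))
  expect_error(fascicle(pop, radius = max(rr) / 2), "beyond the fascicle")

  fb <- fascicle(pop, center = c(200, 0), length = 5000)
  expect_error(nerve(list(fa, fa), diameter = 1000), "overlap")
  n <- nerve(list(fascicle(pop, center = c(-100, 0), length = 5000),
                  fascicle(pop, center = c(100, 0), length = 5000)),
             diameter = 500)
  expect_length(n$fascicles, 2L)
})

test_that("populations round-trip through CSV", {
  pop <- axon_packing(create_axon_population(15, 0.4, seed = 8), seed = 8)
  tf <- tempfile(fileext = ".csv")
  write_population(pop, tf)
  p2 <- read_population(tf)
  expect_equal(p2$diameter, pop$diameter)
  expect_equal(p2$y, pop$y)
  expect_equal(p2$type, pop$type)
  unlink(tf)
})
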