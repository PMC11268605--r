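test_that("energy-recruitment cost matches its closed forms", {
  # zero stimulus, zero recruited -> alpha_r * N
  expect_equal(energy_recruitment_cost(numeric(10), 205, 0,
                                       alpha_e = 2e-4, alpha_r = 3),
               3 * 205)
  # full recruitment -> energy term only
  i <- c(0, -11, -11, 0)
  expect_equal(energy_recruitment_cost(i, 205, 205,
                                       alpha_e = 2e-4, alpha_r = 3),
               2e-4 * sum(i^2))
  # doubling the stimulus quadruples the energy term
  e1 <- energy_recruitment_cost(i, 10, 10, alpha_e = 1, alpha_r = 5)
  e2 <- energy_recruitment_cost(2 * i, 10, 10, alpha_e = 1, alpha_r = 5)
  expect_equal(e2, 4 * e1)
  # dt-weighted variant
  expect_equal(energy_recruitment_cost(i, 1, 1, alpha_e = 1, alpha_r = 0,
                                       dt_weighted = TRUE, dt = 0.01),
               0.01 * sum(i^2))
})

test_that("full recruitment dominates when alpha_r exceeds the energy bound", {
  # bound on the energy sum implied by amplitude/duration bounds
  n_axon <- 50
  alpha_e <- 1e-3; max_energy <- 100^2 * 20
  alpha_r <- alpha_e * max_energy + 1
  full <- energy_recruitment_cost(rep(-100, 20), n_axon, n_axon,
                                  alpha_e = alpha_e, alpha_r = alpha_r)
  missing_one <- energy_recruitment_cost(numeric(20), n_axon, n_axon - 1,
                                         alpha_e = alpha_e,
                                         alpha_r = alpha_r)
  expect_lt(full, missing_one)
})

test_that("square parameterization realizes the commanded pulse", {
  par <- waveform_parameterization("square", t_start = 0.1)
  s <- par$build(c(11, 0.232))
  expect_equal(s$times, c(0.1, 0.1 + 0.232))
  expect_equal(s$values, c(-11, 0))
  expect_equal(par$dimension, 2L)
})

test_that("spline parameterization is cathodic, pinned and sort-invariant", {
  par <- waveform_parameterization("spline", n_knots = 1L, t_end = 1)
  s <- par$build(c(40, 0.5))
  expect_equal(stim_eval(s, par$t_start + 0.5), -40, tolerance = 1e-6)
  expect_equal(stim_eval(s, par$t_start), 0)
  expect_equal(stim_eval(s, par$t_start + 1), 0)
  expect_true(all(s$values <= 0))

  par2 <- waveform_parameterization("spline", n_knots = 2L, t_end = 1)
  expect_equal(par2$dimension, 4L)
  s1 <- par2$build(c(10, 0.3, 30, 0.7))
  s2 <- par2$build(c(30, 0.7, 10, 0.3))     # unsorted knots
  expect_equal(s1$values, s2$values)
})

test_that("the waveform context modifier never mutates the static context", {
  static_ctx <- list(stim = make_pulse(0, -1, 1), tag = "static")
  h0 <- config_hash(static_ctx["stim"])
  par <- waveform_parameterization("square")
  ctx2 <- context_modifier_waveform(c(5, 0.2), par, static_ctx)
  expect_equal(config_hash(static_ctx["stim"]), h0)
  expect_false(identical(ctx2$stim, static_ctx$stim))
  expect_equal(ctx2$tag, "static")
})

test_that("PSO solves the 2-D sphere problem to high accuracy", {
  vals <- vapply(1:5, function(s)
    pso_optimize(function(x) sum(x^2), c(-5, -5), c(5, 5),
                 n_particles = 25L, n_iterations = 60L, seed = s)$value,
    numeric(1L))
  expect_lt(mean(vals), 1e-3)
})

test_that("PSO bookkeeping: monotone trace, determinism, degenerate runs", {
  r <- pso_optimize(function(x) sum((x - 1)^2), c(-4, -4), c(4, 4), seed = 3)
  expect_true(all(diff(r$trace$best) <= 0))
  r2 <- pso_optimize(function(x) sum((x - 1)^2), c(-4, -4), c(4, 4), seed = 3)
  expect_identical(r$par, r2$par)
  r0 <- pso_optimize(function(x) sum(x^2), c(-1, -1), c(1, 1),
                     n_iterations = 0L, seed = 5)
  expect_equal(nrow(r0$trace), 1L)      # best of the initial swarm
  expect_true(all(abs(r0$par) <= 1))
})

test_that("identity filter composed into a cost function changes nothing", {
  sim <- function(ctx) ctx$stim$values
  ce <- function(v) sum(v^2)
  cm <- function(x, ctx) { ctx$stim <- stimulus(seq_along(x), x); ctx }
  base_cf <- cost_function(list(), cm, ce, sim)
  filt_cf <- cost_function(list(), cm, ce, sim, filter = identity)
  x <- c(0.3, -2, 1)
  expect_identical(base_cf(x), filt_cf(x))
})

test_that("optimization logs a JSONL trace", {
  tf <- tempfile(fileext = ".jsonl")
  optimize_problem(function(x) sum(x^2),
                   list(lower = c(-1, -1), upper = c(1, 1)),
                   n_particles = 5L, n_iterations = 3L, seed = 1,
                   log_path = tf)
  lines <- readLines(tf)
  expect_length(lines, 4L)              # iterations 0..3
  rec <- jsonlite::fromJSON(lines[2L])
  expect_named(rec, c("iteration", "best", "mean"))
  unlink(tf)
})
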