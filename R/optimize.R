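#' Cost function formalism for stimulation optimization
#'
#' A cost function binds four objects: an optional `filter` (vector
#' transform, identity if not given), a `static_context` (any simulable
#' description: fiber, fascicle + stimulation set-up, or an arbitrary list),
#' a `context_modifier` mapping an input vector to a modified *copy* of the
#' static context, and a `cost_evaluation` mapping the simulation outcome of
#' the modified context to a scalar. The resulting object is callable:
#' `cf(x)` evaluates `cost_evaluation(simulate(context_modifier(filter(x),
#' static_context)))`, where `simulate` is a user-supplied runner.
#'
#' @param static_context the base simulation description (never mutated).
#' @param context_modifier `function(x, context) -> context`.
#' @param cost_evaluation `function(sim_outcome) -> scalar`.
#' @param simulate_context `function(context) -> sim_outcome`.
#' @param filter optional `function(x) -> x'` (default identity).
#' @return a function of class `cost_function`.
#' @export
cost_function <- function(static_context, context_modifier, cost_evaluation,
                          simulate_context, filter = identity) {
  force(static_context); force(context_modifier); force(cost_evaluation)
  force(simulate_context); force(filter)
  f <- function(x) {
    ctx <- context_modifier(filter(x), static_context)
    cost_evaluation(simulate_context(ctx))
  }
  class(f) <- c("cost_function", "function")
  f
}

#' Energy-plus-recruitment stimulation cost
#'
#' `cost = alpha_e * sum_k i(t_k)^2 + alpha_r * (N_axon - N_recruited)`,
#' where the energy term sums the squared stimulus samples over the discrete
#' solver time steps (no dt weighting: the sum-of-squares form). Choosing
#' `alpha_r >> alpha_e` makes any fully recruiting stimulus cheaper than any
#' stimulus missing a fiber. A physically weighted variant
#' (`energy = dt * sum i^2`, uA^2*ms) is available via `dt_weighted`.
#'
#' @param stim_samples stimulus current sampled on the solver grid (uA).
#' @param n_axon population size.
#' @param n_recruited number of fibers with a detected propagating AP.
#' @param alpha_e,alpha_r weights.
#' @param dt_weighted if `TRUE`, weight the energy sum by `dt`.
#' @param dt solver step (ms), needed when `dt_weighted`.
#' @return scalar cost.
#' @export
energy_recruitment_cost <- function(stim_samples, n_axon, n_recruited,
                                    alpha_e = 1e-5, alpha_r = 1,
                                    dt_weighted = FALSE, dt = NULL) {
  stopifnot(n_recruited <= n_axon)
  energy <- sum(stim_samples^2)
  if (dt_weighted) {
    stopifnot(!is.null(dt))
    energy <- energy * dt
  }
  alpha_e * energy + alpha_r * (n_axon - n_recruited)
}

#' Waveform parameterizations for stimulus optimization
#'
#' Two parameterizations of a cathodic stimulation pulse are built in:
#' \describe{
#'   \item{square}{vector `(I_sq, T_sq)` - amplitude (uA, magnitude of the
#'     cathodic phase) and width (ms); dimension 2.}
#'   \item{spline_N}{vector `(I_1, t_1, ..., I_N, t_N)` - N free knots,
#'     dimension 2N. The pulse is a cubic spline through `(0, 0)`, the knots
#'     `(t_i, -I_i)` sorted by time, and `(t_end, 0)`, sampled as a
#'     linear-interpolation stimulus and clipped to non-positive (cathodic)
#'     currents.}
#' }
#'
#' @param kind `"square"` or `"spline"`.
#' @param n_knots number of spline knots (N).
#' @param t_start pulse onset (ms).
#' @param t_end end of the allowed pulse window, relative to onset (ms).
#' @param n_samples samples used to realize the spline pulse.
#' @return an object of class `waveform_parameterization` with fields
#'   `kind`, `dimension`, and a `build(x)` closure returning a [stimulus()].
#' @export
waveform_parameterization <- function(kind = c("square", "spline"),
                                      n_knots = 1L, t_start = 0.1,
                                      t_end = 1, n_samples = 41L) {
  kind <- match.arg(kind)
  if (kind == "square") {
    build <- function(x) {
      stopifnot(length(x) == 2L)
      make_pulse(t_start, -abs(x[1L]), max(x[2L], 1e-6))
    }
    dim <- 2L
  } else {
    stopifnot(n_knots >= 1L)
    dim <- 2L * n_knots
    build <- function(x) {
      stopifnot(length(x) == dim)
      ii <- -abs(x[seq(1L, dim, by = 2L)])
      tt <- x[seq(2L, dim, by = 2L)]
      ord <- order(tt)
      tt <- pmin(pmax(tt[ord], 0), t_end)
      ii <- ii[ord]
      kt <- c(0, tt, t_end)
      ki <- c(0, ii, 0)
      keep <- !duplicated(kt)
      sf <- stats::splinefun(kt[keep], ki[keep], method = "natural")
      ts <- seq(0, t_end, length.out = n_samples)
      vals <- pmin(sf(ts), 0)          # cathodic-only clipping
      vals[c(1L, n_samples)] <- 0
      stimulus(t_start + ts, vals, interpolation = "linear")
    }
  }
  structure(list(kind = kind, dimension = dim, t_start = t_start,
                 t_end = t_end, build = build),
            class = "waveform_parameterization")
}

#' Attach a parameterized waveform to a copy of a context
#'
#' The standard stimulus context modifier: builds the waveform for the input
#' vector and returns a copy of `static_context` with its `stim` replaced.
#' The static context itself is never mutated (R copy semantics; the
#' returned object is a modified copy).
#'
#' @param x input vector (see [waveform_parameterization()]).
#' @param parameterization a [waveform_parameterization()].
#' @param static_context a list with (at least) a `stim` field, e.g.
#'   `list(fiber =, electrode =, mat =, stim =, config =)`.
#' @return modified copy of `static_context`.
#' @export
context_modifier_waveform <- function(x, parameterization, static_context) {
  stopifnot(inherits(parameterization, "waveform_parameterization"))
  ctx <- static_context
  ctx$stim <- parameterization$build(x)
  ctx
}

#' Particle swarm optimization
#'
#' Standard global-best PSO with inertia, cognitive and social coefficients,
#' bound handling by reflection, and a nonincreasing best-cost trace.
#' Reproducible under `seed`.
#'
#' @param fn cost function of a numeric vector.
#' @param lower,upper bound vectors (finite, equal length).
#' @param n_particles swarm size (default 25).
#' @param n_iterations iteration count (default 60); 0 returns the best of
#'   the initial swarm.
#' @param seed RNG seed.
#' @param inertia,cognitive,social PSO coefficients.
#' @return list with `par` (best vector), `value` (best cost), `trace`
#'   (data frame: iteration, best, mean; iteration 0 is the initial swarm).
#' @export
pso_optimize <- function(fn, lower, upper, n_particles = 25L,
                         n_iterations = 60L, seed = 1L,
                         inertia = 0.7, cognitive = 1.5, social = 1.5) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower), n_particles >= 2L,
            n_iterations >= 0L)
  d <- length(lower)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  span <- upper - lower
  X <- matrix(stats::runif(n_particles * d), n_particles, d)
  X <- sweep(sweep(X, 2L, span, `*`), 2L, lower, `+`)
  Vel <- matrix(stats::runif(n_particles * d, -1, 1), n_particles, d) *
    matrix(span / 10, n_particles, d, byrow = TRUE)
  cost <- apply(X, 1L, fn)
  if (all(!is.finite(cost))) stop("all cost evaluations failed", call. = FALSE)
  Pbest <- X; pcost <- cost
  gi <- which.min(pcost)
  gbest <- Pbest[gi, ]; gcost <- pcost[gi]
  trace <- data.frame(iteration = 0L, best = gcost,
                      mean = mean(cost[is.finite(cost)]))
  for (it in seq_len(n_iterations)) {
    r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
    r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
    Vel <- inertia * Vel + cognitive * r1 * (Pbest - X) +
      social * r2 * sweep(-X, 2L, gbest, `+`)
    X <- X + Vel
    # reflect at bounds
    for (j in seq_len(d)) {
      lo <- lower[j]; hi <- upper[j]
      below <- X[, j] < lo; above <- X[, j] > hi
      X[below, j] <- pmin(2 * lo - X[below, j], hi)
      Vel[below, j] <- -Vel[below, j]
      X[above, j] <- pmax(2 * hi - X[above, j], lo)
      Vel[above, j] <- -Vel[above, j]
      X[, j] <- pmin(pmax(X[, j], lo), hi)
    }
    cost <- apply(X, 1L, fn)
    better <- is.finite(cost) & cost < pcost
    Pbest[better, ] <- X[better, , drop = FALSE]
    pcost[better] <- cost[better]
    gi <- which.min(pcost)
    if (pcost[gi] < gcost) { gbest <- Pbest[gi, ]; gcost <- pcost[gi] }
    trace <- rbind(trace, data.frame(iteration = it, best = gcost,
                                     mean = mean(cost[is.finite(cost)])))
  }
  list(par = gbest, value = gcost, trace = trace)
}

#' Optimization problem runner
#'
#' Binds a [cost_function()] (or any scalar function) to the particle-swarm
#' optimizer and logs the per-iteration best/mean trace as JSONL if asked.
#'
#' @param cost a function of a numeric vector.
#' @param bounds 2-row matrix (`rbind(lower, upper)`) or list with `lower`,
#'   `upper`.
#' @param n_particles,n_iterations,seed optimizer settings.
#' @param log_path optional JSONL path: one record per iteration.
#' @param ... passed to [pso_optimize()].
#' @return the [pso_optimize()] result.
#' @export
optimize_problem <- function(cost, bounds, n_particles = 25L,
                             n_iterations = 60L, seed = 1L,
                             log_path = NULL, ...) {
  if (is.list(bounds)) { lower <- bounds$lower; upper <- bounds$upper }
  else { lower <- bounds[1L, ]; upper <- bounds[2L, ] }
  res <- pso_optimize(cost, lower, upper, n_particles = n_particles,
                      n_iterations = n_iterations, seed = seed, ...)
  if (!is.null(log_path)) {
    con <- file(log_path, "w"); on.exit(close(con))
    for (i in seq_len(nrow(res$trace)))
      writeLines(as.character(jsonlite::toJSON(
        as.list(res$trace[i, ]), auto_unbox = TRUE, digits = NA)), con)
  }
  res
}
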