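#' Simulation configuration
#'
#' @param dt time step (ms), > 0. The default 0.001 ms resolves
#'   kilohertz-frequency waveforms up to 40 kHz.
#' @param t_sim simulated duration (ms), >= dt.
#' @param record_gates record gating traces.
#' @param record_imem record per-compartment membrane currents (needed for
#'   eCAP recording).
#' @param record_every record every k-th step (output decimation).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.001, t_sim = 5, record_gates = FALSE,
                       record_imem = FALSE, record_every = 1L) {
  stopifnot(dt > 0, t_sim >= dt, record_every >= 1)
  structure(list(dt = dt, t_sim = t_sim, record_gates = record_gates,
                 record_imem = record_imem,
                 record_every = as.integer(record_every)),
            class = "sim_config")
}

#' Intracellular clamps
#'
#' A current clamp injects the stimulus current (uA) into the axoplasm of one
#' compartment; a voltage clamp pins the compartment's membrane potential to
#' the stimulus value (mV).
#'
#' @param compartment compartment index (1-based), within the fiber.
#' @param stim a [stimulus()] (current in uA, or command voltage in mV).
#' @return an object of class `fiber_clamp`.
#' @export
clamp_current <- function(compartment, stim) {
  stopifnot(inherits(stim, "stimulus"), compartment >= 1)
  structure(list(kind = "current", compartment = as.integer(compartment),
                 stim = stim), class = "fiber_clamp")
}

#' @rdname clamp_current
#' @export
clamp_voltage <- function(compartment, stim) {
  stopifnot(inherits(stim, "stimulus"), compartment >= 1)
  structure(list(kind = "voltage", compartment = as.integer(compartment),
                 stim = stim), class = "fiber_clamp")
}

#' Simulate one fiber
#'
#' Integrates the compartmental cable equations of a fiber under an optional
#' extracellular stimulation context and intracellular clamps, with implicit
#' (backward-Euler) time stepping of the coupled voltage system, staggered
#' exponential-Euler gating, and sealed-end (zero axial current) boundary
#' conditions. Extracellular potentials are applied from electrode footprints
#' evaluated once at the compartment centers and reused at every time step.
#' The run is deterministic for fixed inputs.
#'
#' @param fiber a [nerve_fiber] from [unmyelinated_fiber()] or
#'   [myelinated_fiber()].
#' @param context an [extracellular_context()] or `NULL`.
#' @param clamps list of [clamp_current()] / [clamp_voltage()] objects.
#' @param config a [sim_config()].
#' @return an object of class `sim_result`: `time` (ms), `x` (compartment
#'   centers, um), `V` (compartments x time, mV), `gates` (list of matrices,
#'   if recorded), `imem` (compartments x time, uA, if recorded),
#'   `periaxonal` (mV), and metadata (`fiber`, `config`).
#' @export
simulate_fiber <- function(fiber, context = NULL, clamps = list(),
                           config = sim_config()) {
  stopifnot(inherits(fiber, "nerve_fiber"), inherits(config, "sim_config"))
  if (inherits(clamps, "fiber_clamp")) clamps <- list(clamps)
  el <- .fiber_electrics(fiber)
  n <- el$n
  n_steps <- max(1L, round(config$t_sim / config$dt))
  n_steps <- as.integer(ceiling(n_steps / config$record_every) *
                          config$record_every)
  tt <- seq_len(n_steps) * config$dt

  pts <- cbind(fiber$comp$x, fiber$y, fiber$z)
  if (!is.null(context) && length(context$sources) > 0L) {
    stopifnot(inherits(context, "extracellular_context"))
    fp <- context_footprints(pts, context) / 1000      # V/A -> mV/uA (kOhm)
    isrc <- t(vapply(context$sources, function(s) stim_eval(s$stim, tt),
                     numeric(n_steps)))
    if (length(context$sources) == 1L) isrc <- matrix(isrc, nrow = 1L)
  } else {
    fp <- matrix(0, n, 0L)
    isrc <- matrix(0, 0L, n_steps)
  }

  ic <- Filter(function(cl) cl$kind == "current", clamps)
  vc <- Filter(function(cl) cl$kind == "voltage", clamps)
  for (cl in clamps)
    if (cl$compartment > n)
      stop("clamp compartment index out of range", call. = FALSE)
  clampI <- if (length(ic))
    t(vapply(ic, function(cl) stim_eval(cl$stim, tt), numeric(n_steps))) else
      matrix(0, 0L, n_steps)
  if (length(ic) == 1L) clampI <- matrix(clampI, nrow = 1L)
  vclampV <- if (length(vc))
    t(vapply(vc, function(cl) stim_eval(cl$stim, tt), numeric(n_steps))) else
      matrix(0, 0L, n_steps)
  if (length(vc) == 1L) vclampV <- matrix(vclampV, nrow = 1L)

  raw <- .simulate_cable_cpp(
    el$Cm, el$mech, el$gpas, el$epas, el$gna, el$gk, el$gnap,
    el$ena, el$ek, el$Cmy, el$gmy, el$wfree, el$Ra, el$Rp,
    fp, isrc, clampI,
    vapply(ic, function(cl) cl$compartment, integer(1L)) - 1L,
    vclampV,
    vapply(vc, function(cl) cl$compartment, integer(1L)) - 1L,
    config$dt, n_steps, config$record_every, fiber$v_rest,
    config$record_gates, config$record_imem)

  gates <- NULL
  if (config$record_gates) {
    g <- raw$gates
    gates <- if (fiber$model == "hh")
      list(m = g$g1, h = g$g2, n = g$g3)
    else list(m = g$g1, h = g$g2, mp = g$g3, s = g$g4)
  }
  structure(list(time = raw$time, x = fiber$comp$x, V = raw$V,
                 periaxonal = raw$W, gates = gates,
                 imem = if (config$record_imem) raw$imem else NULL,
                 fiber = fiber, config = config,
                 labels = fiber$comp$label),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result: %d compartments x %d samples, t in [0, %g] ms, V in [%.1f, %.1f] mV>\n",
              nrow(x$V), ncol(x$V), max(x$time), min(x$V), max(x$V)))
  invisible(x)
}

# First upward crossing time of `thr` at compartment `ci`; NA if none.
.crossing_time <- function(result, ci, thr = 0) {
  v <- result$V[ci, ]
  idx <- which(v[-1L] >= thr & v[-length(v)] < thr)
  if (!length(idx)) return(NA_real_)
  i <- idx[1L]
  t0 <- result$time[i]; t1 <- result$time[i + 1L]
  v0 <- v[i]; v1 <- v[i + 1L]
  t0 + (thr - v0) / (v1 - v0) * (t1 - t0)
}

# Nearest compartment to x; for myelinated fibers, nearest node of Ranvier
# (internodal axolemma potential is attenuated by the myelin and does not
# reflect spike threshold crossings).
.nearest_compartment <- function(result, x_um) {
  idx <- seq_along(result$x)
  if (!is.null(result$labels) && any(result$labels == "node"))
    idx <- idx[result$labels == "node"]
  idx[which.min(abs(result$x[idx] - x_um))]
}

#' Conduction velocity from a simulation
#'
#' Velocity between two positions from the first upward 0 mV crossings:
#' `(x2 - x1) / (t_cross(x2) - t_cross(x1))`, reported in m/s.
#'
#' @param result a [simulate_fiber()] result.
#' @param x1,x2 positions along the fiber (um), `x1 != x2`.
#' @param v_threshold crossing threshold (mV).
#' @return conduction velocity (m/s).
#' @export
conduction_velocity <- function(result, x1, x2, v_threshold = 0) {
  stopifnot(inherits(result, "sim_result"))
  c1 <- .nearest_compartment(result, x1)
  c2 <- .nearest_compartment(result, x2)
  if (c1 == c2)
    stop("`x1` and `x2` resolve to the same compartment", call. = FALSE)
  t1 <- .crossing_time(result, c1, v_threshold)
  t2 <- .crossing_time(result, c2, v_threshold)
  if (is.na(t1) || is.na(t2))
    stop("no action potential detected at one of the positions",
         call. = FALSE)
  if (t2 == t1)
    stop("identical crossing times; positions too close", call. = FALSE)
  # um/ms = mm/s; m/s = um/ms * 1e-3
  (result$x[c2] - result$x[c1]) / (t2 - t1) * 1e-3
}

#' Export simulation traces
#'
#' Writes a JSON header (fiber, configuration) next to a CSV of the voltage
#' traces (one row per sample, one column per compartment), optionally
#' downsampled.
#'
#' @param result a [sim_result].
#' @param path base path (without extension).
#' @param every keep every k-th sample.
#' @return invisibly, the paths written.
#' @export
export_result <- function(result, path, every = 1L) {
  keep <- seq(1L, length(result$time), by = every)
  header <- list(fiber = jsonlite::fromJSON(fiber_to_json(result$fiber)),
                 dt = result$config$dt, t_sim = result$config$t_sim,
                 n_compartments = nrow(result$V))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  df <- data.frame(time = result$time[keep], t(result$V[, keep, drop = FALSE]))
  names(df) <- c("time_ms", paste0("V", seq_len(nrow(result$V))))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  invisible(c(paste0(path, ".json"), paste0(path, ".csv")))
}
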