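#' Detect a propagating action potential
#'
#' True when the membrane potential at the compartment nearest
#' `detect_position` crosses `v_threshold` upward within `window`.
#'
#' @param result a [sim_result].
#' @param detect_position x position (um), within the fiber.
#' @param v_threshold crossing threshold (mV), default 0.
#' @param window optional `c(t_min, t_max)` (ms) restricting detection.
#' @return list with `detected` (logical) and `t_cross` (ms, `NA` if none).
#' @export
detect_propagating_ap <- function(result, detect_position, v_threshold = 0,
                                  window = NULL) {
  stopifnot(inherits(result, "sim_result"))
  ci <- .nearest_compartment(result, detect_position)
  v <- result$V[ci, ]
  tt <- result$time
  if (!is.null(window)) {
    keep <- tt >= window[1L] & tt <= window[2L]
    v <- v[keep]; tt <- tt[keep]
  }
  up <- which(v[-1L] >= v_threshold & v[-length(v)] < v_threshold)
  if (!length(up)) return(list(detected = FALSE, t_cross = NA_real_))
  i <- up[1L]
  tc <- tt[i] + (v_threshold - v[i]) / (v[i + 1L] - v[i]) *
    (tt[i + 1L] - tt[i])
  list(detected = TRUE, t_cross = tc)
}

#' Threshold search specification
#'
#' @param lower,upper initial amplitude bracket (uA), positive,
#'   `lower < upper`. The bracket is expanded automatically (doubling /
#'   halving) if it does not straddle the threshold.
#' @param tol relative tolerance of the binary search: iteration stops when
#'   `(upper - lower)/lower <= tol`. Default 0.001 (0.1%) for activation
#'   searches; block searches conventionally use 0.01 (1%).
#' @param max_iter bisection iteration cap.
#' @param max_expand bracket expansion cap.
#' @return an object of class `threshold_spec`.
#' @export
threshold_spec <- function(lower = 1, upper = 1000, tol = 0.001,
                           max_iter = 60L, max_expand = 12L) {
  stopifnot(lower > 0, upper > lower, tol > 0, tol < 0.5)
  structure(list(lower = lower, upper = upper, tol = tol,
                 max_iter = as.integer(max_iter),
                 max_expand = as.integer(max_expand)),
            class = "threshold_spec")
}

#' Binary threshold search over a monotone response
#'
#' Core bisection used by [activation_threshold()] and [block_threshold()]:
#' `responds(amplitude)` must be monotone (FALSE below threshold, TRUE
#' above). Returns the responding (upper) bracket edge, so the reported
#' threshold is guaranteed to produce the response.
#'
#' @param responds function of one positive amplitude returning logical.
#' @param spec a [threshold_spec()].
#' @return list with `threshold` (upper edge), `lower`, `n_evaluations`.
#' @export
threshold_search <- function(responds, spec = threshold_spec()) {
  lo <- spec$lower; hi <- spec$upper
  nev <- 0L
  ask <- function(a) { nev <<- nev + 1L; isTRUE(responds(a)) }
  r_hi <- ask(hi)
  k <- 0L
  while (!r_hi && k < spec$max_expand) {
    lo <- hi; hi <- hi * 2; r_hi <- ask(hi); k <- k + 1L
  }
  if (!r_hi)
    stop("no response at the largest tested amplitude (", hi, " uA)",
         call. = FALSE)
  r_lo <- ask(lo)
  k <- 0L
  while (r_lo && k < spec$max_expand) {
    hi <- lo; lo <- lo / 2; r_lo <- ask(lo); k <- k + 1L
  }
  if (r_lo)
    stop("response persists at the smallest tested amplitude (", lo, " uA)",
         call. = FALSE)
  it <- 0L
  while ((hi - lo) / lo > spec$tol && it < spec$max_iter) {
    mid <- (hi + lo) / 2
    if (ask(mid)) hi <- mid else lo <- mid
    it <- it + 1L
  }
  list(threshold = hi, lower = lo, n_evaluations = nev)
}

#' Activation threshold of a fiber
#'
#' Minimum stimulation current required to induce a propagating action
#' potential, estimated by binary search with a relative search tolerance
#' (default 0.1%). The waveform shape is fixed and its amplitude scaled: the
#' `waveform` argument is a unit-amplitude [stimulus()] (e.g. a cathodic
#' pulse of amplitude -1), and candidate amplitudes multiply it.
#'
#' The bisection assumes a monotone response within the bracket: choose
#' `spec$upper` below the overdrive regime (far above threshold, virtual
#' anodes flanking the cathode can themselves block conduction, so very
#' large amplitudes may fail to yield a propagating response).
#'
#' @param fiber a [nerve_fiber].
#' @param electrode a [point_source()].
#' @param mat a [material()].
#' @param waveform unit-amplitude [stimulus()].
#' @param config a [sim_config()].
#' @param detect_position x position for AP detection (um); default 3/4 of
#'   the fiber length.
#' @param spec a [threshold_spec()].
#' @return list with `threshold` (uA, the activating bracket edge), `lower`,
#'   `n_evaluations`.
#' @export
activation_threshold <- function(fiber, electrode, mat, waveform,
                                 config = sim_config(dt = 0.002, t_sim = 3),
                                 detect_position = NULL,
                                 spec = threshold_spec()) {
  stopifnot(inherits(fiber, "nerve_fiber"))
  if (is.null(detect_position)) detect_position <- 0.75 * fiber$length
  responds <- function(amp) {
    ctx <- extracellular_context(
      mat, list(list(electrode = electrode, stim = stim_scale(waveform, amp))))
    r <- simulate_fiber(fiber, ctx, config = config)
    detect_propagating_ap(r, detect_position)$detected
  }
  threshold_search(responds, spec)
}

#' Kilohertz-frequency block threshold
#'
#' Replicates the standard in-silico block protocol: a 51-node myelinated
#' fiber in a homogeneous isotropic medium (0.2 S/m), a point-source
#' electrode over the central node at `electrode_distance`, conduction
#' verified with a test action potential clamped at the first node of
#' Ranvier. The block threshold is the minimum HFAC peak-to-peak amplitude
#' for which a test action potential delivered during HFAC steady state (by
#' default at 15 ms, past the onset-response settling window) fails to
#' propagate past the electrode. Binary search with 1% relative tolerance.
#'
#' @param diameter fiber diameter (um).
#' @param hfac_freq HFAC frequency (kHz).
#' @param electrode_distance electrode-to-axon distance (um).
#' @param spec a [threshold_spec()]; defaults to a 1% tolerance bracket
#'   suited to mA-scale thresholds.
#' @param n_nodes number of nodes (default 51).
#' @param sigma medium conductivity (S/m, isotropic; default 0.2).
#' @param hfac_window HFAC on-window `c(t_on, t_off)` (ms), default
#'   `c(3, 23)`.
#' @param test_time onset of the steady-state test AP (ms), default 15.
#' @param settle onset-response exclusion window after HFAC onset (ms),
#'   default 5; detection only considers crossings after
#'   `max(test_time, t_on + settle)`.
#' @param dt solver step (ms); default resolves the HFAC period with >= 25
#'   samples.
#' @param keep_traces return the supra-threshold gating traces as well.
#' @return list with `threshold` (peak-to-peak uA), `lower`,
#'   `n_evaluations`, and the protocol parameters.
#' @export
block_threshold <- function(diameter, hfac_freq, electrode_distance,
                            spec = threshold_spec(lower = 50, upper = 6400,
                                                  tol = 0.01),
                            n_nodes = 51L, sigma = 0.2,
                            hfac_window = c(3, 23), test_time = 15,
                            settle = 5, dt = NULL, keep_traces = FALSE) {
  fiber <- myelinated_fiber(diameter, n_nodes = n_nodes)
  nodes <- which(fiber$comp$label == "node")
  center_node <- nodes[(n_nodes + 1L) %/% 2L]
  el <- point_source(fiber$comp$x[center_node], fiber$y + electrode_distance,
                     fiber$z, id = 1L)
  mat <- material(sigma)
  if (is.null(dt)) dt <- min(0.001, 1 / (25 * hfac_freq))
  t_sim <- hfac_window[2L]
  detect_node <- nodes[min(n_nodes, (n_nodes + 1L) %/% 2L + 14L)]
  t_detect0 <- max(test_time, hfac_window[1L] + settle)
  clamps <- list(
    clamp_current(nodes[1L], make_pulse(0.5, 0.002, 0.1)),
    clamp_current(nodes[1L], make_pulse(test_time, 0.002, 0.1)))
  run <- function(pp) {
    hf <- make_sine(hfac_window[1L], hfac_freq, pp,
                    hfac_window[2L] - hfac_window[1L])
    ctx <- extracellular_context(mat, list(list(electrode = el, stim = hf)))
    simulate_fiber(fiber, ctx, clamps = clamps,
                   config = sim_config(dt = dt, t_sim = t_sim,
                                       record_every = 5L))
  }
  blocks <- function(pp) {
    r <- run(pp)
    !detect_propagating_ap(r, fiber$comp$x[detect_node],
                           window = c(t_detect0, t_sim - 0.5))$detected
  }
  out <- threshold_search(blocks, spec)
  out$protocol <- list(diameter = diameter, hfac_freq = hfac_freq,
                       electrode_distance = electrode_distance,
                       n_nodes = n_nodes, sigma = sigma,
                       hfac_window = hfac_window, test_time = test_time,
                       settle = settle, dt = dt)
  if (keep_traces) {
    hf <- make_sine(hfac_window[1L], hfac_freq, out$threshold * 1.1,
                    hfac_window[2L] - hfac_window[1L])
    ctx <- extracellular_context(mat, list(list(electrode = el, stim = hf)))
    out$trace <- simulate_fiber(
      fiber, ctx, clamps = clamps,
      config = sim_config(dt = dt, t_sim = t_sim, record_every = 5L,
                          record_gates = TRUE))
    out$center_node_index <- center_node
  }
  out
}

#' Recruitment curve of a fascicle
#'
#' Fraction of fibers producing a propagating action potential as a function
#' of stimulation amplitude (or of pulse width at fixed amplitude). The
#' recruitment rate is the slope of the curve between 0.2 and 0.8
#' recruitment: a least-squares line over the sweep points whose recruitment
#' lies in [0.2, 0.8] (when fewer than two sweep points fall inside the
#' band, the secant through the interpolated 0.2 and 0.8 crossings is used).
#'
#' @param fasc a [fascicle()].
#' @param electrode a [point_source()].
#' @param mat a [material()].
#' @param sweep numeric vector of amplitudes (uA) or pulse widths (ms).
#' @param sweep_type `"amplitude"` or `"width"`.
#' @param waveform for amplitude sweeps, a unit-amplitude [stimulus()];
#'   ignored for width sweeps.
#' @param amplitude for width sweeps, the fixed pulse amplitude (uA).
#' @param pulse_start pulse onset for width sweeps (ms).
#' @param config a [sim_config()].
#' @param n_nodes_myel optional fixed node count for myelinated fibers; by
#'   default fibers span the fascicle length (diameter-dependent node
#'   count), so every fiber covers the same x range.
#' @return an object of class `recruitment_curve`: data frame `sweep`,
#'   `recruited` plus attributes `rate` (per uA or per ms; `NA` if the band
#'   is never reached, with attribute `rate_defined = FALSE`).
#' @export
recruitment_curve <- function(fasc, electrode, mat, sweep,
                              sweep_type = c("amplitude", "width"),
                              waveform = NULL, amplitude = NULL,
                              pulse_start = 0.1,
                              config = sim_config(dt = 0.002, t_sim = 3),
                              n_nodes_myel = NULL) {
  sweep_type <- match.arg(sweep_type)
  stopifnot(inherits(fasc, "fascicle"))
  pop <- fasc$population
  fibers <- lapply(seq_len(nrow(pop)), function(i)
    .build_fiber(pop$type[i], pop$diameter[i], pop$y[i], pop$z[i],
                 fasc$length, n_nodes_myel))
  frac <- vapply(sweep, function(s) {
    stim <- if (sweep_type == "amplitude") stim_scale(waveform, s) else
      make_pulse(pulse_start, amplitude, s)
    ctx <- extracellular_context(mat,
                                 list(list(electrode = electrode, stim = stim)))
    mean(vapply(fibers, function(f) {
      r <- simulate_fiber(f, ctx, config = config)
      detect_propagating_ap(r, 0.75 * f$length)$detected
    }, logical(1L)))
  }, numeric(1L))
  df <- data.frame(sweep = sweep, recruited = frac)
  in_band <- frac >= 0.2 & frac <= 0.8
  rate <- NA_real_; defined <- FALSE
  if (sum(in_band) >= 2L) {
    rate <- stats::coef(stats::lm(recruited ~ sweep, df[in_band, ]))[[2L]]
    defined <- TRUE
  } else if (max(frac) >= 0.8 && min(frac) <= 0.2) {
    a20 <- stats::approx(frac, sweep, xout = 0.2, ties = "ordered")$y
    a80 <- stats::approx(frac, sweep, xout = 0.8, ties = "ordered")$y
    if (is.finite(a20) && is.finite(a80) && a80 != a20) {
      rate <- 0.6 / (a80 - a20); defined <- TRUE
    }
  }
  attr(df, "rate") <- rate
  attr(df, "rate_defined") <- defined
  class(df) <- c("recruitment_curve", "data.frame")
  df
}

.build_fiber <- function(type, diameter, y, z, length, n_nodes_myel = NULL) {
  if (type == "myelinated") {
    if (!is.null(n_nodes_myel))
      myelinated_fiber(diameter, y = y, z = z, n_nodes = n_nodes_myel)
    else myelinated_fiber(diameter, y = y, z = z, length = length)
  } else {
    unmyelinated_fiber(diameter, length, y = y, z = z)
  }
}

#' Amplitude-latency characterization of an eCAP
#'
#' For each recording point, the peak amplitude is `max |V|` within the
#' trace (optionally windowed) and the latency the time of that peak
#' relative to `t_activation`. The log-log slope is the least-squares slope
#' of `log(peak)` against `log(latency)`, conventionally excluding the first
#' recording point (where the eCAP is small and overlaps the stimulation
#' artifact).
#'
#' @param ecap a [compute_ecap()] result.
#' @param t_activation activation time reference (ms), default 0.
#' @param exclude_first drop the first recording point from the fit.
#' @param window optional `c(t_min, t_max)` (ms) restricting the peak search
#'   at every point.
#' @param distances optional per-point propagation distances (um); together
#'   with `velocity_window` they restrict each point's peak search to
#'   physically possible arrival times, which excludes the synchronous
#'   activation transient (the in-silico analog of the stimulation artifact,
#'   visible at all points with near-zero latency).
#' @param velocity_window `c(v_min, v_max)` conduction velocities (m/s)
#'   bounding the arrival window when `distances` is given.
#' @return list with `points` (data frame: point, amplitude mV, latency ms)
#'   and `slope` (dimensionless log-log slope).
#' @export
amplitude_latency_fit <- function(ecap, t_activation = 0,
                                  exclude_first = TRUE, window = NULL,
                                  distances = NULL,
                                  velocity_window = c(4, 80)) {
  v <- ecap$potential
  tt <- ecap$time
  if (!is.null(window)) {
    keep <- tt >= window[1L] & tt <= window[2L]
    v <- v[, keep, drop = FALSE]; tt <- tt[keep]
  }
  np <- nrow(v)
  if (!is.null(distances)) stopifnot(length(distances) == np)
  amp <- numeric(np); lat <- numeric(np)
  for (p in seq_len(np)) {
    keep <- seq_along(tt)
    if (!is.null(distances)) {
      # distance um / (velocity m/s * 1000 um/ms) = arrival time ms
      t_lo <- t_activation + distances[p] / (velocity_window[2L] * 1000)
      t_hi <- t_activation + distances[p] / (velocity_window[1L] * 1000)
      keep <- which(tt >= t_lo & tt <= t_hi)
      if (!length(keep)) keep <- seq_along(tt)
    }
    i <- keep[which.max(abs(v[p, keep]))]
    amp[p] <- abs(v[p, i])
    lat[p] <- tt[i] - t_activation
  }
  df <- data.frame(point = seq_len(np), amplitude = amp, latency = lat)
  fit_df <- df[df$amplitude > 0 & df$latency > 0, ]
  if (exclude_first) fit_df <- fit_df[fit_df$point != 1L, ]
  if (nrow(fit_df) < 3L)
    stop("need at least 3 recording points with detected peaks",
         call. = FALSE)
  slope <- stats::coef(stats::lm(log(amplitude) ~ log(latency),
                                 fit_df))[[2L]]
  list(points = df, slope = slope)
}
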