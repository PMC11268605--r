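#' Extracellular recorders
#'
#' A recorder binds one homogeneous material (default endoneurium) and a
#' recording method to a set of recording points. Fiber activity at the
#' recording points is reconstructed as the dot product of per-compartment
#' membrane currents with a precomputed footprint matrix (points x
#' compartments, V/A): the point-source approximation (PSA) treats each
#' compartment as a point, the line-source approximation (LSA, isotropic
#' materials only) as a finite line of current.
#'
#' @param points n-by-3 matrix (or length-3 vector) of recording positions
#'   `(x, y, z)` (um).
#' @param mat a [material()]; LSA requires an isotropic one.
#' @param method `"PSA"` or `"LSA"`.
#' @return an object of class `ecap_recorder`.
#' @export
recorder <- function(points, mat = load_material("endoneurium"),
                     method = c("PSA", "LSA")) {
  method <- match.arg(method)
  if (!is.matrix(points)) points <- matrix(as.numeric(points), ncol = 3L)
  stopifnot(inherits(mat, "nerve_material"))
  if (method == "LSA" && !is_isotropic(mat))
    stop("LSA recording requires an isotropic material", call. = FALSE)
  structure(list(points = points, material = mat, method = method),
            class = "ecap_recorder")
}

#' Point-source recorder footprint
#'
#' Transfer resistance (V/A) between a fiber compartment and a recording
#' point; same functional form as [psa_footprint()] with the offsets taken
#' compartment minus recorder.
#'
#' @param point recording position, length-3 (um).
#' @param comp_pos compartment position, length-3 or n-by-3 (um).
#' @param mat a [material()].
#' @return footprint(s), V/A.
#' @export
recorder_footprint_psa <- function(point, comp_pos, mat) {
  psa_footprint(comp_pos, point, mat)
}

#' Line-source recorder footprint
#'
#' Analytic potential per unit current of a uniform line source of length
#' `dl` along x (the compartment) at a recording point, for an isotropic
#' medium: `1/(4*pi*sigma*dl) * log((b0 + sqrt(b0^2 + r^2)) /
#' (b1 + sqrt(b1^2 + r^2)))` with `b0`, `b1` the signed axial offsets of the
#' recording point from the two segment ends and `r` its transverse distance.
#' Valid for recording points anywhere off the segment axis; it reduces to
#' the absolute-offset textbook form when the point lies beyond a segment
#' end, and converges to the PSA value of the segment midpoint as
#' `dl -> 0`.
#'
#' @param point recording position `(x, y, z)` (um).
#' @param x0,x1 segment end coordinates along x (um), `x1 > x0`.
#' @param y,z transverse coordinates of the segment (um).
#' @param mat an isotropic [material()].
#' @return footprint, V/A.
#' @export
recorder_footprint_lsa <- function(point, x0, x1, y, z, mat) {
  stopifnot(inherits(mat, "nerve_material"))
  if (!is_isotropic(mat))
    stop("LSA requires an isotropic material", call. = FALSE)
  dl <- (x1 - x0) * 1e-6
  if (any(dl <= 0)) stop("segment length must be positive", call. = FALSE)
  r <- sqrt((y - point[2L])^2 + (z - point[3L])^2) * 1e-6
  if (any(r == 0))
    stop("singularity: recording point on the segment axis", call. = FALSE)
  b0 <- (point[1L] - x0) * 1e-6       # signed axial offset from near end
  b1 <- (point[1L] - x1) * 1e-6
  sigma <- mat$sigma_xx
  1 / (4 * pi * sigma * dl) *
    log((b0 + sqrt(b0^2 + r^2)) / (b1 + sqrt(b1^2 + r^2)))
}

#' Footprint matrix of a recorder for one fiber
#'
#' @param rec an [recorder()].
#' @param fiber a [nerve_fiber].
#' @return points x compartments matrix (V/A).
#' @export
recorder_footprints <- function(rec, fiber) {
  stopifnot(inherits(rec, "ecap_recorder"), inherits(fiber, "nerve_fiber"))
  np <- nrow(rec$points)
  comp <- fiber$comp
  fp <- matrix(0, np, nrow(comp))
  if (rec$method == "PSA") {
    pts <- cbind(comp$x, fiber$y, fiber$z)
    for (p in seq_len(np))
      fp[p, ] <- psa_footprint(pts, rec$points[p, ], rec$material)
  } else {
    x0 <- comp$x - comp$length / 2
    x1 <- comp$x + comp$length / 2
    for (p in seq_len(np))
      fp[p, ] <- recorder_footprint_lsa(rec$points[p, ], x0, x1,
                                        fiber$y, fiber$z, rec$material)
  }
  fp
}

#' Compound action potential at the recording points
#'
#' Space-time decoupled reconstruction: the potential at recording point `r`
#' and time `t` is the sum over axons and compartments of
#' `I_mem(t) * footprint` (uA times V/A, reported in mV). All results must
#' share a common time grid and have been simulated with
#' `record_imem = TRUE`. The stimulation-artifact contribution of an
#' extracellular context can optionally be superposed by evaluating its
#' field at the recording points.
#'
#' @param results a [sim_result] or list of them (one per axon).
#' @param rec an [recorder()].
#' @param artifact_context optional [extracellular_context()] whose field at
#'   the recording points is added (stimulation artifact).
#' @return list with `time` (ms) and `potential` (points x time, mV).
#' @export
compute_ecap <- function(results, rec, artifact_context = NULL) {
  if (inherits(results, "sim_result")) results <- list(results)
  stopifnot(length(results) >= 1L, inherits(rec, "ecap_recorder"))
  tt <- results[[1L]]$time
  for (r in results) {
    if (length(r$time) != length(tt) || any(r$time != tt))
      stop("all results must share a common time grid", call. = FALSE)
    if (is.null(r$imem))
      stop("results must be simulated with record_imem = TRUE", call. = FALSE)
  }
  v <- matrix(0, nrow(rec$points), length(tt))
  for (r in results) {
    fp <- recorder_footprints(rec, r$fiber)
    v <- v + fp %*% r$imem / 1000            # uA * V/A = uV -> mV
  }
  if (!is.null(artifact_context))
    v <- v + field_at(rec$points, tt, artifact_context)
  list(time = tt, potential = v)
}

#' Write eCAP traces to CSV
#'
#' One `time` column plus one column per recording point.
#'
#' @param ecap a [compute_ecap()] result.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_ecap_csv <- function(ecap, path) {
  df <- data.frame(time_ms = ecap$time, t(ecap$potential))
  names(df) <- c("time_ms", paste0("point", seq_len(nrow(ecap$potential))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
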