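#' Conductive materials
#'
#' A material is a diagonal conductivity tensor `(sigma_xx, sigma_yy,
#' sigma_zz)` in S/m. Isotropic materials have all three components equal.
#' Named presets reflect values commonly used for nerve tissue, with the x
#' axis longitudinal (along the fiber):
#' \describe{
#'   \item{endoneurium}{anisotropic, 0.57 S/m longitudinal, 0.085 S/m
#'     transverse}
#'   \item{epineurium}{isotropic 0.085 S/m}
#'   \item{perineurium}{isotropic 0.002 S/m}
#'   \item{saline}{isotropic 2 S/m}
#' }
#'
#' @param sigma either a single conductivity (isotropic) or a length-3 vector
#'   `(sigma_xx, sigma_yy, sigma_zz)`, S/m, all > 0.
#' @param name optional label.
#' @return an object of class `nerve_material` with fields `sigma_xx`,
#'   `sigma_yy`, `sigma_zz`, `name`.
#' @export
material <- function(sigma, name = "custom") {
  sigma <- as.numeric(sigma)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  if (length(sigma) != 3L || any(!is.finite(sigma)) || any(sigma <= 0))
    stop("`sigma` must be 1 or 3 positive finite conductivities (S/m)",
         call. = FALSE)
  structure(list(sigma_xx = sigma[1L], sigma_yy = sigma[2L],
                 sigma_zz = sigma[3L], name = name),
            class = "nerve_material")
}

.material_presets <- list(
  endoneurium = c(0.57, 0.085, 0.085),
  epineurium  = c(0.085, 0.085, 0.085),
  perineurium = c(0.002, 0.002, 0.002),
  saline      = c(2, 2, 2)
)

#' @rdname material
#' @param preset one of `"endoneurium"`, `"epineurium"`, `"perineurium"`,
#'   `"saline"`, or a path to a JSON file with fields `sigma` (scalar or
#'   length 3) and optional `name` for user overrides.
#' @export
load_material <- function(preset) {
  if (preset %in% names(.material_presets))
    return(material(.material_presets[[preset]], name = preset))
  if (file.exists(preset)) {
    x <- jsonlite::fromJSON(preset)
    return(material(x$sigma, name = if (is.null(x$name)) preset else x$name))
  }
  stop("unknown material preset: ", preset, call. = FALSE)
}

#' @export
print.nerve_material <- function(x, ...) {
  cat(sprintf("<material '%s': sigma = (%g, %g, %g) S/m%s>\n", x$name,
              x$sigma_xx, x$sigma_yy, x$sigma_zz,
              if (is_isotropic(x)) ", isotropic" else ""))
  invisible(x)
}

#' @rdname material
#' @param x a `nerve_material`.
#' @export
is_isotropic <- function(x) {
  x$sigma_xx == x$sigma_yy && x$sigma_yy == x$sigma_zz
}

#' Point-source electrode
#'
#' A dimensionless current source at a point in space (point-source
#' approximation, PSA). Electrode ids must be unique within an extracellular
#' context.
#'
#' @param x,y,z position (um).
#' @param id integer identifier.
#' @return an object of class `point_source`.
#' @export
point_source <- function(x, y, z, id = 1L) {
  stopifnot(is.finite(x), is.finite(y), is.finite(z))
  structure(list(id = as.integer(id), position = c(x = x, y = y, z = z)),
            class = "point_source")
}

#' Transfer resistance of a point source (PSA footprint)
#'
#' The footprint is the extracellular potential per unit injected current
#' (V/A, a transfer resistance) between an electrode and a target point in an
#' infinite homogeneous medium. Isotropic:
#' `1 / (4*pi*sigma*r)`. Anisotropic (diagonal tensor):
#' `1 / (4*pi*sqrt(syy*szz*dx^2 + sxx*szz*dy^2 + sxx*syy*dz^2))`,
#' which reduces to the isotropic form when the components are equal.
#'
#' @param target numeric length-3 `(x, y, z)` or an n-by-3 matrix of target
#'   points (um).
#' @param electrode a [point_source()] or a length-3 position (um).
#' @param mat a [material()].
#' @return footprint(s) in V/A.
#' @examples
#' psa_footprint(c(1000, 0, 0), c(0, 0, 0), material(0.2))  # ~397.9 V/A
#' @export
psa_footprint <- function(target, electrode, mat) {
  stopifnot(inherits(mat, "nerve_material"))
  pos <- if (inherits(electrode, "point_source")) electrode$position else
    as.numeric(electrode)
  pts <- if (is.matrix(target)) target else matrix(as.numeric(target), ncol = 3L)
  d <- sweep(pts, 2L, pos) * 1e-6                      # um -> m
  q <- mat$sigma_yy * mat$sigma_zz * d[, 1L]^2 +
       mat$sigma_xx * mat$sigma_zz * d[, 2L]^2 +
       mat$sigma_xx * mat$sigma_yy * d[, 3L]^2
  if (any(q == 0))
    stop("singularity: target coincides with the electrode position",
         call. = FALSE)
  out <- 1 / (4 * pi * sqrt(q))
  if (is.matrix(target)) out else out[[1L]]
}

#' Extracellular stimulation context
#'
#' Binds a homogeneous (an)isotropic medium to a set of point-source
#' electrodes, each driven by its own stimulus. One stimulus per electrode
#' id. Electrode footprints are computed once per set of target points and
#' reused across all time steps (space-time decoupling under the quasi-static
#' approximation).
#'
#' @param mat a [material()].
#' @param sources list of `list(electrode = point_source, stim = stimulus)`
#'   pairs.
#' @return an object of class `extracellular_context`.
#' @export
extracellular_context <- function(mat, sources = list()) {
  stopifnot(inherits(mat, "nerve_material"))
  for (s in sources) {
    if (!inherits(s$electrode, "point_source") || !inherits(s$stim, "stimulus"))
      stop("each source must be list(electrode = point_source, stim = stimulus)",
           call. = FALSE)
  }
  ids <- vapply(sources, function(s) s$electrode$id, integer(1L))
  if (anyDuplicated(ids))
    stop("electrode ids must be unique within a context", call. = FALSE)
  structure(list(material = mat, sources = sources),
            class = "extracellular_context")
}

#' @rdname extracellular_context
#' @param context an `extracellular_context`.
#' @param electrode a [point_source()].
#' @param stim a [stimulus()].
#' @export
add_source <- function(context, electrode, stim) {
  stopifnot(inherits(context, "extracellular_context"))
  extracellular_context(context$material,
                        c(context$sources,
                          list(list(electrode = electrode, stim = stim))))
}

#' Footprint matrix of a context at a set of points
#'
#' @param points n-by-3 matrix of target positions (um).
#' @param context an [extracellular_context()].
#' @return n-by-k matrix of footprints (V/A), one column per electrode.
#' @export
context_footprints <- function(points, context) {
  stopifnot(inherits(context, "extracellular_context"))
  if (!is.matrix(points)) points <- matrix(as.numeric(points), ncol = 3L)
  k <- length(context$sources)
  fp <- matrix(0, nrow(points), max(k, 1L))
  for (j in seq_len(k))
    fp[, j] <- psa_footprint(points, context$sources[[j]]$electrode,
                             context$material)
  fp[, seq_len(k), drop = FALSE]
}

#' Extracellular potential from stimulating electrodes
#'
#' Linear superposition over electrodes: at each point,
#' `V(t) = sum_k I_k(t) * footprint_k` (current in uA, footprint in V/A,
#' potential returned in mV).
#'
#' @param points n-by-3 matrix of positions (um).
#' @param t numeric vector of times (ms).
#' @param context an [extracellular_context()].
#' @param footprints optional precomputed [context_footprints()] matrix for
#'   these points (cached reuse across calls).
#' @return n-by-length(t) matrix of potentials (mV).
#' @export
field_at <- function(points, t, context, footprints = NULL) {
  stopifnot(inherits(context, "extracellular_context"))
  if (!is.matrix(points)) points <- matrix(as.numeric(points), ncol = 3L)
  if (length(context$sources) == 0L)
    stop("context has no sources", call. = FALSE)
  if (is.null(footprints)) footprints <- context_footprints(points, context)
  icurr <- vapply(context$sources, function(s) stim_eval(s$stim, t),
                  numeric(length(t)))                     # |t| x k
  if (length(t) == 1L) icurr <- matrix(icurr, nrow = 1L)
  # uA * (V/A) = uV; report mV
  footprints %*% t(icurr) / 1000
}
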