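#' Built-in fiber diameter distributions
#'
#' Diameter statistics are named distribution specs. Two parametric families
#' are built in, plus presets that emulate published sciatic/tibial nerve
#' morphometry (bimodal myelinated distributions, small-diameter lognormal
#' unmyelinated distributions). Presets are labeled "emulating": they
#' reproduce the qualitative shape (ranges, modes) of the cited statistics,
#' not the exact histograms.
#'
#' \describe{
#'   \item{trunc_lognormal}{`list(name, meanlog, sdlog, min, max)`}
#'   \item{bimodal_normal}{`list(name, w, mean1, sd1, mean2, sd2, min, max)`
#'     (mixture weight `w` on the first mode, truncated to `[min, max]`)}
#'   \item{"sciatic_myelinated"}{bimodal, modes near 4 and 9 um, range
#'     [2, 16] um}
#'   \item{"sciatic_unmyelinated"}{lognormal, mode near 0.8 um, range
#'     [0.1, 2] um}
#'   \item{"tibial_myelinated"}{bimodal, modes near 5.5 and 11 um, range
#'     [1, 16] um}
#' }
#'
#' @param spec a distribution spec list or preset name.
#' @return normalized spec list.
#' @export
diameter_distribution <- function(spec) {
  presets <- list(
    sciatic_myelinated = list(name = "bimodal_normal", w = 0.55,
                              mean1 = 4, sd1 = 1.3, mean2 = 9, sd2 = 2,
                              min = 2, max = 16),
    sciatic_unmyelinated = list(name = "trunc_lognormal",
                                meanlog = log(0.8), sdlog = 0.4,
                                min = 0.1, max = 2),
    tibial_myelinated = list(name = "bimodal_normal", w = 0.5,
                             mean1 = 5.5, sd1 = 1.5, mean2 = 11, sd2 = 2,
                             min = 1, max = 16)
  )
  if (is.character(spec)) {
    if (!spec %in% names(presets))
      stop("unknown diameter distribution: ", spec, call. = FALSE)
    return(presets[[spec]])
  }
  if (is.null(spec$name) ||
      !spec$name %in% c("trunc_lognormal", "bimodal_normal"))
    stop("unknown diameter distribution: ",
         if (is.null(spec$name)) "<unnamed>" else spec$name, call. = FALSE)
  spec
}

.sample_diameters <- function(n, spec) {
  spec <- diameter_distribution(spec)
  if (n == 0L) return(numeric(0))
  if (spec$name == "trunc_lognormal") {
    pa <- stats::plnorm(spec$min, spec$meanlog, spec$sdlog)
    pb <- stats::plnorm(spec$max, spec$meanlog, spec$sdlog)
    stats::qlnorm(stats::runif(n, pa, pb), spec$meanlog, spec$sdlog)
  } else {
    mode1 <- stats::runif(n) < spec$w
    mu <- ifelse(mode1, spec$mean1, spec$mean2)
    sd <- ifelse(mode1, spec$sd1, spec$sd2)
    pa <- stats::pnorm(spec$min, mu, sd)
    pb <- stats::pnorm(spec$max, mu, sd)
    stats::qnorm(stats::runif(n, pa, pb), mu, sd)
  }
}

#' Mean of a truncated lognormal distribution
#'
#' Closed-form first moment of a lognormal truncated to `[min, max]`; used as
#' the analytic reference for the sampled diameter distributions.
#'
#' @param meanlog,sdlog lognormal parameters.
#' @param min,max truncation bounds.
#' @return the analytic mean.
#' @export
trunc_lognormal_mean <- function(meanlog, sdlog, min, max) {
  a <- (log(min) - meanlog) / sdlog
  b <- (log(max) - meanlog) / sdlog
  exp(meanlog + sdlog^2 / 2) *
    (stats::pnorm(b - sdlog) - stats::pnorm(a - sdlog)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Generate an axon population
#'
#' Draws fiber types from a Bernoulli(`myelinated_fraction`) and per-type
#' diameters from named distributions. Positions are left unplaced (`NA`)
#' until [axon_packing()] or manual placement. Reproducible under `seed`.
#'
#' @param n number of axons (>= 1).
#' @param myelinated_fraction fraction of myelinated fibers in [0, 1].
#' @param diameter_stats list with elements `myelinated` and `unmyelinated`,
#'   each a spec for [diameter_distribution()]; either may be omitted if the
#'   corresponding type cannot occur.
#' @param seed integer RNG seed.
#' @return an `axon_population`: data frame with columns `type`
#'   (`"myelinated"`/`"unmyelinated"`), `diameter` (um), `y`, `z` (um, `NA`
#'   until placed), with the seed stored as an attribute.
#' @export
create_axon_population <- function(n, myelinated_fraction,
                                   diameter_stats =
                                     list(myelinated = "sciatic_myelinated",
                                          unmyelinated = "sciatic_unmyelinated"),
                                   seed = 1L) {
  stopifnot(n >= 1, myelinated_fraction >= 0, myelinated_fraction <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  myel <- stats::runif(n) < myelinated_fraction
  d <- numeric(n)
  if (any(myel)) {
    if (is.null(diameter_stats$myelinated))
      stop("no myelinated diameter distribution given", call. = FALSE)
    d[myel] <- .sample_diameters(sum(myel), diameter_stats$myelinated)
  }
  if (any(!myel)) {
    if (is.null(diameter_stats$unmyelinated))
      stop("no unmyelinated diameter distribution given", call. = FALSE)
    d[!myel] <- .sample_diameters(sum(!myel), diameter_stats$unmyelinated)
  }
  pop <- data.frame(type = ifelse(myel, "myelinated", "unmyelinated"),
                    diameter = d, y = NA_real_, z = NA_real_)
  attr(pop, "seed") <- seed
  class(pop) <- c("axon_population", "data.frame")
  pop
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Pack an axon population into a circular fascicle
#'
#' Iterative attraction/repulsion packing: fibers are placed on a shuffled
#' grid at initialization and migrate toward the fascicle center with an
#' attraction step proportional to their distance from it (capped), unless
#' they overlap a neighbor (center distance below the sum of radii plus
#' `delta_gap`), in which case a repulsion step proportional to the overlap
#' depth pushes them apart along the center-to-center direction. The
#' attraction magnitude decays geometrically, so the configuration settles;
#' iteration stops when no overlaps remain and the largest displacement falls
#' below `tol`, or at `max_iter`.
#'
#' @param population an [create_axon_population()] result.
#' @param delta_gap minimal gap enforced between fiber surfaces (um).
#' @param max_iter iteration cap.
#' @param seed RNG seed for the initial grid shuffle.
#' @param attraction initial attraction step as a fraction of the distance to
#'   the center.
#' @param repulsion repulsion step as a fraction of the overlap depth.
#' @param decay per-iteration geometric decay of the attraction step.
#' @param clearance extra separation (um) added to each repulsion step so
#'   resolved contacts do not immediately re-overlap.
#' @param tol displacement tolerance (um) for convergence.
#' @return the population with `y`, `z` filled in and attributes
#'   `fitted_radius` (um, `max(|p_i| + r_i)`), `iterations`, `converged`.
#' @export
axon_packing <- function(population, delta_gap = 0, max_iter = 8000L,
                         seed = 1L, attraction = 0.01, repulsion = 0.7,
                         decay = 0.995, clearance = 0.05, tol = 0.01) {
  stopifnot(inherits(population, "axon_population"),
            nrow(population) >= 1L)
  n <- nrow(population)
  r <- population$diameter / 2
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # initial shuffled grid centered on the origin
  pitch <- 2 * max(r) + delta_gap + 1
  side <- ceiling(sqrt(n))
  g <- expand.grid(i = seq_len(side), j = seq_len(side))
  g <- g[sample(nrow(g), n), ]
  pos <- cbind((g$i - (side + 1) / 2) * pitch,
               (g$j - (side + 1) / 2) * pitch)

  rsum <- outer(r, r, `+`) + delta_gap
  attr_step <- attraction
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    dmat <- as.matrix(stats::dist(pos))
    overlap <- rsum - dmat
    diag(overlap) <- -1
    has_overlap <- overlap > 1e-12
    vel <- matrix(0, n, 2L)
    ov_any <- rowSums(has_overlap) > 0L
    if (any(ov_any)) {
      for (i in which(ov_any)) {
        js <- which(has_overlap[i, ])
        dir <- pos[rep(i, length(js)), , drop = FALSE] - pos[js, , drop = FALSE]
        nrm <- sqrt(rowSums(dir^2))
        zero <- nrm < 1e-9
        if (any(zero)) {   # coincident centers: deterministic split
          dir[zero, ] <- cbind(cos(i), sin(i))
          nrm[zero] <- 1
        }
        vel[i, ] <- colSums(dir / nrm * (overlap[i, js] + clearance) *
                              repulsion)
      }
    }
    free <- which(!ov_any)
    if (length(free)) {
      d0 <- sqrt(rowSums(pos[free, , drop = FALSE]^2))
      mv <- free[d0 > 1e-12]
      d0 <- d0[d0 > 1e-12]
      step <- pmin(attr_step * d0, 2)
      vel[mv, ] <- -pos[mv, , drop = FALSE] / d0 * step
    }
    # converged: nothing overlaps and the pending step is negligible --
    # stop before applying it so the final state is the one checked
    if (!any(has_overlap) && max(sqrt(rowSums(vel^2))) < tol) {
      converged <- TRUE
      break
    }
    pos <- pos + vel
    attr_step <- attr_step * decay
  }
  dmat <- as.matrix(stats::dist(pos))
  n_overlap <- sum(dmat < rsum - 1e-9 & upper.tri(dmat))
  if (n_overlap > 0L)
    stop(sprintf(paste0("packing failed to converge: %d overlapping pairs ",
                        "after %d iterations (try raising max_iter)"),
                 n_overlap, it), call. = FALSE)
  population$y <- pos[, 1L]
  population$z <- pos[, 2L]
  attr(population, "fitted_radius") <- max(sqrt(rowSums(pos^2)) + r)
  attr(population, "iterations") <- it
  attr(population, "converged") <- converged
  population
}

#' Logical and geometric operations on populations
#'
#' @param population an `axon_population`.
#' @param min,max diameter bounds (um) for `filter_by_diameter`.
#' @return the transformed population.
#' @export
filter_by_diameter <- function(population, min = -Inf, max = Inf) {
  stopifnot(inherits(population, "axon_population"))
  keep <- population$diameter >= min & population$diameter <= max
  out <- population[keep, , drop = FALSE]
  attributes(out)[c("seed", "fitted_radius")] <-
    attributes(population)[c("seed", "fitted_radius")]
  class(out) <- class(population)
  out
}

#' @rdname filter_by_diameter
#' @param center disk center `(y, z)` (um).
#' @param radius disk radius (um).
#' @export
remove_overlapping_with_disk <- function(population, center, radius) {
  stopifnot(inherits(population, "axon_population"),
            all(!is.na(population$y)))
  d <- sqrt((population$y - center[1L])^2 + (population$z - center[2L])^2)
  keep <- d >= radius + population$diameter / 2
  out <- population[keep, , drop = FALSE]
  attributes(out)[c("seed", "fitted_radius")] <-
    attributes(population)[c("seed", "fitted_radius")]
  class(out) <- class(population)
  out
}

#' @rdname filter_by_diameter
#' @param dy,dz translation (um).
#' @export
translate_population <- function(population, dy, dz) {
  stopifnot(inherits(population, "axon_population"))
  population$y <- population$y + dy
  population$z <- population$z + dz
  population
}

#' @rdname filter_by_diameter
#' @param angle rotation angle (degrees, counterclockwise) about `center`.
#' @export
rotate_population <- function(population, angle, center = c(0, 0)) {
  stopifnot(inherits(population, "axon_population"))
  a <- angle * pi / 180
  y <- population$y - center[1L]; z <- population$z - center[2L]
  population$y <- center[1L] + y * cos(a) - z * sin(a)
  population$z <- center[2L] + y * sin(a) + z * cos(a)
  population
}

#' Count overlapping fiber pairs in a placed population
#'
#' @param population a placed `axon_population`.
#' @param delta_gap gap that was enforced (um).
#' @return number of pairs whose center distance is below the sum of radii
#'   plus `delta_gap` (tolerance 1e-9 um).
#' @export
count_overlaps <- function(population, delta_gap = 0) {
  stopifnot(all(!is.na(population$y)))
  pos <- cbind(population$y, population$z)
  dmat <- as.matrix(stats::dist(pos))
  rsum <- outer(population$diameter / 2, population$diameter / 2, `+`) +
    delta_gap
  sum(dmat < rsum - 1e-9 & upper.tri(dmat))
}

#' Fascicles and nerves
#'
#' A fascicle is a circular bundle of placed axons; a nerve aggregates one or
#' more non-overlapping fascicles.
#'
#' @param population a placed `axon_population`.
#' @param center fascicle center `(y, z)` (um).
#' @param radius fascicle radius (um); defaults to the packing fitted radius.
#' @param length fiber length along x (um).
#' @return an object of class `fascicle`.
#' @export
fascicle <- function(population, center = c(0, 0), radius = NULL,
                     length = 10000) {
  stopifnot(inherits(population, "axon_population"))
  if (any(is.na(population$y)))
    stop("population must be placed (run axon_packing first)", call. = FALSE)
  if (is.null(radius)) {
    radius <- attr(population, "fitted_radius")
    if (is.null(radius))
      radius <- max(sqrt(population$y^2 + population$z^2) +
                      population$diameter / 2)
  }
  rr <- sqrt(population$y^2 + population$z^2) + population$diameter / 2
  if (any(rr > radius + 1e-6))
    stop("some axons extend beyond the fascicle radius", call. = FALSE)
  structure(list(center = center, radius = radius, length = length,
                 population = population),
            class = "fascicle")
}

#' @rdname fascicle
#' @param fascicles list of `fascicle` objects (must not overlap).
#' @param diameter nerve diameter (um).
#' @export
nerve <- function(fascicles, diameter, length = 10000) {
  stopifnot(is.list(fascicles), all(vapply(fascicles, inherits, TRUE,
                                           "fascicle")))
  k <- length(fascicles)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      fi <- fascicles[[i]]; fj <- fascicles[[j]]
      if (sqrt(sum((fi$center - fj$center)^2)) < fi$radius + fj$radius)
        stop("fascicles overlap", call. = FALSE)
    }
  }
  for (f in fascicles)
    if (sqrt(sum(f$center^2)) + f$radius > diameter / 2)
      stop("fascicle extends beyond the nerve", call. = FALSE)
  structure(list(diameter = diameter, length = length, fascicles = fascicles),
            class = "nerve")
}

#' @export
print.fascicle <- function(x, ...) {
  cat(sprintf("<fascicle: %d axons, radius %.1f um, center (%g, %g) um>\n",
              nrow(x$population), x$radius, x$center[1L], x$center[2L]))
  invisible(x)
}

#' Read / write population tables
#'
#' Population CSV files have columns `type`, `diameter_um`, `y_um`, `z_um`
#' (the import path for externally segmented axon tables).
#'
#' @param population an `axon_population`.
#' @param path CSV file path.
#' @return `write_population`: invisibly, `path`; `read_population`: an
#'   `axon_population`.
#' @export
write_population <- function(population, path) {
  df <- data.frame(type = population$type,
                   diameter_um = population$diameter,
                   y_um = population$y, z_um = population$z)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("type", "diameter_um")
  if (!all(need %in% names(df)))
    stop("population CSV must have columns type, diameter_um", call. = FALSE)
  pop <- data.frame(type = df$type, diameter = df$diameter_um,
                    y = if ("y_um" %in% names(df)) df$y_um else NA_real_,
                    z = if ("z_um" %in% names(df)) df$z_um else NA_real_)
  class(pop) <- c("axon_population", "data.frame")
  pop
}
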