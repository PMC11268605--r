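#' Membrane parameter sets
#'
#' `hh_membrane()` returns the classic squid-axon conductance set used for
#' unmyelinated fibers (rates of [hh_rates()], 6.3 C): fast Na (gates m, h),
#' delayed-rectifier K (gate n) and leak. `mrg_node_membrane()` returns the
#' nodal channel set of the standard mammalian double-cable myelinated model
#' (36 C): fast Na (m, h), persistent Na (mp), slow K (s) and leak.
#' Conductances in S/cm2, capacitance in uF/cm2, potentials in mV, axial
#' resistivity in ohm*cm.
#'
#' @return a named list of membrane parameters.
#' @export
hh_membrane <- function() {
  list(model = "hh", cm = 1, gna = 0.120, gk = 0.036, gl = 0.0003,
       ena = 50, ek = -77, el = -54.387, rho_axial = 35.4, v_rest = -65)
}

#' @rdname hh_membrane
#' @export
mrg_node_membrane <- function() {
  list(model = "mrg_node", cm = 2, gna = 3.0, gnap = 0.01, gk = 0.08,
       gl = 0.007, ena = 50, ek = -90, el = -90, rho_axial = 70,
       v_rest = -80)
}

# Singularity-safe x / (1 - exp(-x/y)): -> y as x -> 0.
.vtrap <- function(x, y) {
  out <- x / (1 - exp(-x / y))
  small <- abs(x / y) < 1e-6
  out[small] <- y[small] + x[small] / 2
  out
}

#' Hodgkin-Huxley gate rate constants
#'
#' Standard squid-axon alpha/beta rates (1/ms) for the m, h and n gates,
#' referenced to a resting potential of -65 mV, with singular points of the
#' rate expressions handled by their limits. Steady states are
#' `alpha/(alpha+beta)`.
#'
#' @param V membrane potential (mV), vectorized.
#' @return a list with components `am, bm, ah, bh, an, bn` and steady states
#'   `minf, hinf, ninf` plus time constants `taum, tauh, taun` (ms).
#' @examples
#' r <- hh_rates(-65)
#' c(r$minf, r$hinf, r$ninf)  # ~0.053, 0.596, 0.318
#' @export
hh_rates <- function(V) {
  stopifnot(all(is.finite(V)))
  am <- 0.1 * .vtrap(V + 40, rep(10, length(V)))
  bm <- 4 * exp(-(V + 65) / 18)
  ah <- 0.07 * exp(-(V + 65) / 20)
  bh <- 1 / (1 + exp(-(V + 35) / 10))
  an <- 0.01 * .vtrap(V + 55, rep(10, length(V)))
  bn <- 0.125 * exp(-(V + 65) / 80)
  list(am = am, bm = bm, ah = ah, bh = bh, an = an, bn = bn,
       minf = am / (am + bm), hinf = ah / (ah + bh), ninf = an / (an + bn),
       taum = 1 / (am + bm), tauh = 1 / (ah + bh), taun = 1 / (an + bn))
}

#' Nodal gate rate constants of the myelinated double-cable model
#'
#' Alpha/beta rates (1/ms) at 36 C for the fast sodium activation `m` and
#' inactivation `h`, persistent sodium activation `mp`, and slow potassium
#' activation `s` gates of the node-of-Ranvier membrane.
#'
#' @param V membrane potential (mV), vectorized.
#' @return list with `am, bm, ah, bh, amp, bmp, as_, bs_` and the
#'   corresponding steady states `minf, hinf, mpinf, sinf`.
#' @export
mrg_rates <- function(V) {
  stopifnot(all(is.finite(V)))
  n1 <- rep(1, length(V))
  am  <- 6.57 * .vtrap(V + 20.4, 10.3 * n1)
  bm  <- 0.304 * .vtrap(-(V + 25.7), 9.16 * n1)
  ah  <- 0.34 * .vtrap(-(V + 114), 11 * n1)
  bh  <- 12.6 / (1 + exp(-(V + 31.8) / 13.4))
  amp <- 0.0353 * .vtrap(V + 27, 10.2 * n1)
  bmp <- 0.000883 * .vtrap(-(V + 34), 10 * n1)
  as_ <- 0.3 / (1 + exp(-(V + 53) / 5))
  bs_ <- 0.03 / (1 + exp(-(V + 90) / 1))
  list(am = am, bm = bm, ah = ah, bh = bh, amp = amp, bmp = bmp,
       as_ = as_, bs_ = bs_,
       minf = am / (am + bm), hinf = ah / (ah + bh),
       mpinf = amp / (amp + bmp), sinf = as_ / (as_ + bs_))
}

# Numerically solved resting potential: V where total steady-state ionic
# current is zero, gates at their voltage steady state.
.solve_rest <- function(membrane) {
  f <- if (membrane$model == "hh") {
    function(V) {
      r <- hh_rates(V)
      membrane$gna * r$minf^3 * r$hinf * (V - membrane$ena) +
        membrane$gk * r$ninf^4 * (V - membrane$ek) +
        membrane$gl * (V - membrane$el)
    }
  } else {
    function(V) {
      r <- mrg_rates(V)
      membrane$gna * r$minf^3 * r$hinf * (V - membrane$ena) +
        membrane$gnap * r$mpinf^3 * (V - membrane$ena) +
        membrane$gk * r$sinf * (V - membrane$ek) +
        membrane$gl * (V - membrane$el)
    }
  }
  stats::uniroot(f, c(-99, -50), tol = 1e-10)$root
}

# Published double-cable geometry table: 9 fiber diameters (um) plus
# ratio-consistent anchor rows at 1 and 20 um so that the monotone spline
# interpolation stays positive on the whole [1, 20] domain.
.mrg_table <- data.frame(
  fiber   = c(1,    5.7, 7.3, 8.7, 10,  11.5, 12.8, 14,  15,   16,   20),
  node_d  = c(0.7,  1.9, 2.4, 2.8, 3.3, 3.7,  4.2,  4.7, 5.0,  5.5,  7.5),
  axon_d  = c(1.2,  3.4, 4.6, 5.8, 6.9, 8.1,  8.8,  9.2, 10.4, 10.9, 12.9),
  deltax  = c(100,  500, 750, 1000, 1150, 1250, 1350, 1400, 1450, 1500, 1700),
  flut_l  = c(10,   35,  38,  40,  46,  50,   54,   56,  58,   60,   68),
  nl      = c(20,   80,  100, 110, 120, 130,  135,  140, 145,  150,  170)
)

.mrg_splines <- local({
  tb <- .mrg_table
  lapply(tb[-1L], function(y) stats::splinefun(tb$fiber, y, method = "hyman"))
})

#' Myelinated fiber morphology from fiber diameter
#'
#' Interpolates the published discrete double-cable geometry table (node,
#' paranode/MYSA, juxtaparanode/FLUT and internode/STIN dimensions, number of
#' myelin lamellae) continuously over fiber diameters 1-20 um with monotone
#' cubic splines. The interpolant passes through the tabulated diameters and
#' is strictly positive over the whole domain, including below the smallest
#' tabulated diameter where plain polynomial fits of the original table turn
#' negative.
#'
#' @param fiber_diameter fiber (outer) diameter, um, in [1, 20].
#' @return a list of class `myelinated_morphology`: `node_length`,
#'   `node_diameter`, `mysa_length`, `mysa_diameter`, `flut_length`,
#'   `flut_diameter`, `stin_length` (per segment, 6 segments),
#'   `axon_diameter`, `internode_length` (node-to-node spacing, um) and
#'   `n_lamellae`.
#' @export
mrg_morphology <- function(fiber_diameter) {
  if (!is.finite(fiber_diameter) || fiber_diameter < 1 || fiber_diameter > 20)
    stop("`fiber_diameter` must be in [1, 20] um", call. = FALSE)
  s <- .mrg_splines
  node_l <- 1
  mysa_l <- 3
  flut_l <- s$flut_l(fiber_diameter)
  deltax <- s$deltax(fiber_diameter)
  stin_l <- (deltax - node_l - 2 * mysa_l - 2 * flut_l) / 6
  out <- list(node_length = node_l,
              node_diameter = s$node_d(fiber_diameter),
              mysa_length = mysa_l,
              mysa_diameter = s$node_d(fiber_diameter),
              flut_length = flut_l,
              flut_diameter = s$axon_d(fiber_diameter),
              stin_length = stin_l,
              axon_diameter = s$axon_d(fiber_diameter),
              internode_length = deltax,
              n_lamellae = s$nl(fiber_diameter))
  if (any(unlist(out) <= 0))
    stop("internal error: non-positive morphology value", call. = FALSE)
  class(out) <- "myelinated_morphology"
  out
}

# Periaxonal space widths (um) under MYSA, FLUT and STIN sections.
.space_mysa <- 0.002
.space_flut <- 0.004
.space_stin <- 0.004

#' Construct an unmyelinated fiber
#'
#' A single-cable Hodgkin-Huxley fiber discretized into equal compartments
#' along the x axis, positioned at transverse coordinates `(y, z)`.
#' The default spatial step is 2.5% of the passive length constant
#' `lambda = sqrt(d / (4 * gl * rho_axial))`.
#'
#' @param diameter fiber diameter (um), typically in (0.1, 3].
#' @param length fiber length (um); the fiber spans `[0, length]` on x.
#' @param y,z transverse position (um).
#' @param n_compartments number of compartments (>= 3); default from the
#'   length-constant rule.
#' @param membrane membrane parameter set, default [hh_membrane()].
#' @return an object of class `nerve_fiber`.
#' @export
unmyelinated_fiber <- function(diameter, length, y = 0, z = 0,
                               n_compartments = NULL,
                               membrane = hh_membrane()) {
  stopifnot(diameter > 0, length > 0)
  if (is.null(n_compartments)) {
    lambda_um <- sqrt((diameter * 1e-4) / (4 * membrane$gl * membrane$rho_axial)) * 1e4
    n_compartments <- max(3L, ceiling(length / (0.025 * lambda_um)))
  }
  n_compartments <- as.integer(n_compartments)
  if (n_compartments < 3L) stop("`n_compartments` must be >= 3", call. = FALSE)
  dx <- length / n_compartments
  x <- (seq_len(n_compartments) - 0.5) * dx
  v0 <- .solve_rest(membrane)
  comp <- data.frame(
    x = x, length = rep(dx, n_compartments),
    diameter = rep(diameter, n_compartments),
    label = rep("axon", n_compartments),
    mech = rep(1L, n_compartments)          # 1 = HH active
  )
  structure(list(type = "unmyelinated", diameter = diameter, length = length,
                 y = y, z = z, membrane = membrane, comp = comp,
                 v_rest = v0, model = "hh"),
            class = "nerve_fiber")
}

#' Construct a myelinated double-cable fiber
#'
#' Builds the compartment sequence node, MYSA, FLUT, 6 x STIN, FLUT, MYSA,
#' node, ... along the x axis (starting and ending on a node of Ranvier).
#' Nodes carry the active channel set of [mrg_node_membrane()]; internodal
#' compartments are passive double-cable sections: a passive axolemma under a
#' myelin sheath (capacitance and conductance scaled by the lamella count)
#' separated from it by a thin periaxonal space with its own axial pathway.
#'
#' @param diameter fiber diameter (um), in [1, 20].
#' @param y,z transverse position (um).
#' @param n_nodes number of nodes of Ranvier (>= 3). Give either `n_nodes` or
#'   `length`.
#' @param length target fiber length (um); converted to
#'   `floor(length / internode_length) + 1` nodes.
#' @param node_offset longitudinal shift of the first node (um), used to
#'   randomize node alignment across a population.
#' @param membrane nodal membrane set, default [mrg_node_membrane()].
#' @return an object of class `nerve_fiber`.
#' @export
myelinated_fiber <- function(diameter, y = 0, z = 0, n_nodes = NULL,
                             length = NULL, node_offset = 0,
                             membrane = mrg_node_membrane()) {
  morpho <- mrg_morphology(diameter)
  if (is.null(n_nodes)) {
    if (is.null(length)) stop("give `n_nodes` or `length`", call. = FALSE)
    n_nodes <- max(3L, floor(length / morpho$internode_length) + 1L)
  }
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 3L) stop("`n_nodes` must be >= 3", call. = FALSE)

  seg_l <- c(node = morpho$node_length, mysa = morpho$mysa_length,
             flut = morpho$flut_length, stin = morpho$stin_length)
  seg_d <- c(node = morpho$node_diameter, mysa = morpho$mysa_diameter,
             flut = morpho$flut_diameter, stin = morpho$axon_diameter)
  inter <- c("mysa", "flut", rep("stin", 6L), "flut", "mysa")
  labels <- c("node", rep(c(inter, "node"), n_nodes - 1L))
  lens <- seg_l[labels]
  diams <- seg_d[labels]
  xr <- cumsum(c(0, lens))
  x <- (xr[-length(xr)] + xr[-1L]) / 2 + node_offset
  mech <- ifelse(labels == "node", 2L, 0L)  # 2 = active node, 0 = passive
  v0 <- .solve_rest(membrane)
  comp <- data.frame(x = x, length = as.numeric(lens),
                     diameter = as.numeric(diams),
                     label = labels, mech = mech)
  structure(list(type = "myelinated", diameter = diameter,
                 length = sum(lens), y = y, z = z,
                 membrane = membrane, morphology = morpho, comp = comp,
                 n_nodes = n_nodes, v_rest = v0, model = "mrg"),
            class = "nerve_fiber")
}

#' @export
print.nerve_fiber <- function(x, ...) {
  cat(sprintf("<%s fiber: d = %g um, length = %g um, %d compartments, (y,z) = (%g, %g) um>\n",
              x$type, x$diameter, x$length, nrow(x$comp), x$y, x$z))
  invisible(x)
}

#' Node-of-Ranvier x positions of a fiber
#'
#' @param fiber a [myelinated_fiber()].
#' @return numeric vector of node-center x positions (um).
#' @export
node_positions <- function(fiber) {
  stopifnot(inherits(fiber, "nerve_fiber"))
  fiber$comp$x[fiber$comp$label == "node"]
}

# Electrical discretization shared with the compiled solver: absolute
# quantities per compartment in (mV, ms, uA, uF, mS, kOhm) units.
.fiber_electrics <- function(fiber) {
  comp <- fiber$comp
  n <- nrow(comp)
  mb <- fiber$membrane
  area <- pi * (comp$diameter * 1e-4) * (comp$length * 1e-4)   # cm2, axolemma
  rho_k <- mb$rho_axial / 1000                                 # kOhm*cm
  # axial resistance of each half-compartment through the axoplasm
  half_r <- rho_k * (comp$length / 2 * 1e-4) /
    (pi * (comp$diameter * 1e-4)^2 / 4)
  Ra <- half_r[-n] + half_r[-1L]

  Cm <- numeric(n); gpas <- numeric(n); epas <- numeric(n)
  gna <- numeric(n); gk <- numeric(n); gnap <- numeric(n)
  Cmy <- numeric(n); gmy <- numeric(n); wfree <- logical(n)
  Rp <- rep(Inf, n - 1L)

  if (fiber$model == "hh") {
    Cm <- mb$cm * area
    gna <- mb$gna * area * 1000; gk <- mb$gk * area * 1000
    gpas <- mb$gl * area * 1000; epas <- rep(mb$el, n)
  } else {
    morpho <- fiber$morphology
    is_node <- comp$label == "node"
    Cm <- 2 * area                          # uF (axolemma, 2 uF/cm2)
    g_ax <- c(node = mb$gl, mysa = 0.001, flut = 1e-4, stin = 1e-4)
    gpas <- g_ax[comp$label] * area * 1000  # mS
    epas <- rep(fiber$v_rest, n)            # internodal leak tied to rest
    gna[is_node] <- mb$gna * area[is_node] * 1000
    gnap[is_node] <- mb$gnap * area[is_node] * 1000
    gk[is_node] <- mb$gk * area[is_node] * 1000
    epas[is_node] <- mb$el
    # myelin sheath: per-lamella 0.1 uF/cm2 and 0.001 S/cm2, two membranes
    # per lamella, on the outer (fiber diameter) surface
    my_area <- pi * (fiber$diameter * 1e-4) * (comp$length * 1e-4)
    nl2 <- 2 * morpho$n_lamellae
    Cmy <- ifelse(is_node, 0, 0.1 / nl2 * my_area)
    gmy <- ifelse(is_node, 0, 0.001 / nl2 * my_area * 1000)
    wfree <- !is_node
    # periaxonal axial resistance between compartment centers
    sp <- c(node = .space_mysa, mysa = .space_mysa, flut = .space_flut,
            stin = .space_stin)
    r_cm <- comp$diameter / 2 * 1e-4
    s_cm <- sp[comp$label] * 1e-4
    ann <- pi * ((r_cm + s_cm)^2 - r_cm^2)                     # cm2
    half_p <- rho_k * (comp$length / 2 * 1e-4) / ann
    Rp <- half_p[-n] + half_p[-1L]
  }
  list(n = n, area = area, Cm = Cm, gpas = gpas, epas = epas,
       gna = gna, gk = gk, gnap = gnap,
       ena = rep(mb$ena, n), ek = rep(mb$ek, n),
       Cmy = Cmy, gmy = gmy, wfree = wfree, Ra = Ra, Rp = Rp,
       mech = comp$mech)
}

#' Per-compartment membrane current densities
#'
#' Computes the ionic current density of every compartment for a given
#' membrane state (`I_ion = sum g_max * gate-product * (V - E_rev) + leak`,
#' mA/cm2), and, if `dVdt` is supplied, the total membrane current density
#' `I_ion + C * dV/dt`. Internodal compartments of myelinated fibers
#' contribute their passive axolemma leak.
#'
#' @param fiber a [nerve_fiber].
#' @param V per-compartment membrane potential (mV).
#' @param gates list of per-compartment gate values: `m, h, n` for HH fibers;
#'   `m, h, mp, s` for myelinated fibers (node entries used, others ignored).
#'   If `NULL`, voltage steady states are used.
#' @param dVdt optional per-compartment dV/dt (mV/ms) for the capacitive term.
#' @return list with `i_ion` and (if `dVdt` given) `i_total`, mA/cm2.
#' @export
membrane_currents <- function(fiber, V, gates = NULL, dVdt = NULL) {
  stopifnot(inherits(fiber, "nerve_fiber"), length(V) == nrow(fiber$comp))
  mb <- fiber$membrane
  comp <- fiber$comp
  n <- length(V)
  i_ion <- numeric(n)
  if (fiber$model == "hh") {
    if (is.null(gates)) {
      r <- hh_rates(V)
      gates <- list(m = r$minf, h = r$hinf, n = r$ninf)
    }
    i_ion <- mb$gna * gates$m^3 * gates$h * (V - mb$ena) +
      mb$gk * gates$n^4 * (V - mb$ek) + mb$gl * (V - mb$el)
  } else {
    is_node <- comp$label == "node"
    if (is.null(gates)) {
      r <- mrg_rates(V)
      gates <- list(m = r$minf, h = r$hinf, mp = r$mpinf, s = r$sinf)
    }
    g_ax <- c(node = 0, mysa = 0.001, flut = 1e-4, stin = 1e-4)
    i_ion <- g_ax[comp$label] * (V - fiber$v_rest)
    i_ion[is_node] <-
      (mb$gna * gates$m^3 * gates$h * (V - mb$ena) +
       mb$gnap * gates$mp^3 * (V - mb$ena) +
       mb$gk * gates$s * (V - mb$ek) + mb$gl * (V - mb$el))[is_node]
    i_ion <- as.numeric(i_ion)
  }
  # conductance S/cm2 times potential mV gives mA/cm2 directly
  out <- list(i_ion = i_ion)
  if (!is.null(dVdt)) out$i_total <- i_ion + mb$cm * dVdt * 1e-3
  out
}

#' Serialize a fiber definition to JSON
#'
#' @param fiber a [nerve_fiber].
#' @param path optional output file.
#' @return JSON string, or (invisibly) `path` if written.
#' @export
fiber_to_json <- function(fiber, path = NULL) {
  x <- list(type = fiber$type, diameter = fiber$diameter,
            y = fiber$y, z = fiber$z, length = fiber$length,
            model = fiber$model)
  js <- as.character(jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE))
  if (is.null(path)) return(js)
  writeLines(js, path); invisible(path)
}

#' @rdname fiber_to_json
#' @param json JSON string or file path.
#' @export
fiber_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  if (x$type == "myelinated")
    myelinated_fiber(x$diameter, y = x$y, z = x$z, length = x$length)
  else unmyelinated_fiber(x$diameter, x$length, y = x$y, z = x$z)
}
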