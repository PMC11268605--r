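#' Simulate every fiber of a fascicle
#'
#' Creates a fiber object for each axon of the fascicle, propagates the
#' extracellular stimulation, clamps and recorders to it, and simulates each
#' one. Axon simulations are independent (no ephaptic coupling), so the loop
#' is embarrassingly parallel; results are deterministic and identical for
#' any `workers` value (per-fiber RNG streams are derived from the master
#' seed and the fiber index, never from scheduling).
#'
#' @param fasc a [fascicle()].
#' @param context an [extracellular_context()] or `NULL`.
#' @param clamps either `NULL`, a list of [clamp_current()] objects applied
#'   to every fiber, or a `function(fiber, index)` returning such a list
#'   (broadcast rule; use the function form to restrict to a subset).
#' @param config a [sim_config()]; set `record_imem = TRUE` when a recorder
#'   is attached.
#' @param rec optional [recorder()]: the aggregate eCAP is accumulated
#'   per fiber (traces are then discarded unless `keep_traces`).
#' @param workers process count hint; results are worker-count-invariant.
#' @param seed master seed for per-fiber randomization.
#' @param node_align if `FALSE`, myelinated node positions get a per-fiber
#'   random longitudinal offset in `[0, internode_length)`; if `TRUE`
#'   (default) nodes are aligned across fibers.
#' @param keep_traces keep every per-fiber [sim_result] (memory-heavy).
#' @param out_dir optional directory: per-fiber traces are exported
#'   incrementally as they complete.
#' @return list with `index` (per-fiber data frame: id, type, diameter, y,
#'   z, detected, t_cross), `n_recruited`, `ecap` (if a recorder was given)
#'   and `results` (if `keep_traces`).
#' @export
simulate_fascicle <- function(fasc, context = NULL, clamps = NULL,
                              config = sim_config(), rec = NULL,
                              workers = 1L, seed = 1L, node_align = TRUE,
                              keep_traces = FALSE, out_dir = NULL) {
  stopifnot(inherits(fasc, "fascicle"))
  pop <- fasc$population
  n <- nrow(pop)
  if (!is.null(rec) && !config$record_imem)
    stop("attach a recorder only with record_imem = TRUE", call. = FALSE)

  run_one <- function(i) {
    offset <- 0
    if (!node_align && pop$type[i] == "myelinated") {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(seed + i)
      offset <- stats::runif(1L) *
        mrg_morphology(pop$diameter[i])$internode_length
    }
    f <- if (pop$type[i] == "myelinated")
      myelinated_fiber(pop$diameter[i], y = pop$y[i], z = pop$z[i],
                       length = fasc$length, node_offset = offset)
    else unmyelinated_fiber(pop$diameter[i], fasc$length,
                            y = pop$y[i], z = pop$z[i])
    cl <- if (is.function(clamps)) clamps(f, i) else clamps
    r <- simulate_fiber(f, context, clamps = if (is.null(cl)) list() else cl,
                        config = config)
    det <- detect_propagating_ap(r, 0.75 * f$length)
    ec <- NULL
    if (!is.null(rec)) {
      fp <- recorder_footprints(rec, f)
      ec <- fp %*% r$imem / 1000
    }
    if (!is.null(out_dir))
      export_result(r, file.path(out_dir, sprintf("fiber_%04d", i)))
    list(i = i, detected = det$detected, t_cross = det$t_cross,
         time = r$time, ecap = ec,
         result = if (keep_traces) r else NULL)
  }

  res <- if (workers > 1L && .Platform$OS.type == "unix" &&
             requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(seq_len(n), run_one, mc.cores = workers)
  } else {
    lapply(seq_len(n), run_one)
  }
  for (r in res) if (inherits(r, "try-error") || is.null(r$i))
    stop("fiber simulation failed in the fascicle plan", call. = FALSE)

  index <- data.frame(
    id = seq_len(n), type = pop$type, diameter = pop$diameter,
    y = pop$y, z = pop$z,
    detected = vapply(res, `[[`, logical(1L), "detected"),
    t_cross = vapply(res, `[[`, numeric(1L), "t_cross"))
  out <- list(index = index, n_recruited = sum(index$detected))
  if (!is.null(rec)) {
    ecap <- Reduce(`+`, lapply(res, `[[`, "ecap"))
    out$ecap <- list(time = res[[1L]]$time, potential = ecap)
    if (!is.null(context) && length(context$sources))
      out$ecap_with_artifact <- list(
        time = res[[1L]]$time,
        potential = ecap + field_at(rec$points, res[[1L]]$time, context))
  }
  if (keep_traces) out$results <- lapply(res, `[[`, "result")
  out
}

#' Broadcast intracellular clamp for synchronous population activation
#'
#' Returns a broadcast rule for [simulate_fascicle()] clamping the most
#' proximal compartment of every fiber with a rectangular current pulse
#' (suprathreshold by default for both fiber types).
#'
#' @param start onset (ms).
#' @param amplitude clamp current (uA).
#' @param duration_myel,duration_unmyel pulse durations per fiber type (ms;
#'   unmyelinated fibers need longer depolarization).
#' @return a `function(fiber, index)` for the `clamps` argument.
#' @export
proximal_clamp_rule <- function(start = 0, amplitude = 0.005,
                                duration_myel = 0.1, duration_unmyel = 1) {
  function(fiber, index) {
    dur <- if (fiber$type == "myelinated") duration_myel else duration_unmyel
    list(clamp_current(1L, make_pulse(start, amplitude, dur)))
  }
}

#' Hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; embedded in every output file
#' header for provenance.
#'
#' @param config a list.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

.require_keys <- function(config, keys, task) {
  missing <- setdiff(keys, names(config))
  if (length(missing))
    stop(sprintf("config error for task '%s': missing required key(s): %s",
                 task, paste(missing, collapse = ", ")), call. = FALSE)
}

#' Run a JSON-described simulation task
#'
#' Executes one named task from a JSON configuration file (or an equivalent
#' list) and writes its outputs, each carrying the config hash, package
#' version and seed. Tasks:
#' \describe{
#'   \item{simulate-axon}{single-fiber simulation; keys `fiber`,
#'     optional `electrode` + `material` + `stimulus`, optional `clamp`,
#'     `sim`.}
#'   \item{pack}{population generation + packing; keys `population`.}
#'   \item{threshold}{activation threshold; keys `fiber`, `electrode`,
#'     `material`, `pulse`.}
#'   \item{block-threshold}{KHFAC block threshold; keys `diameter`,
#'     `hfac_freq`, `electrode_distance`.}
#'   \item{block-trace}{one supra-block simulation with gating traces; keys
#'     `diameter`, `hfac_freq`, `electrode_distance`, `amplitude_pp`.}
#'   \item{recruit}{recruitment curve; keys `population`, `electrode`,
#'     `material`, `sweep`.}
#'   \item{ecap}{synchronously activated population eCAP + amplitude-latency
#'     fit; keys `population`, `recording`.}
#'   \item{optimize}{waveform optimization on a single-fiber context; keys
#'     `fiber`, `electrode`, `material`, `parameterization`, `bounds`.}
#' }
#'
#' @param config path to a JSON file or a list.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the task's main results (also written to
#'   `out_dir`).
#' @export
run_config <- function(config, out_dir = ".") {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  .require_keys(config, "task", "<any>")
  task <- config$task
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(task = task, config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("nervesim")),
               seed = seed)

  get_fiber <- function(fc) {
    if (fc$type == "myelinated")
      myelinated_fiber(fc$diameter, y = fc$y %||% 0, z = fc$z %||% 0,
                       n_nodes = fc$n_nodes %||% NULL,
                       length = fc$length %||% NULL)
    else unmyelinated_fiber(fc$diameter, fc$length, y = fc$y %||% 0,
                            z = fc$z %||% 0)
  }
  get_cfg <- function(sc, dt = 0.002, t_sim = 3, imem = FALSE)
    sim_config(dt = sc$dt %||% dt, t_sim = sc$t_sim %||% t_sim,
               record_imem = imem,
               record_gates = isTRUE(sc$record_gates),
               record_every = sc$record_every %||% 1L)
  emit <- function(name, payload) {
    jsonlite::write_json(c(meta, payload), file.path(out_dir,
                                                     paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }

  out <- switch(
    task,
    "simulate-axon" = {
      .require_keys(config, c("fiber", "sim"), task)
      f <- get_fiber(config$fiber)
      ctx <- NULL
      if (!is.null(config$electrode)) {
        .require_keys(config, c("material", "stimulus"), task)
        ctx <- extracellular_context(
          material(config$material$sigma),
          list(list(electrode = point_source(config$electrode$x,
                                             config$electrode$y,
                                             config$electrode$z),
                    stim = stimulus(config$stimulus$times,
                                    config$stimulus$values,
                                    config$stimulus$interpolation %||% "hold"))))
      }
      cl <- list()
      if (!is.null(config$clamp))
        cl <- list(clamp_current(config$clamp$compartment %||% 1L,
                                 make_pulse(config$clamp$start,
                                            config$clamp$amplitude,
                                            config$clamp$duration)))
      r <- simulate_fiber(f, ctx, clamps = cl, config = get_cfg(config$sim))
      export_result(r, file.path(out_dir, "axon"))
      emit("axon_summary",
           list(max_V = max(r$V),
                detected = detect_propagating_ap(r, 0.75 * f$length)$detected))
      r
    },
    "pack" = {
      .require_keys(config, "population", task)
      pc <- config$population
      .require_keys(pc, c("n", "myelinated_fraction"), "pack/population")
      pop <- create_axon_population(pc$n, pc$myelinated_fraction, seed = seed)
      pop <- axon_packing(pop, delta_gap = pc$delta_gap %||% 0, seed = seed)
      write_population(pop, file.path(out_dir, "population.csv"))
      emit("pack_summary",
           list(n = nrow(pop), fitted_radius = attr(pop, "fitted_radius"),
                overlaps = count_overlaps(pop)))
      pop
    },
    "threshold" = {
      .require_keys(config, c("fiber", "electrode", "material", "pulse"), task)
      f <- get_fiber(config$fiber)
      el <- point_source(config$electrode$x, config$electrode$y,
                         config$electrode$z)
      res <- activation_threshold(
        f, el, material(config$material$sigma),
        make_pulse(config$pulse$start %||% 0.1, -1, config$pulse$duration),
        config = get_cfg(config$sim %||% list()))
      emit("threshold", list(threshold_uA = res$threshold,
                             n_evaluations = res$n_evaluations))
      res
    },
    "block-threshold" = {
      .require_keys(config, c("diameter", "hfac_freq", "electrode_distance"),
                    task)
      res <- block_threshold(config$diameter, config$hfac_freq,
                             config$electrode_distance)
      emit("block_threshold",
           list(threshold_pp_uA = res$threshold,
                n_evaluations = res$n_evaluations, protocol = res$protocol))
      res
    },
    "block-trace" = {
      .require_keys(config, c("diameter", "hfac_freq", "electrode_distance",
                              "amplitude_pp"), task)
      f <- myelinated_fiber(config$diameter, n_nodes = config$n_nodes %||% 51L)
      nodes <- which(f$comp$label == "node")
      cn <- nodes[(length(nodes) + 1L) %/% 2L]
      el <- point_source(f$comp$x[cn], config$electrode_distance, 0)
      hf <- make_sine(3, config$hfac_freq, config$amplitude_pp, 20)
      ctx <- extracellular_context(material(0.2),
                                   list(list(electrode = el, stim = hf)))
      r <- simulate_fiber(
        f, ctx,
        clamps = list(clamp_current(nodes[1L], make_pulse(0.5, 0.002, 0.1))),
        config = sim_config(dt = min(0.001, 1 / (25 * config$hfac_freq)),
                            t_sim = 23, record_gates = TRUE,
                            record_every = 10L))
      gdf <- data.frame(time = r$time, V = r$V[cn, ], m = r$gates$m[cn, ],
                        h = r$gates$h[cn, ], mp = r$gates$mp[cn, ],
                        s = r$gates$s[cn, ])
      utils::write.csv(gdf, file.path(out_dir, "block_trace_center_node.csv"),
                       row.names = FALSE)
      emit("block_trace_summary",
           list(m_max = max(gdf$m), s_final = gdf$s[nrow(gdf)],
                mp_final = gdf$mp[nrow(gdf)]))
      r
    },
    "recruit" = {
      .require_keys(config, c("population", "electrode", "material", "sweep"),
                    task)
      pc <- config$population
      pop <- create_axon_population(pc$n, pc$myelinated_fraction %||% 1,
                                    seed = seed)
      pop <- axon_packing(pop, seed = seed)
      fasc <- fascicle(pop, length = pc$length %||% 10000)
      el <- point_source(config$electrode$x, config$electrode$y,
                         config$electrode$z)
      rc <- recruitment_curve(
        fasc, el, material(config$material$sigma),
        sweep = config$sweep$values,
        sweep_type = config$sweep$type %||% "amplitude",
        waveform = make_pulse(0.1, -1, config$sweep$pulse_duration %||% 0.05),
        amplitude = config$sweep$amplitude %||% NULL)
      utils::write.csv(as.data.frame(rc),
                       file.path(out_dir, "recruitment.csv"),
                       row.names = FALSE)
      emit("recruitment", list(rate = attr(rc, "rate"),
                               rate_defined = attr(rc, "rate_defined")))
      rc
    },
    "ecap" = {
      .require_keys(config, c("population", "recording"), task)
      res <- ecap_pipeline(
        n_fibers = config$population$n %||% 100L,
        seed = seed,
        n_points = config$recording$n_points %||% 8L,
        spacing = config$recording$spacing %||% 2500,
        first_distance = config$recording$first_distance %||% 2500,
        dt = config$sim$dt %||% 0.002,
        t_sim = config$sim$t_sim %||% 4)
      write_ecap_csv(res$ecap, file.path(out_dir, "ecap.csv"))
      emit("ecap_fit", list(slope = res$fit$slope,
                            points = res$fit$points))
      res
    },
    "optimize" = {
      .require_keys(config, c("fiber", "electrode", "material",
                              "parameterization", "bounds"), task)
      f <- get_fiber(config$fiber)
      el <- point_source(config$electrode$x, config$electrode$y,
                         config$electrode$z)
      mat <- material(config$material$sigma)
      par_spec <- waveform_parameterization(
        config$parameterization$kind,
        n_knots = config$parameterization$n_knots %||% 1L,
        t_end = config$parameterization$t_end %||% 1)
      cfg <- get_cfg(config$sim %||% list())
      simulate_ctx <- function(ctx) {
        r <- simulate_fiber(ctx$fiber,
                            extracellular_context(ctx$mat,
                              list(list(electrode = ctx$electrode,
                                        stim = ctx$stim))),
                            config = ctx$config)
        tt <- seq(ctx$config$dt, ctx$config$t_sim, by = ctx$config$dt)
        list(recruited = detect_propagating_ap(r, 0.75 * ctx$fiber$length)$detected,
             samples = stim_eval(ctx$stim, tt))
      }
      static_ctx <- list(fiber = f, electrode = el, mat = mat,
                         stim = NULL, config = cfg)
      cf <- cost_function(
        static_ctx,
        function(x, ctx) context_modifier_waveform(x, par_spec, ctx),
        function(outc) energy_recruitment_cost(
          outc$samples, 1L, as.integer(outc$recruited),
          alpha_e = config$alpha_e %||% 1e-5,
          alpha_r = config$alpha_r %||% 1),
        simulate_ctx)
      res <- optimize_problem(
        cf, list(lower = config$bounds$lower, upper = config$bounds$upper),
        n_particles = config$n_particles %||% 25L,
        n_iterations = config$n_iterations %||% 60L, seed = seed,
        log_path = file.path(out_dir, "optimization.jsonl"))
      emit("optimize", list(best = as.list(res$par), cost = res$value))
      res
    },
    stop("config error: unknown task '", task, "'", call. = FALSE)
  )
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synchronous-activation eCAP pipeline
#'
#' The full extracellular-recording experiment: generate a myelinated
#' population, pack it into a fascicle in homogeneous endoneurium, activate
#' every fiber at t = 0 with a proximal intracellular clamp, record at
#' equally spaced points along the fascicle surface with PSA footprints, and
#' fit the log-log amplitude-latency slope (first recording point excluded).
#'
#' @param n_fibers population size (myelinated).
#' @param seed RNG seed for population and packing.
#' @param n_points number of recording points.
#' @param spacing recording point spacing along x (um).
#' @param first_distance x of the first recording point (um).
#' @param diameter_stats myelinated diameter spec (default the
#'   sciatic-emulating bimodal distribution).
#' @param record_radius transverse distance of the recording points from the
#'   fascicle axis (um). The default 120 um is the fascicle surface radius
#'   of the full-scale recording experiment; it is kept fixed when the
#'   population is scaled down so the recording geometry is unchanged.
#' @param margin fiber length kept beyond the last recording point (um), so
#'   sealed-end transients stay remote from the recorders.
#' @param dt,t_sim solver settings (ms).
#' @param workers forwarded to [simulate_fascicle()].
#' @return list with `fascicle`, `recorder`, `ecap`, `fit`
#'   (from [amplitude_latency_fit()]) and `sim` (the fascicle summary).
#' @export
ecap_pipeline <- function(n_fibers = 100L, seed = 1L, n_points = 8L,
                          spacing = 2500, first_distance = 2500,
                          diameter_stats = "sciatic_myelinated",
                          record_radius = 120, margin = 10000,
                          dt = 0.002, t_sim = 5, workers = 1L) {
  pop <- create_axon_population(
    n_fibers, 1, diameter_stats = list(myelinated = diameter_stats),
    seed = seed)
  pop <- axon_packing(pop, seed = seed)
  dists <- first_distance + spacing * (seq_len(n_points) - 1L)
  fasc <- fascicle(pop, length = max(dists) + margin)
  pts <- cbind(dists, record_radius, 0)
  rec <- recorder(pts)
  sim <- simulate_fascicle(
    fasc, clamps = proximal_clamp_rule(start = 0),
    config = sim_config(dt = dt, t_sim = t_sim, record_imem = TRUE,
                        record_every = 2L),
    rec = rec, seed = seed, workers = workers)
  fit <- amplitude_latency_fit(sim$ecap, t_activation = 0,
                               distances = dists)
  list(fascicle = fasc, recorder = rec, ecap = sim$ecap, fit = fit,
       sim = sim["index"])
}
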