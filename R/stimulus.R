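#' Stimulus waveforms as asynchronous event lists
#'
#' A stimulus is a list of `(time, value)` events: `times` in milliseconds
#' (strictly increasing) and `values` in microamperes. Between events the
#' waveform is interpreted according to the `interpolation` convention:
#' `"hold"` (zero-order hold, the value of the last event at or before `t`)
#' or `"linear"` (linear interpolation between bracketing events, last value
#' held after the final event). Before the first event a stimulus always
#' evaluates to 0. Stimuli are asynchronous: different stimuli need not share
#' a time base, and arithmetic between them is defined on the union of their
#' event times.
#'
#' @param times numeric vector of event times (ms), strictly increasing.
#' @param values numeric vector of currents (uA), same length as `times`.
#' @param interpolation `"hold"` or `"linear"`.
#' @return an object of class `stimulus`.
#' @examples
#' s <- stimulus(c(1, 1.05), c(-10, 0))
#' stim_eval(s, 1.02)  # -10
#' @export
stimulus <- function(times = numeric(0), values = numeric(0),
                     interpolation = c("hold", "linear")) {
  interpolation <- match.arg(interpolation)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have the same length", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("stimulus events must be finite", call. = FALSE)
  structure(list(times = times, values = values, interpolation = interpolation),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("<stimulus: %d events, %s interpolation", length(x$times),
              x$interpolation))
  if (length(x$times))
    cat(sprintf(", t in [%g, %g] ms, i in [%g, %g] uA",
                min(x$times), max(x$times), min(x$values), max(x$values)))
  cat(">\n")
  invisible(x)
}

#' Evaluate a stimulus at arbitrary times
#'
#' @param stim a [stimulus()].
#' @param t numeric vector of times (ms).
#' @return numeric vector of currents (uA); 0 before the first event.
#' @export
stim_eval <- function(stim, t) {
  stopifnot(inherits(stim, "stimulus"))
  if (any(!is.finite(t))) stop("evaluation times must be finite", call. = FALSE)
  n <- length(stim$times)
  if (n == 0L) return(rep(0, length(t)))
  if (stim$interpolation == "hold") {
    idx <- findInterval(t, stim$times)
    out <- c(0, stim$values)[idx + 1L]
  } else {
    if (n == 1L) {
      out <- ifelse(t < stim$times, 0, stim$values)
    } else {
      out <- stats::approx(stim$times, stim$values, xout = t,
                           method = "linear", rule = 2)$y
      out[t < stim$times[1L]] <- 0
    }
  }
  out
}

#' Generate a rectangular stimulation pulse
#'
#' Monophasic pulses are a single rectangular phase. Biphasic pulses are
#' charge-balanced by construction: a leading (typically cathodic) phase of
#' `amplitude` and `duration` followed, after an optional interphase gap, by a
#' counter-phase of amplitude `-amplitude/anodic_ratio` lasting
#' `duration * anodic_ratio`, so the integral of current is exactly zero.
#'
#' @param start pulse onset (ms).
#' @param amplitude first-phase current (uA; negative = cathodic).
#' @param duration first-phase duration (ms), > 0.
#' @param kind `"monophasic"` or `"biphasic"`.
#' @param anodic_ratio duration ratio of the counter phase (> 0); the counter
#'   phase amplitude is scaled by `1/anodic_ratio` to keep charge balance.
#' @param interphase gap between the two phases (ms), >= 0.
#' @return a hold-interpolated [stimulus()].
#' @export
make_pulse <- function(start, amplitude, duration,
                       kind = c("monophasic", "biphasic"),
                       anodic_ratio = 1, interphase = 0) {
  kind <- match.arg(kind)
  if (!is.finite(duration) || duration <= 0)
    stop("`duration` must be positive", call. = FALSE)
  if (kind == "monophasic")
    return(stimulus(c(start, start + duration), c(amplitude, 0)))
  if (!is.finite(anodic_ratio) || anodic_ratio <= 0)
    stop("`anodic_ratio` must be positive", call. = FALSE)
  if (interphase < 0) stop("`interphase` must be >= 0", call. = FALSE)
  t2 <- start + duration          # end of first phase
  t3 <- t2 + interphase           # start of counter phase
  t4 <- t3 + duration * anodic_ratio
  a2 <- -amplitude / anodic_ratio
  if (interphase > 0) {
    stimulus(c(start, t2, t3, t4), c(amplitude, 0, a2, 0))
  } else {
    stimulus(c(start, t2, t4), c(amplitude, a2, 0))
  }
}

#' Generate a sampled sine-wave stimulus
#'
#' Samples `(amplitude_pp/2) * sin(2*pi*freq*(t - start))` on
#' `[start, start + duration]` as a linearly interpolated stimulus; the
#' peak-to-peak span of the waveform is `amplitude_pp`. Used for
#' kilohertz-frequency alternating current (KHFAC) block waveforms.
#'
#' @param start onset (ms).
#' @param freq frequency (kHz).
#' @param amplitude_pp peak-to-peak amplitude (uA).
#' @param duration signal duration (ms).
#' @param dt_sample sample interval (ms); must satisfy the Nyquist bound
#'   `dt_sample < 1/(2*freq)`. Default is 1/20 of a period.
#' @return a linear-interpolated [stimulus()]; the last event is at
#'   `start + duration`.
#' @export
make_sine <- function(start, freq, amplitude_pp, duration,
                      dt_sample = 1 / (20 * freq)) {
  if (!is.finite(duration) || duration <= 0)
    stop("`duration` must be positive", call. = FALSE)
  if (!is.finite(dt_sample) || dt_sample <= 0 || dt_sample >= 1 / (2 * freq))
    stop("`dt_sample` must be positive and below 1/(2*freq) (Nyquist)",
         call. = FALSE)
  t <- seq(start, start + duration, by = dt_sample)
  if (t[length(t)] < start + duration) t <- c(t, start + duration)
  stimulus(t, (amplitude_pp / 2) * sin(2 * pi * freq * (t - start)),
           interpolation = "linear")
}

#' Generate a linear current ramp
#'
#' @param start onset (ms).
#' @param from,to currents at the beginning and end of the ramp (uA).
#' @param duration ramp duration (ms), > 0.
#' @return a linear-interpolated [stimulus()] holding `to` after the ramp.
#' @export
make_ramp <- function(start, from, to, duration) {
  if (!is.finite(duration) || duration <= 0)
    stop("`duration` must be positive", call. = FALSE)
  stimulus(c(start, start + duration), c(from, to), interpolation = "linear")
}

#' Combine two stimuli pointwise
#'
#' The result's time base is the sorted union of both operands' event times;
#' its value at each union time is `op` applied to the two operands evaluated
#' there. Duplicate times are merged. The result uses linear interpolation if
#' either operand does, otherwise hold (hold-hold and linear-linear
#' combinations are exact on the union grid).
#'
#' @param a,b [stimulus()] objects.
#' @param op `"add"`, `"sub"` or `"mul"`.
#' @return a [stimulus()].
#' @export
stim_combine <- function(a, b, op = c("add", "sub", "mul")) {
  op <- match.arg(op)
  stopifnot(inherits(a, "stimulus"), inherits(b, "stimulus"))
  tt <- sort(unique(c(a$times, b$times)))
  f <- switch(op, add = `+`, sub = `-`, mul = `*`)
  interp <- if (a$interpolation == "linear" || b$interpolation == "linear")
    "linear" else "hold"
  stimulus(tt, f(stim_eval(a, tt), stim_eval(b, tt)), interpolation = interp)
}

#' Scale a stimulus by a constant
#'
#' @param a a [stimulus()].
#' @param k scalar multiplier.
#' @return a [stimulus()] with all values multiplied by `k`.
#' @export
stim_scale <- function(a, k) {
  stopifnot(inherits(a, "stimulus"), is.numeric(k), length(k) == 1L)
  stimulus(a$times, a$values * k, interpolation = a$interpolation)
}

#' @export
Ops.stimulus <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(stim_scale(e1, -1))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for stimulus objects", call. = FALSE)
  }
  if (inherits(e1, "stimulus") && inherits(e2, "stimulus")) {
    op <- switch(.Generic, `+` = "add", `-` = "sub", `*` = "mul",
                 stop(.Generic, " not defined for stimulus objects",
                      call. = FALSE))
    return(stim_combine(e1, e2, op))
  }
  # stimulus (op) scalar
  if (inherits(e1, "stimulus")) { s <- e1; k <- e2 } else { s <- e2; k <- e1 }
  stopifnot(is.numeric(k), length(k) == 1L)
  switch(.Generic,
         `*` = stim_scale(s, k),
         `/` = if (inherits(e1, "stimulus")) stim_scale(s, 1 / k) else
           stop("scalar / stimulus not defined", call. = FALSE),
         stop(.Generic, " between stimulus and scalar not defined",
              call. = FALSE))
}

#' Net injected charge of a stimulus
#'
#' Integrates the stimulus over its event span, respecting the interpolation
#' convention (rectangles for hold, trapezoids for linear). Charge is reported
#' in nanocoulombs (uA * ms = nC).
#'
#' @param stim a [stimulus()].
#' @return charge in nC.
#' @export
stim_charge <- function(stim) {
  stopifnot(inherits(stim, "stimulus"))
  n <- length(stim$times)
  if (n < 2L) return(0)
  dt <- diff(stim$times)
  if (stim$interpolation == "hold") {
    sum(stim$values[-n] * dt)
  } else {
    sum((stim$values[-n] + stim$values[-1L]) / 2 * dt)
  }
}

#' Serialize / deserialize a stimulus to JSON
#'
#' @param stim a [stimulus()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `stim_to_json`: a JSON string (invisibly, the path if written);
#'   `stim_from_json`: a [stimulus()].
#' @export
stim_to_json <- function(stim, path = NULL) {
  stopifnot(inherits(stim, "stimulus"))
  x <- list(times = stim$times, values = stim$values,
            interpolation = stim$interpolation)
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname stim_to_json
#' @param json a JSON string or path to a JSON file.
#' @export
stim_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  stimulus(x$times, x$values,
           interpolation = if (is.null(x$interpolation)) "hold" else
             x$interpolation)
}
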