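#' Voltage trace container
#'
#' Sample-aligned membrane potential and injected current.
#'
#' @param dt sample interval (ms)
#' @param V membrane potential samples (mV)
#' @param I_in injected current samples (pA), same length as \code{V}
#' @param source provenance label (\code{"simulated"} or
#'   \code{"synthetic-recording"})
#' @return an object of class \code{voltage_trace}
#' @export
voltage_trace <- function(dt, V, I_in, source = "simulated") {
  if (length(V) != length(I_in))
    stop("V and I_in must be sample-aligned (equal length)")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(dt = dt, V = as.numeric(V), I_in = as.numeric(I_in),
                 source = source),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("voltage_trace (%s): %d samples at dt = %g ms (%.3f s)\n",
              x$source, length(x$V), x$dt, length(x$V) * x$dt / 1000))
  invisible(x)
}

#' Spike train container
#'
#' @param times spike times (ms), strictly increasing
#' @param duration trace duration (ms)
#' @return an object of class \code{spike_train}
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  if (length(times) && (min(times) < 0 || max(times) > duration))
    stop("spike times must lie within the trace duration")
  structure(times, duration = duration, class = "spike_train")
}

#' Integrate the aEIF (or two-compartment) model
#'
#' Forward-Euler integration at the waveform's sampling step. When the
#' voltage exceeds \code{Vspike} the spike time is recorded (the sample at
#' which the crossing is first seen), the voltage is reset to \code{Vr} and
#' the adaptation current incremented by \code{b} within the same step. The
#' recorded trace stores a stylized +30 mV peak at the spike sample.
#'
#' @param params an \code{aeif_params} or \code{two_comp_params} object
#' @param current a \code{current_waveform} (or a numeric vector of pA
#'   samples, in which case \code{dt} must be given)
#' @param init initial state \code{c(V, w)} (or \code{c(V, w, Vd)} for the
#'   two-compartment model); default is the leak reversal with no adaptation
#' @param dt sample interval override (ms)
#' @param record if \code{FALSE}, only spikes and the final state are kept
#' @return list with \code{trace} (a \code{voltage_trace} or \code{NULL}),
#'   \code{spikes} (a \code{spike_train}), \code{w} (adaptation trace if
#'   recorded), and \code{state_end}
#' @export
integrate_aeif <- function(params, current, init = NULL, dt = NULL,
                           record = TRUE) {
  if (inherits(current, "current_waveform")) {
    I <- current$I
    if (is.null(dt)) dt <- current$dt
  } else {
    I <- as.numeric(current)
    if (is.null(dt)) stop("dt required when current is a plain vector")
  }
  two_comp <- inherits(params, "two_comp_params")
  soma <- if (two_comp) params$soma else params
  if (is.null(init))
    init <- if (two_comp) c(soma$EL, 0, soma$EL) else c(soma$EL, 0)
  if (any(!is.finite(init))) stop("init state must be finite")
  if (two_comp) {
    res <- sim_two_comp_cpp(as_param_vector(soma), params$gc, params$Cd,
                            params$gLd, I, dt, init[1], init[2], init[3],
                            record)
    state_end <- c(V = res$V_end, w = res$w_end, Vd = res$Vd_end)
    w_trace <- NULL
  } else {
    res <- sim_aeif_cpp(as_param_vector(soma), I, dt, init[1], init[2],
                        record)
    state_end <- c(V = res$V_end, w = res$w_end)
    w_trace <- if (record) res$w else NULL
  }
  spikes <- spike_train(res$spikes * dt, duration = length(I) * dt)
  trace <- if (record) voltage_trace(dt, res$V, I) else NULL
  list(trace = trace, spikes = spikes, w = w_trace, state_end = state_end)
}

#' State on the noise-free limit cycle
#'
#' Integrates the model without noise from the post-spike reset state and
#' returns the state at the end of the settling window. Used to initialize
#' protocols that require the spiking (up) state. Errors if the trajectory
#' has fallen silent (no spike in the second half of the window).
#'
#' @param params an \code{aeif_params} object
#' @param I constant current (pA)
#' @param settle_ms settling time (ms)
#' @param dt integration step (ms)
#' @return numeric \code{c(V, w)} on the limit cycle
#' @export
limit_cycle_state <- function(params, I, settle_ms = 1000, dt = 0.1) {
  n <- round(settle_ms / dt)
  res <- sim_aeif_cpp(as_param_vector(params), rep(I, n), dt,
                      params$Vr, params$b, FALSE)
  sp <- res$spikes * dt
  if (!length(sp) || max(sp) < settle_ms / 2)
    stop("no sustained spiking at I = ", I,
         " pA: limit cycle absent or not reached")
  c(res$V_end, res$w_end)
}

#' Rest state of the model
#'
#' Returns the stable fixed point \code{c(V*, w*)} at constant current
#' \code{I} (see \code{\link{find_fixed_points}}).
#'
#' @param params an \code{aeif_params} object
#' @param I constant current (pA)
#' @return numeric \code{c(V, w)} at the stable fixed point
#' @export
rest_state <- function(params, I) {
  fps <- find_fixed_points(params, I)
  st <- Filter(function(f) startsWith(f$class, "stable"), fps)
  if (!length(st)) stop("no stable fixed point at I = ", I, " pA")
  c(st[[1]]$V, st[[1]]$w)
}
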