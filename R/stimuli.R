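#' Current waveform container
#'
#' A sampled stimulus waveform with optional per-segment protocol
#' annotations.
#'
#' @param dt sample interval (ms)
#' @param I current samples (pA)
#' @param segments optional data.frame annotating protocol segments
#'   (columns \code{label}, \code{start_ms}, \code{end_ms}, \code{mean},
#'   \code{sigma})
#' @return an object of class \code{current_waveform}
#' @export
current_waveform <- function(dt, I, segments = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  if (any(!is.finite(I))) stop("current samples must be finite")
  structure(list(dt = dt, I = as.numeric(I), segments = segments),
            class = "current_waveform")
}

#' @export
print.current_waveform <- function(x, ...) {
  cat(sprintf("current_waveform: %d samples at dt = %g ms (%.3f s)\n",
              length(x$I), x$dt, length(x$I) * x$dt / 1000))
  if (!is.null(x$segments))
    cat(sprintf("  %d annotated segments (%s)\n", nrow(x$segments),
                paste(unique(x$segments$label), collapse = ", ")))
  invisible(x)
}

#' Ornstein-Uhlenbeck noise current
#'
#' Stationary OU process \eqn{\tau \dot x = \mu - x + \sqrt{2\sigma^2\tau}\,\xi(t)}
#' with mean \code{mu}, stationary SD \code{sigma} and correlation time
#' \code{tau}. Discretized with the exact update
#' \eqn{x \leftarrow \mu + (x-\mu) e^{-\Delta t/\tau} +
#' \sigma\sqrt{1-e^{-2\Delta t/\tau}} z}, which has the exact stationary
#' moments at any step size.
#'
#' @param mu mean (pA)
#' @param sigma stationary standard deviation (pA)
#' @param tau correlation time (ms)
#' @param dt sample interval (ms)
#' @param n number of samples
#' @param seed optional integer seed (the R RNG is used; pass \code{NULL} to
#'   continue the current RNG stream)
#' @return a \code{current_waveform}
#' @export
ou_series <- function(mu, sigma, tau, dt, n, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (tau <= 0) stop("tau must be > 0")
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  x <- ou_series_cpp(n, dt, mu, sigma, tau, 0, TRUE)
  current_waveform(dt, x,
                   segments = data.frame(label = "ou", start_ms = 0,
                                         end_ms = n * dt, mean = mu,
                                         sigma = sigma))
}

#' Dual-timescale OU noise for the dynamic I-V protocol
#'
#' The sum of two independent OU processes with correlation times
#' \code{tau_fast} = 3 ms and \code{tau_slow} = 10 ms (mimicking excitatory
#' and inhibitory synaptic currents), scaled so their combined stationary SD
#' equals \code{sigma}, plus a holding mean. The default protocol is a
#' silent lead-in followed by the noise epoch.
#'
#' @param mean holding mean (pA)
#' @param sigma combined stationary SD (pA)
#' @param dt sample interval (ms)
#' @param duration_ms noise epoch duration (ms)
#' @param lead_ms silent lead-in (ms)
#' @param tau_fast,tau_slow correlation times (ms)
#' @param var_split fraction of the variance assigned to the fast component
#' @param seed optional integer seed
#' @return a \code{current_waveform} with annotated lead-in and noise epochs
#' @export
dual_ou_current <- function(mean, sigma, dt, duration_ms = 20000,
                            lead_ms = 500, tau_fast = 3, tau_slow = 10,
                            var_split = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_lead <- round(lead_ms / dt)
  n <- round(duration_ms / dt)
  s_f <- sigma * sqrt(var_split)
  s_s <- sigma * sqrt(1 - var_split)
  xf <- ou_series_cpp(n, dt, 0, s_f, tau_fast, 0, TRUE)
  xs <- ou_series_cpp(n, dt, 0, s_s, tau_slow, 0, TRUE)
  I <- c(rep(mean, n_lead), mean + xf + xs)
  seg <- data.frame(label = c("lead", "dual_ou"),
                    start_ms = c(0, lead_ms),
                    end_ms = c(lead_ms, lead_ms + duration_ms),
                    mean = mean, sigma = c(0, sigma))
  current_waveform(dt, I, seg)
}

#' Normalization constant of the biexponential synaptic kernel
#'
#' \eqn{K(\tau_1,\tau_2)} scales the impulse response of the cascade
#' \eqn{(\tau_1 \partial_t + 1)(\tau_2 \partial_t + 1) I_{syn} = A_m
#' \delta(t)/K} so that a single event peaks at exactly \eqn{A_m}.
#'
#' @param tau1 rise time constant (ms)
#' @param tau2 decay time constant (ms)
#' @return the normalization constant
#' @export
biexp_K <- function(tau1, tau2) {
  if (tau1 == tau2) stop("tau1 == tau2: K undefined")
  r <- tau2 / tau1
  (r^(tau1 / (tau1 - tau2)) - r^(tau2 / (tau1 - tau2))) / (tau2 - tau1)
}

#' Biexponential synaptic input current
#'
#' Each event at time \eqn{t_{st}} contributes
#' \eqn{A_m (e^{-(t-t_{st})/\tau_2} - e^{-(t-t_{st})/\tau_1}) /
#' ((\tau_2-\tau_1) K(\tau_1,\tau_2))}; events sum linearly. Evaluated with
#' two recursive exponential filters, so arbitrarily long event trains cost
#' O(n).
#'
#' @param event_times event times (ms), within \code{[0, n*dt)}
#' @param Am peak amplitude per event (pA)
#' @param dt sample interval (ms)
#' @param n number of samples
#' @param tau1 rise time constant (ms), default 1.5
#' @param tau2 decay time constant (ms), default 10
#' @return a \code{current_waveform}
#' @export
biexp_current <- function(event_times, Am, dt, n, tau1 = 1.5, tau2 = 10) {
  if (tau1 >= tau2) stop("requires 0 < tau1 < tau2")
  if (length(event_times) &&
      (min(event_times) < 0 || max(event_times) >= n * dt))
    stop("event times must lie within [0, n*dt)")
  impulse <- numeric(n)
  if (length(event_times)) {
    idx <- floor(event_times / dt) + 1
    for (i in idx) impulse[i] <- impulse[i] + 1
  }
  scale <- Am / ((tau2 - tau1) * biexp_K(tau1, tau2))
  s2 <- stats::filter(impulse, exp(-dt / tau2), method = "recursive")
  s1 <- stats::filter(impulse, exp(-dt / tau1), method = "recursive")
  current_waveform(dt, scale * as.numeric(s2 - s1))
}

#' Homogeneous Poisson event times
#'
#' @param rate_hz mean event rate (Hz)
#' @param T_ms duration (ms)
#' @param seed optional integer seed
#' @return event times in ms, sorted
#' @export
poisson_events <- function(rate_hz, T_ms, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, rate_hz * T_ms / 1000)
  sort(stats::runif(n, 0, T_ms))
}

#' Build a standard stimulation protocol
#'
#' Assembles the study's current-injection protocols as annotated waveforms:
#' \describe{
#'   \item{noise_steps}{alternating noise epochs (OU, \code{tau} = 2 ms) and
#'     silent rest epochs, with the noise SD stepped over a grid}
#'   \item{continuous_noise}{OU noise whose amplitude ramps linearly up and
#'     back down (triangle) at a given rate}
#'   \item{ramp}{slow triangular ramps of mean current (ascending then
#'     descending), repeated}
#'   \item{current_steps}{a staircase of 1 s constant-current steps}
#'   \item{pulse}{a single brief square pulse over a holding current}
#' }
#'
#' @param kind one of \code{"noise_steps"}, \code{"continuous_noise"},
#'   \code{"ramp"}, \code{"current_steps"}, \code{"pulse"}
#' @param dt sample interval (ms)
#' @param seed optional integer seed for the stochastic protocols
#' @param mean holding current (pA)
#' @param sigmas noise SD grid for \code{noise_steps} (pA)
#' @param epoch_ms,rest_ms noise/rest epoch durations for
#'   \code{noise_steps} (ms)
#' @param tau OU correlation time (ms)
#' @param sigma_rate amplitude ramp rate for \code{continuous_noise} (pA/ms)
#' @param sigma_max peak noise SD for \code{continuous_noise} (pA)
#' @param ramp_rate current ramp rate for \code{ramp} (pA/ms; 0.9 nA/s =
#'   0.9 pA/ms)
#' @param ramp_ms single-limb ramp duration (ms)
#' @param trials number of triangle repetitions for \code{ramp}
#' @param start start current of the ramp (pA)
#' @param step_pA,n_steps,step_ms staircase definition for
#'   \code{current_steps}
#' @param pulse_ms,pulse_pA,t_pulse,total_ms pulse definition for
#'   \code{pulse}
#' @return a \code{current_waveform} with per-segment annotations
#' @export
build_protocol <- function(kind, dt = 0.1, seed = NULL,
                           mean = -150,
                           sigmas = seq(0, 500, by = 50), epoch_ms = 1000,
                           rest_ms = 1000, tau = 2,
                           sigma_rate = 0.5, sigma_max = 250,
                           ramp_rate = 0.9, ramp_ms = 1000, trials = 10,
                           start = -500,
                           step_pA = 50, n_steps = 30, step_ms = 1000,
                           pulse_ms = 0.5, pulse_pA = 1000, t_pulse = 100,
                           total_ms = 400) {
  if (!is.null(seed)) set.seed(seed)
  kind <- match.arg(kind, c("noise_steps", "continuous_noise", "ramp",
                            "current_steps", "pulse"))
  if (kind == "noise_steps") {
    n_e <- round(epoch_ms / dt); n_r <- round(rest_ms / dt)
    I <- numeric(0); seg <- NULL; t0 <- 0
    for (s in sigmas) {
      noise <- ou_series_cpp(n_e, dt, mean, s, tau, 0, TRUE)
      I <- c(I, noise, rep(mean, n_r))
      seg <- rbind(seg,
                   data.frame(label = c("noise", "rest"),
                              start_ms = c(t0, t0 + epoch_ms),
                              end_ms = c(t0 + epoch_ms,
                                         t0 + epoch_ms + rest_ms),
                              mean = mean, sigma = c(s, 0)))
      t0 <- t0 + epoch_ms + rest_ms
    }
    return(current_waveform(dt, I, seg))
  }
  if (kind == "continuous_noise") {
    # triangular amplitude envelope: 0 -> sigma_max -> 0 at sigma_rate pA/ms
    limb_n <- round(sigma_max / sigma_rate / dt)
    env <- c(seq(0, sigma_max, length.out = limb_n),
             seq(sigma_max, 0, length.out = limb_n))
    z <- ou_series_cpp(length(env), dt, 0, 1, tau, 0, TRUE)
    wf <- current_waveform(dt, mean + env * z,
                           data.frame(label = "continuous_noise",
                                      start_ms = 0,
                                      end_ms = length(env) * dt,
                                      mean = mean, sigma = NA))
    attr(wf, "sigma_envelope") <- env
    return(wf)
  }
  if (kind == "ramp") {
    limb_n <- round(ramp_ms / dt)
    up <- start + ramp_rate * dt * seq_len(limb_n)
    tri <- c(up, rev(up))
    I <- rep(tri, trials)
    seg <- data.frame(label = rep(c("ramp_up", "ramp_down"), trials),
                      start_ms = (seq_len(2 * trials) - 1) * ramp_ms,
                      end_ms = seq_len(2 * trials) * ramp_ms,
                      mean = NA, sigma = 0)
    return(current_waveform(dt, I, seg))
  }
  if (kind == "current_steps") {
    lv <- start + step_pA * (seq_len(n_steps) - 1)
    n_s <- round(step_ms / dt)
    I <- rep(lv, each = n_s)
    seg <- data.frame(label = sprintf("step_%d", seq_len(n_steps)),
                      start_ms = (seq_len(n_steps) - 1) * step_ms,
                      end_ms = seq_len(n_steps) * step_ms,
                      mean = lv, sigma = 0)
    return(current_waveform(dt, I, seg))
  }
  # pulse
  n <- round(total_ms / dt)
  I <- rep(mean, n)
  i0 <- round(t_pulse / dt) + 1
  i1 <- i0 + round(pulse_ms / dt) - 1
  I[i0:i1] <- mean + pulse_pA
  seg <- data.frame(label = c("hold", "pulse", "decay"),
                    start_ms = c(0, t_pulse, t_pulse + pulse_ms),
                    end_ms = c(t_pulse, t_pulse + pulse_ms, total_ms),
                    mean = c(mean, mean + pulse_pA, mean), sigma = 0)
  current_waveform(dt, I, seg)
}
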