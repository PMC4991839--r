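#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings with refractory enforcement; used on
#' experiment-like synthetic recordings where no integrator spike log exists.
#'
#' @param trace a \code{voltage_trace}
#' @param threshold detection threshold (mV)
#' @param refractory minimal inter-spike interval (ms)
#' @return a \code{spike_train}
#' @export
detect_spikes <- function(trace, threshold = -20, refractory = 2) {
  V <- trace$V
  up <- which(V[-1] > threshold & V[-length(V)] <= threshold) + 1
  t <- up * trace$dt
  if (length(t) > 1) {
    keep <- c(TRUE, diff(t) > 0)
    t <- t[keep]
    # enforce refractory sequentially
    out <- t[1]
    for (ti in t[-1]) if (ti - out[length(out)] >= refractory)
      out <- c(out, ti)
    t <- out
  }
  spike_train(t, duration = length(V) * trace$dt)
}

#' ISR tuning curve from constant-amplitude noise epochs
#'
#' Firing rate per epoch, averaged per noise amplitude, then smoothed with a
#' Gaussian filter (width comparable to the amplitude step, truncated at
#' three widths). The optimal noise amplitude for spike inhibition,
#' \code{sigma_opt}, is the grid argmin of the smoothed curve. A flat curve
#' (range below twice the epoch-wise standard error) is flagged.
#'
#' @param epochs data.frame with columns \code{sigma} (pA), \code{count}
#'   (spikes) and \code{duration} (ms); one row per epoch
#' @param smoothing Gaussian smoothing width (pA); default: the sigma grid
#'   step
#' @return an object of class \code{isr_curve}: data.frame of per-sigma mean
#'   rate, SD, smoothed rate; plus \code{sigma_opt} and \code{flat}
#'   attributes
#' @export
isr_curve <- function(epochs, smoothing = NULL) {
  stopifnot(all(c("sigma", "count", "duration") %in% names(epochs)))
  sig <- sort(unique(epochs$sigma))
  if (length(sig) < 3) stop("need at least 3 distinct noise amplitudes")
  rate <- 1000 * epochs$count / epochs$duration  # Hz
  mu <- tapply(rate, epochs$sigma, mean)[as.character(sig)]
  sdv <- tapply(rate, epochs$sigma, stats::sd)[as.character(sig)]
  if (is.null(smoothing)) smoothing <- stats::median(diff(sig))
  sm <- gaussian_smooth(sig, mu, smoothing)
  sem <- sdv / sqrt(tapply(rate, epochs$sigma, length)[as.character(sig)])
  flat <- diff(range(sm)) <= 2 * stats::median(sem, na.rm = TRUE)
  if (flat) warning("ISR curve is flat: sigma_opt is not significant")
  out <- data.frame(sigma = sig, rate = as.numeric(mu),
                    rate_sd = as.numeric(sdv), smoothed = sm)
  structure(out, sigma_opt = sig[which.min(sm)], smoothing = smoothing,
            flat = flat, class = c("isr_curve", "data.frame"))
}

gaussian_smooth <- function(x, y, width) {
  if (width <= 0) return(y)
  vapply(x, function(x0) {
    d <- abs(x - x0)
    w <- exp(-0.5 * (d / width)^2)
    w[d > 3 * width] <- 0
    sum(w * y) / sum(w)
  }, numeric(1))
}

#' Model ISR curve under the stepped-noise protocol
#'
#' Simulates independent constant-amplitude OU noise epochs (each started in
#' the spiking state on the noise-free limit cycle) across a noise-amplitude
#' grid and assembles the ISR tuning curve.
#'
#' @param params an \code{aeif_params} object
#' @param I_mean mean input current (pA)
#' @param sigmas noise SD grid (pA)
#' @param reps epochs per sigma
#' @param T_ms epoch duration (ms)
#' @param tau OU correlation time (ms)
#' @param dt integration step (ms)
#' @param seed optional integer seed
#' @param smoothing passed to \code{\link{isr_curve}}
#' @return an \code{isr_curve}
#' @export
isr_curve_model <- function(params, I_mean = -150, sigmas = seq(0, 100, 10),
                            reps = 20, T_ms = 30000, tau = 2, dt = 0.1,
                            seed = NULL, smoothing = NULL) {
  if (!is.null(seed)) set.seed(seed)
  init <- limit_cycle_state(params, I_mean, dt = dt)
  cnt <- isr_counts_cpp(as_param_vector(params), sigmas, reps,
                        round(T_ms / dt), dt, I_mean, tau, init[1], init[2])
  epochs <- data.frame(sigma = rep(sigmas, each = reps),
                       count = as.numeric(cnt), duration = T_ms)
  isr_curve(epochs, smoothing = smoothing)
}

#' History-resolved ISR curve from a continuously ramped noise protocol
#'
#' Splits the recording into fixed windows, labels each window by whether
#' the cell fired in the previous window, and computes the running-average
#' firing rate against the instantaneous noise amplitude separately for the
#' two histories.
#'
#' @param trace a \code{voltage_trace} carrying a per-sample
#'   \code{sigma_envelope} attribute (as produced by integrating a
#'   \code{build_protocol("continuous_noise")} waveform)
#' @param spikes a \code{spike_train} for the trace
#' @param window analysis window (ms)
#' @param bin noise-amplitude bin width (pA)
#' @return list of two data.frames (\code{was_firing}, \code{was_silent})
#'   with columns \code{sigma}, \code{rate}, \code{n}
#' @export
isr_curve_continuous <- function(trace, spikes, window = 200, bin = 20) {
  env <- attr(trace, "sigma_envelope")
  if (is.null(env)) stop("trace lacks a sigma_envelope annotation")
  n_win <- floor(length(trace$V) * trace$dt / window)
  if (n_win < 2) stop("trace shorter than two analysis windows")
  win_of <- pmin(floor(spikes / window) + 1, n_win)
  counts <- tabulate(win_of, nbins = n_win)
  # mean envelope amplitude per window
  idx <- floor((seq_len(n_win) - 0.5) * window / trace$dt)
  sig_w <- env[pmin(pmax(idx, 1), length(env))]
  firing_prev <- c(FALSE, counts[-n_win] > 0)
  rate <- 1000 * counts / window
  split_curve <- function(sel) {
    if (!any(sel)) return(data.frame(sigma = numeric(0), rate = numeric(0),
                                     n = integer(0)))
    br <- bin * (floor(sig_w[sel] / bin) + 0.5)
    agg <- stats::aggregate(rate[sel], list(sigma = br), mean)
    cnt <- stats::aggregate(rate[sel], list(sigma = br), length)
    data.frame(sigma = agg$sigma, rate = agg$x, n = cnt$x)
  }
  list(was_firing = split_curve(firing_prev),
       was_silent = split_curve(!firing_prev))
}

#' Firing-rate hysteresis under slow current ramps
#'
#' Symmetric triangular current ramps (default 0.9 nA/s, 1 s up then 1 s
#' down, 10 trials). Per spike, the instantaneous frequency (reciprocal of
#' the preceding inter-spike interval; for the first ascending spike, of the
#' following interval) and the instantaneous current are recorded. The
#' hysteresis is \eqn{\Delta f = f_{up} - f_{down}} and
#' \eqn{\Delta I = I_{up} - I_{down}}, from the first ascending and last
#' descending spike, averaged over trials.
#'
#' @param params an \code{aeif_params} object
#' @param rate ramp rate (pA/ms; 0.9 = 0.9 nA/s)
#' @param ramp_ms single-limb duration (ms)
#' @param trials number of triangle repetitions
#' @param start ramp start current (pA); the model should be at rest there
#' @param dt integration step (ms)
#' @return an object of class \code{hysteresis_result}: list with trial
#'   means \code{I_up}, \code{I_down}, \code{f_up}, \code{f_down},
#'   \code{dI}, \code{df}, per-trial values, and the protocol
#' @export
hysteresis_ramp <- function(params, rate = 0.9, ramp_ms = 1000, trials = 10,
                            start = -500, dt = 0.1) {
  limb_n <- round(ramp_ms / dt)
  up <- start + rate * dt * seq_len(limb_n)
  tri <- c(up, rev(up))
  init <- tryCatch(rest_state(params, start), error = function(e)
    c(params$EL, 0))
  per <- data.frame(I_up = rep(NA_real_, trials), f_up = NA_real_,
                    I_down = NA_real_, f_down = NA_real_)
  for (tr in seq_len(trials)) {
    res <- sim_aeif_cpp(as_param_vector(params), tri, dt, init[1], init[2],
                        FALSE)
    sp <- res$spikes  # sample indices
    asc <- sp[sp <= limb_n]
    desc <- sp[sp > limb_n]
    if (length(asc) >= 1) {
      per$I_up[tr] <- tri[asc[1]]
      nxt <- c(asc, desc)[2]
      if (!is.na(nxt)) per$f_up[tr] <- 1000 / ((nxt - asc[1]) * dt)
    }
    if (length(desc) >= 1) {
      last <- desc[length(desc)]
      per$I_down[tr] <- tri[last]
      prev <- c(asc, desc)[length(c(asc, desc)) - 1]
      if (length(c(asc, desc)) >= 2)
        per$f_down[tr] <- 1000 / ((last - prev) * dt)
    }
  }
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else
    mean(x, na.rm = TRUE)
  I_up <- mean_or_na(per$I_up); I_down <- mean_or_na(per$I_down)
  f_up <- mean_or_na(per$f_up); f_down <- mean_or_na(per$f_down)
  structure(list(I_up = I_up, I_down = I_down, f_up = f_up,
                 f_down = f_down, dI = I_up - I_down, df = f_up - f_down,
                 per_trial = per,
                 protocol = list(rate = rate, ramp_ms = ramp_ms,
                                 trials = trials, start = start, dt = dt)),
            class = "hysteresis_result")
}

#' f-I curve from a staircase of current steps
#'
#' Consecutive 1 s constant-current steps (state carried over between
#' steps, as in the staircase protocol). Reports the firing frequency per
#' step and the onset discontinuity (rate at the first spiking step).
#'
#' @param params an \code{aeif_params} object
#' @param start first step current (pA)
#' @param step_pA step increment (pA)
#' @param n_steps number of steps
#' @param step_ms step duration (ms)
#' @param dt integration step (ms)
#' @return data.frame with columns \code{I}, \code{f} (Hz); attribute
#'   \code{f_onset} holds the discontinuity size
#' @export
fi_curve <- function(params, start = -500, step_pA = 50, n_steps = 30,
                     step_ms = 1000, dt = 0.1) {
  wf <- build_protocol("current_steps", dt = dt, start = start,
                       step_pA = step_pA, n_steps = n_steps,
                       step_ms = step_ms)
  init <- tryCatch(rest_state(params, start),
                   error = function(e) c(params$EL, 0))
  res <- integrate_aeif(params, wf, init = init, record = FALSE)
  lv <- start + step_pA * (seq_len(n_steps) - 1)
  step_of <- pmin(floor(res$spikes / step_ms) + 1, n_steps)
  f <- 1000 * tabulate(step_of, nbins = n_steps) / step_ms
  onset <- which(f > 0)[1]
  structure(data.frame(I = lv, f = f),
            f_onset = if (is.na(onset)) NA_real_ else f[onset],
            class = c("fi_curve", "data.frame"))
}

#' Peristimulus time histogram of the spiking probability
#'
#' Repeated sweeps from the rest state under OU noise, with an optional
#' common biexponential synaptic event. Two operational definitions of the
#' per-bin spiking probability are supported. \code{"basin"} (default)
#' implements the phase-space definition: the probability is the fraction
#' of integration time (per bin, across sweeps) that the trajectory spends
#' outside the basin of attraction of the rest state, so a cell in the up
#' state contributes throughout its inter-spike intervals. \code{"spike"}
#' counts the fraction of sweeps with at least one spike in the bin.
#'
#' @param params an \code{aeif_params} object
#' @param sigma OU noise SD (pA)
#' @param Am synaptic event amplitude (pA); 0 disables the stimulus
#' @param t_stim stimulus time (ms)
#' @param I_mean mean input current (pA)
#' @param sweeps number of sweeps
#' @param T_ms sweep duration (ms)
#' @param bin bin width (ms)
#' @param tau OU correlation time (ms)
#' @param dt integration step (ms)
#' @param mode \code{"basin"} or \code{"spike"}
#' @param mask precomputed \code{basin_mask} for \code{mode = "basin"}
#'   (computed at 0.5 mV x 10 pA when \code{NULL}); pass one explicitly
#'   when calling repeatedly at the same holding current
#' @param seed optional integer seed
#' @return an object of class \code{psth_result}: data.frame with
#'   \code{t} (bin left edges, ms) and \code{p}; attributes \code{t_stim},
#'   \code{sweeps}, \code{baseline} (mean probability over the second half
#'   of the pre-stimulus window)
#' @export
psth <- function(params, sigma, Am = 100, t_stim = 2000, I_mean = -150,
                 sweeps = 1000, T_ms = 6000, bin = 20, tau = 2, dt = 0.1,
                 mode = c("basin", "spike"), mask = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  n <- round(T_ms / dt)
  stim <- if (Am > 0)
    biexp_current(t_stim, Am, dt, n)$I
  else numeric(n)
  init <- rest_state(params, I_mean)
  pv <- as_param_vector(params)
  if (mode == "basin") {
    if (is.null(mask)) mask <- rest_basin(params, I_mean)
    p <- psth_occ_cpp(pv, sweeps, n, dt, I_mean, sigma, tau, stim,
                      init[1], init[2], round(bin / dt), mask$inside,
                      mask$V[1], mask$dV, mask$w[1], mask$dw)
  } else {
    counts <- psth_count_cpp(pv, sweeps, n, dt, I_mean, sigma, tau, stim,
                             init[1], init[2], round(bin / dt))
    p <- counts / sweeps
  }
  t <- (seq_along(p) - 1) * bin
  base_win <- t >= t_stim / 2 & t < t_stim
  structure(data.frame(t = t, p = p), t_stim = t_stim, sweeps = sweeps,
            bin = bin, sigma = sigma, Am = Am, mode = mode,
            baseline = mean(p[base_win]),
            class = c("psth_result", "data.frame"))
}

#' Decay time constant of a stimulus-evoked spiking state
#'
#' Fits \eqn{P(t) = P_\infty + (P_0 - P_\infty) e^{-(t-t_{peak})/\tau}} to
#' the post-peak window of a PSTH. A non-decaying histogram (the noise-free
#' latch regime) is reported as infinite.
#'
#' @param ps a \code{psth_result}
#' @param max_tau_s ceiling (s) above which the decay is flagged infinite
#' @return list with \code{tau_s} (s; \code{Inf} when non-decaying),
#'   \code{ci} (95\% interval when available), \code{P0}, \code{Pinf},
#'   \code{t_peak}
#' @export
decay_time_constant <- function(ps, max_tau_s = 50) {
  t_stim <- attr(ps, "t_stim")
  post <- ps[ps$t >= t_stim, , drop = FALSE]
  if (!nrow(post) || max(post$p) <= attr(ps, "baseline"))
    stop("post-stimulus probability does not exceed baseline")
  ipk <- which.max(post$p)
  fitd <- post[ipk:nrow(post), , drop = FALSE]
  tt <- (fitd$t - fitd$t[1]) / 1000  # s
  P0 <- fitd$p[1]
  Pinf0 <- mean(fitd$p[max(1, nrow(fitd) - 10):nrow(fitd)])
  if (P0 - Pinf0 < 0.05 || stats::coef(stats::lm(fitd$p ~ tt))[2] >= 0)
    return(list(tau_s = Inf, ci = c(NA, NA), P0 = P0, Pinf = Pinf0,
                t_peak = fitd$t[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ Pinf + (P0f - Pinf) * exp(-tt / tau),
                      data = data.frame(p = fitd$p, tt = tt),
                      start = list(Pinf = max(Pinf0, 0.01), P0f = P0,
                                   tau = 0.5),
                      lower = c(0, 0, 1e-3), upper = c(1, 1.5, 1e4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau_s = Inf, ci = c(NA, NA), P0 = P0, Pinf = Pinf0,
                t_peak = fitd$t[1]))
  cf <- stats::coef(fit)
  tau <- unname(cf["tau"])
  ci <- tryCatch(suppressMessages(stats::confint.default(fit)["tau", ]),
                 error = function(e) c(NA, NA))
  if (tau > max_tau_s)
    return(list(tau_s = Inf, ci = ci, P0 = P0, Pinf = unname(cf["Pinf"]),
                t_peak = fitd$t[1]))
  list(tau_s = tau, ci = ci, P0 = unname(cf["P0f"]),
       Pinf = unname(cf["Pinf"]), t_peak = fitd$t[1])
}

#' Input-output curve: peak transition probability vs input amplitude
#'
#' Sweeps the synaptic input amplitude, computing the peak post-stimulus
#' PSTH probability per amplitude. The response threshold is the smallest
#' amplitude whose peak exceeds the pre-stimulus baseline by more than
#' \code{threshold_excess}; the saturation amplitude is the smallest one
#' beyond which the peak changes by less than \code{saturation_frac} of the
#' curve's range.
#'
#' @param params an \code{aeif_params} object
#' @param sigma OU noise SD (pA)
#' @param amplitudes amplitude grid (pA)
#' @param sweeps sweeps per amplitude
#' @param t_stim,I_mean,T_ms,bin,tau,dt,mode as in \code{\link{psth}}
#' @param threshold_excess baseline exceedance defining the threshold
#' @param saturation_frac range fraction defining saturation
#' @param seed optional integer seed
#' @return list with \code{curve} (data.frame \code{Am}, \code{peak_p},
#'   \code{baseline}), \code{threshold}, \code{saturation}
#' @export
input_output_curve <- function(params, sigma = 30,
                               amplitudes = seq(0, 150, by = 12.5),
                               sweeps = 500, t_stim = 2000, I_mean = -150,
                               T_ms = 6000, bin = 20, tau = 2, dt = 0.1,
                               mode = c("basin", "spike"),
                               threshold_excess = 0.1,
                               saturation_frac = 0.05, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  mask <- if (mode == "basin") rest_basin(params, I_mean) else NULL
  rows <- lapply(amplitudes, function(Am) {
    ps <- psth(params, sigma = sigma, Am = Am, t_stim = t_stim,
               I_mean = I_mean, sweeps = sweeps, T_ms = T_ms, bin = bin,
               tau = tau, dt = dt, mode = mode, mask = mask)
    post <- ps$p[ps$t >= t_stim & ps$t < t_stim + 1000]
    data.frame(Am = Am, peak_p = max(post), baseline = attr(ps, "baseline"))
  })
  curve <- do.call(rbind, rows)
  excess <- curve$peak_p - curve$baseline
  thr_i <- which(excess > threshold_excess)[1]
  threshold <- if (is.na(thr_i)) NA_real_ else curve$Am[thr_i]
  rng <- diff(range(curve$peak_p))
  sat <- NA_real_
  if (rng > 0) {
    for (k in seq_len(nrow(curve))) {
      later <- seq.int(k, nrow(curve))
      if (all(abs(curve$peak_p[later] - curve$peak_p[k]) <
              saturation_frac * rng)) {
        sat <- curve$Am[k]
        break
      }
    }
  }
  list(curve = curve, threshold = threshold, saturation = sat)
}

#' Membrane potential histograms by firing state
#'
#' Labels fixed windows of a trace as spiking or silent (>= 1 spike in the
#' window) and returns normalized voltage histograms per state. Spike-peak
#' samples (V above the detection threshold) are dropped so the histograms
#' describe the subthreshold envelope.
#'
#' @param trace a \code{voltage_trace}
#' @param spikes a \code{spike_train}
#' @param window state-labeling window (ms)
#' @param breaks histogram breaks (mV)
#' @param spike_cut samples above this voltage are excluded (mV)
#' @return list of two \code{density}-style data.frames (\code{spiking},
#'   \code{silent}) with columns \code{V} (bin mids) and \code{density},
#'   each integrating to 1 when non-empty
#' @export
vm_histogram <- function(trace, spikes, window = 200,
                         breaks = seq(-90, 10, by = 1), spike_cut = -20) {
  n_win <- max(1, floor(length(trace$V) * trace$dt / window))
  win_of_sp <- pmin(floor(spikes / window) + 1, n_win)
  firing <- tabulate(win_of_sp, nbins = n_win) > 0
  samp_win <- pmin(floor((seq_along(trace$V) - 1) * trace$dt / window) + 1,
                   n_win)
  keep <- trace$V <= spike_cut
  hist_of <- function(sel) {
    v <- trace$V[sel & keep]
    if (!length(v)) return(data.frame(V = numeric(0), density = numeric(0)))
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    data.frame(V = h$mids, density = h$density)
  }
  list(spiking = hist_of(firing[samp_win]),
       silent = hist_of(!firing[samp_win]))
}
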