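#' Sample exclusion windows around spikes
#'
#' Marks samples to drop from dynamic I-V analyses: a short pre-peak guard
#' (the unresolved spike peak contaminates the numerical derivative), the
#' after-hyperpolarization and initial repolarization up to \code{post_ms}
#' after each spike peak.
#'
#' @param trace a \code{voltage_trace}
#' @param spikes a \code{spike_train} (detected if \code{NULL})
#' @param post_ms exclusion window after each spike peak (ms)
#' @param pre_ms guard before each peak (ms)
#' @return logical vector, \code{TRUE} = excluded
#' @export
spike_exclusion <- function(trace, spikes = NULL, post_ms = 10,
                            pre_ms = 0.2) {
  if (is.null(spikes)) spikes <- detect_spikes(trace)
  n <- length(trace$V)
  excl <- logical(n)
  jx <- attr(trace, "junctions")
  if (!is.null(jx)) {
    # settle window after each concatenation junction
    for (j in jx) {
      lo <- max(1, j - round(10 / trace$dt))
      hi <- min(n, j + round(300 / trace$dt))
      excl[lo:hi] <- TRUE
    }
  }
  if (!length(spikes)) return(excl)
  i_pk <- round(as.numeric(spikes) / trace$dt)
  lo <- pmax(1, i_pk - round(pre_ms / trace$dt))
  hi <- pmin(n, i_pk + round(post_ms / trace$dt))
  for (k in seq_along(i_pk)) excl[lo[k]:hi[k]] <- TRUE
  excl
}

#' Concatenate recordings from one cell
#'
#' Joins protocol epochs (e.g. noise injections at different holding
#' currents) into a single trace for pooled fitting; junction positions
#' are annotated so downstream exclusions can drop the settle windows.
#'
#' @param traces list of \code{voltage_trace} objects with equal \code{dt}
#' @return a \code{voltage_trace} with attribute \code{junctions}
#' @export
concat_traces <- function(traces) {
  stopifnot(length(traces) >= 1)
  dts <- vapply(traces, `[[`, numeric(1), "dt")
  if (any(abs(dts - dts[1]) > 1e-12)) stop("traces must share dt")
  lens <- vapply(traces, function(x) length(x$V), integer(1))
  out <- voltage_trace(dts[1], unlist(lapply(traces, `[[`, "V")),
                       unlist(lapply(traces, `[[`, "I_in")),
                       source = traces[[1]]$source)
  attr(out, "junctions") <- cumsum(lens)[-length(lens)] + 1L
  out
}

#' Boxcar pre-filter for recorded traces
#'
#' Zero-phase moving-average filter applied to voltage and current before
#' derivative-based analyses. Because the subthreshold dynamics are linear,
#' convolving V, w and I with the same kernel preserves the model equations
#' exactly; the filter only suppresses measurement noise (the recordings it
#' emulates were hardware-filtered at 3-10 kHz before digitization).
#'
#' @param trace a \code{voltage_trace}
#' @param smooth_ms kernel width (ms); 0 disables filtering
#' @return a filtered \code{voltage_trace} (edges trimmed)
#' @export
smooth_trace <- function(trace, smooth_ms = 0.6) {
  if (smooth_ms <= 0) return(trace)
  n <- max(1, round(smooth_ms / trace$dt))
  if (n %% 2 == 0) n <- n + 1
  if (n < 3) return(trace)
  k <- rep(1 / n, n)
  V <- as.numeric(stats::filter(trace$V, k, sides = 2))
  I <- as.numeric(stats::filter(trace$I_in, k, sides = 2))
  # keep sample alignment: edges keep the raw values
  V[is.na(V)] <- trace$V[is.na(V)]
  I[is.na(I)] <- trace$I_in[is.na(I)]
  out <- voltage_trace(trace$dt, V, I, source = trace$source)
  attr(out, "spikes") <- attr(trace, "spikes")
  attr(out, "junctions") <- attr(trace, "junctions")
  out
}

# central-difference derivative at the native sampling rate (mV/ms);
# endpoints get one-sided differences
dvdt_central <- function(V, dt) {
  n <- length(V)
  d <- numeric(n)
  d[2:(n - 1)] <- (V[3:n] - V[1:(n - 2)]) / (2 * dt)
  d[1] <- (V[2] - V[1]) / dt
  d[n] <- (V[n] - V[n - 1]) / dt
  d
}

# per-voltage-bin second moments of (I_in, dV/dt) for the capacitance
# objective and the I-V curve
bin_moments <- function(V, I, D, bin_w, v_range, min_count) {
  br <- seq(v_range[1], v_range[2], by = bin_w)
  nb <- length(br) - 1
  g <- findInterval(V, br, rightmost.closed = TRUE)
  ok <- g >= 1 & g <= nb
  g <- g[ok]; I <- I[ok]; D <- D[ok]
  cnt <- tabulate(g, nbins = nb)
  keep <- which(cnt >= min_count)
  if (!length(keep)) stop("no voltage bin reaches the minimum count")
  sums <- function(x) {
    s <- numeric(nb)
    r <- rowsum(x, g, reorder = FALSE)
    s[as.integer(rownames(r))] <- r[, 1]
    s
  }
  n <- cnt[keep]
  mI <- sums(I)[keep] / n
  mD <- sums(D)[keep] / n
  vI <- sums(I^2)[keep] / n - mI^2
  vD <- sums(D^2)[keep] / n - mD^2
  cID <- sums(I * D)[keep] / n - mI * mD
  list(mid = (br[-1] - bin_w / 2)[keep], n = n, mean_I = mI, mean_D = mD,
       var_I = vI, var_D = vD, cov_ID = cID)
}

#' Estimate the membrane capacitance from a noise-driven trace
#'
#' The capacitance estimate \eqn{C_e} minimizes the count-weighted sum over
#' voltage bins of \eqn{\mathrm{var}[I_{in}/C_e - dV/dt]}: this variance is
#' minimal exactly when \eqn{C_e} equals the true capacitance, since only
#' then does the capacitive current cancel. Searched on a 1 pF grid over the
#' bracket and refined by golden-section.
#'
#' @param trace a \code{voltage_trace} with several seconds of noise-driven
#'   data
#' @param bin_w voltage bin width (mV)
#' @param exclusion logical exclusion vector (from
#'   \code{\link{spike_exclusion}}); computed if \code{NULL}
#' @param bracket capacitance search bracket (pF)
#' @param v_range voltage range binned (mV)
#' @param min_count minimum samples per bin
#' @param deriv optional precomputed \code{dV/dt} (mV/ms)
#' @return \eqn{C_e} (pF) with attributes \code{bracket}, \code{tol},
#'   \code{objective} (grid values) and \code{unimodal}
#' @export
estimate_capacitance <- function(trace, bin_w = 1, exclusion = NULL,
                                 bracket = c(50, 600),
                                 v_range = c(-90, -20), min_count = 50,
                                 deriv = NULL) {
  if (is.null(exclusion)) exclusion <- spike_exclusion(trace)
  if (length(trace$V) * trace$dt < 5000)
    stop("need at least 5 s of noise-driven data")
  keep <- !exclusion
  D <- if (is.null(deriv)) dvdt_central(trace$V, trace$dt) else deriv
  bm <- bin_moments(trace$V[keep], trace$I_in[keep], D[keep], bin_w,
                    v_range, min_count)
  obj <- function(Ce)
    sum(bm$n * (bm$var_I / Ce^2 - 2 * bm$cov_ID / Ce + bm$var_D))
  grid <- seq(bracket[1], bracket[2], by = 1)
  ov <- vapply(grid, obj, numeric(1))
  imin <- which.min(ov)
  # unimodality over the bracket: the sign of successive differences flips once
  flips <- sum(diff(sign(diff(ov))) != 0)
  unimodal <- flips <= 1
  if (!unimodal)
    warning("capacitance objective not unimodal over the bracket; ",
            "using the global grid minimum")
  lo <- grid[max(1, imin - 2)]; hi <- grid[min(length(grid), imin + 2)]
  Ce <- stats::optimize(obj, c(lo, hi), tol = 1e-3)$minimum
  structure(Ce, bracket = bracket, tol = 1e-3, unimodal = unimodal,
            objective = data.frame(Ce = grid, value = ov))
}

#' Dynamic I-V curve
#'
#' The transmembrane ionic current \eqn{I_m = I_{in} - C_e \, dV/dt}
#' computed per sample (central differences), spike windows excluded, and
#' averaged within voltage bins: \eqn{I_{dyn}(V) = \langle I_m \rangle_V}.
#'
#' @param trace a \code{voltage_trace}
#' @param Ce capacitance estimate (pF)
#' @param bin_w voltage bin width (mV)
#' @param exclusion logical exclusion vector; computed if \code{NULL}
#' @param v_range voltage range (mV)
#' @param min_count bins with fewer samples are omitted (never interpolated)
#' @param deriv optional precomputed \code{dV/dt} (mV/ms)
#' @return an object of class \code{dynamic_iv_curve}: data.frame with
#'   columns \code{V} (bin centers), \code{I_dyn}, \code{sd}, \code{n};
#'   attribute \code{Ce}
#' @export
dynamic_iv_curve <- function(trace, Ce, bin_w = 1, exclusion = NULL,
                             v_range = c(-90, -20), min_count = 50,
                             deriv = NULL) {
  if (Ce <= 0) stop("Ce must be > 0")
  if (is.null(exclusion)) exclusion <- spike_exclusion(trace)
  keep <- !exclusion
  D <- if (is.null(deriv)) dvdt_central(trace$V, trace$dt) else deriv
  Im <- trace$I_in[keep] - as.numeric(Ce) * D[keep]
  br <- seq(v_range[1], v_range[2], by = bin_w)
  nb <- length(br) - 1
  g <- findInterval(trace$V[keep], br, rightmost.closed = TRUE)
  ok <- g >= 1 & g <= nb
  g <- g[ok]; Imk <- Im[ok]
  cnt <- tabulate(g, nbins = nb)
  sel <- which(cnt >= min_count)
  sums <- function(x) {
    z <- numeric(nb)
    r <- rowsum(x, g, reorder = FALSE)
    z[as.integer(rownames(r))] <- r[, 1]
    z
  }
  mu <- sums(Imk)[sel] / cnt[sel]
  m2 <- sums(Imk^2)[sel] / cnt[sel]
  sdv <- sqrt(pmax(0, m2 - mu^2) * cnt[sel] / pmax(1, cnt[sel] - 1))
  out <- data.frame(V = (br[-1] - bin_w / 2)[sel],
                    I_dyn = mu, sd = sdv, n = cnt[sel])
  structure(out, Ce = as.numeric(Ce),
            class = c("dynamic_iv_curve", "data.frame"))
}

#' Fit the EIF model function to a dynamic I-V curve
#'
#' Weighted nonlinear least squares of \eqn{F(V) = -I_{dyn}(V)/C_e} against
#' \deqn{F(V) = \frac{1}{\tau_m}\left(E_L - V +
#'   \Delta_T e^{(V - V_T)/\Delta_T}\right)}
#' (weights = per-bin counts). Note that for a cell with subthreshold
#' adaptation the effective slope of the linear part is \eqn{(g_L + a)/C},
#' so \code{tau_m_dyn} is the fast effective time constant
#' \eqn{C/(g_L + a)}, not \eqn{C/g_L}.
#'
#' @param curve a \code{dynamic_iv_curve}
#' @param Ce capacitance (pF); defaults to the curve's attribute
#' @return an object of class \code{eif_fit}: list with \code{tau_m_dyn},
#'   \code{EL}, \code{VT}, \code{DeltaT}, \code{Ce}, \code{residual_norm}
#' @export
fit_eif <- function(curve, Ce = attr(curve, "Ce")) {
  FV <- -curve$I_dyn / Ce
  V <- curve$V
  w <- curve$n
  # starts from the linear lower part and the departure point
  lower <- V <= stats::quantile(V, 0.5)
  lf <- stats::lm(FV ~ V, weights = w, subset = lower)
  slope <- stats::coef(lf)[2]
  if (slope >= 0) stop("dynamic I-V curve lacks a decreasing linear part")
  tau0 <- -1 / slope
  EL0 <- -stats::coef(lf)[1] / slope
  resid_all <- FV - (stats::coef(lf)[1] + slope * V)
  dep <- which(resid_all > 3 * stats::sd(resid_all[lower]) & !lower)
  VT0 <- if (length(dep)) V[dep[1]] else stats::quantile(V, 0.8)
  fit <- minpack.lm::nlsLM(
    FV ~ (EL - V + DeltaT * exp((V - VT) / DeltaT)) / tau_m,
    data = data.frame(FV = FV, V = V),
    start = list(tau_m = unname(tau0), EL = unname(EL0),
                 VT = unname(VT0), DeltaT = 1),
    weights = w,
    lower = c(0.1, -90, -90, 0.05), upper = c(200, -20, -20, 10),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  if (cf[["DeltaT"]] <= 0 || cf[["tau_m"]] <= 0)
    stop("EIF fit did not converge to a valid parameter set")
  structure(list(tau_m_dyn = cf[["tau_m"]], EL = cf[["EL"]],
                 VT = cf[["VT"]], DeltaT = cf[["DeltaT"]], Ce = Ce,
                 residual_norm = sqrt(sum(w * stats::resid(fit)^2) / sum(w)),
                 fit = fit),
            class = "eif_fit")
}

#' Subthreshold adaptation conductance from the I-V slope
#'
#' The linear part of the dynamic I-V curve has slope \eqn{g_L + a} (the
#' quasi-static adaptation current adds to the leak); \eqn{a} is the fitted
#' slope minus the leak conductance.
#'
#' @param curve a \code{dynamic_iv_curve}
#' @param gL leak conductance to subtract (nS); pass 0 to obtain the raw
#'   slope
#' @param window voltage window \code{c(lo, hi)} for the linear fit (mV);
#'   it must stay clear of the exponential region (default upper edge
#'   \eqn{V_T - 3\Delta_T} is applied by \code{\link{fit_full}})
#' @return \eqn{a} (nS) with attributes \code{slope} and \code{se}
#' @export
estimate_subthreshold_a <- function(curve, gL, window) {
  sel <- curve$V >= window[1] & curve$V <= window[2]
  if (sum(sel) < 5) stop("fewer than 5 bins in the linear window")
  lf <- stats::lm(I_dyn ~ V, data = curve[sel, ], weights = curve$n[sel])
  slope <- stats::coef(lf)[[2]]
  se <- summary(lf)$coefficients["V", "Std. Error"]
  structure(slope - gL, slope = slope, se = se)
}

#' Spike-triggered adaptation fit
#'
#' Computes the per-sample spike-triggered adaptation estimate
#' \eqn{w_{spike} = I_{in} - C_e \, dV/dt - (g_L + a)(V - E_L)}, bins it by
#' time since the most recent spike, averages, and fits a single
#' exponential \eqn{b \, e^{-t/\tau_w}}; the reset increment is the
#' extrapolated value at the spike time.
#'
#' @param trace a \code{voltage_trace}
#' @param Ce capacitance (pF)
#' @param gL leak conductance (nS)
#' @param a subthreshold adaptation conductance (nS)
#' @param EL leak reversal (mV)
#' @param spikes a \code{spike_train}; detected if \code{NULL}
#' @param window time-after-spike fit window (ms); the lower edge avoids
#'   the reset transient
#' @param t_bin time bin width (ms)
#' @param vt_cut samples with V above this are dropped (exponential region)
#' @param min_count minimum samples per time bin
#' @param deriv optional precomputed \code{dV/dt} (mV/ms)
#' @return an object of class \code{adaptation_fit}: list with \code{b}
#'   (the extrapolated \eqn{w_{spike}(0)}), \code{tau_w}, \code{offset},
#'   the binned decay curve and residuals
#' @export
fit_spike_adaptation <- function(trace, Ce, gL, a, EL, spikes = NULL,
                                 window = c(5, 100), t_bin = 2,
                                 vt_cut = -45, min_count = 50,
                                 deriv = NULL) {
  if (is.null(spikes)) spikes <- detect_spikes(trace)
  if (length(spikes) < 100)
    stop("need at least 100 spikes for the adaptation fit")
  slope <- gL + a
  D <- if (is.null(deriv)) dvdt_central(trace$V, trace$dt) else deriv
  wsp <- trace$I_in - Ce * D - slope * (trace$V - EL)
  tsamp <- (seq_along(trace$V)) * trace$dt
  # time since the most recent spike (NA before the first spike)
  idx <- findInterval(tsamp, as.numeric(spikes))
  tsince <- tsamp - c(NA, as.numeric(spikes))[idx + 1]
  guard <- spike_exclusion(trace, spikes, post_ms = 1, pre_ms = 0.2)
  ok <- !is.na(tsince) & tsince >= window[1] & tsince <= window[2] &
    trace$V <= vt_cut & !guard
  if (max(tsince[ok]) < 3 * 10)
    warning("post-spike coverage is short relative to the adaptation decay")
  g <- floor((tsince[ok] - window[1]) / t_bin) + 1
  nb <- max(g)
  cnt <- tabulate(g, nbins = nb)
  sel <- which(cnt >= min_count)
  mu <- tapply(wsp[ok], g, mean)[as.character(sel)]
  tmid <- window[1] + (sel - 0.5) * t_bin
  dfit <- data.frame(t = tmid, w = as.numeric(mu), n = cnt[sel])
  pos <- dfit$w > 0
  tau0 <- if (sum(pos) > 3) {
    lc <- stats::coef(stats::lm(log(w) ~ t, data = dfit[pos, ]))
    max(2, -1 / lc[2])
  } else 15
  fit <- minpack.lm::nlsLM(w ~ A * exp(-t / tau_w) + c0, data = dfit,
                           start = list(A = max(dfit$w) *
                                          exp(dfit$t[1] / tau0),
                                        tau_w = tau0, c0 = 0),
                           weights = dfit$n,
                           lower = c(1, 1, -2000), upper = c(8000, 500, 2000),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(b = cf[["A"]] + cf[["c0"]], tau_w = cf[["tau_w"]],
                 amplitude = cf[["A"]], offset = cf[["c0"]], decay = dfit,
                 window = window,
                 residuals = stats::resid(fit)),
            class = "adaptation_fit")
}

#' Subthreshold adaptation dynamics by windowed ODE regression
#'
#' Away from threshold the residual current \eqn{r = I_{in} - C_e\,dV/dt}
#' equals \eqn{g_L (V - E_L) + w}, and eliminating \eqn{w} through its
#' linear dynamics gives the exact integral relation over any window
#' \eqn{[t, t+T]} of spike-free data:
#' \deqn{r(t{+}T) - r(t) = \frac{g_L + a}{\tau_w}\int V\,dt
#'   - \frac{1}{\tau_w}\int r\,dt + g_L\,\Delta V + c_0}
#' with the constant absorbing the \eqn{E_L} terms. Ordinary least squares
#' over non-overlapping windows therefore recovers \eqn{g_L}, \eqn{a},
#' \eqn{\tau_w} and \eqn{E_L} jointly, honoring the adaptation dynamics
#' that the quasi-static slope reading of the I-V curve ignores (the
#' adaptation current cannot follow the 3/10 ms input fluctuations, so the
#' apparent I-V slope understates \eqn{g_L + a}).
#'
#' @param trace a (filtered) \code{voltage_trace}
#' @param Ce capacitance (pF)
#' @param vt_cut upper voltage bound of the linear regime (mV)
#' @param exclusion logical exclusion vector (spike windows)
#' @param window_ms regression window length (ms)
#' @param v_floor lower voltage bound (mV)
#' @param deriv optional precomputed \code{dV/dt} (mV/ms)
#' @return list with \code{gL}, \code{a}, \code{tau_w}, \code{EL} (nS, nS,
#'   ms, mV), \code{rss}, \code{n_windows}
#' @export
fit_adaptation_dynamics <- function(trace, Ce, vt_cut, exclusion,
                                    window_ms = 5, v_floor = -85,
                                    deriv = NULL) {
  st <- adaptation_window_stats(trace, vt_cut, exclusion, window_ms,
                                v_floor, deriv)
  solve_adaptation_windows(st, Ce)
}

# per-window sufficient statistics; the capacitance enters the regression
# linearly, so these are computed once and reused across the Ce scan
adaptation_window_stats <- function(trace, vt_cut, exclusion,
                                    window_ms = 5, v_floor = -85,
                                    deriv = NULL) {
  dt <- trace$dt
  V <- trace$V; I <- trace$I_in
  D <- if (is.null(deriv)) dvdt_central(V, dt) else deriv
  valid <- !exclusion & V < vt_cut & V > v_floor
  Tn <- round(window_ms / dt)
  starts <- seq(1, length(V) - Tn - 1, by = Tn)
  cs <- cumsum(valid)
  ok <- (cs[starts + Tn] - cs[pmax(starts - 1, 1)]) >= Tn
  s <- starts[ok]; e <- s + Tn
  if (length(s) < 50) stop("too few spike-free windows for the regression")
  cumV <- cumsum(V) * dt
  cumI <- cumsum(I) * dt
  list(dI = I[e] - I[s], dD = D[e] - D[s],
       intV = cumV[e] - cumV[s], intI = cumI[e] - cumI[s],
       dV = V[e] - V[s], n_windows = length(s), window_ms = window_ms)
}

solve_adaptation_windows <- function(st, Ce) {
  y <- st$dI - Ce * st$dD
  intR <- st$intI - Ce * st$dV
  intV <- st$intV
  dV <- st$dV
  fit <- stats::lm(y ~ intV + intR + dV)
  cf <- stats::coef(fit)
  tau_w <- -1 / cf[["intR"]]
  gL <- cf[["dV"]]
  a <- cf[["intV"]] * tau_w - gL
  EL <- -cf[["(Intercept)"]] * tau_w / ((gL + a) * st$window_ms)
  list(gL = gL, a = a, tau_w = tau_w, EL = EL,
       rss = sum(stats::resid(fit)^2), n_windows = st$n_windows)
}

#' Measurement-noise SD of a recording
#'
#' Estimated from lag-1 sample differences outside spike windows: at 50 kHz
#' the subthreshold signal changes by ~0.01 mV per sample, so the
#' difference variance is dominated by (twice) the additive noise variance.
#'
#' @param trace a raw \code{voltage_trace}
#' @param exclusion logical exclusion vector
#' @return noise SD (mV)
#' @export
estimate_noise_sd <- function(trace, exclusion = NULL) {
  if (is.null(exclusion)) exclusion <- spike_exclusion(trace)
  d <- diff(trace$V)
  ok <- !exclusion[-1] & !exclusion[-length(exclusion)]
  sqrt(max(0, stats::var(d[ok]) / 2))
}

#' Capacitance refinement by regression residual
#'
#' Scans candidate capacitances and returns the one minimizing the
#' noise-corrected residual sum of squares of
#' \code{\link{fit_adaptation_dynamics}}: a wrong capacitance leaves
#' capacitive current in the residual that the linear (V, w) model cannot
#' absorb. This removes the upward bias of the variance-minimization
#' estimate caused by the adaptation current's correlation with the
#' injected current. Because the regression response carries
#' derivative-noise variance proportional to \eqn{C_e^2}, the raw residual
#' is corrected by subtracting the analytic noise contribution
#' \eqn{2 N C_e^2 \sigma_n^2 / (n_s \Delta t)^2} (boxcar width \eqn{n_s});
#' without this the scan is biased toward small capacitances.
#'
#' @param trace a (filtered) \code{voltage_trace}
#' @param Ce0 initial capacitance estimate (pF)
#' @param vt_cut,exclusion as in \code{\link{fit_adaptation_dynamics}}
#' @param noise_sd measurement noise SD (mV) of the raw recording
#' @param smooth_n boxcar width (samples) used to filter the trace
#' @param span relative search span around \code{Ce0}
#' @param step grid step (pF)
#' @param stats optional precomputed window statistics
#' @return refined capacitance (pF) with attribute \code{rss_profile}
#' @export
refine_capacitance <- function(trace, Ce0, vt_cut, exclusion,
                               noise_sd = 0, smooth_n = 1,
                               span = c(0.5, 1.4), step = 5,
                               stats = NULL) {
  dvar <- if (smooth_n >= 3)
    noise_sd^2 / (smooth_n * trace$dt)^2
  else noise_sd^2 / (2 * trace$dt^2)
  st <- if (is.null(stats))
    adaptation_window_stats(trace, vt_cut, exclusion) else stats
  nwin <- st$n_windows
  f <- function(Cc)
    solve_adaptation_windows(st, Cc)$rss - 2 * nwin * dvar * Cc^2
  Cs <- seq(span[1] * Ce0, span[2] * Ce0, by = step)
  rss <- vapply(Cs, f, numeric(1))
  i <- which.min(rss)
  lo <- Cs[max(1, i - 1)]; hi <- Cs[min(length(Cs), i + 1)]
  Ce <- stats::optimize(f, c(lo, hi), tol = 0.1)$minimum
  structure(Ce, rss_profile = data.frame(Ce = Cs, rss = rss))
}

#' Membrane time constant from a brief current pulse
#'
#' Fits the post-pulse voltage decay with a biexponential
#' \eqn{V_\infty + A_1 e^{-t/\tau_c} + A_2 e^{-t/\tau_m}} (fast
#' \eqn{\tau_c}, slow \eqn{\tau_m}). When the relaxation is an
#' underdamped spiral (a single-compartment cell with strong subthreshold
#' adaptation), a damped-cosine model
#' \eqn{V_\infty + A e^{-t/\tau}\cos(\omega t + \phi)} is fitted instead
#' and both reported time constants equal \eqn{\tau}. The model with the
#' lower weighted residual is kept.
#'
#' @param trace_pulse a \code{voltage_trace} containing a brief pulse and
#'   at least 50 ms of post-pulse decay
#' @param offset_ms fit start after the pulse end (ms)
#' @param fit_ms fit window length (ms)
#' @return an object of class \code{pulse_fit}: list with \code{tau_m}
#'   (slow, ms), \code{tau_c} (fast, ms), \code{amplitudes}, \code{model}
#'   (\code{"biexp"} or \code{"damped_oscillation"}), \code{rate_sum}
#'   (\eqn{1/\tau_m + 1/\tau_c}, equal to \eqn{2/\tau} for the oscillatory
#'   model; this is minus the trace of the subthreshold Jacobian), and
#'   \code{degenerate} (within 10 percent)
#' @export
fit_membrane_tau_pulse <- function(trace_pulse, offset_ms = 1,
                                   fit_ms = 150) {
  i_pk <- which.max(trace_pulse$I_in)
  i_end <- i_pk
  while (i_end < length(trace_pulse$I_in) &&
         trace_pulse$I_in[i_end + 1] == trace_pulse$I_in[i_pk]) i_end <- i_end + 1
  i0 <- i_end + round(offset_ms / trace_pulse$dt)
  i1 <- min(length(trace_pulse$V), i0 + round(fit_ms / trace_pulse$dt))
  if ((i1 - i0) * trace_pulse$dt < 50)
    stop("need at least 50 ms of post-pulse decay")
  tt <- (seq.int(i0, i1) - i0) * trace_pulse$dt
  vv <- trace_pulse$V[i0:i1]
  Vinf0 <- mean(vv[tt > 0.8 * max(tt)])
  A0 <- vv[1] - Vinf0
  bi <- tryCatch(minpack.lm::nlsLM(
    v ~ Vinf + A1 * exp(-t / t1) + A2 * exp(-t / t2),
    data = data.frame(v = vv, t = tt),
    start = list(Vinf = Vinf0, A1 = A0 / 2, A2 = A0 / 2, t1 = 2, t2 = 20),
    lower = c(-90, -50, -50, 0.05, 0.5), upper = c(0, 50, 50, 50, 500),
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  osc <- tryCatch(minpack.lm::nlsLM(
    v ~ Vinf + A * exp(-t / tau) * cos(om * t + ph),
    data = data.frame(v = vv, t = tt),
    start = list(Vinf = Vinf0, A = A0, tau = 20, om = 0.1, ph = 0),
    lower = c(-90, -50, 0.5, 1e-4, -pi), upper = c(0, 50, 500, 2, pi),
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  rss <- function(f) if (is.null(f)) Inf else sum(stats::resid(f)^2)
  if (is.infinite(rss(bi)) && is.infinite(rss(osc)))
    stop("pulse decay fit failed to converge")
  if (rss(osc) < rss(bi)) {
    cf <- stats::coef(osc)
    tau <- cf[["tau"]]
    out <- list(tau_m = tau, tau_c = tau,
                amplitudes = c(A = cf[["A"]]), model = "damped_oscillation",
                rate_sum = 2 / tau, omega = cf[["om"]],
                degenerate = FALSE, fit = osc)
  } else {
    cf <- stats::coef(bi)
    ts <- sort(c(cf[["t1"]], cf[["t2"]]))
    amps <- c(cf[["A1"]], cf[["A2"]])[order(c(cf[["t1"]], cf[["t2"]]))]
    degen <- diff(ts) / ts[2] < 0.1
    if (degen)
      warning("pulse fit degenerate: the two time constants are within 10%")
    out <- list(tau_m = ts[2], tau_c = ts[1],
                amplitudes = c(fast = amps[1], slow = amps[2]),
                model = "biexp", rate_sum = 1 / ts[1] + 1 / ts[2],
                omega = 0, degenerate = degen, fit = bi)
  }
  class(out) <- "pulse_fit"
  out
}

# EIF threshold refinement: with gL fixed, fit the I-V curve as
# linear part + exponential spike-initiation term, resolving the
# amplitude/threshold degeneracy of the free four-parameter form.
fit_eif_constrained <- function(curve, gL, start_VT, start_DT) {
  d <- data.frame(I = curve$I_dyn, V = curve$V, n = curve$n)
  fit <- minpack.lm::nlsLM(
    I ~ c0 + s * V - gL * DeltaT * exp((V - VT) / DeltaT),
    data = d,
    start = list(c0 = 0, s = 20, VT = start_VT,
                 DeltaT = max(start_DT, 0.3)),
    weights = d$n,
    lower = c(-1e4, 0, -80, 0.1), upper = c(1e4, 500, -30, 10),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  list(VT = cf[["VT"]], DeltaT = cf[["DeltaT"]], slope = cf[["s"]],
       fit = fit)
}

#' Full aEIF parameter estimation from paired protocol traces
#'
#' Runs the modified dynamic I-V pipeline end to end:
#' \enumerate{
#'   \item spike detection and exclusion windows on the raw recording;
#'   \item boxcar pre-filtering (see \code{\link{smooth_trace}});
#'   \item capacitance by per-bin variance minimization
#'     (\code{\link{estimate_capacitance}}), then refined against the
#'     subthreshold dynamics residual (\code{\link{refine_capacitance}});
#'   \item dynamic I-V curve and EIF function fit for the threshold
#'     parameters \eqn{V_T, \Delta_T} (exponential amplitude constrained
#'     by the fitted leak, resolving the amplitude/threshold degeneracy);
#'   \item leak, subthreshold adaptation, adaptation time constant and
#'     \eqn{E_L} from the windowed adaptation-dynamics regression
#'     (\code{\link{fit_adaptation_dynamics}});
#'   \item spike-triggered increment \eqn{b} from the exponential decay of
#'     \eqn{w_{spike}} (\code{\link{fit_spike_adaptation}}).
#' }
#' The regression recovers \eqn{g_L} and \eqn{a} separately because it
#' honors the adaptation dynamics; the quasi-static I-V slope alone cannot
#' (the adaptation current does not track the 3/10 ms input fluctuations).
#' When a pulse trace is supplied its biexponential (or damped-cosine) fit
#' is reported, and can drive the leak split instead: \code{"eigen"} uses
#' the trace identity \eqn{g_L = C_e(\sum_i 1/\tau_i - 1/\tau_w)} of the
#' subthreshold linearization, \code{"tau_m"} the conventional
#' \eqn{g_L = C_e/\tau_m}.
#'
#' @param noise_trace dual-OU noise-driven \code{voltage_trace}
#' @param pulse_trace pulse-response \code{voltage_trace} or \code{NULL}
#' @param gL_method \code{"dynamics"} (default), \code{"eigen"} or
#'   \code{"tau_m"}
#' @param smooth_ms pre-filter width (ms)
#' @param bin_w voltage bin width (mV)
#' @param min_count minimum samples per voltage bin
#' @return list with \code{params} (an \code{aeif_params}; the
#'   experimentally unconstrained reset is set to the package convention
#'   Vr = -60 mV) and \code{report} (per-stage estimates, uncertainties
#'   and exclusion statistics)
#' @export
fit_full <- function(noise_trace, pulse_trace = NULL,
                     gL_method = c("dynamics", "eigen", "tau_m"),
                     smooth_ms = 0.6, bin_w = 1, min_count = 50) {
  gL_method <- match.arg(gL_method)
  spikes <- detect_spikes(noise_trace)
  excl <- spike_exclusion(noise_trace, spikes,
                          pre_ms = smooth_ms / 2 + 0.5)
  noise_sd <- estimate_noise_sd(noise_trace, excl)
  ftr <- smooth_trace(noise_trace, smooth_ms)
  smooth_n <- max(1, round(smooth_ms / noise_trace$dt))
  if (smooth_n %% 2 == 0) smooth_n <- smooth_n + 1
  D_f <- dvdt_central(ftr$V, ftr$dt)
  Ce0 <- estimate_capacitance(ftr, bin_w = bin_w, exclusion = excl,
                              min_count = min_count, deriv = D_f)
  curve0 <- dynamic_iv_curve(ftr, Ce0, bin_w = bin_w, exclusion = excl,
                             min_count = min_count, deriv = D_f)
  # the free EIF fit can fail on a curve distorted by a biased Ce0; only a
  # rough threshold location is needed at this stage
  eif0 <- tryCatch(fit_eif(curve0), error = function(e) NULL)
  vt_cut <- if (!is.null(eif0)) eif0$VT - 3 * eif0$DeltaT
            else max(curve0$V) - 5
  wstats <- adaptation_window_stats(ftr, vt_cut, excl, deriv = D_f)
  Ce <- refine_capacitance(ftr, as.numeric(Ce0), vt_cut, excl,
                           noise_sd = noise_sd, smooth_n = smooth_n,
                           stats = wstats)
  dyn <- solve_adaptation_windows(wstats, as.numeric(Ce))
  if (dyn$tau_w <= 0 || dyn$gL <= 0)
    stop("adaptation-dynamics regression failed (non-physical estimates)")
  curve <- dynamic_iv_curve(ftr, Ce, bin_w = bin_w, exclusion = excl,
                            min_count = min_count, deriv = D_f)
  eifc <- fit_eif_constrained(curve, dyn$gL,
                              if (!is.null(eif0)) eif0$VT
                              else max(curve$V) - 3,
                              if (!is.null(eif0)) eif0$DeltaT else 1)
  pulse <- NULL
  gL <- dyn$gL
  if (!is.null(pulse_trace)) {
    pulse <- fit_membrane_tau_pulse(pulse_trace)
    if (gL_method == "eigen")
      gL <- as.numeric(Ce) * (pulse$rate_sum - 1 / dyn$tau_w)
    else if (gL_method == "tau_m")
      gL <- as.numeric(Ce) / pulse$tau_m
  } else if (gL_method != "dynamics") {
    warning("no pulse trace: gL taken from the dynamics regression")
  }
  if (gL <= 0) {
    warning("leak estimate non-positive; keeping the dynamics-regression ",
            "value")
    gL <- dyn$gL
  }
  a <- max(0, dyn$a + dyn$gL - gL)
  adap <- fit_spike_adaptation(ftr, as.numeric(Ce), gL = gL, a = a,
                               EL = dyn$EL, spikes = spikes,
                               vt_cut = vt_cut, deriv = D_f)
  # Vr is unconstrained by these protocols; the package convention (-60 mV,
  # clearing the rest-state basin in the bistable regime) is applied
  params <- aeif_params(C = as.numeric(Ce), gL = gL, EL = dyn$EL,
                        VT = eifc$VT, DeltaT = eifc$DeltaT, a = a,
                        b = adap$b, tau_w = dyn$tau_w, Vr = -60)
  list(params = params,
       report = list(Ce0 = as.numeric(Ce0), Ce = as.numeric(Ce),
                     eif_free = eif0, eif = eifc, dynamics = dyn,
                     adaptation = adap, pulse = pulse,
                     gL_method = gL_method, n_spikes = length(spikes),
                     noise_sd = noise_sd, excluded_frac = mean(excl)))
}

#' Simulation-based bias correction of a dynamic I-V fit
#'
#' One-step indirect-inference correction: the fitted model is simulated
#' through the very same injected-current waveforms (with matched
#' measurement noise), re-fitted with the identical pipeline, and the
#' leak/adaptation parameters (\eqn{g_L}, \eqn{a}, \eqn{b}, \eqn{\tau_w})
#' corrected multiplicatively by the bias the pipeline exhibits on its own
#' estimate. This removes the systematic biases of the closed-form
#' estimators (e.g. the spike-history superposition and the
#' reset-potential term in the \eqn{w_{spike}} extrapolation for \eqn{b})
#' without consulting the ground truth; the near-unbiased \eqn{C},
#' \eqn{E_L}, \eqn{V_T}, \eqn{\Delta_T} are left untouched.
#'
#' @param fit result of \code{\link{fit_full}}
#' @param noise_trace,pulse_trace the original recordings
#' @param gL_method,smooth_ms,bin_w,min_count as passed to
#'   \code{\link{fit_full}}
#' @param iterations correction iterations (each simulates and refits once)
#' @param max_factor per-iteration multiplicative corrections are clamped
#'   to \code{[1/max_factor, max_factor]}
#' @param seed seed for the correction simulations
#' @return the corrected fit (same structure as \code{\link{fit_full}},
#'   with \code{report$first_pass} and \code{report$sim_fits} attached)
#' @export
bias_correct_fit <- function(fit, noise_trace, pulse_trace = NULL,
                             gL_method = "dynamics", smooth_ms = 0.6,
                             bin_w = 1, min_count = 50, iterations = 2,
                             max_factor = 2.5, seed = 1) {
  th0 <- fit$params
  keys <- c("gL", "a", "b", "tau_w", "DeltaT")
  obs <- vapply(keys, function(k) th0[[k]], numeric(1))
  clamp <- function(x) pmin(max_factor, pmax(1 / max_factor, x))
  th <- th0
  sim_fits <- list()
  for (it in seq_len(iterations)) {
    spec <- structure(list(params = th,
                           noise_sd_mV = fit$report$noise_sd,
                           fs_khz = 1 / noise_trace$dt / 1000),
                      class = "synthetic_cell_spec")
    set.seed(seed + it)
    ntr2 <- synth_recording(spec, current_waveform(noise_trace$dt,
                                                   noise_trace$I_in))
    attr(ntr2, "junctions") <- attr(noise_trace, "junctions")
    ptr2 <- if (!is.null(pulse_trace)) {
      init2 <- tryCatch(rest_state(th, stats::median(pulse_trace$I_in)),
                        error = function(e) c(th$EL, 0))
      synth_recording(spec, current_waveform(pulse_trace$dt,
                                             pulse_trace$I_in),
                      init = init2)
    } else NULL
    fit2 <- tryCatch(
      fit_full(ntr2, ptr2, gL_method = gL_method, smooth_ms = smooth_ms,
               bin_w = bin_w, min_count = min_count),
      error = function(e) NULL)
    if (is.null(fit2)) break
    sim_fits[[it]] <- fit2$params
    simv <- vapply(keys, function(k) fit2$params[[k]], numeric(1))
    # iterate th so that the pipeline applied to sim(th) reproduces the
    # observed estimates; only the systematically biased parameters move
    # (leak split, adaptation, and the selection-broadened slope factor);
    # C, EL, VT are near-unbiased and a difference-based correction would
    # only add variance there
    upd <- vapply(keys, function(k) th[[k]], numeric(1)) *
      clamp(obs / simv)
    th <- aeif_params(C = th0$C, gL = upd[["gL"]], EL = th0$EL,
                      VT = th0$VT, DeltaT = upd[["DeltaT"]],
                      a = upd[["a"]], b = upd[["b"]],
                      tau_w = upd[["tau_w"]], Vr = th0$Vr,
                      Vspike = th0$Vspike)
  }
  rep <- fit$report
  rep$first_pass <- th0
  rep$sim_fits <- sim_fits
  list(params = th, report = rep)
}
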