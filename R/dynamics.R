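#' Fixed points of the aEIF subthreshold flow
#'
#' Locates all intersections of the V- and w-nullclines. On the w-nullcline
#' \eqn{w = a (V - E_L)}, so fixed points are the roots of the 1-D reduced
#' equation
#' \deqn{g(V) = -(g_L + a)(V - E_L) + g_L \Delta_T e^{(V-V_T)/\Delta_T} + I}
#' found by a dense sign-change scan followed by bracketed root polishing.
#' Each root is classified from the eigenvalues of the analytic Jacobian.
#'
#' @param params an \code{aeif_params} object
#' @param I constant current (pA)
#' @param V_range search interval (mV); defaults to \code{[-90, Vspike]}
#' @param scan_step scan resolution (mV)
#' @return list of fixed points, each a list with \code{V}, \code{w},
#'   \code{eigenvalues} (complex pair) and \code{class} (one of
#'   \code{stable_focus}, \code{stable_node}, \code{unstable_focus},
#'   \code{unstable_node}, \code{saddle}); empty above the fold
#' @export
find_fixed_points <- function(params, I, V_range = NULL, scan_step = 0.01) {
  if (is.null(V_range)) V_range <- c(-90, params$Vspike)
  g <- function(V)
    -(params$gL + params$a) * (V - params$EL) +
    params$gL * params$DeltaT * exp((V - params$VT) / params$DeltaT) + I
  Vs <- seq(V_range[1], V_range[2], by = scan_step)
  gv <- g(Vs)
  sgn <- sign(gv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(idx, function(i)
    stats::uniroot(g, c(Vs[i], Vs[i + 1]), tol = 1e-12)$root, numeric(1))
  # exact zeros hit by the scan
  roots <- sort(unique(c(roots, Vs[gv == 0])))
  lapply(roots, function(V) {
    w <- params$a * (V - params$EL)
    J <- aeif_jacobian(params, V)
    ev <- eigen(J, only.values = TRUE)$values
    list(V = V, w = w, eigenvalues = ev, class = classify_eigen(ev))
  })
}

# Jacobian of the aEIF flow at voltage V (w enters linearly)
aeif_jacobian <- function(params, V) {
  dfdV <- (-params$gL +
             params$gL * exp((V - params$VT) / params$DeltaT)) / params$C
  matrix(c(dfdV, params$a / params$tau_w,
           -1 / params$C, -1 / params$tau_w), 2, 2)
}

classify_eigen <- function(ev) {
  re <- Re(ev); im <- Im(ev)
  if (all(abs(im) < 1e-12) && prod(re) < 0) return("saddle")
  stable <- all(re < 0)
  focus <- any(abs(im) > 1e-12)
  paste0(if (stable) "stable" else "unstable",
         if (focus) "_focus" else "_node")
}

#' Scan for the Andronov-Hopf bifurcation current
#'
#' Tracks the lowest-voltage fixed point over a current range and bisects on
#' the maximum real part of its Jacobian eigenvalues. A nonzero imaginary
#' part at the crossing identifies a Hopf bifurcation (type II); a zero
#' imaginary part indicates loss of the rest state through a saddle-node
#' (type I).
#'
#' @param params an \code{aeif_params} object
#' @param I_range current interval to scan (pA)
#' @param tol bisection tolerance on the current (pA)
#' @return list with \code{I_HB} (pA), \code{omega} (imaginary part of the
#'   eigenvalue at the crossing, rad/ms) and \code{hopf} (logical); or a
#'   \code{not_found = TRUE} result when the range brackets no stability
#'   change
#' @export
hopf_scan <- function(params, I_range = c(-300, 0), tol = 1e-4) {
  low_fp <- function(I) {
    fps <- find_fixed_points(params, I)
    if (!length(fps)) NULL else fps[[1]]
  }
  max_re <- function(I) {
    fp <- low_fp(I)
    if (is.null(fp)) NA_real_ else max(Re(fp$eigenvalues))
  }
  lo <- I_range[1]; hi <- I_range[2]
  f_lo <- max_re(lo)
  if (is.na(f_lo) || f_lo >= 0)
    stop("lower end of I_range must have a stable low-V fixed point")
  at_fold <- FALSE
  if (is.na(max_re(hi))) {
    # locate the fold (existence boundary) by bisection, then work just below
    elo <- lo; ehi <- hi
    while (ehi - elo > tol) {
      mid <- (elo + ehi) / 2
      if (is.null(low_fp(mid))) ehi <- mid else elo <- mid
    }
    hi <- elo
    at_fold <- TRUE
  }
  f_hi <- max_re(hi)
  if (is.na(f_hi)) return(list(not_found = TRUE))
  if (f_hi <= 0) {
    if (!at_fold) return(list(not_found = TRUE))
    # rest state stays stable up to the fold: saddle-node loss (type I)
    ev <- low_fp(hi)$eigenvalues
    return(list(I_HB = hi, omega = max(abs(Im(ev))), hopf = FALSE,
                saddle_node = TRUE, not_found = FALSE))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- max_re(mid)
    if (is.na(fm) || fm > 0) hi <- mid else lo <- mid
  }
  I_HB <- (lo + hi) / 2
  ev <- low_fp(lo)$eigenvalues
  omega <- max(abs(Im(ev)))
  list(I_HB = I_HB, omega = omega, hopf = omega > 1e-9,
       saddle_node = FALSE, not_found = FALSE)
}

#' Basin of attraction of the rest state
#'
#' Classifies a grid over the (V, w) phase plane by noise-free forward
#' integration: a cell belongs to the basin iff its trajectory neither
#' spikes within the horizon nor ends away from the stable fixed point.
#'
#' @param params an \code{aeif_params} object
#' @param I constant current (pA); a stable fixed point must exist
#' @param V_lim,w_lim grid bounds (mV, pA)
#' @param dV,dw grid spacing (mV, pA)
#' @param horizon_ms classification horizon (ms)
#' @param dt integration step (ms)
#' @return an object of class \code{basin_mask}: list with the grid axes,
#'   logical membership matrix \code{inside} (V rows, w columns), the fixed
#'   point and \code{I}
#' @export
rest_basin <- function(params, I, V_lim = c(-90, 0), w_lim = c(-300, 1500),
                       dV = 0.5, dw = 10, horizon_ms = 500, dt = 0.1) {
  fp <- rest_state(params, I)
  Vg <- seq(V_lim[1], V_lim[2], by = dV)
  wg <- seq(w_lim[1], w_lim[2], by = dw)
  inside <- basin_cpp(as_param_vector(params), I, Vg, wg,
                      round(horizon_ms / dt), dt, fp[1], fp[2],
                      Vtol = 1, wtol = 20)
  structure(list(V = Vg, w = wg, inside = inside, fixed_point = fp, I = I,
                 dV = dV, dw = dw),
            class = "basin_mask")
}

#' Membership lookup in a basin mask
#'
#' @param mask a \code{basin_mask}
#' @param V,w coordinates (vectors recycled to common length)
#' @return logical vector; points off the grid are \code{FALSE}
#' @export
in_basin <- function(mask, V, w) {
  iv <- round((V - mask$V[1]) / mask$dV) + 1
  iw <- round((w - mask$w[1]) / mask$dw) + 1
  ok <- iv >= 1 & iv <= length(mask$V) & iw >= 1 & iw <= length(mask$w)
  out <- logical(max(length(iv), length(iw)))
  out[ok] <- mask$inside[cbind(iv[ok], iw[ok])]
  out
}

#' Probability of spiking under OU noise
#'
#' The fraction of integration time the noisy trajectory spends outside the
#' basin of attraction of the rest state: \eqn{P_{sp} = 1 - P_r}, with
#' \eqn{P_r} the occupancy of the basin (instantaneous nearest-cell
#' membership). Averaged over independent repetitions. When no stable fixed
#' point exists the model is purely spiking and \eqn{P_{sp} = 1} by
#' convention.
#'
#' @param params an \code{aeif_params} object
#' @param I_mean mean input current (pA)
#' @param sigma OU noise SD (pA)
#' @param tau OU correlation time (ms)
#' @param reps number of repetitions
#' @param T_ms duration per repetition (ms)
#' @param dt integration step (ms)
#' @param init initial state; default: on the noise-free limit cycle when it
#'   exists, otherwise the rest state
#' @param mask optional precomputed \code{basin_mask} (reused across sigma
#'   values); defaults to a 0.25 mV x 5 pA grid
#' @param seed optional integer seed
#' @return list with \code{P_sp}, \code{P_sp_sd} (across repetitions),
#'   \code{per_rep}, and the mask used
#' @export
spiking_probability <- function(params, I_mean, sigma, tau = 2, reps = 20,
                                T_ms = 30000, dt = 0.1, init = NULL,
                                mask = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fps <- find_fixed_points(params, I_mean)
  if (!length(Filter(function(f) startsWith(f$class, "stable"), fps)))
    return(list(P_sp = 1, P_sp_sd = 0, per_rep = rep(1, reps), mask = NULL))
  if (is.null(mask))
    mask <- rest_basin(params, I_mean, dV = 0.25, dw = 5)
  if (is.null(init))
    init <- tryCatch(limit_cycle_state(params, I_mean),
                     error = function(e) mask$fixed_point)
  pv <- as_param_vector(params)
  n <- round(T_ms / dt)
  per_rep <- vapply(seq_len(reps), function(r) {
    1 - occupancy_cpp(pv, mask$inside, mask$V[1], mask$dV, mask$w[1],
                      mask$dw, n, dt, I_mean, sigma, tau, init[1], init[2])
  }, numeric(1))
  list(P_sp = mean(per_rep), P_sp_sd = stats::sd(per_rep),
       per_rep = per_rep, mask = mask)
}
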