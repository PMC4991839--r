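#' aEIF neuron parameter set
#'
#' Constructs and validates a parameter set for the adaptive exponential
#' integrate-and-fire (aEIF) model
#' \deqn{C \dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T} - w + I(t)}
#' \deqn{\tau_w \dot w = a (V - E_L) - w}
#' with the reset rule: if \eqn{V > V_{spike}} then \eqn{V \to V_r},
#' \eqn{w \to w + b}. Units are mV, ms, pA, nS, pF throughout, so that
#' \eqn{C \, dV/dt} is in pA.
#'
#' @param C capacitance (pF)
#' @param gL leak conductance (nS)
#' @param EL leak reversal potential (mV)
#' @param VT threshold potential (mV)
#' @param DeltaT spike slope factor (mV)
#' @param a subthreshold adaptation conductance (nS)
#' @param b spike-triggered adaptation increment (pA)
#' @param tau_w adaptation time constant (ms)
#' @param Vr post-spike voltage reset (mV); the reset value is not
#'   experimentally constrained for spontaneously active cells and defaults
#'   to \code{EL}
#' @param Vspike spike-cut threshold (mV)
#' @return an object of class \code{aeif_params} (a named list including the
#'   derived membrane time constant \code{tau_m = C/gL} in ms)
#' @export
aeif_params <- function(C, gL, EL, VT, DeltaT, a, b, tau_w,
                        Vr = EL, Vspike = 0) {
  vals <- c(C = C, gL = gL, EL = EL, VT = VT, DeltaT = DeltaT,
            a = a, b = b, tau_w = tau_w, Vr = Vr, Vspike = Vspike)
  if (any(!is.finite(vals)))
    stop("all aEIF parameters must be finite")
  if (C <= 0) stop("C must be > 0")
  if (gL <= 0) stop("gL must be > 0")
  if (DeltaT <= 0) stop("DeltaT must be > 0")
  if (tau_w <= 0) stop("tau_w must be > 0")
  if (a < 0) stop("a must be >= 0")
  if (Vr >= Vspike) stop("Vr must be below Vspike")
  p <- as.list(vals)
  p$tau_m <- C / gL
  structure(p, class = "aeif_params")
}

#' @export
print.aeif_params <- function(x, ...) {
  cat("aEIF parameters (mV, ms, pA, nS, pF):\n")
  cat(sprintf("  C = %.4g pF, gL = %.4g nS, EL = %.4g mV, VT = %.4g mV\n",
              x$C, x$gL, x$EL, x$VT))
  cat(sprintf("  DeltaT = %.4g mV, a = %.4g nS, b = %.4g pA, tau_w = %.4g ms\n",
              x$DeltaT, x$a, x$b, x$tau_w))
  cat(sprintf("  Vr = %.4g mV, Vspike = %.4g mV, tau_m = %.4g ms  [%s]\n",
              x$Vr, x$Vspike, x$tau_m,
              suppressWarnings(classify_excitability(x))))
  invisible(x)
}

# fixed-order numeric vector consumed by the compiled integrator
as_param_vector <- function(p) {
  c(p$C, p$gL, p$EL, p$VT, p$DeltaT, p$a, p$b, p$tau_w, p$Vr, p$Vspike)
}

#' Representative Purkinje-cell parameter set
#'
#' The aEIF parameters of the representative Purkinje cell used throughout
#' the bistability and ISR analyses, read from the bundled JSON file.
#'
#' @return an \code{aeif_params} object
#' @export
representative_params <- function() {
  path <- system.file("extdata", "representative_cell.json", package = "isrpc")
  read_params_json(path)
}

#' aEIF vector field
#'
#' Right-hand side of the aEIF equations at a given state.
#'
#' @param state numeric length 2, \code{c(V, w)} in (mV, pA)
#' @param params an \code{aeif_params} object
#' @param I injected current (pA)
#' @return numeric length 2: \code{c(dV/dt, dw/dt)} in (mV/ms, pA/ms)
#' @export
aeif_derivatives <- function(state, params, I = 0) {
  if (any(!is.finite(state))) stop("state must be finite")
  V <- state[1]; w <- state[2]
  dV <- (-params$gL * (V - params$EL) +
           params$gL * params$DeltaT * exp((V - params$VT) / params$DeltaT) -
           w + I) / params$C
  dw <- (params$a * (V - params$EL) - w) / params$tau_w
  c(dV, dw)
}

#' Rescale the aEIF model to dimensionless form
#'
#' Maps the aEIF model to the two-parameter dimensionless form
#' \deqn{\dot{\bar V} = -\bar V + e^{\bar V} - \bar w + \bar I, \quad
#'       T \dot{\bar w} = A \bar V - \bar w}
#' with \eqn{T = \tau_w/\tau_m}, \eqn{A = a/g_L},
#' \eqn{\bar I = I/(g_L \Delta_T) + (1 + A)(E_L - V_T)/\Delta_T},
#' \eqn{\bar t = t/\tau_m}, \eqn{\bar b = b/(g_L \Delta_T)},
#' \eqn{\bar V_r = (V_r - V_T)/\Delta_T}.
#'
#' @param params an \code{aeif_params} object
#' @param I input current (pA)
#' @return a \code{rescaled_params} object with fields \code{T}, \code{A},
#'   \code{Ibar}, \code{bbar}, \code{Vbar_r}; the anchor quantities needed to
#'   invert the map are kept as an attribute (see \code{\link{unscale_params}})
#' @export
rescale_params <- function(params, I = 0) {
  rs <- list(T = params$tau_w / params$tau_m,
             A = params$a / params$gL,
             Ibar = I / (params$gL * params$DeltaT) +
               (1 + params$a / params$gL) * (params$EL - params$VT) / params$DeltaT,
             bbar = params$b / (params$gL * params$DeltaT),
             Vbar_r = (params$Vr - params$VT) / params$DeltaT)
  attr(rs, "anchor") <- list(C = params$C, gL = params$gL, EL = params$EL,
                             VT = params$VT, DeltaT = params$DeltaT,
                             Vspike = params$Vspike)
  class(rs) <- "rescaled_params"
  rs
}

#' Invert the aEIF rescaling
#'
#' Reconstructs the physical parameter set and input current from a
#' \code{rescaled_params} object produced by \code{\link{rescale_params}}.
#'
#' @param rs a \code{rescaled_params} object
#' @return list with elements \code{params} (an \code{aeif_params}) and
#'   \code{I} (pA)
#' @export
unscale_params <- function(rs) {
  an <- attr(rs, "anchor")
  if (is.null(an)) stop("rescaled_params lacks its anchor attribute")
  gL <- an$gL; DeltaT <- an$DeltaT
  a <- rs$A * gL
  tau_m <- an$C / gL
  p <- aeif_params(C = an$C, gL = gL, EL = an$EL, VT = an$VT,
                   DeltaT = DeltaT, a = a,
                   b = rs$bbar * gL * DeltaT,
                   tau_w = rs$T * tau_m,
                   Vr = an$VT + rs$Vbar_r * DeltaT,
                   Vspike = an$Vspike)
  I <- (rs$Ibar - (1 + rs$A) * (an$EL - an$VT) / DeltaT) * gL * DeltaT
  list(params = p, I = I)
}

#' Classify aEIF excitability type
#'
#' Type II excitability (firing onset with nonzero frequency, rest state lost
#' through an Andronov-Hopf bifurcation) holds when \eqn{a/g_L > \tau_m/\tau_w};
#' otherwise the model is type I. The measure-zero boundary case is assigned
#' to type I with a warning.
#'
#' @param params an \code{aeif_params} object
#' @return \code{"type_I"} or \code{"type_II"}
#' @export
classify_excitability <- function(params) {
  lhs <- params$a / params$gL
  rhs <- params$tau_m / params$tau_w
  if (lhs == rhs) {
    warning("a/gL equals tau_m/tau_w: boundary case classified as type_I")
    return("type_I")
  }
  if (lhs > rhs) "type_II" else "type_I"
}

#' Rheobase current of the type II aEIF model
#'
#' Closed-form minimal constant current that destabilizes the rest state of a
#' type II aEIF model (the current of the subcritical Andronov-Hopf
#' bifurcation):
#' \deqn{I_{up} = (g_L + a)\left[V_T - E_L - \Delta_T +
#'   \Delta_T \log(1 + \tau_m/\tau_w)\right] +
#'   \Delta_T g_L (a/g_L - \tau_m/\tau_w)}
#'
#' @param params an \code{aeif_params} object; must classify as type II
#' @return rheobase current \eqn{I_{up}} (pA)
#' @export
rheobase_up <- function(params) {
  if (classify_excitability(params) != "type_II")
    stop("rheobase_up: closed form only valid for type II parameter sets")
  r <- params$tau_m / params$tau_w
  (params$gL + params$a) *
    (params$VT - params$EL - params$DeltaT +
       params$DeltaT * log(1 + r)) +
    params$DeltaT * params$gL * (params$a / params$gL - r)
}

#' Two-compartment aEIF parameter set
#'
#' An aEIF soma coupled to a passive dendritic compartment through a
#' conductance \code{gc}:
#' \deqn{C \dot V = [\mathrm{aEIF\ terms}] + g_c (V_d - V)}
#' \deqn{C_d \dot V_d = -g_{Ld} (V_d - E_L) + g_c (V - V_d)}
#'
#' @param soma an \code{aeif_params} object for the somatic compartment
#' @param gc somato-dendritic coupling conductance (nS)
#' @param Cd dendritic capacitance (pF)
#' @param gLd dendritic leak conductance (nS)
#' @return an object of class \code{two_comp_params}
#' @export
two_compartment_params <- function(soma, gc, Cd, gLd) {
  stopifnot(inherits(soma, "aeif_params"))
  if (gc <= 0) stop("gc must be > 0")
  if (Cd <= 0) stop("Cd must be > 0")
  if (gLd < 0) stop("gLd must be >= 0")
  structure(list(soma = soma, gc = gc, Cd = Cd, gLd = gLd),
            class = "two_comp_params")
}

#' Two-compartment aEIF vector field
#'
#' @param state numeric length 3, \code{c(V, w, Vd)}
#' @param params a \code{two_comp_params} object
#' @param I somatic injected current (pA)
#' @return numeric length 3: \code{c(dV/dt, dw/dt, dVd/dt)}
#' @export
two_compartment_derivatives <- function(state, params, I = 0) {
  s <- params$soma
  V <- state[1]; w <- state[2]; Vd <- state[3]
  base <- aeif_derivatives(c(V, w), s, I)
  dV <- base[1] + params$gc * (Vd - V) / s$C
  dVd <- (-params$gLd * (Vd - s$EL) + params$gc * (V - Vd)) / params$Cd
  c(dV, base[2], dVd)
}

#' Read aEIF parameters from JSON
#'
#' Parameter files use explicit unit suffixes in their key names
#' (\code{C_pF}, \code{gL_nS}, \code{EL_mV}, \code{VT_mV}, \code{DeltaT_mV},
#' \code{a_nS}, \code{b_pA}, \code{tau_w_ms}, \code{Vr_mV}, \code{Vspike_mV}).
#'
#' @param path path to a JSON file
#' @return an \code{aeif_params} object
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("C_pF", "gL_nS", "EL_mV", "VT_mV", "DeltaT_mV",
            "a_nS", "b_pA", "tau_w_ms")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("parameter file missing keys: ", paste(miss, collapse = ", "))
  aeif_params(C = x$C_pF, gL = x$gL_nS, EL = x$EL_mV, VT = x$VT_mV,
              DeltaT = x$DeltaT_mV, a = x$a_nS, b = x$b_pA,
              tau_w = x$tau_w_ms,
              Vr = if (!is.null(x$Vr_mV)) x$Vr_mV else x$EL_mV,
              Vspike = if (!is.null(x$Vspike_mV)) x$Vspike_mV else 0)
}

#' Write aEIF parameters to JSON
#'
#' @param params an \code{aeif_params} object
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_params_json <- function(params, path) {
  x <- list(C_pF = params$C, gL_nS = params$gL, EL_mV = params$EL,
            VT_mV = params$VT, DeltaT_mV = params$DeltaT, a_nS = params$a,
            b_pA = params$b, tau_w_ms = params$tau_w, Vr_mV = params$Vr,
            Vspike_mV = params$Vspike)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
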