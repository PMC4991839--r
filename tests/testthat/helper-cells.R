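# shared fixtures: parameter sets used across the suite

rep_cell <- function() representative_params()

# a type I parameter set (weak subthreshold adaptation)
type1_cell <- function() {
  p <- rep_cell()
  aeif_params(p$C, p$gL, p$EL, p$VT, p$DeltaT, a = 2, b = p$b,
              tau_w = p$tau_w, Vr = p$Vr)
}

# a passive RC cell: no adaptation, threshold far above the operating range
rc_cell <- function(C = 200, gL = 10, EL = -60) {
  aeif_params(C = C, gL = gL, EL = EL, VT = -20, DeltaT = 2,
              a = 0, b = 0, tau_w = 10, Vr = -65, Vspike = 0)
}

rel_err <- function(est, true) abs(est - true) / abs(true)
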