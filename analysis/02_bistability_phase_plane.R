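#!/usr/bin/env Rscript
# Bifurcation structure and phase-plane geometry of the representative
# model: fixed-point branches over the input current, the Andronov-Hopf
# point against the closed-form rheobase, the rest-state basin at the ISR
# operating point, and the ramp hysteresis that brackets the bistable range.

library(isrpc)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
set.seed(seed)
dir.create("results", showWarnings = FALSE)

p <- representative_params()

# fixed-point branches
scan <- do.call(rbind, lapply(seq(-300, -20, by = 2), function(I) {
  fps <- find_fixed_points(p, I)
  if (!length(fps)) return(NULL)
  do.call(rbind, lapply(fps, function(f)
    data.frame(I = I, V = f$V, w = f$w, class = f$class)))
}))
write.table(format(scan, digits = 6), "results/fixed_point_branches.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

hb <- hopf_scan(p, c(-200, 0))
iup <- rheobase_up(p)
cat(sprintf("Andronov-Hopf current: %.2f pA (closed-form rheobase %.2f pA, omega %.4f rad/ms)\n",
            hb$I_HB, iup, hb$omega))

# basin of attraction at the ISR operating point
mask <- rest_basin(p, -150, dV = 0.5, dw = 10)
grid <- expand.grid(V = mask$V, w = mask$w)
grid$inside <- as.integer(as.vector(mask$inside))
write.table(grid[grid$inside == 1, ], "results/basin_minus150pA.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("Rest basin at -150 pA: %d of %d grid cells; fixed point (%.2f mV, %.1f pA)\n",
            sum(grid$inside), nrow(grid), mask$fixed_point[1],
            mask$fixed_point[2]))

# hysteresis at the standard protocol rate and in the quasi-static limit
hy <- hysteresis_ramp(p)
hq <- hysteresis_ramp(p, rate = 0.09, ramp_ms = 10000, trials = 1)
tab <- data.frame(protocol = c("ramp_0.9nA_per_s", "ramp_0.09nA_per_s"),
                  I_up = c(hy$I_up, hq$I_up),
                  I_down = c(hy$I_down, hq$I_down),
                  dI = c(hy$dI, hq$dI), df = c(hy$df, hq$df))
write.table(format(tab, digits = 5), "results/hysteresis.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("Hysteresis:\n"); print(tab, digits = 4)

# f-I staircase: the type II discontinuity
fi <- fi_curve(p)
write.table(fi, "results/fi_curve.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("f-I onset discontinuity: %.1f Hz\n", attr(fi, "f_onset")))
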