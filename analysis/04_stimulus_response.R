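#!/usr/bin/env Rscript
# Stimulus-response analyses at the ISR operating point (-150 pA):
# peristimulus spiking probability under three noise regimes, decay time
# constants of the evoked spiking state, and the input-output curve.

library(isrpc)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
dir.create("results", showWarnings = FALSE)

p <- representative_params()
mask <- rest_basin(p, -150)
sweeps <- 400

psths <- do.call(rbind, lapply(c(10, 30, 60), function(s) {
  ps <- psth(p, sigma = s, Am = 100, t_stim = 2000, sweeps = sweeps,
             T_ms = 6000, mask = mask, seed = seed + s)
  data.frame(sigma = s, t = ps$t, p = ps$p,
             baseline = attr(ps, "baseline"))
}))
write.table(format(psths, digits = 4), "results/psth.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

for (s in c(10, 30, 60)) {
  sub <- psths[psths$sigma == s, ]
  ps <- structure(sub[, c("t", "p")], t_stim = 2000,
                  baseline = sub$baseline[1], bin = 20,
                  class = c("psth_result", "data.frame"))
  dc <- tryCatch(decay_time_constant(ps), error = function(e)
    list(tau_s = NA))
  cat(sprintf("sigma %2d pA: baseline %.3f, peak %.3f, decay tau %s s\n",
              s, sub$baseline[1], max(sub$p),
              format(dc$tau_s, digits = 3)))
}

io <- input_output_curve(p, sigma = 30, sweeps = sweeps, seed = seed + 99)
write.table(format(io$curve, digits = 4), "results/io_curve.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("input-output at sigma 30: threshold %g pA, saturation %g pA\n",
            io$threshold, io$saturation))
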