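#!/usr/bin/env Rscript
# ISR tuning: mean firing rate versus noise amplitude at holding currents
# inside and outside the bistable range, the phase-space spiking
# probability, and the history-resolved curves from the continuously
# ramped-amplitude protocol.

library(isrpc)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
dir.create("results", showWarnings = FALSE)

p <- representative_params()

curves <- do.call(rbind, lapply(c(-100, -150, -200), function(I) {
  ic <- tryCatch(
    isr_curve_model(p, I_mean = I, reps = 10, T_ms = 15000,
                    seed = seed + I),
    error = function(e) NULL)
  if (is.null(ic)) return(NULL)
  data.frame(I_mean = I, sigma = ic$sigma, rate = ic$rate,
             smoothed = ic$smoothed, sigma_opt = attr(ic, "sigma_opt"))
}))
write.table(format(curves, digits = 5), "results/isr_curves.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
for (I in unique(curves$I_mean)) {
  sub <- curves[curves$I_mean == I, ]
  cat(sprintf("I = %4d pA: f(0) = %5.1f Hz, minimum %5.2f Hz at sigma = %d pA\n",
              I, sub$rate[1], min(sub$smoothed), sub$sigma_opt[1]))
}

# spiking probability (basin occupancy) across the same noise grid
mask <- rest_basin(p, -150)
psp <- vapply(seq(0, 100, 10), function(s)
  spiking_probability(p, -150, sigma = s, reps = 8, T_ms = 15000,
                      mask = mask, seed = seed + s)$P_sp, numeric(1))
write.table(data.frame(sigma = seq(0, 100, 10), P_sp = psp),
            "results/spiking_probability.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("P_sp minimum %.3f at sigma = %d pA\n", min(psp),
            seq(0, 100, 10)[which.min(psp)]))

# continuous-amplitude protocol, split by firing history
set.seed(seed)
wf <- build_protocol("continuous_noise", dt = 0.1, mean = -150,
                     sigma_rate = 0.0002, sigma_max = 100)
tr <- synth_recording(p, wf, init = limit_cycle_state(p, -150))
cc <- isr_curve_continuous(tr, attr(tr, "spikes"))
cc$was_firing$history <- "firing"
cc$was_silent$history <- "silent"
write.table(rbind(cc$was_firing, cc$was_silent),
            "results/isr_continuous.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("continuous protocol: firing-history minimum at %g pA\n",
            cc$was_firing$sigma[which.min(cc$was_firing$rate)]))
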