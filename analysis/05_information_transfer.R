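#!/usr/bin/env Rscript
# Mutual information rate between a 1 Hz Poisson synaptic signal and the
# model's output spike train, across noise amplitudes and signal strengths
# (CTW estimator, 25 ms bins, depth 40).

library(isrpc)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
dir.create("results", showWarnings = FALSE)

p <- representative_params()
sig <- c(10, 20, 30, 40, 60, 80)

tab <- do.call(rbind, lapply(c(60, 100, 140), function(Am)
  do.call(rbind, lapply(seq_along(sig), function(i) {
    mi <- mi_experiment(p, sigma = sig[i], Am = Am, rate_hz = 1,
                        T_ms = 200000, repeats = 2,
                        seed = seed + 100 * Am + i)
    data.frame(Am = Am, sigma = sig[i],
               mi_bits_per_s = mi$mi_bits_per_s)
  }))))
write.table(format(tab, digits = 4), "results/mi_vs_sigma.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

for (Am in unique(tab$Am)) {
  sub <- tab[tab$Am == Am, ]
  cat(sprintf("Am %3d pA: MI peak %.2f bits/s at sigma = %d pA\n", Am,
              max(sub$mi_bits_per_s),
              sub$sigma[which.max(sub$mi_bits_per_s)]))
}
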