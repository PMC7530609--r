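#!/usr/bin/env Rscript
# Step 2: demonstrate that spike-in normalization recovers planted global
# reductions of heterochromatin-mark abundance that plain ChIP/input
# normalization is blind to.

suppressMessages(library(hetsink))

cfg <- analysis_config(rng_seed = 1)
dir.create("results", showWarnings = FALSE)

g <- build_genome_model(seed = cfg$rng_seed)
s <- sink_model()
dilutions <- c(1.0, 0.7, 0.5)

rows <- lapply(dilutions, function(d) {
  e <- simulate_chip_experiment(g, karyotype_spec("XY"), s, depth = 1e6,
                                noise = TRUE, seed = cfg$rng_seed + 11,
                                mark_dilution = d)
  f_ratio <- spike_scaling_ratio(e$chip, e$input)
  f_reg <- spike_scaling_regression(e$chip, e$input)$factor
  spiked <- window_signal(e$chip, e$input, f_ratio, mask = e$mask)
  plain <- unspiked_signal(e$chip, e$input, mask = e$mask)
  data.frame(dilution_true = d, factor_ratio = f_ratio,
             factor_regression = f_reg,
             mean_spiked_signal = mean(spiked$value, na.rm = TRUE),
             mean_unspiked_signal = mean(plain$value, na.rm = TRUE))
})
tab <- do.call(rbind, rows)
tab$factor_rel_to_undiluted <- tab$factor_ratio / tab$factor_ratio[1]
tab$unspiked_rel_to_undiluted <-
  tab$mean_unspiked_signal / tab$mean_unspiked_signal[1]
utils::write.table(format(tab, digits = 6), "results/spike_normalization.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("spike normalization under planted global mark dilution:\n")
print(tab[, c("dilution_true", "factor_rel_to_undiluted",
              "unspiked_rel_to_undiluted")], row.names = FALSE)
cat("the spike factor tracks the planted dilution; the unspiked ratio stays at ~1.\n")
cat("wrote results/spike_normalization.tsv\n")
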