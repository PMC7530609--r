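#!/usr/bin/env Rscript
# Step 1: build the synthetic genome model all later steps analyze, and
# write its annotation out as standard browser formats.

suppressMessages(library(hetsink))

cfg <- analysis_config(rng_seed = 1)
dir.create("results", showWarnings = FALSE)

g <- build_genome_model(seed = cfg$rng_seed, window_width = cfg$window_width)

write_bed(transform(g$blocks, name = region), "results/genome_blocks.bed",
          config = cfg)
write_bed(data.frame(chrom = g$windows$chrom[g$crossmap_mask],
                     start = g$windows$start[g$crossmap_mask],
                     end = g$windows$end[g$crossmap_mask]),
          "results/crossmap_mask.bed", config = cfg)
write_window_track(window_track(g$windows$chrom, g$windows$start,
                                g$windows$end, g$gc),
                   "results/gc_track.tsv", config = cfg)
utils::write.table(g$repeat_families, "results/repeat_families.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("genome: %d arms, %d windows of %d bp, %d repeat families (%d Y-linked)\n",
            nrow(g$arms), nrow(g$windows), g$window_width,
            nrow(g$repeat_families),
            sum(g$repeat_families$label_true == "male_specific")))
for (k in c("X0", "XX", "XY", "XXY", "XYY"))
  cat(sprintf("  %-4s physical het content %.2f Mb\n",
              k, het_content_mb(g, karyotype_spec(k))))
cat("wrote results/genome_blocks.bed, crossmap_mask.bed, gc_track.tsv, repeat_families.tsv\n")
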