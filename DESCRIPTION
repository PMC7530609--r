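Package: hetsink
Title: Spike-In Normalized Chromatin Profiling Across Karyotypes with
    Variable Repeat Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of repressive histone-mark landscapes in
    genomes whose repeat content varies with sex-chromosome karyotype.
    Implements spike-in (reference chromatin) normalization of windowed
    ChIP-seq coverage by the spike-ratio and spike-regression methods,
    GC-bias correction of window and repeat coverage by binned expected
    coverage, heterochromatin/euchromatin boundary profiling with a
    spreading index, classification of male-specific (Y-linked) repeats
    from sex-resolved genomic coverage, copy-number-corrected repeat
    expression, and permutation statistics for top-k gene-set overlap
    between expression contrasts. Ships a synthetic-data generator that
    reproduces the statistical structure these analyses assume
    (heterochromatin-sink dilution of marks, GC-dependent coverage bias,
    sex-limited repeats, karyotype-dependent differential expression), so
    the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
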