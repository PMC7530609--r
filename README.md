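# hetsink

Quantitative, spike-in-normalized analysis of repressive chromatin across
karyotypes that differ in repeat content — for epigenomics researchers who
need to compare the *absolute* abundance of a histone mark (H3K9me2/3)
between samples, not just its distribution.

## The problem and the method

Large repetitive regions such as the Y chromosome are thought to act as a
*heterochromatin sink*: the writers and readers of repressive marks exist
in limited amounts, so extra repetitive DNA (XXY, XYY) dilutes
heterochromatin genome-wide while less repetitive DNA (X0) concentrates it
and lets it spread past the normal heterochromatin/euchromatin boundary.
Standard ChIP-seq normalization erases exactly the genome-wide differences
this predicts. The fix is a fixed amount of reference-species spike-in
chromatin per sample: with target reads `M`, spike reads `S` and spike
fraction `phi = S/(M+S)` per library, the sample's scaling factor is

    f = phi_input / phi_chip

and the per-window signal

    signal_w = [c_w/(Mc+Sc)] / [i_w/(Mi+Si)] * f  =  (c_w / i_w) * (S_i / S_c)

which scales exactly linearly with any global change in mark abundance,
while the input ratio absorbs ploidy and genome-size differences between
karyotypes. Around this core the package implements binned GC-bias
correction (5% GC bins), region and boundary statistics with Wilcoxon rank
tests, a boundary spreading index (isotonic step fit), classification of
male-specific (Y-linked) repeats from sex-resolved genomic coverage,
copy-number-corrected repeat expression, and a permutation test for the
top-k overlap of differential-expression contrasts (null expectation
`N*(k/N)^m`). A seeded synthetic-data generator reproduces the statistical
structure of the design — sink dilution, GC bias, sex-limited repeats,
karyotype-dependent expression — so everything is testable without
sequencing data.

## Worked example

Simulate a wildtype-male experiment with a planted 2x global loss of the
mark and recover it:

```r
library(hetsink)
g <- build_genome_model(seed = 1)           # 7 arms, 2180 x 5-kb windows
s <- sink_model()                           # sink rule, measured het gradient
e1 <- simulate_chip_experiment(g, karyotype_spec("XY"), s, seed = 12)
e2 <- simulate_chip_experiment(g, karyotype_spec("XY"), s, seed = 12,
                               mark_dilution = 0.5)
f1 <- spike_scaling_ratio(e1$chip, e1$input)
f2 <- spike_scaling_ratio(e2$chip, e2$input)
f2 / f1
#> [1] 0.5154373
mean(unspiked_signal(e2$chip, e2$input, mask = e2$mask)$value, na.rm = TRUE) /
  mean(unspiked_signal(e1$chip, e1$input, mask = e1$mask)$value, na.rm = TRUE)
#> [1] 0.9994615
```

The spike factor tracks the planted dilution (0.52 vs truth 0.50); the
unspiked ChIP/input ratio is blind to it (1.00) — the quantitative case
for the spike-in. The numbered drivers under `analysis/` run the full
workflow (genome build, normalization, five-karyotype landscape, GC
correction, repeat classification and per-copy expression, expression
overlap), each printing what it found and writing tables under `results/`.
For example `analysis/03_chromatin_landscape.R` reports the mean
pericentromeric signal falling strictly with repeat content across
X0/XX/XY/XXY/XYY (Spearman rho = -1) and a +80 kb outward boundary shift
in X0, and `analysis/06_expression_overlap.R` reports 693 of the top 1,000
genes shared across the three karyotype contrasts against 111 expected by
chance at its simulation's universe size (N = 3000, permutation
p = 1e-4, the add-one floor at 10^4 permutations).

See `vignettes/heterochromatin-sink.Rmd` for the models, parameter
conventions and the generator's scope.

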