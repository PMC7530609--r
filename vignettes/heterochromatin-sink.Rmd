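---
title: "Quantitative chromatin profiling across karyotypes with variable repeat content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative chromatin profiling across karyotypes with variable repeat content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetsink)
```

## The scientific problem

Constitutive heterochromatin — pericentromeres, the dot chromosome, and the
nearly fully repetitive Y — is marked by the repressive histone
modifications H3K9me2/3. The *heterochromatin sink* hypothesis holds that
the proteins that write and bind these marks are present in limited
amounts, so that adding repetitive DNA to a genome (an extra Y) dilutes
repressive marks at all repeats genome-wide, while removing repetitive DNA
(an X0 male) concentrates them and lets heterochromatin spread outward past
its normal boundaries. Fly karyotypes with one euchromatic gene complement
but very different repeat loads (X0, XX, XY, XXY, XYY) are the natural
experiment for this hypothesis.

Testing it quantitatively requires comparing the *absolute* abundance of a
histone mark between samples. Standard ChIP-seq cannot do that: dividing
ChIP by input and normalizing by sequencing depth erases any genome-wide
change in mark abundance. `hetsink` implements the spike-in solution — a
fixed amount of reference-species chromatin added to each sample before
immunoprecipitation — together with every downstream step of the analysis:
GC-bias correction, window and region comparisons, boundary profiling,
male-specific repeat classification, copy-number-corrected repeat
expression, and permutation statistics for top-k gene-set overlap. A
synthetic-data generator with the same statistical structure stands in for
sequencing data, so the whole pipeline is testable offline.

## Spike-in normalization

Each library is split into target reads $M$ and spike reads $S$, with spike
fraction $\varphi = S/(M+S)$. The scaling factor between the ChIP and input
library of one sample is

$$f = \varphi_\mathrm{input} / \varphi_\mathrm{ChIP},$$

and the per-window signal is the library-size-normalized ChIP/input ratio
times $f$:

$$\mathrm{signal}_w = \frac{c_w/(M_c+S_c)}{i_w/(M_i+S_i)} \cdot f
 = \frac{c_w}{i_w}\cdot\frac{S_i}{S_c}.$$

The input ratio absorbs ploidy and genome-size differences between
karyotypes; the spike terms restore the absolute scale. If the true mark
density is globally multiplied by $d$ while the spike is constant, every
$\mathrm{signal}_w$ scales exactly by $d$ (the algebraic reduction above
makes this an identity), and the factor $f$ scales by $d$ up to a term of
order the spike fraction. The directionality — a genome-wide loss of the
mark *lowers* $f$ and the signal — is what makes the method interpretable;
the opposite reading of the normalization would invert every contrast.

A second estimate of the same scaling fits a least-squares slope through
the origin of depth-normalized spike ChIP coverage on spike input coverage
over spike windows (`spike_scaling_regression`). On noiseless data the two
estimates coincide exactly; `align_regression_factors` puts regression
factors on the ratio scale via a designated reference sample. The unspiked
estimator `unspiked_signal` (plain depth-normalized ChIP/input) is provided
deliberately: it is blind to global dilution, which is the package's
demonstration of why the spike is needed.

Zero-input windows are missing, not zero; an optional pseudocount (default
0, i.e. off) is added to both ChIP and input coverage when enabled.
Windows overlapping the cross-mapping mask are excluded from all
window-level statistics; library totals are computed before masking.

## GC-bias correction

Coverage depends on GC content, and repeats have extreme GC. Expected
coverage is estimated as the mean observed coverage of unmasked windows
within GC bins of width 0.05 (bins are half-open $[lo, hi)$, the last bin
closed, so GC = 1 is counted once); observed coverage is divided by the
expectation of its bin. Repeat families are corrected identically, keyed on
the consensus GC. Bins with fewer than 10 windows are flagged unreliable;
empty bins yield missing values, with counts reported. The model is fitted
per input library (recorded in the model's metadata), and correction is
intended for the heterochromatic-mark pipelines; nothing prevents applying
it elsewhere.

The generator plants bias as $\exp(\beta(g - 0.5))$ with, by default, $g$
snapped to the midpoint of the window's 5%-wide GC bin (`gc_bias_factor`,
`resolution = "bin"`). Modeling the bias at the resolution at which the
binned estimator corrects it makes the estimator well specified, so the
noiseless tests can demand essentially exact removal (post-correction
slope below 1% of the pre-correction slope, per-bin means equal to within
2%). `resolution = "continuous"` plants bias at full GC resolution and
leaves a within-bin residual — useful for studying the limits of binned
correction, but not the default study condition.

## Windows, regions, boundaries

All coordinates are 0-based half-open; windows are fixed-width (default
5 kb), sorted, non-overlapping. Cross-karyotype comparisons use signed
subtraction tracks (`A - B`, with `|A - B|` available), region box
summaries (type-7 quartiles — linear interpolation, stated because whisker
reach depends on it; whiskers at the most extreme point within 1.5 IQR),
and two-sided rank-sum tests against a designated reference karyotype.
`rank_sum_test` uses the exact null when $\min(n) \le 8$ with no ties and
the normal approximation with tie and continuity correction otherwise; the
test suite checks it against exhaustive enumeration of all labelings.
Multiple region-by-karyotype tests are reported with unadjusted p plus
Benjamini–Hochberg q-values.

Boundary profiles collect windows within a flank (default 1 Mb on real
genomes; 300 kb on the scaled-down synthetic genome, matching its 300–600
kb arm-to-boundary distances) of the annotated
heterochromatin/euchromatin boundary, assigning windows to a side by
midpoint — deterministic, with error bounded by one window width. The
spreading index summarizes a profile by (i) the boundary contrast
$(\bar{x}_\mathrm{in} - \bar{x}_\mathrm{out})/(\bar{x}_\mathrm{in} +
\bar{x}_\mathrm{out})$ and (ii) the midpoint shift: an isotonic (monotone)
fit of signal on distance-into-heterochromatin, interpolated where it
crosses half-height, minus the annotated boundary. Isotonic regression was
chosen over a parametric sigmoid because it is deterministic, free of
starting-value failures, and localizes a step to within one window; a flat
profile has no half-height crossing and returns a missing shift.

## Male-specific repeats and copy-number-corrected expression

A repeat family is called male-specific when its depth-normalized male
coverage is high (default threshold: 5 times the median single-copy
coverage) and female coverage is absent, or both below 10% of the male
value and significantly depleted by a one-sided binomial test of the
female read share against the depth-expected share at $\alpha = 0.01$ with
Bonferroni correction across families. The thresholds are config-exposed
and echoed in the output, since "high" and "significantly lower" are
judgment calls; classification is invariant to joint rescaling of the two
libraries' depths.

Mark enrichment per family is the GC-corrected ChIP/input ratio scaled by
the sample's spike factor and divided by its genome-wide signal; the input
denominator removes copy number. Copies are estimated as family input
coverage over the single-copy euchromatic baseline. Expression is counts
per million over the repeat+gene universe, per kb, divided by copies —
distinguishing true per-copy derepression from mere dosage: doubling
copies at a fixed per-copy rate doubles raw counts but leaves per-copy
expression unchanged.

## Top-k overlap statistics

Genes are ranked per contrast by $|\log_2$ fold change$|$ of
pseudocount-stabilized mean CPM (a deliberately simple stand-in for a full
differential-expression model, which is out of scope here), ties broken by
gene id. The overlap statistic is the size of the intersection of the
top-$k$ sets of $m$ contrasts over a universe of $N$ genes. The null
treats the $m$ top sets as independent uniform $k$-subsets — the minimal
exchangeable-gene null, whose closed-form expectation is $N(k/N)^m$; with
$m = 3$, $k = 1000$, $N = 9535$ that expectation is 11.0. The p-value uses
the add-one estimator $(1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(B+1)$,
bounded below by $1/(B+1)$. $N$ is always reported because the expectation
depends on it. A stricter correlated-contrast null (permuting sample
labels) would be appropriate when contrasts share samples; the
independent-subsets null is the one whose expectation matches the
"expected by chance" arithmetic, and the test suite verifies both the
closed form (within 3 SE over a grid of $(m, k, N)$) and p-value validity.

On calibration: the add-one estimator over a *discrete* statistic is
super-uniform by construction (ties at the $\ge$ comparison inflate p), so
its null distribution is close to, but detectably more conservative than,
uniform. The calibration experiment that is exactly uniform is the
gene-set contrast p under random gene sets: `geneset_contrast` compares a
set's $|\mathrm{lfc}|$ against all genes with a rank-sum test, and with a
set that is a small fraction of the universe (60 of 2000 in the test
suite, mirroring real curated sets) 500 null draws pass a
Kolmogorov–Smirnov uniformity test at $\alpha = 0.01$. For the overlap p
itself the suite checks validity, $P(p \le \alpha) \le \alpha$ within
Monte-Carlo error.

## The synthetic genome and what it does (not) emulate

`build_genome_model` tiles a scaled-down fly-like genome — four 2-Mb
autosomal arms, a 1.5-Mb X, a fully heterochromatic 1-Mb Y and 0.4-Mb dot,
5-kb windows — into blocks with one heterochromatin/euchromatin boundary
per non-dot, non-Y arm (heterochromatin at the centromere-proximal, low
coordinate end). Per-window GC is Beta-distributed, AT-richer and broader
in heterochromatin; 2.5% of windows are masked for cross-mapping, and the
simulator leaks 2.5% of spike reads into those windows (they are excluded
downstream). Repeat families carry autosome/X/Y-resolved copy numbers;
Y-linked families have zero female copies.

The sink rule is the generative embodiment of the hypothesis: mark density
in heterochromatic windows is
$\mathrm{base} \times (\mathrm{het}_\mathrm{ref}/\mathrm{het}(k))^
{\mathrm{exponent}}$, never below the euchromatic floor, with the measured
diploid heterochromatin gradient (X0 109 < XX 125 < XY 148 < XXY 158 <
XYY 185 Mb, reference 148) as the default per-karyotype lookup — the toy
genome's physical blocks say *where* marks sit, the lookup says *how much*
they are diluted. Karyotypes below the reference repeat content
additionally spread marks outward past the boundary, proportionally to
their repeat deficit (default scale 300 kb per unit relative deficit,
about +79 kb for X0 — around 16 windows, comfortably detectable yet small
against a 600-kb heterochromatin block). Setting the exponent to 0
switches both effects off and makes all karyotypes statistically
identical, the null the tests lean on. ChIP and input libraries are
multinomial draws at a configured depth (default $10^6$ read-equivalents;
`noise = FALSE` returns expected counts for exactness tests), with a fixed
spike mass of 2% of the diploid target chromatin and a constant spike mark
level, so spike totals vary across karyotypes only through the
few-percent difference in target genome mass. RNA-seq counts are negative
binomial with two replicates per karyotype by default; a configurable set
of genes responds to Y presence in either sex (the structure behind the
top-k overlap), others to sex only; repeat expression scales with copy
number times a per-copy rate that derepression multiplies.

What passing tests on this generator show is that every estimator recovers
the parameters of the process it assumes, at desk-scale problem sizes
(about 2,200 windows, 60–200 repeat families, 1,200–3,000 genes,
$10^6$–$2\times10^7$ read-equivalents, $10^4$ permutations). What they do
not show: robustness to read-level artifacts (alignment, duplicates,
fragment-length effects — the pipeline consumes coverage, not reads), to
GC bias that varies within a bin (available via `resolution =
"continuous"` but not the default condition), to biological replicate
variation in ChIP (the generator draws one library per karyotype), or to
repeat families diverging from their consensus. Genome-scale effect sizes
on real data are not reproduced here — only the qualitative orderings and
the estimators' correctness.

## Degenerate inputs and numerical conventions

Missing is distinct from zero throughout (masked windows, zero-input
windows, empty GC bins). Medians of even-length sets are the average of
the middle two, reported to one decimal where file summaries print them.
The euchromatin-constant rule for heterochromatin content is keyed only on
the X count (232 Mb diploid for two or more X, 210 Mb for one); other
ploidies are rejected rather than extrapolated. A rank test on completely
constant data returns p = 1 rather than NaN. Fixed seeds make every
generator output byte-identical; every written track or table can carry a
provenance header with the seed and a config digest.
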