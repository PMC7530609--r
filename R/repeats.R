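#' Classify male-specific (Y-linked) repeat families
#'
#' A family is called `male_specific` when its depth-normalized male coverage
#' is high (at least `min_male_cov`) and its female coverage is either
#' exactly zero or both (a) at most `max_female_ratio` of the male coverage
#' and (b) significantly lower than expected under equal per-copy abundance,
#' by a one-sided binomial test of the female read share against the
#' depth-expected share, Bonferroni-corrected across families. Families with
#' appreciable female coverage are `shared`; families seen only in females
#' are `female_only`.
#'
#' @param families Data frame with one row per family: `name`, `male_reads`,
#'   `female_reads`, `male_cov`, `female_cov` (mean per-bp coverage).
#' @param male_depth,female_depth Library sizes used for depth normalization.
#' @param min_male_cov Minimum depth-normalized male coverage (same units as
#'   `male_cov` after normalization; conventionally 5x the median single-copy
#'   coverage).
#' @param max_female_ratio Maximum female/male normalized coverage ratio for
#'   a male-specific call (default 0.1).
#' @param alpha Significance level for the binomial test (default 0.01),
#'   Bonferroni-corrected across families.
#' @return `families` with added columns `male_cov_norm`, `female_cov_norm`,
#'   `p_binom`, `label`.
#' @export
classify_male_specific <- function(families, male_depth, female_depth,
                                   min_male_cov, max_female_ratio = 0.1,
                                   alpha = 0.01) {
  need <- c("name", "male_reads", "female_reads", "male_cov", "female_cov")
  missing_cols <- setdiff(need, names(families))
  if (length(missing_cols))
    stop("families table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  mean_depth <- (male_depth + female_depth) / 2
  fam <- families
  fam$male_cov_norm <- fam$male_cov * mean_depth / male_depth
  fam$female_cov_norm <- fam$female_cov * mean_depth / female_depth

  # one-sided test: is the female read share lower than the depth share?
  p0 <- female_depth / (male_depth + female_depth)
  fam$p_binom <- vapply(seq_len(nrow(fam)), function(i) {
    tot <- fam$male_reads[i] + fam$female_reads[i]
    if (tot == 0) return(1)
    stats::binom.test(fam$female_reads[i], tot, p = p0,
                      alternative = "less")$p.value
  }, numeric(1))
  alpha_bonf <- alpha / nrow(fam)

  ratio <- ifelse(fam$male_cov_norm > 0,
                  fam$female_cov_norm / fam$male_cov_norm, Inf)
  high_male <- fam$male_cov_norm >= min_male_cov
  female_absent <- fam$female_cov_norm == 0
  female_low <- ratio <= max_female_ratio & fam$p_binom < alpha_bonf
  fam$label <- ifelse(high_male & (female_absent | female_low),
                      "male_specific",
                      ifelse(fam$male_cov_norm == 0 & fam$female_cov_norm > 0,
                             "female_only", "shared"))
  attr(fam, "params") <- list(min_male_cov = min_male_cov,
                              max_female_ratio = max_female_ratio,
                              alpha = alpha, alpha_bonferroni = alpha_bonf)
  fam
}

#' Relative mark enrichment of a repeat family
#'
#' GC-corrected ChIP over GC-corrected input coverage, scaled by the sample's
#' spike factor, and divided by the sample's genome-wide signal, giving
#' enrichment relative to genome-wide levels. The input ratio removes copy
#' number, so families of very different abundance are comparable. Zero
#' input yields a missing value with a flag.
#'
#' @param chip_cov,input_cov Depth-normalized mean coverage of the family in
#'   the ChIP and input library (vectorized).
#' @param repeat_gc GC fraction(s) of the repeat consensus.
#' @param gc_model A `gc_model` (or `NULL` to skip GC correction).
#' @param spike_factor Spike scaling factor of the sample.
#' @param genomewide_signal The sample's genome-wide mean signal.
#' @return List with `enrichment` (numeric, `NA` where input is 0) and
#'   `zero_input` (logical flag).
#' @export
repeat_enrichment <- function(chip_cov, input_cov, repeat_gc = NULL,
                              gc_model = NULL, spike_factor = 1,
                              genomewide_signal = 1) {
  if (!is.null(gc_model)) {
    chip_cov <- gc_correct_repeat(chip_cov, repeat_gc, gc_model)$value
    input_cov <- gc_correct_repeat(input_cov, repeat_gc, gc_model)$value
  }
  zero_input <- !is.na(input_cov) & input_cov == 0
  enr <- (chip_cov / input_cov) * spike_factor / genomewide_signal
  enr[zero_input] <- NA_real_
  list(enrichment = enr, zero_input = zero_input)
}

#' Genomic copy number from input coverage
#'
#' Copies are estimated as the family's mean per-bp input coverage divided by
#' the mean per-bp input coverage of annotated single-copy euchromatin.
#'
#' @param family_input_cov Mean per-bp input coverage of the family
#'   (vectorized).
#' @param single_copy_baseline_cov Mean per-bp input coverage over single-copy
#'   regions (> 0).
#' @return Estimated copy number(s).
#' @export
copy_number_estimate <- function(family_input_cov, single_copy_baseline_cov) {
  if (single_copy_baseline_cov <= 0)
    stop("single-copy baseline coverage must be positive")
  family_input_cov / single_copy_baseline_cov
}

#' Copy-number-corrected expression
#'
#' Divides expression (CPM, length-normalized per kb upstream of this call)
#' by genomic copies, distinguishing true per-copy derepression from mere
#' dosage. Zero copies with nonzero expression is flagged (expression from an
#' unassembled source) and yields `NA` rather than infinity.
#'
#' @param expression_cpm Expression value(s).
#' @param copies Genomic copy number(s).
#' @return List with `per_copy` and `flag_no_copies` (logical).
#' @export
cn_corrected_expression <- function(expression_cpm, copies) {
  if (any(copies < 0, na.rm = TRUE)) stop("copies must be >= 0")
  flag <- !is.na(copies) & copies == 0 & expression_cpm > 0
  out <- expression_cpm / copies
  out[copies == 0] <- NA_real_
  list(per_copy = out, flag_no_copies = flag)
}

#' Length-normalized CPM over a count universe
#'
#' Counts per million over the combined repeat + gene universe, then per kb
#' of feature length; the expression unit fed to
#' [cn_corrected_expression()].
#'
#' @param counts Counts for the features of interest.
#' @param total_counts Library total over the whole universe.
#' @param length_bp Feature lengths in bp.
#' @return Numeric CPM per kb.
#' @export
cpm_per_kb <- function(counts, total_counts, length_bp) {
  counts / total_counts * 1e6 / (length_bp / 1000)
}
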