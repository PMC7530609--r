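#' Spike-ratio scaling factor
#'
#' The quantitative scaling between samples is carried by the spike fractions
#' `phi = S / (M + S)` of the ChIP and input libraries: a sample whose target
#' chromatin recovers less of the mark yields a ChIP library richer in spike
#' reads. The factor is `phi_input / phi_chip`, so a genome-wide loss of the
#' mark lowers it. Combined with library-size normalization in
#' [window_signal()], the per-window signal reduces algebraically to
#' `(c_w / i_w) * (S_input / S_chip)`.
#'
#' @param chip,input [library_composition()]s of the ChIP and input library.
#' @return Scaling factor (positive scalar).
#' @export
spike_scaling_ratio <- function(chip, input) {
  stopifnot(inherits(chip, "library_composition"),
            inherits(input, "library_composition"))
  if (chip$spike_reads <= 0 || input$spike_reads <= 0)
    stop("zero spike reads: spike-in failed, ratio undefined")
  if (chip$target_reads <= 0 || input$target_reads <= 0)
    stop("zero target reads")
  spike_fraction(input) / spike_fraction(chip)
}

#' Spike-regression scaling factor
#'
#' Alternative estimate of the same scaling: a least-squares slope through
#' the origin of depth-normalized spike ChIP coverage on depth-normalized
#' spike input coverage, fitted genome-wide over spike windows. The factor is
#' the reciprocal slope; on exactly proportional (noiseless) spike profiles
#' it coincides with the ratio method. Factors from several samples can be
#' put on the ratio method's scale with [align_regression_factors()].
#'
#' @inheritParams spike_scaling_ratio
#' @param min_windows Minimum spike windows with nonzero input (default 20).
#' @return List with `slope` (`a = sum(xy)/sum(x^2)`) and `factor` (`1/a`).
#' @export
spike_scaling_regression <- function(chip, input, min_windows = 20L) {
  stopifnot(inherits(chip, "library_composition"),
            inherits(input, "library_composition"))
  y <- chip$spike_coverage / chip$total
  x <- input$spike_coverage / input$total
  if (length(x) != length(y)) stop("spike coverage vectors differ in length")
  if (all(x == 0) || all(y == 0))
    stop("degenerate all-zero spike coverage")
  if (sum(x > 0) < min_windows)
    stop("need >= ", min_windows, " spike windows with nonzero input")
  a <- sum(x * y) / sum(x * x)
  list(slope = a, factor = 1 / a)
}

#' Put regression factors on the ratio method's scale
#'
#' Rescales a vector of regression factors so a designated reference sample's
#' factor equals its ratio-method value.
#'
#' @param regression_factors Numeric vector of factors from
#'   [spike_scaling_regression()].
#' @param ratio_factor_reference Ratio-method factor of the reference sample.
#' @param reference Index of the reference sample (default 1).
#' @return Rescaled factors.
#' @export
align_regression_factors <- function(regression_factors,
                                     ratio_factor_reference,
                                     reference = 1L) {
  regression_factors * ratio_factor_reference /
    regression_factors[reference]
}

#' Spike-normalized per-window ChIP signal
#'
#' `signal_w = [(c_w / (Mc+Sc)) / (i_w / (Mi+Si))] * factor`: ChIP and input
#' window coverage are each normalized by total library size (target plus
#' spike reads), ratioed, and multiplied by the spike scaling factor. The
#' input ratio absorbs ploidy and genome-size differences between samples;
#' the spike factor restores the absolute scale of mark recovery. Windows
#' with zero input are missing unless a pseudocount is enabled; masked
#' windows are always missing.
#'
#' @inheritParams spike_scaling_ratio
#' @param factor Scaling factor (ratio or aligned regression method).
#' @param pseudocount Added to both ChIP and input window coverage when > 0.
#' @param mask Optional logical per window; `TRUE` windows become missing.
#' @return A [window_track()] of signal with attributes `method`, `factor`,
#'   `pseudocount`.
#' @export
window_signal <- function(chip, input, factor, pseudocount = 0, mask = NULL) {
  stopifnot(inherits(chip, "library_composition"),
            inherits(input, "library_composition"))
  if (!same_windows(chip$coverage, input$coverage))
    stop("ChIP and input are not on identical windows")
  c_w <- chip$coverage$value + pseudocount
  i_w <- input$coverage$value + pseudocount
  sig <- (c_w / chip$total) / (i_w / input$total) * factor
  sig[i_w == 0] <- NA_real_
  if (!is.null(mask)) sig[mask] <- NA_real_
  out <- chip$coverage
  out$value <- sig
  attr(out, "method") <- "spike_ratio"
  attr(out, "factor") <- factor
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Unspiked per-window ChIP signal
#'
#' Plain depth-normalized ChIP/input ratio using target reads only:
#' `(c_w / Mc) / (i_w / Mi)`. Insensitive to genome-wide changes in mark
#' abundance (the normalization absorbs them), which is exactly why the
#' spike is needed for cross-karyotype quantification.
#'
#' @inheritParams window_signal
#' @return A [window_track()] of signal, attribute `method = "unspiked"`.
#' @export
unspiked_signal <- function(chip, input, pseudocount = 0, mask = NULL) {
  stopifnot(inherits(chip, "library_composition"),
            inherits(input, "library_composition"))
  if (!same_windows(chip$coverage, input$coverage))
    stop("ChIP and input are not on identical windows")
  c_w <- chip$coverage$value + pseudocount
  i_w <- input$coverage$value + pseudocount
  sig <- (c_w / chip$target_reads) / (i_w / input$target_reads)
  sig[i_w == 0] <- NA_real_
  if (!is.null(mask)) sig[mask] <- NA_real_
  out <- chip$coverage
  out$value <- sig
  attr(out, "method") <- "unspiked"
  attr(out, "factor") <- 1
  attr(out, "pseudocount") <- pseudocount
  out
}
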