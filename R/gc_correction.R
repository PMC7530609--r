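#' Fit a binned GC coverage model
#'
#' Estimates expected coverage as a function of GC content by averaging
#' observed window coverage within GC bins of fixed width (default 5\%) over
#' the mappable (unmasked) windows. Bins are half-open `[lo, hi)` with the
#' last bin closed, so GC = 1 falls in the top bin. Bins used by fewer than
#' `min_windows` windows are flagged unreliable (a warning is raised);
#' empty bins carry `NA` expectation.
#'
#' @param coverage_track A [window_track()] of observed coverage.
#' @param gc_track Numeric GC fraction per window (same windows) or a
#'   `window_track` carrying GC in `value`.
#' @param mask Logical per window; `TRUE` windows (non-mappable/cross-map)
#'   are excluded from fitting. `NULL` for none.
#' @param bin_width GC bin width (default 0.05).
#' @param min_windows Minimum windows per used bin before it is flagged.
#' @return Object of class `gc_model`: data frame with `bin_lo`, `bin_hi`,
#'   `expected`, `n`, `reliable`.
#' @export
fit_gc_model <- function(coverage_track, gc_track, mask = NULL,
                         bin_width = 0.05, min_windows = 10L) {
  gc <- gc_values(gc_track, coverage_track)
  v <- coverage_track$value
  if (is.null(mask)) mask <- rep(FALSE, length(v))
  stopifnot(length(mask) == length(v))
  keep <- !mask & !is.na(v) & !is.na(gc)
  if (any(gc[keep] < 0 | gc[keep] > 1)) stop("GC values outside [0, 1]")
  n_bins <- ceiling(1 / bin_width)
  idx <- gc_bin_index(gc, bin_width)
  model <- data.frame(bin_lo = (seq_len(n_bins) - 1) * bin_width,
                      bin_hi = pmin(seq_len(n_bins) * bin_width, 1))
  model$expected <- NA_real_
  model$n <- 0L
  for (b in seq_len(n_bins)) {
    sel <- keep & idx == b
    model$n[b] <- sum(sel)
    if (model$n[b] > 0) model$expected[b] <- mean(v[sel])
  }
  model$reliable <- model$n >= min_windows
  unreliable_used <- model$n > 0 & !model$reliable
  if (any(unreliable_used))
    warning(sum(unreliable_used), " GC bin(s) have fewer than ", min_windows,
            " windows and are flagged unreliable")
  class(model) <- c("gc_model", "data.frame")
  attr(model, "bin_width") <- bin_width
  attr(model, "fitted_from") <- "per input library (unmasked windows)"
  model
}

gc_bin_index <- function(gc, bin_width) {
  n_bins <- ceiling(1 / bin_width)
  pmin(floor(gc / bin_width) + 1L, n_bins)
}

gc_values <- function(gc_track, ref_track = NULL) {
  if (inherits(gc_track, "window_track")) {
    if (!is.null(ref_track) && !same_windows(gc_track, ref_track))
      stop("GC track windows do not match the coverage track")
    gc_track$value
  } else as.numeric(gc_track)
}

#' GC-correct a coverage track
#'
#' Divides each window's value by the model's expected coverage for its GC
#' bin. Windows in empty bins (no expectation) become missing; the count of
#' such windows is attached as attribute `n_missing_bin`. Optionally rescales
#' the corrected track so its mean matches the raw mean, keeping downstream
#' ratios comparable.
#'
#' @param track A [window_track()] to correct.
#' @param gc_track GC per window (vector or `window_track`).
#' @param model A `gc_model` from [fit_gc_model()].
#' @param preserve_mean Rescale corrected values to the raw mean
#'   (default FALSE).
#' @return A corrected [window_track()].
#' @export
gc_correct_track <- function(track, gc_track, model, preserve_mean = FALSE) {
  stopifnot(inherits(model, "gc_model"))
  gc <- gc_values(gc_track, track)
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) stop("GC values outside [0, 1]")
  bw <- attr(model, "bin_width")
  expected <- model$expected[gc_bin_index(gc, bw)]
  corrected <- track$value / expected
  out <- track
  out$value <- corrected
  attr(out, "n_missing_bin") <- sum(!is.na(track$value) & is.na(expected))
  if (preserve_mean) {
    raw_mean <- mean(track$value, na.rm = TRUE)
    cor_mean <- mean(out$value, na.rm = TRUE)
    if (is.finite(cor_mean) && cor_mean > 0)
      out$value <- out$value * raw_mean / cor_mean
  }
  out
}

#' GC-correct a repeat family's coverage
#'
#' Same correction as [gc_correct_track()] but keyed on the repeat consensus
#' GC content rather than a window's.
#'
#' @param repeat_coverage Observed mean coverage of the repeat (vectorized).
#' @param repeat_gc GC fraction of the repeat consensus.
#' @param model A `gc_model`.
#' @return List with `value` (corrected coverage, `NA` where the bin is
#'   empty) and `unreliable` (logical: bin flagged unreliable).
#' @export
gc_correct_repeat <- function(repeat_coverage, repeat_gc, model) {
  stopifnot(inherits(model, "gc_model"))
  if (any(repeat_gc < 0 | repeat_gc > 1, na.rm = TRUE))
    stop("GC values outside [0, 1]")
  bw <- attr(model, "bin_width")
  b <- gc_bin_index(repeat_gc, bw)
  unreliable <- !model$reliable[b]
  if (any(unreliable, na.rm = TRUE))
    warning("repeat GC falls in unreliable GC bin(s)")
  list(value = repeat_coverage / model$expected[b], unreliable = unreliable)
}
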