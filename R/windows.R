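#' Subtraction track between two samples
#'
#' Per-window signed difference A - B between two signal tracks on identical
#' windows (same mark, same method). The absolute difference is attached as
#' column `abs_diff` when `keep_abs = TRUE`.
#'
#' @param signal_A,signal_B [window_track()]s on identical windows.
#' @param keep_abs Also carry `|A - B|` (default TRUE).
#' @return A [window_track()] of differences.
#' @export
subtraction_track <- function(signal_A, signal_B, keep_abs = TRUE) {
  if (!same_windows(signal_A, signal_B))
    stop("tracks are not on identical windows")
  out <- signal_A
  out$value <- signal_A$value - signal_B$value
  if (keep_abs) out$abs_diff <- abs(out$value)
  out
}

#' Rank-sum (Mann-Whitney/Wilcoxon) test
#'
#' Two-sample rank test as used for all region and boundary comparisons:
#' exact null when `min(n) <= 8` and there are no ties, normal approximation
#' with tie and continuity correction otherwise.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `U` (Mann-Whitney U for `x` vs `y`), `p`, and `method`.
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0 || length(y) == 0) stop("empty input to rank_sum_test")
  if (length(unique(c(x, y))) == 1)  # degenerate: no rank information at all
    return(list(U = length(x) * length(y) / 2, p = 1, method = "degenerate"))
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- min(length(x), length(y)) <= 8 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = use_exact, correct = TRUE)
  )
  list(U = unname(ht$statistic), p = ht$p.value,
       method = if (use_exact) "exact" else "normal approximation with ties/continuity correction")
}

#' Summarize signal over an annotated region
#'
#' Boxplot-style summary of all window values whose midpoints fall in blocks
#' with the given region label: quartiles by linear interpolation (type 7),
#' whiskers at the most extreme points within 1.5 IQR of the box, and a
#' two-sided rank-sum p-value against a designated reference sample's values
#' over the same region.
#'
#' @param signal A [window_track()].
#' @param blocks Data frame `chrom`, `start`, `end`, `region` (as in a
#'   `genome_model`).
#' @param region Region label (e.g. `"euchromatin"`, `"pericentromere_2L"`,
#'   `"dot"`, `"Y_het"`); `"pericentromere"` matches all pericentromeric
#'   blocks.
#' @param reference_signal Optional [window_track()] of the reference sample
#'   (same windows); when given, a two-sided rank-sum p-value is computed.
#' @return Object of class `region_summary`: list with `region`, `n`,
#'   `values`, `quartiles` (Q1/median/Q3), `whiskers`, `mean`, `p`,
#'   `reference_n`.
#' @export
region_summary <- function(signal, blocks, region, reference_signal = NULL) {
  sel <- region_window_index(signal, blocks, region)
  v <- signal$value[sel]
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("region '", region, "' has fewer than 2 windows with signal")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr; hi_fence <- q[3] + 1.5 * iqr
  whisk <- c(min(v[v >= lo_fence]), max(v[v <= hi_fence]))
  p <- NA_real_; ref_n <- NA_integer_
  if (!is.null(reference_signal)) {
    rv <- reference_signal$value[region_window_index(reference_signal, blocks,
                                                     region)]
    rv <- rv[!is.na(rv)]
    ref_n <- length(rv)
    p <- rank_sum_test(v, rv)$p
  }
  structure(list(region = region, n = length(v), values = v,
                 quartiles = c(Q1 = q[1], median = q[2], Q3 = q[3]),
                 whiskers = c(lower = whisk[1], upper = whisk[2]),
                 mean = mean(v), p = p, reference_n = ref_n,
                 quartile_convention = "type 7 (linear interpolation)"),
            class = "region_summary")
}

region_window_index <- function(signal, blocks, region) {
  hit_blocks <- if (region == "pericentromere")
    grepl("^pericentromere", blocks$region) else blocks$region == region
  bl <- blocks[hit_blocks, , drop = FALSE]
  if (nrow(bl) == 0) stop("no blocks labeled '", region, "'")
  mid <- (signal$start + signal$end) / 2
  sel <- rep(FALSE, nrow(signal))
  for (j in seq_len(nrow(bl)))
    sel <- sel | (signal$chrom == bl$chrom[j] & mid >= bl$start[j] &
                    mid < bl$end[j])
  sel
}

#' Profile signal around a heterochromatin/euchromatin boundary
#'
#' Collects windows within `flank` bp of an arm's annotated boundary,
#' assigns each to the heterochromatin side ("inside", positions below the
#' boundary) or euchromatin side ("outside") by window midpoint, and
#' summarizes the two sides with means, medians and a rank-sum test.
#'
#' @param signal A [window_track()].
#' @param chrom Arm name.
#' @param boundary Boundary position in bp.
#' @param flank Flank width in bp on each side (default 1e6). Truncated with
#'   a warning where it exceeds the arm extent.
#' @param arm_length Optional arm length for truncation detection.
#' @return Object of class `boundary_profile`: list with `chrom`, `boundary`,
#'   `flank`, `windows` (data frame with `midpoint`, `value`, `side`),
#'   `inside_mean`, `outside_mean`, `inside_median`, `outside_median`,
#'   `U`, `p`.
#' @export
boundary_profile <- function(signal, chrom, boundary, flank = 1e6,
                             arm_length = NULL) {
  on_arm <- signal$chrom == chrom
  if (!any(on_arm)) stop("no windows on ", chrom)
  if (is.null(arm_length)) arm_length <- max(signal$end[on_arm])
  if (boundary - flank < 0 || boundary + flank > arm_length)
    warning("flank exceeds arm extent; profile truncated")
  mid <- (signal$start + signal$end) / 2
  sel <- on_arm & mid >= boundary - flank & mid < boundary + flank
  w <- data.frame(midpoint = mid[sel], value = signal$value[sel])
  w$side <- ifelse(w$midpoint < boundary, "inside", "outside")
  w <- w[!is.na(w$value), , drop = FALSE]
  vin <- w$value[w$side == "inside"]; vout <- w$value[w$side == "outside"]
  if (length(vin) == 0 || length(vout) == 0)
    stop("boundary profile has an empty side; check boundary/flank")
  rt <- rank_sum_test(vin, vout)
  structure(list(chrom = chrom, boundary = boundary, flank = flank,
                 windows = w,
                 inside_mean = mean(vin), outside_mean = mean(vout),
                 inside_median = stats::median(vin),
                 outside_median = stats::median(vout),
                 U = rt$U, p = rt$p),
            class = "boundary_profile")
}

#' Boundary contrast and spreading shift
#'
#' Quantifies how sharp a boundary is and where the signal transition
#' actually sits relative to the annotation. `boundary_contrast` is
#' `(mean_in - mean_out) / (mean_in + mean_out)`; values near 0 mean the
#' boundary has been diluted away. The midpoint shift fits a monotone step
#' to the profile (isotonic regression of signal on distance into
#' heterochromatin) and reports where the fit crosses half-height, minus the
#' annotated boundary; positive shifts mean the mark has spread outward into
#' normally euchromatic sequence.
#'
#' @param profile A [boundary_profile()] with at least 10 windows per side.
#' @return List with `boundary_contrast` and `midpoint_shift` (bp; `NA` when
#'   the fit is degenerate, e.g. a flat profile).
#' @export
spreading_index <- function(profile) {
  stopifnot(inherits(profile, "boundary_profile"))
  w <- profile$windows
  if (min(table(w$side)) < 10)
    stop("need >= 10 windows per side for spreading_index")
  contrast <- (profile$inside_mean - profile$outside_mean) /
    (profile$inside_mean + profile$outside_mean)
  # signed distance into heterochromatin; signal should increase with d
  d <- profile$boundary - w$midpoint
  ord <- order(d)
  d <- d[ord]; v <- w$value[ord]
  fit <- stats::isoreg(d, v)$yf
  lo <- min(fit); hi <- max(fit)
  shift <- NA_real_
  if (is.finite(lo) && is.finite(hi) && hi > lo) {
    half <- (lo + hi) / 2
    i <- which(fit >= half)[1]
    d_cross <- if (i == 1) d[1] else {
      # linear interpolation between the flanking fitted points
      d[i - 1] + (half - fit[i - 1]) / (fit[i] - fit[i - 1]) * (d[i] - d[i - 1])
    }
    shift <- -d_cross
  }
  list(boundary_contrast = contrast, midpoint_shift = shift)
}

#' Mean signal per gene
#'
#' Length-weighted mean of the window signal overlapping each gene (weights
#' are the overlap in bp). Genes overlapping masked/missing windows are
#' flagged; genes outside the assembly get `NA` and a flag rather than an
#' error.
#'
#' @param signal A [window_track()].
#' @param genes Data frame `gene`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Data frame `gene`, `signal`, `masked_overlap` (logical),
#'   `outside_assembly` (logical).
#' @export
gene_signal <- function(signal, genes) {
  mid_na <- is.na(signal$value)
  out <- data.frame(gene = genes$gene, signal = NA_real_,
                    masked_overlap = FALSE, outside_assembly = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) {
    on_chrom <- which(signal$chrom == genes$chrom[i])
    if (length(on_chrom) == 0) { out$outside_assembly[i] <- TRUE; next }
    ov_bp <- pmin(signal$end[on_chrom], genes$end[i]) -
      pmax(signal$start[on_chrom], genes$start[i])
    hit <- on_chrom[ov_bp > 0]
    ov_bp <- ov_bp[ov_bp > 0]
    if (length(hit) == 0) { out$outside_assembly[i] <- TRUE; next }
    v <- signal$value[hit]
    if (any(is.na(v))) out$masked_overlap[i] <- TRUE
    keep <- !is.na(v)
    if (any(keep))
      out$signal[i] <- sum(v[keep] * ov_bp[keep]) / sum(ov_bp[keep])
  }
  out
}

#' Concordance QC between two signal tracks
#'
#' Pearson correlation over shared non-missing windows plus the overlap of
#' the top quantile of windows (default top 40\%) between the two tracks,
#' reported as `|topA intersect topB| / (q * n)`.
#'
#' @param signal_A,signal_B [window_track()]s on identical windows.
#' @param top_q Top quantile in (0, 1); default 0.40.
#' @return List with `pearson_r`, `top_overlap`, `n`, `k` (top set size).
#' @export
qc_concordance <- function(signal_A, signal_B, top_q = 0.40) {
  if (!same_windows(signal_A, signal_B))
    stop("tracks are not on identical windows")
  if (top_q <= 0 || top_q >= 1) stop("top_q must lie in (0, 1)")
  keep <- !is.na(signal_A$value) & !is.na(signal_B$value)
  if (sum(keep) < 3) stop("fewer than 3 shared windows")
  a <- signal_A$value[keep]; b <- signal_B$value[keep]
  n <- length(a)
  k <- max(1L, round(top_q * n))
  top_a <- order(a, decreasing = TRUE)[seq_len(k)]
  top_b <- order(b, decreasing = TRUE)[seq_len(k)]
  list(pearson_r = stats::cor(a, b),
       top_overlap = length(intersect(top_a, top_b)) / k,
       n = n, k = k)
}

#' Benjamini-Hochberg adjust a vector of region/karyotype p-values
#'
#' Convenience wrapper: reports q-values alongside the unadjusted rank-sum
#' p-values accumulated over multiple regions and karyotypes.
#'
#' @param p Numeric vector of p-values.
#' @return Numeric vector of BH q-values.
#' @export
adjust_region_pvalues <- function(p) stats::p.adjust(p, method = "BH")
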