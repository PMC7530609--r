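#' Default toy chromosome-arm table
#'
#' A scaled-down fly-like genome: four major autosomal arms, an X, a fully
#' heterochromatic Y, and a small, fully heterochromatic dot chromosome.
#' `het_fraction` is the fraction of the arm occupied by the pericentromeric
#' heterochromatin block, which sits at the centromere-proximal (low
#' coordinate) end of each arm.
#'
#' @return Data frame with columns `name`, `length`, `het_fraction`, `type`.
#' @export
default_arms <- function() {
  data.frame(
    name = c("2L", "2R", "3L", "3R", "X", "Y", "4"),
    length = c(2e6, 2e6, 2e6, 2e6, 1.5e6, 1e6, 4e5),
    het_fraction = c(0.3, 0.3, 0.3, 0.3, 0.3, 1, 1),
    type = c("autosome", "autosome", "autosome", "autosome", "X", "Y", "dot"),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic genome model
#'
#' Tiles each arm into fixed-width windows, annotates
#' euchromatin/heterochromatin blocks (one boundary per non-dot, non-Y arm,
#' heterochromatin at the centromere-proximal end), draws a per-window GC
#' track (heterochromatic windows are AT-richer, as repeat-dense DNA tends to
#' be), designates a cross-mapping mask, and creates a table of repeat
#' families with sex-chromosome-resolved copy numbers. A fixed seed gives a
#' byte-identical model.
#'
#' @param arms Arm table as from [default_arms()]; columns `name`, `length`,
#'   `het_fraction` in `[0,1]`, `type` in autosome/X/Y/dot.
#' @param window_width Window width in bp (default 5000).
#' @param crossmap_fraction Fraction of windows masked for cross-mapping
#'   artifacts (default 0.025, the residual cross-mapping rate of short
#'   reads between sufficiently diverged species).
#' @param n_repeat_families,n_y_linked Number of repeat families and how many
#'   of them are Y-linked (zero copies in females).
#' @param n_spike_windows Number of windows representing the spike species'
#'   genome.
#' @param seed Integer seed.
#'
#' @return Object of class `genome_model`: list with `arms`, `windows`
#'   (data frame chrom/start/end/arm_type), `blocks` (chrom/start/end/region),
#'   `boundaries` (chrom/pos), `gc` (per window), `crossmap_mask` (logical per
#'   window), `repeat_families`, `spike` (list `n`, `gc`), `window_width`,
#'   `seed`.
#' @export
build_genome_model <- function(arms = default_arms(),
                               window_width = 5000L,
                               crossmap_fraction = 0.025,
                               n_repeat_families = 60L,
                               n_y_linked = 15L,
                               n_spike_windows = 200L,
                               seed = 1L) {
  if (any(arms$het_fraction < 0 | arms$het_fraction > 1))
    stop("het_fraction must lie in [0, 1]")
  if (any(arms$length <= 0)) stop("arm lengths must be positive")
  W <- as.integer(window_width)

  set.seed(seed)

  win_list <- lapply(seq_len(nrow(arms)), function(i) {
    L <- arms$length[i]
    starts <- seq(0, L - 1, by = W)
    data.frame(chrom = arms$name[i], start = starts,
               end = pmin(starts + W, L),
               arm_type = arms$type[i], stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, win_list)
  # canonical window_track order, so per-window vectors stay aligned with
  # any track built on these windows
  windows <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  rownames(windows) <- NULL

  # blocks + boundaries: het occupies [0, b), eu [b, L); b snapped to the grid
  blocks <- list(); bounds <- list()
  for (i in seq_len(nrow(arms))) {
    nm <- arms$name[i]; L <- arms$length[i]
    ty <- arms$type[i]; f <- arms$het_fraction[i]
    if (ty %in% c("dot", "Y")) {
      region <- if (ty == "dot") "dot" else "Y_het"
      blocks[[length(blocks) + 1]] <-
        data.frame(chrom = nm, start = 0, end = L, region = region)
      next
    }
    b <- W * round(L * f / W)
    if (b > 0)
      blocks[[length(blocks) + 1]] <-
        data.frame(chrom = nm, start = 0, end = b,
                   region = paste0("pericentromere_", nm))
    if (b < L)
      blocks[[length(blocks) + 1]] <-
        data.frame(chrom = nm, start = b, end = L, region = "euchromatin")
    bounds[[length(bounds) + 1]] <- data.frame(chrom = nm, pos = b)
  }
  blocks <- do.call(rbind, blocks)
  boundaries <- do.call(rbind, bounds)

  # GC per window: heterochromatin AT-richer and broader than euchromatin
  mid <- (windows$start + windows$end) / 2
  is_het <- window_in_het(windows, blocks)
  gc <- numeric(nrow(windows))
  gc[is_het]  <- stats::rbeta(sum(is_het), 6, 14)    # mean 0.30
  gc[!is_het] <- stats::rbeta(sum(!is_het), 10.7, 13.1) # mean 0.45
  gc <- pmin(pmax(gc, 0), 1)

  n_win <- nrow(windows)
  mask <- rep(FALSE, n_win)
  mask[sample.int(n_win, max(1L, round(crossmap_fraction * n_win)))] <- TRUE

  repeat_families <- make_repeat_families(n_repeat_families, n_y_linked)

  spike <- list(n = as.integer(n_spike_windows),
                gc = stats::rbeta(n_spike_windows, 25, 35))

  structure(list(arms = arms, windows = windows, blocks = blocks,
                 boundaries = boundaries, gc = gc, crossmap_mask = mask,
                 repeat_families = repeat_families, spike = spike,
                 window_width = W, seed = as.integer(seed)),
            class = "genome_model")
}

# TRUE for windows whose midpoint lies in a non-euchromatin block
window_in_het <- function(windows, blocks) {
  mid <- (windows$start + windows$end) / 2
  out <- rep(FALSE, nrow(windows))
  het_blocks <- blocks[blocks$region != "euchromatin", , drop = FALSE]
  for (j in seq_len(nrow(het_blocks))) {
    hit <- windows$chrom == het_blocks$chrom[j] &
      mid >= het_blocks$start[j] & mid < het_blocks$end[j]
    out[hit] <- TRUE
  }
  out
}

make_repeat_families <- function(n, n_y) {
  if (n_y > n) stop("n_y_linked cannot exceed n_repeat_families")
  name <- sprintf("rep%03d", seq_len(n))
  length_bp <- round(stats::runif(n, 300, 3000))
  gc <- stats::rbeta(n, 7, 13)
  copies_auto <- numeric(n); copies_X <- numeric(n); copies_Y <- numeric(n)
  idx_y <- seq_len(n_y)
  copies_Y[idx_y] <- round(stats::runif(n_y, 15, 150))
  idx_rest <- setdiff(seq_len(n), idx_y)
  copies_auto[idx_rest] <- round(stats::runif(length(idx_rest), 2, 30))
  # a few X-enriched families among the shared ones
  idx_x <- idx_rest[seq_len(min(5L, length(idx_rest)))]
  copies_X[idx_x] <- round(stats::runif(length(idx_x), 5, 20))
  data.frame(name = name, length = length_bp, gc = gc,
             copies_auto = copies_auto, copies_X = copies_X,
             copies_Y = copies_Y,
             label_true = ifelse(copies_Y > 0 & copies_auto == 0 &
                                   copies_X == 0, "male_specific", "shared"),
             stringsAsFactors = FALSE)
}

#' Per-karyotype copy number of each repeat family
#' @param genome A `genome_model`.
#' @param karyotype A [karyotype_spec()].
#' @return Numeric vector of genomic copies per family.
#' @export
repeat_copy_number <- function(genome, karyotype) {
  rf <- genome$repeat_families
  rf$copies_auto * karyotype$autosome_ploidy +
    rf$copies_X * karyotype$n_X + rf$copies_Y * karyotype$n_Y
}

# Window copy number for a karyotype (autosome/dot -> autosome ploidy).
window_copy_number <- function(genome, karyotype) {
  ct <- c(autosome = karyotype$autosome_ploidy, dot = karyotype$autosome_ploidy,
          X = karyotype$n_X, Y = karyotype$n_Y)
  unname(ct[genome$windows$arm_type])
}

#' Physical heterochromatin content of an instantiated karyotype
#'
#' Sums non-euchromatic block lengths weighted by the karyotype's copy number
#' of each arm. Used to check that the generator reproduces the expected
#' ordering of heterochromatin content across karyotypes.
#'
#' @inheritParams repeat_copy_number
#' @return Heterochromatin content in Mb.
#' @export
het_content_mb <- function(genome, karyotype) {
  ct <- c(autosome = karyotype$autosome_ploidy, dot = karyotype$autosome_ploidy,
          X = karyotype$n_X, Y = karyotype$n_Y)
  arm_type <- genome$arms$type[match(genome$blocks$chrom, genome$arms$name)]
  het <- genome$blocks$region != "euchromatin"
  sum((genome$blocks$end - genome$blocks$start)[het] *
        unname(ct[arm_type[het]])) / 1e6
}

#' GC-dependent coverage bias factor
#'
#' Multiplicative coverage bias `exp(beta * (g - 0.5))`. By default `g` is the
#' window's GC snapped to the midpoint of its 5\%-wide GC bin: the bias is
#' modeled at the same resolution at which the binned correction estimates
#' it, so the estimator is well specified on synthetic data. `resolution =
#' "continuous"` uses the raw GC value instead, leaving a within-bin residual
#' that the binned correction cannot remove.
#'
#' @param gc GC fractions in `[0,1]`.
#' @param beta Bias strength (0 = no bias).
#' @param resolution `"bin"` (default) or `"continuous"`.
#' @param bin_width GC bin width used for `"bin"` resolution.
#' @return Multiplicative factors, same length as `gc`.
#' @export
gc_bias_factor <- function(gc, beta, resolution = c("bin", "continuous"),
                           bin_width = 0.05) {
  resolution <- match.arg(resolution)
  g <- if (resolution == "bin") {
    idx <- pmin(floor(gc / bin_width), ceiling(1 / bin_width) - 1)
    (idx + 0.5) * bin_width
  } else gc
  exp(beta * (g - 0.5))
}
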