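#' Library composition for one sequencing library
#'
#' Holds the split of a library between target-species reads (`M`, with their
#' per-window coverage) and spike-species reads (`S`, with per-spike-window
#' coverage). The spike fraction `phi = S / (M + S)` is the quantity the
#' spike-ratio normalization is built on.
#'
#' @param coverage A [window_track()] of target-genome window read counts.
#' @param spike_coverage Numeric vector of spike-genome window read counts.
#' @return Object of class `library_composition` with fields `coverage`,
#'   `spike_coverage`, `target_reads`, `spike_reads`, `total`.
#' @export
library_composition <- function(coverage, spike_coverage) {
  stopifnot(inherits(coverage, "window_track"))
  M <- sum(coverage$value, na.rm = TRUE)
  S <- sum(spike_coverage)
  structure(list(coverage = coverage, spike_coverage = spike_coverage,
                 target_reads = M, spike_reads = S, total = M + S),
            class = "library_composition")
}

#' @export
print.library_composition <- function(x, ...) {
  cat(sprintf("library_composition: M=%.0f target, S=%.0f spike (phi=%.4f), %d windows\n",
              x$target_reads, x$spike_reads, x$spike_reads / x$total,
              nrow(x$coverage)))
  invisible(x)
}

spike_fraction <- function(lib) lib$spike_reads / lib$total

#' Simulate a spiked ChIP/input experiment for one karyotype
#'
#' Generates paired ChIP and input library compositions over a genome model.
#' Input coverage is proportional to window copy number times a GC-bias
#' factor; ChIP coverage additionally carries the mark density (the sink
#' density in heterochromatic windows, the euchromatic floor elsewhere, with
#' the boundary moved outward by the karyotype's sink spreading). A fixed
#' amount of spike chromatin with a constant mark level is added to both
#' libraries, so spike read totals are karyotype-independent up to sampling.
#' A configured fraction of spike reads leaks into the cross-map-masked
#' target windows (those windows are excluded by downstream analyses). Reads
#' are multinomially sampled at the given depth; with `noise = FALSE` the
#' expected (non-integer) counts are returned, which is what the
#' noiseless-recovery tests consume.
#'
#' @param genome A `genome_model`.
#' @param karyotype A [karyotype_spec()].
#' @param sink A [sink_model()].
#' @param spike_amount Spike chromatin mass as a fraction of the diploid
#'   target chromatin mass (default 0.02).
#' @param depth Reads per library (>= 1e4).
#' @param noise Multinomial sampling (TRUE) or expected counts (FALSE).
#' @param seed Integer seed.
#' @param gc_beta GC-bias strength passed to [gc_bias_factor()].
#' @param gc_resolution GC-bias resolution, `"bin"` or `"continuous"`.
#' @param mark_dilution Extra global multiplier on target mark density
#'   (1 = none); used to plant known global dilution factors.
#' @param spike_mark_level Constant mark density of the spike chromatin.
#' @param crossmap_leak Fraction of spike reads leaking into masked target
#'   windows (default 0.025).
#'
#' @return Object of class `chip_experiment`: list with `chip` and `input`
#'   [library_composition()]s, `karyotype`, `mask` (logical per window),
#'   and `truth` (copy numbers, densities, GC factors, effective boundaries,
#'   dilution) for parameter-recovery tests.
#' @export
simulate_chip_experiment <- function(genome, karyotype, sink,
                                     spike_amount = 0.02,
                                     depth = 1e6,
                                     noise = TRUE,
                                     seed = 1L,
                                     gc_beta = 1,
                                     gc_resolution = "bin",
                                     mark_dilution = 1,
                                     spike_mark_level = 4,
                                     crossmap_leak = 0.025) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(karyotype, "karyotype_spec"),
            inherits(sink, "sink_model"))
  if (depth < 1e4) stop("depth must be >= 1e4 read-equivalents")
  if (spike_amount <= 0) stop("spike_amount must be > 0")
  if (nrow(genome$windows) == 0) stop("zero-length genome")

  set.seed(seed)
  win <- genome$windows
  copy <- window_copy_number(genome, karyotype)
  gcfac <- gc_bias_factor(genome$gc, gc_beta, gc_resolution)

  density <- mark_density_per_window(genome, karyotype, sink)
  dens_eff <- density * mark_dilution

  # chromatin masses (arbitrary units; one unit = one window-copy)
  w_in_target <- copy * gcfac
  w_ch_target <- copy * dens_eff * gcfac

  spike_gcfac <- gc_bias_factor(genome$spike$gc, gc_beta, gc_resolution)
  spike_mass <- spike_amount * 2 * nrow(win)  # fixed: diploid-equivalent
  w_in_spike <- spike_mass * spike_gcfac / sum(spike_gcfac)
  w_ch_spike <- w_in_spike * spike_mark_level

  leak_in <- crossmap_allocate(w_in_spike, crossmap_leak, genome$crossmap_mask,
                               w_in_target)
  leak_ch <- crossmap_allocate(w_ch_spike, crossmap_leak, genome$crossmap_mask,
                               w_in_target)

  input <- sample_library(w_in_target + leak_in$target,
                          leak_in$spike, depth, noise)
  chip <- sample_library(w_ch_target + leak_ch$target,
                         leak_ch$spike, depth, noise)

  mk_track <- function(v) window_track(win$chrom, win$start, win$end, v)
  structure(list(
    chip  = library_composition(mk_track(chip$target), chip$spike),
    input = library_composition(mk_track(input$target), input$spike),
    karyotype = karyotype,
    mask = genome$crossmap_mask,
    truth = list(copy = copy, density = dens_eff, gc_factor = gcfac,
                 mark_dilution = mark_dilution,
                 mark_density = sink_mark_density(sink, karyotype),
                 boundary_shift = sink_boundary_shift(sink, karyotype),
                 spike_mass = spike_mass, spike_mark_level = spike_mark_level)
  ), class = "chip_experiment")
}

# per-window mark density with the sink's boundary spreading applied
mark_density_per_window <- function(genome, karyotype, sink) {
  win <- genome$windows
  mid <- (win$start + win$end) / 2
  dens_het <- sink_mark_density(sink, karyotype)
  shift <- sink_boundary_shift(sink, karyotype)
  density <- rep(sink$euchromatin_floor, nrow(win))
  density[win$arm_type %in% c("Y", "dot")] <- dens_het
  for (j in seq_len(nrow(genome$boundaries))) {
    b_eff <- genome$boundaries$pos[j] + shift
    arm_len <- genome$arms$length[genome$arms$name == genome$boundaries$chrom[j]]
    b_eff <- min(b_eff, arm_len)
    hit <- win$chrom == genome$boundaries$chrom[j] & mid < b_eff
    density[hit] <- dens_het
  }
  density
}

# move `leak` of the spike mass onto masked target windows (in proportion to
# their underlying abundance); returns adjusted target-extra and spike masses
crossmap_allocate <- function(w_spike, leak, mask, target_weight) {
  extra <- numeric(length(mask))
  total_leak <- leak * sum(w_spike)
  if (any(mask) && total_leak > 0) {
    wm <- target_weight[mask]
    if (sum(wm) == 0) wm <- rep(1, sum(mask))
    extra[mask] <- total_leak * wm / sum(wm)
    w_spike <- w_spike * (1 - leak)
  }
  list(target = extra, spike = w_spike)
}

sample_library <- function(w_target, w_spike, depth, noise) {
  w <- c(w_target, w_spike)
  p <- w / sum(w)
  counts <- if (noise) as.numeric(stats::rmultinom(1, depth, p)) else depth * p
  n_t <- length(w_target)
  list(target = counts[seq_len(n_t)], spike = counts[-seq_len(n_t)])
}
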