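#' Analysis configuration
#'
#' Bundles the constants the pipeline uses everywhere: window width, GC bin
#' width, boundary flank, pseudocount, top-k size for overlap statistics,
#' permutation count and the RNG seed. The seed is stamped into every output
#' header so any written track or table can be traced back to the run that
#' produced it.
#'
#' @param window_width Window width in bp. Default 5000 (5-kb windows).
#' @param gc_bin_width GC bin width as a fraction of GC content. Default 0.05
#'   (5\% intervals).
#' @param boundary_flank Flank around the heterochromatin/euchromatin boundary
#'   in bp used by boundary profiles. Default 1e6 (1 Mb).
#' @param pseudocount Pseudocount added to coverage ratios when enabled.
#' @param top_k Number of top-ranked genes per contrast for overlap tests.
#' @param n_permutations Number of permutations for the overlap null.
#' @param rng_seed Integer seed recorded in output headers.
#'
#' @return An object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(window_width = 5000L,
                            gc_bin_width = 0.05,
                            boundary_flank = 1e6,
                            pseudocount = 0,
                            top_k = 1000L,
                            n_permutations = 10000L,
                            rng_seed = 1L) {
  if (!is.numeric(window_width) || window_width <= 0)
    stop("window_width must be > 0")
  if (!is.numeric(gc_bin_width) || gc_bin_width <= 0 || gc_bin_width > 1)
    stop("gc_bin_width must lie in (0, 1]")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (top_k < 1) stop("top_k must be >= 1")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  cfg <- list(
    window_width   = as.integer(window_width),
    gc_bin_width   = gc_bin_width,
    boundary_flank = boundary_flank,
    pseudocount    = pseudocount,
    top_k          = as.integer(top_k),
    n_permutations = as.integer(n_permutations),
    rng_seed       = as.integer(rng_seed)
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# One-line provenance string stamped into output file headers.
config_provenance <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  body <- paste(sprintf("%s=%s", names(config), vapply(config, format, "")),
                collapse = ";")
  sprintf("hetsink %s seed=%d config_sha=%s",
          as.character(utils::packageVersion("hetsink")),
          config$rng_seed,
          substr(sprintf("%08x", sum(utf8ToInt(body) * seq_along(utf8ToInt(body)))), 1, 8))
}
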