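# Shared fixtures, built once per test run and memoized.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_env <- new.env(parent = emptyenv())

shared_genome <- function() {
  if (is.null(.fixture_env$genome))
    .fixture_env$genome <- build_genome_model(seed = 42)
  .fixture_env$genome
}

shared_sink <- function() sink_model()

# small noiseless experiment for arithmetic-level checks
quick_experiment <- function(karyotype = "XY", noise = FALSE, seed = 7, ...) {
  simulate_chip_experiment(shared_genome(), karyotype_spec(karyotype),
                           shared_sink(), noise = noise, seed = seed, ...)
}

# exhaustive two-sided Mann-Whitney p-value by enumerating all labelings
enumerate_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  cmb <- utils::combn(length(pooled), n)
  u_of <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_of(x, y)
  mu <- n * length(y) / 2
  us <- apply(cmb, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# independent line-by-line FASTA parser used as an oracle
naive_fasta_lengths <- function(path) {
  lines <- readLines(path)
  lens <- integer(0); cur <- NA_integer_
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      if (!is.na(cur)) lens <- c(lens, cur)
      cur <- 0L
    } else cur <- cur + nchar(trimws(ln))
  }
  if (!is.na(cur)) lens <- c(lens, cur)
  lens
}
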