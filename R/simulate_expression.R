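#' Simulate sex-resolved genomic coverage of repeat families
#'
#' Maps male (XY) or female (XX) genomic read-equivalents onto the genome
#' model's repeat families plus a single-copy background. Expected reads per
#' family are proportional to copies times consensus length; counts are
#' Poisson. Y-linked families have zero copies in females, so their expected
#' female coverage is exactly zero. Truth labels are carried through for
#' classifier benchmarking.
#'
#' @param genome A `genome_model`.
#' @param sex `"male"` (XY) or `"female"` (XX).
#' @param depth Total genomic read-equivalents.
#' @param seed Integer seed.
#' @param read_length Read length in bp used to convert read counts to mean
#'   per-bp coverage (default 100).
#' @return Data frame with one row per family: `name`, `length`, `gc`,
#'   `copies`, `reads`, `cov` (mean per-bp coverage), `label_true`; attribute
#'   `singlecopy_cov` holds the realized mean per-bp coverage of the diploid
#'   single-copy background, and `depth` the library size.
#' @export
simulate_sex_coverage <- function(genome, sex = c("male", "female"),
                                  depth = 1e6, seed = 1L, read_length = 100) {
  sex <- match.arg(sex)
  kar <- karyotype_spec(if (sex == "male") "XY" else "XX")
  set.seed(seed + (sex == "female"))
  rf <- genome$repeat_families
  copies <- repeat_copy_number(genome, kar)
  fam_mass <- copies * rf$length
  bg_len <- sum(genome$arms$length)
  bg_mass <- 2 * bg_len
  total <- sum(fam_mass) + bg_mass
  reads <- stats::rpois(nrow(rf), depth * fam_mass / total)
  bg_reads <- stats::rpois(1, depth * bg_mass / total)
  out <- data.frame(name = rf$name, length = rf$length, gc = rf$gc,
                    copies = copies, reads = reads,
                    cov = reads * read_length / rf$length,
                    label_true = rf$label_true,
                    stringsAsFactors = FALSE)
  attr(out, "singlecopy_cov") <- bg_reads * read_length / bg_len
  attr(out, "depth") <- depth
  attr(out, "read_length") <- read_length
  out
}

#' Simulate gene-level RNA-seq counts across karyotypes
#'
#' Negative-binomial counts for a gene universe over replicate libraries of
#' several karyotypes. A configurable set of "shared" genes responds to the
#' presence of a Y chromosome (in either sex), so the same genes surface in
#' the male/female, X0-vs-XY and XX-vs-XXY contrasts -- the structure behind
#' the top-k overlap statistic. Additional genes respond only to sex
#' (contrast-specific signal), and the rest are null.
#'
#' @param n_genes Universe size (must be >= `top_k` downstream).
#' @param karyotypes Character vector of karyotype labels to simulate.
#' @param n_shared Number of genes with a Y-presence effect.
#' @param shared_effect Fold change of the Y-presence effect (default 4).
#' @param n_sex Number of genes with a sex (X-dose) effect only.
#' @param sex_effect Fold change of the sex effect.
#' @param n_reps Replicates per karyotype (default 2).
#' @param depth Mean library size.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param seed Integer seed.
#' @return List with `counts` (genes x samples matrix), `samples` (data frame
#'   `sample`, `karyotype`, `rep`), and `truth` (ids of shared-effect and
#'   sex-effect genes, per-gene effect signs).
#' @export
simulate_rnaseq <- function(n_genes = 3000L,
                            karyotypes = c("X0", "XX", "XY", "XXY"),
                            n_shared = 660L, shared_effect = 4,
                            n_sex = 150L, sex_effect = 3,
                            n_reps = 2L, depth = 2e6, dispersion = 0.05,
                            seed = 1L) {
  if (n_shared + n_sex > n_genes)
    stop("n_shared + n_sex must not exceed n_genes")
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  base <- stats::rlnorm(n_genes, meanlog = 4, sdlog = 1.2)

  shared_idx <- seq_len(n_shared)
  sex_idx <- n_shared + seq_len(n_sex)
  sign_shared <- sample(c(-1, 1), n_shared, replace = TRUE)
  sign_sex <- sample(c(-1, 1), n_sex, replace = TRUE)

  kar_specs <- lapply(karyotypes, karyotype_spec)
  samples <- expand.grid(rep = seq_len(n_reps), karyotype = karyotypes,
                         stringsAsFactors = FALSE)[, 2:1]
  samples$sample <- paste0(samples$karyotype, "_r", samples$rep)

  counts <- matrix(0, n_genes, nrow(samples),
                   dimnames = list(genes, samples$sample))
  for (s in seq_len(nrow(samples))) {
    kar <- kar_specs[[match(samples$karyotype[s], karyotypes)]]
    mu <- base
    if (kar$n_Y > 0)
      mu[shared_idx] <- mu[shared_idx] * shared_effect^sign_shared
    if (kar$n_X >= 2)
      mu[sex_idx] <- mu[sex_idx] * sex_effect^sign_sex
    mu <- mu / sum(mu) * depth
    counts[, s] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  list(counts = counts, samples = samples,
       truth = list(shared_genes = genes[shared_idx],
                    sex_genes = genes[sex_idx],
                    sign_shared = sign_shared, sign_sex = sign_sex))
}

#' Simulate repeat-family expression counts across karyotypes
#'
#' Counts per family scale with genomic copy number times a per-copy
#' transcription rate. Heterochromatin loss can derepress a subset of
#' Y-linked families in Y-duplicated karyotypes: their per-copy rate is
#' multiplied by `derepression_factor` in karyotypes with `n_Y != 1`
#' that carry a Y, and in XXY females. Copy-number inflation (e.g. XYY
#' doubling Y-linked copies) raises raw counts without touching the per-copy
#' rate, which is exactly what copy-number correction must reject.
#'
#' @param genome A `genome_model`.
#' @param karyotypes Karyotype labels (default XY, XXY, XYY).
#' @param per_copy_rate Expected reads per copy per kb at unit depth scale.
#' @param derepressed_frac Fraction of Y-linked families that are truly
#'   derepressed (per-copy) in Y-aberrant karyotypes.
#' @param derepression_factor Per-copy fold change for derepressed families.
#' @param n_reps Replicates per karyotype.
#' @param dispersion NB dispersion.
#' @param background_mean Expected counts of the non-repeat (gene) portion of
#'   each library; included in the reported library totals so repeat CPM is
#'   computed over the full repeat+gene universe.
#' @param seed Integer seed.
#' @return List with `counts` (families x samples), `totals` (per-sample
#'   library size including the gene background), `copies` (families x
#'   karyotypes), `samples`, and `truth$derepressed` (family names).
#' @export
simulate_repeat_expression <- function(genome,
                                       karyotypes = c("XY", "XXY", "XYY"),
                                       per_copy_rate = 50,
                                       derepressed_frac = 0.3,
                                       derepression_factor = 3,
                                       n_reps = 2L, dispersion = 0.05,
                                       background_mean = 2e6,
                                       seed = 1L) {
  set.seed(seed)
  rf <- genome$repeat_families
  y_fams <- which(rf$label_true == "male_specific")
  n_der <- round(derepressed_frac * length(y_fams))
  der_idx <- y_fams[seq_len(n_der)]
  if (n_der == 0) der_idx <- integer(0)

  kar_specs <- lapply(karyotypes, karyotype_spec)
  copies <- vapply(kar_specs, function(k) repeat_copy_number(genome, k),
                   numeric(nrow(rf)))
  colnames(copies) <- karyotypes
  rownames(copies) <- rf$name

  samples <- expand.grid(rep = seq_len(n_reps), karyotype = karyotypes,
                         stringsAsFactors = FALSE)[, 2:1]
  samples$sample <- paste0(samples$karyotype, "_r", samples$rep)
  counts <- matrix(0, nrow(rf), nrow(samples),
                   dimnames = list(rf$name, samples$sample))
  for (s in seq_len(nrow(samples))) {
    kl <- samples$karyotype[s]
    kar <- kar_specs[[match(kl, karyotypes)]]
    rate <- rep(per_copy_rate, nrow(rf))
    aberrant_y <- (kar$n_Y >= 2) || (kar$n_Y >= 1 && kar$n_X >= 2)
    if (aberrant_y) rate[der_idx] <- rate[der_idx] * derepression_factor
    mu <- copies[, kl] * rate * rf$length / 1000
    counts[, s] <- stats::rnbinom(nrow(rf), mu = mu, size = 1 / dispersion)
  }
  totals <- colSums(counts) +
    stats::rnbinom(nrow(samples), mu = background_mean, size = 1 / dispersion)
  names(totals) <- samples$sample
  list(counts = counts, totals = totals, copies = copies, samples = samples,
       truth = list(derepressed = rf$name[der_idx],
                    per_copy_rate = per_copy_rate,
                    derepression_factor = derepression_factor))
}
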