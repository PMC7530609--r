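fam_row <- function(name, m_reads, f_reads, m_cov, f_cov) {
  data.frame(name = name, male_reads = m_reads, female_reads = f_reads,
             male_cov = m_cov, female_cov = f_cov, stringsAsFactors = FALSE)
}

test_that("clear-cut families are labeled by coverage alone", {
  fams <- rbind(fam_row("ylinked", 500, 0, 50, 0),
                fam_row("shared", 500, 480, 50, 48),
                fam_row("lowcov", 20, 0, 2, 0),
                fam_row("femonly", 0, 300, 0, 30))
  out <- classify_male_specific(fams, male_depth = 1e6, female_depth = 1e6,
                                min_male_cov = 10)
  expect_equal(out$label,
               c("male_specific", "shared", "shared", "female_only"))
})

test_that("classification is invariant to a joint depth rescaling", {
  fams <- rbind(fam_row("a", 500, 0, 50, 0),
                fam_row("b", 400, 30, 40, 3),
                fam_row("c", 300, 290, 30, 29))
  out1 <- classify_male_specific(fams, 1e6, 1e6, min_male_cov = 10)
  fams2 <- fams
  fams2$female_reads <- fams$female_reads * 3
  fams2$female_cov <- fams$female_cov * 3
  out2 <- classify_male_specific(fams2, 1e6, 3e6, min_male_cov = 10)
  expect_equal(out1$label, out2$label)
})

test_that("the binomial branch requires significantly depleted female coverage", {
  # "few" sits under the ratio cutoff but its read counts are too shallow to
  # clear the Bonferroni-corrected binomial test; "many" has the same ratio
  # at depth and is called. Filler rows set the Bonferroni denominator.
  fams <- rbind(fam_row("few", 11, 1, 22, 2),
                fam_row("many", 1500, 100, 150, 10),
                fam_row("s1", 200, 190, 20, 19),
                fam_row("s2", 210, 200, 21, 20),
                fam_row("s3", 190, 185, 19, 18.5))
  out <- classify_male_specific(fams, 1e6, 1e6, min_male_cov = 5)
  expect_equal(out$label[out$name == "few"], "shared")
  expect_gt(out$p_binom[out$name == "few"], attr(out, "params")$alpha_bonferroni)
  expect_equal(out$label[out$name == "many"], "male_specific")
})

test_that("planted library is recovered with high sensitivity and low FDR", {
  g <- build_genome_model(n_repeat_families = 200, n_y_linked = 20, seed = 77)
  male <- simulate_sex_coverage(g, "male", depth = 2e7, seed = 78)
  female <- simulate_sex_coverage(g, "female", depth = 2e7, seed = 78)
  fams <- data.frame(name = male$name,
                     male_reads = male$reads, female_reads = female$reads,
                     male_cov = male$cov, female_cov = female$cov)
  min_cov <- 5 * attr(male, "singlecopy_cov") / 2
  out <- classify_male_specific(fams, attr(male, "depth"),
                                attr(female, "depth"),
                                min_male_cov = min_cov)
  truth <- male$label_true == "male_specific"
  called <- out$label == "male_specific"
  sens <- sum(called & truth) / sum(truth)
  fdr <- if (sum(called) > 0) sum(called & !truth) / sum(called) else 0
  expect_gte(sens, 0.95)
  expect_lte(fdr, 0.05)
})

test_that("repeat enrichment is the scaled, GC-corrected chip/input ratio", {
  expect_equal(repeat_enrichment(300, 100, spike_factor = 1,
                                 genomewide_signal = 1.5)$enrichment, 2)
  e <- repeat_enrichment(c(100, 50), c(100, 0))
  expect_equal(e$enrichment[1], 1)
  expect_true(is.na(e$enrichment[2]))
  expect_true(e$zero_input[2])

  # with a GC model, both coverages are corrected before ratioing
  gc <- seq(0.05, 0.95, length.out = 300)
  tr <- window_track(rep("a", 300), seq(0, by = 100, length.out = 300),
                     seq(100, by = 100, length.out = 300),
                     80 * exp(gc - 0.5))
  m <- suppressWarnings(fit_gc_model(tr, gc, min_windows = 5))
  enr <- repeat_enrichment(160, 80, repeat_gc = 0.42, gc_model = m,
                           spike_factor = 2, genomewide_signal = 1)
  expect_equal(enr$enrichment, 160 / 80 * 2)  # same bin cancels in the ratio
})

test_that("copy numbers come from the input-coverage baseline", {
  expect_equal(copy_number_estimate(80, 80), 1)
  expect_equal(copy_number_estimate(800, 80), 10)
  expect_error(copy_number_estimate(10, 0), "positive")

  # synthetic family with known copies recovered within 10%
  arms <- default_arms()
  g <- build_genome_model(arms, n_repeat_families = 30, n_y_linked = 5,
                          seed = 55)
  g$repeat_families$copies_auto[10] <- 3.5  # 7 copies diploid
  g$repeat_families$copies_X[10] <- 0
  g$repeat_families$copies_Y[10] <- 0
  male <- simulate_sex_coverage(g, "male", depth = 1e6, seed = 56)
  est <- copy_number_estimate(male$cov[10], attr(male, "singlecopy_cov") / 2)
  expect_equal(est, 7, tolerance = 0.1)
})

test_that("per-copy expression is scale-invariant and flags orphan expression", {
  expect_equal(cn_corrected_expression(40, 8)$per_copy, 5)
  lam <- 2.7
  expect_equal(cn_corrected_expression(40 * lam, 8 * lam)$per_copy,
               cn_corrected_expression(40, 8)$per_copy)
  orphan <- cn_corrected_expression(c(10, 0), c(0, 0))
  expect_true(orphan$flag_no_copies[1])
  expect_false(orphan$flag_no_copies[2])
  expect_true(all(is.na(orphan$per_copy)))
})

test_that("copy-number correction separates derepression from dosage", {
  g <- shared_genome()
  sim <- simulate_repeat_expression(g, karyotypes = c("XY", "XYY"),
                                    derepressed_frac = 0.4,
                                    derepression_factor = 3,
                                    n_reps = 4, seed = 61)
  rf <- g$repeat_families
  y_idx <- which(rf$label_true == "male_specific")
  tot <- sim$totals
  per_copy <- sapply(c("XY", "XYY"), function(kk) {
    cols <- grepl(paste0("^", kk, "_"), colnames(sim$counts))
    cpm <- rowMeans(sapply(which(cols), function(j)
      cpm_per_kb(sim$counts[, j], tot[j], rf$length)))
    cn_corrected_expression(cpm, sim$copies[, kk])$per_copy
  })
  ratio <- per_copy[y_idx, "XYY"] / per_copy[y_idx, "XY"]
  derep <- rf$name[y_idx] %in% sim$truth$derepressed
  # planted per-copy derepression survives correction ...
  expect_true(all(ratio[derep] > 1.5))
  # ... pure copy-number doubling does not
  expect_true(all(abs(ratio[!derep] - 1) < 0.5))
  expect_equal(median(ratio[derep]), 3, tolerance = 0.25)
})

test_that("male-specific families lose marks and gain expression in Y-aberrant karyotypes", {
  g <- shared_genome()
  s <- shared_sink()
  rf <- g$repeat_families
  y_idx <- rf$label_true == "male_specific"
  # mark enrichment at repeats follows the sink density of the karyotype
  dens <- vapply(c("XY", "XXY", "XYY"),
                 function(k) sink_mark_density(s, karyotype_spec(k)), 0)
  expect_true(all(dens[c("XXY", "XYY")] < dens["XY"]))

  sim <- simulate_repeat_expression(g, karyotypes = c("XY", "XXY", "XYY"),
                                    n_reps = 4, seed = 62)
  tot <- sim$totals
  per_copy <- sapply(c("XY", "XXY", "XYY"), function(kk) {
    cols <- which(grepl(paste0("^", kk, "_"), colnames(sim$counts)))
    cpm <- rowMeans(sapply(cols, function(j)
      cpm_per_kb(sim$counts[, j], tot[j], rf$length)))
    cn_corrected_expression(cpm, sim$copies[, kk])$per_copy
  })
  derep <- rf$name %in% sim$truth$derepressed
  expect_gt(median(per_copy[derep, "XXY"] / per_copy[derep, "XY"]), 1.5)
  expect_gt(median(per_copy[derep, "XYY"] / per_copy[derep, "XY"]), 1.5)
})
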