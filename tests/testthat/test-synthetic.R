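test_that("genome model tiles arms into the expected windows", {
  arms <- data.frame(name = c("a1", "a2", "X", "Y"),
                     length = c(2e6, 2e6, 1.5e6, 1e6),
                     het_fraction = c(0.3, 0.3, 0.3, 1),
                     type = c("autosome", "autosome", "X", "Y"))
  g <- build_genome_model(arms, window_width = 5000, seed = 1)
  expect_equal(nrow(g$windows), 1300)  # 6.5 Mb / 5 kb
  expect_equal(length(g$gc), 1300)
  expect_equal(length(g$crossmap_mask), 1300)

  # same config + seed => identical model
  g2 <- build_genome_model(arms, window_width = 5000, seed = 1)
  expect_identical(g, g2)

  # partial terminal windows are kept and truncated
  arms$length[1] <- 2e6 + 1234
  g3 <- build_genome_model(arms, window_width = 5000, seed = 1)
  expect_equal(nrow(g3$windows), 1301)
  w <- g3$windows[g3$windows$chrom == "a1", ]
  expect_equal(max(w$end), 2e6 + 1234)
})

test_that("zero heterochromatin fraction puts the boundary at 0", {
  arms <- data.frame(name = c("a1", "Y"), length = c(1e6, 5e5),
                     het_fraction = c(0, 1), type = c("autosome", "Y"))
  g <- build_genome_model(arms, seed = 1)
  expect_equal(g$boundaries$pos[g$boundaries$chrom == "a1"], 0)
  expect_false(any(grepl("pericentromere", g$blocks$region) &
                     g$blocks$chrom == "a1"))
  expect_error(build_genome_model(
    data.frame(name = "a", length = 1e6, het_fraction = 1.2,
               type = "autosome")), "het_fraction")
})

test_that("blocks tile each arm without overlap or gap", {
  g <- shared_genome()
  for (arm in g$arms$name) {
    b <- g$blocks[g$blocks$chrom == arm, ]
    b <- b[order(b$start), ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], g$arms$length[g$arms$name == arm])
    if (nrow(b) > 1) expect_equal(b$start[-1], b$end[-nrow(b)])
  }
})

test_that("instantiated heterochromatin content follows the karyotype order", {
  g <- shared_genome()
  h <- vapply(c("X0", "XX", "XY", "XXY", "XYY"),
              function(k) het_content_mb(g, karyotype_spec(k)), 0)
  expect_true(all(diff(h) > 0))
})

test_that("without a sink, karyotypes are indistinguishable after normalization", {
  g <- shared_genome()
  s0 <- sink_model(exponent = 0)
  sigs <- lapply(c("X0", "XY", "XYY"), function(k) {
    e <- simulate_chip_experiment(g, karyotype_spec(k), s0,
                                  noise = FALSE, seed = 3)
    window_signal(e$chip, e$input, spike_scaling_ratio(e$chip, e$input),
                  mask = e$mask)
  })
  shared <- !is.na(sigs[[1]]$value) & !is.na(sigs[[2]]$value) &
    !is.na(sigs[[3]]$value)
  expect_equal(sigs[[1]]$value[shared], sigs[[2]]$value[shared],
               tolerance = 1e-10)
  expect_equal(sigs[[2]]$value[shared], sigs[[3]]$value[shared],
               tolerance = 1e-10)
})

test_that("sink densities scale inversely with configured het content", {
  s <- sink_model(reference_het_content = 100, mark_density_base = 6,
                  het_content_table = c(XY = 100, XYY = 200))
  d1 <- sink_mark_density(s, karyotype_spec("XY"))
  d2 <- sink_mark_density(s, karyotype_spec("XYY"))
  expect_equal(d1 / d2, 2)
  # exponent shapes the dilution
  s2 <- sink_model(reference_het_content = 100, exponent = 0.5,
                   het_content_table = c(XY = 100, XYY = 400))
  expect_equal(sink_mark_density(s2, karyotype_spec("XY")) /
                 sink_mark_density(s2, karyotype_spec("XYY")), 2)
})

test_that("sampled coverage is multinomially consistent with expectations", {
  g <- shared_genome()
  s <- shared_sink()
  depth <- 1e6
  noiseless <- simulate_chip_experiment(g, karyotype_spec("XY"), s,
                                        depth = depth, noise = FALSE, seed = 8)
  noisy <- simulate_chip_experiment(g, karyotype_spec("XY"), s,
                                    depth = depth, noise = TRUE, seed = 8)
  p <- noiseless$input$coverage$value / depth
  obs <- noisy$input$coverage$value
  se <- sqrt(depth * p * (1 - p))
  z <- (obs - depth * p)[se > 0] / se[se > 0]
  # binomial SE oracle: ~99.7% of windows within 3 SD
  expect_lt(mean(abs(z) > 3), 0.01)
  expect_lt(abs(mean(z)), 0.1)
})

test_that("spike read totals are stable across karyotypes and respond only to target mass", {
  g <- shared_genome()
  s <- shared_sink()
  spikes <- vapply(c("X0", "XX", "XY", "XXY", "XYY"), function(k) {
    e <- simulate_chip_experiment(g, karyotype_spec(k), s,
                                  noise = FALSE, seed = 4)
    e$input$spike_reads
  }, 0)
  # constant spike mass; totals differ only via the few-percent difference
  # in target genome mass between karyotypes
  expect_lt(diff(range(spikes)) / mean(spikes), 0.15)

  # a global mark dilution inflates the ChIP spike share but not the input's
  e1 <- simulate_chip_experiment(g, karyotype_spec("XY"), s, noise = FALSE,
                                 seed = 4, mark_dilution = 1)
  e2 <- simulate_chip_experiment(g, karyotype_spec("XY"), s, noise = FALSE,
                                 seed = 4, mark_dilution = 0.5)
  expect_equal(e1$input$spike_reads, e2$input$spike_reads, tolerance = 1e-12)
  expect_gt(e2$chip$spike_reads, e1$chip$spike_reads)
})

test_that("sex-resolved repeat coverage reflects copy numbers", {
  g <- shared_genome()
  male <- simulate_sex_coverage(g, "male", depth = 2e6, seed = 9)
  female <- simulate_sex_coverage(g, "female", depth = 2e6, seed = 9)
  y_fams <- male$label_true == "male_specific"
  expect_true(any(y_fams))
  expect_true(all(female$cov[y_fams] == 0))

  # coverage proportional to copies at high depth
  shared_idx <- which(!y_fams & male$copies > 0)
  ratio <- male$cov[shared_idx] / (male$copies[shared_idx] *
                                     attr(male, "singlecopy_cov") / 2)
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})

test_that("rnaseq generator plants recoverable karyotype effects", {
  # null: no effects => top-k overlap at chance level. Replicates are split
  # so the three contrasts share no samples (shared samples would correlate
  # the rankings even under the null).
  null_sim <- simulate_rnaseq(n_genes = 1200, n_shared = 0, n_sex = 0,
                              n_reps = 4, seed = 21)
  cs <- list(
    rank_genes_by_contrast(null_sim$counts, c("XX_r1", "XX_r2"),
                           c("XY_r1", "XY_r2"), label = "sex"),
    rank_genes_by_contrast(null_sim$counts, c("X0_r1", "X0_r2"),
                           c("XY_r3", "XY_r4"), label = "maleY"),
    rank_genes_by_contrast(null_sim$counts, c("XX_r3", "XX_r4"),
                           c("XXY_r1", "XXY_r2"), label = "femaleY")
  )
  k <- 300
  ov <- topk_overlap(cs, k)
  expected <- 1200 * (k / 1200)^3
  expect_lt(abs(ov - expected), 4 * sqrt(expected) + 5)

  # planted shared Y-response genes dominate all three contrasts
  sim <- simulate_rnaseq(n_genes = 1500, n_shared = 300, shared_effect = 4,
                         n_sex = 80, seed = 22)
  cs <- list(
    rank_genes_by_contrast(sim$counts, c("XX_r1", "XX_r2"),
                           c("XY_r1", "XY_r2"), label = "sex"),
    rank_genes_by_contrast(sim$counts, c("X0_r1", "X0_r2"),
                           c("XY_r1", "XY_r2"), label = "maleY"),
    rank_genes_by_contrast(sim$counts, c("XX_r1", "XX_r2"),
                           c("XXY_r1", "XXY_r2"), label = "femaleY")
  )
  top <- Reduce(intersect, lapply(cs, function(cc)
    names(sort(cc$rank))[seq_len(500)]))
  recall <- mean(sim$truth$shared_genes %in% top)
  expect_gte(recall, 0.9)
})

test_that("repeat expression doubles with copy number at fixed per-copy rate", {
  g <- shared_genome()
  sim <- simulate_repeat_expression(g, karyotypes = c("XY", "XYY"),
                                    derepressed_frac = 0, seed = 30,
                                    n_reps = 8, dispersion = 0.01)
  y_fams <- g$repeat_families$label_true == "male_specific"
  m_xy <- rowMeans(sim$counts[y_fams, grepl("^XY_", colnames(sim$counts))])
  m_xyy <- rowMeans(sim$counts[y_fams, grepl("^XYY_", colnames(sim$counts))])
  expect_equal(sim$copies[y_fams, "XYY"] / sim$copies[y_fams, "XY"],
               rep(2, sum(y_fams)), ignore_attr = TRUE)
  expect_equal(mean(m_xyy / m_xy), 2, tolerance = 0.1)
})

test_that("fixture files are byte-identical under a fixed seed", {
  g <- build_genome_model(seed = 99)
  e <- simulate_chip_experiment(g, karyotype_spec("XY"), sink_model(),
                                depth = 1e5, seed = 99)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_window_track(e$chip$coverage, p1)
  e2 <- simulate_chip_experiment(g, karyotype_spec("XY"), sink_model(),
                                 depth = 1e5, seed = 99)
  write_window_track(e2$chip$coverage, p2)
  expect_identical(readLines(p1), readLines(p2))
})
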