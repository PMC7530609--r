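sig_track <- function(values, chrom = "a", width = 5000) {
  n <- length(values)
  window_track(rep(chrom, n), seq(0, by = width, length.out = n),
               seq(width, by = width, length.out = n), values)
}

test_that("subtraction tracks are antisymmetric and zero on identity", {
  set.seed(1)
  a <- sig_track(rnorm(50)); b <- sig_track(rnorm(50))
  expect_true(all(subtraction_track(a, a)$value == 0))
  ab <- subtraction_track(a, b); ba <- subtraction_track(b, a)
  expect_equal(ab$value, -ba$value)
  expect_equal(ab$abs_diff, abs(ab$value))

  shifted <- a; shifted$value <- a$value + 0.5
  expect_equal(subtraction_track(shifted, a)$value, rep(0.5, 50))

  expect_error(subtraction_track(a, sig_track(rnorm(10))), "identical windows")
})

test_that("rank_sum_test matches exhaustive enumeration for small samples", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6)
  expect_equal(r$p, enumerate_ranksum_p(c(1, 2), c(3, 4)))

  # identical multisets: p = 1
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # 8 vs 8 random fixture against brute force over all C(16,8) labelings
  set.seed(8)
  x <- round(rnorm(8), 3); y <- round(rnorm(8, mean = 0.5), 3)
  r8 <- rank_sum_test(x, y)
  expect_equal(r8$p, enumerate_ranksum_p(x, y))

  # a second fixture with a strong shift
  x2 <- 1:8 / 10; y2 <- (1:8) + 2
  expect_equal(rank_sum_test(x2, y2)$p, enumerate_ranksum_p(x2, y2))

  # permutation invariance of the inputs
  expect_equal(rank_sum_test(sample(x), sample(y))$p, r8$p)

  expect_error(rank_sum_test(numeric(0), 1:3), "empty")
})

test_that("region summaries use type-7 quartiles and boxplot whiskers", {
  blocks <- data.frame(chrom = "a", start = 0, end = 25000,
                       region = "pericentromere_a")
  s <- sig_track(c(1, 2, 3, 4, 5))
  rs <- region_summary(s, blocks, "pericentromere_a")
  expect_equal(unname(rs$quartiles), c(2, 3, 4))
  expect_equal(unname(rs$whiskers), c(1, 5))

  # identical values vs reference: two-sided p = 1
  rs2 <- region_summary(s, blocks, "pericentromere_a", reference_signal = s)
  expect_equal(rs2$p, 1)

  expect_error(region_summary(s, blocks, "dot"), "dot")
})

test_that("a planted 2x regional shift is overwhelmingly significant", {
  set.seed(2)
  n <- 250
  blocks <- data.frame(chrom = "a", start = 0, end = n * 5000,
                       region = "pericentromere_a")
  base <- sig_track(rlnorm(n, 0, 0.3))
  shifted <- base; shifted$value <- base$value * 2
  rs <- region_summary(shifted, blocks, "pericentromere_a",
                       reference_signal = base)
  expect_lt(rs$p, 1e-6)
})

test_that("boundary profiles split sides correctly and detect steps", {
  # 40 windows, boundary at 100 kb: het side [0,100k), eu side [100k,200k)
  v <- c(rep(2, 20), rep(1, 20))
  s <- sig_track(v)
  bp <- boundary_profile(s, "a", 1e5, flank = 1e5, arm_length = 2e5)
  expect_equal(bp$inside_mean, 2)
  expect_equal(bp$outside_mean, 1)
  expect_equal(sum(bp$windows$side == "inside"), 20)
  expect_lt(bp$p, 1e-6)

  flat <- sig_track(rep(1.3, 40))
  bpf <- boundary_profile(flat, "a", 1e5, flank = 1e5, arm_length = 2e5)
  expect_equal(bpf$inside_mean, bpf$outside_mean)
  expect_equal(bpf$p, 1)

  expect_warning(boundary_profile(s, "a", 1e5, flank = 5e5,
                                  arm_length = 2e5), "truncated")
})

test_that("spreading index localizes the true transition", {
  # perfect step at the annotated boundary
  s <- sig_track(c(rep(2, 30), rep(1, 30)))
  bp <- boundary_profile(s, "a", 150000, flank = 150000, arm_length = 3e5)
  si <- spreading_index(bp)
  expect_equal(si$boundary_contrast, 1 / 3)
  expect_lt(abs(si$midpoint_shift), 5000)

  # step moved +200 kb armward (mark spread into euchromatin)
  n <- 200; b <- 5e5
  v <- ifelse(seq(2500, by = 5000, length.out = n) < b + 2e5, 2, 1)
  s2 <- sig_track(v)
  bp2 <- boundary_profile(s2, "a", b, flank = 5e5, arm_length = 1e6)
  si2 <- spreading_index(bp2)
  expect_lt(abs(si2$midpoint_shift - 2e5), 5000 + 1e-9)

  # constant signal: zero contrast, undefined shift
  bp3 <- boundary_profile(sig_track(rep(2, 60)), "a", 150000,
                          flank = 150000, arm_length = 3e5)
  si3 <- spreading_index(bp3)
  expect_equal(si3$boundary_contrast, 0)
  expect_true(is.na(si3$midpoint_shift))
})

test_that("gene signal is the length-weighted window mean", {
  s <- sig_track(c(1, 3, 5, 7))
  genes <- data.frame(gene = c("one", "two", "skewed", "off"),
                      chrom = c("a", "a", "a", "chrUn"),
                      start = c(1000, 2500, 7500, 0),
                      end = c(4000, 7500, 12500, 500))
  gs <- gene_signal(s, genes)
  expect_equal(gs$signal[1], 1)                  # inside one window
  expect_equal(gs$signal[2], 2)                  # equal halves of 1 and 3
  expect_equal(gs$signal[3], (3 * 2500 + 5 * 2500) / 5000)
  expect_true(gs$outside_assembly[4])

  # per-base oracle on a random fixture
  set.seed(3)
  vals <- rnorm(20)
  s2 <- sig_track(vals, width = 100)
  genes2 <- data.frame(gene = sprintf("g%d", 1:15),
                       chrom = "a",
                       start = sample(0:1800, 15),
                       end = NA)
  genes2$end <- genes2$start + sample(30:200, 15)
  gs2 <- gene_signal(s2, genes2)
  oracle <- vapply(seq_len(15), function(i) {
    bases <- seq(genes2$start[i], min(genes2$end[i], 2000) - 1)
    mean(vals[pmin(bases %/% 100 + 1, 20)])
  }, 0)
  expect_equal(gs2$signal, oracle)

  # masked windows flagged and excluded from the mean
  s3 <- sig_track(c(1, NA, 5))
  g3 <- data.frame(gene = "m", chrom = "a", start = 0, end = 15000)
  gm <- gene_signal(s3, g3)
  expect_true(gm$masked_overlap)
  expect_equal(gm$signal, 3)
})

test_that("concordance QC reports correlation and top-window overlap", {
  set.seed(4)
  a <- sig_track(rnorm(500))
  expect_equal(qc_concordance(a, a)$pearson_r, 1)
  expect_equal(qc_concordance(a, a)$top_overlap, 1)

  # reversed ranks at q = 0.4: combinatorial floor max(0, 2q-1)/q = 0
  rev_a <- a; rev_a$value <- -a$value
  expect_equal(qc_concordance(a, rev_a, 0.4)$top_overlap, 0)

  # independent tracks: overlap concentrates near q
  b <- sig_track(rnorm(500))
  ov <- qc_concordance(a, b, 0.4)$top_overlap
  expect_lt(abs(ov - 0.4), 0.15)

  expect_error(qc_concordance(sig_track(1:2), sig_track(2:1)), "3")
})

test_that("BH adjustment is applied over accumulated region tests", {
  p <- c(0.001, 0.01, 0.04, 0.5)
  expect_equal(adjust_region_pvalues(p), p.adjust(p, "BH"))
})
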