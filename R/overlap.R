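#' Rank genes by an expression contrast
#'
#' Simple normalized fold-change ranker standing in for a full
#' differential-expression model: per-sample CPM, group means, and
#' `lfc = log2((mean_A + pc) / (mean_B + pc))`. Genes are ranked by `|lfc|`
#' descending with deterministic ties broken by gene id. All-zero genes keep
#' `lfc = 0` and are flagged.
#'
#' @param counts Genes x samples count matrix with rownames.
#' @param group_A,group_B Column names or indices of the two groups (>= 1
#'   sample each).
#' @param pseudocount Stabilizing pseudocount (default 0.5 CPM).
#' @param label Contrast label.
#' @return Object of class `ranked_contrast`: list with `label`, `lfc`
#'   (named), `rank` (named permutation of 1..N), `universe`, `all_zero`
#'   (logical), `N`.
#' @export
rank_genes_by_contrast <- function(counts, group_A, group_B,
                                   pseudocount = 0.5,
                                   label = "A_vs_B") {
  if (length(group_A) < 1 || length(group_B) < 1)
    stop("each group needs >= 1 sample")
  cpm <- t(t(counts) / colSums(counts)) * 1e6
  mean_A <- rowMeans(cpm[, group_A, drop = FALSE])
  mean_B <- rowMeans(cpm[, group_B, drop = FALSE])
  lfc <- log2((mean_A + pseudocount) / (mean_B + pseudocount))
  all_zero <- rowSums(counts) == 0
  lfc[all_zero] <- 0
  genes <- rownames(counts)
  ord <- order(-abs(lfc), genes)
  rnk <- integer(length(lfc)); rnk[ord] <- seq_along(ord)
  names(rnk) <- genes
  structure(list(label = label, lfc = stats::setNames(lfc, genes),
                 rank = rnk, universe = genes, all_zero = all_zero,
                 N = length(genes)),
            class = "ranked_contrast")
}

top_genes <- function(contrast, k) {
  stopifnot(inherits(contrast, "ranked_contrast"))
  names(sort(contrast$rank))[seq_len(k)]
}

#' Top-k overlap between contrasts
#'
#' Size of the intersection of the top-k gene sets of two or more ranked
#' contrasts sharing one gene universe.
#'
#' @param contrasts List of `ranked_contrast` objects (or character vectors
#'   of pre-ranked gene ids, best first).
#' @param k Top set size; `k <= N`.
#' @return Integer overlap size.
#' @export
topk_overlap <- function(contrasts, k) {
  sets <- lapply(contrasts, function(cc) {
    if (inherits(cc, "ranked_contrast")) {
      if (k > cc$N) stop("k exceeds universe size")
      top_genes(cc, k)
    } else utils::head(cc, k)
  })
  if (length(sets) >= 2) {
    universes <- lapply(contrasts, function(cc)
      if (inherits(cc, "ranked_contrast")) sort(cc$universe) else NULL)
    universes <- Filter(Negate(is.null), universes)
    if (length(universes) >= 2 &&
        !all(vapply(universes[-1], identical, TRUE, universes[[1]])))
      stop("contrasts do not share one gene universe")
  }
  length(Reduce(intersect, sets))
}

#' Permutation test for multi-set top-k overlap
#'
#' Null model: each of the `m` contrasts contributes an independent uniform
#' k-subset of the N-gene universe; the null statistic is the size of their
#' intersection. The closed-form expectation is `N * (k/N)^m`. The p-value
#' uses the add-one estimator `(1 + #(perm >= observed)) / (n_perm + 1)`, so
#' it is never zero and is bounded below by `1/(n_perm+1)`.
#'
#' @param m Number of contrasts.
#' @param k Top set size (`k < N` unless `k == N`, which is degenerate but
#'   allowed).
#' @param N Universe size.
#' @param observed Observed overlap (0..k).
#' @param n_perm Number of permutations (>= 1000 recommended).
#' @param seed Integer seed.
#' @return Object of class `overlap_test`: list with `m`, `k`, `N`,
#'   `observed`, `expected_closed_form`, `perm_mean`, `perm_sd`, `p`,
#'   `n_perm`, `seed`.
#' @export
overlap_permutation_test <- function(m, k, N, observed, n_perm = 10000L,
                                     seed = 1L) {
  if (observed > k || observed < 0) stop("observed overlap must lie in [0, k]")
  if (k > N) stop("k must be <= N")
  set.seed(seed)
  perm <- null_overlap_draws(m, k, N, n_perm)
  p <- (1 + sum(perm >= observed)) / (n_perm + 1)
  structure(list(m = m, k = k, N = N, observed = observed,
                 expected_closed_form = N * (k / N)^m,
                 perm_mean = mean(perm), perm_sd = stats::sd(perm),
                 p = p, n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "overlap_test")
}

# draws from the null distribution of the m-set top-k overlap
null_overlap_draws <- function(m, k, N, n_draws) {
  vapply(seq_len(n_draws), function(i) {
    tab <- integer(N)
    for (j in seq_len(m)) {
      s <- sample.int(N, k)
      tab[s] <- tab[s] + 1L
    }
    sum(tab == m)
  }, integer(1))
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "top-%d overlap of %d sets over N=%d: observed %d, expected %.2f (closed form) / %.2f (permutation), p = %.3g (%d permutations)\n",
    x$k, x$m, x$N, x$observed, x$expected_closed_form, x$perm_mean, x$p,
    x$n_perm))
  invisible(x)
}

#' Gene-set contrast summary
#'
#' For each contrast, compares the absolute log2 fold changes of a gene set
#' against the background of all genes in the universe: median `|lfc|` in the
#' set and background, plus a two-sided rank-sum p-value. Set members absent
#' from the universe are reported, not fatal.
#'
#' @param gene_set Character vector of gene ids (non-empty).
#' @param contrasts List of `ranked_contrast` objects.
#' @return Data frame: one row per contrast with `label`, `n_set`,
#'   `n_background`, `median_abs_lfc_set`, `median_abs_lfc_background`, `p`;
#'   attribute `missing_genes` lists ids absent from the universe.
#' @export
geneset_contrast <- function(gene_set, contrasts) {
  if (length(gene_set) == 0) stop("empty gene set")
  rows <- lapply(contrasts, function(cc) {
    stopifnot(inherits(cc, "ranked_contrast"))
    in_set <- cc$universe %in% gene_set
    a <- abs(cc$lfc[in_set]); b <- abs(cc$lfc)
    p <- rank_sum_test(a, b)$p
    data.frame(label = cc$label, n_set = length(a), n_background = length(b),
               median_abs_lfc_set = stats::median(a),
               median_abs_lfc_background = stats::median(b),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  miss <- setdiff(gene_set, contrasts[[1]]$universe)
  attr(out, "missing_genes") <- miss
  if (length(miss))
    message(length(miss), " gene-set id(s) absent from the universe")
  out
}
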