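# Statistical primitives used throughout the cohort analytics.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided P by summing hypergeometric outcome probabilities not
#' exceeding the observed table's probability (the convention of
#' [stats::fisher.test()], which performs the computation).  The reported
#' odds ratio is the sample (cross-product) odds ratio, with a Haldane
#' 0.5 correction applied when any cell is zero, so the direction of
#' association is always defined.
#'
#' @param table A 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `(a, b, c, d)` filled row-wise.
#' @return One-row tibble: `p_value`, `odds_ratio`.
#' @examples
#' fisher_exact_2x2(c(1, 9, 11, 3))
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  if (any(table < 0) || any(table != floor(table)) || any(!is.finite(table))) {
    abort_invalid("table entries must be non-negative integers.")
  }
  p <- if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    1  # a degenerate margin admits only the observed table
  } else {
    fisher.test(table)$p.value
  }
  t2 <- table
  if (any(table == 0)) t2 <- table + 0.5
  tibble(p_value = p,
         odds_ratio = (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1]))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples.  The U statistic is computed from
#' midranks; P values use the exact rank distribution for small samples
#' without ties and a tie-corrected normal approximation with continuity
#' correction otherwise (delegated to [stats::wilcox.test()], whose `W` is
#' exactly the U statistic for the first sample).
#'
#' @param x,y Numeric samples.
#' @param exact_threshold Use the exact distribution when both samples have
#'   at most this many observations and there are no ties.
#' @return One-row tibble: `u`, `p_value`.
#' @export
mann_whitney_u <- function(x, y, exact_threshold = 50L) {
  if (!length(x) || !length(y)) abort_degenerate("both samples must be non-empty.")
  exact <- length(x) < exact_threshold && length(y) < exact_threshold &&
    !any(duplicated(c(x, y)))
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble(u = unname(ht$statistic), p_value = ht$p.value)
}

#' Hypergeometric pathway enrichment
#'
#' One-sided over-representation test of a hit-gene set against each
#' pathway in a gene-to-pathway map:
#' `P = P(X >= k)` for `X ~ Hypergeom(pathway size, universe rest, hits)`.
#'
#' @param hit_genes Character vector of genes with events.
#' @param universe Character vector of all assayed genes.
#' @param pathways Named character vector mapping gene to pathway
#'   (default the packaged map).
#' @param adjust If `TRUE`, add Benjamini-Hochberg adjusted P values.
#' @return Tibble: `pathway`, `n_pathway`, `n_hit`, `p_value`
#'   (and `p_adjusted` when requested), sorted by P.
#' @export
pathway_enrichment <- function(hit_genes, universe, pathways = pathway_map(),
                               adjust = FALSE) {
  hit_genes <- unique(hit_genes)
  universe <- unique(universe)
  if (!all(hit_genes %in% universe)) {
    abort_invalid("every hit gene must be in the universe.")
  }
  pw <- pathways[names(pathways) %in% universe]
  out <- map(split(names(pw), unname(pw)), function(genes) {
    m <- length(genes)
    k <- sum(hit_genes %in% genes)
    tibble(
      n_pathway = m, n_hit = k,
      p_value = phyper(k - 1, m, length(universe) - m, length(hit_genes),
                       lower.tail = FALSE)
    )
  })
  out <- bind_rows(out, .id = "pathway") %>% arrange(.data$p_value)
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, "BH")
  out
}
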