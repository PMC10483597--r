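# Shared fixtures: tiny panels and hand-built depth matrices.

tiny_panel <- function(n_genes = 4, exons_per_gene = 6, seed = 42) {
  build_panel(n_genes = n_genes, exons_per_gene = exons_per_gene, seed = seed)
}

# A depth matrix with `n_normals` identical normals at `base` reads per
# target and one case sample given by `case_counts` (default: the baseline
# itself).  Noise-free by construction.
flat_depth <- function(panel, base = 500, case_counts = NULL, n_normals = 5) {
  n_t <- nrow(panel)
  if (is.null(case_counts)) case_counts <- rep(base, n_t)
  counts <- cbind(
    matrix(case_counts, n_t, 1, dimnames = list(NULL, "case1")),
    matrix(base, n_t, n_normals,
           dimnames = list(NULL, sprintf("N%02d", seq_len(n_normals))))
  )
  rownames(counts) <- paste(panel$gene, panel$exon_index, sep = ":")
  depth_matrix(counts, panel, c("case", rep("reference_normal", n_normals)))
}

# A noise-free log2ratio track with values `l` over a tiny panel.
flat_track <- function(l, gene = "BRCA1") {
  n <- length(l)
  track <- tibble::tibble(
    chromosome = "chr1",
    start = seq(0, by = 1000, length.out = n),
    end = seq(200, by = 1000, length.out = n),
    gene = gene, exon_index = seq_len(n), predisposition = TRUE,
    sample_id = "S1", l = l
  )
  class(track) <- c("log2ratio_track", class(track))
  track
}

# SNP rows targeted at specific exons of a gene.
snps_at <- function(gene, exon_index, baf, depth = 100, sample_id = "S1") {
  alt <- round(depth * baf)
  tibble::tibble(
    sample_id = sample_id, chromosome = "chr1",
    position = exon_index * 1000 + 10, gene = gene, exon_index = exon_index,
    ref_depth = depth - alt, alt_depth = alt,
    truth_zygosity = ifelse(baf > 0.2 & baf < 0.8, "het",
                            ifelse(baf <= 0.2, "hom_ref", "hom_alt"))
  )
}

# Independent two-sided Fisher oracle: full enumeration of the
# hypergeometric support with fixed margins.
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0 || n2 == 0 || k == 0 || sum(tab[, 2]) == 0) return(1)
  x <- max(0, k - n2):min(m, k)
  p <- dhyper(x, m, n2, k)
  p_obs <- dhyper(tab[1, 1], m, n2, k)
  sum(p[p <= p_obs * (1 + 1e-7)])
}
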