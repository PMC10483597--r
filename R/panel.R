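# Panel design: ordered exon targets defining the assay footprint.

#' Packaged cancer-predisposition gene list
#'
#' A compact stand-in for the consensus cancer-predisposition gene lists used
#' by clinical germline panels (NCCN / OncoKB / ClinVar derived).  Deletions
#' of whole exons on these genes are treated as pathogenic germline LGRs.
#'
#' @return Character vector of gene symbols.
#' @export
predisposition_genes <- function() {
  names(pathway_map())
}

#' Packaged gene-to-pathway map
#'
#' Maps each predisposition gene to the DNA-repair / signalling pathway it is
#' conventionally assigned to: DNA damage repair (DDR), homologous
#' recombination (HR), mismatch repair (MMR), Fanconi anemia (FA), nucleotide
#' excision repair (NER), cell cycle, PI3K, or Other.
#'
#' @return Named character vector: names are gene symbols, values pathways.
#' @export
pathway_map <- function() {
  c(
    BRCA1 = "HR", BRCA2 = "HR", PALB2 = "HR", RAD51C = "HR", RAD51D = "HR",
    ATM = "DDR", CHEK2 = "DDR", TP53 = "DDR", NBN = "DDR", BLM = "DDR",
    PRF1 = "DDR",
    MSH2 = "MMR", MSH6 = "MMR", MLH1 = "MMR", PMS2 = "MMR",
    FANCA = "FA", FANCC = "FA", FANCM = "FA",
    ERCC2 = "NER", ERCC3 = "NER", XPC = "NER",
    RB1 = "cell cycle", CDKN2A = "cell cycle", CDK4 = "cell cycle",
    PTEN = "PI3K", TSC1 = "PI3K", TSC2 = "PI3K", STK11 = "PI3K",
    PIK3CA = "PI3K",
    APC = "Other", VHL = "Other", RET = "Other", KIT = "Other",
    SMAD4 = "Other", HNF1A = "Other"
  )
}

#' Build a synthetic targeted-panel design
#'
#' Generates an ordered set of exon targets (BED-style 0-based half-open
#' intervals) for `n_genes` genes laid out across chromosomes.  The first
#' genes take symbols from [predisposition_genes()] and are flagged as
#' cancer-predisposition genes; the remainder get synthetic `GENE###` symbols.
#'
#' @param n_genes Number of genes on the panel.
#' @param exons_per_gene Integer, or length-2 integer range, exons per gene.
#' @param exon_length_bp Length-2 range of exon lengths in bp.
#' @param intron_gap_bp Length-2 range of gaps between consecutive exons, bp.
#' @param seed Integer seed; the panel is deterministic given the seed.
#' @param n_predisposition Number of genes flagged as predisposition genes
#'   (capped at the packaged list length and at `n_genes`).
#'
#' @return A tibble of class `panel_design` with columns `chromosome`,
#'   `start`, `end`, `gene`, `exon_index`, `predisposition`, sorted by
#'   (chromosome, start).
#' @examples
#' panel <- build_panel(n_genes = 10, exons_per_gene = 5, seed = 1)
#' dplyr::count(panel, gene)
#' @export
build_panel <- function(n_genes,
                        exons_per_gene = c(5L, 20L),
                        exon_length_bp = c(80L, 300L),
                        intron_gap_bp = c(500L, 5000L),
                        seed = 1L,
                        n_predisposition = min(n_genes, length(predisposition_genes()))) {
  n_genes <- check_count(n_genes, "n_genes")
  if (length(exons_per_gene) == 1L) exons_per_gene <- rep(exons_per_gene, 2L)
  if (any(exons_per_gene < 1) || any(exon_length_bp < 1) || any(intron_gap_bp < 1)) {
    abort_invalid("exon counts, lengths and gaps must all be positive.")
  }
  n_predisposition <- min(n_predisposition, n_genes, length(predisposition_genes()))

  symbols <- character(n_genes)
  if (n_predisposition > 0) {
    symbols[seq_len(n_predisposition)] <- predisposition_genes()[seq_len(n_predisposition)]
  }
  if (n_genes > n_predisposition) {
    extra <- seq.int(n_predisposition + 1L, n_genes)
    symbols[extra] <- sprintf("GENE%03d", extra)
  }

  with_seed(seed, {
    chroms <- paste0("chr", rep_len(1:22, n_genes))
    rows <- vector("list", n_genes)
    offset <- stats::setNames(rep(1e6, 22), paste0("chr", 1:22))
    for (g in seq_len(n_genes)) {
      k <- if (exons_per_gene[1] == exons_per_gene[2]) exons_per_gene[1] else
        sample(seq.int(exons_per_gene[1], exons_per_gene[2]), 1L)
      lens <- sample(seq.int(exon_length_bp[1], exon_length_bp[2]), k, replace = TRUE)
      gaps <- sample(seq.int(intron_gap_bp[1], intron_gap_bp[2]), k, replace = TRUE)
      chrom <- chroms[g]
      pos <- offset[[chrom]]
      starts <- integer(k)
      ends <- integer(k)
      for (e in seq_len(k)) {
        starts[e] <- pos
        ends[e] <- pos + lens[e]
        pos <- ends[e] + gaps[e]
      }
      offset[[chrom]] <- pos + 5e4  # intergenic spacer: genes never overlap
      rows[[g]] <- tibble(
        chromosome = chrom, start = starts, end = ends,
        gene = symbols[g], exon_index = seq_len(k),
        predisposition = g <= n_predisposition
      )
    }
    panel <- list_rbind(rows) %>%
      arrange(factor(.data$chromosome, levels = paste0("chr", 1:22)), .data$start)
    class(panel) <- c("panel_design", class(panel))
    panel
  })
}

validate_panel <- function(panel) {
  if (!is.data.frame(panel) || nrow(panel) == 0) {
    abort_invalid("`panel` must be a non-empty panel_design data frame.")
  }
  req <- c("chromosome", "start", "end", "gene", "exon_index")
  missing <- setdiff(req, names(panel))
  if (length(missing)) {
    abort_invalid(paste0("panel is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(panel$start >= panel$end)) abort_invalid("every target must have positive length.")
  if (any(panel$exon_index < 1)) abort_invalid("exon_index must be >= 1.")
  invisible(panel)
}

# Stable target key used to align depth rows, SNPs and calls to the panel.
target_key <- function(panel) paste(panel$gene, panel$exon_index, sep = ":")
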