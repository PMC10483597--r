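# Plain-text interchange: BED targets, depth/SNP/segment/droplet TSVs,
# minimal VCF 4.2 for annotated small variants, truth JSON.

#' Write / read panel targets as BED6
#'
#' BED convention: 0-based half-open intervals; the name field carries
#' `gene|exon_index`; predisposition genes get score 1000, others 0.
#'
#' @param panel A `panel_design`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_targets_bed <- function(panel, path) {
  validate_panel(panel)
  bed <- tibble(
    chrom = panel$chromosome, start = panel$start, end = panel$end,
    name = paste(panel$gene, panel$exon_index, sep = "|"),
    score = ifelse(panel$predisposition %||% FALSE, 1000L, 0L),
    strand = "+"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_targets_bed
#' @export
read_targets_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                         show_col_types = FALSE)
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  panel <- tibble(
    chromosome = bed$chrom, start = bed$start, end = bed$end,
    gene = map_chr(parts, 1), exon_index = as.integer(map_chr(parts, 2)),
    predisposition = bed$score > 0
  )
  class(panel) <- c("panel_design", class(panel))
  validate_panel(panel)
}

#' Write / read a depth matrix as TSV
#'
#' One row per target (`gene`, `exon_index` first), one column per sample;
#' sample roles are stored in a `#roles:` comment line so the file is
#' self-contained.
#'
#' @param depth A `depth_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(depth, path) {
  stopifnot(inherits(depth, "depth_matrix"))
  writeLines(paste0("#roles:", paste(depth$samples$role, collapse = ",")), path)
  tbl <- bind_cols(
    tibble(gene = depth$panel$gene, exon_index = depth$panel$exon_index),
    as_tibble(depth$counts, .name_repair = "minimal")
  )
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @param panel Panel whose targets the depth rows must match.
#' @rdname write_depth_tsv
#' @export
read_depth_tsv <- function(path, panel) {
  roles_line <- readLines(path, n = 1L)
  roles <- strsplit(sub("^#roles:", "", roles_line), ",", fixed = TRUE)[[1]]
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  key_file <- paste(tbl$gene, tbl$exon_index, sep = ":")
  if (!identical(key_file, target_key(panel))) {
    abort_invalid("depth rows do not match the panel targets.")
  }
  counts <- as.matrix(tbl[, setdiff(names(tbl), c("gene", "exon_index"))])
  rownames(counts) <- key_file
  depth_matrix(counts, panel, roles)
}

#' Write / read SNP observations
#' @param snps SNP tibble from [simulate_snps()].
#' @param path File path.
#' @export
write_snps_tsv <- function(snps, path) {
  readr::write_tsv(snps, path)
  invisible(path)
}

#' @rdname write_snps_tsv
#' @export
read_snps_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write annotated small variants as a minimal VCF 4.2
#'
#' Annotation travels as INFO keys: `GENE`, `CSQ_CLASS` (consequence),
#' `POPAF_MAX`, `PRED_DEL_COUNT`, `PRED_TOTAL`, `CLNSIG` (assertion), and
#' `PGCLASS` when a classification has been assigned.  Reading requires
#' the vcfR package.
#'
#' @param variants Tibble with `patient_id`, `chromosome`, `position` and
#'   annotation columns (somatic tables may omit them).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  info <- map_chr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    kv <- c(
      SAMPLE = v$patient_id, GENE = v$gene,
      CSQ_CLASS = v[["consequence_class"]],
      POPAF_MAX = v[["popaf_max"]],
      PRED_DEL_COUNT = v[["pred_del_count"]],
      PRED_TOTAL = v[["pred_total"]],
      CLNSIG = v[["assertion"]],
      NONSYN = if (!is.null(v[["nonsynonymous"]])) as.integer(v$nonsynonymous),
      PGCLASS = v[["classification"]]
    )
    kv <- kv[!vapply(kv, is.null, TRUE)]
    paste(names(kv), unlist(kv), sep = "=", collapse = ";")
  })
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Patient identifier\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=POPAF_MAX,Number=1,Type=Float,Description=\"Max population allele frequency\">",
    "##INFO=<ID=PRED_DEL_COUNT,Number=1,Type=Integer,Description=\"Deleterious predictor calls\">",
    "##INFO=<ID=PRED_TOTAL,Number=1,Type=Integer,Description=\"Predictors evaluated\">",
    "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"Curated assertion\">",
    "##INFO=<ID=NONSYN,Number=1,Type=Integer,Description=\"Non-synonymous flag\">",
    "##INFO=<ID=PGCLASS,Number=1,Type=String,Description=\"Assigned pathogenicity class\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\tN\t<ALT>\t.\tPASS\t%s",
                  variants$chromosome, as.integer(variants$position), info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_variants_vcf
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    rlang::abort("reading VCF requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_field <- function(key) {
    unname(vcfR::extract.info(v, element = key))
  }
  out <- tibble(
    patient_id = info_field("SAMPLE"),
    chromosome = fix$CHROM,
    position = as.integer(fix$POS),
    gene = info_field("GENE"),
    consequence_class = info_field("CSQ_CLASS"),
    popaf_max = as.numeric(info_field("POPAF_MAX")),
    pred_del_count = as.integer(info_field("PRED_DEL_COUNT")),
    pred_total = as.integer(info_field("PRED_TOTAL")),
    assertion = info_field("CLNSIG"),
    nonsynonymous = as.integer(info_field("NONSYN")) == 1L,
    classification = info_field("PGCLASS")
  )
  out[, colSums(is.na(out)) < nrow(out) | names(out) %in%
        c("patient_id", "chromosome", "position", "gene")]
}

#' Write / read copy-number segments (SEG-like TSV)
#' @param segments Tibble `patient_id`, `chromosome`, `start`, `end`, `cn`.
#' @param path File path.
#' @export
write_segments_seg <- function(segments, path) {
  readr::write_tsv(segments, path)
  invisible(path)
}

#' @rdname write_segments_seg
#' @export
read_segments_seg <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
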