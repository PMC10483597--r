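# Rule-based germline pathogenicity classification.
#
# Emulates a clinical annotation workflow from fields carried on the input:
# an explicit curated assertion (ClinVar-style) wins; otherwise population
# allele frequency and in-silico predictor votes decide.  This is a
# documented, configurable stand-in for manual curation, not an ACMG engine.

#' Classification rule thresholds
#'
#' @param af_common Population allele frequency at or above which a variant
#'   is considered too common to be pathogenic (benign).
#' @param min_del_predictors Minimum number of deleterious predictor calls
#'   (of those evaluated) for a rare missense to be likely pathogenic.
#' @return A list of class `classify_rules`.
#' @export
classify_rules <- function(af_common = 0.005, min_del_predictors = 4L) {
  check_prob(af_common, "af_common")
  structure(list(af_common = af_common,
                 min_del_predictors = as.integer(min_del_predictors)),
            class = "classify_rules")
}

#' Classify germline SNVs/InDels
#'
#' Precedence: (1) an explicit assertion `P`/`LP`/`B` passes through;
#' (2) `popaf_max >= af_common` is benign; (3) a rare loss-of-function
#' variant on a predisposition gene is likely pathogenic; (4) a rare
#' missense with enough deleterious predictor votes is likely pathogenic;
#' anything else is a VUS.  Likely pathogenic is counted together with
#' pathogenic wherever "pathogenic germline mutation" carriers are tallied;
#' `is_pathogenic()` exposes that combined flag.
#'
#' @param variants Tibble with columns `gene`, `consequence_class`
#'   (`lof`/`missense`/`other`), `popaf_max`, `pred_del_count`,
#'   `pred_total`, `assertion` (`P`/`LP`/`VUS`/`B`/`none`).
#' @param predisposition Character vector of predisposition gene symbols.
#' @param rules A [classify_rules()].
#' @return `variants` with a `classification` column
#'   (`pathogenic` / `likely_pathogenic` / `VUS` / `benign`).
#' @export
classify_snv <- function(variants, predisposition = predisposition_genes(),
                         rules = classify_rules()) {
  if (!nrow(variants)) {
    variants$classification <- character()
    return(variants)
  }
  with(variants, {
    if (any(pred_del_count > pred_total | pred_del_count < 0 | pred_total > 6)) {
      abort_invalid("predictor counts must satisfy 0 <= pred_del_count <= pred_total <= 6.")
    }
    if (any(popaf_max < 0 | popaf_max > 1)) {
      abort_invalid("popaf_max must lie in [0, 1].")
    }
  })
  variants$classification <- dplyr::case_when(
    variants$assertion == "P" ~ "pathogenic",
    variants$assertion == "LP" ~ "likely_pathogenic",
    variants$assertion == "B" ~ "benign",
    variants$popaf_max >= rules$af_common ~ "benign",
    variants$consequence_class == "lof" &
      variants$gene %in% predisposition ~ "likely_pathogenic",
    variants$consequence_class == "missense" &
      variants$pred_del_count >= rules$min_del_predictors ~ "likely_pathogenic",
    TRUE ~ "VUS"
  )
  variants
}

#' Classify germline LGR events
#'
#' A whole-exon deletion on a cancer-predisposition gene is pathogenic (it
#' disrupts the reading frame or removes coding sequence of a gene whose
#' loss predisposes to cancer); an internal duplication of such a gene is
#' likely pathogenic; events on other genes are VUS.  Whole-gene
#' duplications do not disrupt the gene and default to VUS.
#'
#' @param calls Tibble of LGR calls with columns `gene`, `event_type` and
#'   optionally `exon_from`/`exon_to`.
#' @param predisposition Character vector of predisposition gene symbols.
#' @param whole_gene_dup_class Class assigned to whole-gene duplications
#'   (requires a `whole_gene` logical column to take effect).
#' @return Character vector of classes, one per call.
#' @export
classify_lgr <- function(calls, predisposition = predisposition_genes(),
                         whole_gene_dup_class = "VUS") {
  if (!nrow(calls)) return(character())
  on_list <- calls$gene %in% predisposition
  whole <- if ("whole_gene" %in% names(calls)) calls$whole_gene else FALSE
  dplyr::case_when(
    !on_list ~ "VUS",
    calls$event_type == "deletion" ~ "pathogenic",
    calls$event_type == "duplication" & whole ~ whole_gene_dup_class,
    calls$event_type == "duplication" ~ "likely_pathogenic",
    TRUE ~ "VUS"
  )
}

#' Combined pathogenic flag
#'
#' Pathogenic germline mutation carriers include likely pathogenic ones.
#'
#' @param classification Character vector of classes.
#' @return Logical vector.
#' @export
is_pathogenic <- function(classification) {
  classification %in% c("pathogenic", "likely_pathogenic")
}
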