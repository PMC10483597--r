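# Per-sample genome instability metrics: TMB, CIN, WGD, MSI.

#' Tumor mutation burden
#'
#' Non-synonymous somatic mutations per megabase of sequenced territory.
#'
#' @param nonsynonymous_count Number of non-synonymous somatic mutations.
#' @param panel_size_mb Sequenced footprint in Mb.
#' @return Mutations per Mb.
#' @export
tmb <- function(nonsynonymous_count, panel_size_mb) {
  if (any(panel_size_mb <= 0)) abort_invalid("`panel_size_mb` must be > 0.")
  if (any(nonsynonymous_count < 0)) abort_invalid("mutation counts must be >= 0.")
  nonsynonymous_count / panel_size_mb
}

validate_segments <- function(segments) {
  if (!nrow(segments)) abort_degenerate("empty segment list.")
  req <- c("chromosome", "start", "end", "cn")
  missing <- setdiff(req, names(segments))
  if (length(missing)) {
    abort_invalid(paste0("segments missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(segments$start >= segments$end)) abort_invalid("segments need start < end.")
  if (any(segments$cn < 0)) abort_invalid("segment copy numbers must be >= 0.")
  invisible(segments)
}

#' Chromosomal instability (CIN)
#'
#' The percentage of copy-number segments whose copy number deviates from
#' neutral.  Following the segment-count definition, splitting a segment
#' into abutting halves changes the denominator; a base-pair-weighted
#' variant is available behind `bp_weighted`.
#'
#' @param segments Tibble with `chromosome`, `start`, `end`, `cn`.
#' @param neutral_cn Neutral copy number (default diploid).
#' @param bp_weighted If `TRUE`, weight segments by length instead of
#'   counting them.
#' @return Percentage in \[0, 100\].
#' @export
cin <- function(segments, neutral_cn = 2, bp_weighted = FALSE) {
  validate_segments(segments)
  altered <- segments$cn != neutral_cn
  if (bp_weighted) {
    len <- segments$end - segments$start
    100 * sum(len[altered]) / sum(len)
  } else {
    100 * sum(altered) / nrow(segments)
  }
}

#' Whole-genome duplication status
#'
#' A segment with copy number strictly greater than two carries a
#' duplication event; the sample is WGD when the summed length of
#' duplicated segments strictly exceeds 50% of the total length covered by
#' its segment profile.
#'
#' @inheritParams cin
#' @return Logical.
#' @export
is_wgd <- function(segments) {
  validate_segments(segments)
  len <- segments$end - segments$start
  sum(len[segments$cn > 2]) > 0.5 * sum(len)
}

#' WGD ratio of a group
#'
#' @param profiles A list of segment tibbles, or one tibble with a
#'   `patient_id` column.
#' @return Proportion of samples that are WGD.
#' @export
wgd_ratio <- function(profiles) {
  if (is.data.frame(profiles)) {
    if (!"patient_id" %in% names(profiles)) {
      abort_invalid("a single segment table needs a `patient_id` column.")
    }
    profiles <- split(profiles, profiles$patient_id)
  }
  if (!length(profiles)) abort_degenerate("empty sample group.")
  mean(map_lgl(profiles, is_wgd))
}

#' Classify microsatellite instability status
#'
#' Threshold on the fraction of unstable microsatellite sites; at or above
#' the threshold the sample is MSI-high, below it microsatellite stable.
#'
#' @param unstable_fraction Fraction of unstable sites, in \[0, 1\].
#' @param threshold Decision threshold (inclusive).
#' @return `"MSI-H"` or `"MSS"` (vectorized).
#' @export
msi_classify <- function(unstable_fraction, threshold = 0.4) {
  if (any(unstable_fraction < 0 | unstable_fraction > 1)) {
    abort_invalid("`unstable_fraction` must lie in [0, 1].")
  }
  ifelse(unstable_fraction >= threshold, "MSI-H", "MSS")
}

#' Per-sample metric table
#'
#' Computes TMB, CIN, WGD and MSI status for every patient from somatic
#' calls, segment profiles and unstable-site fractions.
#'
#' @param somatic Somatic mutation tibble with `patient_id` and a logical
#'   `nonsynonymous` column.
#' @param segments Segment tibble with `patient_id`.
#' @param msi Tibble with `patient_id` and `unstable_fraction`.
#' @param panel_size_mb Sequenced footprint in Mb.
#' @param msi_threshold Threshold for [msi_classify()].
#' @return Tibble: `patient_id`, `tmb`, `cin`, `wgd`, `msi_status`.
#' @export
sample_metrics <- function(somatic, segments, msi, panel_size_mb,
                           msi_threshold = 0.4) {
  ids <- unique(c(somatic$patient_id, segments$patient_id, msi$patient_id))
  ns <- somatic %>%
    filter(.data$nonsynonymous) %>%
    count(.data$patient_id, name = "n_nonsyn")
  seg_split <- split(segments, segments$patient_id)
  tibble(patient_id = ids) %>%
    left_join(ns, by = "patient_id") %>%
    mutate(
      tmb = tmb(dplyr::coalesce(.data$n_nonsyn, 0L), panel_size_mb),
      cin = map_dbl(.data$patient_id, function(p) {
        if (p %in% names(seg_split)) cin(seg_split[[p]]) else NA_real_
      }),
      wgd = map_lgl(.data$patient_id, function(p) {
        if (p %in% names(seg_split)) is_wgd(seg_split[[p]]) else NA
      })
    ) %>%
    left_join(select(msi, "patient_id", "unstable_fraction"), by = "patient_id") %>%
    mutate(msi_status = ifelse(is.na(.data$unstable_fraction), NA_character_,
                               msi_classify(dplyr::coalesce(.data$unstable_fraction, 0),
                                            msi_threshold))) %>%
    select("patient_id", "tmb", "cin", "wgd", "msi_status", "unstable_fraction")
}
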