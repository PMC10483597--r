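# ddPCR validation: positivity rule, Poisson copy-number estimation against
# a stable reference gene, and exon-level NGS-vs-ddPCR concordance.

#' ddPCR well positivity rule
#'
#' A well is positive when it has at least three positive droplets and the
#' positive-droplet count strictly exceeds three times the mean positive
#' count over the negative-control baseline replicates (NA18535-style).
#'
#' @param positive Positive droplet count in the well.
#' @param baseline_positive Numeric vector of positive counts over the
#'   baseline replicates (conventionally five).
#' @return `"positive"` or `"negative"`.
#' @examples
#' classify_well(10, c(1, 1, 1, 1, 1))  # positive
#' classify_well(9, c(3, 3, 3, 3, 3))   # negative: 9 is not > 9
#' @export
classify_well <- function(positive, baseline_positive) {
  if (length(baseline_positive) < 1L) abort_invalid("baseline replicates must be supplied.")
  if (positive < 0 || any(baseline_positive < 0)) {
    abort_invalid("droplet counts must be non-negative.")
  }
  if (positive >= 3 && positive > 3 * mean(baseline_positive)) "positive" else "negative"
}

#' Poisson copy-number estimate from droplet counts
#'
#' Each channel's molecule concentration is the Poisson correction
#' `lambda = -ln(1 - positive/total)`; copy number is the target-to-
#' reference concentration ratio scaled by the reference gene's copy number
#' (RPP30-like reference, assumed copy-number stable at 2).
#'
#' @param target,reference One-row data frames or lists with `positive` and
#'   `total` droplet counts for the target and reference channels.
#' @param reference_cn Copy number of the reference locus.
#' @return Estimated copy number; `NA` (with a warning) when the reference
#'   channel has no positive droplets.
#' @export
estimate_copy_number <- function(target, reference, reference_cn = 2) {
  for (w in list(target, reference)) {
    if (w$total <= 0 || w$positive < 0 || w$positive > w$total) {
      abort_invalid("wells need 0 <= positive <= total with total > 0.")
    }
  }
  if (target$positive == target$total || reference$positive == reference$total) {
    rlang::abort("saturated channel: every droplet positive, concentration unresolvable.",
                 class = "lgrscan_saturation")
  }
  lam_t <- -log(1 - target$positive / target$total)
  lam_r <- -log(1 - reference$positive / reference$total)
  if (lam_r == 0) {
    rlang::warn("reference channel has zero concentration; copy number undefined.")
    return(NA_real_)
  }
  reference_cn * lam_t / lam_r
}

#' Exon-level confusion matrix between NGS and ddPCR calls
#'
#' ddPCR is treated as the reference method and NGS as the prediction
#' (configurable by swapping arguments).  Both inputs are per-exon logical
#' flags over the same exon universe.
#'
#' @param ngs_states,ddpcr_states Logical vectors (or tibbles with columns
#'   `exon` and `state`) of per-exon event flags.
#' @return A one-row tibble of class `confusion_matrix` with columns `tp`,
#'   `fn`, `fp`, `tn`, `n`.
#' @export
exon_concordance <- function(ngs_states, ddpcr_states) {
  if (is.data.frame(ngs_states)) {
    if (!setequal(ngs_states$exon, ddpcr_states$exon)) {
      abort_invalid("NGS and ddPCR exon universes differ.")
    }
    ddpcr_states <- ddpcr_states$state[match(ngs_states$exon, ddpcr_states$exon)]
    ngs_states <- ngs_states$state
  }
  if (length(ngs_states) != length(ddpcr_states)) {
    abort_invalid("NGS and ddPCR exon universes differ.")
  }
  confusion_matrix(
    tp = sum(ngs_states & ddpcr_states),
    fn = sum(!ngs_states & ddpcr_states),
    fp = sum(ngs_states & !ddpcr_states),
    tn = sum(!ngs_states & !ddpcr_states)
  )
}

#' Construct a confusion matrix
#'
#' @param tp,fn,fp,tn Non-negative integer exon counts (ddPCR as truth,
#'   NGS as prediction).
#' @return One-row tibble of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0) || any(v != floor(v))) {
    abort_invalid("confusion-matrix cells must be non-negative integers.")
  }
  out <- tibble(tp = as.integer(tp), fn = as.integer(fn),
                fp = as.integer(fp), tn = as.integer(tn),
                n = as.integer(tp + fn + fp + tn))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Concordance metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and accuracy
#' `(tp+tn)/n`, reported as percentages rounded half-up to two decimals;
#' metrics with an empty denominator are `NA`.
#'
#' @param cm A `confusion_matrix` (or anything with `tp`, `fn`, `fp`, `tn`).
#' @return One-row tibble: `sensitivity_pct`, `specificity_pct`,
#'   `accuracy_pct`, `concordant`, `n`.
#' @export
concordance_metrics <- function(cm) {
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n == 0) abort_degenerate("empty confusion matrix.")
  sens <- if (cm$tp + cm$fn > 0) 100 * cm$tp / (cm$tp + cm$fn) else NA_real_
  spec <- if (cm$tn + cm$fp > 0) 100 * cm$tn / (cm$tn + cm$fp) else NA_real_
  tibble(
    sensitivity_pct = round_half_up(sens, 2),
    specificity_pct = round_half_up(spec, 2),
    accuracy_pct = round_half_up(100 * (cm$tp + cm$tn) / n, 2),
    concordant = as.integer(cm$tp + cm$tn),
    n = as.integer(n)
  )
}

#' Recover the integer confusion matrix behind printed concordance metrics
#'
#' Published validation summaries often print only the exon total, the
#' concordant-call count, and sensitivity/specificity percentages.  This
#' exhaustively searches all non-negative integer tables
#' `(tp, fn, fp, tn)` with `tp+fn+fp+tn = n` and `tp+tn = concordant` whose
#' sensitivity and specificity round (half-up) to the printed two-decimal
#' percentages.
#'
#' @param n Total exon count.
#' @param concordant Concordant exon-call count (`tp + tn`).
#' @param sensitivity_pct,specificity_pct Printed percentages (2 dp).
#' @return A `confusion_matrix` tibble with one row per consistent table
#'   (an `ambiguous` attribute is `TRUE` when more than one exists); errors
#'   when no table is consistent.
#' @export
solve_confusion <- function(n, concordant, sensitivity_pct, specificity_pct) {
  n <- check_count(n, "n")
  concordant <- check_count(concordant, "concordant", min = 0L)
  if (concordant > n) abort_invalid("`concordant` cannot exceed `n`.")
  sols <- list()
  for (tp in 0:concordant) {
    tn <- concordant - tp
    for (fn in 0:(n - concordant)) {
      fp <- n - concordant - fn
      sens <- if (tp + fn > 0) round_half_up(100 * tp / (tp + fn), 2) else NA_real_
      spec <- if (tn + fp > 0) round_half_up(100 * tn / (tn + fp), 2) else NA_real_
      if (isTRUE(sens == sensitivity_pct) && isTRUE(spec == specificity_pct)) {
        sols[[length(sols) + 1L]] <- confusion_matrix(tp, fn, fp, tn)
      }
    }
  }
  if (!length(sols)) {
    rlang::abort("no integer confusion matrix is consistent with these metrics.",
                 class = "lgrscan_inconsistent")
  }
  out <- list_rbind(sols)
  class(out) <- c("confusion_matrix", class(out))
  attr(out, "ambiguous") <- nrow(out) > 1L
  if (nrow(out) > 1L) {
    rlang::warn(sprintf("%d confusion matrices are consistent; all returned.", nrow(out)))
  }
  out
}
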