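# Exon-level germline LGR caller.
#
# Depth is normalized against a panel of reference normals with a
# median-of-ratios size factor; per-target log2ratios are thresholded into
# deletion / duplication / neutral states, checked against SNP zygosity
# (heterozygous B-allele fractions are incompatible with a one-copy region),
# and merged into contiguous whole-exon events.  Each event carries a
# variance-to-previous (VP) quality value: the mean squared difference
# between consecutive target log2ratios across the event span.

#' Caller thresholds and QC parameters
#'
#' @param del_het Log2ratio at or below which a target is called deleted
#'   (a heterozygous single-copy loss sits at -1).
#' @param del_hom Log2ratio at or below which a deletion is considered
#'   homozygous (copy number 0).
#' @param dup Log2ratio at or above which a target is called duplicated
#'   (a single-copy gain sits at +0.585).
#' @param single_del,single_dup Stricter log2ratio thresholds a single-exon
#'   event must reach when it lacks supporting SNP zygosity evidence.
#' @param gap_max Maximum number of intervening neutral/QC-failed exons an
#'   event may bridge.
#' @param extend_frac Boundary refinement: an exon immediately adjacent to
#'   an assembled event is absorbed into it when its log2ratio passes
#'   `extend_frac` times the calling threshold (sub-threshold but clearly
#'   shifted edges belong to the event).
#' @param vp_max VP value above which an event fails QC.
#' @param max_het_fraction Maximum tolerated fraction of heterozygous-BAF
#'   SNPs inside a candidate deletion span.
#' @param min_snp_depth Minimum SNP depth to count as informative.
#' @param dup_baf_band Four numbers `(lo1, hi1, lo2, hi2)`: the BAF windows
#'   around 1/3 and 2/3 consistent with a three-copy heterozygote.
#' @param dup_support_frac Minimum fraction of heterozygous-BAF SNPs inside
#'   the duplication BAF windows for a duplication to count as supported.
#' @param pseudo_count Added to depths before taking ratios so log2ratios
#'   stay finite at zero coverage.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(del_het = -0.6, del_hom = -2.5, dup = 0.45,
                          single_del = -0.8, single_dup = 0.55,
                          gap_max = 1L, extend_frac = 0.75, vp_max = 0.09,
                          max_het_fraction = 0.10, min_snp_depth = 20L,
                          dup_baf_band = c(0.28, 0.40, 0.60, 0.72),
                          dup_support_frac = 0.6, pseudo_count = 0.5) {
  if (!(del_hom < del_het && del_het < 0 && dup > 0)) {
    abort_invalid("thresholds must satisfy del_hom < del_het < 0 < dup.")
  }
  structure(
    list(del_het = del_het, del_hom = del_hom, dup = dup,
         single_del = single_del, single_dup = single_dup,
         gap_max = as.integer(gap_max), extend_frac = extend_frac,
         vp_max = vp_max,
         max_het_fraction = max_het_fraction,
         min_snp_depth = min_snp_depth, dup_baf_band = dup_baf_band,
         dup_support_frac = dup_support_frac, pseudo_count = pseudo_count),
    class = "caller_params"
  )
}

# Per-target baseline from the reference normals: scale each normal by its
# median-of-ratios size factor, then take the per-target median.
baseline_from_normals <- function(depth, pseudo_count = 0.5) {
  normals <- depth$counts[, depth$samples$role == "reference_normal", drop = FALSE]
  if (ncol(normals) < 2L) abort_invalid("need >= 2 reference normals.")
  m0 <- apply(normals, 1, median)
  ok <- m0 > 0
  s_n <- apply(normals, 2, function(d) median(d[ok] / m0[ok]))
  scaled <- sweep(normals, 2, s_n, "/")
  m_t <- pmax(apply(scaled, 1, median), pseudo_count)
  attr(m_t, "baseline_n") <- ncol(normals)
  m_t
}

#' Normalize a sample's depth to log2ratios
#'
#' Computes `l_t = log2(((d_t + c) / s) / m_t)` where `m_t` is the per-target
#' median depth over size-factor-scaled reference normals, `s` the sample's
#' median-of-ratios size factor `median(d_t / m_t)`, and `c` a pseudo-count.
#' Copy-neutral targets have expected log2ratio near 0; a heterozygous
#' deletion sits near -1 and a single-copy duplication near +0.585.
#'
#' @param depth A `depth_matrix`.
#' @param sample_id Sample to normalize (must be present in `depth`).
#' @param params A [caller_params()].
#' @param baseline Optional precomputed baseline from the reference normals
#'   (recomputed from `depth` when `NULL`).
#' @return A tibble of class `log2ratio_track`: the panel columns plus
#'   `sample_id` and `l`, with attribute `baseline_n`.
#' @export
normalize_depth <- function(depth, sample_id, params = caller_params(),
                            baseline = NULL) {
  stopifnot(inherits(depth, "depth_matrix"))
  if (!sample_id %in% colnames(depth$counts)) {
    abort_invalid(sprintf("sample '%s' not found in depth matrix.", sample_id))
  }
  if (is.null(baseline)) {
    baseline <- baseline_from_normals(depth, params$pseudo_count)
  }
  d <- depth$counts[, sample_id]
  if (all(d == 0)) abort_degenerate(sprintf("sample '%s' has zero depth everywhere.", sample_id))
  s <- median(d / baseline)
  if (s <= 0) abort_degenerate(sprintf("sample '%s' has a non-positive size factor.", sample_id))
  l <- log2(((d + params$pseudo_count) / s) / baseline)
  track <- as_tibble(depth$panel)
  track$sample_id <- sample_id
  track$l <- unname(l)
  attr(track, "baseline_n") <- attr(baseline, "baseline_n")
  class(track) <- c("log2ratio_track", class(track))
  track
}

# Log2ratio matrix for every case sample at once (targets x samples).
normalize_all_cases <- function(depth, params = caller_params()) {
  baseline <- baseline_from_normals(depth, params$pseudo_count)
  case_ids <- depth$samples$sample_id[depth$samples$role == "case"]
  d <- depth$counts[, case_ids, drop = FALSE]
  if (any(colSums(d) == 0)) abort_degenerate("a case sample has zero depth everywhere.")
  s <- apply(d / baseline, 2, median)
  l <- log2(sweep(sweep(d + params$pseudo_count, 2, s, "/"), 1, baseline, "/"))
  attr(l, "baseline_n") <- attr(baseline, "baseline_n")
  l
}

#' Variance-to-previous (VP) quality metric
#'
#' For an ordered span of targets `t_1..t_k`,
#' `VP = (1/k) * sum_i (l[t_i] - l[t_(i-1)])^2`, where `t_0` is the target
#' immediately preceding the span within the same gene, or the gene-median
#' log2ratio when the span starts at the gene's first exon.  A clean event
#' (flat shifted segment over a flat background) has VP driven only by the
#' two transition terms; a noisy, fragmented candidate has a large VP.
#'
#' @param track A `log2ratio_track`.
#' @param span Integer vector of row indices into `track`, contiguous and
#'   increasing, all within one gene.
#' @return Non-negative VP value.
#' @export
variance_to_previous <- function(track, span) {
  if (length(span) == 0) abort_invalid("`span` must be non-empty.")
  span <- as.integer(span)
  if (any(span < 1 | span > nrow(track))) abort_invalid("`span` indexes unknown targets.")
  if (is.unsorted(span, strictly = TRUE)) abort_invalid("`span` must be increasing.")
  gene <- unique(track$gene[span])
  if (length(gene) != 1L) abort_invalid("`span` must lie within a single gene.")
  l <- track$l
  first <- span[1]
  prev_in_gene <- first > 1 && track$gene[first - 1L] == gene
  l0 <- if (prev_in_gene) l[first - 1L] else median(l[track$gene == gene])
  seq_l <- c(l0, l[span])
  mean(diff(seq_l)^2)
}

#' Call per-exon copy-number states
#'
#' Thresholds each target's log2ratio: deletion at `l <= del_het`,
#' duplication at `l >= dup`, neutral otherwise (thresholds inclusive).
#' The integer copy-state estimate is `round(2 * 2^l)` clipped at 0.
#'
#' @param track A `log2ratio_track`.
#' @param params A [caller_params()].
#' @return Tibble: the track plus `state` and `copy_state_estimate`.
#' @export
call_exon_states <- function(track, params = caller_params()) {
  out <- as_tibble(track)
  out$state <- dplyr::case_when(
    out$l <= params$del_het ~ "deletion",
    out$l >= params$dup ~ "duplication",
    TRUE ~ "neutral"
  )
  out$copy_state_estimate <- pmax(round(2 * 2^out$l), 0)
  out
}

map_snps_to_targets <- function(snps, panel) {
  if (is.null(snps) || !nrow(snps)) return(snps)
  if (all(c("gene", "exon_index") %in% names(snps))) return(snps)
  hit <- map_int(seq_len(nrow(snps)), function(i) {
    j <- which(panel$chromosome == snps$chromosome[i] &
                 panel$start < snps$position[i] &
                 panel$end >= snps$position[i])
    if (length(j)) j[1] else NA_integer_
  })
  snps$gene <- panel$gene[hit]
  snps$exon_index <- panel$exon_index[hit]
  snps[!is.na(hit), ]
}

#' Annotate exon-state calls with SNP zygosity support
#'
#' A heterozygous deletion leaves one allele, so SNPs inside a true CN = 1
#' span must read homozygous; observing heterozygous B-allele fractions
#' contradicts the call.  A three-copy duplication shifts heterozygous BAFs
#' to 1/3 or 2/3.  Support is assessed per contiguous same-state run:
#'
#' * deletion runs: `contradicted` when more than `max_het_fraction` of
#'   informative SNPs (depth >= `min_snp_depth`) have BAF in (0.2, 0.8);
#'   `supported` when at least one informative SNP and the heterozygous
#'   fraction is within tolerance; `uninformative` with no informative SNPs.
#' * duplication runs: `supported` when at least `dup_support_frac` of
#'   heterozygous-BAF SNPs fall in the 1/3 / 2/3 windows.
#'
#' Contradicted single-exon calls are reset to neutral (dropped);
#' contradicted multi-exon runs keep their state but are flagged
#' `zyg_qc_fail` so the downstream event fails QC rather than vanishing.
#'
#' @param calls Output of [call_exon_states()] for one sample.
#' @param snps SNP observations for the same sample (columns `gene`,
#'   `exon_index` or `chromosome`+`position`, `ref_depth`, `alt_depth`).
#' @param params A [caller_params()].
#' @return `calls` plus columns `zygosity_support` and `zyg_qc_fail`.
#' @export
zygosity_filter <- function(calls, snps = NULL, params = caller_params()) {
  calls$zygosity_support <- "uninformative"
  calls$zyg_qc_fail <- FALSE
  if (is.null(snps) || !nrow(snps)) return(calls)
  snps <- map_snps_to_targets(snps, calls)
  if (!nrow(snps)) return(calls)
  snps <- snps %>%
    mutate(
      depth = .data$ref_depth + .data$alt_depth,
      baf = ifelse(.data$depth > 0, .data$alt_depth / .data$depth, NA_real_)
    ) %>%
    filter(.data$depth >= params$min_snp_depth, !is.na(.data$baf))

  runs <- calls %>%
    mutate(.row = row_number()) %>%
    filter(.data$state != "neutral") %>%
    group_by(.data$gene, .data$state) %>%
    mutate(run = cumsum(c(1L, diff(.data$exon_index) != 1L))) %>%
    ungroup()
  if (!nrow(runs)) return(calls)

  for (grp in split(runs, paste(runs$gene, runs$state, runs$run))) {
    sn <- filter(snps, .data$gene == grp$gene[1],
                 .data$exon_index %in% grp$exon_index)
    het <- sn$baf > 0.2 & sn$baf < 0.8
    support <- "uninformative"
    if (grp$state[1] == "deletion") {
      if (nrow(sn) > 0) {
        het_frac <- mean(het)
        support <- if (het_frac > params$max_het_fraction) "contradicted" else "supported"
      }
    } else {
      b <- params$dup_baf_band
      in_band <- (sn$baf >= b[1] & sn$baf <= b[2]) | (sn$baf >= b[3] & sn$baf <= b[4])
      if (any(het)) {
        support <- if (mean(in_band[het]) >= params$dup_support_frac) "supported" else "uninformative"
      }
    }
    calls$zygosity_support[grp$.row] <- support
    if (support == "contradicted") {
      if (nrow(grp) == 1L) {
        calls$state[grp$.row] <- "neutral"        # single-exon: drop
      } else {
        calls$zyg_qc_fail[grp$.row] <- TRUE       # multi-exon: flag, keep
      }
    }
  }
  calls
}

#' Merge per-exon states into LGR events
#'
#' Consecutive same-state exons of one gene become one event; up to
#' `gap_max` intervening neutral or QC-failed exons may be bridged.  A
#' single-exon event must either have supporting zygosity evidence or reach
#' the stricter single-exon log2ratio threshold; otherwise it is discarded
#' as likely noise.
#'
#' Event QC uses the within-span VP: the mean squared difference between
#' consecutive log2ratios inside the event (0 for a single exon).  A real
#' copy-number event is a flat shifted segment, so its within-span VP stays
#' near twice the per-target noise variance, while a fragmented noise
#' artifact scatters.  The transition into the event is deliberately
#' excluded: a genuine deletion necessarily contains a ~1 log2 jump at its
#' boundary, which says nothing about call quality.
#' `qc_pass = (VP <= vp_max)` and no zygosity contradiction.
#'
#' @param calls Exon-state calls for one sample, in panel order, from
#'   [call_exon_states()] (optionally through [zygosity_filter()]).
#' @param track The `log2ratio_track` the calls came from.
#' @param params A [caller_params()].
#' @return Tibble of LGR events: `gene`, `exon_from`, `exon_to`,
#'   `event_type`, `mean_l`, `vp`, `copy_state_estimate`,
#'   `zygosity_support`, `qc_pass`.
#' @export
merge_calls <- function(calls, track, params = caller_params()) {
  ord <- order(factor(calls$chromosome, levels = unique(track$chromosome)), calls$start)
  if (is.unsorted(ord, strictly = TRUE)) abort_invalid("`calls` must be in panel order.")
  if (!"zygosity_support" %in% names(calls)) {
    calls$zygosity_support <- "uninformative"
    calls$zyg_qc_fail <- FALSE
  }
  events <- list()
  hits <- filter(calls, .data$state != "neutral")
  if (!nrow(hits)) return(empty_lgr_calls())
  for (grp in split(hits, paste(hits$gene, hits$state))) {
    grp <- arrange(grp, .data$exon_index)
    cluster <- cumsum(c(1L, diff(grp$exon_index) - 1L > params$gap_max))
    for (cl in split(grp, cluster)) {
      from <- min(cl$exon_index); to <- max(cl$exon_index)
      # boundary refinement: absorb adjacent sub-threshold but shifted exons
      gene_l <- track$l[track$gene == cl$gene[1]]
      names(gene_l) <- track$exon_index[track$gene == cl$gene[1]]
      passes <- function(e) {
        l <- gene_l[as.character(e)]
        !is.na(l) && if (cl$state[1] == "deletion") {
          l <= params$extend_frac * params$del_het
        } else {
          l >= params$extend_frac * params$dup
        }
      }
      while (passes(from - 1L)) from <- from - 1L
      while (passes(to + 1L)) to <- to + 1L
      support <- if (any(cl$zygosity_support == "contradicted")) "contradicted"
        else if (any(cl$zygosity_support == "supported")) "supported"
        else "uninformative"
      span_rows <- which(track$gene == cl$gene[1] &
                           track$exon_index >= from & track$exon_index <= to)
      mean_l <- mean(track$l[span_rows])
      if (from == to) {
        strict_ok <- if (cl$state[1] == "deletion") mean_l <= params$single_del
          else mean_l >= params$single_dup
        if (!(support == "supported" || strict_ok)) next
      }
      vp <- if (length(span_rows) > 1L) mean(diff(track$l[span_rows])^2) else 0
      events[[length(events) + 1L]] <- tibble(
        gene = cl$gene[1], exon_from = from, exon_to = to,
        event_type = cl$state[1], mean_l = mean_l, vp = vp,
        copy_state_estimate = max(round(2 * 2^mean_l), 0),
        zygosity_support = support,
        qc_pass = vp <= params$vp_max && !any(cl$zyg_qc_fail)
      )
    }
  }
  if (!length(events)) return(empty_lgr_calls())
  list_rbind(events) %>% arrange(.data$gene, .data$exon_from)
}

empty_lgr_calls <- function() {
  tibble(gene = character(), exon_from = integer(), exon_to = integer(),
         event_type = character(), mean_l = numeric(), vp = numeric(),
         copy_state_estimate = numeric(), zygosity_support = character(),
         qc_pass = logical())
}

#' Call germline LGRs for every case sample
#'
#' Orchestrates the full detection path per case sample: baseline
#' normalization against the reference normals, per-exon state calling,
#' SNP-zygosity annotation, event merging and pathogenicity classification.
#' Deterministic given its inputs.
#'
#' @param depth A `depth_matrix` containing case and reference-normal
#'   samples.
#' @param snps SNP observations for the case samples (may be `NULL`; calls
#'   are then emitted with `zygosity_support = "uninformative"`).
#' @param params A [caller_params()].
#' @return Tibble of LGR calls across samples, with `sample_id` and a
#'   `pathogenicity` class per event.
#' @examples
#' panel <- build_panel(n_genes = 8, exons_per_gene = 6, seed = 2)
#' cs <- tibble::tibble(sample_id = "S1", gene = "BRCA1",
#'                      exon_from = 2L, exon_to = 4L, cn = 1L)
#' d <- simulate_depth(panel, cs, sim_config(seed = 2))
#' call_lgrs(d)
#' @export
call_lgrs <- function(depth, snps = NULL, params = caller_params()) {
  stopifnot(inherits(depth, "depth_matrix"))
  l_mat <- normalize_all_cases(depth, params)
  panel_tbl <- as_tibble(depth$panel)
  pred_set <- unique(panel_tbl$gene[panel_tbl$predisposition %||% FALSE])

  del <- l_mat <= params$del_het
  dup <- l_mat >= params$dup
  candidates <- colnames(l_mat)[colSums(del | dup) > 0]

  out <- map(candidates, function(sid) {
    track <- panel_tbl
    track$sample_id <- sid
    track$l <- l_mat[, sid]
    class(track) <- c("log2ratio_track", class(track))
    calls <- call_exon_states(track, params)
    s_snps <- if (!is.null(snps) && nrow(snps)) filter(snps, .data$sample_id == sid)
    calls <- zygosity_filter(calls, s_snps, params)
    ev <- merge_calls(calls, track, params)
    if (nrow(ev)) mutate(ev, sample_id = sid, .before = 1)
  })
  out <- list_rbind(keep(out, ~ !is.null(.x)))
  if (!nrow(out)) {
    out <- mutate(empty_lgr_calls(), sample_id = character(), .before = 1)
  }
  out$pathogenicity <- classify_lgr(out, pred_set)
  class(out) <- c("lgr_calls", class(out))
  out
}
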