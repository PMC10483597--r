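# Cohort-level analytics: grouping, double hits, rate comparisons,
# co-occurrence, clinical tables, exon hotspots.

GROUP_LEVELS <- c("Without", "SNV_InDel", "LGR", "Both")

#' Assign patients to germline mutation groups
#'
#' Splits the cohort by pathogenic germline mutation status: `Without`,
#' `SNV_InDel` only, `LGR` only, or `Both`.  Patients carrying both kinds
#' are flagged `excluded` from between-group statistics (their group
#' membership is ambiguous) but retained in totals.
#'
#' @param patients Tibble with `patient_id`.
#' @param lgrs LGR calls with `sample_id` or `patient_id` and a
#'   `pathogenicity` (or `classification`) column.
#' @param snvs Germline SNV/InDel calls with `patient_id` and
#'   `classification`.
#' @return `patients` with `group` (factor) and `excluded` columns.
#' @export
assign_groups <- function(patients, lgrs = NULL, snvs = NULL) {
  path_ids <- function(tbl) {
    if (is.null(tbl) || !nrow(tbl)) return(character())
    cls <- tbl[["pathogenicity"]] %||% tbl[["classification"]]
    ids <- tbl[["patient_id"]] %||% tbl[["sample_id"]]
    unique(ids[is_pathogenic(cls)])
  }
  has_lgr <- patients$patient_id %in% path_ids(lgrs)
  has_snv <- patients$patient_id %in% path_ids(snvs)
  patients$group <- factor(
    dplyr::case_when(
      has_lgr & has_snv ~ "Both",
      has_lgr ~ "LGR",
      has_snv ~ "SNV_InDel",
      TRUE ~ "Without"
    ),
    levels = GROUP_LEVELS
  )
  patients$excluded <- patients$group == "Both"
  patients
}

#' Cohort group summary
#'
#' Carrier counts and percentages from grouped patients or from the raw
#' Venn counts: LGR-only, SNV/InDel-only, both, and the retained cohort
#' size.  Pathogenic germline carriers comprise all three carrier groups.
#'
#' @param x Either a grouped patients tibble (from [assign_groups()]) or
#'   `NULL` when the counts are given directly.
#' @param n_lgr_only,n_snv_only,n_both,n_total Venn counts (used when `x`
#'   is `NULL`).
#' @return One-row tibble with counts and percentages: `pct_carriers`,
#'   `pct_lgr`, `pct_snv` (LGR / SNV/InDel carriers including the overlap).
#' @examples
#' group_summary(n_lgr_only = 135, n_snv_only = 1411, n_both = 15,
#'               n_total = 15659)
#' @export
group_summary <- function(x = NULL, n_lgr_only = NULL, n_snv_only = NULL,
                          n_both = NULL, n_total = NULL) {
  if (!is.null(x)) {
    stopifnot("group" %in% names(x))
    n_lgr_only <- sum(x$group == "LGR")
    n_snv_only <- sum(x$group == "SNV_InDel")
    n_both <- sum(x$group == "Both")
    n_total <- nrow(x)
  }
  n_carriers <- n_lgr_only + n_snv_only + n_both
  if (n_carriers > n_total) abort_invalid("carrier counts exceed the cohort size.")
  tibble(
    n_total = n_total,
    n_without = n_total - n_carriers,
    n_lgr_only = n_lgr_only, n_snv_only = n_snv_only, n_both = n_both,
    n_carriers = n_carriers,
    pct_carriers = 100 * n_carriers / n_total,
    pct_lgr = 100 * (n_lgr_only + n_both) / n_total,
    pct_snv = 100 * (n_snv_only + n_both) / n_total
  )
}

#' Double-hit rate
#'
#' Proportion of pathogenic germline carriers whose carrier gene also
#' acquired a somatic mutation.
#'
#' @param n_double_hit Number of patients with a double-hit event.
#' @param n_carriers Number of pathogenic germline mutation carriers.
#' @return Percentage.
#' @export
double_hit_rate <- function(n_double_hit, n_carriers) {
  check_count(n_carriers, "n_carriers")
  100 * n_double_hit / n_carriers
}

#' Detect double-hit events
#'
#' A double hit is a pathogenic germline mutation (first hit) and at least
#' one somatic mutation (second hit) on the same gene in the same patient.
#' One record is emitted per (patient, gene); when the germline hit is an
#' LGR the event is recorded as LGR-first.
#'
#' @param germline Tibble of germline events: `patient_id`, `gene`, `kind`
#'   (`"LGR"` or `"SNV_InDel"`), and `classification`/`pathogenicity`.
#' @param somatic Tibble of somatic mutations: `patient_id`, `gene`.
#' @return Tibble: `patient_id`, `gene`, `germline_kind`, `n_somatic`.
#' @export
detect_double_hits <- function(germline, somatic) {
  empty <- tibble(patient_id = character(), gene = character(),
                  germline_kind = character(), n_somatic = integer())
  if (!nrow(germline) || !nrow(somatic)) return(empty)
  cls <- germline[["classification"]] %||% germline[["pathogenicity"]]
  germ <- germline[is_pathogenic(cls), c("patient_id", "gene", "kind")]
  if (!nrow(germ)) return(empty)
  som_counts <- count(somatic, .data$patient_id, .data$gene, name = "n_somatic")
  germ %>%
    group_by(.data$patient_id, .data$gene) %>%
    summarise(
      germline_kind = if (any(.data$kind == "LGR")) "LGR" else "SNV_InDel",
      .groups = "drop"
    ) %>%
    inner_join(som_counts, by = c("patient_id", "gene")) %>%
    arrange(.data$patient_id, .data$gene)
}

#' Per-gene (or per-pathway) carrier rate comparison
#'
#' For each item, forms the 2x2 carrier/non-carrier by group table and
#' tests it with two-sided Fisher's exact; items are ordered by P value.
#' No multiple-testing correction is applied by default; pass
#' `adjust = TRUE` for Benjamini-Hochberg adjusted values alongside.
#'
#' @param counts_a,counts_b Tibbles (`gene`, `n`) of carrier counts per
#'   item in each group (zero-count items may be omitted).
#' @param denom_a,denom_b Group sizes.
#' @param adjust Add BH-adjusted P values.
#' @return Tibble: `gene`, `n_a`, `n_b`, `prop_a`, `prop_b`, `odds_ratio`,
#'   `p_value`, `significant` (P < 0.05).
#' @export
rate_comparison <- function(counts_a, denom_a, counts_b, denom_b,
                            adjust = FALSE) {
  check_count(denom_a, "denom_a")
  check_count(denom_b, "denom_b")
  all_items <- union(counts_a$gene, counts_b$gene)
  lookup <- function(tbl, g) {
    i <- match(g, tbl$gene)
    if (is.na(i)) 0L else tbl$n[i]
  }
  out <- map(all_items, function(g) {
    a <- lookup(counts_a, g); b <- lookup(counts_b, g)
    ft <- fisher_exact_2x2(matrix(c(a, denom_a - a, b, denom_b - b), 2, byrow = TRUE))
    tibble(gene = g, n_a = a, n_b = b,
           prop_a = a / denom_a, prop_b = b / denom_b,
           odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  }) %>% list_rbind() %>% arrange(.data$p_value)
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < 0.05
  out
}

#' Germline-by-somatic co-occurrence testing
#'
#' For every (germline gene, somatic gene) pair, tests the patient-level
#' 2x2 carrier table with two-sided Fisher's exact.  Direction is
#' co-occurrence when the odds ratio exceeds 1 and mutual exclusivity when
#' it is below 1; significance uses raw P < 0.05 (no multiple-testing
#' correction, matching common oncoprint practice).
#'
#' @param germline_ind,somatic_ind Logical patient-by-gene indicator
#'   matrices over the same patients (rows).
#' @param min_carriers Skip genes with fewer carriers than this.
#' @return Tibble: `germline_gene`, `somatic_gene`, `n_both`, `odds_ratio`,
#'   `p_value`, `direction`, `significant`.
#' @export
cooccurrence_matrix <- function(germline_ind, somatic_ind, min_carriers = 3L) {
  if (nrow(germline_ind) != nrow(somatic_ind)) {
    abort_invalid("indicator matrices must share the patient universe.")
  }
  g_keep <- colnames(germline_ind)[colSums(germline_ind) >= min_carriers]
  s_keep <- colnames(somatic_ind)[colSums(somatic_ind) >= min_carriers]
  grid <- tidyr::expand_grid(germline_gene = g_keep, somatic_gene = s_keep)
  if (!nrow(grid)) {
    return(tibble(germline_gene = character(), somatic_gene = character(),
                  n_both = integer(), odds_ratio = numeric(),
                  p_value = numeric(), direction = character(),
                  significant = logical()))
  }
  res <- pmap(grid, function(germline_gene, somatic_gene) {
    g <- germline_ind[, germline_gene]
    s <- somatic_ind[, somatic_gene]
    tab <- matrix(c(sum(g & s), sum(g & !s), sum(!g & s), sum(!g & !s)),
                  2, byrow = TRUE)
    ft <- fisher_exact_2x2(tab)
    tibble(n_both = tab[1, 1], odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  }) %>% list_rbind()
  bind_cols(grid, res) %>%
    mutate(
      direction = dplyr::case_when(
        .data$odds_ratio > 1 ~ "co-occurrence",
        .data$odds_ratio < 1 ~ "mutual_exclusivity",
        TRUE ~ "none"
      ),
      significant = .data$p_value < 0.05
    )
}

#' Clinical characteristics table with between-group tests
#'
#' Summarises age bins, sex, stage, cancer multiplicity and family history
#' per germline mutation group (patients carrying both mutation kinds are
#' excluded, as are their tests), with a Fisher's exact test across groups
#' per characteristic.  `unknown` levels are shown in the counts but left
#' out of the tests.  Large tables fall back to a seeded Monte-Carlo
#' Fisher test.
#'
#' @param patients Grouped patients from [assign_groups()], with clinical
#'   columns `age`, `sex`, `stage`, `n_cancers`, `family_history`.
#' @param mc_reps Monte-Carlo replicates for large tables.
#' @param seed Seed for the Monte-Carlo fallback.
#' @param pairwise Also test every pair of groups per characteristic.
#' @return A list of class `clinical_table`: `summary` (long tibble of
#'   counts and column percentages) and `tests` (P per characteristic and
#'   comparison).
#' @export
clinical_table <- function(patients, mc_reps = 1e5, seed = 1L,
                           pairwise = FALSE) {
  stopifnot("group" %in% names(patients))
  pts <- filter(patients, .data$group != "Both")
  pts$group <- droplevels(pts$group)
  pts <- pts %>% mutate(
    age_bin = dplyr::case_when(
      is.na(.data$age) ~ "unknown",
      .data$age <= 60 ~ "<=60",
      TRUE ~ ">60"
    ),
    n_cancers_bin = ifelse(.data$n_cancers >= 2, "multiple", "single"),
    stage = as.character(.data$stage)
  )
  chars <- c(age_bin = "age_bin", sex = "sex", stage = "stage",
             n_cancers = "n_cancers_bin", family_history = "family_history")

  summary_tbl <- imap(chars, function(col, nm) {
    pts %>%
      count(.data$group, level = .data[[col]]) %>%
      group_by(.data$group) %>%
      mutate(pct = 100 * n / sum(n)) %>%
      ungroup() %>%
      mutate(characteristic = nm, .before = 1)
  }) %>% list_rbind()

  fisher_rc <- function(tab) {
    if (any(dim(tab) < 2) || sum(tab) == 0) return(NA_real_)
    exact <- try(fisher.test(tab, workspace = 2e7)$p.value, silent = TRUE)
    if (!inherits(exact, "try-error")) return(exact)
    with_seed(seed, fisher.test(tab, simulate.p.value = TRUE, B = mc_reps)$p.value)
  }
  test_one <- function(dat, col) {
    known <- dat[dat[[col]] != "unknown" & !is.na(dat[[col]]), ]
    fisher_rc(table(known$group, known[[col]]))
  }
  tests <- imap(chars, function(col, nm) {
    rows <- tibble(characteristic = nm, comparison = "all groups",
                   p_value = test_one(pts, col))
    if (pairwise) {
      gl <- levels(pts$group)
      pairs <- utils::combn(gl, 2, simplify = FALSE)
      rows <- bind_rows(rows, map(pairs, function(pr) {
        tibble(characteristic = nm,
               comparison = paste(pr, collapse = " vs "),
               p_value = test_one(filter(pts, .data$group %in% pr), col))
      }) %>% list_rbind())
    }
    rows
  }) %>% list_rbind()

  age_summary <- pts %>%
    filter(!is.na(.data$age)) %>%
    group_by(.data$group) %>%
    summarise(median_age = median(.data$age),
              age_min = min(.data$age), age_max = max(.data$age),
              .groups = "drop")

  structure(list(summary = summary_tbl, tests = tests, age = age_summary),
            class = "clinical_table")
}

#' @export
print.clinical_table <- function(x, ...) {
  cat("<clinical_table>\n")
  print(tidyr::pivot_wider(x$summary,
                           names_from = "group",
                           values_from = c("n", "pct"), values_fill = 0))
  cat("\nTests:\n")
  print(x$tests)
  invisible(x)
}

#' Per-exon mutation counts and hotspot shares
#'
#' Tallies events per (gene, exon), with an LGR spanning exons i..j
#' incrementing every spanned exon, split by mutation kind.  The per-gene
#' `max_exon_share` (largest single-exon count over the gene total) is the
#' statistic used to judge whether events aggregate on specific exons.
#'
#' @param lgrs LGR events: `gene`, `exon_from`, `exon_to`.
#' @param snvs Small variants: `gene` and `exon_index`.
#' @param panel A `panel_design` providing the exon universe.
#' @return A list: `counts` (tibble `gene`, `exon_index`, `n_lgr`,
#'   `n_snv`) and `share` (per gene and kind, `max_exon_share`).
#' @export
exon_hotspot_counts <- function(lgrs, snvs, panel) {
  validate_panel(panel)
  universe <- as_tibble(panel)[, c("gene", "exon_index")]
  lgr_long <- if (!is.null(lgrs) && nrow(lgrs)) {
    lgrs %>%
      mutate(exon_index = purrr::map2(.data$exon_from, .data$exon_to, seq)) %>%
      tidyr::unnest("exon_index") %>%
      count(.data$gene, .data$exon_index, name = "n_lgr")
  } else {
    tibble(gene = character(), exon_index = integer(), n_lgr = integer())
  }
  snv_long <- if (!is.null(snvs) && nrow(snvs)) {
    count(snvs, .data$gene, .data$exon_index, name = "n_snv")
  } else {
    tibble(gene = character(), exon_index = integer(), n_snv = integer())
  }
  counts <- universe %>%
    left_join(lgr_long, by = c("gene", "exon_index")) %>%
    left_join(snv_long, by = c("gene", "exon_index")) %>%
    mutate(across(c("n_lgr", "n_snv"), ~ dplyr::coalesce(.x, 0L)))
  share <- counts %>%
    tidyr::pivot_longer(c("n_lgr", "n_snv"), names_to = "kind",
                        values_to = "n") %>%
    mutate(kind = ifelse(.data$kind == "n_lgr", "LGR", "SNV_InDel")) %>%
    group_by(.data$gene, .data$kind) %>%
    summarise(total = sum(.data$n),
              max_exon_share = ifelse(sum(.data$n) > 0, max(.data$n) / sum(.data$n), NA_real_),
              .groups = "drop")
  list(counts = counts, share = share)
}
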