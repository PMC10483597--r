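mk_patients <- function(n) tibble::tibble(patient_id = sprintf("P%03d", 1:n))

test_that("group assignment partitions the cohort and flags the overlap", {
  pts <- mk_patients(6)
  lgrs <- tibble::tibble(sample_id = c("P001", "P002"),
                         gene = "BRCA1",
                         pathogenicity = c("pathogenic", "VUS"))
  snvs <- tibble::tibble(patient_id = c("P001", "P003"),
                         gene = "ATM",
                         classification = c("likely_pathogenic", "pathogenic"))
  out <- assign_groups(pts, lgrs, snvs)
  expect_equal(as.character(out$group),
               c("Both", "Without", "SNV_InDel", "Without", "Without", "Without"))
  expect_equal(out$excluded, out$group == "Both")
  expect_equal(sum(table(out$group)), nrow(pts))

  # no calls at all
  none <- assign_groups(pts)
  expect_true(all(none$group == "Without"))
})

test_that("group summary reproduces carrier percentages from Venn counts", {
  gs <- group_summary(n_lgr_only = 135, n_snv_only = 1411, n_both = 15,
                      n_total = 15659)
  expect_equal(gs$n_carriers, 1561)
  expect_equal(round(gs$pct_carriers), 10)
  expect_equal(round(gs$pct_snv, 1), 9.1)
  expect_equal(round(gs$pct_lgr, 1), 1)
  expect_equal(round(double_hit_rate(131, 1561), 1), 8.4)
  expect_error(group_summary(n_lgr_only = 10, n_snv_only = 0, n_both = 0,
                             n_total = 5),
               class = "lgrscan_invalid_parameter")
})

test_that("double-hit detection equals the brute-force nested-loop oracle", {
  germ <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P3"),
    gene = c("BRCA2", "ATM", "MSH2", "TP53"),
    kind = c("SNV_InDel", "LGR", "LGR", "SNV_InDel"),
    classification = c("pathogenic", "pathogenic", "likely_pathogenic", "VUS")
  )
  som <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P3"),
    gene = c("BRCA2", "KRAS", "MSH2", "TP53")
  )
  dh <- detect_double_hits(germ, som)
  expect_equal(nrow(dh), 2L)                      # P3's germline hit is VUS
  expect_equal(dh$gene, c("BRCA2", "MSH2"))
  expect_equal(dh$germline_kind, c("SNV_InDel", "LGR"))

  # randomized cohorts vs explicit nested loops
  set.seed(19)
  genes <- c("A", "B", "C", "D", "E")
  for (rep in 1:5) {
    g <- tibble::tibble(
      patient_id = sample(sprintf("P%02d", 1:10), 25, replace = TRUE),
      gene = sample(genes, 25, replace = TRUE),
      kind = sample(c("LGR", "SNV_InDel"), 25, replace = TRUE),
      classification = sample(c("pathogenic", "VUS"), 25, replace = TRUE)
    )
    s <- tibble::tibble(
      patient_id = sample(sprintf("P%02d", 1:10), 30, replace = TRUE),
      gene = sample(genes, 30, replace = TRUE)
    )
    got <- detect_double_hits(g, s)
    want <- list()
    for (p in unique(g$patient_id)) {
      for (gn in genes) {
        has_g <- any(g$patient_id == p & g$gene == gn &
                       g$classification == "pathogenic")
        has_s <- any(s$patient_id == p & s$gene == gn)
        if (has_g && has_s) want[[length(want) + 1]] <- paste(p, gn)
      }
    }
    expect_setequal(paste(got$patient_id, got$gene), unlist(want))
  }
})

test_that("per-gene rate comparison behaves like Fisher on carrier tables", {
  eq <- rate_comparison(tibble::tibble(gene = "G1", n = 5), 50,
                        tibble::tibble(gene = "G1", n = 5), 50)
  expect_equal(eq$p_value, 1)
  expect_equal(eq$odds_ratio, 1)

  # strong contrast mirroring an RB1-style LGR excess: 9/135 vs 2/1411
  rb1 <- rate_comparison(tibble::tibble(gene = "RB1", n = 9), 135,
                         tibble::tibble(gene = "RB1", n = 2), 1411)
  expect_lt(rb1$p_value, 0.001)
  expect_true(rb1$significant)
  expect_equal(rb1$p_value,
               fisher_oracle(matrix(c(9, 126, 2, 1409), 2, byrow = TRUE)),
               tolerance = 1e-7)

  zero <- rate_comparison(tibble::tibble(gene = "G1", n = 0), 20,
                          tibble::tibble(gene = "G1", n = 0), 30)
  expect_equal(zero$p_value, 1)
})

test_that("co-occurrence directionality follows the odds ratio", {
  n <- 500
  set.seed(3)
  g <- matrix(runif(n) < 0.1, n, 1, dimnames = list(NULL, "G"))
  co_same <- cooccurrence_matrix(g, `colnames<-`(g, "S"))
  expect_gt(co_same$odds_ratio, 1)
  expect_lt(co_same$p_value, 0.05)
  expect_equal(co_same$direction, "co-occurrence")

  a <- runif(n) < 0.3
  b <- !a & (runif(n) < 0.43)  # disjoint carriers
  co_dis <- cooccurrence_matrix(matrix(a, ncol = 1, dimnames = list(NULL, "G")),
                                matrix(b, ncol = 1, dimnames = list(NULL, "S")))
  expect_lt(co_dis$odds_ratio, 1)
  expect_equal(co_dis$direction, "mutual_exclusivity")

  expect_error(cooccurrence_matrix(g, matrix(TRUE, 3, 1)),
               class = "lgrscan_invalid_parameter")
})

test_that("clinical table counts, percentages and tests are coherent", {
  set.seed(8)
  n <- 300
  pts <- tibble::tibble(
    patient_id = sprintf("P%04d", 1:n),
    age = sample(c(30:85, NA), n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    stage = sample(c("I", "II", "III", "IV", "unknown"), n, replace = TRUE),
    n_cancers = sample(1:2, n, replace = TRUE, prob = c(0.95, 0.05)),
    family_history = sample(c("with", "without", "unknown"), n, replace = TRUE),
    group = factor(sample(c("Without", "SNV_InDel", "LGR"), n, replace = TRUE),
                   levels = c("Without", "SNV_InDel", "LGR", "Both"))
  )
  ct <- clinical_table(pts, pairwise = TRUE)
  # column percentages sum to 100 within each group and characteristic
  sums <- ct$summary |>
    dplyr::group_by(characteristic, group) |>
    dplyr::summarise(total = sum(pct), .groups = "drop")
  expect_true(all(abs(sums$total - 100) < 1e-9))
  expect_true(all(ct$tests$p_value >= 0 & ct$tests$p_value <= 1, na.rm = TRUE))
  expect_equal(sum(ct$tests$comparison == "all groups"), 5L)
  expect_equal(nrow(tidy(ct)), nrow(ct$tests))

  # single group: counts only, tests undefined
  ct1 <- clinical_table(dplyr::mutate(pts, group = factor("Without",
                                                          levels = levels(pts$group))))
  expect_true(all(is.na(ct1$tests$p_value)))
})

test_that("exon hotspot counts use span semantics", {
  panel <- tiny_panel(n_genes = 2, exons_per_gene = 6)
  g <- panel$gene[1]
  lgrs <- tibble::tibble(gene = g, exon_from = 2L, exon_to = 4L)
  snvs <- tibble::tibble(gene = g, exon_index = 5L)
  hs <- exon_hotspot_counts(lgrs, snvs, panel)
  cnt <- hs$counts[hs$counts$gene == g, ]
  expect_equal(cnt$n_lgr, c(0, 1, 1, 1, 0, 0))
  expect_equal(cnt$n_snv, c(0, 0, 0, 0, 1, 0))
  share <- hs$share[hs$share$gene == g & hs$share$kind == "LGR", ]
  expect_equal(share$max_exon_share, 1 / 3)

  # uniform LGR starts: max-exon-share stays near the uniform expectation
  set.seed(4)
  k <- 6
  starts <- sample(1:k, 600, replace = TRUE)
  lg_unif <- tibble::tibble(gene = g, exon_from = starts, exon_to = starts)
  hs_u <- exon_hotspot_counts(lg_unif, NULL, panel)
  share_u <- hs_u$share[hs_u$share$gene == g & hs_u$share$kind == "LGR", ]
  expect_lt(share_u$max_exon_share, 1 / k + 4 * sqrt((1 / k) * (1 - 1 / k) / 600))
})
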