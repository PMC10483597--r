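test_that("normalization recovers the expected log2ratios on clean input", {
  panel <- tiny_panel()
  base <- 800

  # sample identical to the baseline: l ~ 0 everywhere
  d0 <- flat_depth(panel, base = base)
  tr0 <- normalize_depth(d0, "case1")
  expect_lt(max(abs(tr0$l)), 0.01)
  expect_equal(attr(tr0, "baseline_n"), 5L)

  # one gene at exactly half depth: l ~ -1 there, ~0 elsewhere
  gene <- panel$gene[1]
  counts <- ifelse(panel$gene == gene, base / 2, base)
  tr1 <- normalize_depth(flat_depth(panel, base = base, case_counts = counts),
                         "case1")
  expect_lt(max(abs(tr1$l[tr1$gene == gene] + 1)), 0.01)
  expect_lt(max(abs(tr1$l[tr1$gene != gene])), 0.01)

  expect_error(
    normalize_depth(flat_depth(panel, case_counts = rep(0, nrow(panel))), "case1"),
    class = "lgrscan_degenerate_input"
  )
})

test_that("normalization recovers log2(3/2) for a simulated CN=3 gene", {
  panel <- build_panel(n_genes = 6, exons_per_gene = 10, seed = 21)
  cfg <- sim_config(mean_depth = 500, depth_dispersion = 0.01, seed = 21)
  cs <- tibble::tibble(sample_id = "S1", gene = "BRCA2",
                       exon_from = 1L, exon_to = 10L, cn = 3L)
  d <- simulate_depth(panel, cs, cfg)
  tr <- normalize_depth(d, "S1")
  expect_lt(abs(mean(tr$l[tr$gene == "BRCA2"]) - log2(3 / 2)), 0.1)
})

test_that("variance_to_previous matches its closed form", {
  # constant track: VP = 0
  tr <- flat_track(rep(0.3, 5))
  expect_equal(variance_to_previous(tr, 2:4), 0)

  # predecessor 0, span (1,1,1): VP = (1 + 0 + 0)/3
  tr2 <- flat_track(c(0, 1, 1, 1))
  expect_equal(variance_to_previous(tr2, 2:4), 1 / 3)

  # span starting at exon 1 uses the gene median as predecessor
  tr3 <- flat_track(c(2, 0, 0, 0, 0))
  expect_equal(variance_to_previous(tr3, 1), (2 - 0)^2)

  # white noise of SD sigma: E[VP] ~ 2 sigma^2 on interior spans
  sigma <- 0.2
  set.seed(123)
  vps <- replicate(400, {
    trk <- flat_track(rnorm(12, 0, sigma))
    variance_to_previous(trk, 5:10)
  })
  expect_lt(abs(mean(vps) - 2 * sigma^2), 0.15 * 2 * sigma^2)

  expect_error(variance_to_previous(tr, integer()), class = "lgrscan_invalid_parameter")
  expect_error(variance_to_previous(tr, c(4, 99)), class = "lgrscan_invalid_parameter")
})

test_that("exon states follow the thresholds with inclusive boundaries", {
  tr <- flat_track(c(0, -1, -0.6, 0.45, 0.3, -2.8))
  st <- call_exon_states(tr)
  expect_equal(st$state, c("neutral", "deletion", "deletion", "duplication",
                           "neutral", "deletion"))
  expect_equal(st$copy_state_estimate, c(2, 1, round(2 * 2^-0.6), 3, 2, 0))
})

test_that("zygosity evidence supports, contradicts, or stays uninformative", {
  tr <- flat_track(c(0, -1, -1, -1, 0, 0))
  st <- call_exon_states(tr)

  het_snps <- snps_at("BRCA1", c(2, 2, 3, 3, 4), baf = 0.5)
  contra <- zygosity_filter(st, het_snps)
  expect_true(all(contra$zygosity_support[2:4] == "contradicted"))
  expect_true(all(contra$zyg_qc_fail[2:4]))    # multi-exon: flagged, kept
  expect_equal(contra$state[2:4], rep("deletion", 3))

  hom_snps <- snps_at("BRCA1", rep(2:4, length.out = 10),
                      baf = rep(c(0, 1), 5))
  supp <- zygosity_filter(st, hom_snps)
  expect_true(all(supp$zygosity_support[2:4] == "supported"))

  non <- zygosity_filter(st, NULL)
  expect_true(all(non$zygosity_support == "uninformative"))

  # duplication span with het BAFs near 1/3: supported
  trd <- flat_track(c(0, 0.58, 0.58, 0.58, 0, 0))
  std <- call_exon_states(trd)
  dup_snps <- snps_at("BRCA1", c(2, 3, 4), baf = 1 / 3)
  supd <- zygosity_filter(std, dup_snps)
  expect_true(all(supd$zygosity_support[2:4] == "supported"))

  # contradicted single-exon call is dropped
  tr1 <- flat_track(c(0, -1, 0, 0, 0, 0))
  st1 <- call_exon_states(tr1)
  drop1 <- zygosity_filter(st1, snps_at("BRCA1", c(2, 2, 2), baf = 0.5))
  expect_equal(drop1$state[2], "neutral")
})

test_that("merging assembles contiguous events and applies the gap rule", {
  tr <- flat_track(c(0, -1, -1, -1, 0, 0, 0, 0), gene = "MSH2")
  st <- call_exon_states(tr)
  ev <- merge_calls(st, tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$exon_from, ev$exon_to), c(2L, 4L))
  expect_equal(ev$event_type, "deletion")

  # deletions on exons 2 and 5 (two intervening exons > gap_max): two events
  tr2 <- flat_track(c(0, -1, 0, 0, -1, 0, 0, 0), gene = "MSH2")
  ev2 <- merge_calls(call_exon_states(tr2), tr2)
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$exon_from, c(2L, 5L))

  # one-exon gap is bridged into a single spanning event
  tr3 <- flat_track(c(0, -1, -0.3, -1, 0, 0, 0, 0), gene = "MSH2")
  ev3 <- merge_calls(call_exon_states(tr3), tr3)
  expect_equal(nrow(ev3), 1L)
  expect_equal(c(ev3$exon_from, ev3$exon_to), c(2L, 4L))

  # unsupported single-exon deletion at -0.7 is discarded; -0.9 is kept
  tr4 <- flat_track(c(0, -0.7, 0, 0, 0, 0))
  expect_equal(nrow(merge_calls(call_exon_states(tr4), tr4)), 0L)
  tr5 <- flat_track(c(0, -0.9, 0, 0, 0, 0))
  expect_equal(nrow(merge_calls(call_exon_states(tr5), tr5)), 1L)

  # clean within-span profile passes QC
  expect_true(ev$qc_pass)
  expect_lte(ev$vp, caller_params()$vp_max)
})

test_that("copy-neutral oracle: baseline-depth input yields zero events", {
  panel <- tiny_panel()
  d <- flat_depth(panel, base = 600)
  calls <- call_lgrs(d)
  expect_equal(nrow(calls), 0L)
})

test_that("end-to-end: a BRCA1 exon 5-8 heterozygous deletion is recovered", {
  panel <- build_panel(n_genes = 6, exons_per_gene = 12, seed = 8)
  cfg <- sim_config(mean_depth = 500, seed = 8)
  cs <- tibble::tibble(sample_id = "S1", gene = "BRCA1",
                       exon_from = 5L, exon_to = 8L, cn = 1L)
  d <- simulate_depth(panel, cs, cfg)
  snps <- simulate_snps(panel, cs, cfg)
  calls <- call_lgrs(d, snps)
  hit <- calls[calls$gene == "BRCA1" & calls$event_type == "deletion", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$exon_from, hit$exon_to), c(5L, 8L))
  expect_equal(hit$pathogenicity, "pathogenic")
  expect_equal(hit$copy_state_estimate, 1)

  # without SNPs the call is still emitted, zygosity uninformative
  calls2 <- call_lgrs(d, NULL)
  hit2 <- calls2[calls2$gene == "BRCA1", ]
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$zygosity_support, "uninformative")
})

test_that("multi-exon span recovery is stable across seeds", {
  panel <- build_panel(n_genes = 4, exons_per_gene = 10, seed = 15)
  exact <- vapply(1:40, function(s) {
    cfg <- sim_config(mean_depth = 500, seed = s)
    cs <- tibble::tibble(sample_id = "S1", gene = "PALB2",
                         exon_from = 3L, exon_to = 7L, cn = 1L)
    d <- simulate_depth(panel, cs, cfg)
    calls <- call_lgrs(d)
    any(calls$gene == "PALB2" & calls$exon_from == 3 & calls$exon_to == 7 &
          calls$event_type == "deletion")
  }, logical(1))
  expect_gte(mean(exact), 0.95)
})
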