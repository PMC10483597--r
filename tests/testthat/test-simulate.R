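test_that("cohort truth respects configured prevalences", {
  panel <- tiny_panel()

  none <- simulate_cohort(panel, sim_config(n_patients = 50, lgr_prevalence = 0,
                                            seed = 1))
  expect_equal(nrow(none$lgrs), 0L)

  both <- simulate_cohort(panel, sim_config(n_patients = 40, lgr_prevalence = 1,
                                            snv_prevalence = 1, seed = 2))
  expect_true(all(both$patients$has_lgr))
  expect_true(all(both$patients$has_snv))

  # binomial check at the default 1% LGR prevalence
  cfg <- sim_config(n_patients = 2000, lgr_prevalence = 0.01, seed = 11)
  truth <- simulate_cohort(panel, cfg)
  frac <- mean(truth$patients$has_lgr)
  se <- sqrt(0.01 * 0.99 / 2000)
  expect_lt(abs(frac - 0.01), 3 * se)
})

test_that("cohort generation is deterministic and patient-stable", {
  panel <- tiny_panel()
  cfg <- sim_config(n_patients = 25, lgr_prevalence = 0.3, seed = 5)
  t1 <- simulate_cohort(panel, cfg)
  t2 <- simulate_cohort(panel, cfg)
  expect_identical(t1$patients, t2$patients)
  expect_identical(t1$lgrs, t2$lgrs)
  # adding patients does not perturb earlier patients' truth
  cfg2 <- sim_config(n_patients = 40, lgr_prevalence = 0.3, seed = 5)
  t3 <- simulate_cohort(panel, cfg2)
  expect_identical(t1$patients, t3$patients[1:25, ])
})

test_that("truth events span whole exons of one gene with legal copy states", {
  panel <- tiny_panel()
  truth <- simulate_cohort(panel, sim_config(n_patients = 60, lgr_prevalence = 0.5,
                                             seed = 9))
  ev <- truth$lgrs
  expect_true(all(ev$exon_from >= 1 & ev$exon_from <= ev$exon_to))
  expect_true(all(ev$cn[ev$type == "deletion"] == 1))
  expect_true(all(ev$cn[ev$type == "duplication"] >= 3))
  n_exons <- dplyr::count(as_tibble(panel), gene, name = "k")
  ev2 <- dplyr::left_join(ev, n_exons, by = "gene")
  expect_true(all(ev2$exon_to <= ev2$k))
})

test_that("depth follows the copy-number scaling of the generative model", {
  panel <- build_panel(n_genes = 2, exons_per_gene = 25, seed = 3)
  # noise off: Poisson limit, unit size factors
  cfg <- sim_config(mean_depth = 2000, depth_dispersion = 0,
                    size_factor_sdlog = 0, seed = 13)
  d <- simulate_depth(panel, NULL, cfg, sample_ids = "S1")
  expect_equal(unname(colnames(d$counts)[1]), "S1")
  # Poisson at depth 2000: each count within 5 SDs of its baseline mean
  mu_hat <- apply(d$counts[, -1], 1, median)
  expect_true(all(abs(d$counts[, "S1"] - mu_hat) < 5 * sqrt(mu_hat) + 5))

  # CN=1 halves expected depth: 10k replicate draws within 2% of half
  ids_del <- sprintf("D%03d", 1:200)
  ids_dip <- sprintf("C%03d", 1:200)
  cs <- tibble::tibble(sample_id = ids_del, gene = "BRCA1",
                       exon_from = 1L, exon_to = 25L, cn = 1L)
  cfg2 <- sim_config(mean_depth = 500, size_factor_sdlog = 0, seed = 17)
  d2 <- simulate_depth(panel, cs, cfg2, sample_ids = c(ids_del, ids_dip))
  on_gene <- d2$panel$gene == "BRCA1"
  ratio <- mean(d2$counts[on_gene, ids_del]) / mean(d2$counts[on_gene, ids_dip])
  expect_lt(abs(ratio - 0.5), 0.01)

  # homozygous deletion: coverage collapses to the contamination floor
  cs0 <- tibble::tibble(sample_id = "Z1", gene = "BRCA1",
                        exon_from = 1L, exon_to = 25L, cn = 0L)
  d0 <- simulate_depth(panel, cs0, cfg2)
  expect_lt(mean(d0$counts[on_gene, "Z1"]),
            2 * cfg2$contamination * cfg2$mean_depth + 3)
  expect_error(
    simulate_depth(panel, dplyr::mutate(cs0, cn = -1L), cfg2),
    class = "lgrscan_invalid_parameter"
  )
})

test_that("expected depth is monotone in copy number", {
  panel <- build_panel(n_genes = 1, exons_per_gene = 40, seed = 4)
  cfg <- sim_config(mean_depth = 500, size_factor_sdlog = 0, seed = 23)
  means <- vapply(0:4, function(cn) {
    cs <- tibble::tibble(sample_id = "S1", gene = panel$gene[1],
                         exon_from = 1L, exon_to = 40L, cn = cn)
    mean(simulate_depth(panel, cs, cfg)$counts[, "S1"])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("SNP B-allele fractions match zygosity and copy state", {
  panel <- tiny_panel()
  cfg <- sim_config(mean_depth = 1000, snp_density = 50, seed = 31)
  gene <- panel$gene[1]
  k <- max(panel$exon_index[panel$gene == gene])

  # diploid: het BAFs concentrate near 1/2
  dip <- simulate_snps(panel, NULL, cfg, sample_ids = "S1")
  het <- dip[dip$truth_zygosity == "het", ]
  baf <- het$alt_depth / (het$ref_depth + het$alt_depth)
  expect_gt(nrow(het), 50)
  expect_gt(mean(baf >= 0.45 & baf <= 0.55), 0.95)

  # CN=1 deletion: no het observation survives inside the lost region
  cs1 <- tibble::tibble(sample_id = "S1", gene = gene,
                        exon_from = 1L, exon_to = k, cn = 1L)
  del <- simulate_snps(panel, cs1, cfg)
  in_del <- del[del$gene == gene, ]
  expect_gt(nrow(in_del), 0)
  expect_true(all(in_del$truth_zygosity != "het"))
  baf_del <- in_del$alt_depth / (in_del$ref_depth + in_del$alt_depth)
  expect_true(all(baf_del < 0.2 | baf_del > 0.8))

  # CN=3 duplication: het BAFs sit near 1/3 or 2/3
  cs3 <- tibble::tibble(sample_id = "S1", gene = gene,
                        exon_from = 1L, exon_to = k, cn = 3L)
  dup <- simulate_snps(panel, cs3, cfg)
  het3 <- dup[dup$gene == gene & dup$truth_zygosity == "het", ]
  baf3 <- het3$alt_depth / (het3$ref_depth + het3$alt_depth)
  expect_gt(nrow(het3), 10)
  expect_true(all(abs(baf3 - 1 / 3) < 0.1 | abs(baf3 - 2 / 3) < 0.1))
})

test_that("droplet counts follow the Poisson partitioning model", {
  # no template, no positives
  w0 <- simulate_droplets(true_cn = 0, n_droplets = 20000, seed = 1)
  expect_equal(w0$positive[w0$channel == "target"], 0L)

  # doubling CN doubles lambda by construction: positive fraction matches
  w2 <- simulate_droplets(true_cn = 2, n_droplets = 200000, rate_per_copy = 0.05,
                          seed = 2)
  w4 <- simulate_droplets(true_cn = 4, n_droplets = 200000, rate_per_copy = 0.05,
                          seed = 3)
  lam <- function(w, ch) -log(1 - w$positive[w$channel == ch] / w$total[w$channel == ch])
  expect_lt(abs(lam(w4, "target") / lam(w2, "target") - 2), 0.05)

  expect_identical(simulate_droplets(2, seed = 9), simulate_droplets(2, seed = 9))
})

test_that("group algebra: carrier groups always partition the cohort", {
  panel <- tiny_panel()
  for (seed in 1:3) {
    truth <- simulate_cohort(panel, sim_config(n_patients = 80, lgr_prevalence = 0.3,
                                               snv_prevalence = 0.4, seed = seed))
    p <- truth$patients
    n4 <- sum(p$has_lgr & p$has_snv) + sum(p$has_lgr & !p$has_snv) +
      sum(!p$has_lgr & p$has_snv) + sum(!p$has_lgr & !p$has_snv)
    expect_equal(n4, nrow(p))
  }
})
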