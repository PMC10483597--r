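# End-to-end pipeline orchestration: simulate -> call -> metrics -> report.

#' Pipeline run configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; recorded in the manifest and every stage.
#' @param n_genes,exons_per_gene Panel size.
#' @param sim A [sim_config()] (its seed is overridden by `seed`).
#' @param caller A [caller_params()].
#' @param rules A [classify_rules()].
#' @param panel_size_mb Sequenced footprint used for TMB.
#' @param min_carriers Carrier threshold for co-occurrence testing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, n_genes = 40L,
                       exons_per_gene = c(5L, 15L),
                       sim = sim_config(), caller = caller_params(),
                       rules = classify_rules(), panel_size_mb = 1.5,
                       min_carriers = 3L) {
  sim$seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), n_genes = n_genes,
         exons_per_gene = exons_per_gene, sim = sim, caller = caller,
         rules = rules, panel_size_mb = panel_size_mb,
         min_carriers = min_carriers),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `out_dir`, `seed`, `n_genes`,
#' `exons_per_gene`, plus `sim`, `caller` and `rules` blocks whose entries
#' override the documented defaults of [sim_config()], [caller_params()]
#' and [classify_rules()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  caller <- do.call(caller_params, y$caller %||% list())
  rules <- do.call(classify_rules, y$rules %||% list())
  run_config(
    out_dir = y$out_dir %||% ".",
    seed = y$seed %||% 1L,
    n_genes = y$n_genes %||% 40L,
    exons_per_gene = unlist(y$exons_per_gene %||% c(5L, 15L)),
    sim = sim, caller = caller, rules = rules,
    panel_size_mb = y$panel_size_mb %||% 1.5,
    min_carriers = y$min_carriers %||% 3L
  )
}

stage_run <- function(stage, out_dir, expr) {
  tryCatch(force(expr), error = function(e) {
    writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    rlang::abort(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                 class = "lgrscan_stage_error", parent = e)
  })
}

#' Run the full pipeline
#'
#' Executes simulate, call, metrics and report stages in order, writing
#' every intermediate as plain text under `config$out_dir` and a
#' `manifest.json` recording the seed, package version and MD5 digest of
#' each data output.  Re-running with the same config reproduces
#' byte-identical data files.
#'
#' @param config A [run_config()] or path to a YAML file.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report_dir <- file.path(config$out_dir, "cohort_report")
  dir.create(report_dir, showWarnings = FALSE)
  unlink(file.path(config$out_dir, "FAILED"))
  out <- function(...) file.path(config$out_dir, ...)

  # -- simulate ---------------------------------------------------------------
  sim_data <- stage_run("simulate", config$out_dir, {
    panel <- build_panel(config$n_genes, config$exons_per_gene,
                         seed = config$seed)
    truth <- simulate_cohort(panel, config$sim)
    cs <- cohort_copy_states(truth)
    ids <- truth$patients$patient_id
    depth <- simulate_depth(panel, cs, config$sim, sample_ids = ids)
    snps <- simulate_snps(panel, cs, config$sim, sample_ids = ids)
    write_targets_bed(panel, out("targets.bed"))
    write_depth_tsv(depth, out("depth.tsv"))
    write_snps_tsv(snps, out("snps.tsv"))
    write_variants_vcf(truth$snvs, out("germline.vcf"))
    write_variants_vcf(truth$somatic, out("somatic.vcf"))
    write_segments_seg(truth$segments, out("segments.seg.tsv"))
    jsonlite::write_json(truth$patients, out("truth.json"))
    list(panel = panel, truth = truth, depth = depth, snps = snps)
  })

  # -- call -------------------------------------------------------------------
  calls <- stage_run("call", config$out_dir, {
    calls <- call_lgrs(sim_data$depth, sim_data$snps, config$caller)
    readr::write_tsv(calls, out("lgr_calls.tsv"))
    calls
  })

  # -- metrics ----------------------------------------------------------------
  metrics <- stage_run("metrics", config$out_dir, {
    truth <- sim_data$truth
    m <- sample_metrics(
      truth$somatic, truth$segments,
      msi = select(truth$patients, "patient_id",
                   unstable_fraction = "msi_unstable_fraction"),
      panel_size_mb = config$panel_size_mb
    )
    readr::write_tsv(m, out("metrics.tsv"))
    m
  })

  # -- report -----------------------------------------------------------------
  stage_run("report", config$out_dir, {
    truth <- sim_data$truth
    snvs <- classify_snv(truth$snvs, rules = config$rules)
    patients <- assign_groups(truth$patients, calls, snvs)
    rpt <- function(...) file.path(report_dir, ...)

    gsum <- group_summary(patients)
    readr::write_tsv(gsum, rpt("group_summary.tsv"))

    ct <- clinical_table(patients, seed = config$seed)
    readr::write_tsv(ct$summary, rpt("table1.tsv"))

    path_lgr <- filter(calls, is_pathogenic(.data$pathogenicity))
    path_snv <- filter(snvs, is_pathogenic(.data$classification))
    lgr_counts <- path_lgr %>% distinct(.data$sample_id, .data$gene) %>%
      count(.data$gene)
    snv_counts <- path_snv %>% distinct(.data$patient_id, .data$gene) %>%
      count(.data$gene)
    rates <- rate_comparison(lgr_counts, max(gsum$n_lgr_only + gsum$n_both, 1L),
                             snv_counts, max(gsum$n_snv_only + gsum$n_both, 1L))
    readr::write_tsv(rates, rpt("gene_rates.tsv"))

    germ <- bind_rows(
      path_lgr %>% select(patient_id = "sample_id", "gene") %>% mutate(kind = "LGR"),
      path_snv %>% select("patient_id", "gene") %>% mutate(kind = "SNV_InDel")
    ) %>% mutate(classification = "pathogenic")
    dh <- detect_double_hits(germ, truth$somatic)
    readr::write_tsv(dh, rpt("double_hits.tsv"))

    genes <- sort(unique(sim_data$panel$gene))
    ind <- function(tbl) {
      m <- matrix(FALSE, nrow(patients), length(genes),
                  dimnames = list(patients$patient_id, genes))
      if (nrow(tbl)) m[cbind(tbl$patient_id, tbl$gene)] <- TRUE
      m
    }
    co <- cooccurrence_matrix(ind(germ), ind(truth$somatic),
                              min_carriers = config$min_carriers)
    readr::write_tsv(co, rpt("cooccurrence.tsv"))

    hs <- exon_hotspot_counts(path_lgr,
                              select(path_snv, "gene", "exon_index"),
                              sim_data$panel)
    readr::write_tsv(hs$counts, rpt("hotspots.tsv"))

    enr <- pathway_enrichment(unique(dh$gene), genes)
    readr::write_tsv(enr, rpt("enrichment.tsv"))
  })

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, out("manifest.json"))
  manifest <- list(
    package = "lgrscan",
    version = as.character(utils::packageVersion("lgrscan")),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = tibble(
      file = sub(paste0("^", config$out_dir, "/?"), "", files),
      md5 = unname(tools::md5sum(files))
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
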