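# Synthetic cohort generator: panels, patients, depth, SNPs, droplets.
#
# The generator emulates the data a germline targeted-panel pipeline sees:
# per-exon read depth with overdispersion scaled by germline copy number,
# SNP B-allele fractions consistent with zygosity and copy state, whole-exon
# germline deletion/duplication events restricted to predisposition genes,
# annotated germline/somatic small variants, copy-number segment profiles,
# MSI unstable-site fractions, and Poisson-process droplet counts.

#' Simulation configuration
#'
#' Default rates mirror the cohort structure of a large pan-cancer germline
#' series: about 1% of patients carry a pathogenic germline LGR and about
#' 9.1% a pathogenic germline SNV/InDel, drawn independently.
#'
#' @param n_patients Number of patients.
#' @param cancer_type_weights Named probability vector over cancer types
#'   (must sum to 1).
#' @param lgr_prevalence Probability a patient carries a pathogenic germline
#'   LGR.
#' @param snv_prevalence Probability a patient carries a pathogenic germline
#'   SNV/InDel.
#' @param mean_depth Mean per-target read depth for a diploid sample.
#' @param depth_dispersion Negative-binomial dispersion phi, so that
#'   Var = mu + phi * mu^2.  `0` gives Poisson counts.
#' @param snp_density Expected heterozygous-informative SNPs per kb of
#'   target footprint.
#' @param msi_h_rate Probability a tumor is microsatellite-unstable.
#' @param somatic_rate Mean somatic SNV/InDel count per tumor.
#' @param background_snv_rate Mean count of non-pathogenic (benign/VUS)
#'   germline variants per patient.
#' @param wgd_rate Probability a tumor has undergone whole-genome duplication.
#' @param contamination Floor on the relative depth of a homozygously deleted
#'   target (ambient molecules), as a fraction of diploid depth.
#' @param size_factor_sdlog Log-SD of per-sample library size factors.
#' @param baseline_sdlog Log-SD of per-target baseline depth.
#' @param n_normals Number of reference-normal samples in the depth matrix.
#' @param seq_error Per-read allele miscall rate at SNP loci.
#' @param seed Master integer seed; all per-patient streams derive from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 200L,
                       cancer_type_weights = c(
                         breast = 0.20, colorectal = 0.20, lung = 0.25,
                         gastric = 0.15, ovarian = 0.10, renal = 0.10
                       ),
                       lgr_prevalence = 0.01,
                       snv_prevalence = 0.091,
                       mean_depth = 500,
                       depth_dispersion = 0.01,
                       snp_density = 1,
                       msi_h_rate = 0.05,
                       somatic_rate = 8,
                       background_snv_rate = 2,
                       wgd_rate = 0.1,
                       contamination = 0.005,
                       size_factor_sdlog = 0.1,
                       baseline_sdlog = 0.3,
                       n_normals = 30L,
                       seq_error = 0.001,
                       seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients")
  check_prob(lgr_prevalence, "lgr_prevalence")
  check_prob(snv_prevalence, "snv_prevalence")
  check_prob(msi_h_rate, "msi_h_rate")
  check_prob(wgd_rate, "wgd_rate")
  check_positive(mean_depth, "mean_depth")
  if (depth_dispersion < 0) abort_invalid("`depth_dispersion` must be >= 0.")
  if (snp_density < 0) abort_invalid("`snp_density` must be >= 0.")
  if (abs(sum(cancer_type_weights) - 1) > 1e-8 || any(cancer_type_weights < 0)) {
    abort_invalid("`cancer_type_weights` must be non-negative and sum to 1.")
  }
  n_normals <- check_count(n_normals, "n_normals", min = 2L)
  cfg <- list(
    n_patients = n_patients, cancer_type_weights = cancer_type_weights,
    lgr_prevalence = lgr_prevalence, snv_prevalence = snv_prevalence,
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    snp_density = snp_density, msi_h_rate = msi_h_rate,
    somatic_rate = somatic_rate, background_snv_rate = background_snv_rate,
    wgd_rate = wgd_rate, contamination = contamination,
    size_factor_sdlog = size_factor_sdlog, baseline_sdlog = baseline_sdlog,
    n_normals = n_normals, seq_error = seq_error, seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Simulate a cohort's ground truth
#'
#' Draws per-patient clinical covariates, pathogenic germline LGR and
#' SNV/InDel carrier status (independent Bernoulli draws at the configured
#' prevalences), somatic mutations, copy-number segment profiles and MSI
#' state.  Each patient uses a sub-seed derived from the master seed, so the
#' truth for patient *i* does not depend on how many patients follow it.
#'
#' @param panel A `panel_design` from [build_panel()].
#' @param config A [sim_config()].
#' @param pathogenic_only If `TRUE` (default), LGR events are placed only on
#'   predisposition-flagged genes.
#'
#' @return A list of class `cohort_truth` with tibbles `patients`, `lgrs`,
#'   `snvs`, `somatic`, `segments`.
#' @export
simulate_cohort <- function(panel, config = sim_config(), pathogenic_only = TRUE) {
  validate_panel(panel)
  stopifnot(inherits(config, "sim_config"))
  gene_tbl <- panel %>%
    group_by(.data$gene) %>%
    summarise(
      n_exons = max(.data$exon_index),
      chromosome = first(.data$chromosome),
      start = min(.data$start),
      predisposition = first(.data$predisposition),
      .groups = "drop"
    )
  lgr_genes <- if (pathogenic_only) filter(gene_tbl, .data$predisposition) else gene_tbl
  if (pathogenic_only && nrow(lgr_genes) == 0 && config$lgr_prevalence > 0) {
    abort_invalid("panel has no predisposition genes to place LGRs on.")
  }
  pred_genes <- filter(gene_tbl, .data$predisposition)

  types <- names(config$cancer_type_weights)
  pat_rows <- vector("list", config$n_patients)
  lgr_rows <- list()
  snv_rows <- list()
  som_rows <- list()
  seg_rows <- list()

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%05d", i)
    with_seed(derive_seed(config$seed, i), {
      ctype <- sample(types, 1L, prob = config$cancer_type_weights)
      p_female <- if (ctype == "ovarian") 1 else if (ctype == "breast") 0.95 else 0.45
      sex <- sample(c("female", "male"), 1L, prob = c(p_female, 1 - p_female))
      age <- max(2L, min(94L, round(rnorm(1, 60, 13))))
      age_known <- runif(1) > 0.15
      stage <- sample(c("I", "II", "III", "IV", "unknown"), 1L,
                      prob = c(0.008, 0.008, 0.017, 0.127, 0.84))
      n_cancers <- if (runif(1) < 0.018) 2L else 1L
      fam <- sample(c("with", "without", "unknown"), 1L, prob = c(0.24, 0.07, 0.69))
      msi_h <- runif(1) < config$msi_h_rate
      unstable <- if (msi_h) runif(1, 0.45, 0.9) else runif(1, 0, 0.25)

      has_lgr <- runif(1) < config$lgr_prevalence && nrow(lgr_genes) > 0
      has_snv <- runif(1) < config$snv_prevalence && nrow(pred_genes) > 0

      if (has_lgr) {
        g <- lgr_genes[sample.int(nrow(lgr_genes), 1L), ]
        type <- if (runif(1) < 0.8) "deletion" else "duplication"
        span_len <- min(sample(1:5, 1L, prob = c(0.15, 0.3, 0.25, 0.2, 0.1)), g$n_exons)
        from <- sample.int(g$n_exons - span_len + 1L, 1L)
        lgr_rows[[length(lgr_rows) + 1L]] <- tibble(
          patient_id = pid, gene = g$gene,
          exon_from = from, exon_to = from + span_len - 1L,
          type = type, cn = if (type == "deletion") 1L else 3L
        )
      }
      if (has_snv) {
        g <- pred_genes[sample.int(nrow(pred_genes), 1L), ]
        lof <- runif(1) < 0.6
        snv_rows[[length(snv_rows) + 1L]] <- tibble(
          patient_id = pid, gene = g$gene, chromosome = g$chromosome,
          position = g$start + sample.int(2000L, 1L),
          exon_index = sample.int(g$n_exons, 1L),
          consequence_class = if (lof) "lof" else "missense",
          popaf_max = runif(1, 0, 2e-4),
          pred_del_count = if (lof) sample(0:6, 1L) else sample(4:6, 1L),
          pred_total = 6L,
          assertion = sample(c("P", "LP", "none"), 1L, prob = c(0.3, 0.2, 0.5))
        )
      }
      # benign / VUS background germline variants
      n_bg <- rpois(1, config$background_snv_rate)
      if (n_bg > 0) {
        gs <- gene_tbl[sample.int(nrow(gene_tbl), n_bg, replace = TRUE), ]
        common <- runif(n_bg) < 0.6
        snv_rows[[length(snv_rows) + 1L]] <- tibble(
          patient_id = pid, gene = gs$gene, chromosome = gs$chromosome,
          position = gs$start + sample.int(2000L, n_bg, replace = TRUE),
          exon_index = map_int(gs$n_exons, ~ sample.int(.x, 1L)),
          consequence_class = sample(c("missense", "other"), n_bg,
                                     replace = TRUE, prob = c(0.7, 0.3)),
          popaf_max = ifelse(common, runif(n_bg, 0.01, 0.4), runif(n_bg, 0, 1e-4)),
          pred_del_count = sample(0:3, n_bg, replace = TRUE),
          pred_total = 6L,
          assertion = "none"
        )
      }
      # somatic mutations
      n_som <- rpois(1, config$somatic_rate * (if (msi_h) 4 else 1))
      if (n_som > 0) {
        gs <- gene_tbl[sample.int(nrow(gene_tbl), n_som, replace = TRUE), ]
        som_rows[[length(som_rows) + 1L]] <- tibble(
          patient_id = pid, gene = gs$gene, chromosome = gs$chromosome,
          position = gs$start + sample.int(2000L, n_som, replace = TRUE),
          nonsynonymous = runif(n_som) < 0.75
        )
      }
      # tumor copy-number segment profile: a few segments per chromosome
      wgd <- runif(1) < config$wgd_rate
      k <- sample(1:3, 22L, replace = TRUE)
      n_seg <- sum(k)
      chrom <- rep(paste0("chr", 1:22), k)
      starts <- ends <- numeric(n_seg)
      pos <- 1L
      for (ci in 1:22) {
        bounds <- sort(c(0, runif(k[ci] - 1, 0.2, 0.8), 1)) * 1e8
        idx <- pos:(pos + k[ci] - 1L)
        starts[idx] <- floor(bounds[-length(bounds)])
        ends[idx] <- floor(bounds[-1])
        pos <- pos + k[ci]
      }
      cn <- if (wgd) {
        sample(c(3L, 4L, 2L), n_seg, replace = TRUE, prob = c(0.45, 0.4, 0.15))
      } else {
        sample(c(2L, 1L, 3L), n_seg, replace = TRUE, prob = c(0.85, 0.075, 0.075))
      }
      seg_rows[[length(seg_rows) + 1L]] <- tibble(
        patient_id = pid, chromosome = chrom,
        start = starts, end = ends, cn = cn
      )

      pat_rows[[i]] <- tibble(
        patient_id = pid, cancer_type = ctype, sex = sex,
        age = if (age_known) age else NA_integer_,
        stage = stage, n_cancers = n_cancers, family_history = fam,
        msi_unstable_fraction = unstable, wgd_truth = wgd,
        has_lgr = has_lgr, has_snv = has_snv
      )
    })
  }

  empty_lgr <- tibble(patient_id = character(), gene = character(),
                      exon_from = integer(), exon_to = integer(),
                      type = character(), cn = integer())
  out <- list(
    patients = list_rbind(pat_rows),
    lgrs = if (length(lgr_rows)) list_rbind(lgr_rows) else empty_lgr,
    snvs = list_rbind(snv_rows),
    somatic = list_rbind(som_rows),
    segments = list_rbind(seg_rows)
  )
  attr(out, "panel") <- panel
  attr(out, "config") <- config
  class(out) <- "cohort_truth"
  out
}

#' Per-target copy states implied by a cohort's truth LGR events
#'
#' @param truth A `cohort_truth`.
#' @return Tibble (`sample_id`, `gene`, `exon_from`, `exon_to`, `cn`) ready
#'   for [simulate_depth()] / [simulate_snps()].
#' @export
cohort_copy_states <- function(truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  truth$lgrs %>%
    select(sample_id = "patient_id", "gene", "exon_from", "exon_to", "cn")
}

expand_copy_states <- function(panel, copy_states, sample_ids) {
  cn_mat <- matrix(2, nrow(panel), length(sample_ids),
                   dimnames = list(target_key(panel), sample_ids))
  if (!is.null(copy_states) && nrow(copy_states)) {
    unknown <- setdiff(copy_states$gene, panel$gene)
    if (length(unknown)) {
      abort_invalid(paste0("copy states refer to genes absent from the panel: ",
                           paste(unknown, collapse = ", ")))
    }
    for (r in seq_len(nrow(copy_states))) {
      cs <- copy_states[r, ]
      if (cs$cn < 0) abort_invalid("copy numbers must be >= 0.")
      if (!cs$sample_id %in% sample_ids) next
      hit <- panel$gene == cs$gene &
        panel$exon_index >= cs$exon_from & panel$exon_index <= cs$exon_to
      cn_mat[hit, cs$sample_id] <- cs$cn
    }
  }
  cn_mat
}

#' Simulate a per-exon read-depth matrix
#'
#' Counts are negative-binomial with mean `mu_t * s_p * CN / 2`: `mu_t` a
#' log-normal target-specific baseline with mean `mean_depth`, `s_p` a
#' log-normal per-sample size factor, and `CN` the germline copy number of
#' that target in that sample.  Reference normals are simulated diploid.
#'
#' @param panel A `panel_design`.
#' @param copy_states Tibble (`sample_id`, `gene`, `exon_from`, `exon_to`,
#'   `cn`) of non-diploid regions; targets not covered default to CN = 2.
#'   `NULL` means all samples diploid.
#' @param config A [sim_config()].
#' @param sample_ids Case sample ids; defaults to those in `copy_states`.
#' @param n_normals Number of reference normals (defaults from `config`).
#' @param seed Seed; defaults to the config master seed.
#'
#' @return A `depth_matrix` object (see [depth_matrix()]).
#' @export
simulate_depth <- function(panel, copy_states = NULL, config = sim_config(),
                           sample_ids = NULL, n_normals = config$n_normals,
                           seed = config$seed) {
  validate_panel(panel)
  if (is.null(sample_ids)) {
    if (is.null(copy_states) || !nrow(copy_states)) {
      abort_invalid("supply `sample_ids` when `copy_states` is empty.")
    }
    sample_ids <- unique(copy_states$sample_id)
  }
  cn_mat <- expand_copy_states(panel, copy_states, sample_ids)
  n_t <- nrow(panel)

  mu_t <- with_seed(derive_seed(seed, 0L), {
    rlnorm(n_t, log(config$mean_depth) - config$baseline_sdlog^2 / 2,
           config$baseline_sdlog)
  })

  draw_counts <- function(mu) {
    if (config$depth_dispersion == 0) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / config$depth_dispersion)
  }

  case_counts <- vapply(seq_along(sample_ids), function(j) {
    with_seed(derive_seed(seed, 1000000L + j), {
      s_p <- rlnorm(1, 0, config$size_factor_sdlog)
      rel <- pmax(cn_mat[, j] / 2, config$contamination)
      draw_counts(mu_t * s_p * rel)
    })
  }, numeric(n_t))

  normal_ids <- sprintf("N%04d", seq_len(n_normals))
  normal_counts <- vapply(seq_len(n_normals), function(j) {
    with_seed(derive_seed(seed, 2000000L + j), {
      s_p <- rlnorm(1, 0, config$size_factor_sdlog)
      draw_counts(mu_t * s_p)
    })
  }, numeric(n_t))

  counts <- cbind(case_counts, normal_counts)
  colnames(counts) <- c(sample_ids, normal_ids)
  rownames(counts) <- target_key(panel)
  depth_matrix(counts, panel,
               roles = c(rep("case", length(sample_ids)),
                         rep("reference_normal", n_normals)))
}

#' Construct a depth matrix object
#'
#' @param counts Integer matrix, targets x samples, rownames `gene:exon`.
#' @param panel The `panel_design` the rows refer to (same order).
#' @param roles Character vector per sample: `"case"` or `"reference_normal"`.
#' @return A list of class `depth_matrix` with elements `counts`, `panel`,
#'   `samples`.
#' @export
depth_matrix <- function(counts, panel, roles) {
  validate_panel(panel)
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(panel)) {
    abort_invalid("`counts` must have one row per panel target.")
  }
  if (length(roles) != ncol(counts)) {
    abort_invalid("`roles` must have one entry per sample column.")
  }
  if (any(counts < 0)) abort_invalid("read counts must be non-negative.")
  if (!all(roles %in% c("case", "reference_normal"))) {
    abort_invalid("roles must be 'case' or 'reference_normal'.")
  }
  structure(
    list(counts = counts, panel = panel,
         samples = tibble(sample_id = colnames(counts), role = roles)),
    class = "depth_matrix"
  )
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat(sprintf("<depth_matrix> %d targets x %d samples (%d case, %d normals)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$role == "case"),
              sum(x$samples$role == "reference_normal")))
  invisible(x)
}

#' @export
as_tibble.depth_matrix <- function(x, ...) {
  bind_cols(as_tibble(x$panel),
            as_tibble(x$counts, .name_repair = "minimal"))
}

#' Simulate SNP allele-depth observations
#'
#' SNP loci are scattered over the panel footprint at `snp_density` per kb.
#' Alternate-allele depth is binomial with a B-allele fraction set by the
#' truth zygosity and local copy number: 1/2 for a diploid heterozygote, 0 or
#' 1 for homozygotes, 1/3 or 2/3 for a heterozygote inside a CN = 3
#' duplication.  Heterozygous loci falling inside a CN = 1 heterozygous
#' deletion lose one allele and are emitted as homozygous for the surviving
#' allele.
#'
#' @inheritParams simulate_depth
#' @return Tibble with columns `sample_id`, `chromosome`, `position`, `gene`,
#'   `exon_index`, `ref_depth`, `alt_depth`, `truth_zygosity`.
#' @export
simulate_snps <- function(panel, copy_states = NULL, config = sim_config(),
                          sample_ids = NULL, seed = config$seed) {
  validate_panel(panel)
  if (is.null(sample_ids)) {
    if (is.null(copy_states) || !nrow(copy_states)) {
      abort_invalid("supply `sample_ids` when `copy_states` is empty.")
    }
    sample_ids <- unique(copy_states$sample_id)
  }
  if (config$snp_density < 0) abort_invalid("`snp_density` must be >= 0.")
  cn_mat <- expand_copy_states(panel, copy_states, sample_ids)

  out <- map(seq_along(sample_ids), function(j) {
    with_seed(derive_seed(seed, 3000000L + j), {
      lens <- panel$end - panel$start
      n_snp <- rpois(nrow(panel), lens / 1000 * config$snp_density)
      idx <- rep.int(seq_len(nrow(panel)), n_snp)
      if (!length(idx)) return(NULL)
      cn <- cn_mat[idx, j]
      zyg <- sample(c("hom_ref", "het", "hom_alt"), length(idx),
                    replace = TRUE, prob = c(0.45, 0.35, 0.20))
      # allele loss inside heterozygous deletions
      lost <- zyg == "het" & cn == 1
      zyg[lost] <- sample(c("hom_ref", "hom_alt"), sum(lost), replace = TRUE)
      baf <- dplyr::case_when(
        zyg == "hom_ref" ~ config$seq_error,
        zyg == "hom_alt" ~ 1 - config$seq_error,
        cn == 3 ~ sample(c(1 / 3, 2 / 3), length(idx), replace = TRUE),
        TRUE ~ 0.5
      )
      depth <- rpois(length(idx), config$mean_depth * pmax(cn, 2 * config$contamination) / 2)
      alt <- rbinom(length(idx), depth, baf)
      tibble(
        sample_id = sample_ids[j],
        chromosome = panel$chromosome[idx],
        position = panel$start[idx] +
          vapply(panel$end[idx] - panel$start[idx], function(l) sample.int(l, 1L), 1L),
        gene = panel$gene[idx],
        exon_index = panel$exon_index[idx],
        ref_depth = depth - alt,
        alt_depth = alt,
        truth_zygosity = zyg
      )
    })
  })
  list_rbind(keep(out, ~ !is.null(.x)))
}

#' Simulate ddPCR droplet counts
#'
#' Target molecules partition into droplets as a Poisson process: a droplet
#' is positive with probability `1 - exp(-lambda)` where
#' `lambda = rate_per_copy * CN`.  A copy-number-stable reference channel
#' (RPP30-like) is simulated at `reference_cn`.
#'
#' @param true_cn True copy number of the target locus.
#' @param n_droplets Total droplets per well.
#' @param reference_cn Copy number of the reference locus (default diploid).
#' @param rate_per_copy Mean target molecules per droplet per genome copy.
#' @param seed Integer seed.
#' @param sample_id,assay Labels carried through to the output.
#' @return Tibble with one row per channel: `sample_id`, `assay`, `channel`
#'   (`"target"` / `"reference"`), `positive`, `total`.
#' @export
simulate_droplets <- function(true_cn, n_droplets = 20000L, reference_cn = 2,
                              rate_per_copy = 0.05, seed = 1L,
                              sample_id = "S1", assay = "assay1") {
  if (true_cn < 0 || reference_cn < 0) abort_invalid("copy numbers must be >= 0.")
  if (rate_per_copy < 0) abort_invalid("`rate_per_copy` must be >= 0.")
  n_droplets <- check_count(n_droplets, "n_droplets")
  with_seed(seed, {
    p_t <- 1 - exp(-rate_per_copy * true_cn)
    p_r <- 1 - exp(-rate_per_copy * reference_cn)
    tibble(
      sample_id = sample_id, assay = assay,
      channel = c("target", "reference"),
      positive = c(rbinom(1, n_droplets, p_t), rbinom(1, n_droplets, p_r)),
      total = n_droplets
    )
  })
}
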