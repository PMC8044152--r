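#' Pipeline configuration
#'
#' All analysis thresholds in one serialisable list, defaulting to the
#' values the pipeline is designed around: ISS at z below -2, rare-variant
#' masks at within-cohort MAF below 1e-4 with a per-gene cumulative allele
#' count of at least 20, the 0-1 similarity sweep in steps of 0.01, and
#' Bonferroni adjustment over five gene-level tests.
#'
#' @param sim [simulation_config()] describing the synthetic inputs.
#' @param maf_cutoff mask minor-allele-frequency cutoff (strict `<`).
#' @param min_cum_ac per-gene cumulative allele count needed for
#'   gene-level tests.
#' @param iss_threshold ISS z-score cutoff.
#' @param similarity_grid thresholds for the approval-odds sweep.
#' @param n_tests_genes,n_tests_sets Bonferroni denominators for
#'   gene-level and set-level batteries.
#' @param stages character vector of stages to run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            maf_cutoff = 1e-4,
                            min_cum_ac = 20,
                            iss_threshold = -2,
                            similarity_grid = seq(0, 1, by = 0.01),
                            n_tests_genes = 5,
                            n_tests_sets = 25,
                            stages = c("screen", "approval", "qc", "assoc",
                                       "prs", "functional")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains the stages end to end: catalog simulation and bidirectional
#' screen; trial simulation and approval-odds sweep; cohort simulation and
#' QC cascade; burden/SKAT association battery over gene sets and core
#' genes; polygenic scoring, quintile stratification, heterogeneity and
#' ISS odds ratios; functional-assay integration. Later stages consume
#' earlier stages' outputs only, and the report carries a provenance
#' record (config hash, seed, package version) so reruns are verifiable.
#'
#' @param config [pipeline_config()].
#' @return a report list with one named element per stage plus
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$sim
  report <- list()
  stage_on <- function(s) s %in% config$stages

  ## screen ------------------------------------------------------------------
  cat_sim <- simulate_catalog(cfg)
  if (stage_on("screen")) {
    scr <- call_bidirectional(cat_sim$catalog)
    report$screen <- list(best_genes = scr$best_genes,
                          review_queue = scr$review_queue,
                          planted = cat_sim$best_genes)
    best_gene_list <- unique(scr$best_genes$gene)
  } else {
    best_gene_list <- unique(cat_sim$best_genes$gene)
  }

  ## approval odds -----------------------------------------------------------
  if (stage_on("approval")) {
    tr <- simulate_trials(cfg, best_gene_list)
    sw <- sweep_thresholds(tr$table, tr$evidence, tr$similarity,
                           grid = config$similarity_grid)
    report$approval <- list(estimates = sw$estimates, argmax = sw$argmax)
  }

  ## cohort + qc -------------------------------------------------------------
  needs_cohort <- any(vapply(c("qc", "assoc", "prs", "functional"),
                             stage_on, logical(1)))
  if (needs_cohort) {
    cohort <- simulate_cohort(cfg)
    if (!stage_on("qc")) {
      stop("stage `qc` is required by the association stages; enable it")
    }
    sq <- filter_samples(cohort$samples)
    kept_ids <- remove_related(sq$kept, cohort$kinship)
    kept_var <- filter_variants(cohort$variants)
    conc <- external_af_concordance(cohort$variants$cohort_ac,
                                    cohort$variants$cohort_an,
                                    cohort$variants$external_ref_af)
    kept_var <- intersect(kept_var, cohort$variants$variant_id[conc$keep])
    variants_qc <- cohort$variants[cohort$variants$variant_id %in% kept_var, ]
    samples_qc <- cohort$samples[cohort$samples$sample_id %in% kept_ids, ]
    dosages_qc <- cohort$dosages[kept_ids, kept_var, drop = FALSE]
    masks <- build_masks(variants_qc, maf_cutoff = config$maf_cutoff,
                         min_cum_ac = config$min_cum_ac)
    report$qc <- list(attrition = sq$attrition,
                      n_samples = length(kept_ids),
                      n_variants = length(kept_var),
                      gene_ac = masks$gene_ac)
  }

  ## association battery -----------------------------------------------------
  if ((stage_on("prs") || stage_on("functional")) && !stage_on("assoc")) {
    stop("stages `prs` and `functional` depend on `assoc`; enable it")
  }
  if (stage_on("assoc")) {
    pheno <- normalize_height(samples_qc)
    pheno <- define_iss(pheno, config$iss_threshold)
    pheno$sex <- samples_qc$sex[match(pheno$sample_id,
                                      samples_qc$sample_id)]
    pheno$age <- samples_qc$age[match(pheno$sample_id,
                                      samples_qc$sample_id)]
    dos <- dosages_qc[pheno$sample_id, , drop = FALSE]
    sets <- build_gene_sets(cohort$annotations)
    pa <- masks$masks[masks$masks$mask == "protein_altering", ]
    ptv <- masks$masks[masks$masks$mask == "ptv", ]
    core <- union(sets$sets$Set1, sets$sets$Set2)

    unit_rows <- list()
    run_unit <- function(unit, ids_pa, ids_ptv) {
      dplyr::bind_rows(
        burden_test(dos, ids_pa, unit, pheno, "linear",
                    mask = "protein_altering"),
        burden_test(dos, ids_ptv, unit, pheno, "linear", mask = "ptv"),
        burden_test(dos, ids_pa, unit, pheno, "logistic",
                    mask = "protein_altering"),
        skat_test(dos, ids_pa, unit, pheno, mask = "protein_altering")
      )
    }
    for (g in core) {
      unit_rows[[g]] <- run_unit(g, pa$variant_id[pa$gene == g],
                                 ptv$variant_id[ptv$gene == g])
    }
    unit_rows[["Set1+Set2"]] <- run_unit(
      "Set1+Set2", pa$variant_id[pa$gene %in% core],
      ptv$variant_id[ptv$gene %in% core])
    assoc <- adjust_significance(dplyr::bind_rows(unit_rows),
                                 config$n_tests_genes)
    report$assoc <- list(results = assoc, sets = sets$sets,
                         n_set_cells = sum(sets$cells$n_genes > 0))
  }

  ## polygenic stratification ------------------------------------------------
  if (stage_on("prs")) {
    ss <- cohort$sumstats
    wts <- ldpred_inf_weights(ss$beta, NULL, n_gwas = ss$n[1],
                              h2 = max(cfg$prs_h2, 0.01),
                              variant_ids = ss$variant_id,
                              effect_alleles = ss$effect_allele)
    ps <- score_samples(cohort$common_dosages[match(pheno$sample_id,
                                                    cohort$samples$sample_id),
                                              , drop = FALSE], wts)
    qt <- assign_quintiles(ps)
    carrier <- rep("none", nrow(pheno))
    core_pa <- pa$variant_id[pa$gene %in% core]
    core_ptv <- ptv$variant_id[ptv$gene %in% core]
    mis_ids <- setdiff(core_pa, core_ptv)
    has_mis <- burden_score(dos, mis_ids) > 0
    has_lof <- burden_score(dos, core_ptv) > 0
    carrier[has_mis] <- "missense"
    carrier[has_lof] <- "lof"          # lof takes precedence
    strat <- stratified_effects(pheno, carrier, qt)
    or_tab <- iss_or_by_group(pheno$iss, carrier, qt)
    r2 <- summary(stats::lm(pheno$z_height ~ ps))$r.squared
    beta_q <- stats::coef(stats::lm(pheno$z_height ~ qt))[["qt"]]
    report$prs <- list(effects = strat$effects,
                       heterogeneity = strat$heterogeneity,
                       or_table = or_tab, ps_r2 = r2,
                       beta_per_quintile = beta_q,
                       quintiles = qt, carrier_class = carrier, ps = ps)
  }

  ## functional integration --------------------------------------------------
  if (stage_on("functional")) {
    core_gene1 <- cohort$truth$core_genes[1]
    vids <- cohort$variants$variant_id[cohort$variants$gene == core_gene1]
    vids <- intersect(vids, colnames(dos))
    eff <- cohort$truth$variant_effect[vids]
    carriers_of <- lapply(vids, function(v) {
      pheno$z_height[as.numeric(dos[, v]) > 0]
    })
    ftab <- tibble::tibble(variant_id = vids, effect = unname(eff),
                           carrier_heights = carriers_of)
    ftab <- ftab[lengths(ftab$carrier_heights) > 0, ]
    ftab <- simulate_functional(ftab, cfg)
    report$functional <- list(
      table = ftab,
      bins = table(bin_activity(ftab$activity)),
      regression = activity_regression(ftab),
      predictor_comparison = compare_predictors(ftab)
    )
  }

  report$provenance <- list(
    config_hash = rlang::hash(config),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("bestgene")),
    thresholds = list(maf_cutoff = config$maf_cutoff,
                      min_cum_ac = config$min_cum_ac,
                      iss_threshold = config$iss_threshold,
                      n_tests_genes = config$n_tests_genes,
                      n_tests_sets = config$n_tests_sets)
  )
  report
}
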