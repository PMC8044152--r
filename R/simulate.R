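#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate
#' the study conditions the pipeline is designed for: a post-QC exome
#' cohort of 34,000 individuals in which idiopathic short stature (height
#' z below -2) has its Gaussian-tail prevalence, a five-gene
#' bidirectional core set whose rare protein-altering alleles lower height
#' by 0.20 SD on average (protein-truncating alleles by 0.85 SD) and
#' carry an ISS odds ratio near 2.75, a polygenic score explaining 20% of
#' height variance, and a clinical-trial table in which genetically
#' supported target-indication pairs are 4-fold enriched for approval.
#'
#' @param seed root seed; all four generator stages draw from named
#'   substreams derived from it.
#' @param n_samples cohort size (>= 100).
#' @param n_genes genes carrying rare variants.
#' @param n_best_genes planted bidirectional (core) genes, `<= n_genes`.
#' @param carrier_freq expected per-gene carrier probability.
#' @param rare_effect_sd mean per-allele height effect (SD units) of core
#'   set alleles; split into a protein-truncating component
#'   (`ptv_effect`, fraction `ptv_fraction` of alleles) and a missense
#'   component whose mean is derived so the overall mean equals
#'   `rare_effect_sd` and whose SD is `missense_effect_sd`.
#' @param prs_h2 fraction of height variance explained by the common-variant
#'   score, in `[0, 1)`.
#' @param iss_threshold z-score cutoff defining ISS (strict `<`).
#' @param trial_rr planted Phase I -> Approval relative risk for supported
#'   pairs (> 0); applied as `trial_rr^(1/3)` per transition on the risk
#'   scale so the cumulative relative risk equals `trial_rr`.
#' @param phase_attrition base success probabilities for the three
#'   transitions (Phase I->II, II->III, III->Approval), each in (0, 1).
#' @param n_pairs target-indication pairs in the trial table.
#' @param support_similarity similarity above which a supported pair's
#'   planted enrichment applies.
#' @param n_common_snps,n_gwas,ld_block_size common-variant score settings:
#'   number of scored SNPs, GWAS sample size behind the summary
#'   statistics, LD block size (1 = independent SNPs).
#' @param variants_per_gene mean rare variants per gene (Poisson).
#' @param ptv_fraction,ptv_effect,missense_effect_sd rare-allele effect
#'   mixture (see `rare_effect_sd`).
#' @param qc_fail_frac fraction of samples/variants planted to fail each
#'   QC criterion class.
#' @param functional_noise_sd assay noise on the cGMP activity readout.
#' @return validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_samples = 34000L,
                              n_genes = 40L,
                              n_best_genes = 5L,
                              carrier_freq = 0.0055,
                              rare_effect_sd = -0.20,
                              prs_h2 = 0.20,
                              iss_threshold = -2,
                              trial_rr = 4,
                              phase_attrition = c(0.54, 0.35, 0.62),
                              n_pairs = 26884L,
                              support_similarity = 0.8,
                              n_common_snps = 200L,
                              n_gwas = 7e5,
                              ld_block_size = 1L,
                              variants_per_gene = 120,
                              ptv_fraction = 0.05,
                              ptv_effect = -0.85,
                              missense_effect_sd = 0.58,
                              qc_fail_frac = 0.004,
                              functional_noise_sd = 0.08) {
  cfg <- as.list(environment())
  with(cfg, {
    if (!is.numeric(seed) || length(seed) != 1) stop("invalid seed")
    if (n_samples < 100) stop("n_samples must be >= 100")
    if (n_best_genes < 0 || n_best_genes > n_genes) {
      stop("need 0 <= n_best_genes <= n_genes")
    }
    if (carrier_freq < 0 || carrier_freq > 1) stop("carrier_freq in [0,1]")
    if (prs_h2 < 0 || prs_h2 >= 1) stop("prs_h2 in [0, 1)")
    if (trial_rr <= 0) stop("trial_rr must be positive")
    if (length(phase_attrition) != 3 ||
        any(phase_attrition <= 0 | phase_attrition >= 1)) {
      stop("phase_attrition must be three probabilities in (0,1)")
    }
    if (ptv_fraction < 0 || ptv_fraction >= 1) stop("ptv_fraction in [0,1)")
  })
  structure(cfg, class = "simulation_config")
}

# named substreams off the root seed keep the four generator stages
# independently reproducible
substream_seed <- function(seed, stream) {
  offset <- c(catalog = 101L, trials = 202L, cohort = 303L,
              functional = 404L)[[stream]]
  as.integer((abs(as.numeric(seed)) * 7919 + offset) %% 2147483629)
}

mean_missense_effect <- function(cfg) {
  (cfg$rare_effect_sd - cfg$ptv_fraction * cfg$ptv_effect) /
    (1 - cfg$ptv_fraction)
}

# phenotype axes available to planted bidirectional genes; categories echo
# the large disease areas of real mutation catalogs
catalog_axes <- function() {
  tibble::tibble(
    axis = c("ldl cholesterol", "stature", "blood glucose",
             "clotting factor viii activity", "qt interval",
             "thyroid hormone level", "blood pressure"),
    up_label = c("high ldl cholesterol", "tall stature",
                 "high blood glucose", "high clotting factor viii activity",
                 "long qt syndrome", "high thyroid hormone level",
                 "high blood pressure"),
    down_label = c("low ldl cholesterol", "short stature",
                   "low blood glucose", "low clotting factor viii activity",
                   "short qt syndrome", "low thyroid hormone level",
                   "low blood pressure"),
    category = c("lipids", "height", "glucose", "clotting",
                 "cardiovascular", "endocrine", "cardiovascular")
  )
}

#' Simulate a gene-disease mutation catalog
#'
#' Produces HGMD-like (gene, disease, variant_class) records in which
#' exactly `n_best_genes` genes carry at least one "up" and one "down"
#' disease label on the same phenotype axis. The remaining genes exercise
#' the screen's negative paths: unidirectional labels, opposing labels on
#' different axes, benign/molecular phenotypes on the exclusion list, and
#' genes with fewer than two unique diseases.
#'
#' @param cfg [simulation_config()].
#' @return list with `catalog` (tibble: gene, disease, variant_class),
#'   `best_genes` (planted truth: gene, axis, category).
#' @export
simulate_catalog <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(substream_seed(cfg$seed, "catalog"))
  axes <- catalog_axes()
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  best <- genes[seq_len(cfg$n_best_genes)]

  rows <- list()
  truth <- tibble::tibble(gene = character(), axis = character(),
                          category = character())
  for (i in seq_along(best)) {
    ax <- axes[((i - 1) %% nrow(axes)) + 1, ]
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene = best[i],
      disease = c(ax$up_label, ax$down_label),
      variant_class = "DM"
    )
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      gene = best[i], axis = ax$axis, category = ax$category))
  }

  others <- setdiff(genes, best)
  for (j in seq_along(others)) {
    g <- others[j]
    ax <- axes[(j %% nrow(axes)) + 1, ]
    kind <- j %% 4
    dis <- switch(as.character(kind),
      # unidirectional: two unique diseases, same direction
      "0" = c(ax$up_label, paste("familial", ax$axis, "disorder")),
      # opposing directions but on two different axes
      "1" = c(ax$up_label,
              axes$down_label[(j %% nrow(axes) + 1) %% nrow(axes) + 1]),
      # benign/molecular bidirectionality: excluded by the lexicon
      "2" = c("increased pigmentation", "decreased pigmentation"),
      # fewer than two unique diseases: dropped by the min-2 filter
      "3" = ax$down_label
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene = g, disease = dis,
      variant_class = if (j %% 7 == 0) "DM?" else "DM"
    )
  }
  catalog <- dplyr::bind_rows(rows)
  # duplicated records must collapse to unique pairs downstream
  catalog <- dplyr::bind_rows(catalog, catalog[1, ])
  list(catalog = catalog, best_genes = truth)
}

#' Simulate a clinical-trial target-indication table
#'
#' Each pair traverses Phase I -> II -> III -> Approval as a Bernoulli
#' chain with the base transition probabilities of
#' `cfg$phase_attrition`. Pairs whose target is a planted bidirectional
#' gene and whose indication has similarity above
#' `cfg$support_similarity` to the gene's trait get each transition
#' probability multiplied by `trial_rr^(1/3)` (risk scale), so the
#' cumulative Phase I -> Approval relative risk equals `trial_rr`.
#' Unsupported evidence classes (OMIM unidirectional, GWAS) are annotated
#' on other genes but carry no planted enrichment.
#'
#' @param cfg [simulation_config()].
#' @param best_genes character vector of supported target genes (e.g. the
#'   planted truth of [simulate_catalog()]).
#' @return list: `table` (pair_id, target_gene, indication, reached,
#'   category), `similarity` (long tibble indication/trait/value),
#'   `evidence` (gene, trait, class, category), `truth` (logical supported
#'   flag per pair).
#' @export
simulate_trials <- function(cfg, best_genes) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(substream_seed(cfg$seed, "trials"))
  m <- cfg$trial_rr^(1 / 3)
  if (any(cfg$phase_attrition * m >= 1)) {
    stop("trial_rr too large for the configured phase_attrition ",
         "(a transition probability would exceed 1)")
  }

  axes <- catalog_axes()
  n_ind <- 400L
  indications <- sprintf("IND%03d", seq_len(n_ind))
  ind_category <- sample(axes$category, n_ind, replace = TRUE)

  genes <- unique(c(best_genes,
                    sprintf("GENE%04d", seq_len(cfg$n_genes)),
                    sprintf("NONG%04d", seq_len(200))))
  traits <- tibble::tibble(
    gene = genes,
    trait = paste0("trait_", genes),
    class = ifelse(genes %in% best_genes, "BEST",
                   sample(c("OMIM_unidirectional", "GWAS", "none"),
                          length(genes), replace = TRUE,
                          prob = c(0.2, 0.3, 0.5)))
  )
  evidence <- traits[traits$class != "none", c("gene", "trait", "class")]
  evidence$category <- sample(axes$category, nrow(evidence), replace = TRUE)
  # planted BEST genes keep the category of their catalog axis
  idx <- match(best_genes, evidence$gene)
  evidence$category[idx[!is.na(idx)]] <-
    axes$category[((seq_along(best_genes) - 1) %% nrow(axes)) + 1][!is.na(idx)]

  # similarity: background Beta(2, 8); each evidence trait gets a block of
  # genuinely linked indications drawn from a high mode Beta(24, 3)
  n_linked <- max(3L, n_ind %/% 20L)
  sim_rows <- vector("list", nrow(traits))
  linked_of <- list()
  for (i in seq_len(nrow(traits))) {
    v <- stats::rbeta(n_ind, 2, 8)
    linked <- sample.int(n_ind, n_linked)
    v[linked] <- stats::rbeta(n_linked, 24, 3)
    linked_of[[traits$trait[i]]] <- indications[linked]
    sim_rows[[i]] <- tibble::tibble(indication = indications,
                                    trait = traits$trait[i], value = v)
  }
  similarity <- dplyr::bind_rows(sim_rows)
  lut <- sim_lookup(similarity)

  # drug programs concentrate on genetically evidenced targets, so planted
  # bidirectional genes are oversampled among pair targets
  target <- sample(genes, cfg$n_pairs, replace = TRUE,
                   prob = ifelse(genes %in% best_genes, 8, 1))
  indication <- sample(indications, cfg$n_pairs, replace = TRUE)
  trait <- traits$trait[match(target, traits$gene)]
  sim <- unname(lut[paste(indication, trait, sep = "\r")])
  supported <- target %in% best_genes & sim > cfg$support_similarity

  p <- matrix(rep(cfg$phase_attrition, each = cfg$n_pairs), ncol = 3)
  p[supported, ] <- p[supported, ] * m
  pass <- matrix(stats::runif(cfg$n_pairs * 3), ncol = 3) < p
  reached <- phase_levels[1 + pass[, 1] + (pass[, 1] & pass[, 2]) +
                            (pass[, 1] & pass[, 2] & pass[, 3])]

  list(
    table = tibble::tibble(
      pair_id = sprintf("pair%05d", seq_len(cfg$n_pairs)),
      target_gene = target,
      indication = indication,
      reached = reached,
      category = ind_category[match(indication, indications)]
    ),
    similarity = similarity,
    evidence = evidence,
    truth = supported
  )
}

#' Simulate an exome cohort with planted rare-variant and polygenic effects
#'
#' Generates (i) independent common-SNP dosages plus true per-allele
#' weights scaled so the true score explains `prs_h2` of height variance,
#' with GWAS summary statistics observed at sample size `n_gwas`; (ii)
#' rare variants (within-cohort allele frequency on the 1e-4 scale)
#' assigned to genes with consequence classes, where alleles in the core
#' (bidirectional) genes carry the configured height-effect mixture and
#' all other genes are null; (iii) height built from sex/age/PC structure
#' plus score plus rare effects plus Gaussian noise, with the residual
#' variance chosen so the standardized height has unit variance; and (iv)
#' sample/variant QC metrics with a small planted fraction of failures,
#' kinship pairs, gene annotations for the five evidence lists, and the
#' per-variant truth needed by recovery tests.
#'
#' @param cfg [simulation_config()].
#' @return object of class `best_cohort`: list with `samples`, `variants`,
#'   `dosages` (sparse sample x rare-variant matrix), `common_dosages`,
#'   `sumstats`, `kinship`, `annotations`, `truth`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$carrier_freq * cfg$n_samples < 1) {
    warning("carrier_freq * n_samples < 1: expect empty carrier sets")
  }
  set.seed(substream_seed(cfg$seed, "cohort"))
  n <- cfg$n_samples
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  core <- genes[seq_len(cfg$n_best_genes)]

  ## --- samples: covariates -------------------------------------------------
  sample_id <- sprintf("S%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < 0.54, "F", "M")
  age <- stats::runif(n, 45, 75)
  pcs <- matrix(stats::rnorm(n * 5), ncol = 5,
                dimnames = list(NULL, paste0("pc", 1:5)))

  ## --- common-variant score ------------------------------------------------
  m <- cfg$n_common_snps
  af <- stats::runif(m, 0.05, 0.5)
  common <- vapply(seq_len(m), function(j) stats::rbinom(n, 2, af[j]),
                   numeric(n))
  colnames(common) <- sprintf("rs%05d", seq_len(m))
  w_raw <- stats::rnorm(m)
  scale_w <- if (cfg$prs_h2 > 0)
    sqrt(cfg$prs_h2 / sum(w_raw^2 * 2 * af * (1 - af))) else 0
  w_true <- w_raw * scale_w
  g_score <- drop(common %*% w_true)
  g_score <- g_score - mean(g_score)
  se_gwas <- 1 / sqrt(2 * af * (1 - af) * cfg$n_gwas)
  sumstats <- tibble::tibble(
    variant_id = colnames(common),
    effect_allele = "A",
    beta = w_true + stats::rnorm(m, 0, se_gwas),
    se = se_gwas, af = af, n = cfg$n_gwas
  )

  ## --- rare variants -------------------------------------------------------
  n_var_gene <- pmax(1L, stats::rpois(cfg$n_genes, cfg$variants_per_gene))
  # per-gene expected carriers ~ carrier_freq * n; allele counts per variant
  # are 1 + Poisson, truncated so within-cohort AF stays below 1e-4 at the
  # default cohort size (mirrors the observed singleton-heavy sparsity)
  gene_of <- rep(genes, n_var_gene)
  n_var <- length(gene_of)
  target_ac <- cfg$carrier_freq * n
  mean_extra <- max(target_ac / mean(n_var_gene) - 1, 0.05)
  ac <- 1L + stats::rpois(n_var, mean_extra)
  ac <- pmin(ac, max(6, floor(2 * n * 1e-4) - 1))

  is_core <- gene_of %in% core
  cons <- ifelse(stats::runif(n_var) < cfg$ptv_fraction,
                 sample(ptv_classes, n_var, replace = TRUE),
                 "missense")
  effect <- numeric(n_var)
  mu_mis <- mean_missense_effect(cfg)
  effect[is_core] <- ifelse(
    cons[is_core] %in% ptv_classes,
    cfg$ptv_effect,
    stats::rnorm(sum(is_core), mu_mis, cfg$missense_effect_sd) *
      (cfg$rare_effect_sd != 0)
  )
  if (cfg$rare_effect_sd == 0) effect[] <- 0

  # a small fraction of non-core filler variants are planted as QC
  # failures: low call rate, HWE violation (homozygous carriers), or
  # reference-frequency inflation
  fail_pool <- which(!is_core)
  n_fail <- ceiling(cfg$qc_fail_frac * n_var)
  fail_callrate <- fail_pool[seq_len(min(n_fail, length(fail_pool)))]
  fail_pool <- setdiff(fail_pool, fail_callrate)
  fail_hwe <- fail_pool[seq_len(min(n_fail, length(fail_pool)))]
  fail_pool <- setdiff(fail_pool, fail_hwe)
  fail_afcon <- fail_pool[seq_len(min(n_fail, length(fail_pool)))]
  ac[fail_afcon] <- pmax(ac[fail_afcon], 30L)

  variant_id <- sprintf("var%05d", seq_len(n_var))
  carrier_i <- integer(0); carrier_j <- integer(0); carrier_x <- integer(0)
  hom <- seq_len(n_var) %in% fail_hwe
  for (v in seq_len(n_var)) {
    if (hom[v]) {
      # homozygous carriers only: grossly violates Hardy-Weinberg
      n_hom <- 4L
      who <- sample.int(n, n_hom)
      carrier_i <- c(carrier_i, who)
      carrier_j <- c(carrier_j, rep(v, n_hom))
      carrier_x <- c(carrier_x, rep(2L, n_hom))
    } else {
      who <- sample.int(n, min(ac[v], n))
      carrier_i <- c(carrier_i, who)
      carrier_j <- c(carrier_j, rep(v, length(who)))
      carrier_x <- c(carrier_x, rep(1L, length(who)))
    }
  }
  dosages <- Matrix::sparseMatrix(
    i = carrier_i, j = carrier_j, x = carrier_x,
    dims = c(n, n_var), dimnames = list(sample_id, variant_id)
  )

  ## --- height --------------------------------------------------------------
  rare_contrib <- as.numeric(dosages[, is_core, drop = FALSE] %*%
                               effect[is_core])
  var_rare <- cfg$n_best_genes * cfg$carrier_freq *
    (cfg$ptv_fraction * cfg$ptv_effect^2 +
       (1 - cfg$ptv_fraction) * (mu_mis^2 + cfg$missense_effect_sd^2)) *
    (cfg$rare_effect_sd != 0)
  eps_sd <- sqrt(max(1 - cfg$prs_h2 - var_rare, 0.05))
  z_core <- g_score + rare_contrib + stats::rnorm(n, 0, eps_sd)
  height_cm <- ifelse(sex == "F", 162.7, 175.6) -
    0.06 * (age - 60) + drop(pcs %*% c(0.3, -0.2, 0.1, 0.05, -0.05)) +
    6.2 * z_core

  ## --- sample QC metrics (mostly passing; planted failures) ---------------
  samples <- tibble::tibble(
    sample_id = sample_id, sex = sex, age = age,
    pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3], pc4 = pcs[, 4],
    pc5 = pcs[, 5], height_cm = height_cm,
    ancestry_flag = TRUE, aneuploidy_flag = FALSE,
    het_rate = stats::runif(n, 0.175, 0.205),
    n_non_ref = round(stats::rnorm(n, 65000, 3000)),
    n_singletons = stats::rpois(n, 60),
    het_hom_ratio = stats::runif(n, 1.4, 1.7),
    ti_tv = stats::rnorm(n, 3.0, 0.05),
    call_rate = stats::runif(n, 0.995, 1),
    chip_het_concordance = stats::runif(n, 0.985, 1)
  )
  n_fail_s <- ceiling(cfg$qc_fail_frac * n)
  planted <- split(sample(seq_len(n), 8 * n_fail_s),
                   rep(1:8, each = n_fail_s))
  samples$ancestry_flag[planted[[1]]] <- FALSE
  samples$aneuploidy_flag[planted[[2]]] <- TRUE
  samples$het_rate[planted[[3]]] <- 0.22
  samples$n_non_ref[planted[[4]]] <- 90000
  samples$n_singletons[planted[[5]]] <- 250
  samples$het_hom_ratio[planted[[6]]] <- 1.2
  samples$call_rate[planted[[7]]] <- 0.98
  samples$chip_het_concordance[planted[[8]]] <- 0.97

  n_kin <- max(1L, n_fail_s)
  kin_ids <- sample(sample_id, 2 * n_kin)
  kinship <- tibble::tibble(
    id1 = kin_ids[seq_len(n_kin)],
    id2 = kin_ids[n_kin + seq_len(n_kin)],
    degree = sample(1:3, n_kin, replace = TRUE)
  )

  ## --- variant records -----------------------------------------------------
  an <- 2L * n
  geno_ac <- Matrix::colSums(dosages)
  n_het <- tabulate(carrier_j[carrier_x == 1L], nbins = n_var)
  n_hom <- tabulate(carrier_j[carrier_x == 2L], nbins = n_var)
  hwe_p <- vapply(seq_len(n_var), function(v) {
    hwe_exact_p(n - n_het[v] - n_hom[v], n_het[v], n_hom[v])
  }, numeric(1))
  call_rate_v <- stats::runif(n_var, 0.992, 1)
  call_rate_v[fail_callrate] <- 0.985
  ref_af <- pmax(geno_ac / an * exp(stats::rnorm(n_var, 0, 0.2)), 1e-7)
  ref_af[fail_afcon] <- 1e-6
  ref_af[sample.int(n_var, ceiling(0.3 * n_var))] <- NA  # novel variants
  variants <- tibble::tibble(
    variant_id = variant_id,
    chrom = ifelse(gene_of == genes[cfg$n_genes], "X", "1"),
    pos = 10000L + 100L * seq_len(n_var),
    ref = "A", alt = "G",
    gene = gene_of,
    consequence_class = cons,
    impact = ifelse(cons %in% ptv_classes, "high", "moderate"),
    cohort_ac = as.integer(geno_ac),
    # on the X, males contribute a single allele to the allele number
    cohort_an = ifelse(gene_of == genes[cfg$n_genes],
                       2L * sum(sex == "F") + sum(sex == "M"), an),
    call_rate = call_rate_v,
    hwe_p = hwe_p,
    external_ref_af = ref_af
  )

  ## --- gene annotations for the five evidence lists ------------------------
  n_core <- cfg$n_best_genes
  annotations <- tibble::tibble(
    gene = genes,
    GWAS = FALSE, HGMD_SHORT = FALSE, HGMD_TALL = FALSE,
    OMIM_SHORT = FALSE, OMIM_OVERGROWTH = FALSE
  )
  if (n_core > 0) {
    core_idx <- seq_len(n_core)
    annotations[core_idx, c("HGMD_SHORT", "HGMD_TALL", "OMIM_SHORT",
                            "OMIM_OVERGROWTH")] <- TRUE
    # roughly the first half of the core set also has a GWAS signal
    annotations$GWAS[core_idx[seq_len(ceiling(n_core / 2))]] <- TRUE
  }
  others_idx <- setdiff(seq_len(cfg$n_genes), seq_len(n_core))
  flag_cols <- c("GWAS", "HGMD_SHORT", "HGMD_TALL", "OMIM_SHORT",
                 "OMIM_OVERGROWTH")
  for (i in others_idx) {
    pick <- sample(flag_cols, sample(1:2, 1))
    annotations[i, pick] <- TRUE
  }

  structure(list(
    samples = samples,
    variants = variants,
    dosages = dosages,
    common_dosages = common,
    sumstats = sumstats,
    kinship = kinship,
    annotations = annotations,
    config = cfg,
    truth = list(
      core_genes = core,
      variant_effect = stats::setNames(effect, variant_id),
      w_true = stats::setNames(w_true, colnames(common)),
      g_score = g_score,
      z_core = z_core,
      planted_sample_failures = planted,
      planted_variant_failures = list(call_rate = fail_callrate,
                                      hwe = fail_hwe,
                                      af_concordance = fail_afcon)
    )
  ), class = "best_cohort")
}

#' @export
print.best_cohort <- function(x, ...) {
  cat("<best_cohort> ", nrow(x$samples), " samples, ",
      nrow(x$variants), " rare variants in ",
      length(unique(x$variants$gene)), " genes, ",
      ncol(x$common_dosages), " common SNPs\n", sep = "")
  invisible(x)
}

#' Simulate a cGMP functional-assay table for a set of variants
#'
#' Activity relative to wild type is generated as
#' `1 + effect / slope + noise` (clamped at 0) with `slope = 0.9` SD of
#' height per 100% activity, so loss-of-function alleles fall below
#' wild-type activity, strong losses below 0.2, and gain-of-function
#' alleles above 1. The in-silico score is a weak, CADD-like predictor:
#' mostly noise with a small deleteriousness signal.
#'
#' @param variants tibble with `variant_id` and `effect` (true height
#'   effect in SD units); optionally `carrier_heights` (list column)
#'   carried through.
#' @param cfg [simulation_config()].
#' @param slope height SD per 100% activity used by the generative map.
#' @return functional table: `variant_id`, `activity`, `activity_sd`,
#'   `n_replicates`, `insilico_score` plus any input columns.
#' @export
simulate_functional <- function(variants, cfg, slope = 0.9) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(variants) || nrow(variants) == 0) {
    stop("`variants` must be non-empty")
  }
  set.seed(substream_seed(cfg$seed, "functional"))
  k <- nrow(variants)
  activity <- pmax(0, 1 + variants$effect / slope +
                     stats::rnorm(k, 0, cfg$functional_noise_sd))
  variants$activity <- activity
  variants$activity_sd <- stats::runif(k, 0.02, 0.12)
  variants$n_replicates <- 3L
  variants$insilico_score <- pmax(0, 15 - 2 * variants$effect +
                                    stats::rnorm(k, 0, 6))
  variants
}
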