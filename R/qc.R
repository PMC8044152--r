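#' Exact Hardy-Weinberg equilibrium test p-value
#'
#' Conditional exact test of Hardy-Weinberg proportions (Wigginton-style):
#' given the observed allele counts, the p-value is the summed probability of
#' every heterozygote count whose conditional probability does not exceed the
#' observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers).
#' @return p-value in `(0, 1]`; monomorphic sites return 1.
#' @export
#' @examples
#' hwe_exact_p(1, 0, 1)  # 1/3
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("at least one genotype required")
  n_a <- 2L * n_aa + n_Aa          # minor-or-not, symmetry handled below
  n_A <- 2L * n_AA + n_Aa
  if (n_a == 0 || n_A == 0) return(1)
  rare <- min(n_a, n_A)

  # all heterozygote counts with the parity of the rare allele count
  het <- seq(rare %% 2L, rare, by = 2L)
  # log P(n_Aa = h | allele counts) up to a common constant:
  #   log n! - log nAA! - log h! - log naa! + h log 2
  hom_rare <- (rare - het) / 2
  hom_common <- n - het - hom_rare
  logp <- het * log(2) - lgamma(hom_rare + 1) - lgamma(het + 1) -
    lgamma(hom_common + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[het == n_Aa]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

default_sample_qc <- function() {
  list(
    het_rate = c(0.17, 0.21),
    n_non_ref_max = 80000,
    n_singletons_max = 200,
    het_hom_ratio = c(1.3, 1.85),
    call_rate_min = 0.985,
    chip_concordance_min = 0.98,
    # two-sided Ti/Tv window, disabled by default; the one-sided upper rule
    # (drop samples with Ti/Tv > 2.5) is available via `ti_tv_upper_rule`
    ti_tv = NULL,
    ti_tv_upper_rule = FALSE
  )
}

#' Sample-level quality-control cascade for an exome cohort
#'
#' Applies, in order: ancestry inclusion; sex-chromosome aneuploidy
#' exclusion; PCA-corrected heterozygosity window \[0.17, 0.21\]; more than
#' 80,000 non-reference variants; more than 200 singletons; het/hom ratio
#' outside \[1.3, 1.85\]; optional Ti/Tv rules; call rate below 0.985;
#' chip heterozygote concordance below 0.98 (only when the metric is
#' present). All criteria are conjunctive, so the kept set does not depend
#' on the ordering; the attrition table reports removals sequentially in
#' the order above.
#'
#' @param samples tibble with columns `sample_id`, `ancestry_flag`,
#'   `aneuploidy_flag`, `het_rate`, `n_non_ref`, `n_singletons`,
#'   `het_hom_ratio`, `ti_tv`, `call_rate` and optionally
#'   `chip_het_concordance`.
#' @param limits thresholds; see `default_sample_qc()` internals. Any entry
#'   supplied here overrides the default.
#' @return list with `kept` (character ids) and `attrition` (tibble of
#'   criterion, n_removed, n_remaining).
#' @export
filter_samples <- function(samples, limits = list()) {
  limits <- utils::modifyList(default_sample_qc(), limits)
  required <- c("sample_id", "ancestry_flag", "aneuploidy_flag", "het_rate",
                "n_non_ref", "n_singletons", "het_hom_ratio", "call_rate")
  for (f in required) {
    if (!f %in% names(samples)) stop("missing required column: ", f)
    bad <- is.na(samples[[f]])
    if (any(bad)) {
      stop("missing `", f, "` for sample ",
           samples$sample_id[which(bad)[1]])
    }
  }

  fails <- list(
    not_in_ancestry_group = !samples$ancestry_flag,
    sex_chromosome_aneuploidy = samples$aneuploidy_flag,
    het_rate_outside_window =
      samples$het_rate < limits$het_rate[1] |
      samples$het_rate > limits$het_rate[2],
    excess_non_reference_variants = samples$n_non_ref > limits$n_non_ref_max,
    excess_singletons = samples$n_singletons > limits$n_singletons_max,
    het_hom_ratio_outside_window =
      samples$het_hom_ratio < limits$het_hom_ratio[1] |
      samples$het_hom_ratio > limits$het_hom_ratio[2],
    low_call_rate = samples$call_rate < limits$call_rate_min
  )
  if (!is.null(limits$ti_tv)) {
    fails$ti_tv_outside_window <-
      samples$ti_tv < limits$ti_tv[1] | samples$ti_tv > limits$ti_tv[2]
  } else if (isTRUE(limits$ti_tv_upper_rule)) {
    fails$ti_tv_above_upper <- samples$ti_tv > 2.5
  }
  if ("chip_het_concordance" %in% names(samples)) {
    conc <- samples$chip_het_concordance
    fails$low_chip_het_concordance <-
      !is.na(conc) & conc < limits$chip_concordance_min
  }

  keep <- rep(TRUE, nrow(samples))
  attrition <- vector("list", length(fails))
  for (i in seq_along(fails)) {
    removed <- keep & fails[[i]]
    keep <- keep & !fails[[i]]
    attrition[[i]] <- tibble::tibble(
      criterion = names(fails)[i],
      n_removed = sum(removed),
      n_remaining = sum(keep)
    )
  }
  list(
    kept = samples$sample_id[keep],
    attrition = dplyr::bind_rows(attrition)
  )
}

#' Remove close relatives from a kept-sample set
#'
#' Greedily removes, among samples participating in a relatedness pair of
#' degree `max_degree` or closer, the sample with the most such connections
#' (ties broken by sample id, ascending) until no close pair remains.
#'
#' @param kept_ids character vector of sample ids passing sample QC.
#' @param kinship_pairs tibble with columns `id1`, `id2`, `degree`
#'   (1 = parent/offspring or sibling, 2 = second degree, ...).
#' @param max_degree closest retained degree is `max_degree + 1`.
#' @return character vector of ids with related samples removed.
#' @export
remove_related <- function(kept_ids, kinship_pairs, max_degree = 2) {
  if (is.null(kinship_pairs) || nrow(kinship_pairs) == 0) return(kept_ids)
  pairs <- kinship_pairs[kinship_pairs$degree <= max_degree &
                           kinship_pairs$id1 %in% kept_ids &
                           kinship_pairs$id2 %in% kept_ids, , drop = FALSE]
  kept <- kept_ids
  while (nrow(pairs) > 0) {
    conn <- sort(table(c(pairs$id1, pairs$id2)), decreasing = TRUE)
    top <- max(conn)
    victim <- sort(names(conn)[conn == top])[1]
    kept <- setdiff(kept, victim)
    pairs <- pairs[pairs$id1 != victim & pairs$id2 != victim, , drop = FALSE]
  }
  kept
}

#' Variant-level quality-control filter
#'
#' Keeps variants with call rate at least 0.99 and Hardy-Weinberg exact
#' p-value at least 1e-10.
#'
#' @param variants tibble with `variant_id`, `call_rate`, `hwe_p`.
#' @param call_rate_min,hwe_p_min thresholds (kept iff `>=`).
#' @return character vector of kept variant ids.
#' @export
filter_variants <- function(variants, call_rate_min = 0.99,
                            hwe_p_min = 1e-10) {
  keep <- variants$call_rate >= call_rate_min & variants$hwe_p >= hwe_p_min
  variants$variant_id[keep]
}

#' Binomial concordance of a cohort allele count with a reference frequency
#'
#' Two-sided exact binomial test of the observed alternate-allele count
#' against the frequency reported by an external reference panel (e.g.
#' gnomAD non-Finnish Europeans). Variants whose cohort frequency is wildly
#' inflated relative to the reference are flagged for removal. A reference
#' frequency of exactly zero for a covered site is floored at
#' `1 / (2 * ref_panel_size)`; a missing reference frequency is kept and
#' flagged unfilterable.
#'
#' @param cohort_ac,cohort_an observed alternate allele count and total
#'   allele number (vectors recycle).
#' @param ref_af reference allele frequency in `[0, 1]`, `NA` if the variant
#'   is absent from the reference.
#' @param p_cutoff keep iff `p >= p_cutoff`.
#' @param ref_panel_size number of individuals in the reference panel, used
#'   only for the zero-frequency floor.
#' @return tibble with `p`, `keep`, `flag` per variant.
#' @export
external_af_concordance <- function(cohort_ac, cohort_an, ref_af,
                                    p_cutoff = 1e-7,
                                    ref_panel_size = 32000) {
  n <- max(length(cohort_ac), length(cohort_an), length(ref_af))
  cohort_ac <- rep_len(cohort_ac, n)
  cohort_an <- rep_len(cohort_an, n)
  ref_af <- rep_len(ref_af, n)
  if (any(cohort_an <= 0)) stop("cohort_an must be positive")

  p <- numeric(n)
  flag <- character(n)
  floor_af <- 1 / (2 * ref_panel_size)
  for (i in seq_len(n)) {
    if (is.na(ref_af[i])) {
      p[i] <- NA_real_
      flag[i] <- "unfilterable"
      next
    }
    p0 <- max(ref_af[i], floor_af)
    p[i] <- stats::binom.test(cohort_ac[i], cohort_an[i], p = p0)$p.value
    flag[i] <- ""
  }
  tibble::tibble(
    p = p,
    keep = is.na(p) | p >= p_cutoff,
    flag = flag
  )
}

ptv_classes <- c("stop_gained", "frameshift", "splice_acceptor",
                 "splice_donor")

#' Build rare-variant analysis masks
#'
#' Constructs the two consequence masks used for gene-level testing from
#' QC-passed annotated variants: `protein_altering` (predicted protein
#' truncating plus missense) and `ptv` (stop-gained, frameshift, splice
#' acceptor/donor), both restricted to within-cohort minor allele frequency
#' strictly below `maf_cutoff`. Genes whose cumulative mask allele count
#' falls below `min_cum_ac` are dropped from that mask's gene-level tests.
#'
#' @param variants tibble with `variant_id`, `gene`, `consequence_class`,
#'   `cohort_ac`, `cohort_an`.
#' @param maf_cutoff within-cohort minor-allele-frequency cutoff (strict).
#' @param min_cum_ac per-gene cumulative allele count required.
#' @param gene_filter `"cumulative_ac"` counts alleles; `"carriers"` counts
#'   distinct samples carrying any mask allele of the gene (requires
#'   `dosages`) — in a rare-variant regime the two differ only for samples
#'   carrying two alleles.
#' @param dosages optional sample-by-variant dosage matrix (columns named by
#'   `variant_id`), needed only for `gene_filter = "carriers"`.
#' @return list with `masks` (tibble: mask, gene, variant_id) and `gene_ac`
#'   (tibble: mask, gene, cum_ac, gene_stat, kept). Variants of excluded
#'   genes stay in `masks` (set-level tests still use them); gene-level
#'   tests should honour `gene_ac$kept`.
#' @export
build_masks <- function(variants, maf_cutoff = 1e-4, min_cum_ac = 20,
                        gene_filter = c("cumulative_ac", "carriers"),
                        dosages = NULL) {
  gene_filter <- match.arg(gene_filter)
  if (gene_filter == "carriers" && is.null(dosages)) {
    stop("`dosages` is required for gene_filter = \"carriers\"")
  }
  maf <- pmin(variants$cohort_ac, variants$cohort_an - variants$cohort_ac) /
    variants$cohort_an
  is_ptv <- variants$consequence_class %in% ptv_classes
  is_pa <- is_ptv | variants$consequence_class == "missense"
  rare <- maf < maf_cutoff

  mask_tbl <- dplyr::bind_rows(
    tibble::tibble(mask = "protein_altering",
                   gene = variants$gene[is_pa & rare],
                   variant_id = variants$variant_id[is_pa & rare],
                   ac = variants$cohort_ac[is_pa & rare]),
    tibble::tibble(mask = "ptv",
                   gene = variants$gene[is_ptv & rare],
                   variant_id = variants$variant_id[is_ptv & rare],
                   ac = variants$cohort_ac[is_ptv & rare])
  )
  gene_ac <- mask_tbl |>
    dplyr::group_by(.data$mask, .data$gene) |>
    dplyr::summarise(cum_ac = sum(.data$ac), .groups = "drop")
  if (gene_filter == "cumulative_ac") {
    gene_ac$gene_stat <- gene_ac$cum_ac
  } else {
    gene_ac$gene_stat <- vapply(seq_len(nrow(gene_ac)), function(i) {
      ids <- mask_tbl$variant_id[mask_tbl$mask == gene_ac$mask[i] &
                                   mask_tbl$gene == gene_ac$gene[i]]
      ids <- intersect(ids, colnames(dosages))
      if (length(ids) == 0) return(0)
      sum(Matrix::rowSums(dosages[, ids, drop = FALSE]) > 0)
    }, numeric(1))
  }
  gene_ac$kept <- gene_ac$gene_stat >= min_cum_ac
  list(masks = mask_tbl[c("mask", "gene", "variant_id")], gene_ac = gene_ac)
}
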