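#' Infinitesimal-model shrinkage of GWAS marginal effects
#'
#' Closed-form posterior mean weights under the infinitesimal model:
#' within each linkage-disequilibrium block, `w = (M/(N h2) I + D)^-1 b`,
#' where `D` is the block LD (correlation) matrix, `b` the marginal GWAS
#' effects, `N` the GWAS sample size, `h2` the trait heritability captured
#' by the `M` scored variants. The ridge term makes the system
#' well-conditioned for any `h2 > 0`. Blocks are processed independently.
#'
#' @param marginal_betas numeric vector of per-allele marginal effects, in
#'   block order.
#' @param ld_blocks list of square positive semi-definite LD matrices whose
#'   dimensions sum to `length(marginal_betas)`. `NULL` means independent
#'   variants (identity LD).
#' @param n_gwas GWAS sample size.
#' @param h2 heritability attributed to the scored variants, in (0, 1).
#' @param m_snps total number of scored variants `M` (defaults to
#'   `length(marginal_betas)`).
#' @param variant_ids,effect_alleles optional metadata copied into the
#'   output weight table.
#' @return tibble `variant_id`, `effect_allele`, `weight`.
#' @export
ldpred_inf_weights <- function(marginal_betas, ld_blocks = NULL, n_gwas,
                               h2, m_snps = length(marginal_betas),
                               variant_ids = NULL, effect_alleles = NULL) {
  m <- length(marginal_betas)
  stopifnot(h2 > 0, h2 < 1, n_gwas > 0, m >= 1)
  if (is.null(ld_blocks)) ld_blocks <- list(diag(m))
  sizes <- vapply(ld_blocks, nrow, integer(1))
  if (sum(sizes) != m) stop("LD block sizes must sum to length(marginal_betas)")
  ridge <- m_snps / (n_gwas * h2)

  w <- numeric(m)
  offset <- 0
  for (D in ld_blocks) {
    k <- nrow(D)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      stop("LD block is not positive semi-definite")
    }
    idx <- offset + seq_len(k)
    w[idx] <- solve(ridge * diag(k) + D, marginal_betas[idx])
    offset <- offset + k
  }
  tibble::tibble(
    variant_id = variant_ids %||% paste0("snp", seq_len(m)),
    effect_allele = effect_alleles %||% rep("A", m),
    weight = w
  )
}

#' Score samples with a polygenic weight table
#'
#' `PS_i = sum_j w_j d_ij` after reconciling effect alleles to the dosage
#' orientation: when the weight's effect allele matches the cohort's
#' reference (non-counted) allele the weight sign is flipped and the
#' dosage complemented. Missing dosages are imputed to `2 * AF`.
#'
#' @param dosages sample-by-variant numeric matrix with variant ids as
#'   column names (alternate-allele counts in 0..2, `NA` allowed).
#' @param weights tibble from [ldpred_inf_weights()] (columns `variant_id`,
#'   `effect_allele`, `weight`).
#' @param alt_alleles optional named character vector giving the cohort's
#'   counted (alternate) allele per variant; variants whose effect allele
#'   differs are flipped. Default assumes weights are already oriented.
#' @return numeric vector of per-sample scores, named by rownames.
#' @export
score_samples <- function(dosages, weights, alt_alleles = NULL) {
  common <- intersect(weights$variant_id, colnames(dosages))
  if (length(common) == 0) stop("no overlapping variants between dosages and weights")
  w <- weights$weight[match(common, weights$variant_id)]
  D <- as.matrix(dosages[, common, drop = FALSE])
  if (!is.null(alt_alleles)) {
    ea <- weights$effect_allele[match(common, weights$variant_id)]
    flip <- !is.na(alt_alleles[common]) & ea != alt_alleles[common]
    if (any(flip)) {
      D[, flip] <- 2 - D[, flip]
    }
  }
  if (anyNA(D)) {
    af <- colMeans(D, na.rm = TRUE) / 2
    for (j in which(colSums(is.na(D)) > 0)) {
      D[is.na(D[, j]), j] <- 2 * af[j]
    }
  }
  drop(D %*% w)
}

#' Assign samples to polygenic-score quintiles
#'
#' Rank-based partition into `k` equal groups (group 1 = lowest scores).
#' Remainders go to the lower groups; ties are broken by stable input
#' order, so the assignment is deterministic.
#'
#' @param ps numeric score vector.
#' @param k number of groups.
#' @return integer vector in `1..k`; attribute `degenerate` is TRUE when
#'   all scores are equal.
#' @export
assign_quintiles <- function(ps, k = 5) {
  n <- length(ps)
  stopifnot(n >= k)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  ord <- order(ps, seq_len(n))           # stable tie-break
  grp <- integer(n)
  grp[ord] <- rep(seq_len(k), sizes)
  if (length(unique(ps)) == 1) attr(grp, "degenerate") <- TRUE
  grp
}

#' Cochran's Q, I-squared and heterogeneity p-value
#'
#' Fixed-effect inverse-variance meta-analysis across strata:
#' `Q = sum w_i (b_i - b_bar)^2` with `w_i = 1/se_i^2`,
#' `I2 = max(0, (Q - df) / Q)`, `p_het = P(chisq_df >= Q)`.
#'
#' @param betas,ses stratum effect estimates and standard errors.
#' @return list: `beta_fe`, `se_fe`, `Q`, `df`, `i2`, `p_het`.
#' @export
heterogeneity_stats <- function(betas, ses) {
  stopifnot(length(betas) == length(ses), all(ses > 0))
  w <- 1 / ses^2
  beta_fe <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - beta_fe)^2)
  df <- length(betas) - 1
  i2 <- if (Q > 0) max(0, (Q - df) / Q) else 0
  p_het <- if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  list(beta_fe = beta_fe, se_fe = sqrt(1 / sum(w)),
       Q = Q, df = df, i2 = i2, p_het = p_het)
}

#' Carrier height effects stratified by polygenic-score group
#'
#' Within each score quintile and carrier class, contrasts carrier versus
#' non-carrier standardized height by linear regression, then combines the
#' per-quintile effects with a fixed-effect meta-analysis and reports
#' Cochran's Q, I-squared and the heterogeneity p-value per class.
#' Quintiles without carriers of a class are omitted from the meta with a
#' message. A sample in several classes is assigned by the precedence
#' `lof > missense`.
#'
#' @param phenotype tibble with `z_height`, aligned with `quintiles`.
#' @param carrier_class character vector per sample: `"none"`,
#'   `"missense"` or `"lof"`.
#' @param quintiles integer group per sample (from [assign_quintiles()]).
#' @param classes carrier classes to contrast against non-carriers.
#' @return list with `effects` (tibble: class, quintile, effect, se, n
#'   carriers) and `heterogeneity` (tibble: class, Q, df, i2, p_het,
#'   beta_fe, se_fe).
#' @export
stratified_effects <- function(phenotype, carrier_class, quintiles,
                               classes = c("missense", "lof")) {
  stopifnot(length(carrier_class) == nrow(phenotype),
            length(quintiles) == nrow(phenotype))
  eff <- list(); het <- list()
  for (cl in classes) {
    rows <- list()
    for (qt in sort(unique(quintiles))) {
      in_q <- quintiles == qt
      is_carrier <- in_q & carrier_class == cl
      is_ref <- in_q & carrier_class == "none"
      if (sum(is_carrier) == 0) {
        message("quintile ", qt, ": no ", cl, " carriers; omitted")
        next
      }
      y <- phenotype$z_height[is_carrier | is_ref]
      x <- as.integer(is_carrier[is_carrier | is_ref])
      fit <- summary(stats::lm(y ~ x))$coefficients
      rows[[length(rows) + 1]] <- tibble::tibble(
        class = cl, quintile = qt,
        effect = fit["x", "Estimate"], se = fit["x", "Std. Error"],
        n_carriers = sum(is_carrier)
      )
    }
    rows <- dplyr::bind_rows(rows)
    eff[[cl]] <- rows
    if (nrow(rows) >= 1) {
      h <- heterogeneity_stats(rows$effect, rows$se)
      het[[cl]] <- tibble::tibble(class = cl, Q = h$Q, df = h$df,
                                  i2 = h$i2, p_het = h$p_het,
                                  beta_fe = h$beta_fe, se_fe = h$se_fe)
    }
  }
  list(effects = dplyr::bind_rows(eff),
       heterogeneity = dplyr::bind_rows(het))
}

#' ISS odds ratios by carrier class and score quintile
#'
#' Logistic regression of ISS case status on the carrier-class-by-quintile
#' group indicators, with middle-quintile non-carriers as the reference.
#' Groups whose coefficient standard error exceeds `se_cutoff` (fitted on
#' essentially no cases) are removed from the output.
#'
#' @param iss logical case vector.
#' @param carrier_class `"none"`/`"missense"`/`"lof"` per sample; any
#'   non-`"none"` value counts as carrier.
#' @param quintiles integer group per sample.
#' @param reference_quintile quintile forming the non-carrier reference.
#' @param se_cutoff coefficient SE above which a group is dropped.
#' @return tibble: group, carrier, quintile, or, ci_low, ci_high, p,
#'   n, n_cases (reference row has or = 1).
#' @export
iss_or_by_group <- function(iss, carrier_class, quintiles,
                            reference_quintile = 3, se_cutoff = 100) {
  carrier <- ifelse(carrier_class == "none", "noncarrier", "carrier")
  grp <- paste0(carrier, "_q", quintiles)
  ref <- paste0("noncarrier_q", reference_quintile)
  if (!any(grp == ref)) stop("empty reference group")
  if (sum(iss[grp == ref]) == 0) stop("reference group has no cases")
  f <- stats::relevel(factor(grp), ref = ref)
  fit <- stats::glm(iss ~ f, family = stats::binomial())
  cf <- summary(fit)$coefficients
  lev <- levels(f)[-1]
  rows <- tibble::tibble(
    group = c(ref, lev),
    carrier = sub("_q.*", "", c(ref, lev)) == "carrier",
    quintile = as.integer(sub(".*_q", "", c(ref, lev))),
    or = unname(c(1, exp(cf[paste0("f", lev), "Estimate"]))),
    se = unname(c(0, cf[paste0("f", lev), "Std. Error"])),
    p = unname(c(NA, cf[paste0("f", lev), "Pr(>|z|)"])),
    n = as.integer(table(grp)[c(ref, lev)]),
    n_cases = vapply(c(ref, lev), function(g) sum(iss[grp == g]),
                     numeric(1))
  )
  rows$ci_low <- exp(log(rows$or) - 1.96 * rows$se)
  rows$ci_high <- exp(log(rows$or) + 1.96 * rows$se)
  rows[rows$se <= se_cutoff, , drop = FALSE]
}
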