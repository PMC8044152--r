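#' Sex-stratified height normalisation
#'
#' Within each sex stratum, height is residualised on age and the first
#' five genotype principal components by least squares and the residuals
#' are divided by their standard deviation, giving a z-score with mean 0
#' and SD 1 per stratum. Samples with a missing covariate are dropped with
#' a message.
#'
#' @param samples tibble with `sample_id`, `sex` (`"F"`/`"M"`), `age`,
#'   `pc1`..`pc5`, `height_cm`.
#' @return tibble `sample_id`, `sex`, `z_height`.
#' @export
normalize_height <- function(samples) {
  covs <- c("sex", "age", "pc1", "pc2", "pc3", "pc4", "pc5", "height_cm")
  stopifnot(all(c("sample_id", covs) %in% names(samples)))
  complete <- stats::complete.cases(samples[covs])
  if (any(!complete)) {
    message(sum(!complete), " sample(s) dropped for missing covariates")
    samples <- samples[complete, , drop = FALSE]
  }
  out <- lapply(split(samples, samples$sex), function(d) {
    if (nrow(d) < 30) stop("sex stratum with fewer than 30 samples")
    fit <- stats::lm(height_cm ~ age + pc1 + pc2 + pc3 + pc4 + pc5, data = d)
    r <- stats::residuals(fit)
    tibble::tibble(sample_id = d$sample_id, sex = d$sex,
                   z_height = as.numeric(r / stats::sd(r)))
  })
  res <- dplyr::bind_rows(out)
  res[order(match(res$sample_id, samples$sample_id)), ]
}

#' Idiopathic short stature case labels
#'
#' A sample is an ISS case when its standardized height lies strictly below
#' `threshold` standard deviations (default -2).
#'
#' @param z tibble with `z_height` (e.g. from [normalize_height()]).
#' @param threshold z-score cutoff; strict `<`.
#' @return the input with a logical `iss` column.
#' @export
define_iss <- function(z, threshold = -2) {
  z$iss <- z$z_height < threshold
  z
}

annotation_flags <- c("GWAS", "HGMD_SHORT", "HGMD_TALL", "OMIM_SHORT",
                      "OMIM_OVERGROWTH")

#' Gene sets from the five evidence annotations
#'
#' Enumerates all 2^5 = 32 exclusive combinations of the five gene
#' annotations (GWAS, HGMD_SHORT, HGMD_TALL, OMIM_SHORT, OMIM_OVERGROWTH),
#' reporting empty cells, and builds the named analysis sets:
#' * `Set1`: genes carrying all five annotations;
#' * `Set2`: genes carrying the four mutation-catalog annotations but not
#'   GWAS;
#' * `Bidirectional`: genes present in HGMD_SHORT, HGMD_TALL,
#'   OMIM_OVERGROWTH and OMIM_SHORT;
#' * `Tall`: genes in HGMD_TALL or OMIM_OVERGROWTH but in neither short
#'   list;
#' * `Short`: genes in HGMD_SHORT and OMIM_SHORT but in neither tall list.
#'
#' @param annotations tibble with `gene` and logical columns named after
#'   the five flags (missing columns are treated as all-FALSE).
#' @return list with `cells` (tibble: one row per flag combination with
#'   `n_genes` and the member genes) and `sets` (named list of gene
#'   vectors).
#' @export
build_gene_sets <- function(annotations) {
  for (f in annotation_flags) {
    if (!f %in% names(annotations)) annotations[[f]] <- FALSE
  }
  flags <- as.matrix(annotations[annotation_flags]) > 0
  if (any(rowSums(flags) == 0)) {
    stop("every annotated gene must carry at least one flag")
  }
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  names(combos) <- annotation_flags
  key <- apply(flags, 1, function(r) paste(as.integer(r), collapse = ""))
  cells <- tibble::tibble(
    cell = apply(combos, 1, function(r) paste(as.integer(r), collapse = "")),
    combos,
    genes = lapply(apply(combos, 1, function(r)
      paste(as.integer(r), collapse = "")),
      function(k) sort(annotations$gene[key == k]))
  )
  cells$n_genes <- lengths(cells$genes)

  g <- annotations$gene
  sets <- list(
    Set1 = sort(g[rowSums(flags) == 5]),
    Set2 = sort(g[!flags[, "GWAS"] &
                    rowSums(flags[, annotation_flags != "GWAS"]) == 4]),
    Bidirectional = sort(g[flags[, "HGMD_SHORT"] & flags[, "HGMD_TALL"] &
                             flags[, "OMIM_OVERGROWTH"] &
                             flags[, "OMIM_SHORT"]]),
    Tall = sort(g[(flags[, "HGMD_TALL"] | flags[, "OMIM_OVERGROWTH"]) &
                    !flags[, "HGMD_SHORT"] & !flags[, "OMIM_SHORT"]]),
    Short = sort(g[flags[, "HGMD_SHORT"] & flags[, "OMIM_SHORT"] &
                     !flags[, "HGMD_TALL"] & !flags[, "OMIM_OVERGROWTH"]])
  )
  list(cells = cells, sets = sets)
}

burden_score <- function(dosages, variant_ids, carrier_indicator = FALSE) {
  ids <- intersect(variant_ids, colnames(dosages))
  if (length(ids) == 0) return(rep(0, nrow(dosages)))
  s <- as.numeric(Matrix::rowSums(dosages[, ids, drop = FALSE]))
  if (carrier_indicator) s <- as.numeric(s > 0)
  s
}

# Firth-penalised logistic regression (Jeffreys prior); used as fallback
# under complete separation, where plain ML diverges.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * w
    info <- crossprod(X, XW)
    h <- rowSums((X %*% solve(info)) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- solve(info, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  se <- sqrt(diag(solve(crossprod(X, X * w))))
  list(coef = beta, se = se)
}

#' Rare-variant burden association test
#'
#' The per-sample burden score is the sum of alternate-allele dosages over
#' the unit's mask variants (missing genotypes count as zero alternate
#' alleles; a carrier-indicator score is available via
#' `carrier_indicator`). The linear test regresses standardized height on
#' the burden; the logistic test regresses ISS case status on the burden
#' plus optional covariates and reports an odds ratio with Wald confidence
#' interval. Complete separation triggers a Firth-penalised refit, flagged
#' in the output.
#'
#' @param dosages sample-by-variant dosage matrix (dense or `Matrix`),
#'   columns named by variant id, rows aligned with `phenotype`.
#' @param variant_ids mask variant ids for the tested unit.
#' @param unit label for the output row.
#' @param phenotype tibble aligned with `dosages` rows, containing
#'   `z_height` (linear) or `iss` plus any covariate columns (logistic).
#' @param kind `"linear"` or `"logistic"`.
#' @param covariates column names in `phenotype` to adjust for (logistic
#'   only; default sex and age when present).
#' @param mask mask label carried into the output.
#' @param carrier_indicator use a 0/1 any-carrier score instead of the
#'   allele-count sum.
#' @return one-row tibble: unit, mask, test, effect (beta or OR), se,
#'   ci_low, ci_high, p, ac, and case/control allele counts for the
#'   logistic test. `note` records untestable/separation flags.
#' @export
burden_test <- function(dosages, variant_ids, unit, phenotype,
                        kind = c("linear", "logistic"),
                        covariates = NULL, mask = NA_character_,
                        carrier_indicator = FALSE) {
  kind <- match.arg(kind)
  s <- burden_score(dosages, variant_ids, carrier_indicator)
  ac <- sum(burden_score(dosages, variant_ids, FALSE))
  base <- tibble::tibble(
    unit = unit, mask = mask,
    test = paste0("burden_", kind),
    effect = NA_real_, se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p = NA_real_, ac = ac, ac_case = NA_real_, ac_control = NA_real_,
    note = ""
  )
  if (all(s == 0)) {
    base$note <- "untestable: no carriers"
    return(base)
  }

  if (kind == "linear") {
    fit <- stats::lm(phenotype$z_height ~ s)
    cf <- summary(fit)$coefficients["s", ]
    base$effect <- cf[["Estimate"]]
    base$se <- cf[["Std. Error"]]
    base$ci_low <- base$effect - 1.96 * base$se
    base$ci_high <- base$effect + 1.96 * base$se
    base$p <- cf[["Pr(>|t|)"]]
    return(base)
  }

  y <- as.integer(phenotype$iss)
  raw <- burden_score(dosages, variant_ids, FALSE)
  base$ac_case <- sum(raw[y == 1])
  base$ac_control <- sum(raw[y == 0])
  if (is.null(covariates)) {
    covariates <- intersect(c("sex", "age"), names(phenotype))
  }
  X <- stats::model.matrix(
    stats::reformulate(c("s", covariates)),
    data = cbind(phenotype, s = s)
  )
  fit <- suppressWarnings(stats::glm.fit(X, y,
                                         family = stats::binomial()))
  sep <- !fit$converged ||
    any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  if (sep || abs(fit$coefficients["s"]) > 15) {
    ff <- firth_logistic(X, y)
    b <- ff$coef[colnames(X) == "s"]
    se <- ff$se[colnames(X) == "s"]
    base$note <- "separation: Firth fallback"
  } else {
    pr <- fit$fitted.values
    info <- crossprod(X, X * (pr * (1 - pr)))
    se_all <- sqrt(diag(solve(info)))
    b <- fit$coefficients[["s"]]
    se <- se_all[colnames(X) == "s"]
  }
  base$effect <- exp(b)
  base$se <- se
  base$ci_low <- exp(b - 1.96 * se)
  base$ci_high <- exp(b + 1.96 * se)
  base$p <- 2 * stats::pnorm(-abs(b / se))
  base
}

#' Variance-component (SKAT) rare-variant test
#'
#' Computes `Q = r' G W^2 G' r` where `r` are the null-model residuals of
#' the standardized height (intercept-only null: covariates are already
#' absorbed into the z-score), `G` the dosage matrix over the unit's mask
#' variants and `W` per-variant weights (default: `dbeta(MAF, 1, 25)`, the
#' usual rare-variant up-weighting; flat weights via `weights = "flat"`).
#' The p-value comes from the eigenvalues of the projected weighted kernel
#' via [davies_pvalue()].
#'
#' @inheritParams burden_test
#' @param weights `"beta"`, `"flat"`, or a numeric vector aligned with
#'   `variant_ids`.
#' @return one-row tibble with the Q statistic in `effect`, p, and the
#'   p-value method in `note`.
#' @export
skat_test <- function(dosages, variant_ids, unit, phenotype,
                      weights = "beta", mask = NA_character_) {
  ids <- intersect(variant_ids, colnames(dosages))
  base <- tibble::tibble(
    unit = unit, mask = mask, test = "skat",
    effect = NA_real_, se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p = NA_real_, ac = 0, ac_case = NA_real_, ac_control = NA_real_,
    note = ""
  )
  if (length(ids) == 0) {
    base$note <- "untestable: no mask variants in dosage matrix"
    return(base)
  }
  G <- as.matrix(dosages[, ids, drop = FALSE])
  nonzero <- colSums(G) > 0
  G <- G[, nonzero, drop = FALSE]
  if (ncol(G) == 0) {
    base$note <- "untestable: all genotype columns zero"
    return(base)
  }
  base$ac <- sum(G)

  n <- nrow(G)
  if (is.character(weights) && length(weights) == 1) {
    w <- switch(weights,
      beta = {
        maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
        stats::dbeta(maf, 1, 25)
      },
      flat = rep(1, ncol(G)),
      stop("unknown weights: ", weights)
    )
  } else {
    w <- rep_len(as.numeric(weights[nonzero]), ncol(G))
  }

  y <- phenotype$z_height
  r <- y - mean(y)
  sigma2 <- sum(r^2) / (n - 1)
  Zc <- sweep(G, 2, colMeans(G)) * rep(w, each = n)  # centered & weighted
  q <- sum((crossprod(Zc, r))^2)
  lam <- eigen(crossprod(Zc), symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam) * 1e-10] * sigma2
  p <- davies_pvalue(lam, q)
  base$effect <- q
  base$p <- as.numeric(p)
  base$note <- paste0("pvalue_method=", attr(p, "method"))
  base
}

#' Bonferroni significance flags
#'
#' @param results tibble with a `p` column.
#' @param n_tests number of tests adjusted for (`>= 1`).
#' @param alpha family-wise error rate.
#' @return input with `significant` (p < alpha / n_tests) and `p_cutoff`.
#' @export
adjust_significance <- function(results, n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  results$p_cutoff <- alpha / n_tests
  results$significant <- !is.na(results$p) & results$p < results$p_cutoff
  results
}
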