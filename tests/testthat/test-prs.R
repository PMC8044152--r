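test_that("infinitesimal shrinkage matches scalar and 2x2 closed forms", {
  # identity LD: weight = beta / (1 + M/(N h2))
  w <- ldpred_inf_weights(rep(0.12, 100), NULL, n_gwas = 1000, h2 = 0.5,
                          m_snps = 100)
  expect_equal(w$weight, rep(0.10, 100), tolerance = 1e-12)

  # vanishing heritability shrinks weights toward zero
  w0 <- ldpred_inf_weights(rep(0.12, 10), NULL, n_gwas = 1000, h2 = 1e-6)
  expect_true(all(abs(w0$weight) < 1e-3))

  # two perfectly correlated SNPs sharing one signal split the weight
  D <- matrix(c(1, 1, 1, 1), 2)
  b <- c(0.2, 0.2)
  w2 <- ldpred_inf_weights(b, list(D), n_gwas = 1e4, h2 = 0.5, m_snps = 2)
  expect_equal(w2$weight[1], w2$weight[2])
  ridge <- 2 / (1e4 * 0.5)
  manual <- solve(ridge * diag(2) + D, b)
  expect_equal(w2$weight, manual)

  expect_error(ldpred_inf_weights(b, list(matrix(c(1, 2, 2, 1), 2)),
                                  n_gwas = 1e4, h2 = 0.5),
               "positive semi-definite")
  expect_error(ldpred_inf_weights(c(1, 2, 3), list(diag(2)),
                                  n_gwas = 100, h2 = 0.5), "sum")
})

test_that("scoring is a dot product with flips, imputation and linearity", {
  set.seed(21)
  n <- 100; m <- 50
  D <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(NULL, paste0("rs", 1:m)))
  wt <- tibble::tibble(variant_id = paste0("rs", 1:m),
                       effect_allele = "A",
                       weight = rnorm(m))
  expect_equal(score_samples(D, wt), drop(D %*% wt$weight))

  # all-zero weights and the single-SNP identity
  wt0 <- wt; wt0$weight <- 0
  expect_equal(unname(score_samples(D, wt0)), rep(0, n))
  wt1 <- tibble::tibble(variant_id = "rs1", effect_allele = "A", weight = 1)
  expect_equal(score_samples(D, wt1), D[, "rs1"])

  # allele flip: weight applied to the complementary dosage
  alt <- setNames(rep("A", m), colnames(D)); alt["rs1"] <- "G"
  flipped <- score_samples(D, wt, alt_alleles = alt)
  manual <- drop(cbind(2 - D[, 1], D[, -1]) %*% wt$weight)
  expect_equal(flipped, manual)

  # missing dosages impute to twice the allele frequency
  Dna <- D; Dna[1, 1] <- NA
  imp <- score_samples(Dna, wt1)
  expect_equal(imp[1], mean(D[-1, 1]), tolerance = 1e-12)  # 2 * observed AF

  # linearity: score of summed weights = sum of scores
  wa <- wt; wa$weight <- rnorm(m)
  wsum <- wt; wsum$weight <- wt$weight + wa$weight
  expect_equal(score_samples(D, wsum),
               score_samples(D, wt) + score_samples(D, wa))
  expect_error(score_samples(D, tibble::tibble(variant_id = "zz",
                                               effect_allele = "A",
                                               weight = 1)), "overlap")
})

test_that("quintile assignment partitions with remainders to lower groups", {
  q10 <- assign_quintiles(c(10, 1, 9, 2, 8, 3, 7, 4, 6, 5))
  expect_equal(as.vector(table(q10)), rep(2, 5))
  expect_equal(q10[2], 1L)  # lowest score in group 1
  expect_equal(q10[1], 5L)  # highest score in group 5

  q12 <- assign_quintiles(rnorm(12))
  expect_equal(as.vector(table(q12)), c(3, 3, 2, 2, 2))

  # full partition: every sample in exactly one group
  set.seed(22)
  q <- assign_quintiles(rnorm(34120))
  expect_equal(as.vector(table(q)), rep(6824, 5))

  # degenerate ties: stable order, flagged
  qt <- assign_quintiles(rep(1, 10))
  expect_true(attr(qt, "degenerate"))
  expect_equal(as.integer(qt), rep(1:5, each = 2))
})

test_that("heterogeneity statistics match hand arithmetic", {
  h0 <- heterogeneity_stats(c(0.5, 0.5, 0.5), c(1, 2, 3))
  expect_equal(h0$Q, 0)
  expect_equal(h0$i2, 0)
  h <- heterogeneity_stats(c(0, 2), c(1, 1))
  expect_equal(h$Q, 2)
  expect_equal(h$df, 1)
  expect_equal(h$i2, 0.5)
  expect_equal(h$p_het, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(h$beta_fe, 1)
  # I2 floors at zero when Q < df
  expect_equal(heterogeneity_stats(c(0, 0.1), c(1, 1))$i2, 0)
})

test_that("stratified effects recover additivity with I2 near zero", {
  set.seed(23)
  n <- 20000
  ps <- rnorm(n)
  carrier <- sample(c("none", "missense", "lof"), n, replace = TRUE,
                    prob = c(0.95, 0.04, 0.01))
  z <- 0.45 * ps - 0.2 * (carrier == "missense") -
    0.8 * (carrier == "lof") + rnorm(n, 0, 0.9)
  ph <- tibble::tibble(z_height = z)
  qt <- assign_quintiles(ps)
  res <- stratified_effects(ph, carrier, qt)
  expect_equal(nrow(res$effects), 10)  # 2 classes x 5 quintiles
  het <- res$heterogeneity
  expect_lt(het$i2[het$class == "lof"], 0.6)
  expect_gt(het$p_het[het$class == "lof"], 0.01)
  # fixed-effect estimates recover the planted contrasts
  expect_lt(abs(het$beta_fe[het$class == "missense"] - (-0.2)),
            3 * het$se_fe[het$class == "missense"])
  expect_lt(abs(het$beta_fe[het$class == "lof"] - (-0.8)),
            3 * het$se_fe[het$class == "lof"])
  # quintile without carriers is omitted with a message
  carrier2 <- carrier
  carrier2[qt == 5 & carrier2 == "lof"] <- "none"
  expect_message(stratified_effects(ph, carrier2, qt), "omitted")
})

test_that("ISS odds ratios are referenced to mid-score non-carriers", {
  set.seed(24)
  n <- 30000
  ps <- rnorm(n)
  qt <- assign_quintiles(ps)
  carrier <- sample(c("none", "missense"), n, replace = TRUE,
                    prob = c(0.97, 0.03))
  base_p <- 0.02
  # plant 5x odds in the lowest-score non-carriers
  odds_mult <- ifelse(qt == 1 & carrier == "none", 5, 1)
  y <- rbinom(n, 1, plogis(qlogis(base_p) + log(odds_mult))) == 1
  out <- iss_or_by_group(y, carrier, qt)
  ref <- out[out$group == "noncarrier_q3", ]
  expect_equal(ref$or, 1)
  ps1 <- out[out$group == "noncarrier_q1", ]
  expect_lt(ps1$ci_low, 5)
  expect_gt(ps1$ci_high, 5)
  expect_gt(ps1$or, 2)
  # groups are a partition of the cohort
  expect_equal(sum(out$n), n)
  expect_error(iss_or_by_group(rep(FALSE, n), carrier, qt), "no cases")
})

test_that("groups with essentially no cases are removed by the SE rule", {
  set.seed(25)
  n <- 5000
  qt <- assign_quintiles(rnorm(n))
  carrier <- rep("none", n)
  carrier[sample.int(n, 150)] <- "missense"
  y <- rbinom(n, 1, 0.02) == 1
  y[carrier == "missense" & qt == 5] <- FALSE   # zero-case cell
  out <- iss_or_by_group(y, carrier, qt)
  expect_false("carrier_q5" %in% out$group)
})
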