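make_pheno <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("s%05d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = runif(n, 45, 75),
    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n),
    pc5 = rnorm(n)
  )
}

test_that("height normalisation gives unit moments and removes covariates", {
  d <- make_pheno(10000, seed = 2)
  d$height_cm <- ifelse(d$sex == "F", 162, 176) + 0.5 * (d$age - 60) +
    1.2 * d$pc1 + rnorm(nrow(d), 0, 6)
  z <- normalize_height(d)
  for (s in c("F", "M")) {
    expect_equal(mean(z$z_height[z$sex == s]), 0, tolerance = 1e-6)
    expect_equal(sd(z$z_height[z$sex == s]), 1, tolerance = 1e-6)
  }
  # residuals uncorrelated with the adjusted covariates
  expect_lt(abs(cor(z$z_height, d$age[match(z$sample_id, d$sample_id)])),
            0.01)
  expect_lt(abs(cor(z$z_height, d$pc1[match(z$sample_id, d$sample_id)])),
            0.01)
  # with no covariate structure the z equals a plain sex-stratified z-score
  d2 <- make_pheno(2000, seed = 3)
  d2$height_cm <- rnorm(2000, 170, 6)
  z2 <- normalize_height(d2)
  for (s in c("F", "M")) {
    ref <- d2$height_cm[d2$sex == s]
    expect_gt(cor(z2$z_height[z2$sex == s], scale(ref)), 0.99)
  }
  # missing covariates are dropped with a message
  d3 <- make_pheno(200, seed = 4)
  d3$height_cm <- rnorm(200, 170, 6)
  d3$age[1] <- NA
  expect_message(z3 <- normalize_height(d3), "dropped")
  expect_equal(nrow(z3), 199)
})

test_that("ISS labels use a strict threshold and the Gaussian tail rate", {
  z <- tibble::tibble(z_height = c(-2.1, -2.0, -1.9, 0))
  iss <- define_iss(z)
  expect_identical(iss$iss, c(TRUE, FALSE, FALSE, FALSE))
  set.seed(5)
  big <- define_iss(tibble::tibble(z_height = rnorm(34000)))
  expect_equal(mean(big$iss), pnorm(-2), tolerance = 0.15)
})

test_that("gene sets enumerate all 32 intersection cells and named sets", {
  ann <- tibble::tibble(
    gene = c("A", "B", "C", "D", "E"),
    GWAS = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    HGMD_SHORT = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    HGMD_TALL = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    OMIM_SHORT = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    OMIM_OVERGROWTH = c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  gs <- build_gene_sets(ann)
  expect_equal(nrow(gs$cells), 32)
  expect_equal(sum(gs$cells$n_genes), 5)
  expect_equal(gs$sets$Set1, "A")       # all five flags
  expect_equal(gs$sets$Set2, "B")       # four catalog flags, no GWAS
  expect_setequal(gs$sets$Bidirectional, c("A", "B"))
  expect_equal(gs$sets$Tall, "E")       # tall lists only
  expect_equal(gs$sets$Short, "D")      # both short lists, no tall
  expect_equal(gs$sets$Set1, gs$cells$genes[[which(gs$cells$cell == "11111")]])
  expect_error(build_gene_sets(tibble::tibble(gene = "Z", GWAS = FALSE)),
               "at least one flag")
})

test_that("burden equals single-variant regression and a mean contrast", {
  set.seed(6)
  n <- 1500
  G <- matrix(rbinom(n, 1, 0.02), ncol = 1,
              dimnames = list(NULL, "v1"))
  ph <- tibble::tibble(z_height = rnorm(n) - 0.5 * G[, 1])
  b <- burden_test(G, "v1", "u", ph, "linear")
  direct <- summary(lm(ph$z_height ~ G[, 1]))$coefficients
  expect_equal(b$effect, direct[2, "Estimate"])
  expect_equal(b$p, direct[2, "Pr(>|t|)"])
  # 0/1 burden is a two-sample mean contrast
  contrast <- mean(ph$z_height[G[, 1] == 1]) - mean(ph$z_height[G[, 1] == 0])
  expect_equal(b$effect, contrast, tolerance = 1e-10)

  # burden score is invariant to variant ordering
  G3 <- cbind(G, v2 = rbinom(n, 1, 0.01), v3 = rbinom(n, 1, 0.01))
  b12 <- burden_test(G3, c("v1", "v2", "v3"), "u", ph, "linear")
  b21 <- burden_test(G3, c("v3", "v1", "v2"), "u", ph, "linear")
  expect_identical(b12$effect, b21$effect)

  # zero carriers: untestable flag
  empty <- burden_test(G3 * 0, "v1", "u", ph, "linear")
  expect_match(empty$note, "untestable")
})

test_that("logistic burden recovers an odds ratio and reports allele counts", {
  set.seed(7)
  n <- 30000
  g <- rbinom(n, 1, 0.03)
  or_true <- 2.75
  p0 <- 0.02
  logit <- qlogis(p0) + log(or_true) * g
  y <- rbinom(n, 1, plogis(logit))
  ph <- tibble::tibble(iss = y == 1, sex = sample(c("F", "M"), n, TRUE),
                       age = runif(n, 45, 75))
  G <- matrix(g, ncol = 1, dimnames = list(NULL, "v1"))
  b <- burden_test(G, "v1", "u", ph, "logistic")
  expect_lt(b$ci_low, or_true)
  expect_gt(b$ci_high, or_true)
  expect_equal(b$ac_case + b$ac_control, sum(g))
  expect_equal(b$ac_case, sum(g[y == 1]))

  # complete separation triggers the penalised fallback
  ph2 <- tibble::tibble(iss = g == 1, sex = "F", age = 50)
  b2 <- burden_test(G, "v1", "u", ph2, "logistic", covariates = character())
  expect_match(b2$note, "Firth")
  expect_true(is.finite(b2$effect))
})

test_that("SKAT reduces to the marginal score test for one variant", {
  set.seed(8)
  n <- 800
  G <- matrix(rbinom(n, 2, 0.05), ncol = 1, dimnames = list(NULL, "v1"))
  ph <- tibble::tibble(z_height = rnorm(n) - 0.3 * G[, 1])
  sk <- skat_test(G, "v1", "u", ph, weights = "flat")
  # score test: U^2 / (sigma2 * x'Px) ~ chisq_1
  y <- ph$z_height; r <- y - mean(y)
  xc <- G[, 1] - mean(G[, 1])
  stat <- sum(xc * r)^2 / (sum(r^2) / (n - 1) * sum(xc^2))
  p_score <- pchisq(stat, 1, lower.tail = FALSE)
  expect_equal(sk$p, p_score, tolerance = 1e-6)
})

test_that("SKAT p-value matches a permutation oracle on a small case", {
  set.seed(9)
  n <- 200; m <- 5
  G <- matrix(rbinom(n * m, 2, 0.05), ncol = m,
              dimnames = list(NULL, paste0("v", 1:m)))
  y <- rnorm(n) - 0.25 * rowSums(G[, 1:2])
  ph <- tibble::tibble(z_height = y)
  sk <- skat_test(G, colnames(G), "u", ph, weights = "flat")

  # permutation distribution of Q = || Zc' r ||^2 under label shuffling
  r <- y - mean(y)
  Zc <- sweep(G, 2, colMeans(G))
  q_obs <- sum(crossprod(Zc, r)^2)
  n_perm <- 1e6
  block <- 2e4
  exceed <- 0
  done <- 0
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    R <- vapply(seq_len(b), function(i) r[sample.int(n)], numeric(n))
    exceed <- exceed + sum(colSums(crossprod(Zc, R)^2) >= q_obs)
    done <- done + b
  }
  p_perm <- (exceed + 1) / (n_perm + 1)
  se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  # the analytic p is asymptotic (plug-in residual variance), so allow a
  # small finite-sample gap on top of the Monte-Carlo error
  expect_lt(abs(sk$p - p_perm), 3 * se + 0.003)
})

test_that("SKAT statistic is non-negative and drops all-zero columns", {
  set.seed(10)
  G <- cbind(v1 = rbinom(300, 1, 0.05), v2 = 0)
  ph <- tibble::tibble(z_height = rnorm(300))
  sk <- skat_test(G, c("v1", "v2"), "u", ph)
  expect_gte(sk$effect, 0)
  all0 <- skat_test(G * 0, c("v1", "v2"), "u", ph)
  expect_match(all0$note, "untestable")
})

test_that("larger planted effects give smaller median burden p-values", {
  set.seed(12)
  n <- 3000
  meds <- vapply(c(0, -0.3, -0.8), function(b) {
    ps <- vapply(1:20, function(i) {
      G <- matrix(rbinom(n, 1, 0.02), ncol = 1,
                  dimnames = list(NULL, "v1"))
      ph <- tibble::tibble(z_height = rnorm(n) + b * G[, 1])
      burden_test(G, "v1", "u", ph, "linear")$p
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("Bonferroni adjustment flags at the stated boundary", {
  res <- tibble::tibble(p = c(0.009, 0.011, 0.04))
  out5 <- adjust_significance(res, 5)
  expect_identical(out5$significant, c(TRUE, FALSE, FALSE))
  out1 <- adjust_significance(res, 1)
  expect_identical(out1$significant, c(TRUE, TRUE, TRUE))
  expect_error(adjust_significance(res, 0))
})
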