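test_that("relative risk reproduces hand-computed 2x2 values bit-exactly", {
  est <- relative_risk(c(8, 2, 5, 5))
  expect_identical(est$rr, (8 / 10) / (5 / 10))   # 1.6 exactly
  # Katz CI oracle computed independently
  se <- sqrt(1 / 8 - 1 / 10 + 1 / 5 - 1 / 10)
  expect_equal(est$ci_low, exp(log(1.6) - qnorm(0.975) * se))
  expect_equal(est$ci_high, exp(log(1.6) + qnorm(0.975) * se))
  expect_equal(round(est$ci_low, 2), 0.80)
  expect_equal(round(est$ci_high, 2), 3.20)
  expect_false(est$corrected)

  # equal proportions
  expect_identical(relative_risk(c(5, 5, 50, 50))$rr, 1)

  # recomputing from the emitted counts reproduces rr bit-exactly
  est2 <- relative_risk(c(est$a, est$b, est$c, est$d))
  expect_identical(est2$rr, est$rr)

  # degenerate cell: continuity correction, flagged
  z <- relative_risk(c(0, 10, 5, 5))
  expect_true(z$corrected)
  expect_equal(z$rr, (0.5 / 11) / (5.5 / 11))
  expect_error(relative_risk(c(0, 0, 5, 5)), "non-empty")
})

test_that("evidence annotation respects threshold and precedence", {
  table <- tibble::tibble(
    pair_id = c("p1", "p2", "p3"),
    target_gene = c("G1", "G1", "G2"),
    indication = c("I1", "I2", "I1"),
    reached = c("Approved", "PhaseI", "PhaseII")
  )
  evidence <- tibble::tibble(
    gene = c("G1", "G1", "G9"),
    trait = c("T1", "T1", "T9"),
    class = c("BEST", "GWAS", "OMIM_unidirectional")
  )
  similarity <- tidyr::expand_grid(indication = c("I1", "I2"),
                                   trait = c("T1", "T9"))
  similarity$value <- c(0.9, 0.1, 0.5, 0.2)  # I1/T1 high, I2/T1 mid

  expect_message(
    ann <- annotate_evidence(table, evidence, similarity, 0.83),
    "ignored")
  # BEST beats GWAS on the same gene/trait
  expect_equal(ann$evidence_class, c("BEST", "none", "none"))
  # lower threshold picks up the mid-similarity pair
  ann2 <- suppressMessages(
    annotate_evidence(table, evidence, similarity, 0.4))
  expect_equal(ann2$evidence_class[2], "BEST")
  # threshold 1.0 with all similarities < 1: nothing supported
  ann3 <- suppressMessages(
    annotate_evidence(table, evidence, similarity, 1.0))
  expect_true(all(ann3$evidence_class == "none"))
  # precedence is configurable
  ann4 <- suppressMessages(
    annotate_evidence(table, evidence, similarity, 0.4,
                      precedence = c("GWAS", "BEST", "OMIM_unidirectional")))
  expect_equal(ann4$evidence_class[1], "GWAS")
})

test_that("transition counts denominate on the source phase", {
  ann <- tibble::tibble(
    reached = c("PhaseI", "PhaseII", "PhaseIII", "Approved", "Approved"),
    evidence_class = c("BEST", "BEST", "none", "none", "BEST")
  )
  cnt <- transition_counts(ann, "PhaseI", "PhaseII")
  expect_identical(cnt, c(a = 2L, b = 1L, c = 2L, d = 0L))
  cnt2 <- transition_counts(ann, "PhaseII", "Approved")
  expect_identical(cnt2, c(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_equal(sum(cnt2), 4L)  # four pairs reached PhaseII
  expect_equal(sum(cnt), nrow(ann))
})

test_that("threshold sweep recovers the planted enrichment region", {
  cfg <- small_cfg(seed = 2, n_pairs = 20000L, trial_rr = 4)
  cs <- simulate_catalog(cfg)
  tr <- simulate_trials(cfg, cs$best_genes$gene)
  sw <- suppressMessages(sweep_thresholds(
    tr$table, tr$evidence, tr$similarity,
    grid = seq(0.5, 0.95, by = 0.05)))
  # the planted enrichment applies above similarity 0.8
  expect_gte(sw$argmax$threshold, 0.7)
  est <- sw$estimates
  at_plant <- est[abs(est$threshold - 0.8) < 1e-9 & est$from == "PhaseI" &
                    est$to == "Approved", ]
  expect_gt(at_plant$ci_high, 4 * 0.9)
  expect_lt(at_plant$ci_low, 4 * 1.1)

  # single-point grid
  sw1 <- suppressMessages(sweep_thresholds(tr$table, tr$evidence,
                                           tr$similarity, grid = 0.8))
  expect_equal(unique(sw1$estimates$threshold), 0.8)
})

test_that("null planting gives relative risks near one", {
  cfg <- small_cfg(seed = 3, n_pairs = 20000L, trial_rr = 1)
  cs <- simulate_catalog(cfg)
  tr <- simulate_trials(cfg, cs$best_genes$gene)
  ann <- annotate_evidence(tr$table, tr$evidence, tr$similarity, 0.8)
  for (trn in list(c("PhaseI", "PhaseII"), c("PhaseI", "Approved"))) {
    est <- relative_risk(transition_counts(ann, trn[1], trn[2]))
    expect_gt(est$ci_high, 1)
    expect_lt(est$ci_low, 1)
  }
})

test_that("sensitivity analyses exclude and stratify as specified", {
  cfg <- small_cfg(seed = 4, n_pairs = 15000L, trial_rr = 4)
  cs <- simulate_catalog(cfg)
  tr <- simulate_trials(cfg, cs$best_genes$gene)

  base <- suppressMessages(sensitivity_analysis(
    tr$table, tr$evidence, tr$similarity, 0.8,
    mode = "exclude_categories", categories = character()))
  direct <- relative_risk(transition_counts(
    suppressMessages(annotate_evidence(tr$table, tr$evidence,
                                       tr$similarity, 0.8)),
    "PhaseI", "Approved"))
  expect_equal(base$rr[base$from == "PhaseI" & base$to == "Approved"],
               direct$rr)

  # excluding every category that holds planted signal collapses RR
  all_cats <- unique(tr$evidence$category[tr$evidence$class == "BEST"])
  excl <- suppressMessages(sensitivity_analysis(
    tr$table, tr$evidence, tr$similarity, 0.8,
    mode = "exclude_categories", categories = all_cats))
  if (nrow(excl) > 0) {
    rr_excl <- excl$rr[excl$from == "PhaseI" & excl$to == "Approved"]
    if (length(rr_excl) == 1) expect_lt(abs(log(rr_excl)), abs(log(4)) / 2)
  } else {
    # removing every supported category leaves no supported pairs at all
    expect_equal(nrow(excl), 0)
  }

  # stratified mode skips categories with <= 5 supported genes
  msgs <- capture_messages(
    strat <- sensitivity_analysis(tr$table, tr$evidence, tr$similarity, 0.8,
                                  mode = "stratify", min_genes = 5))
  expect_true(any(grepl("skipped", msgs)))
  expect_error(sensitivity_analysis(
    tr$table, tr$evidence, tr$similarity, 0.8,
    mode = "exclude_categories",
    categories = unique(tr$evidence$category)), "all evidence excluded")
})
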