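phase_levels <- c("PhaseI", "PhaseII", "PhaseIII", "Approved")

phase_rank <- function(x) {
  r <- match(x, phase_levels)
  if (anyNA(r)) stop("unknown phase label: ",
                     paste(unique(x[is.na(r)]), collapse = ", "))
  r
}

sim_lookup <- function(similarity) {
  # long tibble (indication, trait, value) -> fast keyed lookup
  stopifnot(all(c("indication", "trait", "value") %in% names(similarity)))
  stats::setNames(similarity$value,
                  paste(similarity$indication, similarity$trait, sep = "\r"))
}

#' Annotate target-indication pairs with their best genetic evidence
#'
#' A pair is supported by evidence class C when its target gene carries
#' class-C evidence for some trait whose semantic similarity to the pair's
#' indication strictly exceeds `threshold`. When several classes apply the
#' first one in `precedence` wins.
#'
#' @param table tibble of pairs: `target_gene`, `indication`, `reached`
#'   (one of PhaseI, PhaseII, PhaseIII, Approved), optionally `category`.
#' @param evidence tibble: `gene`, `trait`, `class` (one of `"BEST"`,
#'   `"OMIM_unidirectional"`, `"GWAS"`), optionally `category`.
#' @param similarity long tibble: `indication`, `trait`, `value` in `[0,1]`.
#' @param threshold similarity cutoff (support requires `value > threshold`).
#' @param precedence class precedence, best first.
#' @return `table` with an `evidence_class` column (`"none"` when
#'   unsupported). Evidence rows whose gene never appears as a target are
#'   ignored with a message.
#' @export
annotate_evidence <- function(table, evidence, similarity, threshold,
                              precedence = c("BEST", "OMIM_unidirectional",
                                             "GWAS")) {
  stopifnot(threshold >= 0, threshold <= 1)
  unknown <- setdiff(unique(evidence$gene), unique(table$target_gene))
  if (length(unknown) > 0) {
    message(length(unknown),
            " evidence gene(s) absent from the target table; ignored")
    evidence <- evidence[!evidence$gene %in% unknown, , drop = FALSE]
  }
  lut <- sim_lookup(similarity)

  # candidate (pair, evidence) joins restricted to matching gene
  cand <- dplyr::inner_join(
    tibble::tibble(pair_row = seq_len(nrow(table)),
                   gene = table$target_gene,
                   indication = table$indication),
    evidence, by = "gene", relationship = "many-to-many"
  )
  cls <- rep("none", nrow(table))
  if (nrow(cand) > 0) {
    sim <- unname(lut[paste(cand$indication, cand$trait, sep = "\r")])
    if (anyNA(sim)) {
      stop("similarity undefined for some (indication, trait) pair, e.g. ",
           cand$indication[which(is.na(sim))[1]], " / ",
           cand$trait[which(is.na(sim))[1]])
    }
    hit <- cand[sim > threshold, , drop = FALSE]
    if (nrow(hit) > 0) {
      rank <- match(hit$class, precedence)
      best <- tapply(rank, hit$pair_row, min)
      cls[as.integer(names(best))] <- precedence[best]
    }
  }
  table$evidence_class <- cls
  table
}

#' 2x2 phase-transition counts for supported vs unsupported pairs
#'
#' Among pairs that reached phase `from` or beyond, cross-tabulates genetic
#' support against reaching phase `to` or beyond.
#'
#' @param annotated output of [annotate_evidence()].
#' @param from,to phase labels defining the transition.
#' @param supported_classes evidence classes counted as "supported".
#' @return named vector `c(a, b, c, d)`: supported successes, supported
#'   failures, unsupported successes, unsupported failures.
#' @export
transition_counts <- function(annotated, from, to,
                              supported_classes = "BEST") {
  r <- phase_rank(annotated$reached)
  at_risk <- r >= phase_rank(from)
  success <- r >= phase_rank(to)
  exposed <- annotated$evidence_class %in% supported_classes
  c(a = sum(at_risk & exposed & success),
    b = sum(at_risk & exposed & !success),
    c = sum(at_risk & !exposed & success),
    d = sum(at_risk & !exposed & !success))
}

#' Relative risk (and odds ratio) from a 2x2 table
#'
#' `rr = (a/(a+b)) / (c/(c+d))` with a 95% confidence interval by the Katz
#' log method, `exp(log rr +/- 1.96 * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#' When `a = 0` or `c = 0` a 0.5 continuity correction is added to all four
#' cells and the estimate is flagged. The odds ratio (`ad/bc`, Woolf CI) is
#' reported alongside since both derive from the same counts.
#'
#' @param counts numeric of length 4 (`a`, `b`, `c`, `d`) or a 2x2 matrix
#'   (rows = exposure, columns = success/failure).
#' @param conf confidence level.
#' @return one-row tibble: counts, `rr`, `ci_low`, `ci_high`, `or`,
#'   `or_ci_low`, `or_ci_high`, `corrected`.
#' @export
#' @examples
#' relative_risk(c(8, 2, 5, 5))  # rr = 1.6
relative_risk <- function(counts, conf = 0.95) {
  if (is.matrix(counts)) counts <- as.numeric(t(counts))
  stopifnot(length(counts) == 4, all(counts >= 0))
  a <- counts[1]; b <- counts[2]; cc <- counts[3]; d <- counts[4]
  if (a + b == 0 || cc + d == 0) {
    stop("both exposure groups must be non-empty (a+b > 0 and c+d > 0)")
  }
  corrected <- (a == 0 || cc == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rr <- (a / (a + b)) / (cc / (cc + d))
  se_log_rr <- sqrt(1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + d))
  or <- (a * d) / (b * cc)
  se_log_or <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  tibble::tibble(
    a = counts[1], b = counts[2], c = counts[3], d = counts[4],
    rr = rr,
    ci_low = exp(log(rr) - z * se_log_rr),
    ci_high = exp(log(rr) + z * se_log_rr),
    or = or,
    or_ci_low = exp(log(or) - z * se_log_or),
    or_ci_high = exp(log(or) + z * se_log_or),
    corrected = corrected
  )
}

default_transitions <- function() {
  list(c("PhaseI", "PhaseII"), c("PhaseII", "PhaseIII"),
       c("PhaseIII", "Approved"), c("PhaseI", "Approved"))
}

#' Sweep similarity thresholds and estimate per-transition relative risks
#'
#' Re-annotates the pair table at every threshold on `grid` and estimates
#' the relative risk of each phase transition for supported versus
#' unsupported pairs. Reports the threshold maximising the Phase I ->
#' Approval relative risk (ties resolved toward the smallest threshold).
#' Thresholds with an empty supported group are omitted with a message.
#'
#' @inheritParams annotate_evidence
#' @param grid similarity thresholds to evaluate.
#' @param supported_classes evidence classes treated as support.
#' @param transitions list of `c(from, to)` phase pairs.
#' @return list with `estimates` (tibble: threshold, from, to, counts, rr,
#'   CI) and `argmax` (list: threshold, rr for Phase I -> Approval).
#' @export
sweep_thresholds <- function(table, evidence, similarity,
                             grid = seq(0, 1, by = 0.01),
                             supported_classes = "BEST",
                             transitions = default_transitions(),
                             precedence = c("BEST", "OMIM_unidirectional",
                                            "GWAS")) {
  if (length(grid) == 0) stop("`grid` must be non-empty")
  out <- vector("list", length(grid) * length(transitions))
  k <- 0
  for (thr in grid) {
    ann <- annotate_evidence(table, evidence, similarity, thr, precedence)
    for (tr in transitions) {
      cnt <- transition_counts(ann, tr[1], tr[2], supported_classes)
      if (cnt["a"] + cnt["b"] == 0) {
        message("threshold ", thr, ": no supported pairs at ", tr[1],
                "; estimate omitted")
        next
      }
      est <- relative_risk(cnt)
      est$threshold <- thr
      est$from <- tr[1]
      est$to <- tr[2]
      k <- k + 1
      out[[k]] <- est
    }
  }
  estimates <- dplyr::bind_rows(out[seq_len(k)])
  argmax <- NULL
  main <- estimates[estimates$from == "PhaseI" & estimates$to == "Approved", ]
  if (nrow(main) > 0) {
    i <- order(-main$rr, main$threshold)[1]
    argmax <- list(threshold = main$threshold[i], rr = main$rr[i])
  }
  list(estimates = estimates, argmax = argmax)
}

#' Category-based sensitivity analyses for the approval-odds estimate
#'
#' `exclude` mode removes the genetic-evidence annotations belonging to the
#' named phenotype categories and recomputes the transition estimates, so a
#' signal driven by one disease area collapses toward 1. `stratify` mode
#' estimates each category separately, skipping categories with 5 or fewer
#' distinct supported (BEST) genes.
#'
#' @inheritParams sweep_thresholds
#' @param threshold single similarity threshold to analyse at.
#' @param mode `"exclude_categories"` or `"stratify"`.
#' @param categories phenotype categories (matched against
#'   `evidence$category`).
#' @param min_genes minimum distinct BEST genes for a stratified category.
#' @return tibble of estimates with `mode` and `category` columns.
#' @export
sensitivity_analysis <- function(table, evidence, similarity, threshold,
                                 mode = c("exclude_categories", "stratify"),
                                 categories = character(),
                                 supported_classes = "BEST",
                                 transitions = default_transitions(),
                                 min_genes = 5) {
  mode <- match.arg(mode)
  if (!"category" %in% names(evidence)) {
    stop("evidence table needs a `category` column for sensitivity analyses")
  }
  run <- function(ev, label) {
    ann <- annotate_evidence(table, ev, similarity, threshold)
    out <- lapply(transitions, function(tr) {
      cnt <- transition_counts(ann, tr[1], tr[2], supported_classes)
      if (cnt["a"] + cnt["b"] == 0) return(NULL)
      est <- relative_risk(cnt)
      est$from <- tr[1]; est$to <- tr[2]
      est
    })
    est <- dplyr::bind_rows(out)
    if (nrow(est) > 0) est$category <- label
    est
  }
  if (mode == "exclude_categories") {
    ev <- evidence[!evidence$category %in% categories, , drop = FALSE]
    if (nrow(ev) == 0) stop("all evidence excluded")
    res <- run(ev, paste0("all_minus_", paste(categories, collapse = "+")))
    res$mode <- "exclude_categories"
    return(res)
  }
  cats <- if (length(categories) > 0) categories else
    sort(unique(evidence$category))
  res <- lapply(cats, function(cat) {
    ev <- evidence[evidence$category == cat, , drop = FALSE]
    n_best <- length(unique(ev$gene[ev$class %in% supported_classes]))
    if (n_best <= min_genes) {
      message("category ", cat, ": only ", n_best,
              " supported genes; skipped")
      return(NULL)
    }
    run(ev, cat)
  })
  res <- dplyr::bind_rows(res)
  if (nrow(res) > 0) res$mode <- "stratify"
  res
}
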