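#' Bin a cGMP activity readout
#'
#' Activity is cGMP production relative to wild type (1.0 = wild-type
#' level). Bins: `low` strictly below 0.2, `supranormal` strictly above
#' 1.0, `intermediate` otherwise — exhaustive and exclusive over
#' `[0, Inf)`; the boundaries 0.2 and 1.0 are intermediate.
#'
#' @param activity numeric vector, `>= 0`.
#' @return character vector of bins.
#' @export
#' @examples
#' bin_activity(c(0.19, 0.2, 0.7, 1, 1.05))
bin_activity <- function(activity) {
  if (any(is.na(activity)) || any(activity < 0)) {
    stop("activity must be non-negative")
  }
  ifelse(activity < 0.2, "low",
         ifelse(activity > 1, "supranormal", "intermediate"))
}

unroll_carriers <- function(table, per = c("carrier", "variant")) {
  per <- match.arg(per)
  stopifnot(all(c("variant_id", "activity", "carrier_heights") %in%
                  names(table)))
  if (per == "variant") {
    z <- vapply(table$carrier_heights, function(h) mean(unlist(h)),
                numeric(1))
    keep <- !is.na(z)
    return(tibble::tibble(variant_id = table$variant_id[keep],
                          activity = table$activity[keep], z = z[keep]))
  }
  n <- lengths(table$carrier_heights)
  tibble::tibble(
    variant_id = rep(table$variant_id, n),
    activity = rep(table$activity, n),
    z = unlist(table$carrier_heights)
  )
}

#' Regression of carrier height on variant functional activity
#'
#' Fits standardized carrier height against cGMP activity (activity unit
#' 1.0 = 100% of wild type, so the slope reads as SD of height per 100%
#' activity change). By default each carrier is one observation; `per =
#' "variant"` collapses to per-variant mean heights.
#'
#' @param table functional table: `variant_id`, `activity`, and
#'   `carrier_heights` (list column of carrier z-scores).
#' @param per observation unit.
#' @return list: `slope`, `se`, `ci_low`, `ci_high`, `p`, `r2`, `n_obs`.
#' @export
activity_regression <- function(table, per = c("carrier", "variant")) {
  d <- unroll_carriers(table, per)
  if (length(unique(d$variant_id)) < 3) {
    stop("need at least 3 variants with carriers")
  }
  if (stats::sd(d$activity) == 0) stop("activity is constant")
  fit <- stats::lm(z ~ activity, data = d)
  sm <- summary(fit)
  cf <- sm$coefficients["activity", ]
  list(slope = cf[["Estimate"]], se = cf[["Std. Error"]],
       ci_low = cf[["Estimate"]] - 1.96 * cf[["Std. Error"]],
       ci_high = cf[["Estimate"]] + 1.96 * cf[["Std. Error"]],
       p = cf[["Pr(>|t|)"]], r2 = sm$r.squared, n_obs = nrow(d))
}

#' Compare the functional readout with an in-silico deleteriousness score
#'
#' Fits carrier height separately on the measured activity and on the
#' in-silico score (CADD-like), reporting slope, p and R-squared for each
#' and flagging the better height classifier (higher R-squared). Variants
#' missing either predictor are excluded pairwise with a message.
#'
#' @param table functional table with `activity`, `insilico_score` and
#'   `carrier_heights`.
#' @inheritParams activity_regression
#' @return tibble with one row per predictor (`slope`, `se`, `p`, `r2`,
#'   `best`).
#' @export
compare_predictors <- function(table, per = c("carrier", "variant")) {
  per <- match.arg(per)
  miss <- is.na(table$activity) | is.na(table$insilico_score)
  if (any(miss)) {
    message(sum(miss), " variant(s) missing a predictor; excluded")
    table <- table[!miss, , drop = FALSE]
  }
  fit_one <- function(col) {
    d <- unroll_carriers(table, per)
    d$x <- table[[col]][match(d$variant_id, table$variant_id)]
    sm <- summary(stats::lm(z ~ x, data = d))
    tibble::tibble(predictor = col, slope = sm$coefficients["x", "Estimate"],
                   se = sm$coefficients["x", "Std. Error"],
                   p = sm$coefficients["x", "Pr(>|t|)"],
                   r2 = sm$r.squared)
  }
  out <- dplyr::bind_rows(fit_one("activity"), fit_one("insilico_score"))
  out$best <- out$r2 == max(out$r2)
  out
}
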