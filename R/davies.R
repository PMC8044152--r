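#' Tail probability of a positively weighted sum of chi-square(1) variables
#'
#' Computes `P(Q >= q)` where `Q = sum_i lambda_i * chisq_1` via numerical
#' inversion of the characteristic function (Davies/Imhof construction),
#' with a moment-matching fallback ([liu_pvalue()]) when the quadrature does
#' not converge. This is the numerical backend for [skat_test()].
#'
#' @param lambdas positive eigenvalue weights (non-positive entries are an
#'   error; near-zero eigenvalues should be dropped by the caller).
#' @param q observed statistic, `q >= 0`.
#' @param abs_tol absolute tolerance passed to the quadrature.
#'
#' @return p-value in `(0, 1]` with attribute `method` (`"davies"` or
#'   `"liu"`).
#' @export
#' @examples
#' davies_pvalue(1, qchisq(0.95, df = 1))   # ~0.05
#' davies_pvalue(c(1, 1), qchisq(0.95, 2))  # ~0.05
davies_pvalue <- function(lambdas, q, abs_tol = 1e-9) {
  if (length(lambdas) == 0) stop("`lambdas` must be non-empty")
  if (any(!is.finite(lambdas)) || any(lambdas <= 0)) {
    stop("`lambdas` must be finite and positive")
  }
  if (!is.finite(q) || q < 0) stop("`q` must be a non-negative number")
  if (q == 0) {
    return(structure(1, method = "davies"))
  }

  # Imhof's inversion formula:
  #   P(Q > q) = 1/2 + (1/pi) * Int_0^Inf sin(theta(u)) / (u * rho(u)) du
  # theta(u) = 0.5 * sum(atan(lambda_i u)) - 0.5 * q * u
  # rho(u)   = prod((1 + lambda_i^2 u^2))^(1/4)
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambdas, u))) - 0.5 * q * u
    log_rho <- 0.25 * colSums(log1p(outer(lambdas^2, u^2)))
    sin(theta) / (u * exp(log_rho))
  }

  p <- tryCatch({
    int <- stats::integrate(integrand, lower = 0, upper = Inf,
                            abs.tol = abs_tol, rel.tol = abs_tol^0.5,
                            subdivisions = 2000L, stop.on.error = TRUE)
    0.5 + int$value / pi
  }, error = function(e) NA_real_)

  method <- "davies"
  if (is.na(p) || p < -1e-6 || p > 1 + 1e-6) {
    p <- liu_pvalue(lambdas, q)
    method <- "liu"
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(p, method = method)
}

#' Liu moment-matching approximation to the chi-square mixture tail
#'
#' Matches the first cumulants and the skewness/kurtosis trade-off of
#' `sum lambda_i chisq_1` to a (possibly non-central) chi-square and reads
#' off the tail. Used as a fallback by [davies_pvalue()].
#'
#' @inheritParams davies_pvalue
#' @return approximate p-value in `(0, 1]`.
#' @export
liu_pvalue <- function(lambdas, q) {
  c1 <- sum(lambdas)
  c2 <- sum(lambdas^2)
  c3 <- sum(lambdas^3)
  c4 <- sum(lambdas^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  mu_q <- c1
  sigma_q <- sqrt(2 * c2)
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    df <- c2^3 / c3^2
  }
  mu_x <- df + delta
  sigma_x <- sqrt(2) * a
  t_star <- (q - mu_q) / sigma_q
  p <- stats::pchisq(t_star * sigma_x + mu_x, df = df, ncp = delta,
                     lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}
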