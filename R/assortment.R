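#' Estimate gamete frequencies from karyotype-class counts
#'
#' For a population segregating 2n = 8 / 9 / 10 karyotypes (zero, one or two
#' additional large chromosomes), the frequency of n = 4 gametes (one large
#' chromosome) is estimated by allele counting: each 2n = 8 specimen
#' contributes two n = 4 gametes, each 2n = 9 one of each kind. This is the
#' maximum-likelihood estimator under the trinomial (p^2, 2pq, q^2) model.
#' 'Abnormal' karyotypes must be excluded by the caller before estimation.
#'
#' @param c8,c9,c10 non-negative specimen counts for the 2n = 8, 9 and 10
#'   classes.
#' @return list with `p` (frequency of n = 4 gametes), `q = 1 - p`, and
#'   `n_specimens`.
#' @examples
#' estimate_gamete_freqs(16, 77, 36)  # p = 0.422
#' @export
estimate_gamete_freqs <- function(c8, c9, c10) {
  counts <- c(c8, c9, c10)
  if (anyNA(counts) || any(counts < 0)) stop_karyo("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop_karyo("cannot estimate gamete frequencies from all-zero counts")
  p <- (2 * c8 + c9) / (2 * n)
  list(p = p, q = 1 - p, n_specimens = n)
}

#' Expected karyotype-class frequencies under independent assortment
#'
#' With gamete frequencies p (n = 4) and q (n = 5) and random union of
#' gametes, the offspring classes 2n = 8, 9, 10 occur at Hardy-Weinberg-style
#' proportions p^2, 2pq, q^2.
#'
#' @param g output of [estimate_gamete_freqs()], or a single numeric p.
#' @return named numeric vector `c(p8 = p^2, p9 = 2pq, p10 = q^2)`, summing
#'   to 1.
#' @export
expected_karyotype_freqs <- function(g) {
  p <- if (is.list(g)) g$p else g
  check_number(p, "p", lower = 0, upper = 1)
  q <- 1 - p
  c(p8 = p^2, p9 = 2 * p * q, p10 = q^2)
}

#' Chi-squared test for independent assortment of karyotype classes
#'
#' Estimates the gamete frequency p from the observed 2n = 8/9/10 counts,
#' forms expected counts N * (p^2, 2pq, q^2), and computes the Pearson
#' chi-squared statistic without continuity correction. Because one parameter
#' is estimated from the data, the reference distribution has
#' 3 - 1 - 1 = 1 degree of freedom.
#'
#' @inheritParams estimate_gamete_freqs
#' @return an object of class `htest` with `statistic`, `parameter` (df),
#'   `p.value`, `observed`, `expected` and `estimate` (p, q) components.
#' @examples
#' assortment_chisq(16, 77, 36)  # X-squared = 6.43, p = 0.011
#' @export
assortment_chisq <- function(c8, c9, c10) {
  g <- estimate_gamete_freqs(c8, c9, c10)
  probs <- expected_karyotype_freqs(g)
  obs <- c(p8 = c8, p9 = c9, p10 = c10)
  expected <- g$n_specimens * probs
  if (any(expected == 0 & obs > 0)) {
    stop_karyo("observed count in a class with zero expected frequency; test degenerate")
  }
  keep <- expected > 0
  stat <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  df <- 1
  structure(list(
    statistic = c("X-squared" = stat),
    parameter = c(df = df),
    p.value = stats::pchisq(stat, df, lower.tail = FALSE),
    estimate = c(p = g$p, q = g$q),
    observed = obs,
    expected = expected,
    method = "Chi-squared test for independent assortment of large chromosomes",
    data.name = sprintf("counts (2n=8: %d, 2n=9: %d, 2n=10: %d)", c8, c9, c10)),
    class = "htest")
}

#' Fisher's combined probability test
#'
#' Combines independent p-values with the statistic -2 * sum(log(p)). Under
#' the `standard` convention the statistic is referred to a chi-squared
#' distribution with 2k degrees of freedom (k = number of p-values); the
#' `fixed2` convention uses 2 degrees of freedom regardless of k, a
#' convention found in some published karyotype analyses and provided here so
#' that such results can be reproduced exactly. With a single p-value the two
#' conventions coincide and return the input p unchanged.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param convention `"standard"` (df = 2k) or `"fixed2"` (df = 2).
#' @return object of class `htest` with `statistic`, `parameter`, `p.value`.
#' @examples
#' fisher_combined(c(0.011, 0.141), convention = "fixed2")  # X2 = 12.94
#' @export
fisher_combined <- function(p_values, convention = c("standard", "fixed2")) {
  convention <- match.arg(convention)
  if (length(p_values) == 0L || anyNA(p_values)) stop_karyo("p_values must be non-missing")
  if (any(p_values <= 0)) stop_karyo("p-value of 0 gives an infinite combined statistic")
  if (any(p_values > 1)) stop_karyo("p-values must lie in (0, 1]")
  stat <- -2 * sum(log(p_values))
  df <- if (convention == "standard") 2 * length(p_values) else 2
  structure(list(
    statistic = c("X-squared" = stat),
    parameter = c(df = df),
    p.value = stats::pchisq(stat, df, lower.tail = FALSE),
    method = sprintf("Fisher's combined probability test (%s convention, df = %d)",
                     convention, df),
    data.name = paste(length(p_values), "p-values")),
    class = "htest")
}
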