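#' Gamete distribution of a parental karyotype
#'
#' Under fair meiosis a 2n = 8 parent (two large chromosomes) produces only
#' n = 4 gametes, a 2n = 9 parent produces n = 4 and n = 5 gametes at 50:50,
#' and a 2n = 10 parent only n = 5 gametes.
#'
#' @param two_n parental diploid number, one of 8, 9, 10.
#' @return named numeric vector `c(n4 = ..., n5 = ...)` summing to 1.
#' @export
gamete_dist <- function(two_n) {
  if (!two_n %in% c(8, 9, 10)) stop_karyo("parental karyotype must be 2n = 8, 9 or 10")
  switch(as.character(two_n),
         "8"  = c(n4 = 1,   n5 = 0),
         "9"  = c(n4 = 0.5, n5 = 0.5),
         "10" = c(n4 = 0,   n5 = 1))
}

#' Mendelian offspring-class distribution of a cross
#'
#' The offspring's number of large chromosomes is the sum of the two parental
#' gametes' contributions, so the offspring distribution is the convolution of
#' the two gamete distributions. The result is symmetric in the parents.
#'
#' @param parent1,parent2 parental diploid numbers (8, 9 or 10).
#' @return named numeric vector `c(p8, p9, p10)` summing to 1.
#' @examples
#' offspring_dist(9, 9)   # 0.25, 0.50, 0.25
#' offspring_dist(9, 8)   # 0.50, 0.50, 0
#' @export
offspring_dist <- function(parent1, parent2) {
  g1 <- gamete_dist(parent1)
  g2 <- gamete_dist(parent2)
  c(p8 = g1[["n4"]] * g2[["n4"]],
    p9 = g1[["n4"]] * g2[["n5"]] + g1[["n5"]] * g2[["n4"]],
    p10 = g1[["n5"]] * g2[["n5"]])
}

#' Chi-squared test of Mendelian expectations in a cross
#'
#' Compares observed offspring karyotype-class counts with the Mendelian
#' expectation from the parental karyotypes. Classes with zero expected
#' probability are dropped before testing (they carry no information);
#' a nonzero observed count in such a class signals a non-Mendelian event or
#' a parental miscall and raises an error. Pearson chi-squared without
#' continuity correction; df = (number of possible classes) - 1.
#'
#' @param observed numeric vector of length 3: offspring counts for
#'   2n = 8, 9, 10.
#' @param parents numeric vector of length 2 with the parental diploid
#'   numbers.
#' @param n_crosses optional number of replicate pairs contributing offspring
#'   (bookkeeping only).
#' @return object of class `htest` with `observed`, `expected`, `statistic`,
#'   `parameter`, `p.value` and `n_crosses`.
#' @examples
#' cross_chisq(c(8, 54, 25), c(9, 9))  # X-squared = 11.71, df = 2
#' @export
cross_chisq <- function(observed, parents, n_crosses = NA_integer_) {
  if (length(observed) != 3L || anyNA(observed) || any(observed < 0)) {
    stop_karyo("observed must be 3 non-negative counts (2n = 8, 9, 10)")
  }
  probs <- offspring_dist(parents[1], parents[2])
  if (any(observed > 0 & probs == 0)) {
    stop_karyo("offspring observed in a class with zero Mendelian probability ",
               "(non-Mendelian event or parental miscall)",
               class = "karyopoly_impossible_offspring")
  }
  keep <- probs > 0
  n <- sum(observed)
  if (n == 0) stop_karyo("no offspring observed")
  expected <- n * probs
  stat <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  df <- sum(keep) - 1L
  structure(list(
    statistic = c("X-squared" = stat),
    parameter = c(df = df),
    p.value = stats::pchisq(stat, df, lower.tail = FALSE),
    observed = stats::setNames(observed, c("p8", "p9", "p10")),
    expected = expected,
    n_crosses = n_crosses,
    method = sprintf("Chi-squared test of Mendelian segregation in a 2n=%d x 2n=%d cross",
                     parents[1], parents[2]),
    data.name = paste(n, "offspring")),
    class = "htest")
}

#' Maximum-likelihood viability selection against 2n = 8 offspring
#'
#' Models a viability deficit of the euploid 2n = 8 class: offspring-class
#' probabilities are proportional to `(m8 * (1 - s), m9, m10)` where
#' `(m8, m9, m10)` is the Mendelian expectation of the cross and `s` in
#' `[0, 1]` is the selection coefficient. The MLE has the closed form
#' `s_hat = (N * m8 - c8) / (m8 * (N - c8))`, clamped to `[0, 1]`; the
#' confidence interval is obtained from the likelihood-ratio profile at the
#' chi-squared(1) cutoff.
#'
#' @inheritParams cross_chisq
#' @param conf_level coverage of the profile-likelihood interval
#'   (default 0.95).
#' @return list with `s_hat`, `ci` (length-2 vector), `conf_level`,
#'   `log_lik` at the MLE, and `probs` (fitted class probabilities).
#' @examples
#' estimate_selection_from_cross(c(8, 54, 25), c(9, 9))  # s_hat ~ 0.696
#' @export
estimate_selection_from_cross <- function(observed, parents, conf_level = 0.95) {
  if (length(observed) != 3L || anyNA(observed) || any(observed < 0)) {
    stop_karyo("observed must be 3 non-negative counts (2n = 8, 9, 10)")
  }
  m <- offspring_dist(parents[1], parents[2])
  if (m[1] == 0) {
    stop_karyo("no 2n = 8 offspring possible in this cross: s is unidentifiable")
  }
  c8 <- observed[1]
  n <- sum(observed)
  if (n == 0) stop_karyo("no offspring observed")

  # log-likelihood up to an s-free constant; c8 = 0 handled as 0 * log -> 0
  ll <- function(s) {
    (if (c8 > 0) c8 * log(m[1] * (1 - s)) else 0) - n * log(1 - m[1] * s)
  }
  s_hat <- (n * m[1] - c8) / (m[1] * (n - c8))
  s_hat <- unname(min(max(s_hat, 0), 1))
  ll_max <- ll(s_hat)
  cut <- ll_max - stats::qchisq(conf_level, df = 1) / 2

  lower <- if (ll(0) >= cut) 0 else
    stats::uniroot(function(s) ll(s) - cut, c(0, s_hat), tol = 1e-9)$root
  upper <- if (c8 == 0 || ll(1 - 1e-12) >= cut) 1 else
    stats::uniroot(function(s) ll(s) - cut, c(s_hat, 1 - 1e-12), tol = 1e-9)$root

  fitted <- c(m[1] * (1 - s_hat), m[2], m[3])
  fitted <- fitted / sum(fitted)
  list(s_hat = s_hat, ci = c(lower = lower, upper = upper),
       conf_level = conf_level, log_lik = ll_max,
       probs = stats::setNames(fitted, c("p8", "p9", "p10")))
}
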