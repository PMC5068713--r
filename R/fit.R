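#' Fit transmission-model parameters to karyotype-class counts
#'
#' Maximum-likelihood estimation of the viability-selection coefficient `s`
#' (against 2n = 8 zygotes) and/or the meiotic transmission probability `k`
#' (of the extra large chromosome from 2n = 9 parents) from a single vector
#' of karyotype-class counts. The observed generation is modelled as one
#' application of [deterministic_recursion()] to the parental class
#' frequencies: gametes are pooled from the parents, united at random and
#' filtered by viability, so the expected class probabilities are
#' proportional to `((1 - s) * g4^2, 2 * g4 * g5, g5^2)` with
#' `g5 = f10 + k * f9` taken over the parental frequencies.
#'
#' When the parental composition is known (e.g. a previous census of the same
#' line) supply it via `parental_freqs` and the fit is a proper multinomial
#' likelihood. When it is not, the parental frequencies default to the
#' observed frequencies themselves (a stationarity assumption appropriate for
#' a long-established line); the fit is then exploratory and flagged as such
#' in the output.
#'
#' Identifiability: `selection_only` and `distortion_only` each estimate one
#' parameter from two degrees of freedom and leave a goodness-of-fit residual;
#' the `joint` model is exactly identified (two parameters, two degrees of
#' freedom) and will fit any count vector whose implied parameters fall inside
#' the unit square, so its value lies in the estimates and their confidence
#' intervals, not in goodness of fit. A single count vector cannot distinguish
#' gamete-level distortion from zygote-level selection when both are free and
#' the data carry no parental anchor; flat likelihood profiles are flagged.
#'
#' @param observed numeric vector of length 3: counts for 2n = 8, 9, 10.
#' @param model `"selection_only"` (k fixed at 0.5), `"distortion_only"`
#'   (s fixed at 0) or `"joint"`.
#' @param parental_freqs optional numeric vector of length 3 with the parental
#'   class frequencies; defaults to the observed frequencies.
#' @param conf_level coverage of profile-likelihood intervals (default 0.95).
#' @return list of class `karyo_fit`: `model`, `estimates` (named vector),
#'   `ci` (matrix, one row per free parameter), `log_lik`, `fitted_probs`,
#'   `stationarity_assumed`, `identifiable` (FALSE when a profile is flat).
#' @examples
#' fit_karyotype_model(c(16, 77, 36), "selection_only")
#' @export
fit_karyotype_model <- function(observed,
                                model = c("selection_only", "distortion_only", "joint"),
                                parental_freqs = NULL, conf_level = 0.95) {
  model <- match.arg(model)
  if (length(observed) != 3L || anyNA(observed) || any(observed < 0)) {
    stop_karyo("observed must be 3 non-negative counts (2n = 8, 9, 10)")
  }
  n <- sum(observed)
  if (n == 0) stop_karyo("all-zero counts")
  stationarity <- is.null(parental_freqs)
  if (stationarity) parental_freqs <- observed / n
  if (length(parental_freqs) != 3L || any(parental_freqs < 0) ||
      abs(sum(parental_freqs) - 1) > 1e-6) {
    stop_karyo("parental_freqs must be 3 frequencies summing to 1")
  }

  loglik <- function(s, k) {
    probs <- deterministic_recursion(parental_freqs, s, k)
    # capped rather than -Inf so box-constrained optimisers stay finite
    if (any(probs == 0 & observed > 0)) return(-1e12)
    sum(observed[observed > 0] * log(probs[observed > 0]))
  }
  cutoff <- stats::qchisq(conf_level, df = 1) / 2
  profile_ci <- function(prof, mle, ll_max) {
    # prof: function of the free parameter returning profile log-likelihood;
    # values are capped so uniroot can bracket even where the profile is -Inf
    target <- function(x) max(prof(x) - (ll_max - cutoff), -1e12)
    lower <- if (mle <= 0 || target(0) >= 0) 0 else
      stats::uniroot(target, c(0, mle), tol = 1e-8)$root
    upper <- if (mle >= 1 || target(1) >= 0) 1 else
      stats::uniroot(target, c(mle, 1), tol = 1e-8)$root
    c(lower = lower, upper = upper)
  }
  flat <- function(prof) {
    vals <- vapply(seq(0, 1, length.out = 41), prof, numeric(1))
    diff(range(vals[is.finite(vals)])) < 1e-6
  }

  if (model == "selection_only") {
    m <- deterministic_recursion(parental_freqs, 0, 0.5)
    # closed-form MLE, same structure as the cross estimator
    s_hat <- (n * m[1] - observed[1]) / (m[1] * (n - observed[1]))
    s_hat <- min(max(s_hat, 0), 1)
    prof <- function(s) loglik(s, 0.5)
    ll_max <- prof(s_hat)
    if (flat(prof)) {
      return(karyo_fit(model, c(s = s_hat), NULL, ll_max,
                       deterministic_recursion(parental_freqs, s_hat, 0.5),
                       stationarity, identifiable = FALSE, conf_level))
    }
    ci <- rbind(s = profile_ci(prof, s_hat, ll_max))
    karyo_fit(model, c(s = s_hat), ci, ll_max,
              deterministic_recursion(parental_freqs, s_hat, 0.5),
              stationarity, TRUE, conf_level)
  } else if (model == "distortion_only") {
    if (parental_freqs[2] == 0) {
      stop_karyo("no 2n = 9 parents: distortion parameter is unidentifiable")
    }
    prof <- function(k) loglik(0, k)
    if (flat(prof)) {
      return(karyo_fit(model, c(k = 0.5), NULL, prof(0.5),
                       deterministic_recursion(parental_freqs, 0, 0.5),
                       stationarity, identifiable = FALSE, conf_level))
    }
    opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-9)
    k_hat <- opt$maximum
    # snap to boundary when the optimum lies against it
    for (b in c(0, 1)) if (prof(b) >= opt$objective) k_hat <- b
    ll_max <- prof(k_hat)
    ci <- rbind(k = profile_ci(prof, k_hat, ll_max))
    karyo_fit(model, c(k = k_hat), ci, ll_max,
              deterministic_recursion(parental_freqs, 0, k_hat),
              stationarity, TRUE, conf_level)
  } else {
    prof_s <- function(s) {
      stats::optimize(function(k) loglik(s, k), c(0, 1), maximum = TRUE,
                      tol = 1e-9)$objective
    }
    prof_k <- function(k) {
      stats::optimize(function(s) loglik(s, k), c(0, 1), maximum = TRUE,
                      tol = 1e-9)$objective
    }
    opt <- stats::optim(c(0.3, 0.4), function(par) -loglik(par[1], par[2]),
                        method = "L-BFGS-B", lower = c(0, 0), upper = c(1, 1))
    # analytic start: the saturated solution matching the observed frequencies
    # exactly, where it lies inside the unit square
    f <- observed / n
    starts <- list()
    if (f[2] + f[3] > 0 && parental_freqs[2] > 0 && f[3] > 0) {
      g5 <- 2 * f[3] / (f[2] + 2 * f[3])
      k0 <- min(max((g5 - parental_freqs[3]) / parental_freqs[2], 0), 1)
      s0 <- min(max(1 - f[1] * g5^2 / (f[3] * (1 - g5)^2), 0), 1)
      starts <- list(c(s0, k0))
    }
    for (st in starts) {
      cand <- stats::optim(st, function(par) -loglik(par[1], par[2]),
                           method = "L-BFGS-B", lower = c(0, 0), upper = c(1, 1))
      if (cand$value < opt$value) opt <- cand
    }
    # grid restarts guard against local optima on the boundary
    for (s0 in c(0.05, 0.5, 0.9)) for (k0 in c(0.1, 0.5, 0.9)) {
      cand <- stats::optim(c(s0, k0), function(par) -loglik(par[1], par[2]),
                           method = "L-BFGS-B", lower = c(0, 0), upper = c(1, 1))
      if (cand$value < opt$value) opt <- cand
    }
    est <- c(s = opt$par[1], k = opt$par[2])
    ll_max <- -opt$value
    ident <- !(flat(prof_s) || flat(prof_k))
    ci <- NULL
    if (ident) {
      ci <- rbind(s = profile_ci(prof_s, est["s"], ll_max),
                  k = profile_ci(prof_k, est["k"], ll_max))
    }
    karyo_fit(model, est, ci, ll_max,
              deterministic_recursion(parental_freqs, est["s"], est["k"]),
              stationarity, ident, conf_level)
  }
}

karyo_fit <- function(model, estimates, ci, log_lik, fitted_probs,
                      stationarity_assumed, identifiable, conf_level) {
  structure(list(model = model, estimates = estimates, ci = ci,
                 log_lik = log_lik,
                 fitted_probs = stats::setNames(fitted_probs, c("p8", "p9", "p10")),
                 stationarity_assumed = stationarity_assumed,
                 identifiable = identifiable, conf_level = conf_level),
            class = "karyo_fit")
}

#' @export
print.karyo_fit <- function(x, ...) {
  cat("Karyotype transmission-model fit (", x$model, ")\n", sep = "")
  for (nm in names(x$estimates)) {
    cat(sprintf("  %s = %.4f", nm, x$estimates[[nm]]))
    if (!is.null(x$ci) && nm %in% rownames(x$ci)) {
      cat(sprintf("  [%.0f%% CI %.4f, %.4f]", 100 * x$conf_level,
                  x$ci[nm, "lower"], x$ci[nm, "upper"]))
    }
    cat("\n")
  }
  if (!x$identifiable) cat("  WARNING: likelihood profile is flat; parameter(s) not identifiable\n")
  if (x$stationarity_assumed) {
    cat("  (parental frequencies taken from the observed counts: stationarity assumed)\n")
  }
  cat(sprintf("  log-likelihood %.3f; fitted probs %.3f / %.3f / %.3f\n",
              x$log_lik, x$fitted_probs[1], x$fitted_probs[2], x$fitted_probs[3]))
  invisible(x)
}
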