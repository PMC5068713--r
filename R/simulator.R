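#' One-generation deterministic recursion of karyotype-class frequencies
#'
#' Infinite-population limit of the transmission model for the 2n = 8/9/10
#' system. Parents at class frequencies `freqs` produce a gamete pool with
#' n = 5 frequency `g5 = f10 + k * f9` (a 2n = 9 parent transmits its extra
#' large chromosome with probability `k`; `k = 0.5` is fair meiosis), gametes
#' unite at random into zygotes at `(g4^2, 2 g4 g5, g5^2)`, and zygote
#' viabilities are `(1 - s, 1, 1)`: selection acts against the euploid
#' 2n = 8 class only. The result is renormalised to sum to 1.
#'
#' @param freqs numeric vector of length 3 (classes 2n = 8, 9, 10) summing
#'   to 1.
#' @param selection_s viability deficit of 2n = 8 zygotes, in `[0, 1]`.
#' @param distortion_k transmission probability of the extra large chromosome
#'   from 2n = 9 parents, in `[0, 1]`.
#' @return numeric vector `c(f8, f9, f10)` of next-generation frequencies.
#' @examples
#' deterministic_recursion(c(0.25, 0.5, 0.25), 0, 0.5)  # Hardy-Weinberg fixed point
#' deterministic_recursion(c(0.25, 0.5, 0.25), 1, 0.5)  # c(0, 2/3, 1/3)
#' @export
deterministic_recursion <- function(freqs, selection_s = 0, distortion_k = 0.5) {
  if (length(freqs) != 3L || anyNA(freqs) || any(freqs < 0)) {
    stop_karyo("freqs must be 3 non-negative frequencies")
  }
  if (abs(sum(freqs) - 1) > 1e-8) stop_karyo("freqs must sum to 1")
  check_number(selection_s, "selection_s", 0, 1)
  check_number(distortion_k, "distortion_k", 0, 1)
  g5 <- freqs[3] + distortion_k * freqs[2]
  g4 <- 1 - g5
  zyg <- c(g4^2, 2 * g4 * g5, g5^2)
  w <- c(1 - selection_s, 1, 1)
  mass <- sum(zyg * w)
  if (mass <= 0) stop_karyo("all reachable zygote classes are lethal")
  zyg * w / mass
}

#' Iterate the deterministic recursion to a fixed point
#'
#' @inheritParams deterministic_recursion
#' @param init starting frequencies (default uniform).
#' @param tol convergence tolerance on the maximum frequency change per
#'   iteration (default 1e-10).
#' @param max_iter iteration cap.
#' @return list with `freqs` (the fixed point), `iterations`, `converged`.
#'   Note that for fair meiosis (`k = 0.5`) with `s > 0` the only stable fixed
#'   point is fixation of the extra large chromosome; interior equilibria
#'   exist only on the balance manifold `s * (1 - g5) = 1 - 2k` (drive toward
#'   the n = 4 gamete balanced by viability selection against 2n = 8).
#' @export
equilibrium_freqs <- function(selection_s = 0, distortion_k = 0.5,
                              init = c(1, 1, 1) / 3, tol = 1e-10,
                              max_iter = 1e6) {
  f <- init / sum(init)
  for (i in seq_len(max_iter)) {
    f_new <- deterministic_recursion(f, selection_s, distortion_k)
    if (max(abs(f_new - f)) < tol) {
      return(list(freqs = f_new, iterations = i, converged = TRUE))
    }
    f <- f_new
  }
  list(freqs = f, iterations = max_iter, converged = FALSE)
}

#' Configuration for the forward karyotype simulator
#'
#' @param population_size number of individuals per generation (>= 2;
#'   outcrossing needs two distinct parents).
#' @param generations number of generations to simulate.
#' @param initial_counts integer vector `c(c8, c9, c10)` summing to
#'   `population_size`.
#' @param selection_s,distortion_k see [deterministic_recursion()].
#' @param replicates number of independent replicate populations.
#' @param random_seed optional integer seed; the whole run is reproducible
#'   given the seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(population_size, generations, initial_counts,
                       selection_s = 0, distortion_k = 0.5, replicates = 1,
                       random_seed = NULL) {
  check_number(population_size, "population_size", lower = 2)
  check_number(generations, "generations", lower = 1)
  check_number(replicates, "replicates", lower = 1)
  check_number(selection_s, "selection_s", 0, 1)
  check_number(distortion_k, "distortion_k", 0, 1)
  if (length(initial_counts) != 3L || any(initial_counts < 0) ||
      sum(initial_counts) != population_size) {
    stop_karyo("initial_counts must be 3 non-negative counts summing to population_size")
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 initial_counts = as.integer(initial_counts),
                 selection_s = selection_s, distortion_k = distortion_k,
                 replicates = as.integer(replicates),
                 random_seed = random_seed),
            class = "sim_config")
}

# one Wright-Fisher generation: counts -> counts, vectorised over offspring
wf_generation <- function(counts, s, k) {
  n <- sum(counts)
  # can any surviving zygote class be produced at all?
  n5_possible <- counts[3] > 0 || (counts[2] > 0 && k > 0)
  if (s >= 1 && !n5_possible) {
    stop_karyo("all producible zygotes are 2n = 8 and lethal: population cannot reproduce")
  }
  cum <- cumsum(counts)
  out <- integer(3)
  got <- 0L
  while (got < n) {
    m <- as.integer(ceiling((n - got) * 1.5) + 16L)
    i1 <- sample.int(n, m, replace = TRUE)
    i2 <- sample.int(n, m, replace = TRUE)
    while (any(clash <- i1 == i2)) {          # parents must be distinct individuals
      i2[clash] <- sample.int(n, sum(clash), replace = TRUE)
    }
    cl1 <- 1L + (i1 > cum[1]) + (i1 > cum[2])
    cl2 <- 1L + (i2 > cum[1]) + (i2 > cum[2])
    x1 <- integer(m); x2 <- integer(m)
    x1[cl1 == 3L] <- 1L
    x2[cl2 == 3L] <- 1L
    het1 <- cl1 == 2L; het2 <- cl2 == 2L
    x1[het1] <- stats::rbinom(sum(het1), 1L, k)
    x2[het2] <- stats::rbinom(sum(het2), 1L, k)
    zyg <- 1L + x1 + x2                        # 1 = 2n8, 2 = 2n9, 3 = 2n10
    keep <- zyg != 1L | stats::runif(m) < 1 - s
    zyg <- zyg[keep]
    if (length(zyg) > n - got) zyg <- zyg[seq_len(n - got)]
    out <- out + tabulate(zyg, nbins = 3L)
    got <- got + length(zyg)
  }
  out
}

#' Forward-simulate karyotype-class dynamics
#'
#' Wright-Fisher-style simulation with discrete non-overlapping generations:
#' each offspring is formed by drawing two distinct parents uniformly at
#' random (obligate outcrossing — no self-fertilisation), one gamete from
#' each under the transmission rules of [deterministic_recursion()], and the
#' zygote survives with probability `1 - selection_s` if 2n = 8 and 1
#' otherwise; rejected zygotes are redrawn until the next generation reaches
#' `population_size`.
#'
#' @param config a [sim_config()].
#' @return data frame of class `karyo_trajectory` with columns `replicate`,
#'   `generation` (0 = initial state), `c8`, `c9`, `c10`. The configuration
#'   is attached as attribute `config`.
#' @seealso [trajectory_summary()] for final-generation summaries.
#' @export
simulate_karyotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$random_seed, {
    rows <- vector("list", config$replicates)
    for (r in seq_len(config$replicates)) {
      counts <- matrix(0L, nrow = config$generations + 1L, ncol = 3L)
      counts[1L, ] <- config$initial_counts
      for (g in seq_len(config$generations)) {
        counts[g + 1L, ] <- wf_generation(counts[g, ], config$selection_s,
                                          config$distortion_k)
      }
      rows[[r]] <- data.frame(replicate = r,
                              generation = 0:config$generations,
                              c8 = counts[, 1], c9 = counts[, 2],
                              c10 = counts[, 3])
    }
    out <- do.call(rbind, rows)
    attr(out, "config") <- config
    class(out) <- c("karyo_trajectory", "data.frame")
    out
  })
}

#' Summarise the final generation of a simulated trajectory
#'
#' @param trajectory output of [simulate_karyotypes()].
#' @return data frame with one row per class: mean and SD of the
#'   final-generation class frequency across replicates.
#' @export
trajectory_summary <- function(trajectory) {
  check_columns(trajectory, c("replicate", "generation", "c8", "c9", "c10"),
                "trajectory")
  last <- trajectory[trajectory$generation == max(trajectory$generation), ]
  n <- last$c8 + last$c9 + last$c10
  freqs <- cbind(last$c8, last$c9, last$c10) / n
  data.frame(class = c("2n8", "2n9", "2n10"),
             mean_freq = colMeans(freqs),
             sd_freq = apply(freqs, 2, stats::sd))
}
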