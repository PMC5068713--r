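#' Parameters for the synthetic morphometry generator
#'
#' Describes, per chromosome pair of the 'normal' karyotype, the mean and SD
#' of long- and short-arm lengths (micrometres), together with a plate-level
#' condensation factor and a per-arm measurement noise. Chromosome length in
#' a metaphase spread depends strongly on the stage of mitosis, which affects
#' all chromosomes of a plate together; the generator therefore draws one
#' multiplicative lognormal condensation factor per plate (mean exactly 1)
#' and keeps the chromosome-level arm SDs correspondingly smaller than the
#' total observed spread.
#'
#' @param pair_params data frame with columns `pair`, `long_mean`, `long_sd`,
#'   `short_mean`, `short_sd`, ordered by decreasing size; the first
#'   `large_pairs` rows describe the large chromosome pairs.
#' @param large_pairs number of leading rows that are large pairs.
#' @param condensation_sdlog sdlog of the plate-level lognormal condensation
#'   factor (meanlog is set to `-sdlog^2/2` so the factor has mean 1).
#' @param noise_sd SD of additive per-arm measurement noise, in micrometres.
#' @return object of class `morphometry_params`.
#' @export
morphometry_params <- function(pair_params, large_pairs,
                               condensation_sdlog = 0.12, noise_sd = 0.05) {
  check_columns(pair_params, c("pair", "long_mean", "long_sd", "short_mean",
                               "short_sd"), "pair_params")
  if (any(pair_params$long_mean <= 0) || any(pair_params$short_mean <= 0) ||
      any(pair_params$long_sd < 0) || any(pair_params$short_sd < 0)) {
    stop_karyo("arm-length means must be positive and SDs non-negative")
  }
  check_number(large_pairs, "large_pairs", lower = 0, upper = nrow(pair_params))
  check_number(condensation_sdlog, "condensation_sdlog", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(pair_params = pair_params, large_pairs = as.integer(large_pairs),
                 condensation_sdlog = condensation_sdlog, noise_sd = noise_sd),
            class = "morphometry_params")
}

#' Built-in morphometry parameters for the studied species
#'
#' Pair-wise arm-length means are the observed karyotype means of the four
#' species; the chromosome-level SDs are set to half the observed total SDs,
#' leaving the remaining spread to the plate-level condensation factor so
#' that the marginal spread of generated lengths approximately matches the
#' observed one while within-plate length ratios stay tight.
#'
#' @inheritParams macrostomum_profile
#' @inheritParams morphometry_params
#' @return a [morphometry_params()].
#' @export
species_morphometry_params <- function(species = c("lignano", "sp8", "spirale", "hystrix"),
                                       condensation_sdlog = 0.12, noise_sd = 0.05) {
  species <- match.arg(species)
  tab <- switch(species,
    lignano = list(l = c(2.81, 1.47, 1.34, 1.19), lsd = c(0.46, 0.16, 0.15, 0.14),
                   s = c(2.46, 1.26, 1.15, 1.06), ssd = c(0.39, 0.16, 0.13, 0.19),
                   large = 1L),
    sp8     = list(l = c(3.29, 2.89, 1.55, 1.59, 1.23), lsd = c(0.13, 0.19, 0.01, 0.09, 0.06),
                   s = c(3.05, 2.86, 1.43, 1.24, 1.13), ssd = c(0.21, 0.21, 0.03, 0.19, 0.04),
                   large = 2L),
    spirale = list(l = c(2.06, 1.87, 1.67), lsd = c(0.35, 0.26, 0.17),
                   s = c(1.67, 1.57, 1.45), ssd = c(0.20, 0.28, 0.27),
                   large = 0L),
    hystrix = list(l = c(2.09, 2.10, 1.94), lsd = c(0.37, 0.35, 0.36),
                   s = c(1.78, 1.27, 1.04), ssd = c(0.32, 0.27, 0.18),
                   large = 0L))
  morphometry_params(
    data.frame(pair = seq_along(tab$l),
               long_mean = tab$l, long_sd = tab$lsd / 2,
               short_mean = tab$s, short_sd = tab$ssd / 2),
    large_pairs = tab$large,
    condensation_sdlog = condensation_sdlog, noise_sd = noise_sd)
}

# parameter-row template for one (n_large, n_small) karyotype: large copies
# use the large-pair rows (two copies each, extras reuse row 1), small copies
# cycle through the small-pair rows
pair_row_template <- function(n_large, n_small, params) {
  pp <- params$pair_params
  large_rows <- seq_len(params$large_pairs)
  small_rows <- setdiff(seq_len(nrow(pp)), large_rows)
  if (n_large > 0 && length(large_rows) == 0L) large_rows <- 1L
  # two copies per pair row; extra copies recycle from the first pair
  lg <- rep(rep(large_rows, each = 2L), length.out = n_large)
  sm <- rep(rep(small_rows, each = 2L), length.out = n_small)
  c(lg, sm)
}

# truncated-at-zero normal draws, vectorised (redraw rejected values)
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  x
}

# vectorised measurement generator: one row per chromosome
generate_measurements <- function(plate_df, params) {
  # plate_df: specimen_id, plate_id, n_large, n_small (one row per plate)
  key <- paste(plate_df$n_large, plate_df$n_small)
  tmpl <- lapply(stats::setNames(unique(key), unique(key)), function(k) {
    i <- match(k, key)
    pair_row_template(plate_df$n_large[i], plate_df$n_small[i], params)
  })
  rows_per_plate <- lengths(tmpl)[key]
  plate_idx <- rep(seq_len(nrow(plate_df)), times = rows_per_plate)
  prow <- unlist(tmpl[key], use.names = FALSE)
  pp <- params$pair_params
  n <- length(prow)
  sdl <- params$condensation_sdlog
  cond <- stats::rlnorm(nrow(plate_df), meanlog = -sdl^2 / 2, sdlog = sdl)
  a1 <- rnorm_pos(n, pp$long_mean[prow], pp$long_sd[prow]) * cond[plate_idx]
  a2 <- rnorm_pos(n, pp$short_mean[prow], pp$short_sd[prow]) * cond[plate_idx]
  if (params$noise_sd > 0) {
    a1 <- a1 + stats::rnorm(n, 0, params$noise_sd)
    a2 <- a2 + stats::rnorm(n, 0, params$noise_sd)
    eps <- 1e-3  # a measured arm is never reported as zero or negative
    a1 <- pmax(a1, eps); a2 <- pmax(a2, eps)
  }
  data.frame(specimen_id = plate_df$specimen_id[plate_idx],
             plate_id = plate_df$plate_id[plate_idx],
             short_arm_um = pmin(a1, a2),
             long_arm_um = pmax(a1, a2))
}

#' Generate one synthetic metaphase plate
#'
#' Draws arm-length measurements for a plate with the given karyotype:
#' one plate-level condensation factor, per-chromosome truncated-normal arm
#' lengths from the pair-appropriate parameters (additional large copies
#' reuse the pair-1 parameters), plus additive measurement noise. The longer
#' measured arm is always reported as the long arm.
#'
#' @param karyotype integer vector `c(n_large, n_small)`.
#' @param params a [morphometry_params()].
#' @param specimen_id,plate_id identifiers for the emitted rows.
#' @param seed optional seed; the same seed reproduces the plate exactly.
#' @return measurement data frame (`specimen_id`, `plate_id`,
#'   `short_arm_um`, `long_arm_um`), one row per chromosome.
#' @export
generate_plate <- function(karyotype, params, specimen_id = "S1",
                           plate_id = "P1", seed = NULL) {
  stopifnot(inherits(params, "morphometry_params"))
  if (length(karyotype) != 2L || any(karyotype < 0) || sum(karyotype) < 1) {
    stop_karyo("karyotype must be c(n_large, n_small) with at least one chromosome")
  }
  with_seed(seed, generate_measurements(
    data.frame(specimen_id = specimen_id, plate_id = plate_id,
               n_large = karyotype[1], n_small = karyotype[2]),
    params))
}

#' Specification of a synthetic population
#'
#' @param category_probs numeric vector of length 4 (probabilities of the
#'   `normal`, `plus_one_large`, `plus_two_large`, `abnormal` categories),
#'   summing to 1.
#' @param n_specimens number of specimens to generate.
#' @param plates_per_specimen plates per specimen (default 10, the minimum
#'   for a reliable karyotype call).
#' @param mosaic_rate probability that a specimen is a 50:50 mosaic of its
#'   assigned karyotype and the karyotype with one more large chromosome.
#' @param profile a [species_profile()].
#' @param params a [morphometry_params()] for the measurement tables.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(category_probs, n_specimens,
                            plates_per_specimen = 10, mosaic_rate = 0,
                            profile = macrostomum_profile("lignano"),
                            params = species_morphometry_params("lignano")) {
  if (length(category_probs) != 4L || any(category_probs < 0) ||
      abs(sum(category_probs) - 1) > 1e-8) {
    stop_karyo("category_probs must be 4 probabilities summing to 1")
  }
  check_number(n_specimens, "n_specimens", lower = 1)
  check_number(plates_per_specimen, "plates_per_specimen", lower = 1)
  check_number(mosaic_rate, "mosaic_rate", 0, 1)
  structure(list(category_probs = category_probs,
                 n_specimens = as.integer(n_specimens),
                 plates_per_specimen = as.integer(plates_per_specimen),
                 mosaic_rate = mosaic_rate, profile = profile, params = params),
            class = "population_spec")
}

# repertoire of 'abnormal' karyotype variants relative to a profile's normal
# (nl0, ns0): aneuploidies of small chromosomes, combined aneuploidies, a
# doubled-complement variant, and structurally rearranged plates
abnormal_variants <- function(profile) {
  nl0 <- 2L * profile$normal_large_pairs
  ns0 <- 2L * profile$normal_small_pairs
  data.frame(n_large = c(nl0 + 1L, nl0 + 2L, nl0, nl0 + 2L, nl0, nl0),
             n_small = c(ns0 - 1L, ns0 - 1L, ns0 + 1L, ns0 + 6L, ns0 + 1L, ns0),
             structural_anomaly = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
}

#' Generate a synthetic specimen set with measurement and plate-count tables
#'
#' Assigns each specimen a karyotype category (abnormal specimens get a
#' concrete variant drawn uniformly from a small repertoire of observed
#' abnormality types), emits `plates_per_specimen` plates per specimen, and
#' optionally makes specimens mosaic (their plates alternate between the
#' assigned karyotype and the karyotype with one extra large chromosome).
#'
#' @param spec a [population_spec()].
#' @param seed optional seed for full reproducibility.
#' @return list with `specimens` (true per-specimen karyotypes),
#'   `plate_counts` (per-plate chromosome counts, the input format of
#'   [call_specimens()]) and `measurements` (per-chromosome arm lengths, the
#'   input format of [chromosome_metrics()]).
#' @export
generate_specimen_set <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(seed, {
    ns <- spec$n_specimens
    nl0 <- 2L * spec$profile$normal_large_pairs
    ns0 <- 2L * spec$profile$normal_small_pairs
    cat_idx <- sample.int(4L, ns, replace = TRUE, prob = spec$category_probs)
    n_large <- c(nl0, nl0 + 1L, nl0 + 2L, NA)[cat_idx]
    n_small <- c(ns0, ns0, ns0, NA)[cat_idx]
    anomaly <- rep(FALSE, ns)
    if (any(cat_idx == 4L)) {
      var <- abnormal_variants(spec$profile)
      pick <- sample.int(nrow(var), sum(cat_idx == 4L), replace = TRUE)
      n_large[cat_idx == 4L] <- var$n_large[pick]
      n_small[cat_idx == 4L] <- var$n_small[pick]
      anomaly[cat_idx == 4L] <- var$structural_anomaly[pick]
    }
    mosaic <- stats::runif(ns) < spec$mosaic_rate
    specimens <- data.frame(
      specimen_id = sprintf("S%05d", seq_len(ns)),
      category = factor(karyotype_categories()[cat_idx],
                        levels = karyotype_categories()),
      n_large = n_large, n_small = n_small,
      structural_anomaly = anomaly, mosaic = mosaic)

    np <- spec$plates_per_specimen
    sp_idx <- rep(seq_len(ns), each = np)
    plate_no <- rep(seq_len(np), times = ns)
    # mosaic specimens: alternate plates carry one extra large chromosome
    extra <- mosaic[sp_idx] & plate_no %% 2L == 0L
    plate_counts <- data.frame(
      specimen_id = specimens$specimen_id[sp_idx],
      plate_id = sprintf("S%05d.P%02d", sp_idx, plate_no),
      n_large = n_large[sp_idx] + as.integer(extra),
      n_small = n_small[sp_idx],
      structural_anomaly = anomaly[sp_idx])
    measurements <- generate_measurements(plate_counts, spec$params)
    list(specimens = specimens, plate_counts = plate_counts,
         measurements = measurements)
  })
}

#' Generate offspring counts for a synthetic cross
#'
#' Offspring classes are drawn from the Mendelian expectation of the cross
#' reweighted by viabilities `(1 - s, 1, 1)` for the 2n = 8/9/10 classes and
#' renormalised, i.e. from the same viability-selection model fitted by
#' [estimate_selection_from_cross()].
#'
#' @inheritParams cross_chisq
#' @param n_offspring number of surviving offspring to draw.
#' @param selection_s viability deficit of 2n = 8 zygotes in `[0, 1]`.
#' @param seed optional seed.
#' @return integer vector `c(c8, c9, c10)`.
#' @export
generate_cross_offspring <- function(parents, n_offspring, selection_s = 0,
                                     seed = NULL) {
  check_number(n_offspring, "n_offspring", lower = 1)
  check_number(selection_s, "selection_s", 0, 1)
  probs <- offspring_dist(parents[1], parents[2]) * c(1 - selection_s, 1, 1)
  if (sum(probs) <= 0) stop_karyo("all reachable offspring classes are lethal")
  probs <- probs / sum(probs)
  with_seed(seed, {
    stats::setNames(as.integer(stats::rmultinom(1, n_offspring, probs)),
                    c("c8", "c9", "c10"))
  })
}
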