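lignano_params <- species_morphometry_params("lignano")

test_that("degenerate generator parameters reproduce the karyotype means exactly", {
  p <- species_morphometry_params("lignano", condensation_sdlog = 0, noise_sd = 0)
  p$pair_params$long_sd <- 0
  p$pair_params$short_sd <- 0
  plate <- generate_plate(c(2, 6), p, seed = 1)
  m <- chromosome_metrics(plate)
  expect_equal(sort(unique(round(m$al_um, 2)), decreasing = TRUE),
               c(5.27, 2.73, 2.49, 2.25))   # sums of the pair arm means
  expect_equal(sort(m$long_arm_um, decreasing = TRUE)[1:2], c(2.81, 2.81))
  expect_true(all(m$centromere_class == "m"))
  split <- split_size_classes(m)
  expect_equal(sum(split$size_class == "large"), 2)
})

test_that("generated plates are deterministic under a fixed seed", {
  a <- generate_plate(c(3, 6), lignano_params, seed = 7)
  b <- generate_plate(c(3, 6), lignano_params, seed = 7)
  expect_identical(a, b)
  c <- generate_plate(c(3, 6), lignano_params, seed = 8)
  expect_false(identical(a, c))

  spec <- population_spec(c(0.5, 0.3, 0.2, 0), 30)
  expect_identical(generate_specimen_set(spec, seed = 5),
                   generate_specimen_set(spec, seed = 5))
})

test_that("generator moments match the generating parameters over many plates", {
  set.seed(1234)
  plates <- data.frame(specimen_id = sprintf("S%04d", 1:5000),
                       plate_id = "P1", n_large = 2, n_small = 6)
  meas <- karyopoly:::generate_measurements(plates, lignano_params)
  ps <- summarize_pairs(chromosome_metrics(meas))
  target_al <- c(2.81 + 2.46, 1.47 + 1.26, 1.34 + 1.15, 1.19 + 1.06)
  expect_equal(ps$al_mean, target_al, tolerance = 0.01)   # within 1 percent
  # arm invariant survives generation: long >= short > 0
  expect_true(all(meas$long_arm_um >= meas$short_arm_um))
  expect_true(all(meas$short_arm_um > 0))
})

test_that("additional large chromosomes reuse the first-pair parameters", {
  p <- species_morphometry_params("lignano", condensation_sdlog = 0, noise_sd = 0)
  p$pair_params$long_sd <- 0
  p$pair_params$short_sd <- 0
  plate <- generate_plate(c(3, 6), p, seed = 2)
  al <- sort(plate$short_arm_um + plate$long_arm_um, decreasing = TRUE)
  expect_equal(al[1:3], rep(5.27, 3))
})

test_that("specimen sets follow the category specification", {
  all_normal <- generate_specimen_set(
    population_spec(c(1, 0, 0, 0), 50), seed = 3)
  expect_true(all(all_normal$specimens$category == "normal"))
  expect_true(all(all_normal$plate_counts$n_large == 2))
  expect_true(all(all_normal$plate_counts$n_small == 6))

  # generating proportions are recovered by the calling pipeline at large n
  spec <- population_spec(c(0.124, 0.597, 0.279, 0), 4000, mosaic_rate = 0)
  set <- generate_specimen_set(spec, seed = 11)
  calls <- call_specimens(set$plate_counts, macrostomum_profile("lignano"))
  tab <- tabulate_population(calls, "synthetic")
  got <- c(tab$normal, tab$plus_one_large, tab$plus_two_large) / tab$n
  expect_equal(got, c(0.124, 0.597, 0.279), tolerance = 0.031)  # ~4 binomial SDs
})

test_that("forced mosaicism is always detected", {
  spec <- population_spec(c(0.3, 0.4, 0.3, 0), 40, mosaic_rate = 1)
  set <- generate_specimen_set(spec, seed = 21)
  calls <- call_specimens(set$plate_counts, macrostomum_profile("lignano"))
  expect_true(all(calls$mosaic))
})

test_that("abnormal specimens draw concrete variants and are called abnormal", {
  spec <- population_spec(c(0, 0, 0, 1), 200, mosaic_rate = 0)
  set <- generate_specimen_set(spec, seed = 31)
  calls <- call_specimens(set$plate_counts, macrostomum_profile("lignano"))
  expect_true(all(calls$category == "abnormal"))
  combos <- unique(set$specimens[, c("n_large", "n_small", "structural_anomaly")])
  expect_gt(nrow(combos), 3)   # the repertoire is actually sampled
})

test_that("synthetic cross offspring follow the viability-reweighted expectation", {
  expect_equal(generate_cross_offspring(c(9, 10), 500, seed = 1)[["c8"]], 0)

  big <- generate_cross_offspring(c(9, 9), 1e5, selection_s = 0, seed = 2)
  expect_equal(unname(big / sum(big)), c(0.25, 0.5, 0.25), tolerance = 0.025)

  lethal <- generate_cross_offspring(c(9, 9), 1e5, selection_s = 1, seed = 3)
  expect_equal(lethal[["c8"]], 0)
  expect_equal(unname(lethal / sum(lethal)), c(0, 2 / 3, 1 / 3), tolerance = 0.02)

  expect_identical(generate_cross_offspring(c(9, 9), 100, 0.3, seed = 9),
                   generate_cross_offspring(c(9, 9), 100, 0.3, seed = 9))
  expect_error(generate_cross_offspring(c(8, 8), 10, selection_s = 1), "lethal")
})
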