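test_that("chromosome metrics follow the defining formulas", {
  # two-chromosome plate, symmetric metacentric: AL 2 in a plate totalling 4
  df <- data.frame(specimen_id = "S1", plate_id = "P1",
                   short_arm_um = c(1, 1), long_arm_um = c(1, 1))
  m <- chromosome_metrics(df)
  expect_equal(m$al_um, c(2, 2))
  expect_equal(m$rl_pct, c(100, 100))
  expect_equal(m$arm_ratio, c(1, 1))
  expect_equal(m$ci, c(0.5, 0.5))
  expect_equal(as.character(m$centromere_class), c("m", "m"))

  # submetacentric chromosome in a plate totalling 5.7
  df2 <- data.frame(specimen_id = "S1", plate_id = "P1",
                    short_arm_um = c(1.0, 1.425), long_arm_um = c(1.85, 1.425))
  m2 <- chromosome_metrics(df2)
  expect_equal(m2$al_um[1], 2.85)
  expect_equal(m2$rl_pct[1], 100)           # 2.85 * 100 / (5.7 / 2)
  expect_equal(m2$arm_ratio[1], 1.85)
  expect_equal(m2$ci[1], 1 / 2.85, tolerance = 1e-10)
  expect_equal(as.character(m2$centromere_class)[1], "sm")
})

test_that("relative length of the largest chromosome on the mean 2n = 8 karyotype", {
  m <- chromosome_metrics(plate_from_lengths(lignano_mean_lengths))
  # direct evaluation of the RL formula: 5.27 * 100 / (25.48 / 2)
  expect_equal(max(m$rl_pct), 5.27 * 100 / (sum(lignano_mean_lengths) / 2),
               tolerance = 1e-10)
  expect_equal(max(m$rl_pct), 41.37, tolerance = 1e-3)
})

test_that("metric invariants hold on randomly generated plates", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    s <- runif(n, 0.5, 3); l <- s * runif(n, 1, 8)
    df <- data.frame(specimen_id = "S", plate_id = paste0("P", i),
                     short_arm_um = s, long_arm_um = l)
    m <- chromosome_metrics(df)
    expect_equal(sum(m$rl_pct), 200, tolerance = 1e-9)       # RL normalised per plate
    expect_equal(m$ci * (1 + m$arm_ratio), rep(1, n), tolerance = 1e-9)
    expect_equal(m$al_um, s + l)
  }
})

test_that("invalid arm lengths are rejected with informative errors", {
  bad <- data.frame(specimen_id = "S1", plate_id = "P1",
                    short_arm_um = c(1, -0.2), long_arm_um = c(1, 1))
  expect_error(chromosome_metrics(bad), "positive")
  swapped <- data.frame(specimen_id = "S1", plate_id = "P1",
                        short_arm_um = 2, long_arm_um = 1)
  expect_error(chromosome_metrics(swapped), "long arm shorter")
})

test_that("centromere classification uses Levan thresholds with closed lower classes", {
  expect_equal(as.character(classify_centromere(c(1, 1.15, 1.7, 1.85, 3, 3.2, 7, 7.5))),
               c("m", "m", "m", "sm", "sm", "st", "st", "t"))
  expect_error(classify_centromere(0.9), "ordered")
  # monotone step function of R
  r <- seq(1, 10, by = 0.01)
  cls <- as.integer(classify_centromere(r))
  expect_true(all(diff(cls) >= 0))
})

test_that("size-class splitting finds the gap and matches the brute-force oracle", {
  m <- split_size_classes(chromosome_metrics(plate_from_lengths(lignano_mean_lengths)))
  expect_equal(sum(m$size_class == "large"), 2)
  expect_equal(sum(m$size_class == "small"), 6)

  # gradually decreasing karyotype: no gap, everything small
  spirale <- c(3.75, 3.75, 3.37, 3.37, 3.07, 3.07)
  m2 <- split_size_classes(chromosome_metrics(plate_from_lengths(spirale)))
  expect_true(all(m2$size_class == "small"))

  m3 <- split_size_classes(chromosome_metrics(plate_from_lengths(c(2, 2))))
  expect_true(all(m3$size_class == "small"))

  set.seed(7)
  for (i in 1:25) {
    al <- round(runif(sample(4:10, 1), 1, 8), 2)
    df <- split_size_classes(chromosome_metrics(plate_from_lengths(al)))
    got <- as.character(df$size_class[order(-df$al_um)])
    expect_equal(got, oracle_size_split(al))
  }
})

test_that("size-class splitting is invariant to uniform rescaling of a plate", {
  set.seed(11)
  al <- runif(8, 1, 6)
  a <- split_size_classes(chromosome_metrics(plate_from_lengths(al)))
  b <- split_size_classes(chromosome_metrics(plate_from_lengths(al * 3.7)))
  expect_equal(as.character(a$size_class), as.character(b$size_class))
  expect_error(split_size_classes(chromosome_metrics(
    plate_from_lengths(5, plate_id = "solo"))), "at least 2")
})

test_that("pair summaries average sorted consecutive pairs across plates", {
  # identical plates: zero SD, sorted pair means
  two <- rbind(plate_from_lengths(c(4, 4, 2, 2), plate_id = "P1"),
               plate_from_lengths(c(4, 4, 2, 2), plate_id = "P2"))
  ps <- summarize_pairs(chromosome_metrics(two))
  expect_equal(ps$al_mean, c(4, 2))
  expect_equal(ps$al_sd, c(0, 0))

  # hand-computed means over sorted, consecutively paired values
  mixed <- rbind(plate_from_lengths(c(4, 4, 2, 2), plate_id = "P1"),
                 plate_from_lengths(c(4.2, 3.8, 2.1, 1.9), plate_id = "P2"))
  ps2 <- summarize_pairs(chromosome_metrics(mixed))
  expect_equal(ps2$al_mean, c(4.0, 2.0))
  expect_equal(ps2$n_plates, c(2, 2))

  # k copies of one plate reproduce that plate with zero SD
  one <- plate_from_lengths(c(5.0, 5.0, 2.1, 2.1, 1.7, 1.7))
  many <- do.call(rbind, lapply(1:5, function(i) {
    x <- one; x$plate_id <- paste0("P", i); x
  }))
  ps3 <- summarize_pairs(chromosome_metrics(many))
  expect_equal(ps3$al_mean, c(5.0, 2.1, 1.7))
  expect_true(all(ps3$al_sd == 0))
  expect_true(all(diff(ps3$al_mean) < 0))   # decreasing size order

  odd <- plate_from_lengths(c(4, 3, 2, 2, 1, 1, 1))
  expect_error(summarize_pairs(chromosome_metrics(odd)), "odd chromosome count")
})
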