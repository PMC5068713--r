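lignano <- macrostomum_profile("lignano")
sp8 <- macrostomum_profile("sp8")

test_that("karyotype categories are defined relative to the species profile", {
  expect_equal(as.character(classify_category(2, 6, FALSE, lignano)), "normal")
  expect_equal(as.character(classify_category(3, 6, FALSE, lignano)), "plus_one_large")
  expect_equal(as.character(classify_category(4, 6, FALSE, lignano)), "plus_two_large")
  # deviant small complement is abnormal even at 2n = 9
  expect_equal(as.character(classify_category(2, 7, FALSE, lignano)), "abnormal")
  # structural anomaly dominates everything
  expect_equal(as.character(classify_category(2, 6, TRUE, lignano)), "abnormal")
  # monosomy of the large pair is abnormal (no 'minus' category exists)
  expect_equal(as.character(classify_category(1, 6, FALSE, lignano)), "abnormal")

  # species with four large chromosomes in its normal complement
  expect_equal(as.character(classify_category(5, 6, FALSE, sp8)), "plus_one_large")
  expect_equal(as.character(classify_category(3, 6, FALSE, sp8)), "abnormal")
  expect_equal(as.character(classify_category(4, 6, FALSE, sp8)), "normal")
})

test_that("a plus category is never returned when the small complement deviates", {
  set.seed(5)
  nl <- sample(0:6, 50, replace = TRUE)
  ns <- sample(0:10, 50, replace = TRUE)
  cat <- classify_category(nl, ns, FALSE, lignano)
  deviant <- ns != 6
  expect_true(all(cat[deviant] == "abnormal"))
})

test_that("specimen calls take the modal plate combination", {
  call <- call_specimen(uniform_plates(10, 3, 6), lignano)
  expect_equal(call$two_n, 9)
  expect_equal(as.character(call$category), "plus_one_large")
  expect_false(call$mosaic)
  expect_false(call$insufficient)

  # one aberrant spread in ten is tolerated
  pc <- uniform_plates(10, 2, 6)
  pc$n_large[10] <- 3
  call2 <- call_specimen(pc, lignano)
  expect_equal(call2$two_n, 8)
  expect_false(call2$mosaic)
  expect_equal(call2$modal_fraction, 0.9)

  expect_error(call_specimen(uniform_plates(10, 2, 6)[0, ], lignano), "no plates")
})

test_that("modal ties break to the smaller 2n and are flagged mosaic", {
  pc <- rbind(uniform_plates(6, 2, 6), uniform_plates(6, 3, 6))
  call <- call_specimen(pc, lignano)
  expect_true(call$mosaic)
  expect_equal(call$two_n, 8)
  expect_equal(as.character(call$category), "normal")
})

test_that("specimens with fewer than the minimum plates are flagged insufficient", {
  call <- call_specimen(uniform_plates(9, 2, 6), lignano)
  expect_true(call$insufficient)
  call2 <- call_specimen(uniform_plates(9, 2, 6), lignano, min_plates = 5)
  expect_false(call2$insufficient)
})

test_that("specimen calls are invariant to plate order", {
  set.seed(13)
  pc <- rbind(uniform_plates(8, 3, 6), uniform_plates(4, 2, 6))
  pc$plate_id <- paste0("P", 1:12)
  a <- call_specimen(pc, lignano)
  b <- call_specimen(pc[sample(12), ], lignano)
  expect_equal(a, b)
})

test_that("population tabulation reproduces counts and one-decimal percentages", {
  calls <- data.frame(
    category = factor(rep(karyotype_categories(), c(16, 77, 36, 5)),
                      levels = karyotype_categories()),
    mosaic = FALSE)
  tab <- tabulate_population(calls, "DV1")
  expect_equal(tab$n, 134)
  expect_equal(c(tab$normal_pct, tab$plus_one_large_pct,
                 tab$plus_two_large_pct, tab$abnormal_pct),
               c(11.9, 57.5, 26.9, 3.7))

  mono <- data.frame(category = factor(rep("normal", 61),
                                       levels = karyotype_categories()),
                     mosaic = FALSE)
  tab2 <- tabulate_population(mono, "LS2")
  expect_equal(c(tab2$normal_pct, tab2$plus_one_large_pct), c(100, 0))

  quarter <- data.frame(category = factor(karyotype_categories(),
                                          levels = karyotype_categories()),
                        mosaic = FALSE)
  tab3 <- tabulate_population(quarter)
  expect_true(all(c(tab3$normal_pct, tab3$plus_one_large_pct,
                    tab3$plus_two_large_pct, tab3$abnormal_pct) == 25))
  expect_error(tabulate_population(calls[0, ]), "no karyotype calls")
})

test_that("percentages sum to 100 within rounding and mosaics count as abnormal", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(30:300, 1)
    calls <- data.frame(
      category = factor(sample(karyotype_categories(), n, replace = TRUE),
                        levels = karyotype_categories()),
      mosaic = runif(n) < 0.1)
    tab <- tabulate_population(calls)
    pct <- c(tab$normal_pct, tab$plus_one_large_pct, tab$plus_two_large_pct,
             tab$abnormal_pct)
    expect_lt(abs(sum(pct) - 100), 0.2)
    expect_equal(tab$abnormal,
                 sum(calls$mosaic | calls$category == "abnormal"))
  }
})

test_that("noise-free synthetic specimens are recovered perfectly from plate counts", {
  spec <- population_spec(c(0.2, 0.5, 0.25, 0.05), n_specimens = 300,
                          mosaic_rate = 0)
  set <- generate_specimen_set(spec, seed = 99)
  calls <- call_specimens(set$plate_counts, lignano)
  expect_false(any(calls$mosaic))
  expect_false(any(calls$insufficient))
  expect_equal(as.character(calls$category), as.character(set$specimens$category))
  expect_equal(calls$n_large, set$specimens$n_large)
  expect_equal(calls$n_small, set$specimens$n_small)
})
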