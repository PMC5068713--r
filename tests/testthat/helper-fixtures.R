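# shared fixtures and independent oracles used across test files

# measurement table built from absolute lengths, split into near-equal arms
# (metacentric shape) unless arm ratios are supplied
plate_from_lengths <- function(al, specimen_id = "S1", plate_id = "P1",
                               arm_ratio = 1) {
  s <- al / (1 + arm_ratio)
  data.frame(specimen_id = specimen_id, plate_id = plate_id,
             short_arm_um = s, long_arm_um = al - s)
}

# Table-2a mean absolute lengths of the 'normal' 2n = 8 karyotype
lignano_mean_lengths <- c(5.27, 5.27, 2.74, 2.74, 2.49, 2.49, 2.24, 2.24)

# brute-force size-class oracle: evaluate every split point of the sorted
# lengths and place the split at the largest adjacent ratio
oracle_size_split <- function(al, gap_ratio = 1.5) {
  al <- sort(al, decreasing = TRUE)
  ratios <- al[-length(al)] / al[-1]
  j <- which.max(ratios)
  if (ratios[j] >= gap_ratio) {
    c(rep("large", j), rep("small", length(al) - j))
  } else {
    rep("small", length(al))
  }
}

# grid-search oracle for the cross viability-selection MLE
oracle_selection_mle <- function(observed, mendelian, step = 1e-4) {
  s <- seq(0, 1, by = step)
  n <- sum(observed)
  ll <- ifelse(rep(observed[1] > 0, length(s)),
               observed[1] * log(mendelian[1] * (1 - s)), 0) -
    n * log(1 - mendelian[1] * s)
  s[which.max(ll)]
}

# plate-count table for one specimen, all plates identical
uniform_plates <- function(n_plates, n_large, n_small, specimen_id = "S1",
                           anomaly = FALSE) {
  data.frame(specimen_id = specimen_id,
             plate_id = paste0("P", seq_len(n_plates)),
             n_large = n_large, n_small = n_small,
             structural_anomaly = anomaly)
}
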