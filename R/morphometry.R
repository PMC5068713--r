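#' Classify centromere position from the arm ratio
#'
#' Assigns the Levan centromere-position class from the arm ratio
#' R = L/S (long arm over short arm): metacentric (`m`) for
#' 1 <= R <= 1.7, submetacentric (`sm`) for 1.7 < R <= 3, subtelocentric
#' (`st`) for 3 < R <= 7 and acrocentric/telocentric (`t`) for R > 7.
#' Boundary values belong to the lower class, so R = 1.7 is `m` and
#' R = 3 is `sm`.
#'
#' @param arm_ratio numeric vector of arm ratios, all >= 1 (arms must be
#'   ordered so that the long arm is the numerator).
#' @return factor with levels `m`, `sm`, `st`, `t`.
#' @examples
#' classify_centromere(c(1, 1.15, 1.85, 3.2, 8))
#' @export
classify_centromere <- function(arm_ratio) {
  if (!is.numeric(arm_ratio) || anyNA(arm_ratio)) {
    stop_karyo("arm_ratio must be numeric without missing values")
  }
  if (any(arm_ratio < 1)) {
    stop_karyo("arm ratio < 1: arms must be ordered with long arm >= short arm")
  }
  cut(arm_ratio, breaks = c(1, 1.7, 3, 7, Inf), labels = c("m", "sm", "st", "t"),
      include.lowest = TRUE, right = TRUE)
}

#' Per-chromosome morphometric metrics
#'
#' Computes, for every measured chromosome, the absolute length
#' AL = S + L, the relative length RL = AL * 100 / (half the summed AL of
#' all chromosomes in its metaphase plate), the arm ratio R = L/S, the
#' centromeric index CI = S/(S + L), and the Levan centromere class.
#' RL is normalised per plate, so within any plate the RL values sum to
#' 200 (each chromosome is expressed relative to the haploid complement
#' length).
#'
#' @param measures data frame with columns `specimen_id`, `plate_id`,
#'   `short_arm_um`, `long_arm_um`; one row per chromosome. Arm lengths are
#'   in micrometres and must be positive, with `long_arm_um >= short_arm_um`.
#' @return the input data frame with columns `al_um`, `rl_pct`, `arm_ratio`,
#'   `ci` and `centromere_class` appended.
#' @seealso [classify_centromere()], [split_size_classes()], [summarize_pairs()]
#' @export
chromosome_metrics <- function(measures) {
  check_columns(measures, c("specimen_id", "plate_id", "short_arm_um", "long_arm_um"),
                "measurement table")
  s <- measures$short_arm_um
  l <- measures$long_arm_um
  if (!is.numeric(s) || !is.numeric(l) || anyNA(s) || anyNA(l)) {
    stop_karyo("arm lengths must be numeric and non-missing")
  }
  if (any(s <= 0) || any(l <= 0)) {
    stop_karyo("arm lengths must be positive; offending row(s): ",
               paste(which(s <= 0 | l <= 0), collapse = ", "))
  }
  if (any(l < s)) {
    stop_karyo("long arm shorter than short arm; offending row(s): ",
               paste(which(l < s), collapse = ", "))
  }
  al <- s + l
  plate <- plate_key(measures$specimen_id, measures$plate_id)
  plate_total <- rowsum(al, plate)[plate, 1]
  out <- measures
  out$al_um <- al
  out$rl_pct <- al * 100 / (plate_total / 2)
  out$arm_ratio <- l / s
  out$ci <- s / al
  out$centromere_class <- classify_centromere(out$arm_ratio)
  out
}

#' Split the chromosomes of each plate into large and small size classes
#'
#' Within each metaphase plate, chromosomes are ranked by decreasing
#' absolute length and the candidate split point is placed at the largest
#' adjacent length ratio. If that ratio reaches `gap_ratio` the chromosomes
#' above the split are labelled `large` and the rest `small`; otherwise the
#' karyotype is treated as uniform in size and every chromosome is `small`
#' (as in species whose chromosomes decrease gradually in length). The
#' labelling is invariant to uniform rescaling of a plate's lengths, so
#' chromosome condensation stage does not affect it.
#'
#' @param metrics output of [chromosome_metrics()] (needs `al_um`).
#' @param gap_ratio minimum adjacent-length ratio accepted as a genuine size
#'   gap; default 1.5. The bimodal karyotypes analysed here show a gap of
#'   roughly 1.9, while gradual karyotypes stay below roughly 1.2.
#' @return `metrics` with a `size_class` factor (`large`/`small`) appended.
#' @export
split_size_classes <- function(metrics, gap_ratio = 1.5) {
  check_columns(metrics, c("specimen_id", "plate_id", "al_um"), "metrics table")
  check_number(gap_ratio, "gap_ratio", lower = 1)
  plate <- plate_key(metrics$specimen_id, metrics$plate_id)
  sizes <- tabulate(plate)
  if (any(sizes < 2L)) {
    stop_karyo("every plate needs at least 2 chromosomes to be size-classified")
  }
  ord <- order(plate, -metrics$al_um)
  al <- metrics$al_um[ord]
  pl <- plate[ord]
  n <- length(al)
  same <- pl[-n] == pl[-1]                    # adjacent rows in the same plate
  ratio <- ifelse(same, al[-n] / al[-1], -Inf)
  # index (within the full sorted vector) of each plate's largest adjacent
  # ratio, found for all plates at once via a secondary sort
  grp <- pl[-n]
  o2 <- order(grp, -ratio)
  best <- o2[!duplicated(grp[o2])]
  keep <- best[ratio[best] >= gap_ratio]      # plates with a genuine gap
  label <- rep("small", n)
  if (length(keep) > 0L) {
    rank_in_plate <- sequence(sizes)
    cut_rank <- rep(NA_integer_, length(sizes))
    cut_rank[pl[keep]] <- rank_in_plate[keep]
    label[rank_in_plate <= cut_rank[pl] & !is.na(cut_rank[pl])] <- "large"
  }
  out <- metrics
  out$size_class <- factor("small", levels = c("large", "small"))
  out$size_class[ord] <- factor(label, levels = c("large", "small"))
  out
}

#' Summarize euploid plates as ranked chromosome pairs
#'
#' Within each plate, chromosomes are sorted by decreasing absolute length and
#' paired consecutively (ranks 1, 1, 2, 2, ...); no homology information is
#' available from measurements alone, so rank-pairing is the only defensible
#' rule, and it can slightly overestimate between-pair size differences.
#' Per pair rank, the mean and standard deviation of each metric are taken
#' across all plates and both homologs, and the modal centromere class is
#' reported.
#'
#' @param metrics output of [chromosome_metrics()]. Every plate must carry the
#'   same even number of chromosomes; aneuploid plates cannot be summarised as
#'   pairs and should go through karyotype calling instead.
#' @return data frame with one row per pair rank: `pair`, `n_plates`, then
#'   `mean`/`sd` columns for AL, RL, L, S, R and CI, and `modal_class`.
#' @export
summarize_pairs <- function(metrics) {
  check_columns(metrics, c("specimen_id", "plate_id", "al_um", "rl_pct",
                           "long_arm_um", "short_arm_um", "arm_ratio", "ci",
                           "centromere_class"),
                "metrics table")
  plate <- plate_key(metrics$specimen_id, metrics$plate_id)
  counts <- tabulate(plate)
  if (length(unique(counts)) != 1L) {
    stop_karyo("plates have unequal chromosome counts; summarize only one karyotype at a time")
  }
  if (counts[1] %% 2L != 0L) {
    stop_karyo("odd chromosome count (", counts[1], "): aneuploid plates cannot be ",
               "summarised as pairs; use the karyotype-calling functions instead")
  }
  ord <- order(plate, -metrics$al_um)
  m <- metrics[ord, ]
  pair_rank <- rep(ceiling(seq_len(counts[1]) / 2), length(counts))

  one <- function(x) c(mean = mean(x), sd = stats::sd(x))
  stat_cols <- c(al_um = "al", rl_pct = "rl", long_arm_um = "l",
                 short_arm_um = "s", arm_ratio = "r", ci = "ci")
  out <- data.frame(pair = sort(unique(pair_rank)))
  for (col in names(stat_cols)) {
    st <- vapply(split(m[[col]], pair_rank), one, numeric(2))
    out[[paste0(stat_cols[[col]], "_mean")]] <- st["mean", ]
    out[[paste0(stat_cols[[col]], "_sd")]] <- st["sd", ]
  }
  out$modal_class <- vapply(split(as.character(m$centromere_class), pair_rank),
                            function(x) names(sort(table(x), decreasing = TRUE))[1],
                            character(1))
  out$n_plates <- length(counts)
  out[order(-out$al_mean), , drop = FALSE]
}
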