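# Tabular input/output for the four pipeline schemas, plus the end-to-end
# pipeline driver. All tables are plain delimited text (comma or tab).

karyo_schemas <- list(
  measurements = list(
    required = c("specimen_id", "plate_id", "short_arm_um", "long_arm_um"),
    numeric = c("short_arm_um", "long_arm_um"),
    positive = c("short_arm_um", "long_arm_um")),
  plate_counts = list(
    required = c("specimen_id", "plate_id", "n_large", "n_small"),
    numeric = c("n_large", "n_small"),
    positive = character(0)),
  population_counts = list(
    required = c("line", "c8", "c9", "c10"),
    numeric = c("c8", "c9", "c10"),
    positive = character(0)),
  cross_counts = list(
    required = c("parent1", "parent2", "c8", "c9", "c10"),
    numeric = c("parent1", "parent2", "c8", "c9", "c10"),
    positive = character(0)))

#' Read and validate a pipeline table
#'
#' Reads one of the four delimited table schemas used by the pipeline
#' (comma- or tab-separated, sniffed from the header line) and validates
#' column presence, numeric types and sign constraints, reporting offending
#' rows by line number.
#'
#' Schemas: `measurements` (specimen_id, plate_id, short_arm_um,
#' long_arm_um), `plate_counts` (specimen_id, plate_id, n_large, n_small
#' \[, structural_anomaly\]), `population_counts` (line, c8, c9, c10
#' \[, abnormal\]), `cross_counts` (parent1, parent2, c8, c9, c10
#' \[, n_crosses\]).
#'
#' @param path file path.
#' @param schema one of `"measurements"`, `"plate_counts"`,
#'   `"population_counts"`, `"cross_counts"`.
#' @return validated data frame.
#' @export
read_karyo_table <- function(path, schema = names(karyo_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_karyo("file not found: ", path,
                                     class = "karyopoly_schema_error")
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop_karyo("empty file: ", path,
                                       class = "karyopoly_schema_error")
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_karyo("no data rows in ", path,
                                 class = "karyopoly_schema_error")
  sc <- karyo_schemas[[schema]]
  check_columns(df, sc$required, paste0(schema, " table '", path, "'"))
  for (col in sc$numeric) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(vals)) {
      stop_karyo("non-numeric values in column '", col, "' of ", path,
                 " at line(s): ",
                 paste(which(is.na(vals)) + 1L, collapse = ", "),
                 class = "karyopoly_schema_error")
    }
    df[[col]] <- vals
    bad <- if (col %in% sc$positive) vals <= 0 else vals < 0
    if (any(bad)) {
      stop_karyo("invalid (non-positive) values in column '", col, "' of ",
                 path, " at line(s): ", paste(which(bad) + 1L, collapse = ", "),
                 class = "karyopoly_schema_error")
    }
  }
  if (schema == "plate_counts") {
    if (is.null(df$structural_anomaly)) df$structural_anomaly <- FALSE
    df$structural_anomaly <- as.logical(df$structural_anomaly)
  }
  if (schema == "cross_counts" && is.null(df$n_crosses)) df$n_crosses <- NA_integer_
  df
}

#' Write a pipeline table
#'
#' @param df data frame.
#' @param path output path; written as CSV.
#' @export
write_karyo_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Independent-assortment test report for population counts
#'
#' Runs [estimate_gamete_freqs()], [expected_karyotype_freqs()] and
#' [assortment_chisq()] on each line of a population-count table and combines
#' the per-line p-values with [fisher_combined()] under both degrees-of-
#' freedom conventions.
#'
#' @param pop_counts data frame with columns `line`, `c8`, `c9`, `c10`
#'   ('abnormal' specimens must already be excluded from these three classes).
#' @return list with `per_line` (one row per line: p, q, expected
#'   percentages, chi-squared, df, p-value) and `combined` (list of the two
#'   [fisher_combined()] results).
#' @export
assortment_report <- function(pop_counts) {
  check_columns(pop_counts, c("line", "c8", "c9", "c10"), "population-count table")
  rows <- lapply(seq_len(nrow(pop_counts)), function(i) {
    ct <- pop_counts[i, ]
    test <- assortment_chisq(ct$c8, ct$c9, ct$c10)
    ex <- expected_karyotype_freqs(unname(test$estimate["p"]))
    data.frame(line = ct$line, n = ct$c8 + ct$c9 + ct$c10,
               c8 = ct$c8, c9 = ct$c9, c10 = ct$c10,
               p = unname(test$estimate["p"]), q = unname(test$estimate["q"]),
               exp8_pct = round(100 * ex[["p8"]], 1),
               exp9_pct = round(100 * ex[["p9"]], 1),
               exp10_pct = round(100 * ex[["p10"]], 1),
               chi_sq = unname(test$statistic), df = unname(test$parameter),
               p_value = test$p.value)
  })
  per_line <- do.call(rbind, rows)
  combined <- NULL
  if (nrow(per_line) > 1L) {
    combined <- list(standard = fisher_combined(per_line$p_value, "standard"),
                     fixed2 = fisher_combined(per_line$p_value, "fixed2"))
  }
  list(per_line = per_line, combined = combined)
}

#' Mendelian cross-test report
#'
#' Runs [cross_chisq()] on every row of a cross-count table and, where the
#' 2n = 8 class is a possible offspring class, appends the maximum-likelihood
#' viability-selection estimate of [estimate_selection_from_cross()].
#'
#' @param crosses data frame with columns `parent1`, `parent2`, `c8`, `c9`,
#'   `c10` and optionally `n_crosses`.
#' @return data frame with observed counts, expected percentages,
#'   chi-squared, df, p-value, `s_hat` and its confidence bounds (NA where s
#'   is unidentifiable).
#' @export
cross_report <- function(crosses) {
  check_columns(crosses, c("parent1", "parent2", "c8", "c9", "c10"),
                "cross-count table")
  rows <- lapply(seq_len(nrow(crosses)), function(i) {
    cr <- crosses[i, ]
    obs <- c(cr$c8, cr$c9, cr$c10)
    parents <- c(cr$parent1, cr$parent2)
    test <- cross_chisq(obs, parents,
                        n_crosses = if (!is.null(cr$n_crosses)) cr$n_crosses else NA)
    probs <- offspring_dist(parents[1], parents[2])
    sel <- if (probs[1] > 0) estimate_selection_from_cross(obs, parents) else NULL
    data.frame(parent1 = cr$parent1, parent2 = cr$parent2,
               n = sum(obs), n_crosses = test$n_crosses,
               c8 = obs[1], c9 = obs[2], c10 = obs[3],
               exp8_pct = round(100 * probs[[1]], 1),
               exp9_pct = round(100 * probs[[2]], 1),
               exp10_pct = round(100 * probs[[3]], 1),
               chi_sq = unname(test$statistic), df = unname(test$parameter),
               p_value = test$p.value,
               s_hat = if (is.null(sel)) NA_real_ else sel$s_hat,
               s_lower = if (is.null(sel)) NA_real_ else sel$ci[["lower"]],
               s_upper = if (is.null(sel)) NA_real_ else sel$ci[["upper"]])
  })
  do.call(rbind, rows)
}

#' Run the measurement-to-assortment pipeline
#'
#' Chains the pipeline stages on a measurement table: per-chromosome metrics,
#' size-class splitting, per-plate chromosome counts, specimen karyotype
#' calls, population tabulation, and (when the population segregates the
#' three euploid/aneuploid-large classes) the independent-assortment test.
#'
#' @param measurements measurement data frame or path to a measurement table.
#' @param profile a [species_profile()].
#' @param line_name population label for the tabulation.
#' @param gap_ratio see [split_size_classes()].
#' @param min_plates,majority_fraction see [call_specimen()].
#' @param out_dir optional directory; when given, the stage outputs are
#'   written there as CSV files plus a plain-text report.
#' @return list with `metrics`, `plate_counts`, `calls`, `population`,
#'   `assortment` (an `htest`, or NULL if not applicable).
#' @export
run_pipeline <- function(measurements, profile, line_name = "population",
                         gap_ratio = 1.5, min_plates = 10,
                         majority_fraction = 0.9, out_dir = NULL) {
  if (is.character(measurements)) {
    measurements <- read_karyo_table(measurements, "measurements")
  }
  metrics <- split_size_classes(chromosome_metrics(measurements), gap_ratio)
  key <- plate_key(metrics$specimen_id, metrics$plate_id)
  first <- !duplicated(key)
  plate_counts <- data.frame(
    specimen_id = metrics$specimen_id[first],
    plate_id = metrics$plate_id[first],
    n_large = as.integer(rowsum((metrics$size_class == "large") + 0L, key)[, 1]),
    n_small = as.integer(rowsum((metrics$size_class == "small") + 0L, key)[, 1]),
    structural_anomaly = FALSE, row.names = NULL)
  calls <- call_specimens(plate_counts, profile, min_plates, majority_fraction)
  population <- tabulate_population(calls, line_name)
  assortment <- NULL
  usable <- calls[!calls$insufficient & !calls$mosaic, , drop = FALSE]
  cnt <- table(factor(usable$category, levels = karyotype_categories()))
  if (sum(cnt[1:3]) > 0) {
    assortment <- assortment_chisq(cnt[[1]], cnt[[2]], cnt[[3]])
  }
  out <- list(metrics = metrics, plate_counts = plate_counts, calls = calls,
              population = population, assortment = assortment)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_karyo_table(metrics, file.path(out_dir, "chromosome_metrics.csv"))
    write_karyo_table(plate_counts, file.path(out_dir, "plate_counts.csv"))
    write_karyo_table(calls, file.path(out_dir, "karyotype_calls.csv"))
    write_karyo_table(population, file.path(out_dir, "population_table.csv"))
    rpt <- file.path(out_dir, "report.txt")
    con <- file(rpt, "w"); on.exit(close(con), add = TRUE)
    writeLines(c(sprintf("karyopoly pipeline report: %s", line_name),
                 sprintf("specimens called: %d (plates: %d)",
                         nrow(calls), nrow(plate_counts)),
                 utils::capture.output(print(population))), con)
    if (!is.null(assortment)) {
      writeLines(utils::capture.output(print(assortment)), con)
    }
  }
  out
}
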