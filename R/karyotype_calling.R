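#' Species karyotype profile
#'
#' A profile records what the 'normal' euploid karyotype of a species looks
#' like in terms of large and small chromosome pairs; karyotype categories are
#' defined relative to it.
#'
#' @param species_name character label.
#' @param normal_large_pairs number of large chromosome pairs in the normal
#'   karyotype (may be 0 for species without a distinct large class).
#' @param normal_small_pairs number of small chromosome pairs (>= 1).
#' @return an object of class `species_profile`.
#' @examples
#' species_profile("M. lignano", 1, 3)   # normal 2n = 8
#' @export
species_profile <- function(species_name, normal_large_pairs, normal_small_pairs) {
  check_number(normal_large_pairs, "normal_large_pairs", lower = 0)
  check_number(normal_small_pairs, "normal_small_pairs", lower = 1)
  structure(list(species_name = species_name,
                 normal_large_pairs = as.integer(normal_large_pairs),
                 normal_small_pairs = as.integer(normal_small_pairs)),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  two_n <- 2L * (x$normal_large_pairs + x$normal_small_pairs)
  cat(sprintf("Species profile: %s ('normal' 2n = %d: %d large + %d small)\n",
              x$species_name, two_n, 2L * x$normal_large_pairs,
              2L * x$normal_small_pairs))
  invisible(x)
}

#' Built-in species profiles
#'
#' Profiles for the four *Macrostomum* species studied with this pipeline:
#' *M. lignano* (normal 2n = 8: two large, six small metacentrics),
#' *Macrostomum* sp. 8 (2n = 10: four large, six small), and the invariant-
#' karyotype species *M. spirale* (2n = 6) and *M. hystrix* (2n = 6), which
#' have no distinct large class.
#'
#' @param species one of `"lignano"`, `"sp8"`, `"spirale"`, `"hystrix"`.
#' @return a [species_profile()].
#' @export
macrostomum_profile <- function(species = c("lignano", "sp8", "spirale", "hystrix")) {
  species <- match.arg(species)
  switch(species,
         lignano = species_profile("Macrostomum lignano", 1, 3),
         sp8     = species_profile("Macrostomum sp. 8", 2, 3),
         spirale = species_profile("Macrostomum spirale", 0, 3),
         hystrix = species_profile("Macrostomum hystrix", 0, 3))
}

#' Karyotype category of a chromosome-count combination
#'
#' Categories are defined relative to a species profile: `normal` matches the
#' profile exactly; `plus_one_large` / `plus_two_large` carry one or two
#' additional large chromosomes with the small complement intact; everything
#' else — structural anomalies, any deviation in the small complement, or
#' fewer large chromosomes than normal (monosomy) — is `abnormal`.
#'
#' @param n_large,n_small integer vectors of large/small chromosome counts.
#' @param structural_anomaly logical vector: a rearranged or unknown-origin
#'   chromosome is present.
#' @param profile a [species_profile()].
#' @return factor with levels `normal`, `plus_one_large`, `plus_two_large`,
#'   `abnormal`.
#' @export
classify_category <- function(n_large, n_small, structural_anomaly, profile) {
  stopifnot(inherits(profile, "species_profile"))
  if (any(n_large < 0) || any(n_small < 0)) stop_karyo("chromosome counts must be non-negative")
  nl0 <- 2L * profile$normal_large_pairs
  ns0 <- 2L * profile$normal_small_pairs
  out <- rep("abnormal", length(n_large))
  ok_small <- !structural_anomaly & n_small == ns0
  out[ok_small & n_large == nl0] <- "normal"
  out[ok_small & n_large == nl0 + 1L] <- "plus_one_large"
  out[ok_small & n_large == nl0 + 2L] <- "plus_two_large"
  factor(out, levels = karyotype_categories())
}

#' @rdname classify_category
#' @export
karyotype_categories <- function() {
  c("normal", "plus_one_large", "plus_two_large", "abnormal")
}

#' Call a specimen's karyotype from replicate metaphase plates
#'
#' The karyotype of a specimen is the modal (n_large, n_small, anomaly)
#' combination over its plates. Specimens with fewer than `min_plates` plates
#' are flagged `insufficient` and should be excluded from population tables.
#' A specimen is flagged `mosaic` when the modal combination accounts for less
#' than `majority_fraction` of its plates — replicate plates are exactly what
#' makes within-individual mosaicism detectable. Modal ties are broken toward
#' the smaller total chromosome number (conservative against over-calling
#' aneuploidy) and always flagged mosaic.
#'
#' @param plate_counts data frame for one specimen with columns `plate_id`,
#'   `n_large`, `n_small` and optionally `structural_anomaly` (logical,
#'   default `FALSE`).
#' @param profile a [species_profile()].
#' @param min_plates minimum number of plates for a reliable call (default 10).
#' @param majority_fraction minimal fraction of plates the modal combination
#'   must reach for a non-mosaic call (default 0.9, tolerating one aberrant
#'   spread in ten; broken or overlapping spreads are common artifacts).
#' @return one-row data frame: `specimen_id`, `n_large`, `n_small`, `two_n`,
#'   `structural_anomaly`, `category`, `mosaic`, `insufficient`, `n_plates`,
#'   `modal_fraction`.
#' @export
call_specimen <- function(plate_counts, profile, min_plates = 10,
                          majority_fraction = 0.9) {
  if (NROW(plate_counts) == 0L) stop_karyo("no plates supplied for specimen call")
  check_columns(plate_counts, c("n_large", "n_small"), "plate-count table")
  if (is.null(plate_counts$structural_anomaly)) plate_counts$structural_anomaly <- FALSE
  if (!is.null(plate_counts$specimen_id) &&
      length(unique(plate_counts$specimen_id)) > 1L) {
    stop_karyo("call_specimen expects plates from a single specimen; see call_specimens()")
  }
  n <- nrow(plate_counts)
  key <- paste(plate_counts$n_large, plate_counts$n_small,
               as.logical(plate_counts$structural_anomaly), sep = "/")
  tab <- table(key)
  top <- tab[tab == max(tab)]
  tied <- length(top) > 1L
  pick <- names(top)
  if (tied) {
    parts <- do.call(rbind, strsplit(pick, "/", fixed = TRUE))
    two_n <- as.integer(parts[, 1]) + as.integer(parts[, 2])
    pick <- pick[order(two_n, parts[, 3])][1]   # smaller 2n, anomaly-free first
  }
  parts <- strsplit(pick, "/", fixed = TRUE)[[1]]
  n_large <- as.integer(parts[1]); n_small <- as.integer(parts[2])
  anomaly <- as.logical(parts[3])
  modal_fraction <- max(tab) / n
  data.frame(
    specimen_id = if (!is.null(plate_counts$specimen_id)) plate_counts$specimen_id[1] else NA,
    n_large = n_large, n_small = n_small, two_n = n_large + n_small,
    structural_anomaly = anomaly,
    category = classify_category(n_large, n_small, anomaly, profile),
    mosaic = tied || modal_fraction < majority_fraction,
    insufficient = n < min_plates,
    n_plates = n, modal_fraction = modal_fraction,
    stringsAsFactors = FALSE)
}

#' Call every specimen in a plate-count table
#'
#' @param plate_counts data frame with `specimen_id` plus the columns of
#'   [call_specimen()].
#' @inheritParams call_specimen
#' @return data frame with one row per specimen (see [call_specimen()]).
#' @export
call_specimens <- function(plate_counts, profile, min_plates = 10,
                           majority_fraction = 0.9) {
  check_columns(plate_counts, c("specimen_id", "n_large", "n_small"),
                "plate-count table")
  pieces <- lapply(split(plate_counts, plate_counts$specimen_id),
                   call_specimen, profile = profile, min_plates = min_plates,
                   majority_fraction = majority_fraction)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Tabulate karyotype calls for a population
#'
#' Counts specimens per karyotype category for one line or culture and derives
#' percentages (one decimal). Mosaic specimens are tabulated under `abnormal`;
#' calls flagged `insufficient` are dropped with a warning.
#'
#' @param calls data frame of karyotype calls ([call_specimens()] output).
#' @param line_name label for the line/culture.
#' @return one-row data frame: `line`, `n`, then `<category>` counts and
#'   `<category>_pct` percentages.
#' @export
tabulate_population <- function(calls, line_name = "population") {
  if (NROW(calls) == 0L) stop_karyo("no karyotype calls to tabulate")
  check_columns(calls, c("category", "mosaic"), "call table")
  if (!is.null(calls$insufficient) && any(calls$insufficient)) {
    warning(sum(calls$insufficient), " specimen(s) with too few plates dropped")
    calls <- calls[!calls$insufficient, , drop = FALSE]
    if (nrow(calls) == 0L) stop_karyo("no specimen had enough plates to be tabulated")
  }
  cat <- as.character(calls$category)
  cat[calls$mosaic] <- "abnormal"
  cat <- factor(cat, levels = karyotype_categories())
  counts <- table(cat)
  total <- sum(counts)
  out <- data.frame(line = line_name, n = total)
  for (lv in names(counts)) out[[lv]] <- as.integer(counts[[lv]])
  for (lv in names(counts)) out[[paste0(lv, "_pct")]] <- round(100 * counts[[lv]] / total, 1)
  out
}
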