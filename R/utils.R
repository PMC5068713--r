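# internal helpers: seeded evaluation and input validation

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# integer group codes for (specimen, plate) pairs; levels in first-appearance
# order, no cross-product of levels (plates can number in the hundreds of
# thousands)
plate_key <- function(specimen_id, plate_id) {
  k <- paste(specimen_id, plate_id, sep = "\r")
  match(k, unique(k))
}

stop_karyo <- function(..., class = "karyopoly_error") {
  stop(errorCondition(paste0(...), class = c(class, "karyopoly_error")))
}

check_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_karyo(what, " is missing required column(s): ",
               paste(missing, collapse = ", "),
               class = "karyopoly_schema_error")
  }
  invisible(df)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_karyo(name, " must be a single number in [", lower, ", ", upper, "]")
  }
  invisible(x)
}
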