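# internal helpers shared across the pipeline

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

# run expr with a local RNG state seeded from `seed`; the caller's
# .Random.seed is untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# canonical zero-padded well label: "A1" -> "A01"; labels, never indices
normalize_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  ok <- grepl("^[A-P][0-9]{1,2}$", well)
  if (any(!ok & !is.na(well))) {
    stop("malformed well label(s): ",
         paste(unique(well[!ok & !is.na(well)]), collapse = ", "),
         call. = FALSE)
  }
  row <- substr(well, 1, 1)
  col <- as.integer(substring(well, 2))
  if (any(col < 1 | col > 24, na.rm = TRUE)) {
    stop("well column out of range 1-24", call. = FALSE)
  }
  sprintf("%s%02d", row, col)
}

# key strings for grouping without factor overhead surprises
key2 <- function(a, b) paste(a, b, sep = "\r")
key3 <- function(a, b, c) paste(a, b, c, sep = "\r")

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}
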