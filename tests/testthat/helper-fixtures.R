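# fixture builders shared across test files; everything is generated in
# code, nothing is read from disk unless a test writes it first

REFS6 <- paste0("ref", 1:6)

# hand-buildable quantity table: one plate, 6 references plus extra
# targets, two technical replicates per (sample, target)
# values: named list sample_id -> named numeric target -> sample-level ng;
# tech reps are value * (1 +/- half_spread)
build_quants <- function(values, targets = c(REFS6, "t_pre"),
                         half_spread = 0, plate = "P1") {
  rows <- list()
  for (s in names(values)) {
    for (tg in targets) {
      v <- values[[s]][[tg]]
      if (is.null(v) || is.na(v)) next
      for (tr in 1:2) {
        fac <- if (tr == 1) 1 + half_spread else 1 - half_spread
        rows[[length(rows) + 1L]] <- data.frame(
          plate_id = plate, strain_id = s, bio_rep = "A",
          tech_rep = tr, target_id = tg, ng = v * fac,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# uniform-background plate: n_bg identical samples at the plate median
# plus one distinctive test sample; medians are then immune to where the
# test sample lands
uniform_plate <- function(test_values, n_bg = 20, targets = c(REFS6, "t_pre"),
                          bg_value = 1) {
  vals <- stats::setNames(
    rep(list(stats::setNames(rep(bg_value, length(targets)), targets)), n_bg),
    sprintf("bg%02d", seq_len(n_bg)))
  vals$test <- stats::setNames(test_values[targets], targets)
  build_quants(vals, targets = targets)
}

# independent slow hypergeometric upper tail by direct summation
hyper_tail_direct <- function(k, N, K, n) {
  hi <- min(K, n)
  if (k > hi) return(0)
  if (k <= 0) return(1)
  sum(choose(K, k:hi) * choose(N - K, n - (k:hi))) / choose(N, n)
}

# does a computed value, printed to 3 significant digits by either
# rounding or truncation, match a published 3-digit figure?
matches_3sig <- function(computed, printed) {
  e <- floor(log10(abs(computed)))
  mant <- computed / 10^e
  pm <- printed / 10^floor(log10(abs(printed)))
  isTRUE(all.equal(round(mant, 2), pm, tolerance = 1e-9)) ||
    isTRUE(all.equal(floor(mant * 100) / 100, pm, tolerance = 1e-9))
}
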