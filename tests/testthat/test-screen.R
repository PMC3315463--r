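test_that("rank ordering is descending with average ties and matches sort", {
  expect_equal(unname(rank_strains(c(a = 4, b = 2, c = 1))), c(1, 2, 3))
  expect_equal(unname(rank_strains(c(a = 3, b = 3, c = 1))), c(1.5, 1.5, 3))

  set.seed(6)
  v <- stats::setNames(round(rnorm(1000), 2), sprintf("s%04d", 1:1000))
  r <- rank_strains(v)
  ord <- order(-v, na.last = TRUE)
  # sort-based oracle ignoring ties: positions agree where values unique
  uniq <- !(v %in% v[duplicated(v)])
  pos <- match(names(v), names(v)[ord])
  expect_equal(r[uniq], stats::setNames(as.numeric(pos[uniq]),
                                        names(v)[uniq]))
  # NA strains are excluded, not ranked
  v[5] <- NA
  expect_true(is.na(rank_strains(v)[5]))
})

test_that("composite rank averages targets and flags sparse strains", {
  ranks <- list(t1 = c(a = 1, b = 2, c = 3),
                t2 = c(a = 1, b = 3, c = 2),
                t3 = c(a = 1, b = 2, c = 3),
                t4 = c(a = 1, b = 3, c = 2),
                t5 = c(a = 1, b = 2, c = 3))
  comp <- composite_rank(ranks)
  expect_equal(comp$composite_rank[comp$strain == "a"], 1)
  expect_equal(comp$strain[1], "a")    # rank-1 everywhere is the global top

  r2 <- list(t1 = c(a = 1, b = 3), t2 = c(a = 3, b = 5),
             t3 = c(a = 5, b = 7), t4 = c(a = 7, b = 9),
             t5 = c(a = 9, b = 1))
  expect_equal(composite_rank(r2)$composite_rank, c(5, 5))
  # permuting target order changes nothing
  expect_equal(composite_rank(r2[c(3, 1, 5, 2, 4)])$composite_rank, c(5, 5))

  r3 <- list(t1 = c(a = 1, b = 2), t2 = c(a = 1, b = 2),
             t3 = c(a = 1, b = NA))
  c3 <- composite_rank(r3, min_targets = 3)
  expect_false(c3$flagged[c3$strain == "a"])
  expect_true(c3$flagged[c3$strain == "b"])
  expect_equal(c3$strain[nrow(c3)], "b")   # flagged strains placed last
})

test_that("splicing-efficiency index divides precursor by total", {
  expect_equal(splicing_efficiency(1.3, 1.3), 1)
  expect_equal(splicing_efficiency(2, 1), 2)
  expect_warning(out <- splicing_efficiency(2, 0), "nonpositive")
  expect_true(is.na(out))
})

test_that("splicing versus transcriptional spikes are discriminated end to end", {
  base <- list(n_strains = 150, frac_spiked = 0.1, spike_log2_effect = 2,
               tech_cv = 0.02, yield_log2_sd = 0.5, dropout_rate = 0)
  for (mode in c("splicing", "transcriptional")) {
    cfg <- do.call(sim_config, c(base, list(spike_mode = mode, seed = 17)))
    scr <- simulate_screen(cfg)
    norm <- normalize_screen(quantify_cp(scr$cp, scr$curve_points),
                             reference_targets = names(cfg$reference_abundances))
    pre <- rowMeans(rel_matrix(norm, "TEF5_pre", log2 = FALSE))
    tot <- rowMeans(rel_matrix(norm, "TEF5_mRNA", log2 = FALSE))
    eff <- splicing_efficiency(pre, tot[names(pre)])
    spiked <- scr$truth$strains$strain_id[scr$truth$strains$spiked]
    med_spiked <- median(eff[spiked], na.rm = TRUE)
    if (mode == "splicing") {
      # precursor up 4x, total flat: index ~ 4
      expect_equal(med_spiked / median(eff[setdiff(names(eff), spiked)],
                                       na.rm = TRUE),
                   4, tolerance = 0.15)
    } else {
      # both up: the index cancels the transcriptional increase
      expect_equal(med_spiked / median(eff[setdiff(names(eff), spiked)],
                                       na.rm = TRUE),
                   1, tolerance = 0.15)
    }
  }
})

test_that("hypergeometric enrichment is exact and agrees with stats::phyper", {
  et <- enrichment_test(N = 5122, K = 68, n = 50, k = 38)
  expect_equal(et$p, phyper(37, 68, 5122 - 68, 50, lower.tail = FALSE),
               tolerance = 1e-12)
  # certain event: every background strain annotated
  expect_equal(enrichment_test(100, 100, 10, 10)$p, 1)
  # single-term tail when the whole top list is annotated
  expect_equal(enrichment_test(5122, 68, 14, 14)$p,
               exp(lchoose(68, 14) - lchoose(5122, 14)), tolerance = 1e-12)
  expect_error(enrichment_test(10, 5, 4, 5), "inconsistent")

  set.seed(3)
  for (i in 1:25) {
    N <- sample(5:2000, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(enrichment_test(N, K, n, k)$p,
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # monotone: more annotated hits never raise the p-value
  ps <- vapply(0:20, function(k) enrichment_test(1000, 50, 40, k)$p,
               numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("candidate report joins calls, max d, ranks, and set enrichment", {
  set.seed(55)
  G <- 2000
  strains <- sprintf("s%04d", 1:G)
  spiked <- strains[1:30]
  mk <- function(shift_set, seed) {
    set.seed(seed)
    x <- matrix(rnorm(G * 4, 0, 0.3), G, 4, dimnames = list(strains, NULL))
    x[shift_set, ] <- x[shift_set, ] + 2
    x
  }
  fits <- list(U3_pre = sam_one_class(mk(spiked, 1), seed = 1),
               TUB3_pre = sam_one_class(mk(spiked[1:8], 2), seed = 2))
  ranks <- lapply(fits, function(f) rank_strains(
    stats::setNames(f$table$mean, f$table$strain)))
  comp <- composite_rank(ranks, min_targets = 2)
  rep_out <- candidate_report(fits, comp,
                              gene_sets = list(splicing = spiked),
                              top_n = c(50, 200))
  expect_true(all(diff(rep_out$strains$max_d) <= 1e-12))  # descending max d
  # a strain significant for exactly one target appears once, "none" elsewhere
  only1 <- intersect(spiked[9:30],
                     rep_out$candidates$strain[
                       rep_out$candidates$call_U3_pre == "positive"])
  rows <- rep_out$candidates[rep_out$candidates$strain %in% only1, ]
  expect_gt(nrow(rows), 0)
  expect_true(all(rows$call_TUB3_pre == "none"))
  expect_equal(sum(rep_out$strains$strain %in% spiked), length(spiked))
  # 30 spiked "splicing" strains in 2000: strongly enriched in the top 50
  p50 <- rep_out$enrichment$p[rep_out$enrichment$top_n == 50]
  expect_lt(p50, 1e-10)
  # no significant strains anywhere: empty but valid report
  f0 <- sam_one_class(matrix(rnorm(200, 0, 0.2), 50, 4,
                             dimnames = list(strains[1:50], NULL)),
                      delta = 10, seed = 3)
  rep0 <- candidate_report(list(U3_pre = f0))
  expect_equal(nrow(rep0$candidates), 0L)
  expect_null(rep0$enrichment)
  # an empty gene set is skipped with a warning
  expect_warning(candidate_report(fits, comp,
                                  gene_sets = list(empty = character(0))),
                 "empty")
})
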