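test_that("replicate CV matches hand computation and edge rules", {
  expect_equal(replicate_cv(c(5, 5)), 0)
  expect_equal(replicate_cv(c(1, 2)), 0.4714045, tolerance = 1e-6)
  expect_true(is.na(replicate_cv(c(3, NA))))
  expect_error(replicate_cv(c(-1, 1)), "zero")
})

test_that("CV filter boundary is strict: 0.25 passes, above fails", {
  # two tech reps v(1 +/- x) have CV = sqrt(2) * x exactly
  x_at <- 0.25 / sqrt(2)
  x_over <- 0.2501 / sqrt(2)
  vals <- stats::setNames(rep(list(stats::setNames(rep(1, 7),
                                                   c(REFS6, "t_pre"))), 6),
                          paste0("s", 1:6))
  q <- build_quants(vals)
  bump <- function(q, strain, x) {
    sel <- q$strain_id == strain & q$target_id == "t_pre"
    q$ng[sel] <- 1 * c(1 + x, 1 - x)
    q
  }
  q <- bump(q, "s1", x_at)
  q <- bump(q, "s2", x_over)
  norm <- normalize_screen(q, reference_targets = REFS6)
  cv <- norm$cv[norm$cv$target_id == "t_pre", ]
  expect_true(cv$cv_pass[cv$strain_id == "s1"])
  expect_false(cv$cv_pass[cv$strain_id == "s2"])
  # and the failing sample carries no Rel for that target
  rel <- norm$rel[norm$rel$target_id == "t_pre", ]
  expect_true(all(is.na(rel$rel[rel$strain_id == "s2"])))
  expect_false(anyNA(rel$rel[rel$strain_id == "s1"]))
})

test_that("plate medians use the midpoint convention and match a sort oracle", {
  q <- data.frame(plate_id = "P1", target_id = "t",
                  ng = c(1, 2, 3))
  expect_equal(plate_medians(q)$median, 2)
  expect_equal(plate_medians(data.frame(plate_id = "P1", target_id = "t",
                                        ng = c(1, 3)))$median, 2)

  set.seed(5)
  big <- data.frame(plate_id = sample(c("P1", "P2"), 500, TRUE),
                    target_id = sample(c("a", "b", "c"), 500, TRUE),
                    ng = rlnorm(500))
  big$ng[sample(500, 20)] <- NA
  pm <- plate_medians(big)
  for (i in seq_len(nrow(pm))) {
    v <- sort(big$ng[big$plate_id == pm$plate_id[i] &
                       big$target_id == pm$target_id[i] & !is.na(big$ng)])
    n <- length(v)
    oracle <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    expect_equal(pm$median[i], oracle)
  }
})

test_that("composite constant is the geometric mean of reference ratios", {
  med <- stats::setNames(rep(1, 6), REFS6)
  expect_equal(compute_cnorm(stats::setNames(rep(1, 6), REFS6), med), 1)
  expect_equal(compute_cnorm(stats::setNames(rep(4, 6), REFS6), med), 4)
  expect_equal(compute_cnorm(stats::setNames(c(2, 2, 0.5, 1, 1, 1), REFS6),
                             med),
               2 ^ (1 / 6), tolerance = 1e-12)
  # fewer than min_refs usable ratios: no constant
  expect_true(is.na(compute_cnorm(stats::setNames(c(1, 1, 1), REFS6[1:3]),
                                  med)))
  expect_error(compute_cnorm(stats::setNames(c(-1, rep(1, 5)), REFS6), med),
               "nonpositive")
  # monotone: raising one reference strictly raises the constant
  base <- stats::setNames(runif(6, 0.5, 2), REFS6)
  up <- base; up[3] <- up[3] * 1.01
  expect_gt(compute_cnorm(up, med), compute_cnorm(base, med))
  # alternative aggregations
  r <- stats::setNames(c(2, 2, 0.5, 1, 1, 1), REFS6)
  expect_equal(compute_cnorm(r, med, method = "arithmetic"), mean(r))
  expect_equal(compute_cnorm(r, med, method = "median"), 1)
})

test_that("low-yield filter boundary: an exact 8-fold drop still passes", {
  expect_true(apply_cnorm_filter(1))
  expect_true(apply_cnorm_filter(0.125))     # log2 = -3 exactly
  expect_false(apply_cnorm_filter(0.124))    # log2 ~ -3.0116
})

test_that("relative levels reproduce an independent step-by-step oracle", {
  set.seed(31)
  targets <- c(REFS6, "t_pre")
  samples <- paste0("s", 1:8)
  vals <- lapply(samples, function(s) {
    stats::setNames(rlnorm(7, 0, 0.5), targets)
  })
  names(vals) <- samples
  q <- build_quants(vals, half_spread = 0.05)
  norm <- normalize_screen(q, reference_targets = REFS6)

  ## oracle: plain loops, no shared code with the package internals
  sample_ng <- sapply(samples, function(s) sapply(targets, function(tg) {
    mean(q$ng[q$strain_id == s & q$target_id == tg])
  }))                                        # targets x samples
  med <- apply(sample_ng, 1, median)
  cn <- sapply(samples, function(s) {
    exp(mean(log(sample_ng[REFS6, s] / med[REFS6])))
  })
  for (s in samples) {
    expect_equal(norm$samples$cnorm[norm$samples$strain_id == s],
                 unname(cn[s]), tolerance = 1e-12)
  }
  for (tg in targets) {
    norm_lvl <- sapply(samples, function(s) sample_ng[tg, s] / cn[s])
    # replicate-level median over the plate for this target
    reps <- q[q$target_id == tg, ]
    repnorm <- reps$ng / cn[reps$strain_id]
    denom <- median(repnorm)
    for (s in samples) {
      got <- norm$rel$rel[norm$rel$strain_id == s & norm$rel$target_id == tg]
      want <- q$ng[q$strain_id == s & q$target_id == tg] / cn[s] / denom
      expect_equal(got, unname(want), tolerance = 1e-12)
    }
  }
})

test_that("a uniform yield change in one sample leaves its Rel values unchanged", {
  set.seed(13)
  tv <- stats::setNames(c(runif(6, 1.5, 2.5), 2), c(REFS6, "t_pre"))
  q0 <- uniform_plate(tv)
  base <- normalize_screen(q0, reference_targets = REFS6)
  rel0 <- base$rel$rel[base$rel$strain_id == "test"]
  expect_false(anyNA(rel0))
  q7 <- q0
  sel <- q7$strain_id == "test"
  q7$ng[sel] <- q7$ng[sel] * 7
  scaled <- normalize_screen(q7, reference_targets = REFS6)
  expect_equal(scaled$samples$cnorm[scaled$samples$strain_id == "test"],
               7 * base$samples$cnorm[base$samples$strain_id == "test"],
               tolerance = 1e-12)
  expect_equal(scaled$rel$rel[scaled$rel$strain_id == "test"], rel0,
               tolerance = 1e-12)
})

test_that("per plate and target, the median Rel of passing samples is 1", {
  scr <- simulate_screen(sim_config(n_strains = 100, seed = 21,
                                    dropout_rate = 0))
  norm <- normalize_screen(quantify_cp(scr$cp, scr$curve_points),
                           reference_targets = names(scr$config$reference_abundances))
  rel <- norm$rel[!is.na(norm$rel$rel), ]
  med <- tapply(rel$rel, paste(rel$plate_id, rel$target_id), median)
  expect_equal(as.numeric(med), rep(1, length(med)), tolerance = 1e-12)
})

test_that("C_norm tracks injected per-sample yields on a synthetic screen", {
  scr <- simulate_screen(sim_config(n_strains = 300, seed = 9,
                                    tech_cv = 0.05, dropout_rate = 0))
  norm <- normalize_screen(quantify_cp(scr$cp, scr$curve_points),
                           reference_targets = names(scr$config$reference_abundances))
  s <- norm$samples
  truth <- scr$truth$samples
  y <- truth$yield_log2[match(paste(s$strain_id, s$bio_rep),
                              paste(truth$strain_id, truth$bio_rep))]
  keep <- is.finite(s$log2_cnorm)
  expect_gt(cor(s$log2_cnorm[keep], y[keep]), 0.99)
})

test_that("samples failing a reference CV are excluded entirely", {
  tv <- stats::setNames(rep(2, 7), c(REFS6, "t_pre"))
  q <- uniform_plate(tv)
  sel <- q$strain_id == "test" & q$target_id == "ref1"
  q$ng[sel] <- c(4, 1)                     # CV ~ 0.85 on a reference
  norm <- normalize_screen(q, reference_targets = REFS6)
  srow <- norm$samples[norm$samples$strain_id == "test", ]
  expect_true(srow$cv_excluded)
  expect_false(srow$pass)
  expect_true(all(is.na(norm$rel$rel[norm$rel$strain_id == "test"])))
})
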