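#' SAM d-statistic for one strain
#'
#' The moderated one-class statistic \eqn{d = (\bar{x} - \mu_0)/(se + s_0)}
#' with \eqn{se} the standard error of the mean (sample sd / sqrt(n)) and
#' \eqn{s_0} the fudge factor. With \eqn{s_0 = 0} this is the classical
#' one-sample t statistic.
#'
#' @param values replicate measurements (log2 relative levels in the
#'   screen's use), at least 2.
#' @param mu0 null reference value (0 in log2 space).
#' @param s0 fudge factor, >= 0.
#' @return the d statistic.
#' @export
compute_d <- function(values, mu0 = 0, s0 = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("d needs at least 2 replicates", call. = FALSE)
  se <- stats::sd(values) / sqrt(length(values))
  (mean(values) - mu0) / (se + s0)
}

#' Estimate the SAM fudge factor s0
#'
#' Follows the standard SAM recipe: candidate values are the percentiles
#' \{0, 5, ..., 100\} of the per-strain standard errors; for each candidate
#' the d statistics are recomputed, strains are partitioned into
#' se-quantile windows, the median absolute deviation of d is taken within
#' each window, and the candidate minimizing the coefficient of variation
#' of those MADs is chosen (ties to the smallest candidate, so
#' homoscedastic data fall back to the first).
#'
#' @param mean per-strain replicate means.
#' @param se per-strain standard errors of the mean.
#' @param mu0 null reference value.
#' @param probs candidate percentiles of the se distribution.
#' @param n_windows number of se-quantile windows; default
#'   \code{max(3, min(100, floor(G/10)))} for G strains.
#' @return the chosen s0, with attributes \code{percentile} and
#'   \code{criterion} (the CV profile over candidates).
#' @export
estimate_s0 <- function(mean, se, mu0 = 0, probs = seq(0, 1, by = 0.05),
                        n_windows = NULL) {
  stopifnot(length(mean) == length(se))
  G <- length(se)
  if (G < 20L) warning("fewer than 20 strains: s0 estimate is unstable",
                       call. = FALSE)
  if (is.null(n_windows)) n_windows <- max(3L, min(100L, G %/% 10L))
  cand <- stats::quantile(se, probs, names = FALSE, type = 7)
  if (all(se == 0)) {
    warning("all standard errors are zero; s0 criterion is undefined, ",
            "returning a nominal positive value", call. = FALSE)
    pos <- cand[cand > 0]
    return(if (length(pos)) min(pos) else .Machine$double.eps)
  }
  brk <- unique(stats::quantile(se, seq(0, 1, length.out = n_windows + 1L),
                                names = FALSE, type = 7))
  win <- if (length(brk) > 2L) {
    cut(se, breaks = brk, include.lowest = TRUE)
  } else {
    factor(rep(1L, G))
  }
  num <- mean - mu0
  crit <- vapply(cand, function(a) {
    d <- num / (se + a)
    mads <- tapply(d, win, stats::mad)
    mads <- mads[!is.na(mads)]
    if (length(mads) < 2L || base::mean(mads) == 0) return(NA_real_)
    stats::sd(mads) / base::mean(mads)
  }, numeric(1))
  if (all(is.na(crit))) {
    best <- 1L
  } else {
    best <- which(crit == min(crit, na.rm = TRUE))[1L]  # ties -> smallest
  }
  structure(cand[best], percentile = 100 * probs[best],
            criterion = stats::setNames(crit, paste0(100 * probs, "%")))
}

#' One-class SAM sign-flip permutation null
#'
#' The one-class null randomizes the sign of each replicate column (the
#' sample is the exchangeable unit): a sign vector over the n replicates
#' is applied to every strain's deviations from \code{mu0}, d is
#' recomputed and sorted, and the expected order statistics are the means
#' of the sorted statistics over permutations. With \code{n <= 12}
#' replicates and \code{exhaustive} unset or TRUE, all \eqn{2^n} sign
#' assignments are enumerated instead of sampled.
#'
#' @param x strains x replicates matrix, no NAs.
#' @param mu0 null reference value.
#' @param s0 fudge factor used for the permuted statistics.
#' @param n_permutations number of sampled sign vectors (ignored when
#'   exhaustive).
#' @param seed RNG seed for the sampled case.
#' @param exhaustive force (TRUE) or forbid (FALSE) enumeration; default
#'   auto (enumerate when \code{ncol(x) <= 12}).
#' @return list with \code{dbar} (expected order statistics, ascending),
#'   \code{perm_d} (strains x permutations matrix of permuted d) and
#'   \code{exhaustive}.
#' @export
sam_permutation_null <- function(x, mu0 = 0, s0 = 0, n_permutations = 1000L,
                                 seed = 1L, exhaustive = NULL) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (anyNA(x)) stop("permutation null requires complete replicate data",
                     call. = FALSE)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  do_exh <- if (is.null(exhaustive)) n <= 12L else isTRUE(exhaustive) && n <= 12L
  if (do_exh) {
    B <- 2L^n
    S <- 1 - 2 * vapply(seq_len(B) - 1L,
                        function(i) as.integer(intToBits(i))[seq_len(n)],
                        integer(n))
    S <- matrix(as.numeric(S), nrow = n)
  } else {
    B <- as.integer(n_permutations)
    S <- with_seed(seed,
                   matrix(sample(c(-1, 1), n * B, replace = TRUE), nrow = n))
  }
  dev <- x - mu0
  SS <- rowSums(dev^2)
  m <- (dev %*% S) / n                       # permuted numerators, G x B
  se <- sqrt(pmax(0, (SS - n * m^2) / (n - 1)) / n)
  perm_d <- m / (se + s0)
  sorted <- apply(perm_d, 2L, sort)
  list(dbar = unname(rowMeans(sorted)), perm_d = perm_d,
       exhaustive = do_exh)
}

#' Apply the SAM calling rule at a threshold delta
#'
#' With strains ordered by d and paired rank-for-rank with the expected
#' order statistics, the walk starts at the smallest non-negative d and
#' moves up: the first strain with \eqn{d - \bar d \ge \Delta} defines the
#' upper cut, and every strain with d at or beyond it is called positive.
#' The mirror rule gives the negative side. The FDR is the median over
#' permutations of the number of permuted d values beyond the cuts,
#' divided by the number of calls, capped at 1.
#'
#' @param d observed d statistics (any order).
#' @param dbar expected order statistics aligned to \code{sort(d)}
#'   (ascending).
#' @param delta calling threshold, >= 0.
#' @param perm_d optional strains x permutations matrix for the FDR.
#' @return list with \code{call} (factor positive/negative/none aligned to
#'   \code{d}), \code{cut_up}, \code{cut_low}, \code{n_called},
#'   \code{n_positive}, \code{n_negative}, \code{fdr}, \code{no_calls}.
#' @export
sam_call <- function(d, dbar, delta, perm_d = NULL) {
  G <- length(d)
  stopifnot(length(dbar) == G, delta >= 0)
  ord <- order(d)
  ds <- d[ord]
  diff_up <- ds - dbar
  diff_lo <- dbar - ds
  i0 <- match(TRUE, ds >= 0)          # first non-negative rank
  cut_up <- Inf
  if (!is.na(i0)) {
    hit <- which(diff_up[i0:G] >= delta)
    if (length(hit)) cut_up <- ds[i0 + hit[1L] - 1L]
  }
  cut_low <- -Inf
  j0 <- if (is.na(i0)) G else i0 - 1L # last negative rank
  if (j0 >= 1L) {
    hit <- which(diff_lo[j0:1] >= delta)
    if (length(hit)) cut_low <- ds[j0 - hit[1L] + 1L]
  }
  call <- rep("none", G)
  call[d >= cut_up] <- "positive"
  call[d <= cut_low] <- "negative"
  n_pos <- sum(call == "positive"); n_neg <- sum(call == "negative")
  n_called <- n_pos + n_neg
  fdr <- 0; no_calls <- n_called == 0L
  if (!no_calls && !is.null(perm_d)) {
    exceed <- colSums(perm_d >= cut_up | perm_d <= cut_low)
    fdr <- min(1, stats::median(exceed) / n_called)
  }
  list(call = factor(call, levels = c("positive", "negative", "none")),
       cut_up = cut_up, cut_low = cut_low,
       n_called = n_called, n_positive = n_pos, n_negative = n_neg,
       fdr = fdr, no_calls = no_calls)
}

#' One-class Significance Analysis of Microarrays
#'
#' Fits the screen's significance model to a strains x replicates matrix
#' of log2 relative levels: moderated d statistics with an estimated fudge
#' factor, a sign-flip permutation null (exhaustive over all \eqn{2^n}
#' column-sign assignments when the replicate count allows), Δ-threshold
#' calling and permutation FDR. When \code{delta} is NULL the threshold is
#' chosen by a Δ sweep as the smallest value attaining the minimum FDR
#' with at least one call (the screen's "Δ adjusted to minimize the FDR"
#' rule).
#'
#' @param x numeric matrix, strains in rows (rownames = strain labels),
#'   replicates in columns; strains with missing replicates are dropped
#'   with a message.
#' @param mu0 null reference value (default 0: Rel = 1 in log2 space).
#' @param s0 fudge factor; NULL (default) estimates it via [estimate_s0()].
#' @param delta calling threshold; NULL picks the FDR-minimizing value.
#' @param n_permutations sampled permutations when enumeration is not used.
#' @param seed RNG seed (sampled permutations only).
#' @param exhaustive see [sam_permutation_null()].
#' @param keep_perm_d keep the permuted d matrix on the object (needed to
#'   re-call at other deltas; default TRUE).
#' @return an object of class \code{sam_fit}; see [print.sam_fit()],
#'   [summary.sam_fit()], [plot.sam_fit()]. The per-strain table is in
#'   \code{$table} (columns strain, n, mean, se, d, dbar, call), the
#'   Δ-sweep in \code{$sweep}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(400, sd = 0.3), 100, 4,
#'             dimnames = list(sprintf("s%03d", 1:100), NULL))
#' x[1:5, ] <- x[1:5, ] + 2
#' fit <- sam_one_class(x, seed = 1)
#' summary(fit)
#' @export
sam_one_class <- function(x, mu0 = 0, s0 = NULL, delta = NULL,
                          n_permutations = 1000L, seed = 1L,
                          exhaustive = NULL, keep_perm_d = TRUE) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("strain_%05d", seq_len(nrow(x)))
  complete <- rowSums(is.na(x)) == 0L
  dropped <- sum(!complete)
  if (dropped) {
    message(dropped, " strain(s) dropped for incomplete replicates")
    x <- x[complete, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("need at least 2 strains with complete replicates",
                         call. = FALSE)
  if (ncol(x) < 2L) stop("need at least 2 replicates", call. = FALSE)
  n <- ncol(x)
  means <- rowMeans(x)
  se <- sqrt(apply(x, 1L, stats::var) / n)
  if (is.null(s0)) s0 <- estimate_s0(means, se, mu0 = mu0)
  d <- (means - mu0) / (se + as.numeric(s0))

  null <- sam_permutation_null(x, mu0 = mu0, s0 = as.numeric(s0),
                               n_permutations = n_permutations,
                               seed = seed, exhaustive = exhaustive)
  ## rank alignment: ties in d broken by strain label for reproducibility
  ord <- order(d, rownames(x))
  dbar_aligned <- numeric(length(d))
  dbar_aligned[ord] <- null$dbar

  sweep_tab <- sam_delta_sweep_(d, null$dbar, null$perm_d)
  if (is.null(delta)) delta <- sam_best_delta(sweep_tab)
  called <- sam_call(d, null$dbar, delta, null$perm_d)

  tab <- data.frame(strain = rownames(x), n = n, mean = means, se = se,
                    d = d, dbar = dbar_aligned, call = called$call,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, s0 = as.numeric(s0),
                 s0_percentile = attr(s0, "percentile"),
                 mu0 = mu0, delta = delta,
                 cut_up = called$cut_up, cut_low = called$cut_low,
                 fdr = called$fdr, n_called = called$n_called,
                 n_positive = called$n_positive,
                 n_negative = called$n_negative,
                 no_calls = called$no_calls,
                 sweep = sweep_tab,
                 dbar_sorted = null$dbar,
                 perm_d = if (keep_perm_d) null$perm_d else NULL,
                 n_permutations = ncol(null$perm_d),
                 exhaustive = null$exhaustive,
                 seed = seed, dropped = dropped),
            class = "sam_fit")
}

# sweep over candidate deltas (the breakpoints of |d - dbar| where the
# call set can change), returning n_called and FDR per delta
sam_delta_sweep_ <- function(d, dbar_sorted, perm_d, max_deltas = 200L) {
  ds <- sort(d)
  gaps <- sort(unique(c(0, pmax(0, abs(ds - dbar_sorted)))))
  if (length(gaps) > max_deltas) {
    gaps <- unique(stats::quantile(gaps, seq(0, 1, length.out = max_deltas),
                                   names = FALSE, type = 7))
  }
  rows <- lapply(gaps, function(dl) {
    cc <- sam_call(d, dbar_sorted, dl, perm_d)
    data.frame(delta = dl, n_positive = cc$n_positive,
               n_negative = cc$n_negative, n_called = cc$n_called,
               fdr = cc$fdr)
  })
  do.call(rbind, rows)
}

#' Δ-sweep table for a SAM fit
#'
#' @param fit a \code{sam_fit}.
#' @return data.frame with columns delta, n_positive, n_negative,
#'   n_called, fdr.
#' @export
sam_delta_sweep <- function(fit) {
  stopifnot(inherits(fit, "sam_fit"))
  fit$sweep
}

#' FDR-minimizing delta
#'
#' The smallest Δ attaining the minimum FDR among thresholds with at
#' least one call.
#'
#' @param sweep a Δ-sweep table (from [sam_delta_sweep()]) or a
#'   \code{sam_fit}.
#' @return the chosen Δ.
#' @export
sam_best_delta <- function(sweep) {
  if (inherits(sweep, "sam_fit")) sweep <- sweep$sweep
  s <- sweep[sweep$n_called >= 1L, , drop = FALSE]
  if (!nrow(s)) return(0)
  s$delta[which(s$fdr == min(s$fdr))[1L]]
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("One-class SAM fit\n")
  cat(sprintf("  %d strains, %d replicates; %s null (%d permutations)\n",
              nrow(x$table), x$table$n[1L],
              if (x$exhaustive) "exhaustive sign-flip" else "sampled sign-flip",
              x$n_permutations))
  cat(sprintf("  s0 = %.4g (percentile %s), delta = %.4g\n", x$s0,
              ifelse(is.null(x$s0_percentile), "fixed", x$s0_percentile),
              x$delta))
  cat(sprintf("  calls: %d positive, %d negative; FDR = %.4g%s\n",
              x$n_positive, x$n_negative, x$fdr,
              if (x$no_calls) " (no calls)" else ""))
  invisible(x)
}

#' @export
summary.sam_fit <- function(object, ...) {
  print(object)
  cat("\nTop strains by d:\n")
  tab <- object$table[order(-object$table$d), ]
  print(utils::head(tab, 10L), row.names = FALSE)
  invisible(object$table)
}

#' @export
coef.sam_fit <- function(object, ...) {
  stats::setNames(object$table$d, object$table$strain)
}

#' SAM plot: observed versus expected order statistics
#'
#' @param x a \code{sam_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.sam_fit <- function(x, ...) {
  ord <- order(x$table$d, x$table$strain)
  d <- x$table$d[ord]; dbar <- x$dbar_sorted
  col <- c(positive = "firebrick", negative = "steelblue",
           none = "grey40")[as.character(x$table$call[ord])]
  graphics::plot(dbar, d, col = col, pch = 16, cex = 0.6,
                 xlab = "expected order statistic",
                 ylab = "observed d", ...)
  graphics::abline(0, 1)
  graphics::abline(x$delta, 1, lty = 2)
  graphics::abline(-x$delta, 1, lty = 2)
  invisible(x)
}
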