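#' Per-strain replicate summary for ranking
#'
#' The per-strain value entering rank ordering: the mean of the available
#' log2 relative levels across the four replicates (the same summary scale
#' the significance analysis uses).
#'
#' @param norm a \code{screen_norm} object.
#' @param target target_id to summarize.
#' @return named numeric vector of mean log2 Rel per strain (NA when no
#'   replicate passed).
#' @export
strain_rel_summary <- function(norm, target) {
  m <- rel_matrix(norm, target, log2 = TRUE)
  out <- rowMeans(m, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Rank strains by relative level
#'
#' Descending ranks (rank 1 = highest precursor accumulation); ties get
#' average ranks. Strains with no value are excluded (NA rank).
#'
#' @param rel named numeric vector of per-strain summaries.
#' @return named numeric vector of ranks.
#' @export
rank_strains <- function(rel) {
  r <- rank(-rel, ties.method = "average", na.last = "keep")
  stats::setNames(as.numeric(r), names(rel))
}

#' Composite rank across precursor targets
#'
#' The per-strain average of its ranks over the configured precursor
#' species; strains with fewer than \code{min_targets} available ranks are
#' flagged and placed last.
#'
#' @param ranks a list (or matrix with strains in rows) of per-target rank
#'   vectors sharing strain names.
#' @param min_targets minimum targets required (default 3).
#' @return data.frame with columns \code{strain}, \code{n_targets},
#'   \code{composite_rank} (NA when flagged), \code{flagged}, ordered by
#'   composite rank with flagged strains last.
#' @export
composite_rank <- function(ranks, min_targets = 3L) {
  if (is.list(ranks) && !is.data.frame(ranks)) {
    strains <- sort(unique(unlist(lapply(ranks, names))))
    m <- sapply(ranks, function(r) r[strains])
    rownames(m) <- strains
  } else {
    m <- as.matrix(ranks)
  }
  n_tg <- rowSums(!is.na(m))
  comp <- rowMeans(m, na.rm = TRUE)
  flagged <- n_tg < min_targets
  comp[flagged] <- NA_real_
  out <- data.frame(strain = rownames(m), n_targets = n_tg,
                    composite_rank = comp, flagged = flagged,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$flagged, out$composite_rank, out$strain), , drop = FALSE]
}

#' Splicing-efficiency index
#'
#' Relative precursor level divided by relative total level for a
#' transcript — the classical unspliced:spliced measure. It rises when
#' splicing, not transcription, is impaired; a pure transcriptional
#' increase raises both terms and cancels.
#'
#' @param rel_precursor,rel_total positive relative levels (vectorized).
#' @return the index; NA with a warning where the total is nonpositive or
#'   missing.
#' @export
splicing_efficiency <- function(rel_precursor, rel_total) {
  bad <- !is.na(rel_total) & rel_total <= 0
  if (any(bad)) {
    warning(sum(bad), " strain(s) with nonpositive total level; ",
            "efficiency set to NA", call. = FALSE)
    rel_total[bad] <- NA_real_
  }
  rel_precursor / rel_total
}

# log-space upper hypergeometric tail P(X >= k), vectorized over k
hyper_tail <- function(k, N, K, n) {
  vapply(k, function(kk) {
    if (kk <= 0) return(1)
    hi <- min(K, n)
    if (kk > hi) return(0)
    i <- kk:hi
    lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    min(1, exp(logsumexp(lt)))
  }, numeric(1))
}

#' Gene-set over-representation test
#'
#' One-sided Fisher's exact / hypergeometric upper tail:
#' \deqn{p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}}
#' computed by log-space summation so that p-values down to ~1e-300 are
#' exact, with no normal or chi-square approximation.
#'
#' @param N background size (strains passing filters).
#' @param K annotated strains in the background.
#' @param n top-list size.
#' @param k annotated strains in the top list.
#' @return an object of class \code{enrichment_result} with fields
#'   \code{N}, \code{K}, \code{n}, \code{k}, \code{p}, \code{expected}
#'   (n*K/N) and \code{fold} (k / expected).
#' @examples
#' enrichment_test(N = 5122, K = 68, n = 200, k = 53)
#' @export
enrichment_test <- function(N, K, n, k) {
  N <- as.integer(N); K <- as.integer(K); n <- as.integer(n); k <- as.integer(k)
  if (K > N || n > N || k > min(K, n) || any(c(N, K, n, k) < 0)) {
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N", call. = FALSE)
  }
  p <- hyper_tail(k, N, K, n)
  expected <- n * K / N
  structure(list(N = N, K = K, n = n, k = k, p = p, expected = expected,
                 fold = if (expected > 0) k / expected else NA_real_),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Gene-set enrichment: %d of %d annotated in top %d of %d\n",
              x$k, x$K, x$n, x$N))
  cat(sprintf("  expected %.2f, fold %.2f, p = %.3g (one-sided Fisher)\n",
              x$expected, x$fold, x$p))
  invisible(x)
}

#' Candidate report across targets
#'
#' Joins per-target SAM calls, maximal d score, composite rank and
#' gene-set memberships into the screen's hit table, ordered by decreasing
#' maximal d; strains significant for any target form the candidate list.
#' Gene-set over-representation is tested among the top-N strains of the
#' composite rank ordering at each requested cutoff, against the
#' background of ranked strains, with a Bonferroni-adjusted p alongside
#' the raw (primary) value.
#'
#' @param sam_fits named list of \code{sam_fit} objects, one per target.
#' @param composite composite-rank table from [composite_rank()] (or NULL
#'   to order purely by d).
#' @param gene_sets named list of member vectors (may be empty).
#' @param top_n top-list cutoffs for enrichment (default 50, 100, 200).
#' @return list with \code{strains} (full join), \code{candidates}
#'   (strains with >= 1 positive/negative call) and \code{enrichment}
#'   (one row per gene set x cutoff; NULL when no gene sets).
#' @export
candidate_report <- function(sam_fits, composite = NULL, gene_sets = list(),
                             top_n = c(50L, 100L, 200L)) {
  if (!length(sam_fits)) stop("need at least one SAM fit", call. = FALSE)
  if (is.null(names(sam_fits))) stop("sam_fits must be named by target",
                                     call. = FALSE)
  strains <- sort(unique(unlist(lapply(sam_fits, function(f) f$table$strain))))
  out <- data.frame(strain = strains, stringsAsFactors = FALSE)
  d_mat <- matrix(NA_real_, length(strains), length(sam_fits))
  for (j in seq_along(sam_fits)) {
    tab <- sam_fits[[j]]$table
    idx <- match(tab$strain, strains)
    cl <- rep("none", length(strains))
    cl[idx] <- as.character(tab$call)
    out[[paste0("call_", names(sam_fits)[j])]] <- cl
    d_mat[idx, j] <- tab$d
  }
  out$max_d <- apply(d_mat, 1L, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  if (!is.null(composite)) {
    out$composite_rank <- composite$composite_rank[match(out$strain,
                                                         composite$strain)]
  }
  for (gs in names(gene_sets)) {
    out[[paste0("in_", gs)]] <- out$strain %in% gene_sets[[gs]]
  }
  call_cols <- grep("^call_", names(out), value = TRUE)
  out <- out[order(-out$max_d, out$strain), , drop = FALSE]
  rownames(out) <- NULL
  any_call <- Reduce(`|`, lapply(call_cols, function(cc) out[[cc]] != "none"))
  candidates <- out[any_call, , drop = FALSE]

  enr <- NULL
  if (length(gene_sets)) {
    if (!is.null(composite)) {
      ranked <- composite[!composite$flagged & !is.na(composite$composite_rank), ]
      ordering <- ranked$strain[order(ranked$composite_rank)]
    } else {
      ordering <- out$strain
    }
    N <- length(ordering)
    rows <- list()
    for (gs in names(gene_sets)) {
      members <- gene_sets[[gs]]
      if (!length(members)) {
        warning("gene set '", gs, "' is empty: enrichment skipped",
                call. = FALSE)
        next
      }
      K <- sum(ordering %in% members)
      for (tn in top_n) {
        tn <- min(tn, N)
        k <- sum(ordering[seq_len(tn)] %in% members)
        et <- enrichment_test(N, K, tn, k)
        rows[[length(rows) + 1L]] <-
          data.frame(gene_set = gs, top_n = tn, N = N, K = K, k = k,
                     p = et$p, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      enr <- do.call(rbind, rows)
      enr$p_bonferroni <- pmin(1, enr$p * length(gene_sets))
    }
  }
  list(strains = out, candidates = candidates, enrichment = enr)
}

#' Ordered relative-level curve with gene-set members highlighted
#'
#' The screen's signature figure: strains ordered from highest to lowest
#' relative precursor level on a log2 axis, with members of an annotation
#' set (for example GO "RNA splicing") marked along the curve.
#'
#' @param rel named per-strain summary (log2 Rel), e.g. from
#'   [strain_rel_summary()].
#' @param gene_set optional character vector of member strains.
#' @param ... passed to \code{plot}.
#' @export
plot_rel_curve <- function(rel, gene_set = NULL, ...) {
  rel <- rel[!is.na(rel)]
  ord <- order(-rel)
  graphics::plot(seq_along(rel), rel[ord], type = "l",
                 xlab = "strain rank", ylab = "log2 relative level", ...)
  graphics::abline(h = 0, lty = 3)
  if (!is.null(gene_set)) {
    hit <- names(rel)[ord] %in% gene_set
    graphics::points(which(hit), rel[ord][hit], col = "firebrick", pch = 16,
                     cex = 0.6)
    graphics::rug(which(hit), col = "firebrick")
  }
  invisible(ord)
}
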