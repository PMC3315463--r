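#' Run the full screen pipeline
#'
#' Quantify -> normalize -> SAM per precursor target -> rank -> composite
#' rank, in one call. A thin orchestration of the stage functions; each
#' stage can equally be run by hand.
#'
#' @param cp long Cp table (see [read_cp_table()] / [simulate_screen()]).
#' @param curves named list of \code{standard_curve}s or a dilution-point
#'   data.frame (see [quantify_cp()]).
#' @param reference_targets reference primer pairs for C_norm.
#' @param precursor_targets targets to test with SAM and rank.
#' @param sam_seed seed passed to [sam_one_class()].
#' @param min_targets composite-rank requirement, see [composite_rank()].
#' @param ... further arguments to [normalize_screen()].
#' @return list with \code{norm} (screen_norm), \code{sam} (named list of
#'   sam_fit), \code{ranks} (per-target rank vectors) and \code{composite}
#'   (composite-rank table).
#' @export
run_screen_pipeline <- function(cp, curves, reference_targets,
                                precursor_targets, sam_seed = 1L,
                                min_targets = 3L, ...) {
  quants <- quantify_cp(cp, curves)
  norm <- normalize_screen(quants, reference_targets = reference_targets, ...)
  sams <- list(); ranks <- list()
  for (tg in precursor_targets) {
    m <- rel_matrix(norm, tg, log2 = TRUE)
    sams[[tg]] <- sam_one_class(m, seed = sam_seed)
    ranks[[tg]] <- rank_strains(strain_rel_summary(norm, tg))
  }
  comp <- if (length(ranks) > 1L) {
    composite_rank(ranks, min_targets = min(min_targets, length(ranks)))
  } else NULL
  list(norm = norm, sam = sams, ranks = ranks, composite = comp)
}

#' Read a deposited per-replicate relative-level table
#'
#' Loader for locally supplied processed screen tables (for example the
#' per-replicate relative levels deposited under GEO accession GSE34330,
#' exported to TSV). Expected columns: \code{strain_id} plus one column
#' per replicate of relative levels on the linear scale. Published SAM
#' operating points can then be checked by running [sam_one_class()] on
#' \code{log2} of the returned matrix; nothing in this package bundles the
#' deposited data, so these checks only run where the user has placed the
#' tables.
#'
#' @param path path to the table; a clear error if absent.
#' @return numeric matrix, strains x replicates.
#' @export
read_rel_table <- function(path) {
  if (!file.exists(path)) {
    stop("processed relative-level table not found at '", path, "'; ",
         "download the deposited screen tables (GEO GSE34330) and export ",
         "them as TSV with a strain_id column plus one column per replicate",
         call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot_cols(df, "strain_id", "relative-level table")
  m <- as.matrix(df[, setdiff(names(df), "strain_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$strain_id
  m
}
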