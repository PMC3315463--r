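#' Coefficient of variation across replicates
#'
#' Sample standard deviation divided by the mean, on the linear (nanogram)
#' scale — the screen's per-sample reproducibility filter (values above
#' 0.25 are rejected downstream).
#'
#' @param values replicate quantities; NAs dropped.
#' @return the CV, or \code{NA} when fewer than 2 values remain.
#' @export
replicate_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m == 0) stop("replicate mean is zero; CV undefined", call. = FALSE)
  stats::sd(values) / m
}

#' Per-plate per-primer medians
#'
#' The median quantity for each primer pair on each QPCR plate, computed
#' over non-missing values only. Even counts use the midpoint of the two
#' central values.
#'
#' @param quants data.frame with columns \code{plate_id}, \code{target_id}
#'   and a value column.
#' @param value name of the value column (default \code{"ng"}).
#' @return data.frame with columns \code{plate_id}, \code{target_id},
#'   \code{median}.
#' @export
plate_medians <- function(quants, value = "ng") {
  stopifnot_cols(quants, c("plate_id", "target_id", value), "quantity table")
  v <- quants[[value]]
  g <- key2(quants$plate_id, quants$target_id)
  keep <- !is.na(v)
  med <- tapply(v[keep], g[keep], stats::median)
  parts <- strsplit(names(med), "\r", fixed = TRUE)
  data.frame(plate_id = vapply(parts, `[`, "", 1L),
             target_id = vapply(parts, `[`, "", 2L),
             median = as.numeric(med),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Composite normalization constant for one sample
#'
#' Summarizes a sample's total RNA yield from its reference-RNA quantities:
#' each reference is divided by that primer pair's per-plate median, and
#' the ratios are averaged (geometric mean by default, so that a uniform
#' yield change scales C_norm exactly and log2(C_norm) is an average in
#' log space).
#'
#' @param sample_refs named numeric: reference target -> sample quantity.
#' @param medians named numeric: reference target -> per-plate median.
#' @param method \code{"geometric"} (default), \code{"arithmetic"} or
#'   \code{"median"} aggregation of the ratios.
#' @param min_refs minimum number of usable reference ratios (default 4 of
#'   the panel's 6); below it C_norm is \code{NA} and the sample is
#'   excluded.
#' @return the composite constant C_norm, or \code{NA}.
#' @examples
#' compute_cnorm(c(a = 2, b = 2, c = 0.5, d = 1, e = 1, f = 1),
#'               c(a = 1, b = 1, c = 1, d = 1, e = 1, f = 1))  # 2^(1/6)
#' @export
compute_cnorm <- function(sample_refs, medians,
                          method = c("geometric", "arithmetic", "median"),
                          min_refs = 4L) {
  method <- match.arg(method)
  common <- intersect(names(sample_refs), names(medians))
  r <- as.numeric(sample_refs[common]) / as.numeric(medians[common])
  r <- r[!is.na(r)]
  if (length(r) < min_refs) return(NA_real_)
  if (any(r <= 0)) stop("nonpositive reference ratio", call. = FALSE)
  switch(method,
         geometric = geomean(r),
         arithmetic = mean(r),
         median = stats::median(r))
}

#' Low-yield filter on C_norm
#'
#' Samples whose composite constant is more than 8-fold below the plate
#' median — log2(C_norm) less than -3 — carry too little cDNA and are
#' eliminated; the boundary itself passes.
#'
#' @param cnorm positive C_norm values.
#' @param log2_min threshold in log2 units (default -3).
#' @return logical vector, \code{TRUE} = pass.
#' @export
apply_cnorm_filter <- function(cnorm, log2_min = -3) {
  log2(cnorm) >= log2_min
}

#' Normalize a quantified screen
#'
#' Runs the full normalization stage over a long table of per-well relative
#' quantities: replicate CV filter (per strain, biological replicate and
#' primer pair, across technical replicates), per-plate per-primer medians,
#' composite normalization constant from the reference panel, low-yield
#' filter, normalized levels (\code{ng / C_norm}) and relative levels
#' (normalized level divided by the per-plate median of normalized levels
#' for that primer pair, so a typical strain sits at Rel = 1).
#'
#' @param quants data.frame with columns \code{plate_id}, \code{strain_id},
#'   \code{bio_rep}, \code{tech_rep}, \code{target_id}, \code{ng}
#'   (from [quantify_cp()] or [simulate_screen()] + [quantify_cp()]).
#' @param reference_targets character vector of reference primer pairs.
#' @param cv_max CV rejection threshold (strictly greater fails; default
#'   0.25).
#' @param log2_cnorm_min low-yield threshold on log2(C_norm) (default -3).
#' @param min_refs minimum usable reference ratios per sample (default 4).
#' @param cnorm_method ratio aggregation, see [compute_cnorm()].
#' @param strict_cv if \code{TRUE}, samples whose CV cannot be computed
#'   (a single technical replicate) fail the filter; default lenient.
#' @return an object of class \code{screen_norm}: list with
#'   \describe{
#'     \item{samples}{per-sample diagnostics (C_norm, flags).}
#'     \item{rel}{the input table with \code{cv_pass}, \code{normalized}
#'       and \code{rel} columns appended.}
#'     \item{cv}{per (sample, target) CV table.}
#'     \item{plate_medians}{raw-quantity medians used for C_norm.}
#'     \item{params}{the thresholds used.}
#'   }
#' @export
normalize_screen <- function(quants, reference_targets,
                             cv_max = 0.25, log2_cnorm_min = -3,
                             min_refs = 4L,
                             cnorm_method = c("geometric", "arithmetic", "median"),
                             strict_cv = FALSE) {
  cnorm_method <- match.arg(cnorm_method)
  stopifnot_cols(quants, c("plate_id", "strain_id", "bio_rep", "tech_rep",
                           "target_id", "ng"), "quantity table")
  if (!length(reference_targets)) {
    stop("at least one reference target is required", call. = FALSE)
  }
  ng <- quants$ng
  if (any(ng <= 0, na.rm = TRUE)) {
    stop("quantities must be positive", call. = FALSE)
  }

  sk <- key3(quants$plate_id, quants$strain_id, quants$bio_rep)
  st <- key2(sk, quants$target_id)
  f_st <- factor(st, levels = unique(st))
  m <- !is.na(ng)
  ngz <- ifelse(m, ng, 0)

  ## per (sample, target) replicate summaries on the linear scale
  n_rep <- as.vector(rowsum(as.numeric(m), f_st))
  s1 <- as.vector(rowsum(ngz, f_st))
  s2 <- as.vector(rowsum(ngz^2, f_st))
  lev <- levels(f_st)
  mean_st <- ifelse(n_rep > 0, s1 / n_rep, NA_real_)
  var_st <- ifelse(n_rep > 1, pmax(0, (s2 - n_rep * mean_st^2) / (n_rep - 1)),
                   NA_real_)
  cv_st <- sqrt(var_st) / mean_st
  cv_pass_st <- ifelse(is.na(cv_st), !strict_cv & n_rep > 0, cv_st <= cv_max)

  parts <- strsplit(lev, "\r", fixed = TRUE)
  st_sample <- vapply(parts, function(p) paste(p[1:3], collapse = "\r"), "")
  st_plate <- vapply(parts, `[`, "", 1L)
  st_target <- vapply(parts, `[`, "", 4L)
  is_ref <- st_target %in% reference_targets

  ## a sample with any failing reference CV is excluded entirely
  ref_fail <- st_sample[is_ref & !cv_pass_st & n_rep > 0]
  samples <- unique(st_sample)
  cv_excluded <- samples %in% ref_fail

  ## per-plate per-primer medians over CV-passing samples
  ok_med <- n_rep > 0 & cv_pass_st & !(st_sample %in% ref_fail)
  gmed <- key2(st_plate, st_target)
  med_tab <- tapply(mean_st[ok_med], gmed[ok_med], stats::median)
  med_st <- as.numeric(med_tab[gmed])

  ## composite normalization constant per sample
  ratio <- mean_st / med_st
  use_ratio <- is_ref & n_rep > 0 & cv_pass_st & !is.na(ratio)
  if (any(ratio[use_ratio] <= 0)) {
    stop("nonpositive reference ratio", call. = FALSE)
  }
  f_samp <- factor(st_sample, levels = samples)
  n_refs <- as.vector(rowsum(as.numeric(use_ratio), f_samp))
  log_ratio <- ifelse(use_ratio, log(ratio), 0)
  cnorm <- switch(cnorm_method,
    geometric = exp(as.vector(rowsum(log_ratio, f_samp)) / n_refs),
    arithmetic = as.vector(rowsum(ifelse(use_ratio, ratio, 0), f_samp)) / n_refs,
    median = vapply(split(ratio[use_ratio], f_samp[use_ratio])[samples],
                    function(x) if (length(x)) stats::median(x) else NA_real_,
                    numeric(1)))
  cnorm[n_refs < min_refs] <- NA_real_
  cnorm_pass <- !is.na(cnorm) & apply_cnorm_filter(cnorm, log2_cnorm_min)
  pass_sample <- !cv_excluded & cnorm_pass

  ## normalized and relative levels per technical replicate measurement
  row_samp <- match(sk, samples)
  row_st <- match(st, lev)
  normalized <- ng / cnorm[row_samp]
  row_ok <- pass_sample[row_samp] & cv_pass_st[row_st] & !is.na(normalized)
  gnorm <- key2(quants$plate_id, quants$target_id)
  nm_tab <- tapply(normalized[row_ok], gnorm[row_ok], stats::median)
  denom <- as.numeric(nm_tab[gnorm])
  bad_denom <- !is.na(denom) & denom <= 0
  if (any(bad_denom)) {
    skip <- unique(gnorm[bad_denom])
    warning("plate median of normalized levels is nonpositive for ",
            length(skip), " (plate, target) group(s); target skipped there",
            call. = FALSE)
    denom[bad_denom] <- NA_real_
  }
  rel <- ifelse(row_ok, normalized / denom, NA_real_)

  sp <- strsplit(samples, "\r", fixed = TRUE)
  samples_df <- data.frame(
    plate_id = vapply(sp, `[`, "", 1L),
    strain_id = vapply(sp, `[`, "", 2L),
    bio_rep = vapply(sp, `[`, "", 3L),
    n_refs = n_refs,
    cnorm = cnorm,
    log2_cnorm = log2(cnorm),
    cv_excluded = cv_excluded,
    cnorm_pass = cnorm_pass,
    pass = pass_sample,
    stringsAsFactors = FALSE, row.names = NULL)

  cv_df <- data.frame(
    plate_id = st_plate,
    strain_id = vapply(parts, `[`, "", 2L),
    bio_rep = vapply(parts, `[`, "", 3L),
    target_id = st_target,
    n = n_rep, mean_ng = mean_st, cv = cv_st, cv_pass = cv_pass_st,
    stringsAsFactors = FALSE, row.names = NULL)

  out_rel <- quants
  out_rel$cv_pass <- cv_pass_st[row_st]
  out_rel$normalized <- normalized
  out_rel$rel <- rel

  pm <- strsplit(names(med_tab), "\r", fixed = TRUE)
  structure(list(
    samples = samples_df,
    rel = out_rel,
    cv = cv_df,
    plate_medians = data.frame(
      plate_id = vapply(pm, `[`, "", 1L),
      target_id = vapply(pm, `[`, "", 2L),
      median = as.numeric(med_tab),
      stringsAsFactors = FALSE, row.names = NULL),
    params = list(reference_targets = reference_targets, cv_max = cv_max,
                  log2_cnorm_min = log2_cnorm_min, min_refs = min_refs,
                  cnorm_method = cnorm_method, strict_cv = strict_cv)
  ), class = "screen_norm")
}

#' @export
print.screen_norm <- function(x, ...) {
  s <- x$samples
  cat("Normalized QPCR screen\n")
  cat(sprintf("  %d samples on %d plate(s), %d target(s)\n",
              nrow(s), length(unique(s$plate_id)),
              length(unique(x$rel$target_id))))
  cat(sprintf("  excluded: %d by reference CV, %d by C_norm (min_refs/low yield)\n",
              sum(s$cv_excluded), sum(!s$cnorm_pass & !s$cv_excluded)))
  cat(sprintf("  passing samples: %d (%.1f%%)\n", sum(s$pass),
              100 * mean(s$pass)))
  v <- stats::var(s$log2_cnorm[is.finite(s$log2_cnorm)])
  cat(sprintf("  var(log2 C_norm) = %.3f\n", v))
  invisible(x)
}

#' Per-strain replicate matrix of relative levels
#'
#' Assembles, for one target, a strains x replicates matrix of Rel values
#' (columns ordered bio A tech 1, bio A tech 2, bio B tech 1, ...), the
#' shape consumed by [sam_one_class()].
#'
#' @param norm a \code{screen_norm} object.
#' @param target target_id to extract.
#' @param log2 return log2(Rel) (default, the SAM input scale) or linear.
#' @return numeric matrix with strain_id rownames; NA where a replicate is
#'   missing or filtered.
#' @export
rel_matrix <- function(norm, target, log2 = TRUE) {
  stopifnot(inherits(norm, "screen_norm"))
  d <- norm$rel[norm$rel$target_id == target, , drop = FALSE]
  if (!nrow(d)) stop("no measurements for target ", target, call. = FALSE)
  strains <- sort(unique(d$strain_id))
  repcol <- paste0(d$bio_rep, "_t", d$tech_rep)
  cols <- sort(unique(repcol))
  mat <- matrix(NA_real_, length(strains), length(cols),
                dimnames = list(strains, cols))
  mat[cbind(match(d$strain_id, strains), match(repcol, cols))] <- d$rel
  if (log2) base::log2(mat) else mat
}
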