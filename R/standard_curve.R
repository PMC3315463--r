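#' Fit a QPCR standard curve
#'
#' Ordinary least-squares fit of Cp against log10(known quantity) for a
#' dilution series (the screen used 4-fold serial dilutions of genomic
#' DNA). The amplification efficiency is derived from the slope as
#' \eqn{E = 10^{-1/slope} - 1}; a perfect doubling per cycle gives slope
#' \eqn{-1/\log_{10} 2 \approx -3.3219} and E = 1 (100\%).
#'
#' @param known_quantity positive template quantities (relative nanograms),
#'   or a data.frame with columns \code{known_quantity} and \code{cp}.
#' @param cp crossing points (cycles), same length.
#' @param target_id optional primer-pair label carried on the object.
#' @return an object of class \code{standard_curve} with components
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{efficiency},
#'   \code{n}, \code{target_id}.
#' @seealso [cp_to_quantity()], [make_standard_curve()]
#' @examples
#' q <- 4 ^ (0:4)
#' fit_standard_curve(q, 30 - log10(q) / log10(2))
#' @export
fit_standard_curve <- function(known_quantity, cp = NULL, target_id = NA_character_) {
  if (is.data.frame(known_quantity)) {
    stopifnot_cols(known_quantity, c("known_quantity", "cp"), "dilution series")
    cp <- known_quantity$cp
    known_quantity <- known_quantity$known_quantity
  }
  ok <- !is.na(known_quantity) & !is.na(cp)
  known_quantity <- known_quantity[ok]; cp <- cp[ok]
  if (length(cp) < 3L) {
    stop("a standard curve needs at least 3 points", call. = FALSE)
  }
  if (any(known_quantity <= 0)) {
    stop("known quantities must be positive", call. = FALSE)
  }
  lq <- log10(known_quantity)
  if (length(unique(lq)) < 2L) {
    stop("dilution series has no quantity spread (single dilution point)",
         call. = FALSE)
  }
  fit <- stats::lm(cp ~ lq)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope >= 0) {
    stop("fitted slope is non-negative; Cp must fall as template rises ",
         "(invalid dilution series)", call. = FALSE)
  }
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((cp - mean(cp))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  make_standard_curve(slope, intercept, target_id = target_id,
                      r_squared = r2, n = length(cp))
}

#' Construct a standard curve from known parameters
#'
#' For pre-fitted \code{(slope, intercept)} pairs supplied in a
#' configuration rather than as raw dilution points.
#'
#' @param slope cycles per log10 quantity; must be negative.
#' @param intercept cycles at quantity 1.
#' @param target_id optional primer-pair label.
#' @param r_squared fit quality (1 for an exact construction).
#' @param n number of points behind the fit.
#' @return a \code{standard_curve} object.
#' @export
make_standard_curve <- function(slope, intercept, target_id = NA_character_,
                                r_squared = 1, n = NA_integer_) {
  if (!is.finite(slope) || slope >= 0) {
    stop("slope must be finite and negative", call. = FALSE)
  }
  structure(list(target_id = target_id, slope = slope, intercept = intercept,
                 r_squared = r_squared,
                 efficiency = 10 ^ (-1 / slope) - 1, n = n),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("QPCR standard curve",
      if (!is.na(x$target_id)) paste0("[", x$target_id, "]"), "\n")
  cat(sprintf("  Cp = %.4f * log10(quantity) + %.4f\n", x$slope, x$intercept))
  cat(sprintf("  efficiency %.1f%%, r^2 %.4f, n = %s\n",
              100 * x$efficiency, x$r_squared,
              ifelse(is.na(x$n), "?", x$n)))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict Cp from quantity along a standard curve
#'
#' @param object a \code{standard_curve}.
#' @param quantity positive template quantities.
#' @param ... unused.
#' @return predicted Cp values.
#' @export
predict.standard_curve <- function(object, quantity, ...) {
  object$intercept + object$slope * log10(quantity)
}

#' Convert Cp to relative quantity
#'
#' Inverts the fitted line: \eqn{quantity = 10^{(cp - intercept)/slope}}.
#' Missing Cp (no amplification) gives missing quantity.
#'
#' @param cp crossing points (cycles); NAs pass through.
#' @param curve a \code{standard_curve}.
#' @return relative quantities on the curve's scale.
#' @export
cp_to_quantity <- function(cp, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10 ^ ((cp - curve$intercept) / curve$slope)
}

#' ChIP-QPCR fold enrichment over a control locus
#'
#' Mock-subtracted percent-input signal at a region of interest divided by
#' the same difference at an intronless control region (PMA1-style).
#'
#' @param ip_pct,mock_pct percent-input of the IP and mock IP at the region.
#' @param ref_ip_pct,ref_mock_pct same at the control region.
#' @return fold enrichment (vectorized).
#' @export
chip_fold_enrichment <- function(ip_pct, mock_pct, ref_ip_pct, ref_mock_pct) {
  ref <- ref_ip_pct - ref_mock_pct
  if (any(ref == 0, na.rm = TRUE)) {
    stop("control-region IP minus mock is zero: uninformative reference",
         call. = FALSE)
  }
  (ip_pct - mock_pct) / ref
}

#' Convert a Cp table to relative quantities
#'
#' Applies each target's standard curve to its Cp measurements, adding an
#' \code{ng} column (relative nanogram quantity; NA where Cp is missing).
#'
#' @param cp_table a well-record data.frame from [read_cp_table()] or
#'   [simulate_screen()].
#' @param curves a named list of \code{standard_curve} objects keyed by
#'   \code{target_id}, or a data.frame of dilution points with columns
#'   \code{target_id}, \code{known_quantity}, \code{cp} (fitted per target).
#' @return the table with an \code{ng} column appended.
#' @export
quantify_cp <- function(cp_table, curves) {
  stopifnot_cols(cp_table, c("target_id", "cp"), "Cp table")
  if (is.data.frame(curves)) curves <- fit_curve_table(curves)
  missing_curves <- setdiff(unique(cp_table$target_id), names(curves))
  if (length(missing_curves)) {
    stop("no standard curve for target(s): ",
         paste(missing_curves, collapse = ", "), call. = FALSE)
  }
  ng <- rep(NA_real_, nrow(cp_table))
  for (tg in unique(cp_table$target_id)) {
    sel <- cp_table$target_id == tg
    ng[sel] <- cp_to_quantity(cp_table$cp[sel], curves[[tg]])
  }
  cp_table$ng <- ng
  cp_table
}

#' Fit standard curves for every target in a dilution-point table
#'
#' @param points data.frame with columns \code{target_id},
#'   \code{known_quantity}, \code{cp}.
#' @return a named list of \code{standard_curve} objects.
#' @export
fit_curve_table <- function(points) {
  stopifnot_cols(points, c("target_id", "known_quantity", "cp"),
                 "dilution-point table")
  points$known_quantity <- as.numeric(points$known_quantity)
  points$cp <- as.numeric(points$cp)
  out <- lapply(split(points, points$target_id), function(d) {
    fit_standard_curve(d$known_quantity, d$cp, target_id = d$target_id[1L])
  })
  out
}
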