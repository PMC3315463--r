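#' Reference-RNA abundance panel
#'
#' Six reference RNAs whose cellular levels span a broad range, expressed
#' relative to the least-abundant target (value 1) with geometric spacing
#' up to the configured fold-span (default ~300-fold, the span of the
#' screen's panel).
#'
#' @param targets six reference target labels.
#' @param span max/min abundance ratio; must exceed 1.
#' @return named numeric vector of relative abundances.
#' @export
reference_panel <- function(targets = c("U1_snRNA", "SCR1_RNA", "TEF5_mRNA",
                                        "TUB1_mRNA", "SRB2_mRNA",
                                        "FAA1_mRNA"),
                            span = 300) {
  if (span <= 1) stop("abundance span must exceed 1", call. = FALSE)
  stats::setNames(span ^ seq(0, 1, length.out = length(targets)), targets)
}

#' Simulation configuration for a synthetic screen
#'
#' Defaults emulate the study conditions: ~5500 strains in 384-well
#' plates, 2 biological x 2 technical replicates, six reference RNAs
#' spanning ~300-fold, per-sample RNA-yield variation that is log-normal
#' with log2 variance 1.5, subtle per-plate batch offsets, multiplicative
#' technical noise, occasional amplification dropout, and a small fraction
#' of strains spiked with elevated precursor levels.
#'
#' @param n_strains number of mutant strains.
#' @param frac_spiked fraction of strains with a true precursor effect.
#' @param spike_log2_effect log2 effect size for spiked strains (scalar,
#'   or length-2 range sampled uniformly per strain).
#' @param spike_mode \code{"splicing"} (precursor targets only, the
#'   default) or \code{"transcriptional"} (precursor and total together, to
#'   exercise the splicing-efficiency discrimination).
#' @param total_targets targets also raised in transcriptional mode (the
#'   transcript's total-RNA primer pair; Tef5 mRNA doubles as a reference,
#'   as in the screen's panel).
#' @param reference_abundances named vector from [reference_panel()].
#' @param target_abundances named baseline abundances of the
#'   precursor/total targets.
#' @param yield_log2_sd sd of per-sample log2 yield (default sqrt(1.5)).
#' @param plate_log2_sd sd of per-plate log2 batch offset (default 0.25).
#' @param tech_cv coefficient of variation of technical replicate noise.
#' @param dropout_rate probability a well yields no amplification (NA Cp).
#' @param curve_slope,curve_intercept standard-curve parameters shared by
#'   all targets unless named vectors are given (default: slopes drawn
#'   once per target in the 86--97\% efficiency band, intercept 22).
#' @param n_plates number of 384-well plates per biological replicate;
#'   NULL sizes automatically, too few is an error.
#' @param seed integer seed; the whole dataset is deterministic in it.
#' @return a \code{sim_config} list, validated.
#' @export
sim_config <- function(n_strains = 5500L,
                       frac_spiked = 0.02,
                       spike_log2_effect = 2,
                       spike_mode = c("splicing", "transcriptional"),
                       reference_abundances = reference_panel(),
                       target_abundances = c(U3_pre = 5, RPL31B_pre = 1.5,
                                             TEF5_pre = 1.2, TUB3_pre = 1,
                                             UBC13_pre = 1.3),
                       total_targets = "TEF5_mRNA",
                       yield_log2_sd = sqrt(1.5),
                       plate_log2_sd = 0.25,
                       tech_cv = 0.05,
                       dropout_rate = 0.002,
                       curve_slope = NULL,
                       curve_intercept = 22,
                       n_plates = NULL,
                       seed = 1L) {
  spike_mode <- match.arg(spike_mode)
  stopifnot(n_strains >= 1, frac_spiked >= 0, frac_spiked <= 1,
            yield_log2_sd >= 0, plate_log2_sd >= 0, tech_cv >= 0,
            dropout_rate >= 0, dropout_rate <= 1,
            all(reference_abundances > 0), all(target_abundances > 0))
  if (is.null(names(reference_abundances)) ||
      is.null(names(target_abundances))) {
    stop("abundance maps must be named by target_id", call. = FALSE)
  }
  need <- ceiling(n_strains / 384)
  if (!is.null(n_plates) && n_plates < need) {
    stop("layout needs at least ", need, " plate(s) per biological replicate",
         call. = FALSE)
  }
  structure(list(n_strains = as.integer(n_strains),
                 frac_spiked = frac_spiked,
                 spike_log2_effect = spike_log2_effect,
                 spike_mode = spike_mode,
                 total_targets = total_targets,
                 reference_abundances = reference_abundances,
                 target_abundances = target_abundances,
                 yield_log2_sd = yield_log2_sd,
                 plate_log2_sd = plate_log2_sd,
                 tech_cv = tech_cv,
                 dropout_rate = dropout_rate,
                 curve_slope = curve_slope,
                 curve_intercept = curve_intercept,
                 n_plates = if (is.null(n_plates)) need else as.integer(n_plates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a complete synthetic screen
#'
#' Builds plate maps, Cp tables, standard-curve dilution points and a
#' ground-truth table with the statistical structure the analysis assumes.
#' Per sample (strain x biological replicate) and target, the true
#' quantity is
#' \deqn{q = A_t \cdot 2^{effect} \cdot Y_s \cdot 2^{plate offset}}
#' with \eqn{A_t} the baseline abundance, the effect applied only to
#' precursor targets of spiked strains (both precursor and total in
#' transcriptional mode), \eqn{Y_s} a log-normal per-sample yield, and a
#' per-plate batch offset. Each technical replicate adds mean-1
#' multiplicative log-normal noise with CV \code{tech_cv}; the quantity is
#' converted to Cp through the target's standard curve, and dropout
#' replaces Cp with NA. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return an object of class \code{synthetic_screen}: list with
#'   \code{cp} (long Cp table), \code{plate_map}, \code{curve_points}
#'   (4-fold dilution series per target), \code{truth} (list of
#'   \code{strains}, \code{samples}, \code{plates} ground-truth tables),
#'   \code{panel} and \code{config}.
#' @export
simulate_screen <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    ref_t <- names(cfg$reference_abundances)
    tgt_t <- names(cfg$target_abundances)
    targets <- c(ref_t, tgt_t)
    abund <- c(cfg$reference_abundances, cfg$target_abundances)

    slopes <- cfg$curve_slope
    if (is.null(slopes)) {
      eff <- stats::runif(length(targets), 0.86, 0.97)
      slopes <- stats::setNames(-1 / log10(1 + eff), targets)
    } else if (is.null(names(slopes))) {
      slopes <- stats::setNames(rep_len(slopes, length(targets)), targets)
    }
    intercepts <- cfg$curve_intercept
    if (is.null(names(intercepts))) {
      intercepts <- stats::setNames(rep_len(intercepts, length(targets)),
                                    targets)
    }

    strains <- sprintf("strain_%05d", seq_len(cfg$n_strains))
    n_spiked <- round(cfg$frac_spiked * cfg$n_strains)
    spiked <- strains %in% sample(strains, n_spiked)
    eff_rng <- cfg$spike_log2_effect
    strain_effect <- numeric(cfg$n_strains)
    strain_effect[spiked] <- if (length(eff_rng) == 2L) {
      stats::runif(n_spiked, eff_rng[1L], eff_rng[2L])
    } else rep(eff_rng, n_spiked)

    ## layout: row-major wells, bio A plates then bio B plates
    wells384 <- as.vector(t(outer(LETTERS[1:16], sprintf("%02d", 1:24),
                                  paste0)))
    slot <- seq_len(cfg$n_strains)
    plate_of <- (slot - 1L) %/% 384L + 1L
    well_of <- wells384[(slot - 1L) %% 384L + 1L]
    samples <- data.frame(
      strain_id = rep(strains, 2L),
      bio_rep = rep(c("A", "B"), each = cfg$n_strains),
      plate_id = sprintf("P%s%02d", rep(c("A", "B"), each = cfg$n_strains),
                         rep(plate_of, 2L)),
      well = rep(well_of, 2L),
      stringsAsFactors = FALSE)
    samples$yield_log2 <- stats::rnorm(nrow(samples), 0, cfg$yield_log2_sd)

    plate_ids <- unique(samples$plate_id)
    plate_offset <- stats::setNames(
      stats::rnorm(length(plate_ids), 0, cfg$plate_log2_sd), plate_ids)

    ## long design: samples x targets x tech reps
    nS <- nrow(samples); nT <- length(targets)
    idx_s <- rep(seq_len(nS), times = nT)
    tgt <- rep(targets, each = nS)
    is_prec <- tgt %in% tgt_t
    spike_here <- if (cfg$spike_mode == "splicing") {
      is_prec
    } else {
      is_prec | tgt %in% cfg$total_targets
    }
    eff_st <- ifelse(spike_here,
                     strain_effect[match(samples$strain_id[idx_s], strains)],
                     0)
    q_true <- abund[tgt] * 2 ^ eff_st *
      2 ^ samples$yield_log2[idx_s] *
      2 ^ plate_offset[samples$plate_id[idx_s]]

    sdlog <- sqrt(log(1 + cfg$tech_cv^2))
    nW <- length(q_true)
    cp_rows <- function(tech) {
      noise <- if (cfg$tech_cv > 0) {
        exp(stats::rnorm(nW, -sdlog^2 / 2, sdlog))
      } else 1
      q <- q_true * noise
      cp <- intercepts[tgt] + slopes[tgt] * log10(q)
      if (cfg$dropout_rate > 0) {
        cp[stats::runif(nW) < cfg$dropout_rate] <- NA_real_
      }
      data.frame(plate_id = samples$plate_id[idx_s],
                 well = samples$well[idx_s],
                 strain_id = samples$strain_id[idx_s],
                 target_id = tgt,
                 bio_rep = samples$bio_rep[idx_s],
                 tech_rep = tech,
                 cp = unname(cp),
                 stringsAsFactors = FALSE)
    }
    cp_tab <- rbind(cp_rows(1L), cp_rows(2L))
    if (any(cp_tab$cp <= 0, na.rm = TRUE)) {
      stop("generated a nonpositive Cp; raise curve_intercept", call. = FALSE)
    }

    ## exact 4-fold dilution points on each target's curve
    dil <- 4 ^ (0:4)
    curve_points <- do.call(rbind, lapply(targets, function(tg) {
      data.frame(target_id = tg, known_quantity = dil,
                 cp = intercepts[tg] + slopes[tg] * log10(dil),
                 stringsAsFactors = FALSE)
    }))

    truth_strains <- data.frame(strain_id = strains, spiked = spiked,
                                spike_log2_effect = strain_effect,
                                stringsAsFactors = FALSE)
    panel <- primer_panel(
      c(ref_t, tgt_t),
      c(rep("reference", length(ref_t)), rep("precursor", length(tgt_t))))

    structure(list(
      cp = cp_tab,
      plate_map = samples[, c("plate_id", "well", "strain_id", "bio_rep")],
      curve_points = curve_points,
      truth = list(strains = truth_strains,
                   samples = samples,
                   plates = data.frame(plate_id = plate_ids,
                                       offset_log2 = unname(plate_offset),
                                       stringsAsFactors = FALSE)),
      panel = panel,
      config = cfg), class = "synthetic_screen")
  })
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat("Synthetic QPCR screen\n")
  cat(sprintf("  %d strains x 2 bio x 2 tech, %d targets, %d plates\n",
              x$config$n_strains, length(unique(x$cp$target_id)),
              length(unique(x$cp$plate_id))))
  cat(sprintf("  %d spiked strain(s) (%s mode), seed %d\n",
              sum(x$truth$strains$spiked), x$config$spike_mode,
              x$config$seed))
  invisible(x)
}

#' Write a synthetic screen to disk as plain-text fixtures
#'
#' Writes the Cp table, plate map, dilution points, ground-truth tables
#' and the generating configuration (YAML), in the same dialects the
#' readers consume, plus a manifest.
#'
#' @param screen a \code{synthetic_screen}.
#' @param out_dir output directory.
#' @return invisibly, the manifest data.frame.
#' @export
write_fixture <- function(screen, out_dir) {
  stopifnot(inherits(screen, "synthetic_screen"))
  manifest <- write_results(list(
    cp_table = screen$cp,
    plate_map = screen$plate_map,
    curve_points = screen$curve_points,
    panel = screen$panel,
    truth_strains = screen$truth$strains,
    truth_samples = screen$truth$samples,
    truth_plates = screen$truth$plates), out_dir)
  cfg <- screen$config
  cfg$reference_abundances <- as.list(cfg$reference_abundances)
  cfg$target_abundances <- as.list(cfg$target_abundances)
  if (!is.null(cfg$curve_slope)) cfg$curve_slope <- as.list(cfg$curve_slope)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(manifest)
}
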