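#' Read a long-format Cp table
#'
#' Reads one crossing-point measurement per row from a delimited text file.
#' Required columns: \code{plate_id}, \code{well}, \code{strain_id},
#' \code{target_id}, \code{bio_rep}, \code{tech_rep}, \code{cp}. Well labels
#' are normalized to zero-padded form (\code{A1} becomes \code{A01}). Cp
#' values equal to one of \code{missing_tokens} (instrument "no
#' amplification" exports) become \code{NA}.
#'
#' @param path path to a CSV/TSV file (delimiter sniffed from the header).
#' @param panel optional primer panel (see [primer_panel()]); targets absent
#'   from the panel trigger a warning and are tagged \code{role = "unknown"}.
#' @param missing_tokens character values of \code{cp} to treat as missing.
#' @return a data.frame of well records, one Cp measurement per row, with a
#'   \code{role} column when a panel is supplied.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("plate_id,well,strain_id,target_id,bio_rep,tech_rep,cp",
#'              "P1,A1,yfg1,U3_pre,A,1,21.3",
#'              "P1,A1,yfg1,U3_pre,A,2,21.5"), f)
#' read_cp_table(f)
#' @export
read_cp_table <- function(path, panel = NULL, missing_tokens = c("", "NA")) {
  df <- read_delim_sniff(path)
  stopifnot_cols(df, c("plate_id", "well", "strain_id", "target_id",
                       "bio_rep", "tech_rep", "cp"), "Cp table")
  df$well <- normalize_well(df$well)
  cp_raw <- trimws(as.character(df$cp))
  is_missing <- cp_raw %in% missing_tokens | is.na(cp_raw) |
    tolower(cp_raw) == "undetermined"
  cp <- suppressWarnings(as.numeric(cp_raw))
  bad <- !is_missing & is.na(cp)
  if (any(bad)) {
    stop("non-numeric cp value(s) at row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "),
         " (e.g. \"", cp_raw[which(bad)[1L]], "\")", call. = FALSE)
  }
  if (any(!is_missing & cp <= 0, na.rm = TRUE)) {
    stop("cp values must be positive cycles; found nonpositive cp at row(s): ",
         paste(utils::head(which(!is_missing & cp <= 0), 5L), collapse = ", "),
         call. = FALSE)
  }
  df$cp <- ifelse(is_missing, NA_real_, cp)
  df$tech_rep <- as.integer(df$tech_rep)
  key <- paste(df$plate_id, df$well, df$target_id, df$tech_rep, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate (plate, well, target, tech_rep) key(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3L), collapse = "; "),
         call. = FALSE)
  }
  for (col in c("plate_id", "well", "strain_id", "target_id", "bio_rep")) {
    df[[col]] <- as.character(df[[col]])
  }
  if (!is.null(panel)) {
    idx <- match(df$target_id, panel$target_id)
    unknown <- unique(df$target_id[is.na(idx)])
    if (length(unknown)) {
      warning("target(s) not in primer panel, tagged role 'unknown': ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    df$role <- ifelse(is.na(idx), "unknown", panel$role[idx])
  }
  rownames(df) <- NULL
  df
}

#' Define a primer panel
#'
#' @param target_id character vector of primer-pair labels.
#' @param role one of \code{"reference"}, \code{"precursor"}, \code{"total"},
#'   \code{"chip_region"} per target.
#' @param description optional free text per target.
#' @return a data.frame with one row per primer pair.
#' @export
primer_panel <- function(target_id, role, description = "") {
  role <- match.arg(role, c("reference", "precursor", "total", "chip_region"),
                    several.ok = TRUE)
  if (anyDuplicated(target_id)) stop("duplicate target_id in panel", call. = FALSE)
  data.frame(target_id = as.character(target_id), role = role,
             description = description, stringsAsFactors = FALSE)
}

#' Read a plate map
#'
#' Maps \code{(plate_id, well)} to \code{(strain_id, bio_rep)}. Wells may be
#' absent (empty wells are allowed); the same well assigned to two different
#' strains is an error.
#'
#' @param path path to a CSV/TSV with columns \code{plate_id}, \code{well},
#'   \code{strain_id}, \code{bio_rep}.
#' @return a data.frame keyed by (plate_id, well).
#' @export
read_plate_map <- function(path) {
  df <- read_delim_sniff(path)
  stopifnot_cols(df, c("plate_id", "well", "strain_id", "bio_rep"), "plate map")
  for (col in names(df)) df[[col]] <- as.character(df[[col]])
  df$well <- normalize_well(df$well)
  df <- unique(df)
  key <- paste(df$plate_id, df$well, sep = "/")
  if (anyDuplicated(key)) {
    stop("well(s) mapped to more than one strain: ",
         paste(utils::head(unique(key[duplicated(key)]), 3L), collapse = "; "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read gene sets
#'
#' Accepts either a two-column \code{set_name,member} file (several sets) or
#' a one-column member list (a single set named after the file).
#'
#' @param path path to a CSV/TSV file.
#' @return a named list of unique member character vectors.
#' @export
read_gene_sets <- function(path) {
  df <- read_delim_sniff(path, header = NA)
  if (ncol(df) == 1L) {
    members <- as.character(df[[1L]])
    sets <- stats::setNames(list(unique(members)),
                            sub("\\.[^.]*$", "", basename(path)))
  } else {
    if (all(c("set_name", "member") %in% names(df))) {
      nm <- df$set_name; mem <- df$member
    } else {
      nm <- df[[1L]]; mem <- df[[2L]]
    }
    sets <- lapply(split(as.character(mem), as.character(nm)), unique)
  }
  sets
}

#' Read the screen configuration
#'
#' A YAML file declaring the primer panel, reference set, filter thresholds,
#' SAM settings and composite-rank target list. Missing keys fall back to
#' [default_screen_config()].
#'
#' @param path path to a YAML file, or \code{NULL} for pure defaults.
#' @return a named list of configuration values.
#' @export
read_screen_config <- function(path = NULL) {
  cfg <- default_screen_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' Default screen configuration
#'
#' The defaults mirror the screen's published design: six reference RNAs,
#' five precursor reporters, CV filter at 0.25, low-yield filter at
#' log2(C_norm) >= -3, at least 4 of 6 references required per sample.
#'
#' @return a named list.
#' @export
default_screen_config <- function() {
  list(
    reference_targets = c("U1_snRNA", "SCR1_RNA", "TEF5_mRNA",
                          "TUB1_mRNA", "SRB2_mRNA", "FAA1_mRNA"),
    precursor_targets = c("U3_pre", "RPL31B_pre", "TEF5_pre",
                          "TUB3_pre", "UBC13_pre"),
    total_targets = c("TEF5_mRNA"),
    cv_max = 0.25,
    log2_cnorm_min = -3,
    min_refs = 4L,
    cnorm_method = "geometric",
    sam = list(n_permutations = 1000L, seed = 1L, delta = NULL),
    top_n = c(50L, 100L, 200L)
  )
}

#' Write result tables
#'
#' Writes each table as a tab-delimited text file with a stable column
#' order; doubles are written with 17 significant digits so that a
#' write-read cycle is lossless. A \code{manifest.tsv} listing file names
#' and row counts is written alongside.
#'
#' @param tables a named list of data.frames.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the manifest data.frame (columns \code{table},
#'   \code{file}, \code{n_rows}).
#' @export
write_results <- function(tables, out_dir) {
  if (length(tables) && is.null(names(tables))) {
    stop("tables must be a named list", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir,
                                 call. = FALSE)
  files <- character(0); rows <- integer(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    write_table_17(tables[[nm]], f)
    files <- c(files, basename(f)); rows <- c(rows, nrow(tables[[nm]]))
  }
  manifest <- data.frame(table = names(tables) %||% character(0),
                         file = files, n_rows = rows,
                         stringsAsFactors = FALSE)
  write_table_17(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tab-delimited writer with full-precision doubles
write_table_17 <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- "NA"
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# delimiter-sniffing reader (comma vs tab); header = NA probes for one
read_delim_sniff <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  if (is.na(header)) {
    header <- grepl("[A-Za-z_]", strsplit(first, sep, fixed = TRUE)[[1L]][1L]) &&
      grepl("set_name|member|strain|gene", first, ignore.case = TRUE)
  }
  utils::read.table(path, header = header, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", colClasses = "character")
}
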