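# Shared table reader: TSV/CSV with header, required columns, numeric
# coercion with row-level errors, and unknown columns carried through.
read_checked_table <- function(path, required, numeric_cols,
                               delim = "\t", what = "table") {
  if (!file.exists(path)) {
    stop_domain(sprintf("%s file not found: %s", what, path),
      "thermodigest_io_error")
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_domain(sprintf("%s %s is missing required column(s): %s", what,
      path, paste(missing_cols, collapse = ", ")), "thermodigest_schema_error")
  }
  if (nrow(raw) == 0) {
    warn(sprintf("%s %s has a header but no rows", what, path))
  }
  for (col in intersect(numeric_cols, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad) > 0) {
      stop_domain(sprintf(
        "%s %s: non-numeric value '%s' in column '%s', row %d",
        what, path, raw[[col]][bad[1]], col, bad[1]),
        "thermodigest_schema_error")
    }
    raw[[col]] <- v
  }
  raw
}

#' Read one bin's proteins from FASTA
#'
#' Reads a protein FASTA file into a bin table (one row per protein,
#' sequence order preserved). The file is validated line by line before
#' parsing so malformed records are reported with their line number;
#' duplicate protein ids are rejected.
#'
#' @param path FASTA file; by convention named `<bin_id>.faa` with the
#'   protein id as the header word.
#' @param bin_id Bin identifier; defaults to the file name without
#'   extension.
#' @param sample_id Metagenome of origin.
#' @return A bin table ([as_bin_table()]).
#' @export
read_protein_fasta <- function(path, bin_id = NULL, sample_id = "sample1") {
  if (!file.exists(path)) {
    stop_domain(sprintf("FASTA file not found: %s", path),
      "thermodigest_io_error")
  }
  bin_id <- bin_id %||% sub("\\.(fa|faa|fasta)$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) {
    stop_domain(sprintf("%s: empty FASTA file", path), "thermodigest_parse_error")
  }
  if (!startsWith(lines[nonempty[1]], ">")) {
    stop_domain(sprintf("%s: line %d: expected '>' header, got '%s'",
      path, nonempty[1], substr(lines[nonempty[1]], 1, 30)),
      "thermodigest_parse_error")
  }
  seq_lines <- nonempty[!startsWith(lines[nonempty], ">")]
  bad <- seq_lines[!grepl("^[A-Za-z*]+$", trimws(lines[seq_lines]))]
  if (length(bad) > 0) {
    stop_domain(sprintf("%s: line %d: invalid sequence characters",
      path, bad[1]), "thermodigest_parse_error")
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop_domain(sprintf("%s: duplicate protein id '%s'",
      path, ids[duplicated(ids)][1]), "thermodigest_parse_error")
  }
  as_bin_table(tibble(
    bin_id = bin_id, sample_id = sample_id,
    protein_id = ids, sequence = unname(toupper(as.character(set)))
  ))
}

#' Write a bin's proteins to FASTA
#'
#' @param bin A bin table holding one bin.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(bin, path) {
  bin <- as_bin_table(bin)
  stopifnot(dplyr::n_distinct(bin$bin_id) == 1)
  set <- Biostrings::AAStringSet(setNames(bin$sequence, bin$protein_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a directory of per-bin protein FASTA files
#'
#' Each `*.fa`/`*.faa`/`*.fasta` file becomes one bin (bin id = file name
#' without extension). Sample ids are taken from `sample_map` or, by
#' default, from the bin-id prefix before the first underscore.
#'
#' @param dir Directory of FASTA files.
#' @param sample_map Optional named character vector `bin_id -> sample_id`.
#' @return A combined bin table.
#' @export
read_bins_dir <- function(dir, sample_map = NULL) {
  files <- list.files(dir, pattern = "\\.(fa|faa|fasta)$", full.names = TRUE)
  if (length(files) == 0) {
    stop_domain(sprintf("no FASTA files in %s", dir), "thermodigest_io_error")
  }
  purrr::map(files, function(f) {
    bid <- sub("\\.(fa|faa|fasta)$", "", basename(f))
    sid <- if (!is.null(sample_map)) {
      if (!bid %in% names(sample_map)) {
        stop_domain(sprintf("no sample for bin '%s' in sample_map", bid),
          "thermodigest_io_error")
      }
      unname(sample_map[bid])
    } else {
      sub("_.*$", "", bid)
    }
    read_protein_fasta(f, bin_id = bid, sample_id = sid)
  }) |>
    purrr::list_rbind() |>
    as_bin_table()
}

#' Read a CheckM-style bin QC table
#'
#' Tab-separated with header; requires `bin_id`, `completeness`,
#' `contamination` (percent), accepts `strain_heterogeneity`; unknown
#' columns are kept but ignored downstream.
#'
#' @param path TSV file.
#' @return A validated tibble.
#' @export
read_qc_table <- function(path) {
  x <- read_checked_table(path,
    required = c("bin_id", "completeness", "contamination"),
    numeric_cols = c("completeness", "contamination", "strain_heterogeneity"),
    what = "QC table")
  if (nrow(x) > 0) {
    if (any(x$completeness < 0 | x$completeness > 100, na.rm = TRUE)) {
      stop_domain(sprintf("%s: completeness outside [0, 100]", path),
        "thermodigest_schema_error")
    }
    if (any(x$contamination < 0, na.rm = TRUE)) {
      stop_domain(sprintf("%s: negative contamination", path),
        "thermodigest_schema_error")
    }
  }
  x
}

#' Read a domain-annotation table
#'
#' Tab-separated with header: `protein_id`, `bin_id`, `marker_id`,
#' `category`, `start`, `end` (1-based inclusive residue coordinates).
#'
#' @param path TSV file.
#' @return A validated annotation tibble ([as_annotation_table()]).
#' @export
read_annotation_table <- function(path) {
  x <- read_checked_table(path,
    required = c("protein_id", "bin_id", "marker_id", "category",
      "start", "end"),
    numeric_cols = c("start", "end"), what = "annotation table")
  as_annotation_table(x)
}

#' Read a pairwise ANI table
#'
#' Tab-separated with header: `bin_id`, `reference`, `ani_blast`,
#' `ani_mummer` (percent).
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_ani_table <- function(path) {
  read_checked_table(path,
    required = c("bin_id", "reference", "ani_blast", "ani_mummer"),
    numeric_cols = c("ani_blast", "ani_mummer"), what = "ANI table")
}

#' Read a per-bin coverage table
#'
#' Tab-separated with header: `bin_id`, `sample_id`, `coverage_mass`
#' (coverage depth times sequence length, or any proportional mass).
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_coverage_table <- function(path) {
  x <- read_checked_table(path,
    required = c("bin_id", "sample_id", "coverage_mass"),
    numeric_cols = "coverage_mass", what = "coverage table")
  if (nrow(x) > 0 && any(x$coverage_mass < 0, na.rm = TRUE)) {
    stop_domain(sprintf("%s: negative coverage_mass", path),
      "thermodigest_schema_error")
  }
  x
}

#' Read steady-state reactor observations
#'
#' Comma-separated with header: `reactor_id`, `rt_days`, `fcs_total`,
#' `fcs_glucan`, `fcs_xylan`, `ch4_frac`, `co2_frac`, `vfa_g_per_l`, `ph`.
#' Only `reactor_id`, `rt_days` and `fcs_total` are required; the others
#' are validated when present.
#'
#' @param path CSV file.
#' @return A tibble.
#' @export
read_observations_csv <- function(path) {
  x <- read_checked_table(path,
    required = c("reactor_id", "rt_days", "fcs_total"),
    numeric_cols = c("rt_days", "fcs_total", "fcs_glucan", "fcs_xylan",
      "ch4_frac", "co2_frac", "vfa_g_per_l", "ph"),
    delim = ",", what = "observation table")
  if (nrow(x) == 0) return(x)
  if (any(x$rt_days <= 0, na.rm = TRUE)) {
    stop_domain(sprintf("%s: rt_days must be > 0", path),
      "thermodigest_schema_error")
  }
  for (col in intersect(c("fcs_total", "fcs_glucan", "fcs_xylan"), names(x))) {
    if (any(x[[col]] < 0 | x[[col]] > 1, na.rm = TRUE)) {
      stop_domain(sprintf("%s: %s outside [0, 1]", path, col),
        "thermodigest_schema_error")
    }
  }
  if (all(c("ch4_frac", "co2_frac") %in% names(x)) &&
      any(x$ch4_frac + x$co2_frac > 1 + 1e-9, na.rm = TRUE)) {
    stop_domain(sprintf("%s: ch4_frac + co2_frac exceeds 1", path),
      "thermodigest_schema_error")
  }
  x
}

#' Write a tab-separated table
#'
#' UTF-8, tab-separated, `.` decimal — the dialect every reader in the
#' package accepts back.
#'
#' @param x Data frame (list-columns are dropped with a warning).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  listcols <- names(x)[vapply(x, is.list, logical(1))]
  if (length(listcols) > 0) {
    warn(paste0("dropping list column(s) for TSV export: ",
      paste(listcols, collapse = ", ")))
    x <- x[setdiff(names(x), listcols)]
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Write observations as CSV
#'
#' @param x Observation tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_observations_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Export the pruned match network as GraphML
#'
#' Bins become vertices (with a `sample` attribute); same-organism edges
#' carry both directional best-hit proportions.
#'
#' @param edges Edge tibble from [match_bins()]; only
#'   `is_same_organism` rows are exported.
#' @param path Output `.graphml` file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(edges, path) {
  edges <- dplyr::filter(as_tibble(edges), .data$is_same_organism)
  verts <- dplyr::bind_rows(
    dplyr::select(edges, name = "bin_a", sample = "sample_a"),
    dplyr::select(edges, name = "bin_b", sample = "sample_b")
  ) |> dplyr::distinct()
  g <- igraph::graph_from_data_frame(
    edges[, c("bin_a", "bin_b", "prop_a_to_b", "prop_b_to_a")],
    directed = FALSE, vertices = verts)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a kinetic fit report as JSON
#'
#' @param fit A `recalcitrance_fit`.
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "recalcitrance_fit"))
  jsonlite::write_json(list(
    k = fit$k, k_se = fit$k_se, f_r = fit$f_r, f_r_se = fit$f_r_se,
    c0 = fit$c0, r_squared = fit$r_squared,
    points = fit$points
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write organism tracks as JSON
#'
#' @param tracks Track tibble.
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
write_tracks_json <- function(tracks, path) {
  jsonlite::write_json(tracks, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
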