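#' Pipeline thresholds
#'
#' All tunable thresholds of the bin-tracking pipeline with their standard
#' defaults: best-hit proportion 0.70 and identity 90% for the
#' same-organism rule, completeness >= 40% and contamination <= 20% for QC,
#' degree >= 3 and strictly more than 3 samples for track retention,
#' ANI > 95% for species assignment, and the strict 70% pathway
#' partial-completeness band.
#'
#' @param prop_threshold Same-organism best-hit proportion threshold.
#' @param id_threshold Percent-identity cutoff for best hits.
#' @param min_completeness Minimum bin completeness kept by QC, percent.
#' @param max_contamination Maximum bin contamination kept by QC, percent.
#' @param min_edges Minimum degree a bin must retain in the network.
#' @param min_samples_exclusive Tracks must span strictly more samples.
#' @param species_ani_threshold ANI percent for species assignment.
#' @param pathway_partial_threshold Strict lower bound of the partial-high
#'   pathway band.
#' @return A validated list of class `run_thresholds`.
#' @export
run_thresholds <- function(prop_threshold = 0.70, id_threshold = 90,
                           min_completeness = 40, max_contamination = 20,
                           min_edges = 3, min_samples_exclusive = 3,
                           species_ani_threshold = 95,
                           pathway_partial_threshold = 0.70) {
  checks <- c(
    "prop_threshold must lie in [0, 1]" =
      prop_threshold >= 0 && prop_threshold <= 1,
    "id_threshold must lie in [0, 100]" =
      id_threshold >= 0 && id_threshold <= 100,
    "min_completeness must lie in [0, 100]" =
      min_completeness >= 0 && min_completeness <= 100,
    "max_contamination must be >= 0" = max_contamination >= 0,
    "min_edges must be a non-negative integer" =
      min_edges >= 0 && min_edges == round(min_edges),
    "min_samples_exclusive must be a non-negative integer" =
      min_samples_exclusive >= 0 &&
        min_samples_exclusive == round(min_samples_exclusive),
    "species_ani_threshold must lie in [0, 100]" =
      species_ani_threshold >= 0 && species_ani_threshold <= 100,
    "pathway_partial_threshold must lie in [0, 1]" =
      pathway_partial_threshold >= 0 && pathway_partial_threshold <= 1
  )
  if (!all(checks)) {
    stop_domain(paste0("invalid thresholds: ",
      paste(names(checks)[!checks], collapse = "; ")),
      "thermodigest_config_error")
  }
  structure(
    list(
      prop_threshold = prop_threshold, id_threshold = id_threshold,
      min_completeness = min_completeness,
      max_contamination = max_contamination, min_edges = min_edges,
      min_samples_exclusive = min_samples_exclusive,
      species_ani_threshold = species_ani_threshold,
      pathway_partial_threshold = pathway_partial_threshold
    ),
    class = "run_thresholds"
  )
}

#' Run the bin-tracking pipeline
#'
#' Chains the matching stages in their canonical order: all-pairs bin
#' matching, QC filtering, iterative network pruning and track assembly,
#' then (when the corresponding inputs are supplied) taxonomy assignment,
#' relative abundance, pathway completeness and CAZyme profiling. Every
#' threshold application is logged with before/after counts. Deterministic
#' given its inputs.
#'
#' @param bins Bin table ([as_bin_table()]).
#' @param qc QC tibble (`bin_id`, `completeness`, `contamination`).
#' @param annotations Optional annotation table for marker/CAZyme profiling.
#' @param ani Optional ANI tibble for taxonomy.
#' @param coverage Optional coverage tibble for abundance.
#' @param marker_sets Marker sets for [pathway_completeness()].
#' @param thresholds A [run_thresholds()] list.
#' @param output_dir Optional directory; when given, writes `edges.tsv`,
#'   `network.graphml`, `tracks.json`, `pathways.tsv`, `cazymes.tsv` and
#'   `log.tsv` there.
#' @return A list of class `digest_pipeline`: `edges`, `edges_qc`,
#'   `tracks`, `pathways`, `cazymes`, `log` (a tibble of stage counts),
#'   `thresholds`.
#' @export
run_pipeline <- function(bins, qc, annotations = NULL, ani = NULL,
                         coverage = NULL, marker_sets = default_marker_sets(),
                         thresholds = run_thresholds(), output_dir = NULL) {
  stopifnot(inherits(thresholds, "run_thresholds"))
  th <- thresholds
  log_rows <- list()
  note <- function(stage, detail, n_before, n_after) {
    log_rows[[length(log_rows) + 1]] <<- tibble(
      stage = stage, detail = detail,
      n_before = n_before, n_after = n_after)
  }

  bins <- as_bin_table(bins)
  edges <- match_bins(bins, prop_threshold = th$prop_threshold,
    id_threshold = th$id_threshold)
  note("match", sprintf("same-organism rule: prop >= %.2f, identity > %g",
    th$prop_threshold, th$id_threshold),
    nrow(edges), sum(edges$is_same_organism))

  edges_qc <- qc_filter(edges, qc,
    max_contamination = th$max_contamination,
    min_completeness = th$min_completeness)
  note("qc_filter", sprintf("contamination <= %g, completeness >= %g",
    th$max_contamination, th$min_completeness),
    nrow(edges), nrow(edges_qc))

  tracks <- build_tracks(edges_qc, min_edges = th$min_edges,
    min_samples_exclusive = th$min_samples_exclusive)
  note("build_tracks", sprintf("degree >= %d, samples > %d",
    th$min_edges, th$min_samples_exclusive),
    sum(edges_qc$is_same_organism), nrow(tracks))

  if (!is.null(ani) && nrow(tracks) > 0) {
    tracks <- assign_taxonomy(tracks, ani,
      species_threshold = th$species_ani_threshold)
    note("taxonomy", sprintf("ANI > %g (both methods)",
      th$species_ani_threshold), nrow(tracks),
      sum(tracks$taxonomy_flag == "ani"))
  }
  if (!is.null(coverage) && nrow(tracks) > 0) {
    tracks <- track_relative_abundance(tracks, coverage)
  }

  pathways <- NULL
  cazymes <- NULL
  if (!is.null(annotations) && nrow(tracks) > 0) {
    annotations <- as_annotation_table(annotations)
    pathways <- pathway_completeness(tracks, annotations,
      marker_sets = marker_sets,
      partial_threshold = th$pathway_partial_threshold)
    note("pathways", sprintf("complete = 1, partial > %g",
      th$pathway_partial_threshold), nrow(pathways),
      sum(pathways$status == "complete"))
    cazymes <- cazyme_profile(tracks, annotations)
  }

  log_tbl <- purrr::list_rbind(log_rows)
  out <- structure(
    list(edges = edges, edges_qc = edges_qc, tracks = tracks,
      pathways = pathways, cazymes = cazymes, log = log_tbl,
      thresholds = th),
    class = "digest_pipeline"
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_table(edges_qc, file.path(output_dir, "edges.tsv"))
    if (any(edges_qc$is_same_organism)) {
      write_network_graphml(edges_qc, file.path(output_dir, "network.graphml"))
    }
    write_tracks_json(tracks, file.path(output_dir, "tracks.json"))
    if (!is.null(pathways)) {
      write_tsv_table(pathways, file.path(output_dir, "pathways.tsv"))
      write_tsv_table(cazymes, file.path(output_dir, "cazymes.tsv"))
    }
    write_tsv_table(log_tbl, file.path(output_dir, "log.tsv"))
  }
  out
}

#' @export
print.digest_pipeline <- function(x, ...) {
  cat("Cross-metagenome bin-tracking pipeline\n")
  cat(sprintf("  %d cross-sample bin pairs, %d same-organism edges (%d after QC)\n",
    nrow(x$edges), sum(x$edges$is_same_organism),
    sum(x$edges_qc$is_same_organism)))
  cat(sprintf("  %d organism tracks retained\n", nrow(x$tracks)))
  if (!is.null(x$pathways)) {
    cat(sprintf("  %d pathway calls (%d complete)\n", nrow(x$pathways),
      sum(x$pathways$status == "complete")))
  }
  invisible(x)
}
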