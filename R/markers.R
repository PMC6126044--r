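#' Validate a domain-annotation table
#'
#' One row per domain assignment: `protein_id`, `bin_id`, `marker_id`
#' (CAZy family, Pfam accession or KO id), `category`
#' (`"CAZy" | "pfam" | "KO"`) and 1-based inclusive residue coordinates
#' `start`, `end`.
#'
#' @param x Data frame with the columns above.
#' @return The validated tibble.
#' @export
as_annotation_table <- function(x) {
  x <- as_tibble(x)
  req <- c("protein_id", "bin_id", "marker_id", "category", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop_domain(paste0("annotation table is missing column(s): ",
      paste(missing_cols, collapse = ", ")), "thermodigest_schema_error")
  }
  if (nrow(x) > 0) {
    if (any(is.na(x$marker_id)) || any(x$marker_id == "")) {
      stop_domain("marker_id must be non-empty", "thermodigest_domain_error")
    }
    if (any(x$start > x$end) || any(x$start < 1)) {
      stop_domain("domain coordinates must satisfy 1 <= start <= end",
        "thermodigest_domain_error")
    }
  }
  x
}

#' Consensus marker presence across a track's bins
#'
#' A track (organism) is considered to encode a marker when strictly more
#' than half of its member bins carry at least one annotation with that
#' marker id. An exact half is a tie and counts as absent ("majority" read
#' strictly).
#'
#' @param member_bins Character vector of the track's bin ids.
#' @param annotations Annotation table ([as_annotation_table()]).
#' @param marker_id Marker id(s) to test.
#' @return Logical vector, one element per `marker_id`.
#' @export
consensus_marker_presence <- function(member_bins, annotations, marker_id) {
  annotations <- as_annotation_table(annotations)
  if (length(member_bins) == 0) {
    stop_domain("track has no member bins", "thermodigest_domain_error")
  }
  vapply(marker_id, function(m) {
    carrying <- unique(annotations$bin_id[annotations$marker_id == m])
    sum(member_bins %in% carrying) > length(member_bins) / 2
  }, logical(1), USE.NAMES = FALSE)
}

#' Default marker sets
#'
#' Ships only the Pfam accessions the package documents explicitly: xylose
#' catabolism (xylose isomerase pfam01261; xylulokinase pfam00370 +
#' pfam02782), and single sentinel markers for syntrophic acetate oxidation
#' (formyltetrahydrofolate synthetase, pfam01268) and butyrate oxidation
#' (formate dehydrogenase accessory protein, pfam04216). These are starting
#' points: supply complete curated sets (e.g. MetaCyc-derived) for real
#' pathway-completeness analyses.
#'
#' @return A tibble with columns `set_id`, `marker_id`, `note`.
#' @export
default_marker_sets <- function() {
  tibble(
    set_id = c(rep("xylose_catabolism", 3), "acetate_oxidation",
      "butyrate_oxidation"),
    marker_id = c("pfam01261", "pfam00370", "pfam02782", "pfam01268",
      "pfam04216"),
    note = c("xylose isomerase", "xylulokinase", "xylulokinase C-terminal",
      "formyltetrahydrofolate synthetase (Wood-Ljungdahl, reverse)",
      "FDH accessory protein (butyrate syntrophy sentinel)")
  )
}

#' Pathway completeness of a track
#'
#' Fraction of a marker set present by [consensus_marker_presence()], with
#' the display classification used for community figures: `complete` when
#' every member is present, `partial_high` when strictly more than 70% (but
#' not all) are present, `incomplete` otherwise. Exactly 70% is classified
#' incomplete (the threshold is strict).
#'
#' @param tracks Track tibble from [build_tracks()].
#' @param annotations Annotation table.
#' @param marker_sets Tibble with columns `set_id`, `marker_id`; defaults to
#'   [default_marker_sets()].
#' @param partial_threshold Strict lower bound of the `partial_high` band.
#' @return A tibble with one row per track x marker set: `track_id`,
#'   `set_id`, `n_markers`, `n_present`, `fraction`, `status`.
#' @export
pathway_completeness <- function(tracks, annotations,
                                 marker_sets = default_marker_sets(),
                                 partial_threshold = 0.70) {
  tracks <- as_tibble(tracks)
  annotations <- as_annotation_table(annotations)
  marker_sets <- as_tibble(marker_sets)
  stopifnot(all(c("set_id", "marker_id") %in% names(marker_sets)))
  marker_sets <- dplyr::distinct(marker_sets, .data$set_id, .data$marker_id)
  if (nrow(marker_sets) == 0) {
    stop_domain("marker_sets is empty", "thermodigest_domain_error")
  }
  sets <- split(marker_sets$marker_id, marker_sets$set_id)
  purrr::map(seq_len(nrow(tracks)), function(i) {
    bins <- tracks$member_bins[[i]]
    purrr::imap(sets, function(members, sid) {
      present <- consensus_marker_presence(bins, annotations, members)
      frac <- mean(present)
      tibble(
        track_id = tracks$track_id[i], set_id = sid,
        n_markers = length(members), n_present = sum(present),
        fraction = frac,
        status = if (frac == 1) "complete"
          else if (frac > partial_threshold) "partial_high"
          else "incomplete"
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' CAZyme inventory of a track
#'
#' Summarises the carbohydrate-active-enzyme complement of a track from its
#' CAZy-category annotations, normalized per member bin (total domain count
#' divided by the number of matching bins, so deeper-sampled organisms do
#' not look artificially enzyme-rich). A protein is a modular enzyme when
#' it carries two or more CAZy-category domains. GH48, diagnostic of
#' crystalline-cellulose degraders, is flagged if present in any member
#' bin. Dockerin and cohesin modules are identified by configurable marker
#' ids (standard Pfam accessions by default).
#'
#' @param tracks Track tibble from [build_tracks()].
#' @param annotations Annotation table; only `category == "CAZy"` rows are
#'   used.
#' @param dockerin_ids,cohesin_ids Marker ids counted as dockerin/cohesin.
#' @return A tibble, one row per track: `track_id`,
#'   `total_domains_normalized`, `n_families`, `n_gh_domains`,
#'   `n_modular_enzymes`, `n_dockerins`, `n_cohesins`, `has_gh48`.
#' @export
cazyme_profile <- function(tracks, annotations,
                           dockerin_ids = "PF00404",
                           cohesin_ids = "PF00963") {
  tracks <- as_tibble(tracks)
  annotations <- as_annotation_table(annotations)
  caz <- dplyr::filter(annotations, .data$category == "CAZy")
  purrr::map(seq_len(nrow(tracks)), function(i) {
    bins <- tracks$member_bins[[i]]
    a <- dplyr::filter(caz, .data$bin_id %in% bins)
    per_protein <- dplyr::count(a, .data$bin_id, .data$protein_id)
    tibble(
      track_id = tracks$track_id[i],
      total_domains_normalized = nrow(a) / length(bins),
      n_families = dplyr::n_distinct(a$marker_id),
      n_gh_domains = sum(grepl("^GH[0-9]+$", a$marker_id)),
      n_modular_enzymes = sum(per_protein$n >= 2),
      n_dockerins = sum(a$marker_id %in% dockerin_ids),
      n_cohesins = sum(a$marker_id %in% cohesin_ids),
      has_gh48 = any(a$marker_id == "GH48")
    )
  }) |> purrr::list_rbind()
}

#' Modular architecture string of a protein
#'
#' Domain ids joined by `-` in ascending start-coordinate order; domains
#' starting at the same residue are ordered longest first. An unannotated
#' protein yields an empty string with attribute `unannotated = TRUE`.
#'
#' @param protein Protein id to describe.
#' @param annotations Annotation table.
#' @return Architecture string such as `"GH11-CBM6-GH10-CBM6-DOC"`.
#' @export
modular_architecture <- function(protein, annotations) {
  annotations <- as_annotation_table(annotations)
  a <- dplyr::filter(annotations, .data$protein_id == protein)
  if (nrow(a) == 0) {
    return(structure("", unannotated = TRUE))
  }
  a <- dplyr::arrange(a, .data$start, dplyr::desc(.data$end - .data$start))
  paste(a$marker_id, collapse = "-")
}
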