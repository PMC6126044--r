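# Directed protein hits between bins.
#
# Returns one row per (query bin, query protein, target bin) pair for which
# the best-hit identity exceeds `id_threshold`. Identical sequences are
# matched by string equality (identity 100); near-identical pairs are found
# through the lossless k-mer prefilter and scored by exact local alignment.
directed_hits <- function(prot, seqs_unique, id_threshold, k) {
  qt <- dplyr::select(prot, q_bin = "bin_id", q_sample = "sample_id",
    q_protein = "protein_id", "seq")
  tt <- dplyr::select(prot, t_bin = "bin_id", t_sample = "sample_id", "seq")

  # exact-copy hits: same deduplicated sequence index
  same <- dplyr::inner_join(qt, tt, by = "seq",
    relationship = "many-to-many") |>
    dplyr::filter(.data$q_sample != .data$t_sample) |>
    dplyr::mutate(identity = 100)

  near <- candidate_seq_pairs(seqs_unique, k)
  if (nrow(near) > 0) {
    near$identity <- purrr::map2_dbl(near$seq_a, near$seq_b,
      function(a, b) protein_identity(seqs_unique[a], seqs_unique[b]))
    near <- dplyr::filter(near, .data$identity > id_threshold)
  }
  if (nrow(near) > 0) {
    near_both <- dplyr::bind_rows(
      dplyr::rename(near, q_seq = "seq_a", t_seq = "seq_b"),
      dplyr::rename(near, q_seq = "seq_b", t_seq = "seq_a")
    )
    near_hits <- qt |>
      dplyr::rename(q_seq = "seq") |>
      dplyr::inner_join(near_both, by = "q_seq",
        relationship = "many-to-many") |>
      dplyr::inner_join(dplyr::rename(tt, t_seq = "seq"), by = "t_seq",
        relationship = "many-to-many") |>
      dplyr::filter(.data$q_sample != .data$t_sample) |>
      dplyr::select("q_bin", "q_sample", "q_protein", "t_bin", "t_sample",
        "identity")
    same <- dplyr::bind_rows(
      dplyr::select(same, "q_bin", "q_sample", "q_protein", "t_bin",
        "t_sample", "identity"),
      near_hits
    )
  } else {
    same <- dplyr::select(same, "q_bin", "q_sample", "q_protein", "t_bin",
      "t_sample", "identity")
  }
  dplyr::filter(same, .data$identity > id_threshold) |>
    dplyr::distinct(.data$q_bin, .data$q_protein, .data$t_bin,
      .keep_all = TRUE)
}

#' Match genome bins across metagenome samples
#'
#' For every pair of bins from different samples, computes the two
#' directional best-hit proportions — the fraction of one bin's proteins
#' whose best local-alignment identity in the other bin strictly exceeds
#' `id_threshold` — and calls the pair the same organism when either
#' direction reaches `prop_threshold`. The either-direction rule lets a
#' complete bin match a fragment of itself recovered at lower coverage.
#' Proteins with no hit at all still count in the denominator.
#'
#' Candidate protein pairs are generated by an exact-`k`-mer prefilter that
#' is lossless above the identity threshold for proteins of at least 89
#' residues (a >90%-identity local alignment must contain a shared exact run
#' of at least 8 residues), then scored by Smith-Waterman alignment
#' ([protein_identity()]).
#'
#' @param bins A bin table ([as_bin_table()]) covering two or more samples.
#' @param prop_threshold Minimum best-hit proportion to call two bins the
#'   same organism (default 0.70).
#' @param id_threshold Percent-identity cutoff a best hit must strictly
#'   exceed (default 90).
#' @param k Prefilter k-mer size; 8 keeps the filter lossless at the default
#'   identity threshold for proteins >= 89 aa.
#' @return A tibble with one row per unordered cross-sample bin pair:
#'   `bin_a`, `bin_b`, `sample_a`, `sample_b`, `prop_a_to_b`, `prop_b_to_a`,
#'   `is_same_organism`.
#' @export
match_bins <- function(bins, prop_threshold = 0.70, id_threshold = 90, k = 8) {
  bins <- as_bin_table(bins)
  if (prop_threshold < 0 || prop_threshold > 1) {
    stop_domain("prop_threshold must lie in [0, 1]", "thermodigest_config_error")
  }
  if (dplyr::n_distinct(bins$sample_id) < 2) {
    stop_domain("bin matching needs bins from at least two samples",
      "thermodigest_domain_error")
  }
  seqs_unique <- unique(bins$sequence)
  prot <- dplyr::mutate(bins, seq = match(.data$sequence, seqs_unique))

  hits <- directed_hits(prot, seqs_unique, id_threshold, k)
  n_pass <- dplyr::count(hits, .data$q_bin, .data$t_bin, name = "n_pass")

  meta <- dplyr::distinct(prot, .data$bin_id, .data$sample_id) |>
    dplyr::left_join(dplyr::count(prot, .data$bin_id, name = "n_proteins"),
      by = "bin_id")
  ord <- meta$bin_id
  pairs <- tidyr::expand_grid(bin_a = ord, bin_b = ord) |>
    dplyr::filter(match(.data$bin_a, ord) < match(.data$bin_b, ord)) |>
    dplyr::left_join(
      setNames(meta, c("bin_a", "sample_a", "n_a")), by = "bin_a") |>
    dplyr::left_join(
      setNames(meta, c("bin_b", "sample_b", "n_b")), by = "bin_b") |>
    dplyr::filter(.data$sample_a != .data$sample_b)

  pairs |>
    dplyr::left_join(setNames(n_pass, c("bin_a", "bin_b", "n_ab")),
      by = c("bin_a", "bin_b")) |>
    dplyr::left_join(setNames(n_pass, c("bin_b", "bin_a", "n_ba")),
      by = c("bin_a", "bin_b")) |>
    dplyr::mutate(
      prop_a_to_b = dplyr::coalesce(.data$n_ab, 0L) / .data$n_a,
      prop_b_to_a = dplyr::coalesce(.data$n_ba, 0L) / .data$n_b,
      is_same_organism =
        pmax(.data$prop_a_to_b, .data$prop_b_to_a) >= prop_threshold
    ) |>
    dplyr::select("bin_a", "bin_b", "sample_a", "sample_b",
      "prop_a_to_b", "prop_b_to_a", "is_same_organism")
}

#' Directional best-hit proportion between two bins
#'
#' Fraction of `query` proteins whose best-hit identity in `target` strictly
#' exceeds `id_threshold`; proteins with no hit count in the denominator.
#'
#' @param query,target Bin tables each holding a single bin, from different
#'   samples.
#' @inheritParams match_bins
#' @return A fraction in `[0, 1]`.
#' @export
best_hit_proportion <- function(query, target, id_threshold = 90, k = 8) {
  query <- as_bin_table(query)
  target <- as_bin_table(target)
  stopifnot(dplyr::n_distinct(query$bin_id) == 1,
    dplyr::n_distinct(target$bin_id) == 1)
  if (query$sample_id[1] == target$sample_id[1]) {
    stop_domain("query and target bins come from the same sample; cross-sample comparisons only",
      "thermodigest_domain_error")
  }
  edge <- same_organism(query, target, id_threshold = id_threshold, k = k)
  if (edge$bin_a[1] == query$bin_id[1]) edge$prop_a_to_b else edge$prop_b_to_a
}

#' Same-organism call for one pair of bins
#'
#' Applies the cross-sample matching rule to a single bin pair; see
#' [match_bins()] for the rule and thresholds.
#'
#' @param bin_a,bin_b Bin tables each holding a single bin, from different
#'   samples.
#' @inheritParams match_bins
#' @return A one-row edge tibble as returned by [match_bins()].
#' @export
same_organism <- function(bin_a, bin_b, prop_threshold = 0.70,
                          id_threshold = 90, k = 8) {
  bin_a <- as_bin_table(bin_a)
  bin_b <- as_bin_table(bin_b)
  stopifnot(dplyr::n_distinct(bin_a$bin_id) == 1,
    dplyr::n_distinct(bin_b$bin_id) == 1)
  if (bin_a$bin_id[1] == bin_b$bin_id[1]) {
    stop_domain("the two bins must be distinct", "thermodigest_domain_error")
  }
  match_bins(dplyr::bind_rows(bin_a, bin_b),
    prop_threshold = prop_threshold, id_threshold = id_threshold, k = k)
}

#' Remove edges touching low-quality bins
#'
#' An edge survives only if both endpoint bins have contamination at or
#' below `max_contamination` percent and completeness at or above
#' `min_completeness` percent; boundary values survive. Every bin referenced
#' by an edge must have a QC record.
#'
#' @param edges Edge tibble from [match_bins()].
#' @param qc QC tibble with columns `bin_id`, `completeness`,
#'   `contamination` (percent); `strain_heterogeneity` is carried but not
#'   used.
#' @param max_contamination,min_completeness Thresholds in percent.
#' @return The surviving edges.
#' @export
qc_filter <- function(edges, qc, max_contamination = 20,
                      min_completeness = 40) {
  edges <- as_tibble(edges)
  qc <- as_tibble(qc)
  stopifnot(all(c("bin_id", "completeness", "contamination") %in% names(qc)))
  referenced <- unique(c(edges$bin_a, edges$bin_b))
  missing_qc <- setdiff(referenced, qc$bin_id)
  if (length(missing_qc) > 0) {
    stop_domain(paste0("no QC record for bin(s): ",
      paste(missing_qc, collapse = ", ")), "thermodigest_missing_qc")
  }
  ok <- qc$bin_id[qc$contamination <= max_contamination &
    qc$completeness >= min_completeness]
  dplyr::filter(edges, .data$bin_a %in% ok & .data$bin_b %in% ok)
}

#' Assemble organism tracks from the match network
#'
#' Builds the bin graph from same-organism edges, iteratively removes bins
#' supported by fewer than `min_edges` edges (recomputing degrees until the
#' graph is stable), takes connected components, and keeps components
#' spanning strictly more than `min_samples_exclusive` distinct samples.
#' With the defaults a track needs bins from at least four metagenomes,
#' each connected by at least three surviving edges.
#'
#' @param edges QC-filtered edge tibble; only rows with
#'   `is_same_organism == TRUE` are used.
#' @param min_edges Minimum degree a bin must retain.
#' @param min_samples_exclusive Components must span strictly more than
#'   this many samples.
#' @return A tibble with one row per track: `track_id`, `member_bins`
#'   (list-column), `n_bins`, `samples` (list-column), `samples_spanned`.
#' @export
build_tracks <- function(edges, min_edges = 3, min_samples_exclusive = 3) {
  edges <- dplyr::filter(as_tibble(edges), .data$is_same_organism)
  empty <- tibble(track_id = character(), member_bins = list(),
    n_bins = integer(), samples = list(), samples_spanned = integer())
  if (nrow(edges) == 0) return(empty)

  sample_of <- c(
    setNames(edges$sample_a, edges$bin_a),
    setNames(edges$sample_b, edges$bin_b)
  )
  sample_of <- sample_of[!duplicated(names(sample_of))]

  g <- igraph::graph_from_data_frame(
    edges[, c("bin_a", "bin_b")], directed = FALSE)
  repeat {
    weak <- igraph::V(g)[igraph::degree(g) < min_edges]
    if (length(weak) == 0) break
    g <- igraph::delete_vertices(g, weak)
  }
  if (igraph::vcount(g) == 0) return(empty)

  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  tracks <- purrr::map(members, function(b) {
    smp <- unique(unname(sample_of[b]))
    tibble(member_bins = list(sort(b)), n_bins = length(b),
      samples = list(sort(smp)), samples_spanned = length(smp))
  }) |>
    purrr::list_rbind() |>
    dplyr::filter(.data$samples_spanned > min_samples_exclusive)
  if (nrow(tracks) == 0) return(empty)
  tracks |>
    dplyr::arrange(dplyr::desc(.data$n_bins)) |>
    dplyr::mutate(track_id = sprintf("track_%02d", dplyr::row_number()),
      .before = 1)
}

#' Assign species-level taxonomy from ANI evidence
#'
#' For each track, the reference genome with the highest effective ANI to
#' any member bin provides the species label, provided that ANI strictly
#' exceeds `species_threshold`. The effective ANI of a record is the
#' minimum of its BLAST and MUMmer estimates, so both methods must support
#' the call. Otherwise the coarser `rank_label` carried on the track is kept
#' unchanged. A tie between distinct references at the top is flagged
#' `ambiguous`; tracks without any ANI record are flagged `no_ani`.
#'
#' @param tracks Track tibble from [build_tracks()], optionally with a
#'   `rank_label` column (coarse taxonomy); missing labels default to
#'   `"unclassified"`.
#' @param ani_table Tibble with columns `bin_id`, `reference`, and either
#'   `ani_blast` + `ani_mummer` or a single `ani` column (percent).
#' @param species_threshold ANI percent a species call must strictly exceed.
#' @return `tracks` with `taxonomy_label` and `taxonomy_flag`
#'   (`"ani" | "rank" | "ambiguous" | "no_ani"`) columns.
#' @export
assign_taxonomy <- function(tracks, ani_table, species_threshold = 95) {
  tracks <- as_tibble(tracks)
  ani_table <- as_tibble(ani_table)
  if (!"rank_label" %in% names(tracks)) tracks$rank_label <- "unclassified"
  if (all(c("ani_blast", "ani_mummer") %in% names(ani_table))) {
    ani_table$ani <- pmin(ani_table$ani_blast, ani_table$ani_mummer)
  } else if (!"ani" %in% names(ani_table)) {
    stop_domain("ani_table needs ani_blast + ani_mummer, or ani",
      "thermodigest_schema_error")
  }
  one <- function(bins, rank_label) {
    rec <- dplyr::filter(ani_table, .data$bin_id %in% bins)
    if (nrow(rec) == 0) {
      return(tibble(taxonomy_label = rank_label, taxonomy_flag = "no_ani"))
    }
    by_ref <- dplyr::summarise(dplyr::group_by(rec, .data$reference),
      ani = max(.data$ani), .groups = "drop")
    top <- dplyr::filter(by_ref, .data$ani == max(.data$ani))
    if (top$ani[1] <= species_threshold) {
      return(tibble(taxonomy_label = rank_label, taxonomy_flag = "rank"))
    }
    if (nrow(top) > 1) {
      return(tibble(taxonomy_label = rank_label, taxonomy_flag = "ambiguous"))
    }
    tibble(taxonomy_label = top$reference[1], taxonomy_flag = "ani")
  }
  res <- purrr::map2(tracks$member_bins, tracks$rank_label, one) |>
    purrr::list_rbind()
  dplyr::bind_cols(
    dplyr::select(tracks, -dplyr::any_of(c("taxonomy_label", "taxonomy_flag"))),
    res
  )
}

#' Relative abundance of organism tracks
#'
#' Per sample, a track's relative abundance is its member bins' summed
#' coverage mass (coverage depth times sequence length, or any proportional
#' mass) as a percentage of the sample's total coverage mass over all bins
#' in the coverage table. The mean is taken over the samples in which the
#' track has at least one member bin.
#'
#' @param tracks Track tibble from [build_tracks()].
#' @param coverage Tibble with columns `bin_id`, `sample_id`,
#'   `coverage_mass` (>= 0).
#' @return `tracks` with `mean_relative_abundance` (percent) and an
#'   `abundance_by_sample` list-column of per-sample tibbles.
#' @export
track_relative_abundance <- function(tracks, coverage) {
  tracks <- as_tibble(tracks)
  coverage <- as_tibble(coverage)
  stopifnot(all(c("bin_id", "sample_id", "coverage_mass") %in% names(coverage)))
  if (any(coverage$coverage_mass < 0)) {
    stop_domain("coverage_mass must be >= 0", "thermodigest_domain_error")
  }
  totals <- dplyr::summarise(dplyr::group_by(coverage, .data$sample_id),
    total = sum(.data$coverage_mass), .groups = "drop")
  one <- function(bins) {
    per <- coverage |>
      dplyr::filter(.data$bin_id %in% bins) |>
      dplyr::summarise(mass = sum(.data$coverage_mass), .by = "sample_id") |>
      dplyr::left_join(totals, by = "sample_id")
    if (nrow(per) == 0) {
      return(list(mean_ra = NA_real_,
        by_sample = tibble(sample_id = character(), relative_abundance = numeric())))
    }
    if (any(per$total <= 0)) {
      stop_domain(sprintf("sample '%s' has zero total coverage mass",
        per$sample_id[per$total <= 0][1]), "thermodigest_domain_error")
    }
    per$relative_abundance <- 100 * per$mass / per$total
    list(mean_ra = mean(per$relative_abundance),
      by_sample = per[, c("sample_id", "relative_abundance")])
  }
  res <- purrr::map(tracks$member_bins, one)
  tracks$mean_relative_abundance <- purrr::map_dbl(res, "mean_ra")
  tracks$abundance_by_sample <- purrr::map(res, "by_sample")
  tracks
}
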