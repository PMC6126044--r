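AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Describe a synthetic multi-sample community
#'
#' Parameters of the ground-truthed benchmark generator: a set of
#' well-separated genomes (independent random protein complements, so
#' expected inter-genome identity stays far below the matching threshold),
#' observed across several metagenome samples as bins of controlled
#' completeness and contamination.
#'
#' @param n_genomes Number of ground-truth genomes (>= 2).
#' @param proteins_per_genome Proteins per genome.
#' @param protein_length_range Protein length bounds, amino acids.
#' @param n_samples Number of metagenome samples.
#' @param completeness_range Per-bin completeness bounds, percent.
#' @param contamination_range Per-bin contamination bounds, percent
#'   (contaminant-protein share of the bin).
#' @param n_markers Number of distinct genetic markers in the truth pool.
#' @param marker_prob Probability a genome carries a given marker.
#' @param marker_copies Carrier proteins per (genome, marker); several
#'   copies make marker presence robust to bin subsampling, emulating
#'   multi-copy gene families.
#' @param n_strain_pairs Genomes to duplicate as related strains by point
#'   mutation.
#' @param strain_mutation_rate Per-residue substitution rate for strain
#'   duplicates.
#' @param seed RNG seed; all generator output is a deterministic function
#'   of the scenario.
#' @return A list of class `community_scenario`.
#' @export
community_scenario <- function(n_genomes = 10, proteins_per_genome = 1000,
                               protein_length_range = c(100, 400),
                               n_samples = 4,
                               completeness_range = c(50, 95),
                               contamination_range = c(0, 10),
                               n_markers = 5, marker_prob = 0.5,
                               marker_copies = 6,
                               n_strain_pairs = 0,
                               strain_mutation_rate = 0.02,
                               seed = 1) {
  stopifnot(
    n_genomes >= 2, proteins_per_genome >= 1, n_samples >= 1,
    length(protein_length_range) == 2,
    protein_length_range[1] >= 1,
    protein_length_range[1] <= protein_length_range[2],
    completeness_range[1] > 0, completeness_range[2] <= 100,
    completeness_range[1] <= completeness_range[2],
    contamination_range[1] >= 0, contamination_range[2] < 100,
    n_strain_pairs <= n_genomes,
    strain_mutation_rate >= 0, strain_mutation_rate < 1
  )
  structure(
    list(
      n_genomes = n_genomes, proteins_per_genome = proteins_per_genome,
      protein_length_range = protein_length_range, n_samples = n_samples,
      completeness_range = completeness_range,
      contamination_range = contamination_range,
      n_markers = n_markers, marker_prob = marker_prob,
      marker_copies = marker_copies,
      n_strain_pairs = n_strain_pairs,
      strain_mutation_rate = strain_mutation_rate, seed = seed
    ),
    class = "community_scenario"
  )
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(old) {
      sample(setdiff(AA20, old), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Generate ground-truth genomes
#'
#' Draws each genome's protein complement independently at random (lengths
#' uniform in the scenario's range), assigns marker carriers, and
#' optionally emits related-strain duplicates by per-residue point
#' mutation for threshold-boundary experiments. Deterministic under the
#' scenario seed.
#'
#' @param scenario A [community_scenario()].
#' @return A list of class `synthetic_community`: `genomes` (tibble
#'   `genome_id`, `protein_id`, `sequence`), `markers` (tibble `genome_id`,
#'   `marker_id`, `protein_id` — the carrier proteins),
#'   `marker_profile` (tibble `genome_id`, `marker_id`), `scenario`.
#' @export
generate_community <- function(scenario) {
  stopifnot(inherits(scenario, "community_scenario"))
  with_seed(scenario$seed, {
    n <- scenario$n_genomes
    npp <- scenario$proteins_per_genome
    lr <- scenario$protein_length_range
    genomes <- purrr::map(seq_len(n), function(g) {
      lens <- sample(seq(lr[1], lr[2]), npp, replace = TRUE)
      tibble(
        genome_id = sprintf("G%02d", g),
        protein_id = sprintf("G%02d_P%04d", g, seq_len(npp)),
        sequence = vapply(lens, random_protein, character(1))
      )
    }) |> purrr::list_rbind()

    if (scenario$n_strain_pairs > 0) {
      strains <- purrr::map(seq_len(scenario$n_strain_pairs), function(g) {
        parent <- dplyr::filter(genomes,
          .data$genome_id == sprintf("G%02d", g))
        tibble(
          genome_id = sprintf("G%02d_strain", g),
          protein_id = sub(sprintf("^G%02d_", g),
            sprintf("G%02ds_", g), parent$protein_id),
          sequence = vapply(parent$sequence, mutate_protein, character(1),
            rate = scenario$strain_mutation_rate)
        )
      }) |> purrr::list_rbind()
      genomes <- dplyr::bind_rows(genomes, strains)
    }

    marker_ids <- sprintf("marker%02d", seq_len(scenario$n_markers))
    base_ids <- sprintf("G%02d", seq_len(n))
    markers <- purrr::map(base_ids, function(gid) {
      carried <- marker_ids[runif(scenario$n_markers) < scenario$marker_prob]
      if (length(carried) == 0) return(NULL)
      gp <- genomes$protein_id[genomes$genome_id == gid]
      purrr::map(carried, function(m) {
        tibble(genome_id = gid, marker_id = m,
          protein_id = sample(gp, min(scenario$marker_copies, length(gp))))
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
    if (is.null(markers)) {
      markers <- tibble(genome_id = character(), marker_id = character(),
        protein_id = character())
    }

    structure(
      list(
        genomes = genomes,
        markers = markers,
        marker_profile = dplyr::distinct(markers, .data$genome_id,
          .data$marker_id),
        scenario = scenario
      ),
      class = "synthetic_community"
    )
  })
}

#' Sample genome bins from a synthetic community
#'
#' Emulates multi-sample binning: in every sample each genome yields one
#' bin that retains a uniform random fraction of the genome's proteins
#' (the bin's completeness; rounding half-up gives an exact count) and is
#' padded with proteins drawn from the other genomes up to the target
#' contamination percent (contaminant proteins / total proteins x 100).
#' The emitted QC table reports the realized values exactly. Domain
#' annotations are inherited from the genome marker profile for retained
#' (non-contaminant) carrier proteins. Per-sample genome abundances are
#' drawn once and reported both as the coverage table and as truth.
#'
#' @param community A [generate_community()] result.
#' @param seed RNG seed; defaults to the scenario seed plus one so genome
#'   content and binning are independently reproducible.
#' @return A list: `bins` (bin table), `qc`, `annotations`, `coverage`,
#'   `truth` (tibble `bin_id`, `sample_id`, `genome_id`, `completeness`,
#'   `contamination`), `abundance_truth` (tibble `genome_id`, `sample_id`,
#'   `relative_abundance` percent).
#' @export
sample_bins <- function(community, seed = community$scenario$seed + 1) {
  stopifnot(inherits(community, "synthetic_community"))
  sc <- community$scenario
  genomes <- community$genomes
  genome_ids <- unique(genomes$genome_id)
  if (max(sc$contamination_range) > 0 && length(genome_ids) == 1) {
    stop_domain("contamination requires more than one genome",
      "thermodigest_config_error")
  }
  with_seed(seed, {
    abundance <- tidyr::expand_grid(
      genome_id = genome_ids,
      sample_id = sprintf("S%02d", seq_len(sc$n_samples))
    ) |>
      dplyr::mutate(mass = runif(dplyr::n(), 0.5, 1.5)) |>
      dplyr::mutate(
        relative_abundance = 100 * .data$mass / sum(.data$mass),
        .by = "sample_id"
      )

    per_genome <- split(genomes, genomes$genome_id)
    out <- purrr::map(seq_len(sc$n_samples), function(s) {
      sid <- sprintf("S%02d", s)
      purrr::map(genome_ids, function(gid) {
        gp <- per_genome[[gid]]
        n_tot <- nrow(gp)
        comp <- runif(1, sc$completeness_range[1], sc$completeness_range[2])
        n_keep <- max(1L, as.integer(round_half_up(comp / 100 * n_tot)))
        keep <- gp[sort(sample.int(n_tot, n_keep)), ]
        cont <- runif(1, sc$contamination_range[1], sc$contamination_range[2])
        n_cont <- as.integer(round_half_up(n_keep / (1 - cont / 100) - n_keep))
        contam <- NULL
        if (n_cont > 0) {
          pool <- genomes[genomes$genome_id != gid, ]
          contam <- pool[sample.int(nrow(pool), n_cont), ]
        }
        bin_id <- sprintf("%s_%s", sid, gid)
        proteins <- dplyr::bind_rows(keep, contam)
        list(
          bin = tibble(bin_id = bin_id, sample_id = sid,
            protein_id = proteins$protein_id, sequence = proteins$sequence),
          truth = tibble(
            bin_id = bin_id, sample_id = sid, genome_id = gid,
            completeness = 100 * n_keep / n_tot,
            contamination = 100 * n_cont / (n_keep + n_cont)
          ),
          retained = tibble(bin_id = bin_id, genome_id = gid,
            protein_id = keep$protein_id)
        )
      })
    }) |> purrr::list_flatten()

    bins <- purrr::map(out, "bin") |> purrr::list_rbind() |> as_bin_table()
    truth <- purrr::map(out, "truth") |> purrr::list_rbind()
    retained <- purrr::map(out, "retained") |> purrr::list_rbind()

    annotations <- retained |>
      dplyr::inner_join(community$markers,
        by = c("genome_id", "protein_id"),
        relationship = "many-to-many") |>
      dplyr::mutate(category = "pfam", start = 1L, end = 50L) |>
      dplyr::select("protein_id", "bin_id", "marker_id", "category",
        "start", "end")

    qc <- truth |>
      dplyr::transmute(.data$bin_id, .data$completeness,
        .data$contamination, strain_heterogeneity = 0)

    coverage <- truth |>
      dplyr::left_join(abundance, by = c("genome_id", "sample_id")) |>
      dplyr::transmute(.data$bin_id, .data$sample_id,
        coverage_mass = .data$mass)

    list(
      bins = bins, qc = qc, annotations = as_annotation_table(annotations),
      coverage = coverage, truth = truth,
      abundance_truth = dplyr::select(abundance, "genome_id", "sample_id",
        "relative_abundance")
    )
  })
}

#' Genome-mapping accuracy against ground truth
#'
#' Percentage of positive same-organism calls that link two bins derived
#' from the same truth genome (a related-strain duplicate counts as a
#' different genome).
#'
#' @param edges Edge tibble from [match_bins()].
#' @param truth Tibble mapping `bin_id` to `genome_id` (e.g. from
#'   [sample_bins()]).
#' @return A list: `accuracy` (percent, `NA` if no positive call),
#'   `n_calls`, `n_correct`.
#' @export
mapping_accuracy <- function(edges, truth) {
  edges <- dplyr::filter(as_tibble(edges), .data$is_same_organism)
  genome_of <- setNames(truth$genome_id, truth$bin_id)
  unknown <- setdiff(unique(c(edges$bin_a, edges$bin_b)), names(genome_of))
  if (length(unknown) > 0) {
    stop_domain(paste0("no truth genome for bin(s): ",
      paste(unknown, collapse = ", ")), "thermodigest_domain_error")
  }
  correct <- genome_of[edges$bin_a] == genome_of[edges$bin_b]
  list(
    accuracy = if (nrow(edges) == 0) NA_real_ else 100 * mean(correct),
    n_calls = nrow(edges),
    n_correct = sum(correct)
  )
}
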