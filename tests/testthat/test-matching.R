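make_query_target <- function(n_shared = 60, n_query = 100, n_target_extra = 40,
                              len = 100, seed = 201) {
  set.seed(seed)
  shared <- replicate(n_query, random_aa_seq(len))
  extra <- replicate(n_target_extra, random_aa_seq(len))
  query <- one_bin("binQ", "s1", shared)
  target <- one_bin("binT", "s2", c(shared[seq_len(n_shared)], extra))
  list(query = query, target = target)
}

test_that("best-hit proportion counts shared proteins over the query size", {
  qt <- make_query_target()
  expect_equal(best_hit_proportion(qt$query, qt$target), 0.60)

  ident <- dplyr::mutate(qt$query, bin_id = "binQ2", sample_id = "s2")
  expect_equal(best_hit_proportion(qt$query, ident), 1.0)

  set.seed(202)
  unrelated <- one_bin("binU", "s2", replicate(40, random_aa_seq(100)))
  expect_lt(best_hit_proportion(qt$query, unrelated), 0.02)

  same_sample <- dplyr::mutate(qt$target, sample_id = "s1")
  expect_error(best_hit_proportion(qt$query, same_sample),
    class = "thermodigest_domain_error")
})

test_that("best-hit proportion ignores protein order within bins", {
  qt <- make_query_target(seed = 203)
  set.seed(204)
  shuffled_q <- qt$query[sample.int(nrow(qt$query)), ]
  shuffled_t <- qt$target[sample.int(nrow(qt$target)), ]
  expect_equal(best_hit_proportion(shuffled_q, shuffled_t),
    best_hit_proportion(qt$query, qt$target))
})

test_that("same-organism rule takes the better direction at 70%", {
  qt <- make_query_target(seed = 205)
  edge60 <- same_organism(qt$query, qt$target)
  expect_false(edge60$is_same_organism)

  # a 75%-complete fragment of the same genome: fragment -> full is 1.0
  set.seed(206)
  frag <- qt$query[sample.int(100, 75), ] |>
    dplyr::mutate(bin_id = "binF", sample_id = "s3")
  edge_frag <- same_organism(qt$query, frag)
  expect_true(edge_frag$is_same_organism)
  props <- c(edge_frag$prop_a_to_b, edge_frag$prop_b_to_a)
  expect_equal(sort(props), c(0.75, 1.0))

  ident <- dplyr::mutate(qt$query, bin_id = "binQ2", sample_id = "s2")
  edge_id <- same_organism(qt$query, ident)
  expect_true(edge_id$is_same_organism)
  expect_equal(edge_id$prop_a_to_b, 1.0)
  expect_equal(edge_id$prop_b_to_a, 1.0)

  # symmetric boolean under argument order
  expect_equal(same_organism(qt$target, qt$query)$is_same_organism,
    edge60$is_same_organism)
})

test_that("match_bins agrees with pairwise same_organism calls", {
  set.seed(207)
  g1 <- replicate(30, random_aa_seq(100))
  g2 <- replicate(30, random_aa_seq(100))
  bins <- dplyr::bind_rows(
    one_bin("s1_g1", "s1", g1), one_bin("s2_g1", "s2", g1[1:24]),
    one_bin("s1_g2", "s1", g2), one_bin("s2_g2", "s2", g2[1:15])
  )
  edges <- match_bins(bins)
  expect_equal(nrow(edges), 4) # cross-sample pairs only
  e11 <- edges[edges$bin_a == "s1_g1" & edges$bin_b == "s2_g1", ]
  expect_true(e11$is_same_organism)
  expect_equal(sort(c(e11$prop_a_to_b, e11$prop_b_to_a)), c(0.8, 1.0))
  e12 <- edges[edges$bin_a == "s1_g1" & edges$bin_b == "s2_g2", ]
  expect_false(e12$is_same_organism)
  # 15/30 = 0.5 shared fragment fails the 70% rule both ways
  e22 <- edges[edges$bin_a == "s1_g2" & edges$bin_b == "s2_g2", ]
  expect_equal(max(e22$prop_a_to_b, e22$prop_b_to_a), 1.0)
  expect_true(e22$is_same_organism)
})

test_that("QC filter drops edges at the stated boundaries", {
  edges <- tibble::tibble(
    bin_a = c("a", "a", "a"), bin_b = c("b", "c", "d"),
    sample_a = "s1", sample_b = "s2",
    prop_a_to_b = 1, prop_b_to_a = 1, is_same_organism = TRUE
  )
  qc <- tibble::tibble(
    bin_id = c("a", "b", "c", "d"),
    completeness = c(95, 90, 39, 40),
    contamination = c(2, 25, 5, 20)
  )
  kept <- qc_filter(edges, qc)
  # b: contamination 25 > 20 (removed); c: completeness 39 < 40 (removed);
  # d: exactly at both boundaries (kept)
  expect_equal(kept$bin_b, "d")
  expect_error(qc_filter(edges, qc[-2, ]),
    class = "thermodigest_missing_qc")
  expect_match(tryCatch(qc_filter(edges, qc[-2, ]),
    error = conditionMessage), "b")
})

test_that("tightening QC thresholds never adds edges", {
  set.seed(208)
  for (trial in 1:20) {
    edges <- random_edge_set(15, 4, 0.4, seed = 300 + trial)
    if (nrow(edges) == 0) next
    bins <- unique(c(edges$bin_a, edges$bin_b))
    qc <- tibble::tibble(
      bin_id = bins,
      completeness = runif(length(bins), 20, 100),
      contamination = runif(length(bins), 0, 40)
    )
    loose <- qc_filter(edges, qc, max_contamination = 30,
      min_completeness = 30)
    tight1 <- qc_filter(edges, qc, max_contamination = 15,
      min_completeness = 30)
    tight2 <- qc_filter(edges, qc, max_contamination = 30,
      min_completeness = 60)
    key <- function(e) paste(e$bin_a, e$bin_b)
    expect_true(all(key(tight1) %in% key(loose)))
    expect_true(all(key(tight2) %in% key(loose)))
  }
})

test_that("track assembly prunes weak bins and small components", {
  # clique of 5 bins from 5 samples survives intact
  clique_bins <- sprintf("b%d", 1:5)
  pairs <- t(combn(5, 2))
  clique <- tibble::tibble(
    bin_a = clique_bins[pairs[, 1]], bin_b = clique_bins[pairs[, 2]],
    sample_a = sprintf("s%d", pairs[, 1]),
    sample_b = sprintf("s%d", pairs[, 2]),
    prop_a_to_b = 1, prop_b_to_a = 1, is_same_organism = TRUE
  )
  tr <- build_tracks(clique)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$samples_spanned, 5L)
  expect_equal(tr$member_bins[[1]], clique_bins)

  # chain A-B-C: degrees 1, 2, 1 all fall below 3
  chain <- tibble::tibble(
    bin_a = c("A", "B"), bin_b = c("B", "C"),
    sample_a = c("s1", "s2"), sample_b = c("s2", "s3"),
    prop_a_to_b = 1, prop_b_to_a = 1, is_same_organism = TRUE
  )
  expect_equal(nrow(build_tracks(chain)), 0)

  # a 6-bin clique spanning only 3 samples is dropped by the sample rule
  six <- sprintf("c%d", 1:6)
  p6 <- t(combn(6, 2))
  smp <- rep(c("s1", "s2", "s3"), 2)
  comp3 <- tibble::tibble(
    bin_a = six[p6[, 1]], bin_b = six[p6[, 2]],
    sample_a = smp[p6[, 1]], sample_b = smp[p6[, 2]],
    prop_a_to_b = 1, prop_b_to_a = 1, is_same_organism = TRUE
  )
  comp3 <- comp3[comp3$sample_a != comp3$sample_b, ]
  expect_equal(nrow(build_tracks(comp3)), 0)
})

test_that("track assembly equals the brute-force pruning/reachability oracle", {
  for (trial in 1:100) {
    edges <- random_edge_set(
      n_bins = sample(5:30, 1), n_samples = sample(2:6, 1),
      p = runif(1, 0.05, 0.5), seed = 1000 + trial)
    got <- build_tracks(edges)
    want <- bf_tracks(edges)
    got_sets <- lapply(got$member_bins, sort)
    expect_setequal(
      vapply(got_sets, paste, character(1), collapse = ","),
      vapply(want, paste, character(1), collapse = ","))
  }
})

test_that("ANI taxonomy picks the best doubly-supported reference above 95%", {
  tracks <- tibble::tibble(
    track_id = "track_01", member_bins = list(c("b1", "b2")),
    n_bins = 2L, samples = list(c("s1", "s2")), samples_spanned = 2L,
    rank_label = "Clostridia"
  )
  ani <- tibble::tibble(
    bin_id = c("b1", "b1", "b2"),
    reference = c("Defluviitoga tunisiensis", "Clostridium clariflavum",
      "Clostridium clariflavum"),
    ani_blast = c(94.0, 96.5, 96.2),
    ani_mummer = c(96.0, 96.2, 97.0)
  )
  out <- assign_taxonomy(tracks, ani)
  expect_equal(out$taxonomy_label, "Clostridium clariflavum")
  expect_equal(out$taxonomy_flag, "ani")

  below <- dplyr::mutate(ani, ani_blast = c(94, 94.9, 94.9),
    ani_mummer = c(94, 99, 99))
  out2 <- assign_taxonomy(tracks, below)
  expect_equal(out2$taxonomy_label, "Clostridia")
  expect_equal(out2$taxonomy_flag, "rank")

  tie <- tibble::tibble(
    bin_id = c("b1", "b1"), reference = c("spA", "spB"),
    ani = c(96.2, 96.2))
  expect_equal(assign_taxonomy(tracks, tie)$taxonomy_flag, "ambiguous")

  none <- tibble::tibble(bin_id = "zz", reference = "spA", ani = 99)
  out3 <- assign_taxonomy(tracks, none)
  expect_equal(out3$taxonomy_flag, "no_ani")
  expect_equal(out3$taxonomy_label, "Clostridia")
})

test_that("relative abundance is the per-sample coverage share", {
  tracks <- tibble::tibble(
    track_id = c("track_01", "track_02"),
    member_bins = list(c("b1", "b3"), "b2"))
  coverage <- tibble::tibble(
    bin_id = c("b1", "b2", "b3", "b4"),
    sample_id = c("s1", "s1", "s2", "s2"),
    coverage_mass = c(3, 1, 5, 0))
  out <- track_relative_abundance(tracks, coverage)
  expect_equal(out$mean_relative_abundance[1], mean(c(75, 100)))
  expect_equal(out$mean_relative_abundance[2], 25)

  solo <- track_relative_abundance(
    tibble::tibble(track_id = "t", member_bins = list("b3")),
    coverage[coverage$sample_id == "s2", ])
  expect_equal(solo$mean_relative_abundance, 100)

  zero <- tibble::tibble(bin_id = "b9", sample_id = "s9", coverage_mass = 0)
  expect_error(track_relative_abundance(
    tibble::tibble(track_id = "t", member_bins = list("b9")), zero),
    class = "thermodigest_domain_error")
})
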