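# Shared fixtures and independent oracles used across the suite.

# Published per-RT mean fractional solubilization values used as the
# canonical desk-scale kinetics fixture.
printed_obs <- function() {
  tibble::tibble(
    rt_days = c(20, 10, 5, 3.3),
    fcs_total = c(0.711, 0.654, 0.581, 0.538)
  )
}

switchgrass_composition <- function() {
  feedstock_composition(
    glucan_frac = 0.306, xylan_frac = 0.229, arabinan_frac = 0.0407,
    moisture_frac = 0.0605, ash_frac = 0.0592, cod_per_gram = 1.22
  )
}

# Closed-form OLS, computed from first principles (sums of squares), kept
# independent of stats::lm so fit results have a second route.
ols_oracle <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  list(slope = slope, intercept = yb - slope * xb)
}

# Discrete-operation steady state of the two-pool reactor, in closed form
# (geometric fixed point of the between-event map), independent of the
# event-loop simulator. Returns the sampled (pre-feed) FCS.
discrete_sampled_fcs <- function(k, f_r, c0, rt, feeds_per_rt = 10,
                                 replaced = 0.1) {
  q <- exp(-k * rt / feeds_per_rt)
  a_plus <- replaced * c0 * (1 - f_r) / (1 - (1 - replaced) * q)
  1 - (a_plus * q + c0 * f_r) / c0
}

# Noiseless-limit (k, f_r) estimand identified by fitting the rate law to
# sampled FCS from discrete operation at the given RTs.
discrete_fit_estimand <- function(k, f_r, c0, rts) {
  fcs <- vapply(rts, function(rt) discrete_sampled_fcs(k, f_r, c0, rt),
    numeric(1))
  o <- ols_oracle(c0 * (1 - fcs), c0 * fcs / rts)
  list(k = o$slope, f_r = -o$intercept / (o$slope * c0))
}

# Brute-force reference for build_tracks: explicit degree-pruning loop on an
# adjacency matrix, then components via transitive closure by boolean
# matrix powering. Returns the retained components as a set of sorted
# bin-id vectors.
bf_tracks <- function(edges, min_edges = 3, min_samples_exclusive = 3) {
  edges <- edges[edges$is_same_organism, ]
  if (nrow(edges) == 0) return(list())
  sample_of <- c(
    stats::setNames(edges$sample_a, edges$bin_a),
    stats::setNames(edges$sample_b, edges$bin_b)
  )
  sample_of <- sample_of[!duplicated(names(sample_of))]
  bins <- sort(unique(c(edges$bin_a, edges$bin_b)))
  adj <- matrix(FALSE, length(bins), length(bins),
    dimnames = list(bins, bins))
  for (i in seq_len(nrow(edges))) {
    adj[edges$bin_a[i], edges$bin_b[i]] <- TRUE
    adj[edges$bin_b[i], edges$bin_a[i]] <- TRUE
  }
  repeat {
    deg <- rowSums(adj)
    weak <- deg < min_edges
    if (!any(weak) || all(weak)) break
    adj <- adj[!weak, !weak, drop = FALSE]
  }
  if (nrow(adj) == 0 || all(rowSums(adj) < min_edges)) return(list())
  reach <- adj | diag(TRUE, nrow(adj))
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  seen <- character(0)
  comps <- list()
  for (b in rownames(reach)) {
    if (b %in% seen) next
    comp <- rownames(reach)[reach[b, ]]
    seen <- c(seen, comp)
    if (length(unique(sample_of[comp])) > min_samples_exclusive) {
      comps[[length(comps) + 1]] <- sort(comp)
    }
  }
  comps
}

# Random cross-sample same-organism edge sets for graph-property tests.
random_edge_set <- function(n_bins, n_samples, p, seed) {
  set.seed(seed)
  bins <- sprintf("b%02d", seq_len(n_bins))
  samples <- sprintf("s%d", sample.int(n_samples, n_bins, replace = TRUE))
  pairs <- t(utils::combn(n_bins, 2))
  cross <- samples[pairs[, 1]] != samples[pairs[, 2]]
  keep <- cross & stats::runif(nrow(pairs)) < p
  tibble::tibble(
    bin_a = bins[pairs[keep, 1]], bin_b = bins[pairs[keep, 2]],
    sample_a = samples[pairs[keep, 1]], sample_b = samples[pairs[keep, 2]],
    prop_a_to_b = 1, prop_b_to_a = 1, is_same_organism = TRUE
  )
}

random_aa_seq <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
    "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
    collapse = "")
}

# substitute exactly n interior residues (never the first/last 2 positions,
# so the optimal local alignment keeps full length)
substitute_interior <- function(seq, n) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(3:(length(chars) - 2), n)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "D", "E", "F", "G", "H", "I",
      "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
      chars[p]), 1)
  }
  paste(chars, collapse = "")
}

one_bin <- function(bin_id, sample_id, seqs, prefix = bin_id) {
  tibble::tibble(
    bin_id = bin_id, sample_id = sample_id,
    protein_id = sprintf("%s_p%03d", prefix, seq_along(seqs)),
    sequence = seqs
  )
}
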