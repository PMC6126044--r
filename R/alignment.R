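AA_ALPHABET_RE <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

#' Assemble and validate a bin table
#'
#' The package represents genome bins in long form: one row per predicted
#' protein, with columns `bin_id`, `sample_id` (metagenome of origin),
#' `protein_id` and `sequence` (amino acids, 20-letter alphabet plus X).
#' This checks the invariants every matching function relies on: at least
#' one protein per bin, protein ids unique within a bin, non-empty valid
#' sequences, and one sample per bin.
#'
#' @param x Data frame with the four columns above.
#' @return The validated tibble (class `bin_tbl` prepended).
#' @export
as_bin_table <- function(x) {
  x <- as_tibble(x)
  req <- c("bin_id", "sample_id", "protein_id", "sequence")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop_domain(paste0("bin table is missing column(s): ",
      paste(missing_cols, collapse = ", ")), "thermodigest_schema_error")
  }
  if (nrow(x) == 0) {
    stop_domain("bin table has no proteins", "thermodigest_domain_error")
  }
  if (any(is.na(x$sequence)) || any(nchar(x$sequence) == 0)) {
    stop_domain("empty protein sequence", "thermodigest_domain_error")
  }
  bad <- !grepl(AA_ALPHABET_RE, x$sequence)
  if (any(bad)) {
    stop_domain(sprintf(
      "protein %s has characters outside the amino-acid alphabet (20 letters + X)",
      x$protein_id[which(bad)[1]]), "thermodigest_domain_error")
  }
  dup <- dplyr::count(x, .data$bin_id, .data$protein_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_domain(sprintf("duplicate protein id '%s' in bin '%s'",
      dup$protein_id[1], dup$bin_id[1]), "thermodigest_domain_error")
  }
  multi <- dplyr::distinct(x, .data$bin_id, .data$sample_id) |>
    dplyr::count(.data$bin_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    stop_domain(sprintf("bin '%s' is assigned to more than one sample",
      multi$bin_id[1]), "thermodigest_domain_error")
  }
  if (!inherits(x, "bin_tbl")) class(x) <- c("bin_tbl", class(x))
  x
}

#' Percent identity between two proteins
#'
#' Exact local (Smith-Waterman) alignment with affine gap penalties and the
#' BLOSUM62 substitution matrix, via [Biostrings::pairwiseAlignment()].
#' Identity is the percentage of identical aligned residues over the length
#' of the shorter sequence, so `protein_identity(s, s)` is 100, the measure
#' is symmetric, and a short perfect local segment between otherwise
#' unrelated proteins cannot masquerade as a high-identity match (dividing
#' by the local alignment length would let a 5-residue exact hit score
#' 100%).
#'
#' @param seq_a,seq_b Amino-acid sequences (character scalars).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Percent identity in `[0, 100]`.
#' @export
protein_identity <- function(seq_a, seq_b, gap_opening = 10,
                             gap_extension = 1) {
  if (!is.character(seq_a) || !is.character(seq_b) ||
      length(seq_a) != 1 || length(seq_b) != 1 ||
      is.na(seq_a) || is.na(seq_b) || nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop_domain("both sequences must be non-empty strings",
      "thermodigest_domain_error")
  }
  if (seq_a == seq_b) return(100)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  n_id <- Biostrings::nmatch(aln)
  100 * n_id / min(nchar(seq_a), nchar(seq_b))
}

# k-mer table of a set of sequences: one row per distinct (seq index, kmer).
# Sequences shorter than k contribute nothing (they can never carry the
# guaranteed exact run, see below).
kmer_table <- function(sequences, k) {
  idx <- rep.int(seq_along(sequences), pmax(nchar(sequences) - k + 1L, 0L))
  kmers <- unlist(lapply(sequences, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  dplyr::distinct(tibble(seq = idx, kmer = kmers))
}

# Candidate non-identical sequence pairs sharing at least one exact k-mer.
# Losslessness above the 90% identity threshold: two sequences whose best
# local alignment has >90% identity over length L contain, by pigeonhole, a
# shared exact run of at least ceiling((L - m)/(m + 1)) residues, where
# m < 0.1 L is the number of non-identical alignment columns. For L >= 89
# this run is >= k = 8, so every pair that could pass the threshold at the
# protein lengths used here (>= 100 aa) is generated.
candidate_seq_pairs <- function(sequences, k) {
  kt <- kmer_table(sequences, k)
  pairs <- dplyr::inner_join(kt, kt, by = "kmer",
    relationship = "many-to-many", suffix = c("_a", "_b")) |>
    dplyr::filter(.data$seq_a < .data$seq_b) |>
    dplyr::distinct(.data$seq_a, .data$seq_b)
  pairs
}
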