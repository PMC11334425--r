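#' Read an aligned FASTA into a row-named character matrix
#'
#' @param path Aligned FASTA path (rows must have equal length).
#' @return Character matrix, one row per sequence, one column per alignment
#'   column; rownames are sequence ids.
#' @export
read_msa <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  as_msa_matrix(stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa))))
}

as_msa_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  seqs <- toupper(as.character(msa))
  if (length(unique(nchar(seqs))) > 1L)
    stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(msa) %||% paste0("row", seq_along(seqs))
  m
}

GAP_CHARS <- c("-", ".")

#' Per-column conservation statistics for an alignment
#'
#' For each column, residue counts exclude gaps; the information content is
#' `ic_bits = log2(20) - H(p)` with `p` the non-gap residue frequencies, so a
#' fully conserved column scores `log2(20) ~ 4.32` bits and a uniform column
#' 0 bits. Columns with occupancy below `min_occupancy` are flagged (not
#' dropped); all-gap columns get `ic_bits = NA`. No small-sample correction
#' is applied.
#'
#' @param msa Character matrix ([read_msa]) or named character vector of
#'   equal-length aligned sequences.
#' @param min_occupancy Occupancy threshold for the `low_occupancy` flag.
#' @return data.frame with one row per column: `index` (1-based), `occupancy`,
#'   `gap_count`, `ic_bits`, `consensus` (max-frequency residue, alphabetic
#'   tie-break), `consensus_freq`, `low_occupancy`.
#' @export
alignment_stats <- function(msa, min_occupancy = 0.5) {
  m <- as_msa_matrix(msa)
  n <- nrow(m)
  out <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gaps <- col %in% GAP_CHARS
    res <- col[!gaps]
    if (!length(res))
      return(data.frame(index = j, occupancy = 0, gap_count = n,
                        ic_bits = NA_real_, consensus = NA_character_,
                        consensus_freq = NA_real_, low_occupancy = TRUE,
                        stringsAsFactors = FALSE))
    p <- table(res) / length(res)
    H <- -sum(p * log2(p))
    cons <- sort(names(p)[p == max(p)])[1]
    data.frame(index = j, occupancy = length(res) / n, gap_count = sum(gaps),
               ic_bits = log2(20) - H, consensus = cons,
               consensus_freq = max(p),
               low_occupancy = length(res) / n < min_occupancy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Statistics for a single alignment column
#' @inheritParams alignment_stats
#' @param column 1-based column index.
#' @return One-row data.frame (see [alignment_stats]).
#' @export
column_stats <- function(msa, column, min_occupancy = 0.5) {
  m <- as_msa_matrix(msa)
  stopifnot(column >= 1L, column <= ncol(m))
  alignment_stats(m[, column, drop = FALSE], min_occupancy)[1, , drop = FALSE]
}

#' Find near-invariant columns of a given residue type
#'
#' Selects columns whose consensus residue belongs to `residue_filter`, with
#' information content at least `min_ic` bits and occupancy at least
#' `min_occupancy` — e.g. the highly conserved heme-coordinating histidines
#' of transmembrane cytochrome families, or conserved flavinylated
#' threonines. Results are sorted by decreasing information content.
#'
#' @inheritParams alignment_stats
#' @param residue_filter Character vector of residues (e.g. `"H"`,
#'   `c("S","T")`); NULL keeps every consensus.
#' @param min_ic Minimum information content in bits.
#' @param min_occupancy Minimum column occupancy.
#' @return data.frame of the qualifying rows of [alignment_stats], ic
#'   descending.
#' @export
top_conserved <- function(msa, residue_filter = NULL, min_ic = 3.0,
                          min_occupancy = 0.5) {
  stats <- alignment_stats(msa, min_occupancy)
  keep <- !is.na(stats$ic_bits) & stats$ic_bits >= min_ic &
    stats$occupancy >= min_occupancy
  if (!is.null(residue_filter))
    keep <- keep & stats$consensus %in% toupper(residue_filter)
  out <- stats[keep, , drop = FALSE]
  out <- out[order(-out$ic_bits, out$index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map an alignment column to a residue index in a reference sequence
#'
#' @inheritParams alignment_stats
#' @param reference_id Row name of the reference sequence in the MSA.
#' @param column 1-based alignment column.
#' @return The 1-based ungapped residue index of that column in the
#'   reference, or `NA` when the reference is gapped there.
#' @export
map_column_to_structure <- function(msa, reference_id, column) {
  m <- as_msa_matrix(msa)
  if (!reference_id %in% rownames(m))
    stop("reference sequence not in alignment: ", reference_id)
  stopifnot(column >= 1L, column <= ncol(m))
  row <- m[reference_id, ]
  if (row[column] %in% GAP_CHARS) return(NA_integer_)
  sum(!row[seq_len(column)] %in% GAP_CHARS)
}
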