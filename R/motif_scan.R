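#' Define a degenerate flavinylation-motif pattern
#'
#' The default is the canonical ApbE recognition motif \[S/T\]GA\[S/T\], with
#' the final S/T being the residue that receives the covalent FMN. "-like"
#' variants (e.g. a relaxed third position) are expressible by changing the
#' allowed sets, but are off by default.
#'
#' @param positions List of character vectors, the residues allowed at each
#'   position.
#' @param flavinylated_offset 0-based index within the match of the modified
#'   residue (default 3, the final position).
#' @param pattern_id Identifier carried into site tables.
#' @return A `motif_pattern` object.
#' @export
motif_pattern <- function(positions = list(c("S", "T"), "G", "A", c("S", "T")),
                          flavinylated_offset = length(positions) - 1L,
                          pattern_id = NULL) {
  stopifnot(length(positions) >= 1L,
            flavinylated_offset >= 0L,
            flavinylated_offset < length(positions))
  positions <- lapply(positions, function(p) sort(unique(toupper(p))))
  if (is.null(pattern_id))
    pattern_id <- paste(vapply(positions, function(p)
      if (length(p) == 1L) p else paste0("[", paste(p, collapse = "/"), "]"), ""),
      collapse = "")
  structure(list(pattern_id = pattern_id, positions = positions,
                 flavinylated_offset = as.integer(flavinylated_offset)),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s (modified residue at offset %d)\n",
              x$pattern_id, x$flavinylated_offset))
  invisible(x)
}

empty_sites <- function() {
  data.frame(protein_id = character(0), start = integer(0),
             matched = character(0), flavinylated_pos = integer(0),
             stringsAsFactors = FALSE)
}

#' Scan a protein sequence for flavinylation-motif sites
#'
#' All matches at step 1 are reported, overlaps included, positions ascending
#' (1-based). `X` (or any letter outside a position's allowed set) never
#' matches.
#'
#' @param seq Amino-acid sequence (string).
#' @param pattern A [motif_pattern] (default \[S/T\]GA\[S/T\]).
#' @param protein_id Identifier carried into the site rows.
#' @return Motif-site data.frame with columns `protein_id`, `start`,
#'   `matched`, `flavinylated_pos`.
#' @export
scan_motifs <- function(seq, pattern = motif_pattern(),
                        protein_id = NA_character_) {
  stopifnot(inherits(pattern, "motif_pattern"))
  seq <- toupper(seq)
  L <- length(pattern$positions)
  if (nchar(seq) < L) return(empty_sites())
  rx <- paste0("(?=", paste(vapply(pattern$positions, function(p)
    paste0("[", paste(p, collapse = ""), "]"), ""), collapse = ""), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty_sites())
  starts <- as.integer(m)
  data.frame(protein_id = protein_id, start = starts,
             matched = substring(seq, starts, starts + L - 1L),
             flavinylated_pos = starts + pattern$flavinylated_offset,
             stringsAsFactors = FALSE)
}

#' Scan every protein in a proteome for motif sites
#'
#' @param proteome Named character vector of sequences.
#' @inheritParams scan_motifs
#' @return Motif-site data.frame, one row per site.
#' @export
scan_motifs_proteome <- function(proteome, pattern = motif_pattern()) {
  rows <- lapply(names(proteome), function(pid)
    scan_motifs(proteome[[pid]], pattern, protein_id = pid))
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_sites() else out
}

#' Promote co-localized motif-bearing proteins to flavinylation candidates
#'
#' A protein is a candidate iff (a) its best-match family is one of
#' `target_families`, (b) it lies inside at least one anchor window, and
#' (c) it carries at least one motif site. Proteins with more than two sites
#' are classified multi-flavinylated (naturally occurring substrates carry
#' up to 13 sites).
#'
#' @param clusters List of `neighborhood_cluster` from [find_colocalized].
#' @param sites Motif-site table from [scan_motifs_proteome].
#' @param family_of Named vector protein_id -> best-match accession.
#' @param target_families Accessions eligible for candidacy.
#' @return Candidate data.frame: `protein_id`, `family`, `n_sites`,
#'   `genome_id`, `cluster_id`, `anchor_gene_id`, `multi_flavinylated`.
#' @export
call_candidates <- function(clusters, sites, family_of, target_families) {
  empty <- data.frame(protein_id = character(0), family = character(0),
                      n_sites = integer(0), genome_id = character(0),
                      cluster_id = integer(0), anchor_gene_id = character(0),
                      multi_flavinylated = logical(0), stringsAsFactors = FALSE)
  if (!length(clusters)) return(empty)
  site_counts <- table(sites$protein_id)
  rows <- list()
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    pids <- unique(cl$members$protein_id[!is.na(cl$members$protein_id)])
    for (pid in pids) {
      fam <- unname(family_of[pid])
      if (is.na(fam) || !fam %in% target_families) next
      n <- if (pid %in% names(site_counts)) as.integer(site_counts[[pid]]) else 0L
      if (n < 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, family = fam, n_sites = n,
        genome_id = cl$genome_id, cluster_id = i,
        anchor_gene_id = cl$anchor$gene_id,
        multi_flavinylated = n > 2L, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # a protein in two overlapping windows is one candidate: keep first cluster
  out <- out[!duplicated(out[c("protein_id", "genome_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ablate a motif site by point mutation
#'
#' Substitutes `replacement` at the site's flavinylated position (the alanine
#' point-mutation experiment in silico); re-scanning the mutant yields no
#' match at that start.
#'
#' @param seq Protein sequence.
#' @param site One row of a motif-site table (needs `flavinylated_pos`).
#' @param replacement Single residue to substitute (default `"A"`).
#' @return The mutated sequence.
#' @export
mutate_site <- function(seq, site, replacement = "A") {
  pos <- as.integer(site$flavinylated_pos)
  stopifnot(length(pos) == 1L, nchar(replacement) == 1L)
  if (is.na(pos) || pos < 1L || pos > nchar(seq))
    stop("site position ", pos, " out of range for sequence of length ", nchar(seq))
  substr(seq, pos, pos) <- toupper(replacement)
  seq
}
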