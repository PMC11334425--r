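#' Tabulate a genome-level feature across a taxonomic rank
#'
#' Counts, per taxon at the chosen rank, how many genomes carry a feature
#' (each genome counted once regardless of how many proteins in it carry it)
#' out of the genomes observed for that taxon — the computation behind
#' phylum-level distribution panels of candidate flavinylation substrates.
#'
#' @param genomes List of [genome_record] objects.
#' @param feature Either a predicate `function(genome) -> logical(1)` or a
#'   character vector of genome_ids that carry the feature (e.g. the
#'   `genome_id` column of a candidate table).
#' @param rank One of domain, phylum, class, order, family, genus, species.
#' @return data.frame with `rank`, `taxon`, `n_genomes_with_feature`,
#'   `n_genomes_total`, `fraction`, sorted by taxon.
#' @export
tabulate_taxa <- function(genomes, feature, rank = "phylum") {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  if (!rank %in% GTDB_RANKS)
    stop("invalid rank '", rank, "'; must be one of: ",
         paste(GTDB_RANKS, collapse = ", "))
  if (!length(genomes))
    return(data.frame(rank = character(0), taxon = character(0),
                      n_genomes_with_feature = integer(0),
                      n_genomes_total = integer(0), fraction = numeric(0),
                      stringsAsFactors = FALSE))
  has <- if (is.function(feature)) {
    vapply(genomes, function(g) isTRUE(feature(g)), logical(1))
  } else {
    vapply(genomes, function(g) g$genome_id %in% feature, logical(1))
  }
  taxon <- vapply(genomes, function(g) unname(g$lineage[[rank]]), character(1))
  taxa <- sort(unique(taxon))
  out <- data.frame(
    rank = rank, taxon = taxa,
    n_genomes_with_feature = vapply(taxa, function(t) sum(has[taxon == t]), integer(1)),
    n_genomes_total = vapply(taxa, function(t) sum(taxon == t), integer(1)),
    stringsAsFactors = FALSE)
  out$fraction <- out$n_genomes_with_feature / out$n_genomes_total
  rownames(out) <- NULL
  out
}

#' Protein-level feature counts per taxon
#'
#' Companion to [tabulate_taxa] at protein resolution: total feature-carrying
#' proteins per taxon (a genome with 4 candidates contributes 4 here but 1 in
#' [tabulate_taxa]).
#'
#' @param genomes List of [genome_record] objects.
#' @param protein_table data.frame with `genome_id` and `protein_id` columns
#'   (e.g. a candidate table).
#' @inheritParams tabulate_taxa
#' @return data.frame with `rank`, `taxon`, `n_proteins`.
#' @export
tabulate_taxa_proteins <- function(genomes, protein_table, rank = "phylum") {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  if (!rank %in% GTDB_RANKS) stop("invalid rank: ", rank)
  lin <- stats::setNames(
    vapply(genomes, function(g) unname(g$lineage[[rank]]), character(1)),
    vapply(genomes, function(g) g$genome_id, character(1)))
  taxon <- unname(lin[protein_table$genome_id])
  counts <- table(factor(taxon, levels = sort(unique(unname(lin)))))
  data.frame(rank = rank, taxon = names(counts),
             n_proteins = as.integer(counts), stringsAsFactors = FALSE)
}
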