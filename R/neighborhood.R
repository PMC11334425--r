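#' Extract the +/-k gene window around an anchor gene
#'
#' Windows are counted in genes (ordinals along the contig), not base pairs,
#' and are clipped at contig boundaries; strand plays no role. With the
#' default `k = 5` this is the classic "five genes downstream and upstream"
#' neighborhood used to infer functional association with an anchor.
#'
#' @param genome A [genome_record].
#' @param contig_id Contig holding the anchor.
#' @param anchor_ordinal 0-based ordinal of the anchor gene on that contig.
#' @param k Window half-width in genes (default 5).
#' @param family_of Optional named vector protein_id -> family accession used
#'   to fill the cluster's family content.
#' @return A `neighborhood_cluster`: list with `genome_id`, `contig_id`,
#'   `anchor` (1-row gene data.frame), `members` (gene data.frame, ordinal
#'   ascending), `family_content` (named list accession -> member protein
#'   ids), `window_k`.
#' @export
extract_window <- function(genome, contig_id, anchor_ordinal, k = 5L,
                           family_of = NULL) {
  stopifnot(k >= 0L)
  contig <- genome$genes[genome$genes$contig_id == contig_id, , drop = FALSE]
  if (!nrow(contig)) stop("contig not found: ", contig_id)
  contig <- contig[order(contig$ordinal), , drop = FALSE]
  n <- nrow(contig)
  if (!anchor_ordinal %in% contig$ordinal)
    stop(sprintf("anchor ordinal %d not on contig %s (0..%d)",
                 anchor_ordinal, contig_id, n - 1L))
  lo <- max(0L, anchor_ordinal - k)
  hi <- min(n - 1L, anchor_ordinal + k)
  members <- contig[contig$ordinal >= lo & contig$ordinal <= hi, , drop = FALSE]
  rownames(members) <- NULL
  fam <- list()
  if (!is.null(family_of)) {
    pid <- members$protein_id[!is.na(members$protein_id)]
    assigned <- family_of[intersect(pid, names(family_of))]
    fam <- split(names(assigned), unname(assigned))
  }
  structure(list(genome_id = genome$genome_id, contig_id = contig_id,
                 anchor = members[members$ordinal == anchor_ordinal, , drop = FALSE],
                 members = members, family_content = fam, window_k = as.integer(k)),
            class = "neighborhood_cluster")
}

#' @export
print.neighborhood_cluster <- function(x, ...) {
  cat(sprintf("<neighborhood_cluster> %s/%s anchor %s: %d genes (k=%d), families: %s\n",
              x$genome_id, x$contig_id, x$anchor$gene_id, nrow(x$members),
              x$window_k,
              if (length(x$family_content)) paste(names(x$family_content), collapse = ",") else "-"))
  invisible(x)
}

#' Find target families co-localized with an anchor family
#'
#' For every gene whose protein's best-match family is `anchor_family`, the
#' +/-k window is extracted and flagged with which `target_families` occur in
#' it. Windows around distinct anchors are reported separately even when they
#' overlap; no merging is done.
#'
#' @param genomes List of [genome_record] objects.
#' @param family_of Named vector protein_id -> best-match accession
#'   (see [best_family]).
#' @param anchor_family Accession of the anchor family (e.g. ApbE's).
#' @param target_families Character vector of target accessions.
#' @param k Window half-width in genes.
#' @return List of `neighborhood_cluster` objects, each with a
#'   `targets_present` character vector attribute-like element listing which
#'   target families occur in the window (excluding the anchor gene itself
#'   when it carries a target family).
#' @export
find_colocalized <- function(genomes, family_of, anchor_family,
                             target_families, k = 5L) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  if (!anchor_family %in% family_of)
    stop("anchor family not present in any annotation: ", anchor_family)
  clusters <- list()
  for (genome in genomes) {
    genes <- genome$genes
    anchored <- !is.na(genes$protein_id) &
      genes$protein_id %in% names(family_of)[family_of == anchor_family]
    for (i in which(anchored)) {
      cl <- extract_window(genome, genes$contig_id[i], genes$ordinal[i],
                           k = k, family_of = family_of)
      present <- intersect(target_families, names(cl$family_content))
      # a target family counts only via a gene other than the anchor itself
      present <- present[vapply(present, function(f) {
        any(cl$family_content[[f]] != cl$anchor$protein_id)
      }, logical(1))]
      cl$targets_present <- present
      clusters[[length(clusters) + 1L]] <- cl
    }
  }
  clusters
}

#' Flatten clusters to member-level and summary tables
#'
#' @param clusters List of `neighborhood_cluster` (see [find_colocalized]).
#' @param family_of Optional protein_id -> accession vector to annotate rows.
#' @return List of two data.frames: `members` (one row per window gene) and
#'   `summary` (one row per cluster with its target-family content).
#' @export
clusters_to_tables <- function(clusters, family_of = NULL) {
  if (!length(clusters))
    return(list(members = data.frame(), summary = data.frame()))
  members <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    m <- cl$members
    data.frame(cluster_id = i, genome_id = cl$genome_id, contig_id = cl$contig_id,
               anchor_gene_id = cl$anchor$gene_id, gene_id = m$gene_id,
               ordinal = m$ordinal, start = m$start, end = m$end,
               strand = m$strand, protein_id = m$protein_id,
               family = if (is.null(family_of)) NA_character_ else
                 unname(family_of[match(m$protein_id, names(family_of))]),
               is_anchor = m$gene_id == cl$anchor$gene_id,
               stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster_id = i, genome_id = cl$genome_id, contig_id = cl$contig_id,
               anchor_gene_id = cl$anchor$gene_id,
               anchor_protein_id = cl$anchor$protein_id,
               n_members = nrow(cl$members), window_k = cl$window_k,
               targets_present = paste(sort(cl$targets_present %||% character(0)),
                                       collapse = ","),
               stringsAsFactors = FALSE)
  }))
  list(members = members, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of anchor windows containing a target family
#'
#' @param clusters List of clusters from [find_colocalized].
#' @param target Target family accession.
#' @param lineages Optional named list/vector genome_id -> lineage (parsed or
#'   GTDB string); when given, a per-phylum breakdown is attached.
#' @return List with `overall` (fraction in \[0,1\]), `n_anchors`, and
#'   `per_phylum` (data.frame phylum / n_anchors / n_with_target / fraction,
#'   NULL when no lineages supplied).
#' @export
colocalization_frequency <- function(clusters, target, lineages = NULL) {
  if (!length(clusters)) stop("no clusters: co-localization frequency undefined")
  has <- vapply(clusters, function(cl) target %in% cl$targets_present, logical(1))
  out <- list(overall = mean(has), n_anchors = length(clusters), per_phylum = NULL)
  if (!is.null(lineages)) {
    phylum <- vapply(clusters, function(cl) {
      lin <- lineages[[cl$genome_id]]
      if (is.null(lin)) return(NA_character_)
      if (length(lin) == 1L) lin <- parse_lineage(lin)
      unname(lin[["phylum"]])
    }, character(1))
    tab <- data.frame(phylum = sort(unique(phylum)), stringsAsFactors = FALSE)
    tab$n_anchors <- vapply(tab$phylum, function(p) sum(phylum == p), integer(1))
    tab$n_with_target <- vapply(tab$phylum, function(p) sum(has[phylum == p]), integer(1))
    tab$fraction <- tab$n_with_target / tab$n_anchors
    out$per_phylum <- tab
  }
  out
}
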