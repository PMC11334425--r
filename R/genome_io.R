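GTDB_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Construct a genome record
#'
#' A `genome_record` bundles an ordered, stranded gene table, the matching
#' proteome, and a GTDB-style lineage for one genome. Genes are sorted by
#' (contig, start) and given dense 0-based ordinals per contig, which is the
#' coordinate system all neighborhood windows use.
#'
#' @param genome_id Genome identifier.
#' @param genes data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand`, `protein_id` (NA for non-coding rows).
#' @param proteome Named character vector of amino-acid sequences, or an
#'   [Biostrings::AAStringSet].
#' @param lineage GTDB lineage string (`"d__...;p__...;..."`) or a character
#'   vector of up to 7 ranks.
#' @return An object of class `genome_record` with elements `genome_id`,
#'   `lineage` (named length-7 character vector), `genes` (gene table with an
#'   `ordinal` column), and `proteome`.
#' @export
genome_record <- function(genome_id, genes, proteome = character(), lineage = "") {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  required <- c("gene_id", "contig_id", "start", "end", "strand", "protein_id")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols))
    stop("gene table is missing column(s): ", paste(missing_cols, collapse = ", "))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (nrow(genes) && any(genes$start > genes$end))
    stop("gene with start > end: ",
         paste(genes$gene_id[genes$start > genes$end], collapse = ", "))
  if (nrow(genes) && !all(genes$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  genes <- genes[order(genes$contig_id, genes$start, genes$gene_id), , drop = FALSE]
  genes$ordinal <- stats::ave(seq_len(nrow(genes)), genes$contig_id,
                              FUN = seq_along) - 1L
  if (!nrow(genes)) genes$ordinal <- integer(0)
  rownames(genes) <- NULL

  if (methods::is(proteome, "AAStringSet"))
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  proteome <- clean_proteome(proteome)
  coding <- genes$protein_id[!is.na(genes$protein_id) & genes$protein_id != ""]
  absent <- setdiff(coding, names(proteome))
  if (length(absent) && length(proteome))
    stop("protein_id referenced by gene table but absent from proteome: ",
         paste(utils::head(absent, 5), collapse = ", "))

  structure(
    list(genome_id = genome_id, lineage = parse_lineage(lineage),
         genes = genes, proteome = proteome),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d genes on %d contig(s), %d proteins\n",
              x$genome_id, nrow(x$genes), length(unique(x$genes$contig_id)),
              length(x$proteome)))
  lin <- x$lineage[x$lineage != ""]
  if (length(lin)) cat("  lineage:", paste(lin, collapse = "; "), "\n")
  invisible(x)
}

clean_proteome <- function(proteome) {
  if (!length(proteome)) return(stats::setNames(character(0), character(0)))
  if (is.null(names(proteome)) || any(names(proteome) == ""))
    stop("proteome sequences must all be named")
  ids <- sub("\\s.*$", "", names(proteome))
  if (anyDuplicated(ids))
    stop("duplicate protein id in proteome: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(sub("\\*+$", "", as.character(proteome)))
  stats::setNames(seqs, ids)
}

#' Read a gene table (GFF3 or TSV) into a genome record
#'
#' GFF3 input keeps CDS features only and takes the protein identifier from
#' the `protein_id` attribute, falling back to `ID`. TSV input must carry a
#' header row with columns `gene_id`, `contig_id`, `start`, `end`, `strand`,
#' `protein_id`. Coordinates are 1-based inclusive; genes are re-sorted by
#' position so downstream windows never depend on input row order.
#'
#' @param path Path to a `.gff`/`.gff3` or tab-separated gene table.
#' @param genome_id Genome identifier for the resulting record.
#' @param lineage Optional GTDB lineage string.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A [genome_record] with an empty proteome (attach one with
#'   [read_proteome] via [genome_record]).
#' @export
read_gene_table <- function(path, genome_id, lineage = "", format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene table not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  genes <- if (format == "gff3") read_genes_gff3(path) else read_genes_tsv(path)
  genome_record(genome_id, genes, proteome = character(), lineage = lineage)
}

read_genes_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1]]
    stop(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated fields, got %d",
                 bad, path, nf[nf != 9L][1]))
  }
  if (!any(body))
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), protein_id = character(0)))
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[g$type == "CDS", , drop = FALSE]
  pid <- if ("protein_id" %in% names(g)) as.character(g$protein_id) else rep(NA_character_, nrow(g))
  id <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))
  pid <- ifelse(is.na(pid) | pid == "", id, pid)
  if (any(is.na(pid) | pid == ""))
    stop("CDS feature without ID/protein_id attribute in ", path)
  data.frame(gene_id = id %||na% pid, contig_id = as.character(g$seqid),
             start = as.integer(g$start), end = as.integer(g$end),
             strand = as.character(g$strand), protein_id = pid,
             stringsAsFactors = FALSE)
}

`%||na%` <- function(a, b) ifelse(is.na(a) | a == "", b, a)

read_genes_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), protein_id = character(0)))
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != nf[1]))
    stop(sprintf("malformed TSV line %d in %s: expected %d fields, got %d",
                 which(nf != nf[1])[1], path, nf[1], nf[nf != nf[1]][1]))
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "contig_id", "start", "end", "strand", "protein_id")
  miss <- setdiff(required, names(g))
  if (length(miss)) stop("TSV gene table missing column(s): ", paste(miss, collapse = ", "))
  g$protein_id[g$protein_id == "" | g$protein_id == "."] <- NA_character_
  g[required]
}

#' Write a gene table to TSV
#'
#' Writes the indexed gene table (including ordinals) in the package's TSV
#' dialect; [read_gene_table] on the result round-trips coordinates, strands
#' and ordinals.
#'
#' @param genome A [genome_record].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genome, path) {
  g <- genome$genes
  g$protein_id[is.na(g$protein_id)] <- "."
  utils::write.table(g[c("gene_id", "contig_id", "start", "end", "strand",
                         "protein_id", "ordinal")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein FASTA into a named sequence vector
#'
#' Sequences are upper-cased and trailing stop codons (`*`) stripped;
#' identifiers are the first whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @return Named character vector, protein_id -> sequence.
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("proteome FASTA not found: ", path)
  aa <- Biostrings::readBStringSet(path)
  clean_proteome(stats::setNames(as.character(aa), names(aa)))
}

#' Parse a GTDB lineage string
#'
#' Splits a `d__Bacteria;p__Firmicutes;...` string into the seven standard
#' ranks, stripping the `x__` prefixes. Missing trailing ranks are returned
#' as empty strings.
#'
#' @param s Lineage string, or a character vector of already-split ranks.
#' @return Named character vector of length 7
#'   (domain, phylum, class, order, family, genus, species).
#' @export
parse_lineage <- function(s) {
  if (length(s) > 1L) {
    ranks <- as.character(s)
  } else if (is.null(s) || is.na(s) || !nzchar(s)) {
    ranks <- character(0)
  } else {
    ranks <- sub("^[a-z]__", "", trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
  }
  if (length(ranks) > 7L) stop("lineage has more than 7 ranks")
  out <- stats::setNames(rep("", 7L), GTDB_RANKS)
  out[seq_along(ranks)] <- ranks
  out
}
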