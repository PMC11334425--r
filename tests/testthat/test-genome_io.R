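make_genes <- function(starts, contig = "c1", ids = NULL) {
  n <- length(starts)
  data.frame(gene_id = ids %||% paste0("g", seq_len(n)), contig_id = contig,
             start = starts, end = starts + 100L, strand = "+",
             protein_id = NA_character_, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("gene indexing sorts by position and assigns dense per-contig ordinals", {
  g <- genome_record("G1", make_genes(c(100L, 900L, 400L)))
  expect_equal(g$genes$gene_id, c("g1", "g3", "g2"))
  expect_equal(g$genes$ordinal, 0:2)

  two <- rbind(make_genes(c(50L, 10L), contig = "c2", ids = c("a1", "a2")),
               make_genes(c(300L, 100L, 200L), contig = "c1", ids = c("b1", "b2", "b3")))
  g2 <- genome_record("G2", two)
  expect_equal(g2$genes$ordinal[g2$genes$contig_id == "c1"], 0:2)
  expect_equal(g2$genes$ordinal[g2$genes$contig_id == "c2"], 0:1)
  expect_equal(g2$genes$gene_id[g2$genes$contig_id == "c2"], c("a2", "a1"))
})

test_that("gene table validation rejects duplicates and inverted coordinates", {
  bad <- make_genes(c(1L, 2L), ids = c("g1", "g1"))
  expect_error(genome_record("G", bad), "duplicate gene_id")
  inv <- make_genes(10L); inv$end <- 5L
  expect_error(genome_record("G", inv), "start > end")
})

test_that("TSV gene tables round-trip ordinals, strands and coordinates", {
  genes <- make_genes(c(500L, 100L, 900L, 300L))
  genes$strand <- c("+", "-", "+", "-")
  g <- genome_record("G1", genes)
  path <- withr::local_tempfile(fileext = ".genes.tsv")
  write_gene_table(g, path)
  g2 <- read_gene_table(path, "G1")
  expect_equal(g2$genes[c("gene_id", "contig_id", "start", "end", "strand", "ordinal")],
               g$genes[c("gene_id", "contig_id", "start", "end", "strand", "ordinal")])
})

test_that("empty and malformed gene tables are handled", {
  empty <- withr::local_tempfile(fileext = ".genes.tsv")
  writeLines(character(0), empty)
  g <- read_gene_table(empty, "G0")
  expect_equal(nrow(g$genes), 0L)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tCDS\t100\t200\t.\t+\t0\tID=x1",
               "c1\tsrc\tCDS\t300"), gff)
  expect_error(read_gene_table(gff, "G"), "line 3")
})

test_that("GFF3 input keeps CDS only and takes protein ids from attributes", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tgene\t90\t210\t.\t+\t.\tID=gene1",
               "c1\tsrc\tCDS\t100\t200\t.\t+\t0\tID=cds1;protein_id=p1",
               "c1\tsrc\tCDS\t400\t600\t.\t-\t0\tID=cds2;protein_id=p2",
               "c1\tsrc\ttRNA\t700\t800\t.\t+\t.\tID=trna1"), gff)
  g <- read_gene_table(gff, "G")
  expect_equal(nrow(g$genes), 2L)
  expect_equal(g$genes$protein_id, c("p1", "p2"))
  expect_equal(g$genes$strand, c("+", "-"))
  expect_equal(g$genes$ordinal, 0:1)
})

test_that("proteome reading upper-cases, strips stops, and rejects duplicate ids", {
  fa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1 desc", "MKT*", ">p2", "mkt"), fa)
  p <- read_proteome(fa)
  expect_equal(p, c(p1 = "MKT", p2 = "MKT"))

  dup <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1", "MA", ">p1", "MC"), dup)
  expect_error(read_proteome(dup), "duplicate")
})

test_that("GTDB lineage strings parse with prefixes stripped and gaps kept", {
  lin <- parse_lineage("d__Bacteria;p__Firmicutes")
  expect_equal(unname(lin[1:2]), c("Bacteria", "Firmicutes"))
  expect_true(all(lin[3:7] == ""))
  expect_true(all(parse_lineage("") == ""))
  lin3 <- parse_lineage("d__Bacteria;p__;c__Clostridia")
  expect_equal(unname(lin3[["phylum"]]), "")
  expect_equal(unname(lin3[["class"]]), "Clostridia")
})

test_that("windows do not depend on input row order", {
  genes <- make_genes(c(100L, 300L, 500L, 700L, 900L))
  g1 <- genome_record("G", genes)
  g2 <- genome_record("G", genes[c(4, 1, 5, 2, 3), ])
  w1 <- extract_window(g1, "c1", 2L, k = 1L)
  w2 <- extract_window(g2, "c1", 2L, k = 1L)
  expect_equal(w1$members$gene_id, w2$members$gene_id)
})
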