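linear_genome <- function(n = 20L, genome_id = "G1", lineage = "") {
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n)), contig_id = "c1",
                      start = (seq_len(n) - 1L) * 1000L + 1L,
                      end = (seq_len(n) - 1L) * 1000L + 900L,
                      strand = "+", protein_id = sprintf("p%02d", seq_len(n)),
                      stringsAsFactors = FALSE)
  prot <- setNames(rep("MKLV", n), genes$protein_id)
  genome_record(genome_id, genes, prot, lineage)
}

test_that("windows span +/-k ordinals clipped at contig bounds", {
  g <- linear_genome(20L)
  w <- extract_window(g, "c1", 10L, k = 5L)
  expect_equal(w$members$ordinal, 5:15)
  expect_equal(nrow(w$members), 11L)
  edge <- extract_window(g, "c1", 0L, k = 5L)
  expect_equal(edge$members$ordinal, 0:5)
  single <- linear_genome(1L)
  w1 <- extract_window(single, "c1", 0L, k = 5L)
  expect_equal(w1$members$gene_id, w1$anchor$gene_id)
  expect_error(extract_window(g, "c1", 25L), "ordinal 25")
  expect_error(extract_window(g, "nope", 0L), "contig")
})

test_that("window size follows the edge law |w| = min(a,k) + min(n-1-a,k) + 1", {
  g <- linear_genome(20L)
  for (a in 0:19) {
    w <- extract_window(g, "c1", a, k = 5L)
    expect_equal(nrow(w$members), min(a, 5L) + min(19L - a, 5L) + 1L)
  }
})

test_that("window membership is symmetric under genome reversal", {
  n <- 17L
  g <- linear_genome(n)
  rev_genes <- g$genes
  rev_genes$start <- (n - g$genes$ordinal - 1L) * 1000L + 1L
  rev_genes$end <- rev_genes$start + 899L
  g_rev <- genome_record("G1r", rev_genes, g$proteome)
  for (a in c(0L, 3L, 8L, 16L)) {
    w <- extract_window(g, "c1", a, k = 5L)
    w_rev <- extract_window(g_rev, "c1", n - 1L - a, k = 5L)
    expect_setequal(w$members$gene_id, w_rev$members$gene_id)
  }
})

test_that("co-localization is called within k and not beyond", {
  g <- linear_genome(20L)
  fam <- c(p08 = "PF02424", p10 = "PF12682")  # anchor ordinal 7, target 9
  cl <- find_colocalized(g, fam, "PF02424", "PF12682", k = 5L)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$targets_present, "PF12682")

  far <- c(p01 = "PF02424", p07 = "PF12682")  # ordinals 0 and 6: distance 6
  cl2 <- find_colocalized(g, far, "PF02424", "PF12682", k = 5L)
  expect_length(cl2, 1L)
  expect_length(cl2[[1]]$targets_present, 0L)

  expect_error(find_colocalized(g, far, "PF99999", "PF12682"), "anchor family")
})

test_that("two nearby anchors give two separate overlapping clusters", {
  g <- linear_genome(20L)
  fam <- c(p05 = "PF02424", p08 = "PF02424")
  cl <- find_colocalized(g, fam, "PF02424", "PF12682", k = 5L)
  expect_length(cl, 2L)
  shared <- intersect(cl[[1]]$members$gene_id, cl[[2]]$members$gene_id)
  expect_gt(length(shared), 0L)
})

test_that("co-localization frequency is the fraction of anchor windows with the target", {
  g <- linear_genome(30L)
  fam <- c(p02 = "PF02424", p04 = "PF12682",   # hit
           p10 = "PF02424", p13 = "PF12682",   # hit
           p20 = "PF02424",                    # miss
           p27 = "PF02424", p29 = "PF12682")   # hit
  cl <- find_colocalized(g, fam, "PF02424", "PF12682", k = 5L)
  fr <- colocalization_frequency(cl, "PF12682")
  expect_equal(fr$overall, 0.75)
  expect_equal(fr$n_anchors, 4L)
  miss <- colocalization_frequency(cl, "PF03358")
  expect_equal(miss$overall, 0)
  expect_error(colocalization_frequency(list(), "PF12682"), "undefined")
})

test_that("recovered planting frequency matches the binomial expectation", {
  sim <- simulate_genomes(sim_config(seed = 11L, n_genomes = 500L,
                                     genes_per_contig = 12L, p_cluster = 1.0))
  # target planted with probability 0.6 per anchor: drop it from 40% of hits
  fam <- best_family(sim$hits)
  set.seed(11)
  drop <- runif(nrow(sim$truth$pairs)) > 0.6
  fam <- fam[!(names(fam) %in% sim$truth$pairs$target_protein_id[drop])]
  cl <- find_colocalized(sim$genomes, fam, "PF02424", "PF12682", k = 5L)
  fr <- colocalization_frequency(cl, "PF12682")
  se <- sqrt(0.6 * 0.4 / fr$n_anchors)
  expect_lt(abs(fr$overall - 0.6), 3 * se)
})

test_that("per-phylum frequency table uses lineage rank 2", {
  g1 <- linear_genome(20L, "GA", "d__Bacteria;p__Firmicutes")
  g2 <- linear_genome(20L, "GB", "d__Bacteria;p__Proteobacteria")
  fam <- c(p05 = "PF02424", p07 = "PF12682")
  cl <- find_colocalized(list(g1, g2), fam, "PF02424", "PF12682", k = 5L)
  fr <- colocalization_frequency(cl, "PF12682",
                                 lineages = list(GA = g1$lineage, GB = g2$lineage))
  expect_equal(fr$per_phylum$phylum, c("Firmicutes", "Proteobacteria"))
  expect_equal(fr$per_phylum$fraction, c(1, 1))
})
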