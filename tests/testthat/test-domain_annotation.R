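tblout_lines <- function(rows) {
  c("#                                                               --- full sequence ---",
    "# target name        accession  query name           accession    E-value  score  bias",
    rows, "#")
}

test_that("tblout rows parse into hits with full-sequence E-value and score", {
  path <- withr::local_tempfile(fileext = ".tblout")
  writeLines(tblout_lines(c(
    "p1 - FMN_bind PF04205.1 1e-10 85.2 0.1 1.2e-10 84.0 0.1 1.0 1 0 0 1 1 1 1 -",
    "p2 - ApbE PF02424.14 0.5 10.0 0.0 0.6 9.0 0.0 1.0 1 0 0 1 1 1 1 some description")), path)
  hits <- read_tblout(path)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$evalue, c(1e-10, 0.5))
  expect_equal(hits$bit_score, c(85.2, 10.0))
  expect_equal(hits$accession, c("PF04205", "PF02424"))
  # weak hit retained by the reader, filtered only at assign_best
  expect_equal(nrow(assign_best(hits, 0.001)), 1L)
})

test_that("comment-only and malformed tblout files behave as specified", {
  path <- withr::local_tempfile(fileext = ".tblout")
  writeLines(c("# a comment", "#"), path)
  expect_equal(nrow(read_tblout(path)), 0L)
  writeLines(c("# header", "p1 - Fam PF1.1 1e-5 20"), path)
  expect_error(read_tblout(path), "line 2")
})

test_that("pssm_scan matches the spec's two-column example and short-seq rule", {
  m <- matrix(-1, nrow = 2, ncol = 20, dimnames = list(NULL, AA20))
  m[1, "M"] <- 2; m[2, "K"] <- 2
  prof <- domain_profile("PFMK", m)
  hit <- pssm_scan("AMKA", prof, n_shuffles = 0L)
  expect_equal(hit$ali_start, 2L)
  expect_equal(hit$ali_end, 3L)
  expect_equal(hit$bit_score, 4.0)
  # uniform zero profile ties broken to the leftmost window
  zero <- domain_profile("PF0", matrix(0, nrow = 2, ncol = 20,
                                       dimnames = list(NULL, AA20)))
  expect_equal(pssm_scan("MKTA", zero, n_shuffles = 0L)$ali_start, 1L)
  expect_null(pssm_scan("AA", domain_profile("PF3", matrix(0, 3, 20,
    dimnames = list(NULL, AA20))), n_shuffles = 0L))
})

test_that("pssm_scan equals brute-force window enumeration on random cases", {
  set.seed(42)
  for (i in 1:60) {
    prof <- random_profile()
    seq <- random_aa_seq(sample(10:120, 1))
    got <- pssm_scan(seq, prof, n_shuffles = 0L)
    want <- brute_pssm_best(seq, prof$scores)
    expect_equal(got$ali_start, want$start)
    expect_equal(got$bit_score, want$score, tolerance = 1e-10)
  }
})

test_that("empirical p-values are seeded, reproducible, and low for planted tags", {
  prof <- builtin_profiles()$anchor
  seq <- paste0(random_aa_seq(30), "WCHNWKRCWDQW", random_aa_seq(30))
  h1 <- pssm_scan(seq, prof, n_shuffles = 100L, seed = 7L)
  h2 <- pssm_scan(seq, prof, n_shuffles = 100L, seed = 7L)
  expect_identical(h1$evalue, h2$evalue)
  expect_lte(h1$evalue, 0.02)
})

test_that("assign_best keeps one lowest-E-value family per protein at cutoff 0.001", {
  hits <- data.frame(
    protein_id = c("p1", "p1", "p1", "p2"),
    accession = c("PF00002", "PF00001", "PF00003", "PF00009"),
    name = "f", bit_score = c(50, 90, 10, 5),
    evalue = c(1e-4, 1e-9, 0.01, 0.01),
    ali_start = NA_integer_, ali_end = NA_integer_, is_best = FALSE,
    stringsAsFactors = FALSE)
  fam <- best_family(hits, evalue_cutoff = 0.001)
  expect_equal(fam, c(p1 = "PF00001"))   # 1e-9 wins; 0.01 excluded entirely
  # tie on E-value: higher bit score, then lexicographic accession
  tie <- hits[1:2, ]; tie$evalue <- 1e-6; tie$bit_score <- c(50, 50)
  expect_equal(unname(best_family(tie)), "PF00001")
})

test_that("assign_best is idempotent and order-independent", {
  set.seed(1)
  hits <- data.frame(
    protein_id = sample(c("a", "b", "c"), 30, replace = TRUE),
    accession = sample(sprintf("PF%05d", 1:8), 30, replace = TRUE),
    name = "f", bit_score = round(runif(30, 10, 99), 1),
    evalue = 10^runif(30, -12, -1),
    ali_start = NA_integer_, ali_end = NA_integer_, is_best = FALSE,
    stringsAsFactors = FALSE)
  once <- assign_best(hits)
  expect_equal(assign_best(once), once)
  shuffled <- assign_best(hits[sample.int(nrow(hits)), ])
  expect_equal(shuffled, once)
})

test_that("profiles round-trip through the TSV dialect", {
  prof <- random_profile(5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$accession, prof$accession)
  expect_equal(unname(back$scores), unname(prof$scores))
})
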