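pdb_line <- function(record, serial, name, resid, chain, resno, x, y, z,
                     occ = 1, alt = " ") {
  name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name_fmt, alt, resid, chain, resno, x, y, z, occ, 0)
}

test_that("PDB reading keeps MODEL 1 and the highest-occupancy altloc", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1",
               pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0),
               pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 1, 0, 0, occ = 0.6, alt = "A"),
               pdb_line("ATOM", 3, "CA", "GLY", "A", 2, 9, 9, 9, occ = 0.4, alt = "B"),
               "ENDMDL", "MODEL     2",
               pdb_line("ATOM", 4, "CA", "ALA", "A", 1, 50, 50, 50),
               "ENDMDL", "END"), path)
  model <- read_structure(path)
  ca <- model$atoms[model$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 2L)                       # first model only
  expect_equal(ca$x[ca$resno == 2], 1)             # occupancy 0.6 altloc kept
  expect_equal(unname(model$sequence[["A"]]), "AG")
})

test_that("HETATM ligands stay addressable by residue name; no-ATOM files error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line("ATOM", 1, "CA", "SER", "A", 1, 0, 0, 0),
               pdb_line("HETATM", 2, "C1", "FMN", "L", 90, 3, 4, 0), "END"), path)
  model <- read_structure(path)
  expect_true("FMN" %in% model$atoms$resid[model$atoms$type == "HETATM"])
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty), "ATOM")
})

test_that("a hydrophobic core flanked by Asp gives one segment of pure-Ile hydropathy", {
  seq <- paste0(strrep("D", 20), strrep("I", 19), strrep("D", 20))
  seg <- detect_tm_segments(seq)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$mean_hydropathy, 4.5)
  expect_equal(nrow(detect_tm_segments(strrep("D", 60))), 0L)
  expect_equal(nrow(detect_tm_segments("IVLIVL")), 0L)  # shorter than window
})

test_that("six planted hydrophobic stretches yield exactly six TM segments", {
  stretches <- lapply(0:5, function(i) c(20 + i * 40, 38 + i * 40))
  st <- simulate_structure(n_res = 260L, helix_stretches = stretches)
  seg <- detect_tm_segments(st$model$sequence[["A"]])
  expect_equal(nrow(seg), 6L)
  for (i in 1:6)
    expect_true(seg$start[i] >= stretches[[i]][1] && seg$end[i] <= stretches[[i]][2])
})

test_that("bis-His pairs are found at 4.2 A, rejected at 10 A and below min separation", {
  st <- simulate_structure(n_res = 60L, his = data.frame(
    chain = "A", resno = c(10, 40), x = 0, y = 0, z = c(5, 9.2)))
  pairs <- detect_heme_his_pairs(st$model)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$distance, 4.2, tolerance = 1e-6)
  expect_equal(pairs$atom_a, "NE2")
  expect_equal(pairs$sequence_separation, 30L)

  far <- simulate_structure(n_res = 60L, his = data.frame(
    chain = "A", resno = c(10, 40), x = 0, y = 0, z = c(5, 15)))
  expect_equal(nrow(detect_heme_his_pairs(far$model)), 0L)

  near_seq <- simulate_structure(n_res = 60L, his = data.frame(
    chain = "A", resno = c(10, 12), x = 0, y = 0, z = c(5, 9.2)))
  expect_equal(nrow(detect_heme_his_pairs(near_seq$model)), 0L)
  expect_equal(nrow(detect_heme_his_pairs(
    simulate_structure(n_res = 20L)$model)), 0L)
})

test_that("cross-chain His pairs support homodimer heme sites", {
  st <- simulate_structure(n_res = 40L, chains = c("A", "B"), his = data.frame(
    chain = c("A", "B"), resno = c(15, 15), x = c(0, 0), y = c(0, 4.5),
    z = c(10, 10)))
  pairs <- detect_heme_his_pairs(st$model)
  expect_equal(nrow(pairs), 1L)
  expect_false(pairs$same_chain)
  expect_true(is.na(pairs$sequence_separation))
  expect_equal(pairs$distance, 4.5, tolerance = 1e-6)
})

test_that("heme-pair detection is invariant under rigid motion of the structure", {
  st <- simulate_structure(n_res = 60L, his = data.frame(
    chain = "A", resno = c(10, 40), x = c(1, 2), y = c(0, 3), z = c(5, 7)))
  ref <- detect_heme_his_pairs(st$model)
  for (s in 1:20) {
    moved <- rigid_motion(st$model, seed = s)
    got <- detect_heme_his_pairs(moved)
    expect_equal(got$distance, ref$distance, tolerance = 1e-8)
    expect_equal(got[c("resno_a", "resno_b")], ref[c("resno_a", "resno_b")])
  }
})

test_that("Kabsch recovers exact rigid motions with zero rmsd", {
  set.seed(10)
  A <- matrix(rnorm(45), ncol = 3)
  th <- pi / 2
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  B <- A %*% t(Rz) + matrix(rep(c(5, 0, 0), each = 15), ncol = 3)
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  self <- kabsch_superpose(A, A)
  expect_lt(self$rmsd, 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  expect_equal(self$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("Kabsch rejects degenerate inputs", {
  A <- matrix(rnorm(9), ncol = 3)
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "3 paired points")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("rmsd is symmetric and invariant under rigid pre-transforms", {
  set.seed(11)
  A <- matrix(rnorm(60), ncol = 3)
  B <- A + matrix(rnorm(60, sd = 0.3), ncol = 3)
  expect_equal(kabsch_superpose(A, B)$rmsd, kabsch_superpose(B, A)$rmsd,
               tolerance = 1e-9)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  Rq <- quat_rot(q)
  A2 <- A %*% t(Rq) + matrix(rep(c(3, -7, 2), each = 20), ncol = 3)
  expect_equal(kabsch_superpose(A2, B)$rmsd, kabsch_superpose(A, B)$rmsd,
               tolerance = 1e-9)
})

test_that("Kabsch rmsd agrees with the quaternion-search oracle on noisy cases", {
  set.seed(12)
  for (i in 1:8) {
    A <- matrix(rnorm(50 * 3), ncol = 3)
    q <- rnorm(4)
    B <- A %*% t(quat_rot(q)) + matrix(rnorm(150, sd = 0.1), ncol = 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, brute_rmsd(A, B), tolerance = 1e-3)
  }
})

test_that("motif-to-pocket distances use OG and pocket centroids", {
  st <- simulate_structure(n_res = 30L,
                           motif_ser = list(chain = "A", resno = 5, og = c(0, 0, 0)),
                           ligand = list(name = "FMN", center = c(3, 4, 0)))
  d <- motif_pocket_distance(st$model, 5, ligand = "FMN")
  expect_equal(d$distance, 5, tolerance = 1e-6)   # 3-4-5 triangle
  expect_equal(d$motif_atom, "OG")
  expect_true(d$proximal)

  at_centroid <- simulate_structure(n_res = 30L,
    motif_ser = list(chain = "A", resno = 5, og = c(3, 4, 0)),
    ligand = list(name = "FMN", center = c(3, 4, 0)))
  expect_equal(motif_pocket_distance(at_centroid$model, 5, ligand = "FMN")$distance,
               0, tolerance = 1e-6)

  twelve <- simulate_structure(n_res = 30L,
    motif_ser = list(chain = "A", resno = 5, og = c(0, 0, 0)),
    ligand = list(name = "FMN", center = c(12, 0, 0)))
  expect_true(motif_pocket_distance(twelve$model, 5, ligand = "FMN",
                                    proximal_cutoff = 15)$proximal)
  expect_false(motif_pocket_distance(twelve$model, 5, ligand = "FMN",
                                     proximal_cutoff = 10)$proximal)
  expect_error(motif_pocket_distance(st$model, 5, pocket_resnos = c(2, 99)),
               "99")
})
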