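# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Read a PDB file into a structure model
#'
#' Keeps the first MODEL only and, where alternate locations exist, the
#' highest-occupancy altloc per atom. HETATM ligands (e.g. FMN, HEM) are
#' retained and addressable by residue name. Parsing is delegated to
#' [bio3d::read.pdb].
#'
#' @param path PDB file path.
#' @return A `structure_model`: list with `atoms` (data.frame `chain`,
#'   `resno`, `resid`, `elety`, `x`, `y`, `z`, `o`, `type`) and `sequence`
#'   (named per-chain one-letter sequences derived from CA residue names).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  atoms <- pdb$atom
  if (!nrow(atoms[atoms$type == "ATOM", , drop = FALSE]))
    stop("no ATOM records in ", path)
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  # highest-occupancy altloc wins; ties keep the alphabetically first altloc
  key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$elety, sep = "|")
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$type == "HETATM", atoms$chain, atoms$resno,
                       atoms$elety), , drop = FALSE]
  rownames(atoms) <- NULL
  model <- structure(
    list(atoms = atoms[c("chain", "resno", "resid", "elety",
                         "x", "y", "z", "o", "type")],
         sequence = chain_sequences(atoms)),
    class = "structure_model")
  model
}

chain_sequences <- function(atoms) {
  ca <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (!nrow(ca)) return(stats::setNames(character(0), character(0)))
  ca <- ca[order(ca$chain, ca$resno), , drop = FALSE]
  vapply(split(ca, ca$chain), function(ch)
    paste(bio3d::aa321(ch$resid), collapse = ""), "")
}

#' @export
print.structure_model <- function(x, ...) {
  het <- unique(x$atoms$resid[x$atoms$type == "HETATM"])
  cat(sprintf("<structure_model> %d atoms, chains: %s%s\n",
              nrow(x$atoms), paste(names(x$sequence), collapse = ","),
              if (length(het)) paste0(", ligands: ", paste(het, collapse = ",")) else ""))
  invisible(x)
}

#' Detect transmembrane segments by windowed hydropathy
#'
#' Computes the sliding-window mean Kyte-Doolittle hydropathy, assigns each
#' window's mean to its center residue, and reports maximal runs of center
#' residues whose mean is at least `threshold`. The default window of 19 and
#' threshold of 1.6 are the classic settings for calling membrane-spanning
#' helices from sequence alone.
#'
#' @param seq Protein sequence (string); letters outside the 20-residue
#'   alphabet contribute hydropathy 0.
#' @param window Sliding window length in residues (odd recommended).
#' @param threshold Minimum windowed mean hydropathy (Kyte-Doolittle units).
#' @param chain Chain label carried into the output.
#' @return data.frame of segments: `chain`, `start`, `end` (1-based residue
#'   positions of the qualifying center run), `length`, `mean_hydropathy`
#'   (mean raw hydropathy over the segment residues), `peak_window_mean`.
#'   Zero rows when the sequence is shorter than the window.
#' @export
detect_tm_segments <- function(seq, window = 19L, threshold = 1.6,
                               chain = NA_character_) {
  empty <- data.frame(chain = character(0), start = integer(0), end = integer(0),
                      length = integer(0), mean_hydropathy = numeric(0),
                      peak_window_mean = numeric(0), stringsAsFactors = FALSE)
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n < window) return(empty)
  kd <- unname(KD_SCALE[chars])
  kd[is.na(kd)] <- 0
  wmean <- as.numeric(stats::filter(kd, rep(1 / window, window), sides = 2))
  centers <- which(!is.na(wmean) & wmean >= threshold)
  if (!length(centers)) return(empty)
  runs <- split(centers, cumsum(c(1L, diff(centers) != 1L)))
  out <- lapply(runs, function(r) {
    data.frame(chain = chain, start = min(r), end = max(r),
               length = max(r) - min(r) + 1L,
               mean_hydropathy = mean(kd[min(r):max(r)]),
               peak_window_mean = max(wmean[r]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect bis-histidine heme-site candidates
#'
#' Finds all His pairs whose coordinating-atom distance (NE2, falling back to
#' ND1 when NE2 is absent) is at most `max_dist`. Same-chain pairs must be at
#' least `min_seq_sep` residues apart (to exclude trivially adjacent His);
#' cross-chain pairs have no separation requirement, supporting heme sites
#' formed across a homodimer interface. A bis-His axial pair across a heme
#' iron sits near 4.2 A, hence the 6.0 A default cutoff.
#'
#' @param model A [read_structure] model.
#' @param max_dist Maximum coordinating-atom distance in Angstrom.
#' @param min_seq_sep Minimum same-chain residue-number separation.
#' @return data.frame sorted by distance: `chain_a`, `resno_a`, `atom_a`,
#'   `chain_b`, `resno_b`, `atom_b`, `distance`, `same_chain`,
#'   `sequence_separation` (NA across chains).
#' @export
detect_heme_his_pairs <- function(model, max_dist = 6.0, min_seq_sep = 10L) {
  empty <- data.frame(chain_a = character(0), resno_a = integer(0),
                      atom_a = character(0), chain_b = character(0),
                      resno_b = integer(0), atom_b = character(0),
                      distance = numeric(0), same_chain = logical(0),
                      sequence_separation = integer(0), stringsAsFactors = FALSE)
  at <- model$atoms
  his <- at[at$resid == "HIS" & at$type == "ATOM" &
              at$elety %in% c("NE2", "ND1"), , drop = FALSE]
  if (!nrow(his)) return(empty)
  # one coordinating atom per His residue: NE2 preferred
  his <- his[order(his$chain, his$resno, match(his$elety, c("NE2", "ND1"))), ,
             drop = FALSE]
  his <- his[!duplicated(paste(his$chain, his$resno)), , drop = FALSE]
  if (nrow(his) < 2L) return(empty)
  pairs <- utils::combn(nrow(his), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- his[pairs[1, k], ]; b <- his[pairs[2, k], ]
    d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
    same <- identical(a$chain, b$chain)
    sep <- if (same) abs(a$resno - b$resno) else NA_integer_
    if (d > max_dist) return(NULL)
    if (same && sep < min_seq_sep) return(NULL)
    data.frame(chain_a = a$chain, resno_a = a$resno, atom_a = a$elety,
               chain_b = b$chain, resno_b = b$resno, atom_b = b$elety,
               distance = d, same_chain = same,
               sequence_separation = as.integer(sep), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares rigid transform taking point set A onto point set B via SVD
#' of the cross-covariance matrix, with a proper rotation enforced
#' (determinant +1). The transform of a point `x` (column convention) is
#' `R x + t`.
#'
#' @param A,B Numeric n x 3 coordinate matrices.
#' @param correspondence Optional 2-column index matrix pairing rows of A
#'   with rows of B (default: row i of A pairs with row i of B).
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom, after transform), and `transformed` (A after the transform).
#' @export
kabsch_superpose <- function(A, B, correspondence = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!is.null(correspondence)) {
    correspondence <- as.matrix(correspondence)
    A <- A[correspondence[, 1], , drop = FALSE]
    B <- B[correspondence[, 2], , drop = FALSE]
  }
  if (ncol(A) != 3L || ncol(B) != 3L) stop("coordinates must be n x 3")
  if (nrow(A) != nrow(B)) stop("paired point sets differ in size")
  if (nrow(A) < 3L) stop("at least 3 paired points required")
  if (any(!is.finite(A)) || any(!is.finite(B))) stop("non-finite coordinates")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv <- svd(Ac)$d
  if (sv[2] <= 1e-8 * max(sv[1], 1))
    stop("points are collinear: rotation is not determined")
  H <- crossprod(Ac, Bc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- Ac %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Bc)^2)))
  list(rotation = R, translation = as.numeric(cb - R %*% ca),
       rmsd = rmsd, transformed = sweep(moved, 2, cb, "+"))
}

atom_coords <- function(at) as.matrix(at[, c("x", "y", "z"), drop = FALSE])

#' Distance from a motif residue to a flavin-binding pocket
#'
#' Measures the Euclidean distance from the hydroxyl oxygen (OG/OG1, CA
#' fallback) of a flavinylated Ser/Thr to the centroid of a binding pocket —
#' either the CA atoms of named pocket residues or the heavy atoms of a bound
#' ligand (e.g. `"FMN"`). A `proximal` flag marks whether the motif could
#' plausibly engage the pocket at the given cutoff.
#'
#' @param model A [read_structure] model.
#' @param motif_resno Residue number of the motif S/T.
#' @param motif_chain Chain of the motif residue (default first chain).
#' @param pocket_resnos Residue numbers defining the pocket (CA centroid), or
#'   NULL when `ligand` is given.
#' @param ligand HETATM residue name whose heavy atoms define the pocket
#'   centroid (e.g. `"FMN"`).
#' @param proximal_cutoff Distance in Angstrom below which the site is called
#'   proximal (default 15).
#' @return List with `distance` (Angstrom), `proximal` (logical),
#'   `motif_atom`, `pocket_centroid` (length-3 numeric).
#' @export
motif_pocket_distance <- function(model, motif_resno, motif_chain = NULL,
                                  pocket_resnos = NULL, ligand = NULL,
                                  proximal_cutoff = 15) {
  at <- model$atoms
  if (is.null(motif_chain)) motif_chain <- at$chain[at$type == "ATOM"][1]
  res <- at[at$type == "ATOM" & at$chain == motif_chain &
              at$resno == motif_resno, , drop = FALSE]
  if (!nrow(res)) stop("motif residue ", motif_resno, " not found in chain ", motif_chain)
  pick <- intersect(c("OG", "OG1", "CA"), res$elety)
  if (!length(pick)) stop("motif residue has no OG/OG1/CA atom")
  motif_atom <- res[res$elety == pick[1], , drop = FALSE][1, ]
  if (!is.null(ligand)) {
    pocket <- at[at$type == "HETATM" & at$resid == ligand &
                   !grepl("^H", at$elety), , drop = FALSE]
    if (!nrow(pocket)) stop("ligand not found in structure: ", ligand)
  } else {
    if (is.null(pocket_resnos)) stop("supply pocket_resnos or ligand")
    pocket <- at[at$type == "ATOM" & at$elety == "CA" &
                   at$resno %in% pocket_resnos, , drop = FALSE]
    missing <- setdiff(pocket_resnos, pocket$resno)
    if (length(missing))
      stop("pocket residue(s) missing from structure: ",
           paste(missing, collapse = ", "))
  }
  centroid <- colMeans(atom_coords(pocket))
  d <- sqrt(sum((unlist(motif_atom[c("x", "y", "z")]) - centroid)^2))
  list(distance = d, proximal = d <= proximal_cutoff,
       motif_atom = pick[1], pocket_centroid = as.numeric(centroid))
}
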