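# family tags planted into synthetic proteins; chosen to be motif-free
# (no S/T/G/A runs that could form [S/T]GA[S/T]) and unlikely by chance
SIM_FAMILIES <- list(
  anchor = list(accession = "PF02424", name = "ApbE",
                tag = "WCHNWKRCWDQW"),
  target = list(accession = "PF12682", name = "Flavodoxin_4",
                tag = "YHWDKCWNRYQC")
)

#' Configuration for the synthetic genome generator
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' single-contig genomes of 40 ordered genes, an anchor+target pair planted
#' in a genome with probability `p_cluster` at a uniform nonzero offset
#' within the +/-5-gene window, one flavinylation motif per planted target,
#' and motif-free background proteins (rejection-sampled), so planted counts
#' are exact ground truth.
#'
#' @param seed Integer seed; every random draw derives from it.
#' @param n_genomes Number of genomes.
#' @param genes_per_contig Genes per (single-contig) genome.
#' @param p_cluster Probability a genome carries a planted anchor+target pair.
#' @param max_offset Target is placed at a uniform offset in
#'   `[-max_offset, max_offset]` excluding 0.
#' @param n_motif_sites Motif sites per planted target (>2 gives
#'   multi-flavinylated targets; natural substrates reach 13).
#' @param protein_length Background protein length.
#' @param background Residue sampling frequencies (default uniform over 20).
#' @param pattern The [motif_pattern] planted into targets.
#' @param phyla Phyla assigned round-robin to genomes.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genomes = 10L, genes_per_contig = 40L,
                       p_cluster = 0.5, max_offset = 5L, n_motif_sites = 1L,
                       protein_length = 80L,
                       background = rep(1 / 20, 20),
                       pattern = motif_pattern(),
                       phyla = c("Firmicutes", "Proteobacteria",
                                 "Bacteroidota", "Actinobacteriota")) {
  stopifnot(p_cluster >= 0, p_cluster <= 1, max_offset >= 1L,
            n_motif_sites >= 1L, genes_per_contig >= 2L)
  if (max_offset >= genes_per_contig)
    stop("offset range exceeds contig length")
  structure(list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
                 genes_per_contig = as.integer(genes_per_contig),
                 p_cluster = p_cluster, max_offset = as.integer(max_offset),
                 n_motif_sites = as.integer(n_motif_sites),
                 protein_length = as.integer(protein_length),
                 background = background, pattern = pattern, phyla = phyla),
            class = "sim_config")
}

random_seq <- function(n, background) {
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = background), collapse = "")
}

motif_free_seq <- function(n, background, pattern, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    s <- random_seq(n, background)
    if (!nrow(scan_motifs(s, pattern))) return(s)
  }
  stop("could not sample a motif-free sequence")
}

sample_motif <- function(pattern) {
  paste(vapply(pattern$positions, function(p) p[sample.int(length(p), 1L)], ""),
        collapse = "")
}

# assemble a planted protein: motif-free flanks around a family tag and
# exactly n_sites motif insertions, proline-buffered so junctions cannot
# create extra matches; verified by re-scan and resampled if needed
planted_protein <- function(cfg, tag, n_sites) {
  for (try in 1:100) {
    flank_len <- max(5L, (cfg$protein_length - nchar(tag)) %/% (n_sites + 2L))
    parts <- c(motif_free_seq(flank_len, cfg$background, cfg$pattern), "P",
               tag, "P")
    for (i in seq_len(n_sites))
      parts <- c(parts, sample_motif(cfg$pattern), "P",
                 motif_free_seq(flank_len, cfg$background, cfg$pattern), "P")
    seq <- paste(parts, collapse = "")
    if (nrow(scan_motifs(seq, cfg$pattern)) == n_sites) return(seq)
  }
  stop("could not assemble planted protein")
}

#' Built-in PSSM profiles for the synthetic families
#'
#' One profile per synthetic family, scoring +2 bits for each residue of the
#' family's planted tag peptide and -1 elsewhere, so the built-in scanner
#' recovers planted domains with low empirical p-values.
#'
#' @return Named list of [domain_profile] objects (`anchor`, `target`).
#' @export
builtin_profiles <- function() {
  lapply(SIM_FAMILIES, function(fam) {
    chars <- strsplit(fam$tag, "")[[1]]
    m <- matrix(-1, nrow = length(chars), ncol = 20,
                dimnames = list(NULL, AA_ALPHABET))
    for (i in seq_along(chars)) m[i, chars[i]] <- 2
    domain_profile(fam$accession, m, name = fam$name)
  })
}

#' Simulate genomes with planted anchor+target neighborhoods
#'
#' Generates `cfg$n_genomes` single-contig genomes of ordered genes with
#' motif-free background proteins. With probability `p_cluster` a genome gets
#' an anchor-family gene (ApbE-like) and a target-family gene at a uniform
#' nonzero gene offset; the target protein carries exactly
#' `cfg$n_motif_sites` flavinylation motifs. Domain content is realized both
#' as plantable tag peptides (recoverable by [pssm_scan] with
#' [builtin_profiles]) and as a ready-made hmmsearch-style hit table.
#'
#' @param cfg A [sim_config].
#' @return List with `genomes` (list of [genome_record]), `hits` (domain-hit
#'   data.frame equivalent to hmmsearch tblout over the planted families),
#'   `profiles` ([builtin_profiles]), and `truth`: `pairs` (data.frame
#'   genome_id, anchor_gene_id, anchor_protein_id, target_gene_id,
#'   target_protein_id, offset) and `motif_sites` (data.frame genome_id,
#'   protein_id, start, flavinylated_pos).
#' @export
simulate_genomes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    genomes <- vector("list", cfg$n_genomes)
    pairs <- list(); sites <- list(); hits <- list()
    for (gi in seq_len(cfg$n_genomes)) {
      gid <- sprintf("G%04d", gi)
      n <- cfg$genes_per_contig
      gene_ids <- sprintf("%s_g%03d", gid, seq_len(n))
      prot_ids <- sprintf("%s_p%03d", gid, seq_len(n))
      genes <- data.frame(
        gene_id = gene_ids, contig_id = "c1",
        start = (seq_len(n) - 1L) * 1000L + 1L,
        end = (seq_len(n) - 1L) * 1000L + 900L,
        strand = sample(c("+", "-"), n, replace = TRUE),
        protein_id = prot_ids, stringsAsFactors = FALSE)
      proteome <- vapply(seq_len(n), function(i)
        motif_free_seq(cfg$protein_length, cfg$background, cfg$pattern), "")
      names(proteome) <- prot_ids

      if (stats::runif(1) < cfg$p_cluster) {
        offset <- sample(c(-cfg$max_offset:-1, 1:cfg$max_offset), 1L)
        lo <- max(1L, 1L - offset); hi <- min(n, n - offset)
        anchor_i <- sample(lo:hi, 1L)
        target_i <- anchor_i + offset
        proteome[anchor_i] <- planted_protein_tagged(cfg, SIM_FAMILIES$anchor$tag)
        proteome[target_i] <- planted_protein(cfg, SIM_FAMILIES$target$tag,
                                              cfg$n_motif_sites)
        pairs[[length(pairs) + 1L]] <- data.frame(
          genome_id = gid, anchor_gene_id = gene_ids[anchor_i],
          anchor_protein_id = prot_ids[anchor_i],
          target_gene_id = gene_ids[target_i],
          target_protein_id = prot_ids[target_i],
          offset = offset, stringsAsFactors = FALSE)
        st <- scan_motifs(proteome[[target_i]], cfg$pattern,
                          protein_id = prot_ids[target_i])
        st$genome_id <- gid
        sites[[length(sites) + 1L]] <- st
        hits[[length(hits) + 1L]] <- rbind(
          sim_hit(prot_ids[anchor_i], SIM_FAMILIES$anchor),
          sim_hit(prot_ids[target_i], SIM_FAMILIES$target))
      }
      lineage <- sprintf("d__Bacteria;p__%s;c__;o__;f__;g__;s__",
                         cfg$phyla[(gi - 1L) %% length(cfg$phyla) + 1L])
      genomes[[gi]] <- genome_record(gid, genes, proteome, lineage)
    }
    list(genomes = genomes,
         hits = if (length(hits)) do.call(rbind, hits) else empty_hits(),
         profiles = builtin_profiles(),
         truth = list(
           pairs = if (length(pairs)) do.call(rbind, pairs) else
             data.frame(genome_id = character(0)),
           motif_sites = if (length(sites)) do.call(rbind, sites) else
             empty_sites()))
  })
}

planted_protein_tagged <- function(cfg, tag) {
  for (try in 1:100) {
    half <- max(5L, (cfg$protein_length - nchar(tag)) %/% 2L)
    seq <- paste0(motif_free_seq(half, cfg$background, cfg$pattern), "P", tag,
                  "P", motif_free_seq(half, cfg$background, cfg$pattern))
    if (!nrow(scan_motifs(seq, cfg$pattern))) return(seq)
  }
  stop("could not assemble tagged protein")
}

sim_hit <- function(protein_id, fam) {
  data.frame(protein_id = protein_id, accession = fam$accession,
             name = fam$name, bit_score = 150, evalue = 1e-30,
             ali_start = NA_integer_, ali_end = NA_integer_,
             is_best = FALSE, stringsAsFactors = FALSE)
}

#' Write simulated genomes to on-disk fixtures
#'
#' Emits, per genome, a TSV gene table and a FASTA proteome, plus a combined
#' lineage table, an hmmsearch-style `--tblout` file for the planted
#' families, profile TSVs, and a JSON ground-truth manifest. Output is
#' byte-identical for identical configs (fixed-width text, no timestamps).
#'
#' @param sim Result of [simulate_genomes].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_fixtures <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lineages <- data.frame(genome_id = character(0), lineage = character(0))
  for (g in sim$genomes) {
    write_gene_table(g, file.path(dir, paste0(g$genome_id, ".genes.tsv")))
    writeLines(paste0(">", names(g$proteome), "\n", g$proteome),
               file.path(dir, paste0(g$genome_id, ".faa")))
    lineages <- rbind(lineages, data.frame(
      genome_id = g$genome_id,
      lineage = paste0(c("d__", "p__", "c__", "o__", "f__", "g__", "s__"),
                       g$lineage, collapse = ";"), stringsAsFactors = FALSE))
  }
  write_tsv(lineages, file.path(dir, "lineages.tsv"))
  write_tblout(sim$hits, file.path(dir, "planted.tblout"))
  for (prof in sim$profiles)
    write_profile(prof, file.path(dir, paste0(prof$accession, ".profile.tsv")))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a domain-hit table as hmmsearch-style --tblout text
#' @param hits Domain-hit data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tblout <- function(hits, path) {
  header <- c("# target name        accession  query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target",
              "#------------------- ---------- -------------------- ---------- --------- ------ ----- --------- ------ ----- ----- --- --- -- --- --- --- --- ---------------------")
  rows <- sprintf("%-20s %-10s %-20s %-10s %9.2g %6.1f %5.1f %9.2g %6.1f %5.1f %5.1f %3d %3d %2d %3d %3d %3d %3d -",
                  hits$protein_id, "-", hits$name,
                  paste0(hits$accession, ".1"), hits$evalue, hits$bit_score,
                  0, hits$evalue, hits$bit_score, 0, 1, 1, 1, 0, 1, 1, 1, 1)
  writeLines(c(header, rows, "#"), path)
  invisible(path)
}

#' Simulate an alignment with planted near-invariant columns
#'
#' Planted columns draw the designated residue with probability
#' `conservation` (other residues uniform over the remaining 19); background
#' columns are uniform over all 20 residues. No gaps are generated.
#'
#' @param n_rows,n_cols Alignment dimensions.
#' @param planted Named character vector: names are column indices, values
#'   the planted residue (e.g. `c("10" = "H", "25" = "H")`).
#' @param conservation Probability of the planted residue in its column.
#' @param seed Integer seed.
#' @return List with `msa` (character matrix, rows `seq1..seqN`) and `truth`
#'   (data.frame `column`, `residue`, `conservation`).
#' @export
simulate_msa <- function(n_rows = 100L, n_cols = 60L, planted = character(0),
                         conservation = 0.95, seed = 1L) {
  stopifnot(conservation >= 0, conservation <= 1)
  cols <- as.integer(names(planted))
  if (length(cols) && (any(cols < 1L) || any(cols > n_cols)))
    stop("planted column index outside alignment")
  with_seed(seed, {
    m <- matrix(sample(AA_ALPHABET, n_rows * n_cols, replace = TRUE),
                nrow = n_rows, ncol = n_cols)
    for (i in seq_along(cols)) {
      res <- toupper(planted[[i]])
      take <- stats::runif(n_rows) < conservation
      other <- sample(setdiff(AA_ALPHABET, res), n_rows, replace = TRUE)
      m[, cols[i]] <- ifelse(take, res, other)
    }
    rownames(m) <- sprintf("seq%03d", seq_len(n_rows))
    list(msa = m,
         truth = data.frame(column = cols, residue = toupper(unname(planted)),
                            conservation = rep(conservation, length(cols)),
                            stringsAsFactors = FALSE))
  })
}

#' Write an alignment matrix as aligned FASTA
#' @param msa Character matrix (rows = sequences).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  writeLines(paste0(">", rownames(msa), "\n",
                    apply(msa, 1, paste, collapse = "")), path)
  invisible(path)
}

#' Simulate a toy structure with planted features
#'
#' Builds per-chain CA traces as ideal alpha-helices (rise 1.5 A, 100 deg per
#' residue, radius 2.3 A, axis along z; chains offset along x). Residues
#' inside `helix_stretches` are Ile and the rest Asp, so the chain sequence
#' carries plantable hydropathy topology. Planted His residues get an
#' explicit NE2 pseudo-atom at the exact configured coordinates; an optional
#' ligand and an optional motif Ser (with OG at given coordinates) support
#' pocket-distance tests. Minimal by design: CA + planted pseudo-atoms, not
#' physically realistic side chains.
#'
#' @param n_res Residues per chain.
#' @param chains Chain identifiers (1 or 2).
#' @param helix_stretches List of `c(start, end)` residue ranges set to Ile.
#' @param his data.frame with columns `chain`, `resno`, `x`, `y`, `z`: His
#'   residues whose NE2 is placed at (x,y,z).
#' @param ligand NULL, or `list(name, center)` placing 4 heavy pseudo-atoms
#'   around `center`.
#' @param motif_ser NULL, or `list(chain, resno, og = c(x,y,z))` converting
#'   that residue to Ser with an OG atom at `og`.
#' @return List with `model` (a `structure_model`), `pdb_lines` (PDB text),
#'   and `truth` (the planted features echoed back).
#' @export
simulate_structure <- function(n_res = 60L, chains = "A",
                               helix_stretches = list(), his = NULL,
                               ligand = NULL, motif_ser = NULL) {
  stopifnot(length(chains) %in% 1:2)
  if (!is.null(his) && anyDuplicated(paste(his$chain, his$resno)))
    stop("clashing planted His residue numbers")
  atoms <- list(); serial <- 0L
  for (ci in seq_along(chains)) {
    ch <- chains[ci]
    resid <- rep("ASP", n_res)
    for (st in helix_stretches) resid[st[1]:st[2]] <- "ILE"
    if (!is.null(motif_ser) && identical(motif_ser$chain, ch))
      resid[motif_ser$resno] <- "SER"
    if (!is.null(his)) {
      hh <- his[his$chain == ch, , drop = FALSE]
      if (nrow(hh) && any(hh$resno > n_res))
        stop("planted His residue number beyond chain length")
      resid[hh$resno] <- "HIS"
    }
    i <- seq_len(n_res)
    theta <- (i - 1L) * 100 * pi / 180
    xyz <- cbind(2.3 * cos(theta) + (ci - 1L) * 30, 2.3 * sin(theta),
                 1.5 * i)
    for (r in i) {
      serial <- serial + 1L
      atoms[[length(atoms) + 1L]] <- data.frame(
        type = "ATOM", serial = serial, elety = "CA", resid = resid[r],
        chain = ch, resno = r, x = xyz[r, 1], y = xyz[r, 2], z = xyz[r, 3],
        stringsAsFactors = FALSE)
    }
    if (!is.null(his)) {
      hh <- his[his$chain == ch, , drop = FALSE]
      for (r in seq_len(nrow(hh))) {
        serial <- serial + 1L
        atoms[[length(atoms) + 1L]] <- data.frame(
          type = "ATOM", serial = serial, elety = "NE2", resid = "HIS",
          chain = ch, resno = hh$resno[r], x = hh$x[r], y = hh$y[r],
          z = hh$z[r], stringsAsFactors = FALSE)
      }
    }
    if (!is.null(motif_ser) && identical(motif_ser$chain, ch)) {
      serial <- serial + 1L
      atoms[[length(atoms) + 1L]] <- data.frame(
        type = "ATOM", serial = serial, elety = "OG", resid = "SER",
        chain = ch, resno = motif_ser$resno, x = motif_ser$og[1],
        y = motif_ser$og[2], z = motif_ser$og[3], stringsAsFactors = FALSE)
    }
  }
  if (!is.null(ligand)) {
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
    for (r in 1:4) {
      serial <- serial + 1L
      atoms[[length(atoms) + 1L]] <- data.frame(
        type = "HETATM", serial = serial, elety = paste0("C", r),
        resid = ligand$name, chain = "L", resno = 900L + r,
        x = ligand$center[1] + offs[r, 1], y = ligand$center[2] + offs[r, 2],
        z = ligand$center[3] + offs[r, 3], stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, atoms)
  lines <- vapply(seq_len(nrow(at)), function(r) {
    name <- at$elety[r]
    name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
    sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            at$type[r], at$serial[r], name_fmt, at$resid[r], at$chain[r],
            at$resno[r], at$x[r], at$y[r], at$z[r], 1, 0)
  }, "")
  lines <- c(lines, "END")
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  model <- read_structure(tf)
  unlink(tf)
  list(model = model, pdb_lines = lines,
       truth = list(chains = chains, n_res = n_res,
                    helix_stretches = helix_stretches, his = his,
                    ligand = ligand, motif_ser = motif_ser))
}

#' Apply a random rigid motion to a structure model
#'
#' Rotates all atoms by a uniformly random rotation and translates them by a
#' random offset; used to check that geometric detectors are invariant under
#' global rigid motions.
#'
#' @param model A `structure_model`.
#' @param seed Integer seed.
#' @param max_shift Translation components drawn uniform in `[-max_shift, max_shift]`.
#' @return The transformed `structure_model`.
#' @export
rigid_motion <- function(model, seed = 1L, max_shift = 50) {
  with_seed(seed, {
    R <- random_rotation()
    t <- stats::runif(3, -max_shift, max_shift)
    xyz <- atom_coords(model$atoms) %*% t(R)
    model$atoms$x <- xyz[, 1] + t[1]
    model$atoms$y <- xyz[, 2] + t[2]
    model$atoms$z <- xyz[, 3] + t[3]
    model
  })
}

# uniform random rotation via quaternion
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  quat_to_rot(q)
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}
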