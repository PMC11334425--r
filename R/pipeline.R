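#' Default pipeline parameters
#'
#' Window half-width of 5 genes, best-match E-value cutoff of 0.001, the
#' \[S/T\]GA\[S/T\] motif, 6.0 A heme-pair cutoff with sequence separation
#' >= 10, Kyte-Doolittle window 19 at threshold 1.6, and 3.0-bit conservation
#' floor.
#'
#' @return Named list of defaults.
#' @export
default_params <- function() {
  list(window_k = 5L, evalue_cutoff = 0.001,
       pattern = motif_pattern(),
       heme_max_dist = 6.0, heme_min_seq_sep = 10L,
       tm_window = 19L, tm_threshold = 1.6,
       min_ic = 3.0, min_occupancy = 0.5,
       proximal_cutoff = 15)
}

#' Mine genomes for co-localized flavinylation candidates (in memory)
#'
#' Chains the full discovery procedure: best-match domain assignment,
#' anchor-window extraction, motif scanning, candidate calling, and
#' taxonomy/co-localization summaries.
#'
#' @param genomes List of [genome_record] objects (with proteomes).
#' @param hits Domain-hit data.frame ([read_tblout] or
#'   [pssm_scan_proteome]).
#' @param anchor_family Anchor accession (e.g. ApbE's `"PF02424"`).
#' @param target_families Candidate target accessions.
#' @param window_k Window half-width in genes.
#' @param evalue_cutoff Best-match E-value cutoff.
#' @param pattern A [motif_pattern].
#' @return List: `candidates`, `cluster_summary`, `cluster_members`, `sites`
#'   (motif sites of candidate proteins), `taxonomy` (phylum distribution of
#'   candidate-bearing genomes), `frequency` (per-target co-localization
#'   fractions), `family_of`, `clusters`.
#' @export
mine_candidates <- function(genomes, hits, anchor_family, target_families,
                            window_k = 5L, evalue_cutoff = 0.001,
                            pattern = motif_pattern()) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  family_of <- best_family(hits, evalue_cutoff)
  clusters <- find_colocalized(genomes, family_of, anchor_family,
                               target_families, k = window_k)
  proteome <- do.call(c, lapply(genomes, `[[`, "proteome"))
  # scanning only window members keeps large runs cheap; background proteins
  # outside every window can never become candidates
  window_pids <- unique(unlist(lapply(clusters, function(cl)
    cl$members$protein_id[!is.na(cl$members$protein_id)])))
  sites <- scan_motifs_proteome(proteome[intersect(window_pids, names(proteome))],
                                pattern)
  candidates <- call_candidates(clusters, sites, family_of, target_families)
  lineages <- stats::setNames(lapply(genomes, `[[`, "lineage"),
                              vapply(genomes, `[[`, "", "genome_id"))
  frequency <- do.call(rbind, lapply(target_families, function(fam) {
    fr <- colocalization_frequency(clusters, fam, lineages = lineages)
    data.frame(target_family = fam, n_anchors = fr$n_anchors,
               fraction = fr$overall, stringsAsFactors = FALSE)
  }))
  tables <- clusters_to_tables(clusters, family_of)
  list(candidates = candidates, cluster_summary = tables$summary,
       cluster_members = tables$members,
       sites = sites[sites$protein_id %in% candidates$protein_id, , drop = FALSE],
       taxonomy = tabulate_taxa(genomes, unique(candidates$genome_id)),
       frequency = frequency, family_of = family_of, clusters = clusters)
}

#' Read a directory of genome fixtures
#'
#' Expects the layout written by [write_sim_fixtures]: per-genome
#' `<id>.genes.tsv` (or `<id>.gff3`) and `<id>.faa`, plus an optional
#' `lineages.tsv` (columns genome_id, lineage).
#'
#' @param dir Directory path.
#' @return List of [genome_record] objects.
#' @export
read_genomes_dir <- function(dir) {
  tables <- sort(c(list.files(dir, "\\.genes\\.tsv$", full.names = TRUE),
                   list.files(dir, "\\.gff3?$", full.names = TRUE)))
  if (!length(tables)) stop("no gene tables (*.genes.tsv / *.gff3) in ", dir)
  lin <- character(0)
  lin_path <- file.path(dir, "lineages.tsv")
  if (file.exists(lin_path)) {
    lt <- utils::read.delim(lin_path, stringsAsFactors = FALSE)
    lin <- stats::setNames(lt$lineage, lt$genome_id)
  }
  lapply(tables, function(path) {
    gid <- sub("\\.(genes\\.tsv|gff3?)$", "", basename(path))
    rec <- read_gene_table(path, gid,
                           lineage = if (gid %in% names(lin)) lin[[gid]] else "")
    faa <- file.path(dir, paste0(gid, ".faa"))
    if (!file.exists(faa)) stop("missing proteome FASTA: ", faa)
    genome_record(gid, rec$genes, read_proteome(faa), rec$lineage)
  })
}

#' Run the mining pipeline from a configuration
#'
#' File-level entry point: reads genomes, annotates (from `tblout` files or
#' by scanning `profiles`), mines neighborhoods and motifs, and writes
#' candidate/cluster/taxonomy TSVs plus a JSON run manifest. Outputs are
#' written to a staging directory and renamed into place only on success, so
#' partial outputs are never left behind; identical config and inputs give
#' byte-identical outputs.
#'
#' @param config List (or path to a YAML file) with fields: `genomes_dir`;
#'   `tblout` (file or directory of `--tblout` files) or `profiles`
#'   (character vector of profile TSVs); `anchor_family`; `target_families`;
#'   `out_dir`; optional `window_k`, `evalue_cutoff`, `seed` (used by the
#'   PSSM scanner's empirical p-values), `n_shuffles`, `verbose`.
#' @return The [mine_candidates] result, invisibly, with `out_dir` attached.
#' @export
run_mine <- function(config) {
  config <- load_config(config)
  p <- merge_params(config)
  for (field in c("genomes_dir", "anchor_family", "target_families", "out_dir"))
    if (is.null(config[[field]])) stop("config is missing field: ", field)
  if (!dir.exists(config$genomes_dir))
    stop("genomes_dir does not exist: ", config$genomes_dir)
  inputs <- character(0)
  log_msg("INFO", "reading genomes from ", config$genomes_dir,
          verbose = isTRUE(config$verbose))
  genomes <- read_genomes_dir(config$genomes_dir)
  inputs <- c(inputs, list.files(config$genomes_dir, full.names = TRUE))
  if (!is.null(config$tblout)) {
    paths <- if (dir.exists(config$tblout))
      list.files(config$tblout, "\\.tblout$", full.names = TRUE) else config$tblout
    if (!all(file.exists(paths))) stop("tblout input not found")
    hits <- do.call(rbind, lapply(sort(paths), read_tblout))
    inputs <- c(inputs, paths)
  } else if (!is.null(config$profiles)) {
    if (!all(file.exists(config$profiles))) stop("profile file not found")
    profiles <- lapply(sort(config$profiles), read_profile)
    proteome <- do.call(c, lapply(genomes, `[[`, "proteome"))
    hits <- pssm_scan_proteome(proteome, profiles,
                               n_shuffles = config$n_shuffles %||% 200L,
                               seed = config$seed %||% 1L)
    inputs <- c(inputs, config$profiles)
  } else stop("config needs either 'tblout' or 'profiles'")

  res <- mine_candidates(genomes, hits, config$anchor_family,
                         config$target_families, window_k = p$window_k,
                         evalue_cutoff = p$evalue_cutoff, pattern = p$pattern)
  manifest <- list(
    tool = "flavimine", version = as.character(utils::packageVersion("flavimine")),
    seed = config$seed %||% 1L,
    parameters = list(window_k = p$window_k, evalue_cutoff = p$evalue_cutoff,
                      motif = p$pattern$pattern_id,
                      anchor_family = config$anchor_family,
                      target_families = config$target_families),
    n_genomes = length(genomes), n_clusters = length(res$clusters),
    n_candidates = nrow(res$candidates),
    input_md5 = as.list(tools::md5sum(sort(inputs))))
  write_outputs(config$out_dir, c(
    list(candidates = res$candidates, cluster_summary = res$cluster_summary,
         cluster_members = res$cluster_members, motif_sites = res$sites,
         taxonomy = res$taxonomy, colocalization_frequency = res$frequency)),
    manifest)
  res$out_dir <- config$out_dir
  invisible(res)
}

#' Run structure-feature detection from a configuration
#'
#' For each PDB file: per-chain transmembrane segments, bis-His heme-site
#' candidates, and (when a `pocket` is configured and present) the
#' motif-to-pocket distance. Writes `tm_segments.tsv`, `heme_pairs.tsv`,
#' `pocket_distances.tsv` and a manifest, atomically as in [run_mine].
#'
#' @param config List (or YAML path) with `structures` (PDB paths or a
#'   directory), `out_dir`, optional `tm_window`, `tm_threshold`,
#'   `heme_max_dist`, `heme_min_seq_sep`, and optional `pocket =
#'   list(ligand=, motif_resno=, motif_chain=)`.
#' @return List of per-structure feature tables, invisibly.
#' @export
run_structure <- function(config) {
  config <- load_config(config)
  p <- merge_params(config)
  if (is.null(config$structures) || is.null(config$out_dir))
    stop("config needs 'structures' and 'out_dir'")
  paths <- if (length(config$structures) == 1L && dir.exists(config$structures))
    list.files(config$structures, "\\.pdb$", full.names = TRUE)
  else config$structures
  if (!length(paths) || !all(file.exists(paths)))
    stop("structure input not found: ",
         paste(paths[!file.exists(paths)], collapse = ", "))
  paths <- sort(paths)
  tm <- list(); heme <- list(); pocket <- list()
  for (path in paths) {
    id <- tools::file_path_sans_ext(basename(path))
    model <- read_structure(path)
    for (ch in names(model$sequence)) {
      seg <- detect_tm_segments(model$sequence[[ch]], window = p$tm_window,
                                threshold = p$tm_threshold, chain = ch)
      if (nrow(seg)) { seg$structure_id <- id; tm[[length(tm) + 1L]] <- seg }
    }
    hp <- detect_heme_his_pairs(model, max_dist = p$heme_max_dist,
                                min_seq_sep = p$heme_min_seq_sep)
    if (nrow(hp)) { hp$structure_id <- id; heme[[length(heme) + 1L]] <- hp }
    pk <- config$pocket
    if (!is.null(pk) &&
        pk$ligand %in% model$atoms$resid[model$atoms$type == "HETATM"]) {
      d <- motif_pocket_distance(model, pk$motif_resno,
                                 motif_chain = pk$motif_chain,
                                 ligand = pk$ligand,
                                 proximal_cutoff = p$proximal_cutoff)
      pocket[[length(pocket) + 1L]] <- data.frame(
        structure_id = id, motif_resno = pk$motif_resno,
        ligand = pk$ligand, distance = d$distance, proximal = d$proximal,
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else data.frame()
  out <- list(tm_segments = bind(tm), heme_pairs = bind(heme),
              pocket_distances = bind(pocket))
  manifest <- list(
    tool = "flavimine", version = as.character(utils::packageVersion("flavimine")),
    parameters = list(tm_window = p$tm_window, tm_threshold = p$tm_threshold,
                      heme_max_dist = p$heme_max_dist,
                      heme_min_seq_sep = p$heme_min_seq_sep),
    n_structures = length(paths),
    input_md5 = as.list(tools::md5sum(paths)))
  write_outputs(config$out_dir, out, manifest)
  invisible(out)
}

#' Generate and write the synthetic validation fixtures
#'
#' @param config List (or YAML path) with `out_dir` and any [sim_config]
#'   field (`seed`, `n_genomes`, `genes_per_contig`, `p_cluster`, ...).
#' @return The simulation result, invisibly.
#' @export
run_simulate <- function(config) {
  config <- load_config(config)
  if (is.null(config$out_dir)) stop("config needs 'out_dir'")
  args <- config[intersect(names(config),
                           names(formals(sim_config)))]
  sim <- simulate_genomes(do.call(sim_config, args))
  write_sim_fixtures(sim, config$out_dir)
  invisible(sim)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

merge_params <- function(config) {
  p <- default_params()
  if (!is.null(config$motif_positions))
    config$pattern <- motif_pattern(lapply(strsplit(config$motif_positions, ",")[[1]],
                                           function(s) strsplit(s, "")[[1]]))
  for (k in intersect(names(config), names(p))) p[[k]] <- config[[k]]
  p
}

# stage-then-rename so a failed run never leaves partial outputs
write_outputs <- function(out_dir, tables, manifest) {
  staging <- paste0(out_dir, ".staging")
  unlink(staging, recursive = TRUE)
  dir.create(staging, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(staging, recursive = TRUE))
  for (nm in names(tables))
    write_tsv(tables[[nm]], file.path(staging, paste0(nm, ".tsv")))
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(out_dir, recursive = TRUE)
  if (!file.rename(staging, out_dir))
    stop("could not move staged outputs into place: ", out_dir)
  ok <- TRUE
  invisible(out_dir)
}
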