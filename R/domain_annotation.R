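AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

empty_hits <- function() {
  data.frame(protein_id = character(0), accession = character(0),
             name = character(0), bit_score = numeric(0), evalue = numeric(0),
             ali_start = integer(0), ali_end = integer(0),
             is_best = logical(0), stringsAsFactors = FALSE)
}

#' Read hmmsearch --tblout output
#'
#' Parses the HMMER3 per-sequence tabular format (whitespace-delimited, 18
#' fixed columns plus free-text description, `#` comment lines). The
#' full-sequence E-value and bit score are kept; per-domain statistics are
#' ignored. No E-value filtering happens here — see [assign_best].
#'
#' @param path Path to a `--tblout` file.
#' @return Domain-hit data.frame with columns `protein_id`, `accession`,
#'   `name`, `bit_score`, `evalue`, `ali_start`, `ali_end` (NA: tblout has no
#'   alignment coordinates), `is_best` (all FALSE until [assign_best]).
#' @export
read_tblout <- function(path) {
  if (!file.exists(path)) stop("tblout file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(empty_hits())
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 18L)) {
    bad <- which(keep)[which(nf < 18L)[1]]
    stop(sprintf("malformed tblout line %d in %s: expected >=18 whitespace-delimited fields, got %d",
                 bad, path, min(nf)))
  }
  # tblout columns: 1 target name, 3 query name, 4 query accession,
  # 5 full-seq E-value, 6 full-seq score
  acc <- vapply(fields, `[`, "", 4L)
  name <- vapply(fields, `[`, "", 3L)
  acc[acc == "-"] <- name[acc == "-"]
  data.frame(
    protein_id = vapply(fields, `[`, "", 1L),
    accession = sub("\\.\\d+$", "", acc),
    name = name,
    bit_score = as.numeric(vapply(fields, `[`, "", 6L)),
    evalue = as.numeric(vapply(fields, `[`, "", 5L)),
    ali_start = NA_integer_, ali_end = NA_integer_,
    is_best = FALSE, stringsAsFactors = FALSE
  )
}

#' Build a position-specific scoring profile
#'
#' @param accession Pfam-style accession (e.g. `"PF12682"`).
#' @param scores Numeric matrix, one row per profile column, 20 columns of
#'   per-residue log-odds scores in bits, column names the amino-acid
#'   one-letter codes.
#' @param name Human-readable family name.
#' @param background Background residue frequencies (default uniform 1/20).
#' @return A `domain_profile` object.
#' @export
domain_profile <- function(accession, scores, name = accession,
                           background = rep(1 / 20, 20)) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) colnames(scores) <- AA_ALPHABET
  scores <- scores[, AA_ALPHABET, drop = FALSE]
  if (nrow(scores) < 1L) stop("profile needs at least one column")
  if (any(!is.finite(scores))) stop("profile scores must all be finite")
  structure(list(accession = accession, name = name, scores = scores,
                 background = background),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("<domain_profile> %s (%s): %d columns\n",
              x$accession, x$name, nrow(x$scores)))
  invisible(x)
}

#' Read a profile file (TSV dialect)
#'
#' One row per profile column with 20 score fields headed by the amino-acid
#' letters; `accession` and `name` come from `# accession=` / `# name=`
#' header comments, else the file name.
#'
#' @param path Profile TSV path.
#' @return A [domain_profile].
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[grepl("^#", lines)]
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), meta, value = TRUE)
    if (length(hit)) trimws(sub(".*=", "", hit[1])) else default
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)], check.names = FALSE)
  domain_profile(get_meta("accession", tools::file_path_sans_ext(basename(path))),
                 as.matrix(tab), name = get_meta("name", basename(path)))
}

#' Write a profile to the TSV dialect read by [read_profile]
#' @param profile A [domain_profile].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# accession=%s", profile$accession),
               sprintf("# name=%s", profile$name),
               paste(AA_ALPHABET, collapse = "\t")), con)
  utils::write.table(profile$scores, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

score_windows <- function(idx, scores) {
  L <- nrow(scores)
  nw <- length(idx) - L + 1L
  total <- numeric(nw)
  for (i in seq_len(L))
    total <- total + scores[i, idx[i:(i + nw - 1L)]]
  total
}

#' Scan a sequence with an ungapped PSSM
#'
#' Slides the profile along the sequence, scoring each window as the sum of
#' per-column log-odds, and returns the maximum-scoring window (leftmost on
#' ties). Significance is an empirical p-value: the best scores of
#' `n_shuffles` seeded residue shuffles of the sequence, re-scanned with the
#' same profile, give `p = (1 + #{shuffle best >= observed}) / (n_shuffles + 1)`.
#'
#' @param seq Amino-acid sequence (string). Letters outside the 20-residue
#'   alphabet (e.g. `X`) score the profile column minimum.
#' @param profile A [domain_profile].
#' @param protein_id Identifier carried into the hit row.
#' @param n_shuffles Shuffles for the empirical p-value (0 disables: evalue NA).
#' @param seed Integer seed for the shuffles.
#' @return One-row domain-hit data.frame, or NULL when the sequence is
#'   shorter than the profile.
#' @export
pssm_scan <- function(seq, profile, protein_id = NA_character_,
                      n_shuffles = 200L, seed = 1L) {
  stopifnot(inherits(profile, "domain_profile"))
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- nrow(profile$scores)
  if (length(chars) < L) return(NULL)
  scores <- cbind(profile$scores, UNK = apply(profile$scores, 1, min))
  idx <- match(chars, colnames(scores))
  idx[is.na(idx)] <- ncol(scores)
  w <- score_windows(idx, scores)
  best <- which.max(w)
  pval <- NA_real_
  if (n_shuffles > 0L) {
    pval <- with_seed(seed, {
      exceed <- 0L
      for (i in seq_len(n_shuffles)) {
        sh <- idx[sample.int(length(idx))]
        if (max(score_windows(sh, scores)) >= w[best] - 1e-12) exceed <- exceed + 1L
      }
      (1 + exceed) / (n_shuffles + 1)
    })
  }
  data.frame(protein_id = protein_id, accession = profile$accession,
             name = profile$name, bit_score = unname(w[best]), evalue = pval,
             ali_start = best, ali_end = best + L - 1L,
             is_best = FALSE, stringsAsFactors = FALSE)
}

#' Scan a whole proteome against a set of profiles
#'
#' @param proteome Named character vector of sequences.
#' @param profiles List of [domain_profile] objects.
#' @inheritParams pssm_scan
#' @return Domain-hit data.frame (zero rows if nothing scorable).
#' @export
pssm_scan_proteome <- function(proteome, profiles, n_shuffles = 200L, seed = 1L) {
  rows <- list()
  for (pid in names(proteome))
    for (prof in profiles) {
      h <- pssm_scan(proteome[[pid]], prof, protein_id = pid,
                     n_shuffles = n_shuffles,
                     seed = seed + utf8_checksum(paste0(pid, prof$accession)))
      if (!is.null(h)) rows[[length(rows) + 1L]] <- h
    }
  if (!length(rows)) return(empty_hits())
  do.call(rbind, rows)
}

utf8_checksum <- function(s) sum(utf8ToInt(s)) %% 10000L

#' Keep one best-match domain family per protein
#'
#' Among hits with `evalue <= evalue_cutoff` the lowest E-value wins; ties go
#' to the higher bit score, then the lexicographically smaller accession.
#' Proteins with no passing hit are unannotated (absent from the result).
#' Idempotent and invariant to permutation of the hit rows.
#'
#' @param hits Domain-hit data.frame ([read_tblout] / [pssm_scan_proteome]).
#' @param evalue_cutoff Significance cutoff (default 0.001).
#' @return The passing hits with `is_best` set; exactly one TRUE per protein.
#' @export
assign_best <- function(hits, evalue_cutoff = 0.001) {
  hits <- hits[!is.na(hits$evalue) & hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (!nrow(hits)) return(empty_hits())
  ord <- order(hits$protein_id, hits$evalue, -hits$bit_score, hits$accession)
  hits <- hits[ord, , drop = FALSE]
  hits$is_best <- !duplicated(hits$protein_id)
  rownames(hits) <- NULL
  hits
}

#' Best-match family lookup per protein
#' @inheritParams assign_best
#' @return Named character vector protein_id -> accession of the best family.
#' @export
best_family <- function(hits, evalue_cutoff = 0.001) {
  best <- assign_best(hits, evalue_cutoff)
  best <- best[best$is_best, , drop = FALSE]
  stats::setNames(best$accession, best$protein_id)
}
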