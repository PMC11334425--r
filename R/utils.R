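#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so library calls never perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Write a data.frame as canonical TSV
#'
#' Tab-delimited, header row, UTF-8, '.' decimal, no quoting, LF line ends —
#' the package's canonical tabular output dialect.
#'
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (col in names(x))
    if (is.list(x[[col]]))
      x[[col]] <- vapply(x[[col]], function(v) paste(v, collapse = ","), "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(format_df_c(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

# locale-independent numeric formatting for deterministic byte output
format_df_c <- function(x) {
  for (col in names(x))
    if (is.double(x[[col]]))
      x[[col]] <- formatC(x[[col]], format = "g", digits = 10)
  x
}

log_msg <- function(level, ..., verbose = TRUE) {
  if (verbose)
    message(sprintf("[%s] %s", level, paste0(...)))
}
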