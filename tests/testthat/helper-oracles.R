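# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# all-windows degenerate motif matcher
brute_motif_starts <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(positions)
  n <- length(chars)
  if (n < L) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(n - L + 1L)) {
    ok <- TRUE
    for (j in seq_len(L))
      if (!chars[s + j - 1L] %in% positions[[j]]) { ok <- FALSE; break }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# all-windows PSSM scorer; returns leftmost best window and its score
brute_pssm_best <- function(seq, score_matrix) {
  chars <- strsplit(seq, "")[[1]]
  L <- nrow(score_matrix)
  n <- length(chars)
  if (n < L) return(NULL)
  unk <- apply(score_matrix, 1, min)
  best_s <- -Inf; best_i <- NA_integer_
  for (s in seq_len(n - L + 1L)) {
    tot <- 0
    for (j in seq_len(L)) {
      aa <- chars[s + j - 1L]
      tot <- tot + unname(if (aa %in% colnames(score_matrix)) score_matrix[j, aa] else unk[j])
    }
    if (tot > best_s + 1e-12) { best_s <- tot; best_i <- s }
  }
  list(start = best_i, score = best_s)
}

quat_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# superposition rmsd by quaternion search: random-rotation grid plus
# Nelder-Mead refinement on the quaternion; no SVD anywhere
brute_rmsd <- function(A, B, n_grid = 400L) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  obj <- function(q) {
    R <- quat_rot(q)
    sqrt(mean(rowSums((Ac %*% t(R) - Bc)^2)))
  }
  qs <- matrix(rnorm(4L * n_grid), ncol = 4)
  vals <- apply(qs, 1, obj)
  best <- qs[which.min(vals), ]
  fit <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  fit2 <- optim(fit$par, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
  fit2$value
}

random_pattern <- function(len = sample(3:5, 1)) {
  positions <- lapply(seq_len(len), function(i)
    sample(AA20, sample(1:4, 1)))
  motif_pattern(positions, flavinylated_offset = len - 1L)
}

random_profile <- function(len = sample(3:8, 1)) {
  m <- matrix(round(rnorm(len * 20), 2), nrow = len,
              dimnames = list(NULL, AA20))
  domain_profile("PFTEST", m)
}

random_aa_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
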