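# Independent brute-force oracles used across tests. These deliberately use
# the naive three-matrix affine-gap recurrence with no optimizations, and
# share no code with the package kernels.

# Best local alignment score of profile (L x A score matrix, columns named
# by alphabet letters) vs subject letters; gap of length k costs
# open + k * ext.
oracle_profile_sw <- function(profile, subject_chars, open, ext) {
  L <- nrow(profile)
  N <- length(subject_chars)
  NEG <- -1e9
  H <- matrix(0, L + 1, N + 1)
  E <- matrix(NEG, L + 1, N + 1)
  F <- matrix(NEG, L + 1, N + 1)
  best <- 0
  for (i in seq_len(L)) {
    for (j in seq_len(N)) {
      E[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, E[i, j + 1] - ext)
      F[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, F[i + 1, j] - ext)
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + profile[i, subject_chars[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

oracle_seq_sw <- function(q_chars, s_chars, scores, open, ext) {
  profile <- scores[q_chars, , drop = FALSE]
  oracle_profile_sw(profile, s_chars, open, ext)
}

random_protein <- function(n, letters = NULL) {
  if (is.null(letters))
    letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# random gapped alignment rows (no double-gap columns, no all-gap rows)
random_gapped_rows <- function(ncol = 12) {
  aa <- c("A", "C", "D", "E", "F", "G")
  repeat {
    kind <- sample(c("m", "d", "i"), ncol, replace = TRUE,
                   prob = c(0.7, 0.15, 0.15))
    if (any(kind == "m")) break
  }
  q <- ifelse(kind == "i", "-", sample(aa, ncol, replace = TRUE))
  s <- ifelse(kind == "d", "-",
              ifelse(stats::runif(ncol) < 0.5 & kind == "m", q,
                     sample(aa, ncol, replace = TRUE)))
  list(query = paste(q, collapse = ""), subject = paste(s, collapse = ""))
}

# Independent BTOP expansion: aligned (query_pos, subject_pos) pairs, using
# regex tokenization rather than the package's character-walk parser.
oracle_btop_pairs <- function(btop, q_start, s_start) {
  toks <- regmatches(btop, gregexpr("[0-9]+|[A-Z-][A-Z-]", btop))[[1]]
  qp <- q_start - 1L; sp <- s_start - 1L
  out <- matrix(0L, 0L, 2L)
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      n <- as.integer(t)
      if (n > 0L)
        out <- rbind(out, cbind(qp + seq_len(n), sp + seq_len(n)))
      qp <- qp + n; sp <- sp + n
    } else {
      qc <- substr(t, 1, 1); sc <- substr(t, 2, 2)
      if (qc != "-") qp <- qp + 1L
      if (sc != "-") sp <- sp + 1L
      if (qc != "-" && sc != "-") out <- rbind(out, c(qp, sp))
    }
  }
  out
}
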