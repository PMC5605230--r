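#' Decode and encode BTOP alignment strings
#'
#' BTOP (BLAST trace-back operations) encodes a pairwise alignment as a
#' sequence of match-run lengths (integers) and 2-character edit tokens
#' (query character first, then subject character; \code{-} marks a gap on
#' either side, never both). \code{btop_decode()} expands a BTOP string over
#' the aligned query and subject segments into two equal-length gapped rows;
#' \code{btop_encode()} is its inverse and always merges adjacent match runs
#' (canonical form; zero-length runs are tolerated on input).
#'
#' @param btop BTOP string.
#' @param query_segment,subject_segment the exact (ungapped) aligned
#'   segments, i.e. query residues \code{q_start..q_end} and subject
#'   residues \code{s_start..s_end}.
#' @return \code{btop_decode}: a list with gapped character strings
#'   \code{query} and \code{subject}; \code{btop_encode}: a BTOP string.
#' @examples
#' btop_decode("3ED1", "ACDEF", "ACDDF")
#' btop_encode("ACADE", "AC-DE")
#' @export
btop_decode <- function(btop, query_segment, subject_segment) {
  toks <- btop_tokens(btop)
  q <- seq_chars(query_segment); s <- seq_chars(subject_segment)
  qi <- 0L; si <- 0L
  qrow <- character(); srow <- character()
  for (k in seq_along(toks)) {
    t <- toks[[k]]
    if (is.numeric(t)) {
      n <- as.integer(t)
      if (qi + n > length(q) || si + n > length(s))
        stop("BTOP decode error at token ", k,
             ": match run exceeds segment length")
      if (n > 0L) {
        run_q <- q[qi + seq_len(n)]; run_s <- s[si + seq_len(n)]
        if (any(run_q != run_s))
          stop("BTOP decode error at token ", k,
               ": match run covers mismatching residues")
        qrow <- c(qrow, run_q); srow <- c(srow, run_s)
        qi <- qi + n; si <- si + n
      }
    } else {
      qc <- t[1]; sc <- t[2]
      if (qc == "-" && sc == "-")
        stop("BTOP decode error at token ", k, ": double gap")
      if (qc != "-") {
        qi <- qi + 1L
        if (qi > length(q))
          stop("BTOP decode error at token ", k, ": query segment exhausted")
        if (q[qi] != qc)
          stop("BTOP decode error at token ", k, ": query residue mismatch")
      }
      if (sc != "-") {
        si <- si + 1L
        if (si > length(s))
          stop("BTOP decode error at token ", k, ": subject segment exhausted")
        if (s[si] != sc)
          stop("BTOP decode error at token ", k, ": subject residue mismatch")
      }
      qrow <- c(qrow, qc); srow <- c(srow, sc)
    }
  }
  if (qi != length(q) || si != length(s))
    stop("BTOP decode error: segments not fully consumed")
  list(query = paste(qrow, collapse = ""),
       subject = paste(srow, collapse = ""))
}

#' @rdname btop_decode
#' @param query_row,subject_row equal-length gapped rows (gap \code{-}); no
#'   column may have gaps in both.
#' @export
btop_encode <- function(query_row, subject_row) {
  q <- seq_chars(query_row); s <- seq_chars(subject_row)
  if (length(q) != length(s)) stop("rows must have equal length")
  out <- character(); run <- 0L
  for (i in seq_along(q)) {
    if (q[i] == "-" && s[i] == "-")
      stop("BTOP encode error: double-gap column at ", i)
    if (q[i] == s[i] && q[i] != "-") {
      run <- run + 1L
    } else {
      if (run > 0L) { out <- c(out, as.character(run)); run <- 0L }
      out <- c(out, paste0(q[i], s[i]))
    }
  }
  if (run > 0L) out <- c(out, as.character(run))
  paste(out, collapse = "")
}

# Split a BTOP string into numeric match runs and 2-char edit tokens.
btop_tokens <- function(btop) {
  chars <- seq_chars(btop)
  toks <- list(); i <- 1L; n <- length(chars)
  while (i <= n) {
    if (grepl("[0-9]", chars[i])) {
      j <- i
      while (j < n && grepl("[0-9]", chars[j + 1L])) j <- j + 1L
      toks[[length(toks) + 1L]] <- as.numeric(paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      if (i + 1L > n)
        stop("BTOP parse error: dangling edit character at offset ", i)
      toks[[length(toks) + 1L]] <- chars[c(i, i + 1L)]
      i <- i + 2L
    }
  }
  toks
}

# Number of query and subject residues a BTOP string consumes.
btop_consumption <- function(btop) {
  toks <- btop_tokens(btop)
  qn <- 0L; sn <- 0L
  for (t in toks) {
    if (is.numeric(t)) { qn <- qn + t; sn <- sn + t }
    else {
      if (t[1] != "-") qn <- qn + 1L
      if (t[2] != "-") sn <- sn + 1L
    }
  }
  c(query = as.integer(qn), subject = as.integer(sn))
}
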