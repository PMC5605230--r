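#' @title Local alignment objects
#' @description A \code{local_alignment} records one pairwise local
#'   alignment: 1-based inclusive coordinates on query and subject, raw
#'   score in matrix units, bit score, E-value, percent identity (gap
#'   columns included in the denominator), and the BTOP trace.
#' @name local_alignment
NULL

new_local_alignment <- function(q_start, q_end, s_start, s_end, raw_score,
                                bit_score = NA_real_, evalue = NA_real_,
                                percent_identity, btop) {
  structure(list(q_start = as.integer(q_start), q_end = as.integer(q_end),
                 s_start = as.integer(s_start), s_end = as.integer(s_end),
                 raw_score = raw_score, bit_score = bit_score,
                 evalue = evalue, percent_identity = percent_identity,
                 btop = btop),
            class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("local alignment q %d..%d / s %d..%d score %s id %.1f%% E %s\n",
              x$q_start, x$q_end, x$s_start, x$s_end,
              format(x$raw_score), x$percent_identity,
              format(x$evalue, digits = 3)))
  invisible(x)
}

# Build the L x 21 profile for a plain sequence query: row i is the
# substitution-matrix row of query residue i.
profile_from_query <- function(query, matrix) {
  idx <- aa_index(seq_chars(query$residues))
  matrix$scores[idx, , drop = FALSE]
}

# ops string from the C kernel -> gapped rows + alignment stats
ops_to_alignment <- function(res, query_res, subject_res) {
  ops <- seq_chars(res$ops)
  qi <- res$q_start; si <- res$s_start
  qrow <- character(length(ops)); srow <- character(length(ops))
  for (k in seq_along(ops)) {
    if (ops[k] == "M") {
      qrow[k] <- substr(query_res, qi, qi); srow[k] <- substr(subject_res, si, si)
      qi <- qi + 1L; si <- si + 1L
    } else if (ops[k] == "D") {
      qrow[k] <- substr(query_res, qi, qi); srow[k] <- "-"
      qi <- qi + 1L
    } else {
      qrow[k] <- "-"; srow[k] <- substr(subject_res, si, si)
      si <- si + 1L
    }
  }
  list(query_row = paste(qrow, collapse = ""),
       subject_row = paste(srow, collapse = ""),
       identities = sum(qrow == srow & qrow != "-"),
       columns = length(ops))
}

#' Smith-Waterman local alignment of two protein sequences
#'
#' Maximal-scoring local alignment under affine gap penalties (gap of length
#' \eqn{k} costs \code{gap_open + k * gap_extend}). Traceback ties prefer the
#' diagonal, then a gap in the subject, then a gap in the query, so results
#' are deterministic. Returns \code{NULL} when no cell scores above zero
#' (no hit).
#'
#' @param query,subject [protein_seq()] records.
#' @param matrix a [substitution_matrix()]; default [blosum62()].
#' @param params optional [evd_params()] used to attach a bit score and
#'   E-value; when \code{NULL} the alignment carries only the raw score.
#' @return A \code{local_alignment}, or \code{NULL} for no hit.
#' @export
smith_waterman <- function(query, subject, matrix = blosum62(),
                           params = NULL) {
  stopifnot(inherits(query, "protein_seq"), inherits(subject, "protein_seq"))
  prof <- profile_from_query(query, matrix)
  res <- .sw_align(prof, aa_index(seq_chars(subject$residues)) - 1L,
                   matrix$gap_open, matrix$gap_extend)
  finish_alignment(res, query$residues, subject$residues, params)
}

#' Smith-Waterman search of a PSSM against a protein sequence
#'
#' As [smith_waterman()] but match scores come from the PSSM's
#' position-specific integer scores; the query side of the BTOP trace uses
#' the PSSM's query residues. Subject \code{X} residues score
#' \code{x_score} at every position.
#'
#' @param pssm a \code{pssm} object.
#' @param subject a [protein_seq()].
#' @param gap_open,gap_extend affine gap penalties (defaults 11/1).
#' @param params optional [evd_params()] for bit score / E-value.
#' @param x_score score assigned to subject \code{X} residues.
#' @return A \code{local_alignment}, or \code{NULL} for no hit.
#' @export
pssm_search <- function(pssm, subject, gap_open = 11L, gap_extend = 1L,
                        params = NULL, x_score = -1L) {
  stopifnot(inherits(pssm, "pssm"), inherits(subject, "protein_seq"))
  prof <- cbind(pssm$scores, X = as.integer(x_score))
  res <- .sw_align(prof, aa_index(seq_chars(subject$residues)) - 1L,
                   as.integer(gap_open), as.integer(gap_extend))
  finish_alignment(res, pssm$query$residues, subject$residues, params)
}

finish_alignment <- function(res, query_res, subject_res, params) {
  if (res$score <= 0) return(NULL)
  al <- ops_to_alignment(res, query_res, subject_res)
  btop <- btop_encode(al$query_row, al$subject_row)
  aln <- new_local_alignment(res$q_start, res$q_end, res$s_start, res$s_end,
                             raw_score = res$score,
                             percent_identity = 100 * al$identities / al$columns,
                             btop = btop)
  if (!is.null(params)) {
    aln$bit_score <- bit_score(params, aln$raw_score)
    aln$evalue <- evalue(params, aln$raw_score, nchar(query_res))
  }
  aln
}

#' Partition an alignment's raw score across annotated regions
#'
#' Sub-alignment scoring walks the alignment column by column and assigns
#' each column's score contribution (substitution score or gap penalty) to
#' the annotated region containing it; a gap run's opening penalty is
#' charged to the region containing the run's first column. Columns outside
#' every region accumulate in the unannotated remainder, so the partition
#' sums exactly to the alignment raw score. Low score density
#' (score/column) in a region flags non-homologous over-extension.
#'
#' @param alignment a \code{local_alignment}.
#' @param query,subject the aligned [protein_seq()] records (for a PSSM
#'   query pass the PSSM via \code{pssm}).
#' @param regions data frame of domain annotations (columns
#'   \code{domain_id, start, end}), non-overlapping, on the coordinate
#'   system chosen by \code{on}.
#' @param matrix the [substitution_matrix()] that scored the alignment.
#' @param on \code{"subject"} (default) or \code{"query"}: which sequence
#'   the regions annotate.
#' @param pssm optional \code{pssm}; when supplied, per-column substitution
#'   scores come from the PSSM and \code{query} is taken from it.
#' @return A data frame with one row per region plus a \code{"."} remainder
#'   row: \code{region, start, end, score, columns, density}.
#' @export
subalignment_scores <- function(alignment, query, subject, regions,
                                matrix = blosum62(), on = c("subject", "query"),
                                pssm = NULL) {
  on <- match.arg(on)
  if (!is.null(pssm)) query <- pssm$query
  rows <- btop_decode(alignment$btop,
                      substr(query$residues, alignment$q_start, alignment$q_end),
                      substr(subject$residues, alignment$s_start, alignment$s_end))
  qc <- seq_chars(rows$query); sc <- seq_chars(rows$subject)
  ncol <- length(qc)
  qpos <- alignment$q_start - 1L; spos <- alignment$s_start - 1L
  col_score <- numeric(ncol); col_pos <- integer(ncol)
  gap_state <- ""  # "", "D" (subject gap) or "I" (query gap)
  for (k in seq_len(ncol)) {
    if (qc[k] != "-" && sc[k] != "-") {
      qpos <- qpos + 1L; spos <- spos + 1L
      if (!is.null(pssm)) {
        col_score[k] <- if (sc[k] == "X") -1
          else pssm$scores[qpos, sc[k]]
      } else {
        col_score[k] <- matrix$scores[qc[k], sc[k]]
      }
      gap_state <- ""
    } else {
      this_gap <- if (sc[k] == "-") "D" else "I"
      if (qc[k] != "-") qpos <- qpos + 1L
      if (sc[k] != "-") spos <- spos + 1L
      col_score[k] <- -(matrix$gap_extend +
                          if (gap_state == this_gap) 0L else matrix$gap_open)
      gap_state <- this_gap
    }
    # a column with a gap on the tracked side keeps the last seen position
    col_pos[k] <- if (on == "subject") spos else qpos
  }
  stopifnot(sum(col_score) == alignment$raw_score)
  assign_region <- function(p) {
    w <- which(regions$start <= p & regions$end >= p)
    if (length(w)) w[1] else 0L
  }
  reg_of <- vapply(col_pos, assign_region, 0L)
  ids <- c(".", regions$domain_id)
  out <- data.frame(
    region = ids,
    start = c(NA_integer_, regions$start),
    end = c(NA_integer_, regions$end),
    score = vapply(seq_along(ids) - 1L,
                   function(r) sum(col_score[reg_of == r]), 0),
    columns = vapply(seq_along(ids) - 1L,
                     function(r) sum(reg_of == r), 0L),
    stringsAsFactors = FALSE)
  out$density <- ifelse(out$columns > 0, out$score / out$columns, 0)
  out
}
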