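new_pssm <- function(query, scores, scores_unrounded, freqs, n_eff,
                     params = NULL) {
  structure(list(query = query, scores = scores,
                 scores_unrounded = scores_unrounded, freqs = freqs,
                 n_eff = n_eff, params = params),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM:", nrow(x$scores), "positions (query", x$query$id,
      "), mean information", round(mean(relative_entropy(x)), 3), "bits\n")
  invisible(x)
}

#' Henikoff position-based sequence weights
#'
#' For each column, a residue in that column receives weight
#' \eqn{1/(r s)} where \eqn{r} is the number of distinct symbol types in
#' the column and \eqn{s} the number of rows carrying that symbol; per-row
#' weights are the sums over columns, normalized to 1. Gap cells contribute
#' nothing; identical rows receive equal weight.
#'
#' @param rows character vector of equal-length alignment rows (gap
#'   \code{-}), or a \code{query_msa} (query row included, as row 1).
#' @return Numeric weights, one per row, summing to 1.
#' @export
position_weights <- function(rows) {
  if (inherits(rows, "query_msa"))
    rows <- c(rows$query$residues,
              vapply(rows$rows, `[[`, "", "row"))
  if (!length(rows)) stop("empty alignment")
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  w <- numeric(nrow(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    obs <- col != "-"
    if (!any(obs)) next
    tab <- table(col[obs])
    r <- length(tab)
    w[obs] <- w[obs] + 1 / (r * as.numeric(tab[col[obs]]))
  }
  if (sum(w) == 0) w[] <- 1
  w / sum(w)
}

#' Build a PSSM from a (seeded) query-anchored MSA
#'
#' Per column: weighted observed residue frequencies \eqn{f} (Henikoff
#' position-based weights, gap and \code{X} cells excluded), blended with
#' substitution-matrix pseudocount frequencies \eqn{g} as
#' \eqn{Q = (\alpha f + \beta g)/(\alpha + \beta)} with
#' \eqn{\alpha = n_{eff} - 1} (effective count = number of distinct symbol
#' types in the column) and \eqn{\beta} the pseudocount weight;
#' \eqn{g_j = \sum_a f_a q(j|a)} uses BLOSUM62-implied conditional target
#' frequencies. Scores are \eqn{2 \log_2(Q_j / p_j)} (half-bits), rounded
#' to integers; unrounded values are retained. The query is always row 1 of
#' the weighted alignment. An all-gap column falls back to the substitution
#' matrix row of the query residue.
#'
#' @param msa a \code{query_msa}, normally after [fill_gaps()].
#' @param matrix a [substitution_matrix()] providing the pseudocount
#'   conditionals and fallback rows.
#' @param pseudocount_weight \eqn{\beta > 0}; default 10.
#' @return A \code{pssm} object.
#' @export
build_pssm <- function(msa, matrix = blosum62(), pseudocount_weight = 10) {
  stopifnot(inherits(msa, "query_msa"), pseudocount_weight > 0)
  query <- msa$query
  rows <- c(query$residues, vapply(msa$rows, `[[`, "", "row"))
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(mat)
  w <- position_weights(rows)
  qcond <- blosum62_conditionals(matrix)
  p <- AA_BACKGROUND
  scores_u <- matrix(0, L, 20L, dimnames = list(NULL, AA_LETTERS))
  freqs <- matrix(0, L, 20L, dimnames = list(NULL, AA_LETTERS))
  n_eff <- numeric(L)
  qchars <- seq_chars(query$residues)
  scale <- 2  # half-bit units
  for (j in seq_len(L)) {
    col <- mat[, j]
    obs <- col %in% AA_LETTERS
    if (!any(obs)) {
      # no observations: background fallback scored as the query residue row
      scores_u[j, ] <- matrix$scores[qchars[j], AA_LETTERS]
      freqs[j, ] <- p * 2^(scores_u[j, ] / scale)
      freqs[j, ] <- freqs[j, ] / sum(freqs[j, ])
      n_eff[j] <- 0
      next
    }
    f <- vapply(AA_LETTERS, function(a)
      sum(w[obs][col[obs] == a]), 0)
    f <- f / sum(f)
    n_eff[j] <- length(unique(col[obs]))
    alpha <- n_eff[j] - 1
    beta <- pseudocount_weight
    g <- as.numeric(f %*% qcond)
    Q <- (alpha * f + beta * g) / (alpha + beta)
    freqs[j, ] <- Q
    scores_u[j, ] <- scale * log2(Q / p)
  }
  scores_i <- matrix(as.integer(round(scores_u)), L, 20L,
                     dimnames = dimnames(scores_u))
  new_pssm(query = query, scores = scores_i,
           scores_unrounded = scores_u, freqs = freqs, n_eff = n_eff)
}

#' Per-position relative entropy (information content) of a PSSM
#'
#' Kullback-Leibler divergence of the estimated target frequencies from the
#' background composition, in bits per position. Query-seeding raises the
#' mean relative entropy of PSSMs built from gappy alignments, which is the
#' mechanism by which it keeps profiles from drifting.
#'
#' @param pssm a \code{pssm}.
#' @return Numeric vector, one non-negative value per query position.
#' @export
relative_entropy <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  p <- AA_BACKGROUND
  apply(pssm$freqs, 1L, function(q) {
    nz <- q > 0
    sum(q[nz] * log2(q[nz] / p[nz]))
  })
}
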