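#' @useDynLib seedsearch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 20 standard residues in NCBI matrix order, plus 'X' (unknown) as 21st letter.
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET <- c(AA_LETTERS, "X")

# Robinson & Robinson amino-acid background frequencies (the BLAST default
# composition), in AA_LETTERS order.
AA_BACKGROUND <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

# map residue letters to 1-based alphabet indices; NA for anything else
aa_index <- function(chars) {
  match(chars, AA_ALPHABET)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Amino-acid substitution matrix with affine gap penalties
#'
#' Bundles a symmetric residue substitution score matrix with the two affine
#' gap penalties used throughout the package. A gap of length \eqn{k} costs
#' \code{gap_open + k * gap_extend} (the BLAST convention, so the first gap
#' residue pays both penalties).
#'
#' @param scores integer matrix with residue letters as dimnames; must be
#'   symmetric and cover the 20 standard residues plus \code{X}.
#' @param gap_open positive integer gap-opening penalty.
#' @param gap_extend positive integer gap-extension penalty;
#'   \code{gap_open >= gap_extend >= 1}.
#' @return An object of class \code{substitution_matrix}.
#' @seealso [blosum62()], [read_score_matrix()]
#' @export
substitution_matrix <- function(scores, gap_open = 11L, gap_extend = 1L) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)))
  if (!all(AA_ALPHABET %in% rownames(scores)))
    stop("substitution matrix must cover the 20 standard residues plus 'X'")
  scores <- scores[AA_ALPHABET, AA_ALPHABET, drop = FALSE]
  if (!isTRUE(all.equal(scores, t(scores))))
    stop("substitution scores must be symmetric")
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (!(gap_open >= gap_extend && gap_extend >= 1L))
    stop("require gap_open >= gap_extend >= 1")
  structure(list(alphabet = AA_ALPHABET,
                 scores = matrix(as.integer(scores), nrow(scores),
                                 dimnames = dimnames(scores)),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "substitution_matrix")
}

#' BLOSUM62 scoring with BLAST protein gap defaults
#'
#' The package default: BLOSUM62 substitution scores (half-bit units) with
#' gap open 11 and gap extend 1.
#'
#' @param gap_open,gap_extend affine gap penalties (defaults 11/1).
#' @return A \code{substitution_matrix}.
#' @export
blosum62 <- function(gap_open = 11L, gap_extend = 1L) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  substitution_matrix(env$BLOSUM62, gap_open, gap_extend)
}

#' Read a score matrix in NCBI matrix text format
#'
#' Parses the plain-text matrix layout used by BLAST (\code{#} comment lines,
#' a header row of residue letters, one labelled row per residue).
#'
#' @param path path to the matrix file.
#' @param gap_open,gap_extend affine gap penalties to attach.
#' @return A \code{substitution_matrix}.
#' @export
read_score_matrix <- function(path, gap_open = 11L, gap_extend = 1L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labs <- vapply(rows, `[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(header))))
  dimnames(vals) <- list(labs, header)
  substitution_matrix(vals, gap_open, gap_extend)
}

# BLOSUM62-implied conditional substitution frequencies q(b | a) over the 20
# standard residues, derived from the half-bit scores via
# q(b|a) propto p_b * 2^(s_ab / 2). Used as pseudocount frequencies.
blosum62_conditionals <- function(matrix = blosum62()) {
  s <- matrix$scores[AA_LETTERS, AA_LETTERS]
  q <- sweep(2^(s / 2), 2L, AA_BACKGROUND, `*`)
  q / rowSums(q)
}
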