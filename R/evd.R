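#' Extreme-value (Karlin-Altschul) statistics for local alignment scores
#'
#' Local alignment scores against an unrelated database follow an extreme
#' value (Gumbel) law; the expected number of alignments scoring at least
#' \eqn{S} against a database of \eqn{n} residues with a query of \eqn{m}
#' residues is \eqn{E = K m n e^{-\lambda S}}. \code{evd_params()} bundles
#' \eqn{\lambda} (nats per score unit), \eqn{K}, and the database size.
#'
#' @param lambda scale parameter, nats per raw score unit; \code{> 0}.
#' @param K Karlin-Altschul prefactor; \code{> 0}.
#' @param db_residues total residues in the searched database.
#' @param db_sequences number of database sequences.
#' @return An object of class \code{evd_params}.
#' @export
evd_params <- function(lambda, K, db_residues, db_sequences) {
  stopifnot(lambda > 0, K > 0, db_residues >= 1, db_sequences >= 1)
  structure(list(lambda = lambda, K = K,
                 db_residues = as.numeric(db_residues),
                 db_sequences = as.numeric(db_sequences)),
            class = "evd_params")
}

# Published gapped Karlin-Altschul constants for BLOSUM62 with gap open 11 /
# extend 1 (BLAST protein defaults); used for the first, sequence-sequence,
# iteration before empirical calibration is possible.
KA_BLOSUM62_11_1 <- list(lambda = 0.267, K = 0.041)

#' @rdname evd_params
#' @param db list of [protein_seq()] records (the searched database).
#' @export
ka_params_blosum62 <- function(db) {
  evd_params(KA_BLOSUM62_11_1$lambda, KA_BLOSUM62_11_1$K,
             sum(vapply(db, length, 0L)), length(db))
}

#' @rdname evd_params
#' @param params an \code{evd_params} object.
#' @param raw_score raw alignment score(s) in matrix units.
#' @param query_len query length in residues.
#' @export
evalue <- function(params, raw_score, query_len) {
  params$K * query_len * params$db_residues *
    exp(-params$lambda * raw_score)
}

#' @rdname evd_params
#' @export
bit_score <- function(params, raw_score) {
  (params$lambda * raw_score - log(params$K)) / log(2)
}

#' Fit extreme-value parameters to an empirical score distribution
#'
#' Maximum-likelihood Gumbel fit to the best-hit raw scores of a database
#' search, with iterative censoring of the high tail: after each fit, scores
#' whose fitted E-value is below 1 (true homologs and near-homologs, not the
#' null) are removed and the remainder refit, for at most five rounds.
#' \eqn{\lambda} is the reciprocal Gumbel scale; \eqn{K} is recovered from
#' the location via \eqn{e^{\mu/\beta} = K m \bar n} with \eqn{\bar n} the
#' mean subject length.
#'
#' @param scores numeric vector of per-sequence best raw scores (>= 50).
#' @param query_len query length in residues.
#' @param db_residues,db_sequences database size.
#' @param max_rounds censoring rounds (default 5).
#' @return An [evd_params()] object.
#' @export
fit_evd <- function(scores, query_len, db_residues, db_sequences,
                    max_rounds = 5L) {
  if (length(scores) < 50L)
    stop("need at least 50 scores to fit extreme-value parameters")
  if (stats::sd(scores) == 0)
    stop("degenerate (constant) score distribution; cannot fit")
  nbar <- db_residues / db_sequences
  # robust pre-trim for the initial fit only: a heavy homolog tail would
  # otherwise inflate the scale so far that censoring never engages
  init <- scores[scores <= stats::median(scores) +
                   5 * max(stats::mad(scores), 1)]
  if (length(init) < 50L || stats::sd(init) == 0) init <- scores
  fit <- gumbel_ml(init)
  for (r in seq_len(max_rounds)) {
    lambda <- 1 / fit$beta
    K <- exp(fit$mu / fit$beta) / (query_len * nbar)
    e_per_db <- K * query_len * db_residues * exp(-lambda * scores)
    keep <- scores[e_per_db >= 1]
    if (length(keep) < 50L || stats::sd(keep) == 0) break
    newfit <- gumbel_ml(keep)
    if (abs(newfit$beta - fit$beta) < 1e-6 * fit$beta) { fit <- newfit; break }
    fit <- newfit
  }
  lambda <- 1 / fit$beta
  K <- exp(fit$mu / fit$beta) / (query_len * nbar)
  evd_params(lambda, K, db_residues, db_sequences)
}

# ML fit of a Gumbel(mu, beta) by profile likelihood in beta: the ML beta
# solves beta = mean(x) - sum(x e^(-x/beta)) / sum(e^(-x/beta)); mu follows
# in closed form. Moment estimate brackets the root.
gumbel_ml <- function(x) {
  xbar <- mean(x)
  beta0 <- sqrt(6) * stats::sd(x) / pi
  g <- function(beta) {
    w <- exp(-(x - xbar) / beta)  # shift for numerical stability
    beta - xbar + sum(x * w) / sum(w)
  }
  lo <- beta0 / 10; hi <- beta0 * 10
  for (k in 1:20) { if (g(lo) < 0) break; lo <- lo / 2 }
  for (k in 1:20) { if (g(hi) > 0) break; hi <- hi * 2 }
  beta <- tryCatch(stats::uniroot(g, c(lo, hi), tol = 1e-8)$root,
                   error = function(e) beta0)
  mu <- -beta * log(mean(exp(-(x - xbar) / beta))) + xbar
  list(mu = mu, beta = beta)
}
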