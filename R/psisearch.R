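hits_to_df <- function(query, hits) {
  if (!length(hits)) return(empty_hits())
  rows <- lapply(hits, function(h) {
    a <- h$aln
    dec <- btop_decode(a$btop,
                       substr(query$residues, a$q_start, a$q_end),
                       substr(h$subject$residues, a$s_start, a$s_end))
    qc <- seq_chars(dec$query); sc <- seq_chars(dec$subject)
    gap <- qc == "-" | sc == "-"
    gap_opens <- sum(diff(c(FALSE, gap)) == 1L)
    data.frame(query_id = query$id, subject_id = h$subject$id,
               percent_identity = a$percent_identity,
               alignment_length = length(qc),
               mismatches = sum(!gap & qc != sc),
               gap_opens = gap_opens,
               q_start = a$q_start, q_end = a$q_end,
               s_start = a$s_start, s_end = a$s_end,
               evalue = a$evalue, bit_score = a$bit_score,
               btop = a$btop, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Query-seeded iterative profile search
#'
#' Runs the iterative search cycle: a Smith-Waterman sequence search seeds
#' iteration 1; each later iteration selects the hits below the inclusion
#' E-value, applies the alignment-boundary policy, builds the query-anchored
#' MSA, fills its gaps according to the seeding policy, constructs a PSSM,
#' re-searches the database with the profile, and recalibrates E-values on
#' that search's empirical score distribution. The loop stops early when it
#' reaches a fixed point: the included-subject set and every included
#' alignment's boundaries are unchanged between consecutive iterations.
#'
#' @param query the query [protein_seq()], or a path to a FASTA file whose
#'   first record is the query.
#' @param database list of [protein_seq()] records, or a FASTA path.
#' @param n_iterations maximum number of iterations (default 10).
#' @param inclusion_evalue E-value below which a hit enters the next
#'   iteration's MSA/PSSM (default 0.002).
#' @param report_evalue E-value threshold for reported output (default
#'   0.001).
#' @param gapfill a [gapfill_policy()]; the default seeds query residues
#'   into internal and end gaps.
#' @param boundary alignment-boundary policy: \code{"current"} (default),
#'   \code{"history"}, or \code{"domain"}.
#' @param domains query-domain annotations (data frame with
#'   \code{domain_id, start, end}) for the domain policy.
#' @param matrix a [substitution_matrix()]; default [blosum62()].
#' @param pseudocount_weight PSSM pseudocount weight (default 10).
#' @return An object of class \code{psisearch}: a list with the query, the
#'   configuration, one record per executed iteration (\code{hits} data
#'   frame, \code{included} subject ids, the \code{pssm} that produced the
#'   iteration's hits, \code{params}, \code{converged}), the final
#'   \code{pssm} built from the last included set, and the boundary
#'   registry.
#' @seealso [predict.psisearch()], [make_embedded_query()],
#'   [contamination_benchmark()]
#' @examples
#' db <- generate_database(family_spec(
#'   domains = c(A = 80), families = list(A = list(size = 8, identity = 65)),
#'   n_decoys = 20, rng_seed = 7))
#' q <- db$db[[1]]
#' fit <- psisearch(q, db$db, n_iterations = 3)
#' fit
#' @export
psisearch <- function(query, database, n_iterations = 10L,
                      inclusion_evalue = 0.002, report_evalue = 0.001,
                      gapfill = gapfill_policy(),
                      boundary = c("current", "history", "domain"),
                      domains = NULL, matrix = blosum62(),
                      pseudocount_weight = 10) {
  if (is.character(query)) query <- read_fasta(query)[[1]]
  if (is.character(database)) database <- read_fasta(database)
  stopifnot(inherits(query, "protein_seq"), length(database) >= 1,
            inclusion_evalue > 0, report_evalue > 0, n_iterations >= 1)
  boundary <- match.arg(boundary)
  if (boundary == "domain" && is.null(domains))
    stop("boundary = 'domain' requires query-domain annotations")
  config <- list(n_iterations = as.integer(n_iterations),
                 inclusion_evalue = inclusion_evalue,
                 report_evalue = report_evalue,
                 gapfill = gapfill, boundary = boundary,
                 gap_open = matrix$gap_open, gap_extend = matrix$gap_extend,
                 pseudocount_weight = pseudocount_weight)
  keep_thr <- max(inclusion_evalue, report_evalue)
  db_ids <- vapply(database, `[[`, "", "id")
  names(database) <- db_ids
  db_idx <- lapply(database, function(s)
    aa_index(seq_chars(s$residues)) - 1L)
  db_res <- sum(vapply(database, length, 0L))
  registry <- boundary_registry()

  # iteration 1: plain sequence search with published gapped constants
  params <- ka_params_blosum62(database)
  prof <- profile_from_query(query, matrix)
  iterations <- list()
  prev_included <- NULL
  prev_alns <- NULL
  pssm_used <- NULL
  for (iter in seq_len(n_iterations)) {
    if (iter > 1L) {
      hits_in <- prev_alns[prev_included]
      hits_in <- lapply(hits_in, function(h) {
        apply_boundary_policy(h, boundary, query, registry = registry,
                              domains = domains, matrix = matrix,
                              pssm = pssm_used)
      })
      hits_in <- hits_in[!vapply(hits_in, is.null, TRUE)]
      if (!length(hits_in)) break
      msa <- build_query_msa(query, hits_in, iteration = iter)
      filled <- fill_gaps(msa, gapfill)
      pssm_used <- build_pssm(filled$msa, matrix, pseudocount_weight)
      prof <- cbind(pssm_used$scores, X = -1L)
    }
    raw <- .sw_score_db(prof, db_idx, matrix$gap_open, matrix$gap_extend)
    if (iter > 1L) {
      params <- tryCatch(
        fit_evd(raw, length(query), db_res, length(database)),
        error = function(e) params)  # degenerate fit: keep previous
      pssm_used$params <- params
    }
    # raw-score cutoff implied by the loosest threshold we keep
    cutoff <- (log(params$K * length(query) * params$db_residues) -
                 log(keep_thr)) / params$lambda
    cand <- which(raw >= cutoff & raw > 0)
    alns <- list()
    for (k in cand) {
      a <- if (iter == 1L)
        smith_waterman(query, database[[k]], matrix, params)
      else
        pssm_search(pssm_used, database[[k]], matrix$gap_open,
                    matrix$gap_extend, params)
      if (!is.null(a) && a$evalue <= keep_thr)
        alns[[db_ids[k]]] <- list(subject = database[[k]], aln = a)
    }
    evs <- vapply(alns, function(h) h$aln$evalue, 0)
    included <- names(alns)[evs <= inclusion_evalue]
    for (id in included) registry_record(registry, id, alns[[id]]$aln)
    # convergence = fixed point of the iteration map: same included
    # subjects AND same alignment boundaries as the previous iteration
    # (membership alone can be stable while alignments still creep)
    spans <- vapply(alns[included], function(h)
      paste(h$aln$q_start, h$aln$q_end, h$aln$s_start, h$aln$s_end), "")
    converged <- (iter > 1L && setequal(included, prev_included) &&
                    identical(spans[sort(included)],
                              prev_spans[sort(included)])) ||
      (iter == 1L && length(included) == 0L)
    iterations[[iter]] <- list(
      iteration = iter, hits = hits_to_df(query, alns),
      included = included, pssm = if (iter > 1L) pssm_used else NULL,
      msa = if (iter > 1L) filled$msa else NULL,
      params = params, converged = converged)
    prev_included <- included
    prev_alns <- alns
    prev_spans <- spans
    if (converged) break
  }
  # final model: PSSM built from the last iteration's included hits
  final_pssm <- NULL
  if (length(prev_included)) {
    hits_in <- prev_alns[prev_included]
    hits_in <- lapply(hits_in, function(h)
      apply_boundary_policy(h, boundary, query, registry = registry,
                            domains = domains, matrix = matrix,
                            pssm = pssm_used))
    hits_in <- hits_in[!vapply(hits_in, is.null, TRUE)]
    if (length(hits_in)) {
      msa <- build_query_msa(query, hits_in,
                             iteration = length(iterations) + 1L)
      final_pssm <- build_pssm(fill_gaps(msa, gapfill)$msa, matrix,
                               pseudocount_weight)
      final_pssm$params <- params
    }
  }
  structure(list(query = query, config = config,
                 db_sequences = length(database), db_residues = db_res,
                 iterations = iterations, registry = registry,
                 pssm = final_pssm,
                 converged = length(iterations) > 0 &&
                   iterations[[length(iterations)]]$converged,
                 matrix = matrix),
            class = "psisearch")
}

#' @export
print.psisearch <- function(x, ...) {
  cat("Query-seeded iterative profile search\n")
  cat("  query:", x$query$id, sprintf("(%d residues)", length(x$query)),
      "\n")
  cat("  database:", x$db_sequences, "sequences,", x$db_residues,
      "residues\n")
  cat("  gap fill:", x$config$gapfill$mode, "/", x$config$gapfill$scope,
      "; boundary:", x$config$boundary, "\n")
  cat("  iterations run:", length(x$iterations),
      if (x$converged) "(converged)" else "(iteration limit)", "\n")
  for (it in x$iterations)
    cat(sprintf("    iter %d: %d hits <= E %.3g, %d included\n",
                it$iteration, nrow(it$hits),
                max(x$config$inclusion_evalue, x$config$report_evalue),
                length(it$included)))
  invisible(x)
}

#' @export
summary.psisearch <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$iterations, function(it) {
    data.frame(iteration = it$iteration, hits = nrow(it$hits),
               included = length(it$included),
               new = NA_integer_, converged = it$converged)
  }))
  prev <- character()
  for (i in seq_len(nrow(tab))) {
    inc <- object$iterations[[i]]$included
    tab$new[i] <- length(setdiff(inc, prev))
    prev <- inc
  }
  structure(list(query = object$query$id, table = tab,
                 converged = object$converged,
                 mean_information = if (!is.null(object$pssm))
                   mean(relative_entropy(object$pssm)) else NA_real_),
            class = "summary.psisearch")
}

#' @export
print.summary.psisearch <- function(x, ...) {
  cat("psisearch run for query", x$query,
      if (x$converged) "(converged)\n" else "\n")
  print(x$table, row.names = FALSE)
  if (!is.na(x$mean_information))
    cat("final PSSM mean information:", round(x$mean_information, 3),
        "bits/position\n")
  invisible(x)
}

#' @export
coef.psisearch <- function(object, ...) {
  if (is.null(object$pssm)) return(NULL)
  object$pssm$scores
}

#' Score new sequences against the final profile
#'
#' @param object a \code{psisearch} fit.
#' @param newdata list of [protein_seq()] records or a FASTA path.
#' @param evalue_max report threshold (defaults to the fit's report
#'   E-value).
#' @param ... unused.
#' @return A tabular hit data frame (see [read_tabular_hits()] for
#'   columns).
#' @export
predict.psisearch <- function(object, newdata,
                              evalue_max = object$config$report_evalue,
                              ...) {
  if (is.null(object$pssm))
    stop("fit has no final PSSM (no included hits)")
  if (is.character(newdata)) newdata <- read_fasta(newdata)
  if (inherits(newdata, "protein_seq")) newdata <- list(newdata)
  hits <- list()
  for (s in newdata) {
    a <- pssm_search(object$pssm, s, object$matrix$gap_open,
                     object$matrix$gap_extend, object$pssm$params)
    if (!is.null(a) && !is.na(a$evalue) && a$evalue <= evalue_max)
      hits[[s$id]] <- list(subject = s, aln = a)
  }
  hits_to_df(object$query, hits)
}

#' @export
plot.psisearch <- function(x, ...) {
  n <- vapply(x$iterations, function(it) length(it$included), 0L)
  graphics::plot(seq_along(n), n, type = "b", xlab = "iteration",
                 ylab = "included subjects",
                 main = paste("psisearch:", x$query$id), ...)
  invisible(x)
}

#' Write per-iteration outputs of a search run
#'
#' Writes \code{hits.iterN.tsv} (commented tabular with BTOP),
#' \code{msa.iterN.afa} and \code{pssm.iterN.tsv} for each PSSM iteration,
#' and a \code{manifest.json} with the configuration and convergence state.
#'
#' @param fit a \code{psisearch} object.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (it in fit$iterations) {
    write_tabular_hits(it$hits,
                       file.path(dir, sprintf("hits.iter%d.tsv", it$iteration)),
                       comment = sprintf("iteration %d", it$iteration))
    if (!is.null(it$pssm))
      write_pssm(it$pssm,
                 file.path(dir, sprintf("pssm.iter%d.tsv", it$iteration)))
    if (!is.null(it$msa))
      write_msa(it$msa,
                file.path(dir, sprintf("msa.iter%d.afa", it$iteration)))
  }
  cfg <- fit$config
  cfg$gapfill <- cfg$gapfill[c("mode", "scope", "rng_seed")]
  jsonlite::write_json(
    list(query = fit$query$id, config = cfg,
         iterations = length(fit$iterations), converged = fit$converged,
         included_final = if (length(fit$iterations))
           fit$iterations[[length(fit$iterations)]]$included else
           character()),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
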