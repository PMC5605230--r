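#' Build an embedded-domain benchmark query
#'
#' Embeds a domain sequence in random flanking sequence: a domain of length
#' \eqn{L} receives \code{floor(L/2)} random residues on each side, so a
#' 200-residue domain yields a 400-residue query with the domain at
#' positions 101..300. Because the flanks are random, any alignment outside
#' the domain interval is non-homologous by construction.
#'
#' @param domain a [protein_seq()] carrying the genuine domain sequence.
#' @param domain_id,clan_id family identifiers for evaluation.
#' @param rng_seed integer seed for the flank draw.
#' @param background residue composition for the flanks (default uniform
#'   over the 20 standard residues).
#' @return An object of class \code{embedded_query}: the query
#'   \code{sequence} plus \code{domain_id, clan_id, domain_start,
#'   domain_end, flank_len_left, flank_len_right}.
#' @export
make_embedded_query <- function(domain, domain_id, clan_id = "",
                                rng_seed = 1L,
                                background = rep(1 / 20, 20)) {
  stopifnot(inherits(domain, "protein_seq"))
  L <- length(domain)
  flank <- L %/% 2L
  restore <- local_rng(rng_seed)
  on.exit(restore())
  draw <- function(n) paste(sample(AA_LETTERS, n, replace = TRUE,
                                   prob = background), collapse = "")
  left <- draw(flank); right <- draw(flank)
  seq <- protein_seq(paste0(domain$id, "_embedded"),
                     paste0(left, domain$residues, right))
  structure(list(sequence = seq, domain_id = domain_id, clan_id = clan_id,
                 domain_start = flank + 1L, domain_end = flank + L,
                 flank_len_left = flank, flank_len_right = flank),
            class = "embedded_query")
}

#' @export
print.embedded_query <- function(x, ...) {
  cat(sprintf(
    "embedded query %s: domain %s at %d..%d, flanks %d/%d, length %d\n",
    x$sequence$id, x$domain_id, x$domain_start, x$domain_end,
    x$flank_len_left, x$flank_len_right, length(x$sequence)))
  invisible(x)
}

# subject span aligned to the part of the hit overlapping [a, b] on the
# query, via the BTOP walk; NULL when the overlap covers no aligned pair.
subject_span_for_query_interval <- function(hit, a, b) {
  toks <- btop_tokens(hit$btop)
  qpos <- hit$q_start - 1L; spos <- hit$s_start - 1L
  lo <- NA_integer_; hi <- NA_integer_
  note <- function(s) {
    if (is.na(lo)) lo <<- s
    hi <<- s
  }
  step <- function(dq, ds) {
    if (dq) qpos <<- qpos + 1L
    if (ds) spos <<- spos + 1L
    if (dq && ds && qpos >= a && qpos <= b) note(spos)
  }
  for (t in toks) {
    if (is.numeric(t)) {
      for (i in seq_len(t)) step(TRUE, TRUE)
    } else {
      step(t[1] != "-", t[2] != "-")
    }
  }
  if (is.na(lo)) NULL else c(lo, hi)
}

#' Classify one reported hit as true positive, false positive, or ignored
#'
#' Embedded mode: the hit is a true positive only if its query span
#' overlaps the embedded domain interval and the subject residues aligned
#' to that overlap (via the BTOP walk) overlap an annotated subject domain
#' of the same family or the same non-empty clan by at least
#' \code{min_overlap} residues; otherwise it is a false positive —
#' including same-family alignments that lie outside the embedded domain
#' coordinates. Full-length mode (\code{scored_interval} given without an
#' \code{embedded_query}): hits whose query span does not overlap the
#' scored domain interval are ignored rather than counted.
#'
#' @param hit one row of a tabular hit data frame (as a list or
#'   single-row data frame).
#' @param query an \code{embedded_query}, or a list with
#'   \code{domain_id, clan_id, domain_start, domain_end} and
#'   \code{full_length = TRUE} for full-length scoring.
#' @param annotations domain-annotation data frame
#'   (\code{seq_id, domain_id, clan_id, start, end}); subjects absent from
#'   it are treated as unannotated.
#' @param clan_map optional named vector \code{domain_id -> clan_id} used
#'   to complete clan ids.
#' @param min_overlap minimum residue overlap on both sides (default 1).
#' @return \code{"TP"}, \code{"FP"}, or \code{"ignored"}.
#' @export
classify_hit <- function(hit, query, annotations, clan_map = NULL,
                         min_overlap = 1L) {
  if (is.data.frame(hit)) hit <- as.list(hit[1L, ])
  full_length <- isTRUE(query$full_length)
  a <- query$domain_start; b <- query$domain_end
  q_ov <- min(hit$q_end, b) - max(hit$q_start, a) + 1L
  if (q_ov < min_overlap)
    return(if (full_length) "ignored" else "FP")
  span <- subject_span_for_query_interval(hit, a, b)
  if (is.null(span)) return(if (full_length) "ignored" else "FP")
  ann <- annotations[annotations$seq_id == hit$subject_id, , drop = FALSE]
  if (!nrow(ann)) return("FP")
  qclan <- query$clan_id
  if (!nzchar(qclan) && !is.null(clan_map) &&
      !is.na(clan_map[query$domain_id]))
    qclan <- clan_map[query$domain_id]
  same <- ann$domain_id == query$domain_id |
    (nzchar(qclan) & nzchar(ann$clan_id) & ann$clan_id == qclan)
  ann <- ann[same, , drop = FALSE]
  if (!nrow(ann)) return("FP")
  ov <- pmin(ann$end, span[2]) - pmax(ann$start, span[1]) + 1L
  if (any(ov >= min_overlap)) "TP" else "FP"
}

#' Evaluate an iterative search run against known annotations
#'
#' Applies [classify_hit()] to every reported hit (E-value at or below
#' \code{report_evalue}), per query and iteration, and aggregates into
#' per-query sensitivity \eqn{TP/(TP+FN)} and FDR \eqn{FP/(TP+FP)} (defined
#' as 0 when \eqn{TP+FP=0}), then averages across queries with equal
#' per-query weight (weighted sensitivity and FDR).
#'
#' @param runs named list (one element per query id) of per-iteration hit
#'   data frames: \code{runs[[query_id]][[iteration]]}.
#' @param queries named list of \code{embedded_query} (or full-length
#'   descriptor) objects, same names as \code{runs}.
#' @param annotations domain-annotation data frame for the database.
#' @param family_sizes named vector: number of database sequences carrying
#'   each query's family (the TP+FN denominator), named by query id.
#' @param report_evalue scoring threshold (default 0.001).
#' @param clan_map optional \code{domain_id -> clan_id} map.
#' @param min_overlap minimum overlap for [classify_hit()].
#' @return An object of class \code{evaluation_result}: data frame
#'   \code{per_query} (query, iteration, TP, FP, ignored, FN, sensitivity,
#'   FDR) and data frame \code{summary} (iteration, weighted sensitivity,
#'   weighted FDR).
#' @export
evaluate_run <- function(runs, queries, annotations, family_sizes,
                         report_evalue = 0.001, clan_map = NULL,
                         min_overlap = 1L) {
  stopifnot(length(runs) == length(queries))
  per <- list()
  for (qid in names(runs)) {
    fam_n <- family_sizes[[qid]]
    if (is.null(fam_n) || fam_n == 0) {
      warning("query ", qid, " has family size 0; excluded")
      next
    }
    q <- queries[[qid]]
    for (it in seq_along(runs[[qid]])) {
      hits <- runs[[qid]][[it]]
      hits <- hits[hits$evalue <= report_evalue, , drop = FALSE]
      cls <- if (nrow(hits))
        vapply(seq_len(nrow(hits)), function(i)
          classify_hit(hits[i, ], q, annotations, clan_map, min_overlap),
          "") else character()
      # one classification per subject: best (lowest-E) hit was kept upstream
      tp <- sum(cls == "TP"); fp <- sum(cls == "FP")
      ign <- sum(cls == "ignored")
      per[[length(per) + 1L]] <- data.frame(
        query = qid, iteration = it, TP = tp, FP = fp, ignored = ign,
        FN = max(0L, fam_n - tp),
        sensitivity = tp / fam_n,
        FDR = if (tp + fp == 0) 0 else fp / (tp + fp),
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per)
  if (is.null(per) || !nrow(per)) {
    agg <- data.frame(iteration = integer(),
                      weighted_sensitivity = numeric(),
                      weighted_FDR = numeric())
    return(structure(list(per_query = per, summary = agg),
                     class = "evaluation_result"))
  }
  agg <- stats::aggregate(cbind(sensitivity, FDR) ~ iteration, per, mean)
  names(agg) <- c("iteration", "weighted_sensitivity", "weighted_FDR")
  structure(list(per_query = per, summary = agg),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("search evaluation (", length(unique(x$per_query$query)),
      " queries)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Over-extension and identity-quartile statistics
#'
#' \code{overextension_stats()}: for each hit, the over-extension is the
#' number of query positions in the hit span outside the embedded domain
#' interval; the median across hits is returned.
#' \code{identity_q1()}: first quartile (linear interpolation between order
#' statistics) of percent identity across hits. Callers filter hits to the
#' scoring threshold (E < 0.001) first; with no qualifying hits both
#' statistics are \code{NA}.
#'
#' @param hits tabular hit data frame.
#' @param query an \code{embedded_query}.
#' @return A single number (\code{NA} if no hits).
#' @export
overextension_stats <- function(hits, query) {
  if (!nrow(hits)) return(NA_real_)
  left <- pmax(0L, query$domain_start - hits$q_start)
  right <- pmax(0L, hits$q_end - query$domain_end)
  stats::median(left + right)
}

#' @rdname overextension_stats
#' @export
identity_q1 <- function(hits) {
  if (!nrow(hits)) return(NA_real_)
  unname(stats::quantile(hits$percent_identity, 0.25, type = 7))
}
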