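#' Gap-fill (seeding) policy for query-anchored MSAs
#'
#' Controls how gap characters in subject rows of a query-anchored MSA are
#' treated before PSSM construction. \code{query_seed} replaces each in-scope
#' gap with the query residue of that column (the package's default and the
#' configuration that suppresses homologous over-extension); \code{x_fill}
#' inserts \code{X}; \code{random_fill} draws residues from a background
#' composition; \code{none} leaves rows untouched. \code{scope} selects
#' whether only internal gaps (within a row's aligned span) or internal and
#' end gaps are filled.
#'
#' @param mode one of \code{"none"}, \code{"query_seed"}, \code{"x_fill"},
#'   \code{"random_fill"}.
#' @param scope \code{"internal_and_end_gaps"} (default) or
#'   \code{"internal_gaps_only"}.
#' @param rng_seed integer seed, used by \code{random_fill} only.
#' @param background residue sampling weights for \code{random_fill};
#'   defaults to the package background composition.
#' @return An object of class \code{gapfill_policy}.
#' @export
gapfill_policy <- function(mode = c("query_seed", "none", "x_fill",
                                    "random_fill"),
                           scope = c("internal_and_end_gaps",
                                     "internal_gaps_only"),
                           rng_seed = 1L, background = AA_BACKGROUND) {
  structure(list(mode = match.arg(mode), scope = match.arg(scope),
                 rng_seed = as.integer(rng_seed), background = background),
            class = "gapfill_policy")
}

#' Build a query-anchored MSA from pairwise hits
#'
#' Produces the multiple sequence alignment whose columns are exactly the
#' query residues: each subject row is the subject's aligned residues placed
#' at their query columns, subject residues aligned to query-gap columns
#' (query-side insertions) are deleted from the row (their count is kept in
#' row metadata), and positions outside the aligned span are end gaps
#' (\code{-}).
#'
#' @param query the query [protein_seq()].
#' @param hits list of hits, each a list with elements \code{subject} (a
#'   \code{protein_seq}) and \code{aln} (a \code{local_alignment}); at most
#'   one hit per subject id.
#' @param iteration iteration index recorded in row metadata.
#' @return An object of class \code{query_msa} with elements \code{query}
#'   and \code{rows} (each row: \code{subject_id, row, q_start, q_end,
#'   s_start, s_end, n_insertions, iteration}).
#' @export
build_query_msa <- function(query, hits, iteration = 1L) {
  ids <- vapply(hits, function(h) h$subject$id, "")
  if (anyDuplicated(ids))
    stop("multiple hits for subject id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         "; select one alignment per subject first")
  qlen <- length(query)
  rows <- lapply(hits, function(h) {
    a <- h$aln
    dec <- btop_decode(a$btop,
                       substr(query$residues, a$q_start, a$q_end),
                       substr(h$subject$residues, a$s_start, a$s_end))
    qc <- seq_chars(dec$query); sc <- seq_chars(dec$subject)
    keep <- qc != "-"              # drop query-side insertions
    mid <- sc[keep]                # one symbol per query position in span
    row <- paste0(strrep("-", a$q_start - 1L),
                  paste(mid, collapse = ""),
                  strrep("-", qlen - a$q_end))
    list(subject_id = h$subject$id, row = row,
         q_start = a$q_start, q_end = a$q_end,
         s_start = a$s_start, s_end = a$s_end,
         n_insertions = sum(!keep), iteration = as.integer(iteration))
  })
  structure(list(query = query, rows = rows), class = "query_msa")
}

#' @export
print.query_msa <- function(x, ...) {
  cat("query-anchored MSA:", length(x$rows), "subject rows x",
      length(x$query), "columns (query", x$query$id, ")\n")
  invisible(x)
}

#' Boundary registry for the alignment-history policy
#'
#' Records, per subject, the alignment coordinates found the first time that
#' subject appeared with a statistically significant score. Entries are
#' write-once: under the history policy, later alignments are trimmed so
#' they never extend beyond the recorded span.
#'
#' @return \code{boundary_registry()}: an empty registry.
#' @export
boundary_registry <- function() {
  structure(list(env = new.env(parent = emptyenv())),
            class = "boundary_registry")
}

#' @rdname boundary_registry
#' @param registry a \code{boundary_registry}.
#' @param subject_id subject identifier.
#' @param aln the subject's first significant \code{local_alignment}.
#' @export
registry_record <- function(registry, subject_id, aln) {
  if (is.null(registry$env[[subject_id]]))
    registry$env[[subject_id]] <- c(q_start = aln$q_start, q_end = aln$q_end,
                                    s_start = aln$s_start, s_end = aln$s_end)
  invisible(registry)
}

#' @rdname boundary_registry
#' @export
registry_get <- function(registry, subject_id) {
  registry$env[[subject_id]]
}

# Trim a local alignment to a query interval [a, b] via the BTOP walk:
# subject coordinates and score are recomputed from the retained columns,
# and boundary gap columns are shed.
trim_alignment_to_query <- function(aln, query, subject, a, b,
                                    matrix = blosum62(), pssm = NULL) {
  a <- max(a, aln$q_start); b <- min(b, aln$q_end)
  if (a > b) return(NULL)
  dec <- btop_decode(aln$btop,
                     substr(query$residues, aln$q_start, aln$q_end),
                     substr(subject$residues, aln$s_start, aln$s_end))
  qc <- seq_chars(dec$query); sc <- seq_chars(dec$subject)
  qpos <- aln$q_start - 1L; spos <- aln$s_start - 1L
  col_q <- integer(length(qc)); col_s <- integer(length(qc))
  for (k in seq_along(qc)) {
    if (qc[k] != "-") qpos <- qpos + 1L
    if (sc[k] != "-") spos <- spos + 1L
    col_q[k] <- qpos; col_s[k] <- spos
  }
  keep <- which(qc != "-" & col_q >= a & col_q <= b |
                qc == "-" & col_q >= a & col_q < b)
  if (!length(keep)) return(NULL)
  # shed gap columns at the trimmed boundaries
  while (length(keep) && (qc[keep[1]] == "-" || sc[keep[1]] == "-"))
    keep <- keep[-1]
  while (length(keep) &&
         (qc[keep[length(keep)]] == "-" || sc[keep[length(keep)]] == "-"))
    keep <- keep[-length(keep)]
  if (!length(keep)) return(NULL)
  qk <- qc[keep]; sk <- sc[keep]
  q_start <- col_q[keep[1]]; q_end <- col_q[keep[length(keep)]]
  s_start <- col_s[keep[1]]; s_end <- col_s[keep[length(keep)]]
  score <- rescore_columns(qk, sk, q_start, matrix, pssm)
  new_local_alignment(q_start, q_end, s_start, s_end, raw_score = score,
                      bit_score = aln$bit_score, evalue = aln$evalue,
                      percent_identity =
                        100 * sum(qk == sk & qk != "-") / length(qk),
                      btop = btop_encode(paste(qk, collapse = ""),
                                         paste(sk, collapse = "")))
}

rescore_columns <- function(qk, sk, q_start, matrix, pssm = NULL) {
  score <- 0; gap_state <- ""; qpos <- q_start - 1L
  for (k in seq_along(qk)) {
    if (qk[k] != "-" && sk[k] != "-") {
      qpos <- qpos + 1L
      score <- score + if (!is.null(pssm)) {
        if (sk[k] == "X") -1 else pssm$scores[qpos, sk[k]]
      } else matrix$scores[qk[k], sk[k]]
      gap_state <- ""
    } else {
      this_gap <- if (sk[k] == "-") "D" else "I"
      if (qk[k] != "-") qpos <- qpos + 1L
      score <- score - matrix$gap_extend -
        if (gap_state == this_gap) 0L else matrix$gap_open
      gap_state <- this_gap
    }
  }
  score
}

#' Apply an alignment-boundary policy to a hit
#'
#' \code{current} returns the hit unchanged. \code{history} intersects the
#' hit's query span with the span recorded in the boundary registry at the
#' subject's first significant appearance, recomputing subject coordinates
#' via the BTOP walk. \code{domain} trims the hit to the query-domain
#' interval of the annotated region with the highest sub-alignment score
#' density among regions overlapping the hit.
#'
#' @param hit list with elements \code{subject} and \code{aln}.
#' @param policy \code{"current"}, \code{"history"}, or \code{"domain"}.
#' @param query the query [protein_seq()].
#' @param registry a [boundary_registry()] (history policy).
#' @param domains query-domain annotations, a data frame with
#'   \code{domain_id, start, end} in query coordinates (domain policy).
#' @param matrix scoring matrix for trimming / sub-alignment density.
#' @param pssm optional \code{pssm} when the hit came from a profile search.
#' @return The (possibly trimmed) hit, or \code{NULL} when the trim leaves
#'   nothing (the hit is then excluded from the MSA).
#' @export
apply_boundary_policy <- function(hit, policy = c("current", "history",
                                                  "domain"),
                                  query, registry = NULL, domains = NULL,
                                  matrix = blosum62(), pssm = NULL) {
  policy <- match.arg(policy)
  if (policy == "current") return(hit)
  aln <- hit$aln
  if (policy == "history") {
    span <- registry_get(registry, hit$subject$id)
    if (is.null(span)) return(hit)  # first appearance: nothing to enforce
    trimmed <- trim_alignment_to_query(aln, query, hit$subject,
                                       span["q_start"], span["q_end"],
                                       matrix, pssm)
  } else {
    if (is.null(domains) || !nrow(domains))
      stop("domain policy requires query-domain annotations")
    ov <- domains[domains$start <= aln$q_end & domains$end >= aln$q_start, ,
                  drop = FALSE]
    if (!nrow(ov)) return(NULL)
    part <- subalignment_scores(aln, query, hit$subject, ov,
                                matrix = matrix, on = "query", pssm = pssm)
    part <- part[part$region != ".", , drop = FALSE]
    best <- ov[which.max(part$density), , drop = FALSE]
    trimmed <- trim_alignment_to_query(aln, query, hit$subject,
                                       best$start, best$end, matrix, pssm)
  }
  if (is.null(trimmed)) return(NULL)
  list(subject = hit$subject, aln = trimmed)
}

#' Fill MSA gaps according to a seeding policy
#'
#' Applies a [gapfill_policy()] to every subject row of a query-anchored
#' MSA and derives the subject library: per row, the row's non-gap text
#' (fills included) as an ungapped sequence fragment. With
#' \code{query_seed}, every in-scope gap column receives the query residue
#' of that column, which raises the information content of sparsely
#' observed columns when the PSSM is built.
#'
#' @param msa a \code{query_msa}.
#' @param policy a [gapfill_policy()].
#' @return A list: \code{msa} (filled \code{query_msa}) and \code{library}
#'   (list of [protein_seq()] fragments, one per row).
#' @export
fill_gaps <- function(msa, policy = gapfill_policy()) {
  stopifnot(inherits(msa, "query_msa"), inherits(policy, "gapfill_policy"))
  qchars <- seq_chars(msa$query$residues)
  if (policy$mode == "random_fill") {
    rng <- local_rng(policy$rng_seed)
    on.exit(rng())
  }
  letters20 <- names(policy$background)
  filled <- msa
  filled$rows <- lapply(msa$rows, function(r) {
    rc <- seq_chars(r$row)
    gaps <- which(rc == "-")
    if (policy$scope == "internal_gaps_only") {
      ng <- which(rc != "-")
      gaps <- gaps[gaps > min(ng) & gaps < max(ng)]
    }
    if (length(gaps) && policy$mode != "none") {
      rc[gaps] <- switch(policy$mode,
        query_seed = qchars[gaps],
        x_fill = "X",
        random_fill = sample(letters20, length(gaps), replace = TRUE,
                             prob = policy$background))
    }
    r$row <- paste(rc, collapse = "")
    r
  })
  lib <- lapply(filled$rows, function(r) {
    frag <- gsub("-", "", r$row, fixed = TRUE)
    protein_seq(r$subject_id, frag)
  })
  list(msa = filled, library = lib)
}

# Seed the RNG locally; returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
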