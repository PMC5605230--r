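#' Protein sequence record
#'
#' A minimal carrier for one protein sequence: identifier, optional free-text
#' description, and the residue string over the 20 standard amino acids plus
#' \code{X}.
#'
#' @param id identifier (no whitespace).
#' @param residues residue string; uppercased on construction.
#' @param desc optional description.
#' @return An object of class \code{protein_seq}.
#' @export
protein_seq <- function(id, residues, desc = "") {
  residues <- toupper(gsub("\\s", "", residues))
  if (!nzchar(residues)) stop("empty residue string for sequence '", id, "'")
  bad <- which(is.na(aa_index(seq_chars(residues))))
  if (length(bad))
    stop("illegal residue '", substr(residues, bad[1], bad[1]),
         "' in sequence '", id, "' at position ", bad[1])
  structure(list(id = as.character(id), desc = as.character(desc),
                 residues = residues),
            class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(">", x$id, if (nzchar(x$desc)) x$desc else NULL, "\n", sep = " ")
  cat(substr(x$residues, 1, 60),
      if (nchar(x$residues) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.protein_seq <- function(x) nchar(x$residues)

#' Read protein sequences from a FASTA file
#'
#' Wrapped lines are concatenated, whitespace inside sequence lines is
#' stripped, and residues are uppercased. Residues outside the package
#' alphabet (20 standard amino acids plus \code{X}) are an error naming the
#' record and position.
#'
#' @param path path to a FASTA file.
#' @return A named list of [protein_seq()] records.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path)
  out <- lapply(seq_along(set), function(i) {
    nm <- names(set)[i]
    id <- sub("\\s.*$", "", nm)
    desc <- if (grepl("\\s", nm)) sub("^\\S+\\s+", "", nm) else ""
    protein_seq(id, as.character(set[[i]]), desc)
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs a list of [protein_seq()] records (or a single record).
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "protein_seq")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, function(s)
    if (nzchar(s$desc)) paste(s$id, s$desc) else s$id, "")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

TABULAR_COLS <- c("query_id", "subject_id", "percent_identity",
                  "alignment_length", "mismatches", "gap_opens",
                  "q_start", "q_end", "s_start", "s_end",
                  "evalue", "bit_score", "btop")

#' Read or write BLAST-style tabular hits with a BTOP column
#'
#' The on-disk dialect is commented BLAST tabular: lines starting with
#' \code{#} are skipped, records carry the 12 standard columns plus BTOP as
#' the 13th; extra columns are ignored on read. All coordinates are 1-based
#' inclusive. On read, each record's BTOP string is checked to consume
#' exactly \code{q_end - q_start + 1} query and \code{s_end - s_start + 1}
#' subject residues.
#'
#' @param path path to the tabular file.
#' @return A data frame with columns \code{query_id, subject_id,
#'   percent_identity, alignment_length, mismatches, gap_opens, q_start,
#'   q_end, s_start, s_end, evalue, bit_score, btop}.
#' @export
read_tabular_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 13L))
    stop("tabular hit line has ", min(nf), " columns; 13 required")
  hits <- data.frame(
    query_id = vapply(fields, `[`, "", 1L),
    subject_id = vapply(fields, `[`, "", 2L),
    percent_identity = as.numeric(vapply(fields, `[`, "", 3L)),
    alignment_length = as.integer(vapply(fields, `[`, "", 4L)),
    mismatches = as.integer(vapply(fields, `[`, "", 5L)),
    gap_opens = as.integer(vapply(fields, `[`, "", 6L)),
    q_start = as.integer(vapply(fields, `[`, "", 7L)),
    q_end = as.integer(vapply(fields, `[`, "", 8L)),
    s_start = as.integer(vapply(fields, `[`, "", 9L)),
    s_end = as.integer(vapply(fields, `[`, "", 10L)),
    evalue = as.numeric(vapply(fields, `[`, "", 11L)),
    bit_score = as.numeric(vapply(fields, `[`, "", 12L)),
    btop = vapply(fields, `[`, "", 13L),
    stringsAsFactors = FALSE)
  num_cols <- c("percent_identity", "alignment_length", "q_start", "q_end",
                "s_start", "s_end", "evalue", "bit_score")
  for (cc in num_cols)
    if (anyNA(hits[[cc]])) stop("non-numeric value in column ", cc)
  validate_hits(hits)
  hits
}

empty_hits <- function() {
  h <- data.frame(query_id = character(), subject_id = character(),
                  percent_identity = numeric(), alignment_length = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  evalue = numeric(), bit_score = numeric(),
                  btop = character(), stringsAsFactors = FALSE)
  h
}

validate_hits <- function(hits) {
  for (i in seq_len(nrow(hits))) {
    if (hits$q_start[i] > hits$q_end[i] || hits$s_start[i] > hits$s_end[i])
      stop("hit ", i, ": start exceeds end")
    use <- btop_consumption(hits$btop[i])
    if (use["query"] != hits$q_end[i] - hits$q_start[i] + 1L ||
        use["subject"] != hits$s_end[i] - hits$s_start[i] + 1L)
      stop("hit ", i, " (", hits$subject_id[i],
           "): BTOP consumption disagrees with coordinates")
  }
  invisible(hits)
}

#' @rdname read_tabular_hits
#' @param hits hit data frame as returned by [read_tabular_hits()] or
#'   produced by a search.
#' @param comment optional comment lines to write (without the leading
#'   \code{#}).
#' @export
write_tabular_hits <- function(hits, path, comment = character()) {
  validate_hits(hits)
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comment) writeLines(paste0("# ", cm), con)
  if (nrow(hits)) {
    out <- hits[, TABULAR_COLS]
    out$percent_identity <- formatC(out$percent_identity, digits = 2,
                                    format = "f")
    out$evalue <- formatC(out$evalue, digits = 3, format = "g")
    out$bit_score <- formatC(out$bit_score, digits = 1, format = "f")
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read or write a domain-annotation table
#'
#' Domain annotations are a 5-column TSV with header
#' \code{seq_id, domain_id, clan_id, start, end}; \code{clan_id} may be
#' empty; \code{start}/\code{end} are 1-based inclusive and must satisfy
#' \code{start <= end}.
#'
#' @param path path to the TSV file.
#' @return A data frame of annotations.
#' @export
read_domains <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character",
                                        "integer", "integer"))
  need <- c("seq_id", "domain_id", "clan_id", "start", "end")
  if (!identical(names(d), need))
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  d$clan_id[is.na(d$clan_id)] <- ""
  validate_domains(d)
  d
}

validate_domains <- function(d) {
  if (any(d$start < 1L) || any(d$start > d$end))
    stop("domain annotations must satisfy 1 <= start <= end")
  invisible(d)
}

#' @rdname read_domains
#' @param domains annotation data frame.
#' @export
write_domains <- function(domains, path) {
  validate_domains(domains)
  utils::write.table(domains[, c("seq_id", "domain_id", "clan_id",
                                 "start", "end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a PSSM to a TSV score table with a JSON metadata sidecar
#'
#' The TSV holds the rounded half-bit integer scores (one row per query
#' position, one column per residue); \code{<path>.json} holds the query
#' record, unrounded scores, estimated target frequencies, per-position
#' effective observation counts, and any calibrated statistical parameters,
#' at full precision. \code{read_pssm()} restores the object exactly.
#'
#' @param pssm a \code{pssm} object from [build_pssm()].
#' @param path path for the TSV file; the sidecar is \code{<path>.json}.
#' @return \code{write_pssm}: the path, invisibly; \code{read_pssm}: the
#'   restored \code{pssm} object.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  tab <- data.frame(pos = seq_len(nrow(pssm$scores)),
                    residue = seq_chars(pssm$query$residues),
                    pssm$scores, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(query = list(id = pssm$query$id, desc = pssm$query$desc,
                            residues = pssm$query$residues),
               scores_unrounded = pssm$scores_unrounded,
               freqs = pssm$freqs, n_eff = pssm$n_eff,
               params = if (is.null(pssm$params)) NULL
                        else unclass(pssm$params))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  aa <- setdiff(names(tab), c("pos", "residue"))
  if (!all(aa %in% AA_LETTERS))
    stop("unknown amino-acid column in PSSM table: ",
         paste(setdiff(aa, AA_LETTERS), collapse = ","))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  query <- protein_seq(meta$query$id, meta$query$residues,
                       if (is.null(meta$query$desc)) "" else meta$query$desc)
  scores <- matrix(as.integer(as.matrix(tab[, aa])), nrow(tab),
                   dimnames = list(NULL, aa))
  su <- meta$scores_unrounded; dimnames(su) <- list(NULL, aa)
  fr <- meta$freqs; dimnames(fr) <- list(NULL, aa)
  new_pssm(query = query, scores = scores, scores_unrounded = su,
           freqs = fr, n_eff = as.numeric(meta$n_eff),
           params = if (is.null(meta$params) || !length(meta$params)) NULL
                    else meta$params)
}

#' Write a query-anchored MSA as aligned FASTA
#'
#' The query is the first record; every subject row has exactly one column
#' per query residue, with \code{-} for gaps.
#'
#' @param msa a \code{query_msa} object.
#' @param path output path.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "query_msa"))
  recs <- c(list(protein_seq(msa$query$id, msa$query$residues)),
            lapply(msa$rows, function(r)
              structure(list(id = r$subject_id, desc = "", residues = r$row),
                        class = "protein_seq")))
  set <- Biostrings::BStringSet(vapply(recs, `[[`, "", "residues"))
  names(set) <- vapply(recs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
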