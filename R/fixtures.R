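#' Specification for a synthetic protein-family database
#'
#' Describes domain families (ancestor lengths and within-family identity
#' targets), multi-domain architectures, and decoys, from which
#' [generate_database()] derives a FASTA-style database with exact domain
#' annotations and a ground-truth manifest. Members are derived from a
#' family ancestor by point substitutions sampled proportional to BLOSUM62
#' exchangeabilities plus occasional indels (geometric lengths), calibrated
#' so the realized pairwise identity to the ancestor lands on the target.
#'
#' @param domains named integer vector: ancestor length per domain id.
#' @param families named list, one entry per domain id:
#'   \code{list(size, identity)} with target percent identity in (5, 100];
#'   a length-2 \code{identity} is a diversity range, members being spread
#'   uniformly across it.
#'   Used for single-domain architectures when \code{architectures} is
#'   \code{NULL}; always the identity source for domain instances.
#' @param architectures optional list of
#'   \code{list(prefix, n, domains = c(...))}; when \code{NULL}, one
#'   single-domain architecture per family.
#' @param n_decoys number of unannotated random sequences.
#' @param decoy_length decoy length range, \code{c(min, max)}.
#' @param flank flank/linker length range around and between domains.
#' @param indel_rate expected indels per residue (default 0.01).
#' @param indel_mean mean geometric indel length (default 2).
#' @param rng_seed integer seed; all outputs are deterministic given it.
#' @param background residue composition for ancestors, linkers and decoys
#'   (default uniform).
#' @return An object of class \code{family_spec}.
#' @export
family_spec <- function(domains, families, architectures = NULL,
                        n_decoys = 0L, decoy_length = c(150L, 250L),
                        flank = c(5L, 30L), indel_rate = 0.01,
                        indel_mean = 2, rng_seed = 1L,
                        background = rep(1 / 20, 20)) {
  stopifnot(length(domains) >= 1, !is.null(names(domains)))
  for (fid in names(families)) {
    f <- families[[fid]]
    if (!fid %in% names(domains))
      stop("family '", fid, "' references an undeclared domain")
    if (any(f$identity <= 5) || any(f$identity > 100))
      stop("infeasible identity target for family '", fid, "'")
  }
  if (is.null(architectures))
    architectures <- lapply(names(families), function(fid)
      list(prefix = fid, n = families[[fid]]$size, domains = fid))
  for (a in architectures)
    if (!all(a$domains %in% names(domains)))
      stop("architecture references undeclared domain(s)")
  structure(list(domains = domains, families = families,
                 architectures = architectures,
                 n_decoys = as.integer(n_decoys),
                 decoy_length = as.integer(decoy_length),
                 flank = as.integer(flank),
                 indel_rate = indel_rate, indel_mean = indel_mean,
                 rng_seed = as.integer(rng_seed), background = background),
            class = "family_spec")
}

random_residues <- function(n, background) {
  if (n <= 0L) return("")
  paste(sample(AA_LETTERS, n, replace = TRUE, prob = background),
        collapse = "")
}

# Derive one mutated instance of an ancestor at the target identity:
# indels first (so the substitution budget can be corrected for the
# identity the indels will cost), then point substitutions drawn from
# BLOSUM62 exchange frequencies q(b | a), b != a.
mutate_instance <- function(ancestor, identity, indel_rate, indel_mean,
                            background, qcond, sub_adjust = 0L) {
  res <- seq_chars(ancestor)
  L <- length(res)
  n_indel <- stats::rpois(1L, indel_rate * L)
  indel_res <- 0L
  for (k in seq_len(n_indel)) {
    len <- stats::rgeom(1L, 1 / indel_mean) + 1L
    if (stats::runif(1) < 0.5 && length(res) > len + 2L) {  # deletion
      at <- sample.int(length(res) - len, 1L)
      res <- res[-(at:(at + len - 1L))]
    } else {                                                # insertion
      at <- sample.int(length(res) + 1L, 1L)
      ins <- seq_chars(random_residues(len, background))
      res <- append(res, ins, after = at - 1L)
    }
    indel_res <- indel_res + len
  }
  n_sub <- max(0L, round(L * (1 - identity / 100)) - indel_res + sub_adjust)
  n_sub <- min(n_sub, length(res))
  if (n_sub > 0L) {
    pos <- sample.int(length(res), n_sub)
    for (p in pos) {
      a <- res[p]
      pr <- qcond[a, ]
      pr[a] <- 0
      res[p] <- sample(AA_LETTERS, 1L, prob = pr)
    }
  }
  paste(res, collapse = "")
}

# Calibrated instance: generate, measure realized identity with the
# package aligner (local alignment trims mismatch-dense ends, which biases
# the raw substitution budget), and correct the substitution count until
# the measured identity lands on the target.
mutate_instance_calibrated <- function(ancestor, identity, indel_rate,
                                       indel_mean, background, qcond,
                                       matrix = NULL, tol = 1.5,
                                       max_tries = 6L) {
  if (is.null(matrix)) matrix <- blosum62()
  anc <- protein_seq("anc", ancestor)
  adj <- 0L
  inst <- mutate_instance(ancestor, identity, indel_rate, indel_mean,
                          background, qcond, adj)
  if (identity >= 99.5) return(inst)
  for (k in seq_len(max_tries)) {
    a <- smith_waterman(anc, protein_seq("inst", inst), matrix)
    realized <- if (is.null(a)) 0 else a$percent_identity
    if (abs(realized - identity) <= tol) break
    adj <- adj + as.integer(round(nchar(ancestor) *
                                    (realized - identity) / 100))
    inst <- mutate_instance(ancestor, identity, indel_rate, indel_mean,
                            background, qcond, adj)
  }
  inst
}

#' Generate a synthetic protein database with known ground truth
#'
#' Draws one ancestor per domain from the background composition, derives
#' family members per architecture, concatenates multi-domain proteins with
#' random linkers, and records every domain instance's exact coordinates.
#' Deterministic given the spec's \code{rng_seed}.
#'
#' @param spec a [family_spec()].
#' @return A list: \code{db} (named list of [protein_seq()]),
#'   \code{annotations} (domain TSV data frame), \code{ancestors} (named
#'   residue strings), and \code{truth} (per-architecture member ids and
#'   per-family carrier ids).
#' @export
generate_database <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  generate_database_inner(spec, inner_linker = NULL)
}

#' Toy-scale PSSM-contamination benchmark
#'
#' Builds the multi-domain contamination scenario: family A occurs alone
#' and fused directly to family B (A+B architectures), family B also occurs
#' alone, plus unannotated random decoys. The query is an embedded,
#' N-terminally truncated instance of the A domain, so alignments of
#' included A+B subjects can ratchet past the domain boundary into their B
#' domains; once the profile "learns" B, B-only sequences appear as false
#' positives — the signature of PSSM contamination that query-seeding
#' suppresses.
#'
#' @param seed integer seed controlling the database and the query.
#' @param n_family,n_decoys architecture sizes (defaults 30 per family
#'   architecture and 200 decoys).
#' @return A list: \code{query} (an \code{embedded_query} for family A),
#'   \code{db}, \code{annotations}, \code{truth} (with \code{tp_ids}, the
#'   A-carrying ids, and \code{decoy_family_ids}, the B-only ids), and the
#'   underlying \code{spec}.
#' @export
contamination_benchmark <- function(seed = 1L, n_family = 30L,
                                    n_decoys = 200L) {
  # Robinson-Robinson composition for all random sequence: BLOSUM62 is a
  # log-odds matrix against real amino-acid frequencies, and uniform random
  # flanks would make chance matches of rare residues (W, C) far too likely
  spec <- family_spec(
    domains = c(A = 160L, B = 120L),
    families = list(A = list(size = n_family, identity = c(35, 75)),
                    B = list(size = n_family, identity = c(50, 80))),
    architectures = list(
      list(prefix = "A", n = n_family, domains = "A"),
      list(prefix = "AB", n = n_family, domains = c("A", "B")),
      list(prefix = "B", n = n_family, domains = "B")),
    n_decoys = n_decoys, decoy_length = c(150L, 250L),
    flank = c(5L, 30L), rng_seed = seed, background = AA_BACKGROUND)
  # A and B must be adjacent in the fusion proteins for over-extension to
  # reach B: no inter-domain linker.
  gen <- generate_database_fused(spec)
  # the query is itself a distant family member, mirroring far-homolog
  # query selection
  restore <- local_rng(seed + 1000L)
  qcond <- blosum62_conditionals()
  dom_full <- mutate_instance_calibrated(gen$ancestors[["A"]], 50,
                                         spec$indel_rate, spec$indel_mean,
                                         spec$background, qcond)
  restore()
  # N-terminal truncation: keep the C-terminal 80% so the domain end still
  # abuts the fused B domains in the database
  cut <- floor(nchar(dom_full) * 0.2)
  dom <- protein_seq("queryA", substr(dom_full, cut + 1L, nchar(dom_full)))
  query <- make_embedded_query(dom, domain_id = "A", rng_seed = seed + 2000L,
                               background = AA_BACKGROUND)
  list(query = query, db = gen$db, annotations = gen$annotations,
       truth = c(gen$truth,
                 list(tp_ids = gen$truth$carriers$A,
                      decoy_family_ids = gen$truth$members$B)),
       spec = spec)
}

# generate_database with zero-length linkers between domains (fusion
# proteins); leading/trailing flanks unchanged.
generate_database_fused <- function(spec) {
  generate_database_inner(spec, inner_linker = 0L)
}

generate_database_inner <- function(spec, inner_linker = NULL) {
  restore <- local_rng(spec$rng_seed)
  on.exit(restore())
  qcond <- blosum62_conditionals()
  mtx <- blosum62()
  ancestors <- vapply(names(spec$domains), function(d)
    random_residues(spec$domains[[d]], spec$background), "")
  db <- list(); ann <- list(); members <- list()
  rflank <- function() sample(spec$flank[1]:spec$flank[2], 1L)
  for (arch in spec$architectures) {
    ids <- sprintf("%s%03d", arch$prefix, seq_len(arch$n))
    members[[arch$prefix]] <- ids
    for (id in ids) {
      lead <- random_residues(rflank(), spec$background)
      parts <- lead; pos <- nchar(lead)
      for (d in arch$domains) {
        tgt <- spec$families[[d]]$identity
        # a length-2 identity is a diversity range: members are spread
        # uniformly across it, like the member spread of a real family
        if (length(tgt) == 2L) tgt <- stats::runif(1L, tgt[1], tgt[2])
        inst <- mutate_instance_calibrated(ancestors[[d]], tgt,
                                           spec$indel_rate, spec$indel_mean,
                                           spec$background, qcond, mtx)
        ann[[length(ann) + 1L]] <- data.frame(
          seq_id = id, domain_id = d,
          clan_id = if (is.null(spec$families[[d]]$clan)) ""
                    else spec$families[[d]]$clan,
          start = pos + 1L, end = pos + nchar(inst),
          stringsAsFactors = FALSE)
        parts <- c(parts, inst); pos <- pos + nchar(inst)
        if (d != arch$domains[length(arch$domains)]) {
          w <- if (is.null(inner_linker)) rflank() else inner_linker
          link <- random_residues(w, spec$background)
          parts <- c(parts, link); pos <- pos + nchar(link)
        }
      }
      parts <- c(parts, random_residues(rflank(), spec$background))
      db[[id]] <- protein_seq(id, paste(parts, collapse = ""))
    }
  }
  for (k in seq_len(spec$n_decoys)) {
    id <- sprintf("decoy%03d", k)
    len <- sample(spec$decoy_length[1]:spec$decoy_length[2], 1L)
    db[[id]] <- protein_seq(id, random_residues(len, spec$background))
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(seq_id = character(), domain_id = character(),
               clan_id = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  carriers <- lapply(names(spec$domains), function(d)
    unique(annotations$seq_id[annotations$domain_id == d]))
  names(carriers) <- names(spec$domains)
  list(db = db, annotations = annotations, ancestors = ancestors,
       truth = list(members = members, carriers = carriers))
}
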