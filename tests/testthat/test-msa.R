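m62 <- blosum62()

aln_from_rows <- function(qrow, srow, q_start, s_start, matrix = m62) {
  qk <- seq_chars(qrow); sk <- seq_chars(srow)
  score <- seedsearch:::rescore_columns(qk, sk, q_start, matrix)
  seedsearch:::new_local_alignment(
    q_start, q_start + sum(qk != "-") - 1L,
    s_start, s_start + sum(sk != "-") - 1L,
    raw_score = score,
    percent_identity = 100 * sum(qk == sk & qk != "-") / length(qk),
    btop = btop_encode(qrow, srow))
}

test_that("query-anchored rows place residues at query columns", {
  q <- protein_seq("q", "ACDE")
  s <- protein_seq("s", "ACDE")
  hit <- list(subject = s, aln = aln_from_rows("ACDE", "ACDE", 1L, 1L))
  msa <- build_query_msa(q, list(hit))
  expect_equal(msa$rows[[1]]$row, "ACDE")

  # subject insertion is deleted from the row; row keeps query length
  q2 <- protein_seq("q2", "AACC")
  s2 <- protein_seq("s2", "AGAC")  # btop "1-G2": G inserted after query pos 1
  hit2 <- list(subject = s2, aln = aln_from_rows("A-AC", "AGAC", 1L, 1L))
  msa2 <- build_query_msa(q2, list(hit2))
  expect_equal(nchar(msa2$rows[[1]]$row), 4L)
  expect_equal(msa2$rows[[1]]$row, "AAC-")
  expect_equal(msa2$rows[[1]]$n_insertions, 1L)

  # partial span gets end gaps
  q3 <- protein_seq("q3", "WWACDEWW")
  s3 <- protein_seq("s3", "ACDE")
  hit3 <- list(subject = s3, aln = aln_from_rows("ACDE", "ACDE", 3L, 1L))
  msa3 <- build_query_msa(q3, list(hit3))
  expect_equal(msa3$rows[[1]]$row, "--ACDE--")
})

test_that("duplicate subject ids are rejected", {
  q <- protein_seq("q", "ACDE")
  s <- protein_seq("dup", "ACDE")
  hit <- list(subject = s, aln = aln_from_rows("ACDE", "ACDE", 1L, 1L))
  expect_error(build_query_msa(q, list(hit, hit)), "dup")
})

test_that("gap filling follows mode and scope", {
  q <- protein_seq("q", "WYACDEFG")
  s <- protein_seq("s", "ACE")
  aln <- aln_from_rows("ACDE", "AC-E", 3L, 1L)
  msa <- build_query_msa(q, list(list(subject = s, aln = aln)))
  expect_equal(msa$rows[[1]]$row, "--AC-E--")

  both <- fill_gaps(msa, gapfill_policy("query_seed",
                                        "internal_and_end_gaps"))
  expect_equal(both$msa$rows[[1]]$row, "WYACDEFG")
  expect_equal(both$library[[1]]$residues, "WYACDEFG")

  internal <- fill_gaps(msa, gapfill_policy("query_seed",
                                            "internal_gaps_only"))
  expect_equal(internal$msa$rows[[1]]$row, "--ACDE--")
  expect_equal(internal$library[[1]]$residues, "ACDE")

  none <- fill_gaps(msa, gapfill_policy("none"))
  expect_equal(none$msa$rows[[1]]$row, "--AC-E--")

  xf <- fill_gaps(msa, gapfill_policy("x_fill", "internal_gaps_only"))
  expect_equal(xf$msa$rows[[1]]$row, "--ACXE--")

  r1 <- fill_gaps(msa, gapfill_policy("random_fill", rng_seed = 5))
  r2 <- fill_gaps(msa, gapfill_policy("random_fill", rng_seed = 5))
  expect_identical(r1$msa$rows[[1]]$row, r2$msa$rows[[1]]$row)
  expect_false(grepl("-", r1$msa$rows[[1]]$row, fixed = TRUE))
})

test_that("seeded rows have no in-scope gaps and fills equal the query", {
  set.seed(31)
  db <- generate_database(family_spec(
    domains = c(D = 90), families = list(D = list(size = 12, identity = 55)),
    rng_seed = 31))
  q <- protein_seq("anc", db$ancestors[["D"]])
  hits <- list()
  for (s in db$db) {
    a <- smith_waterman(q, s, m62)
    if (!is.null(a)) hits[[s$id]] <- list(subject = s, aln = a)
  }
  msa <- build_query_msa(q, hits)
  filled <- fill_gaps(msa, gapfill_policy("query_seed",
                                          "internal_and_end_gaps"))
  qch <- seq_chars(q$residues)
  for (i in seq_along(msa$rows)) {
    before <- seq_chars(msa$rows[[i]]$row)
    after <- seq_chars(filled$msa$rows[[i]]$row)
    expect_false(any(after == "-"))
    was_gap <- before == "-"
    expect_identical(after[was_gap], qch[was_gap])
    expect_identical(after[!was_gap], before[!was_gap])
  }
})

test_that("boundary registry is write-once and history trims to it", {
  reg <- boundary_registry()
  q <- protein_seq("q", random_protein(60))
  s <- protein_seq("s1", q$residues)
  full <- smith_waterman(q, s, m62)
  first <- seedsearch:::trim_alignment_to_query(full, q, s, 10L, 50L, m62)
  registry_record(reg, "s1", first)
  registry_record(reg, "s1", full)  # second write ignored
  expect_equal(unname(registry_get(reg, "s1")["q_start"]), 10L)
  expect_equal(unname(registry_get(reg, "s1")["q_end"]), 50L)

  hit <- list(subject = s, aln = full)
  trimmed <- apply_boundary_policy(hit, "history", q, registry = reg,
                                   matrix = m62)
  expect_equal(trimmed$aln$q_start, 10L)
  expect_equal(trimmed$aln$q_end, 50L)
  # subject coordinates recomputed via the BTOP walk (identity alignment)
  expect_equal(trimmed$aln$s_start, 10L)
  expect_equal(trimmed$aln$s_end, 50L)
  # current policy is the identity
  expect_identical(apply_boundary_policy(hit, "current", q), hit)
})

test_that("empty history intersection excludes the hit", {
  reg <- boundary_registry()
  q <- protein_seq("q", random_protein(60))
  s <- protein_seq("s1", q$residues)
  full <- smith_waterman(q, s, m62)
  early <- seedsearch:::trim_alignment_to_query(full, q, s, 1L, 10L, m62)
  registry_record(reg, "s1", early)
  late <- seedsearch:::trim_alignment_to_query(full, q, s, 30L, 60L, m62)
  out <- apply_boundary_policy(list(subject = s, aln = late), "history", q,
                               registry = reg, matrix = m62)
  expect_null(out)
})

test_that("domain policy keeps the densest annotated block", {
  set.seed(32)
  core <- random_protein(50)
  q <- protein_seq("q", paste0(core, random_protein(30)))
  s <- protein_seq("s", paste0(core, random_protein(30)))
  a <- smith_waterman(q, s, m62)
  doms <- data.frame(domain_id = c("good", "tail"),
                     start = c(1L, 51L), end = c(50L, 80L))
  out <- apply_boundary_policy(list(subject = s, aln = a), "domain", q,
                               domains = doms, matrix = m62)
  expect_equal(out$aln$q_start, a$q_start)
  expect_lte(out$aln$q_end, 50L)
})

test_that("history policy never extends a row beyond its registry span", {
  set.seed(33)
  db <- generate_database(family_spec(
    domains = c(D = 100),
    families = list(D = list(size = 15, identity = c(40, 70))),
    n_decoys = 40, rng_seed = 33))
  q <- protein_seq("anc", db$ancestors[["D"]])
  fit <- psisearch(q, db$db, n_iterations = 10, boundary = "history")
  for (it in fit$iterations) {
    if (is.null(it$msa)) next
    for (r in it$msa$rows) {
      span <- registry_get(fit$registry, r$subject_id)
      expect_false(is.null(span))
      expect_gte(r$q_start, span["q_start"])
      expect_lte(r$q_end, span["q_end"])
    }
  }
})
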