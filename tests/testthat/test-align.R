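m62 <- blosum62()

test_that("self-alignment recovers the full diagonal", {
  s <- "MKVLATWYCH"
  a <- smith_waterman(protein_seq("q", s), protein_seq("s", s), m62)
  expect_equal(a$q_start, 1L); expect_equal(a$q_end, 10L)
  expect_equal(a$percent_identity, 100)
  diag_sum <- sum(m62$scores[cbind(seq_chars(s), seq_chars(s))])
  expect_equal(a$raw_score, diag_sum)
  expect_equal(a$btop, "10")
})

test_that("all-negative scoring reports no hit", {
  a <- smith_waterman(protein_seq("q", "AAAA"), protein_seq("s", "CCCC"), m62)
  expect_null(a)
  msa <- build_query_msa(protein_seq("q", "AAAA"), list())
  p <- build_pssm(msa)
  expect_null(pssm_search(p, protein_seq("s", "CCCC")))
})

test_that("sequence kernel matches the brute-force DP oracle", {
  set.seed(101)
  for (k in 1:60) {
    q <- random_protein(12); s <- random_protein(12)
    a <- smith_waterman(protein_seq("q", q), protein_seq("s", s), m62)
    got <- if (is.null(a)) 0 else a$raw_score
    expect_equal(got, oracle_seq_sw(seq_chars(q), seq_chars(s),
                                    m62$scores, 11, 1))
  }
})

test_that("profile kernel matches the brute-force profile DP oracle", {
  set.seed(102)
  for (k in 1:40) {
    qs <- random_protein(10)
    msa <- build_query_msa(protein_seq("q", qs), list())
    p <- build_pssm(msa)
    subj <- random_protein(14)
    a <- pssm_search(p, protein_seq("s", subj))
    got <- if (is.null(a)) 0 else a$raw_score
    prof <- p$scores
    expect_equal(got, oracle_profile_sw(prof, seq_chars(subj), 11, 1))
  }
})

test_that("alignment score is invariant under query/subject swap", {
  set.seed(103)
  for (k in 1:30) {
    q <- random_protein(15); s <- random_protein(15)
    a <- smith_waterman(protein_seq("q", q), protein_seq("s", s), m62)
    b <- smith_waterman(protein_seq("q", s), protein_seq("s", q), m62)
    expect_equal(if (is.null(a)) 0 else a$raw_score,
                 if (is.null(b)) 0 else b$raw_score)
  }
})

test_that("scores agree with an independent aligner on random pairs", {
  set.seed(104)
  for (k in 1:25) {
    q <- random_protein(25); s <- random_protein(25)
    a <- smith_waterman(protein_seq("q", q), protein_seq("s", s), m62)
    if (is.null(a)) next
    pa <- Biostrings::pairwiseAlignment(
      q, s, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    expect_equal(a$raw_score, Biostrings::score(pa))
  }
})

test_that("BTOP traces on self-built alignments validate spans", {
  set.seed(105)
  for (k in 1:30) {
    q <- random_protein(30); s <- random_protein(30)
    a <- smith_waterman(protein_seq("q", q), protein_seq("s", s), m62)
    if (is.null(a)) next
    use <- seedsearch:::btop_consumption(a$btop)
    expect_identical(unname(use["query"]), a$q_end - a$q_start + 1L)
    expect_identical(unname(use["subject"]), a$s_end - a$s_start + 1L)
  }
})

test_that("sub-alignment partition conserves the raw score", {
  set.seed(106)
  q <- protein_seq("q", random_protein(40))
  s <- protein_seq("s", paste0(substr(q$residues, 1, 30), random_protein(20)))
  a <- smith_waterman(q, s, m62)
  whole <- data.frame(domain_id = "all", start = 1L, end = length(s))
  part <- subalignment_scores(a, q, s, whole, m62)
  expect_equal(sum(part$score), a$raw_score)
  expect_equal(part$score[part$region == "all"], a$raw_score)
  split <- data.frame(domain_id = c("left", "right"),
                      start = c(1L, 16L), end = c(15L, length(s)))
  part2 <- subalignment_scores(a, q, s, split, m62)
  expect_equal(sum(part2$score), a$raw_score)
  # region fully outside the aligned span contributes zero
  far <- data.frame(domain_id = "far", start = 49L, end = 50L)
  part3 <- subalignment_scores(a, q, s, far, m62)
  expect_equal(part3$score[part3$region == "far"], 0)
})

test_that("over-extended tails show lower sub-alignment score density", {
  set.seed(107)
  core <- random_protein(60)
  # subject: strong copy of the query core, then unrelated tail; query
  # carries the core plus its own unrelated tail of equal length
  q <- protein_seq("q", paste0(core, random_protein(40)))
  s <- protein_seq("s", paste0(core, random_protein(40)))
  a <- smith_waterman(q, s, m62)
  regs <- data.frame(domain_id = c("core", "tail"),
                     start = c(1L, 61L), end = c(60L, length(s)))
  part <- subalignment_scores(a, q, s, regs, m62)
  dens <- part$density[match(c("core", "tail"), part$region)]
  if (part$columns[part$region == "tail"] > 0)
    expect_lt(dens[2], dens[1])
  else succeed("alignment did not extend into the tail")
})

test_that("exhaustive short-sequence sweep matches the oracle", {
  ab <- c("A", "C", "D", "W")
  seqs <- unlist(lapply(1:3, function(L) {
    g <- do.call(expand.grid, rep(list(ab), L))
    apply(g, 1, paste, collapse = "")
  }))
  for (q in seqs) for (s in seqs) {
    a <- smith_waterman(protein_seq("q", q), protein_seq("s", s), m62)
    got <- if (is.null(a)) 0 else a$raw_score
    expect_equal(got, oracle_seq_sw(seq_chars(q), seq_chars(s),
                                    m62$scores, 11, 1))
  }
})
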