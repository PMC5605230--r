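test_that("embedding arithmetic follows the floor(L/2) flank rule", {
  set.seed(61)
  dom200 <- protein_seq("d200", random_protein(200))
  eq <- make_embedded_query(dom200, "PFX", rng_seed = 1)
  expect_equal(length(eq$sequence), 400L)
  expect_equal(eq$domain_start, 101L)
  expect_equal(eq$domain_end, 300L)

  dom173 <- protein_seq("d173", random_protein(173))
  eq2 <- make_embedded_query(dom173, "PFX", rng_seed = 2)
  expect_equal(eq2$flank_len_left, 86L)
  expect_equal(eq2$flank_len_right, 86L)
  expect_equal(length(eq2$sequence), 173L + 2L * 86L)

  # seeded determinism
  eq3 <- make_embedded_query(dom173, "PFX", rng_seed = 2)
  expect_identical(eq2$sequence$residues, eq3$sequence$residues)
  # the embedded domain is recoverable at its recorded coordinates
  expect_equal(substr(eq$sequence$residues, eq$domain_start, eq$domain_end),
               dom200$residues)
})

hitrow <- function(q_start, q_end, s_start, s_end, subject_id = "s1",
                   btop = NULL, evalue = 1e-6, pid = 40) {
  if (is.null(btop)) btop <- as.character(q_end - q_start + 1L)
  data.frame(query_id = "q", subject_id = subject_id,
             percent_identity = pid,
             alignment_length = q_end - q_start + 1L, mismatches = 0L,
             gap_opens = 0L, q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end, evalue = evalue,
             bit_score = 40, btop = btop, stringsAsFactors = FALSE)
}

embq <- list(domain_id = "F", clan_id = "", domain_start = 101L,
             domain_end = 300L)

ann <- data.frame(
  seq_id = c("s1", "s2", "s3"),
  domain_id = c("F", "G", "F2"),
  clan_id = c("", "", "CLF"),
  start = c(50L, 10L, 40L), end = c(250L, 80L, 140L),
  stringsAsFactors = FALSE)

test_that("hits inside the embedded domain onto the right family are TPs", {
  hit <- hitrow(150L, 250L, 60L, 160L)
  expect_equal(classify_hit(hit, embq, ann), "TP")
  # same family but alignment confined to the random flank
  expect_equal(classify_hit(hitrow(1L, 90L, 60L, 149L), embq, ann), "FP")
  # wrong family under the domain
  expect_equal(classify_hit(hitrow(150L, 250L, 1L, 101L,
                                   subject_id = "s2"), embq, ann), "FP")
  # unannotated subject
  expect_equal(classify_hit(hitrow(150L, 250L, 1L, 101L,
                                   subject_id = "nope"), embq, ann), "FP")
  # clan-level homology counts as TP
  q_clan <- modifyList(embq, list(clan_id = "CLF"))
  expect_equal(classify_hit(hitrow(150L, 250L, 40L, 140L,
                                   subject_id = "s3"), q_clan, ann), "TP")
})

test_that("full-length mode ignores hits outside the scored interval", {
  fl <- list(domain_id = "F", clan_id = "", domain_start = 326L,
             domain_end = 607L, full_length = TRUE)
  expect_equal(classify_hit(hitrow(100L, 200L, 50L, 150L), fl, ann),
               "ignored")
  ann_hi <- data.frame(seq_id = "s1", domain_id = "F", clan_id = "",
                       start = 10L, end = 400L, stringsAsFactors = FALSE)
  expect_equal(classify_hit(hitrow(350L, 500L, 60L, 210L), fl, ann_hi),
               "TP")
})

test_that("the subject-side overlap uses the domain-restricted BTOP walk", {
  # alignment covers q 95..106; only q 101..106 is in the domain, and a
  # subject insertion sits between: restricted subject span is 58..63
  hit <- hitrow(95L, 106L, 50L, 63L, btop = "6-A-C6",
                subject_id = "s1")
  # restricted span 58..63 misses a domain ending at 57, though the full
  # subject span 50..63 would overlap it
  ann_near <- data.frame(seq_id = "s1", domain_id = "F", clan_id = "",
                         start = 30L, end = 57L, stringsAsFactors = FALSE)
  expect_equal(classify_hit(hit, embq, ann_near), "FP")
  ann_in <- data.frame(seq_id = "s1", domain_id = "F", clan_id = "",
                       start = 58L, end = 100L, stringsAsFactors = FALSE)
  expect_equal(classify_hit(hit, embq, ann_in), "TP")
})

test_that("evaluation aggregates with equal per-query weight", {
  runs <- list(
    q1 = list(rbind(hitrow(150L, 250L, 60L, 160L),
                    hitrow(150L, 250L, 1L, 101L, subject_id = "s2"))),
    q2 = list(hitrow(150L, 250L, 60L, 160L)))
  queries <- list(q1 = embq, q2 = embq)
  res <- evaluate_run(runs, queries, ann,
                      family_sizes = c(q1 = 2, q2 = 2))
  pq <- res$per_query
  expect_equal(pq$TP[pq$query == "q1"], 1L)
  expect_equal(pq$FP[pq$query == "q1"], 1L)
  expect_equal(pq$FDR[pq$query == "q1"], 0.5)
  expect_equal(pq$sensitivity[pq$query == "q1"], 0.5)
  expect_equal(pq$FDR[pq$query == "q2"], 0)
  expect_equal(res$summary$weighted_FDR, 0.25)
  expect_equal(res$summary$weighted_sensitivity, 0.5)
  # conservation: TP + FP + ignored equals reported hits
  expect_equal(pq$TP + pq$FP + pq$ignored, c(2L, 1L))
})

test_that("zero-family queries are excluded with a warning", {
  runs <- list(q1 = list(hitrow(150L, 250L, 60L, 160L)))
  expect_warning(
    evaluate_run(runs, list(q1 = embq), ann, family_sizes = c(q1 = 0)),
    "family size 0")
})

test_that("over-extension counts query positions outside the domain", {
  q <- modifyList(embq, list())
  expect_equal(overextension_stats(hitrow(101L, 300L, 1L, 200L), q), 0)
  expect_equal(overextension_stats(hitrow(91L, 310L, 1L, 220L), q), 20)
  hits <- rbind(hitrow(101L, 300L, 1L, 200L), hitrow(91L, 310L, 1L, 220L))
  expect_equal(overextension_stats(hits, q), 10)
  expect_true(is.na(overextension_stats(hits[0, ], q)))
})

test_that("identity quartile uses linear interpolation", {
  hits <- do.call(rbind, lapply(c(10, 20, 30, 40), function(p)
    hitrow(101L, 300L, 1L, 200L, pid = p)))
  expect_equal(identity_q1(hits), 17.5)
  expect_true(is.na(identity_q1(hits[0, ])))
})
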