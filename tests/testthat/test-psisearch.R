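test_that("a database holding only the query converges immediately", {
  set.seed(51)
  q <- protein_seq("self", random_protein(120))
  fit <- psisearch(q, list(q), n_iterations = 10)
  expect_true(fit$converged)
  expect_lte(length(fit$iterations), 3L)
  expect_equal(fit$iterations[[1]]$included, "self")
  last <- fit$iterations[[length(fit$iterations)]]
  expect_equal(last$included, "self")
})

test_that("an easy family is fully recovered without decoys", {
  db <- generate_database(family_spec(
    domains = c(F = 110),
    families = list(F = list(size = 20, identity = 60)),
    n_decoys = 200, rng_seed = 52))
  q <- protein_seq("anc", db$ancestors[["F"]])
  fit <- psisearch(q, db$db, n_iterations = 4)
  fam <- db$truth$members$F
  found_iter <- NA_integer_
  for (it in fit$iterations) {
    if (all(fam %in% it$included)) { found_iter <- it$iteration; break }
  }
  expect_lte(found_iter, 2L)
  for (it in fit$iterations)
    expect_length(grep("^decoy", it$included), 0L)
})

test_that("identical configuration and seeds reproduce bit-identical runs", {
  db <- generate_database(family_spec(
    domains = c(F = 90),
    families = list(F = list(size = 10, identity = c(45, 70))),
    n_decoys = 50, rng_seed = 53))
  q <- protein_seq("anc", db$ancestors[["F"]])
  f1 <- psisearch(q, db$db, n_iterations = 4,
                  gapfill = gapfill_policy("random_fill", rng_seed = 9))
  f2 <- psisearch(q, db$db, n_iterations = 4,
                  gapfill = gapfill_policy("random_fill", rng_seed = 9))
  expect_equal(length(f1$iterations), length(f2$iterations))
  for (i in seq_along(f1$iterations))
    expect_identical(f1$iterations[[i]]$hits, f2$iterations[[i]]$hits)
})

test_that("included sets derive from the previous iteration without lookahead", {
  db <- generate_database(family_spec(
    domains = c(F = 100),
    families = list(F = list(size = 12, identity = c(40, 70))),
    n_decoys = 60, rng_seed = 54))
  q <- protein_seq("anc", db$ancestors[["F"]])
  fit <- psisearch(q, db$db, n_iterations = 5)
  for (it in fit$iterations) {
    expect_true(all(it$included %in% it$hits$subject_id))
    evs <- it$hits$evalue[match(it$included, it$hits$subject_id)]
    expect_true(all(evs <= fit$config$inclusion_evalue))
  }
  # once converged, no further iterations run
  if (fit$converged)
    expect_true(fit$iterations[[length(fit$iterations)]]$converged)
  expect_lte(length(fit$iterations), 5L)
})

test_that("model methods expose the fitted profile", {
  db <- generate_database(family_spec(
    domains = c(F = 90),
    families = list(F = list(size = 8, identity = 65)),
    n_decoys = 30, rng_seed = 55))
  q <- protein_seq("anc", db$ancestors[["F"]])
  fit <- psisearch(q, db$db, n_iterations = 3)
  expect_s3_class(fit, "psisearch")
  expect_output(print(fit), "iterations run")
  sm <- summary(fit)
  expect_output(print(sm), "psisearch run")
  expect_equal(nrow(coef(fit)), length(q))
  pred <- predict(fit, db$db[db$truth$members$F[1:3]], evalue_max = 0.01)
  expect_true(all(db$truth$members$F[1:3] %in% pred$subject_id))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("run outputs round-trip through the on-disk formats", {
  db <- generate_database(family_spec(
    domains = c(F = 80),
    families = list(F = list(size = 6, identity = 70)),
    n_decoys = 20, rng_seed = 56))
  q <- protein_seq("anc", db$ancestors[["F"]])
  fit <- psisearch(q, db$db, n_iterations = 3)
  dir <- withr::local_tempdir()
  write_run(fit, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  h1 <- file.path(dir, "hits.iter1.tsv")
  expect_true(file.exists(h1))
  back <- read_tabular_hits(h1)
  expect_equal(back$subject_id, fit$iterations[[1]]$hits$subject_id)
  expect_equal(back$btop, fit$iterations[[1]]$hits$btop)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$query, "anc")
  if (length(fit$iterations) > 1L) {
    pf <- file.path(dir, sprintf("pssm.iter%d.tsv", 2L))
    expect_true(file.exists(pf))
    p <- read_pssm(pf)
    expect_identical(p$scores, fit$iterations[[2]]$pssm$scores)
    mf <- file.path(dir, sprintf("msa.iter%d.afa", 2L))
    msa_back <- read_fasta(mf)
    expect_equal(names(msa_back)[1], "anc")
  }
})

test_that("stringent inclusion thresholds propagate to the included set", {
  db <- generate_database(family_spec(
    domains = c(F = 100),
    families = list(F = list(size = 12, identity = c(40, 70))),
    n_decoys = 60, rng_seed = 57))
  q <- protein_seq("anc", db$ancestors[["F"]])
  loose <- psisearch(q, db$db, n_iterations = 2, inclusion_evalue = 0.002)
  strict <- psisearch(q, db$db, n_iterations = 2,
                      inclusion_evalue = 0.0001)
  expect_equal(strict$config$inclusion_evalue, 0.0001)
  expect_true(all(strict$iterations[[1]]$included %in%
                    loose$iterations[[1]]$included))
  evs <- strict$iterations[[1]]$hits$evalue[
    match(strict$iterations[[1]]$included,
          strict$iterations[[1]]$hits$subject_id)]
  expect_true(all(evs <= 0.0001))
})
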