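# Evaluation metrics: unit values, canonical-form identity, permutation
# invariance, monotonicity, and report assembly.

test_that("validity counts RDKit-parseable strings", {
  expect_equal(validity(c("CCO", "C1CC1", "C(")), 66.67)
  expect_equal(validity(shared_fixture_corpus(200)), 100)
  expect_warning(v0 <- validity(character(0)), "empty")
  expect_identical(v0, 0)
})

test_that("novelty is membership of canonical forms in the training set", {
  expect_equal(novelty(c("CCO", "CCN"), c("CCO", "CCN", "CCC")), 0)
  expect_equal(novelty(c("CCO", "CCN"), c("c1ccccc1")), 100)
  # alias detection: same molecule written differently is not novel
  expect_equal(novelty("OCC", "CCO"), 0)
  # invalid generated strings are excluded before the ratio
  expect_equal(novelty(c("CCO", "C("), "CCN"), 100)
})

test_that("diversity is the unique fraction of canonical forms", {
  expect_equal(diversity(c("CCO", "CCO", "CCN")), 66.67)
  expect_equal(diversity(rep("CCO", 4)), 25)
  expect_equal(diversity(c("CCO", "OCC")), 50)  # canonical duplicates
  corpus <- shared_fixture_corpus(100)
  expect_equal(diversity(corpus), 100)
})

test_that("metrics are permutation invariant and novelty is monotone", {
  gen <- c("CCO", "CCN", "C1CC1", "C(", "CCC")
  train <- c("CCN", "CCCC")
  set.seed(9)
  perm <- sample(length(gen))
  expect_identical(validity(gen), validity(gen[perm]))
  expect_identical(diversity(gen), diversity(gen[perm]))
  expect_identical(novelty(gen, train), novelty(gen[perm], train))
  # appending a training molecule cannot increase novelty
  expect_lte(novelty(c(gen, train[1]), train), novelty(gen, train))
})

test_that("property statistics cover valid molecules only", {
  ps <- property_stats(c("CCO", "C1CC1", "C("))
  expect_identical(ps$n_valid, 2L)
  expect_true(ps$qed_mean > 0 && ps$qed_mean < 1)
  expect_true(ps$sas_mean > 0 && ps$sas_mean < 10)

  single <- property_stats("CCO")
  expect_identical(single$qed_sd, 0)
  expect_identical(single$sas_sd, 0)
  dup <- property_stats(rep("CCO", 5))
  expect_equal(dup$qed_mean, single$qed_mean)
  expect_identical(dup$qed_sd, 0)

  expect_error(property_stats(c("C(", "")), "no valid")
})

test_that("cross-dataset novelty reports one row per corpus", {
  gen <- c("CCO", "CCN")
  tab <- cross_dataset_novelty(gen, list(
    self = gen, other = "c1ccccc1", empty = character(0)))
  expect_identical(tab$corpus, c("self", "other", "empty"))
  expect_equal(tab$novelty_pct, c(0, 100, 100))
  expect_equal(tab$novelty_pct[tab$corpus == "self"], novelty(gen, gen))
})

test_that("evaluate assembles a coherent report", {
  gen <- c("CCO", "CCO", "CCN", "C(")
  train <- c("CCN", "CCC")
  rep <- evaluate(gen, train, n_expected = 4L)
  expect_s3_class(rep, "metrics_report")
  expect_identical(rep$n_generated, 4L)
  expect_identical(rep$n_valid, 3L)
  expect_true(rep$validity_pct >= 0 && rep$validity_pct <= 100)
  expect_true(rep$novelty_pct >= 0 && rep$novelty_pct <= 100)
  expect_true(rep$diversity_pct >= 0 && rep$diversity_pct <= 100)
  expect_true(rep$qed_mean >= 0 && rep$qed_mean <= 1)
  expect_true(rep$sas_mean >= 0 && rep$sas_mean <= 10)

  td <- tidy(rep)
  expect_identical(nrow(td), 1L)
  expect_identical(td$n_valid, 3L)

  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_metrics_report(rep, json = json, csv = csv)
  back <- jsonlite::read_json(json)
  expect_equal(back$validity_pct, rep$validity_pct)
  header <- names(utils::read.csv(csv, check.names = FALSE))
  expect_identical(header, c("QED", "SAS", "Validity", "Diversity", "Novelty"))
})

test_that("fixture panel properties are reproducible against pinned values", {
  # regression pins from the reference scorer (RDKit QED / SA score)
  p <- mol_properties(c("CCO", "c1ccccc1", "CC(C)Cc1ccccc1"))
  expect_equal(p$qed, c(0.4068080, 0.4426284, 0.5830951), tolerance = 1e-6)
  expect_equal(p$sas, c(1.9802570, 1.0000000, 1.1995611), tolerance = 1e-6)
})
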