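test_that("fingerprints are deterministic and fail loudly on bad structures", {
  lib <- fixture_library()
  again <- suppressWarnings(fingerprint_compounds(make_compound_library()))
  expect_identical(lib$fingerprint, again$fingerprint)
  expect_identical(lib$canonical_smiles, again$canonical_smiles)
  # cyclohexane matches at least the alkane keys
  chx <- suppressWarnings(fingerprint_compounds(
    tibble::tibble(id = "chx", smiles = "C1CCCCC1")))
  expect_gt(length(chx$fingerprint[[1]]), 0)
  expect_error(
    suppressWarnings(fingerprint_compounds(
      tibble::tibble(id = "bad", smiles = "not_a_molecule"))),
    "bad")
})

test_that("tanimoto agrees with set arithmetic and is symmetric", {
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(1:4, 1:4), 1)
  expect_equal(tanimoto(1:3, 7:9), 0)
  expect_error(tanimoto(integer(0), integer(0)), "undefined")

  set.seed(42)
  for (k in 1:50) {
    a <- sample(30, sample(0:12, 1))
    b <- sample(30, sample(1:12, 1))
    if (length(a) == 0 && length(b) == 0) next
    expect_equal(tanimoto(a, b), tanimoto_bits(30, a, b))
    expect_equal(tanimoto(a, b), tanimoto(b, a))
  }
})

test_that("analog pairing excludes identical structures and respects the threshold", {
  pairs <- find_analog_pairs(fixture_drugs(), fixture_metabolites())
  # homolog analogs are found
  expect_true(any(pairs$drug_id == "drug_syn" &
                    pairs$metabolite_id == "C90001"))
  # drug_same is octanoic acid = metabolite C90001: excluded despite score 1
  expect_false(any(pairs$drug_id == "drug_same" &
                     pairs$metabolite_id == "C90001"))
  # unrelated scaffold scores low and is excluded
  expect_false("drug_far" %in% pairs$drug_id)
  expect_true(all(pairs$tanimoto > 0.9))
  # sorted by descending score
  expect_true(all(diff(pairs$tanimoto) <= 0))
})

test_that("lowering the pairing threshold never removes pairs", {
  d <- fixture_drugs()
  m <- fixture_metabolites()
  hi <- find_analog_pairs(d, m, threshold = 0.9)
  lo <- find_analog_pairs(d, m, threshold = 0.4)
  key <- function(p) paste(p$drug_id, p$metabolite_id)
  expect_true(all(key(hi) %in% key(lo)))
  expect_gte(nrow(lo), nrow(hi))
  # empty inputs give an empty result, not an error
  expect_identical(nrow(find_analog_pairs(d[0, ], m)), 0L)
})

test_that("shared-target stats exclude unannotated pairs from the denominator", {
  pairs <- tibble::tibble(
    drug_id = paste0("d", 1:4),
    metabolite_id = paste0("m", 1:4),
    tanimoto = 1,
    shared_targets = c(1L, 0L, NA_integer_, 2L)
  )
  st <- shared_target_stats(pairs)
  expect_identical(st$n_pairs, 4L)
  expect_identical(st$n_annotated, 3L)
  expect_identical(st$n_shared, 2L)
  expect_equal(st$fraction, 2 / 3)
  expect_equal(st$histogram$count, c(1L, 1L, 0L, 0L))

  # worked fraction: 10 annotated, 4 sharing
  p2 <- tibble::tibble(drug_id = letters[1:10], metabolite_id = letters[1:10],
                       tanimoto = 1,
                       shared_targets = c(rep(1L, 4), rep(0L, 6)))
  expect_equal(shared_target_stats(p2)$fraction, 0.4)
})

test_that("EC matching is exact at 4 levels with dash wildcards", {
  pairs <- find_analog_pairs(
    tibble::tibble(id = "d", smiles = "x", fingerprint = list(1:3),
                   canonical_smiles = "d", ecs = list("1.1.1.-")),
    tibble::tibble(id = "m", smiles = "y", fingerprint = list(1:3),
                   canonical_smiles = "m", ecs = list(c("1.1.1.42", "2.7.1.1")))
  )
  expect_identical(pairs$shared_targets, 1L)
})

test_that("bootstrap null is seeded, sized, and saturates on an all-sharing library", {
  d <- fixture_drugs()
  m <- fixture_metabolites()
  b1 <- bootstrap_null(d, m, n_pairs = 200, reps = 3, seed = 9)
  b2 <- bootstrap_null(d, m, n_pairs = 200, reps = 3, seed = 9)
  expect_identical(b1, b2)
  expect_length(b1, 3)
  expect_true(all(b1 >= 0 & b1 <= 1))
  expect_error(bootstrap_null(d, m, n_pairs = 0, reps = 3), ">= 1")

  # every drug shares an EC with every metabolite -> every fraction is 1
  allshare_d <- tibble::tibble(id = c("d1", "d2"),
                               ecs = list("1.1.1.1", "1.1.1.1"))
  allshare_m <- tibble::tibble(id = c("m1", "m2"),
                               ecs = list("1.1.1.1", c("1.1.1.1", "9.9.9.9")))
  expect_equal(bootstrap_null(allshare_d, allshare_m, n_pairs = 50,
                              reps = 4, seed = 1),
               rep(1, 4))
})

test_that("bootstrap mean tracks the analytic collision rate on planted annotations", {
  # 4 drugs x 4 metabolites; exactly 4 of the 16 pairings share a target
  d <- tibble::tibble(id = paste0("d", 1:4),
                      ecs = list("1.1.1.1", "2.2.2.2", "3.3.3.3", "4.4.4.4"))
  m <- tibble::tibble(id = paste0("m", 1:4),
                      ecs = list("1.1.1.1", "2.2.2.2", "3.3.3.3", "4.4.4.4"))
  fr <- bootstrap_null(d, m, n_pairs = 2000, reps = 50, seed = 3)
  expect_equal(mean(fr), 4 / 16, tolerance = 0.05)
})

test_that("Fisher enrichment matches full hypergeometric enumeration", {
  # symmetric table
  r <- fisher_enrichment(5, 5, 5, 5)
  expect_equal(r$sample_odds_ratio, 1)
  expect_equal(r$p_value, 1)
  # perfectly separated table
  r2 <- fisher_enrichment(10, 0, 0, 10)
  expect_identical(r2$sample_odds_ratio, Inf)
  expect_equal(r2$p_value, fisher_p_enum(10, 0, 0, 10))
  # worked example
  r3 <- fisher_enrichment(6, 2, 1, 7)
  expect_equal(r3$p_value, fisher_p_enum(6, 2, 1, 7))

  # random tables with margins <= 30
  set.seed(7)
  for (k in 1:40) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c <- sample(0:12, 1); d <- sample(0:12, 1)
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    expect_equal(fisher_enrichment(a, b, c, d)$p_value,
                 fisher_p_enum(a, b, c, d), tolerance = 1e-10)
  }
  expect_error(fisher_enrichment(0, 0, 3, 4), "margin")
})

test_that("tidy and glance expose the enrichment estimates", {
  td <- tidy(fisher_enrichment(6, 2, 1, 7))
  expect_true(all(c("estimate", "sample_odds_ratio", "p.value")
                  %in% names(td)))
  expect_identical(nrow(td), 1L)
})
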