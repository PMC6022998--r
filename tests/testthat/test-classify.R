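cfg <- default_config()

test_that("the decision tree follows the stated rules on canonical cases", {
  el_long <- fake_element(len = 8000L)
  el_short <- fake_element(len = 1500L)

  r <- classify_element(el_long, list(RT = fake_hit("RT", "RLG", "Del")), cfg)
  expect_equal(r$category, "GYPSY")
  expect_equal(r$lineage, "Del")

  r <- classify_element(el_long, list(RT = fake_hit("RT", "RLC", "Tork")), cfg)
  expect_equal(r$category, "COPIA")

  expect_equal(classify_element(el_short, list(), cfg)$category, "TRIM")
  el_2000 <- fake_element(len = 2000L)
  expect_equal(classify_element(el_2000, list(), cfg)$category, "LARD")
  el_1999 <- fake_element(len = 1999L)
  expect_equal(classify_element(el_1999, list(), cfg)$category, "TRIM")

  r <- classify_element(el_long, list(GAG = fake_hit("GAG", "RLG")), cfg)
  expect_equal(r$category, "TR_GAG")
  expect_equal(r$lineage, "NONE")
  r <- classify_element(el_long, list(GAG = fake_hit("GAG", "RLG"),
                                      AP = fake_hit("AP", "RLG")), cfg)
  expect_equal(r$category, "TR_GAG")

  r <- classify_element(el_long, list(RT = fake_hit("RT", "RLG", "Del"),
                                      INT = fake_hit("INT", "RLC", "Tork")),
                        cfg)
  expect_equal(r$category, "NO_CLASS")
  expect_match(r$evidence$rule_fired, "chimeric")

  expect_equal(classify_element(el_long, list(ENV = fake_hit("ENV", "RLC")),
                                cfg)$category, "NO_CLASS")
  expect_equal(classify_element(el_long, list(AP = fake_hit("AP", "RLG")),
                                cfg)$category, "NO_CLASS")
})

test_that("pol domains without an RLC/RLG keyword are not autonomous", {
  el <- fake_element(len = 5000L)
  r <- classify_element(el, list(RT = fake_hit("RT", "NONE")), cfg)
  expect_equal(r$category, "NO_CLASS")
})

test_that("lineage comes from RT, else INT/RNaseH majority, else top score", {
  expect_equal(assign_lineage(list(RT = fake_hit("RT", "RLG", "Del"),
                                   INT = fake_hit("INT", "RLG", "CRM"))),
               "Del")
  expect_equal(assign_lineage(list(INT = fake_hit("INT", "RLC", "Tork"),
                                   RNASEH = fake_hit("RNASEH", "RLC",
                                                     "Tork"))),
               "Tork")
  expect_equal(assign_lineage(list(
    INT = fake_hit("INT", "RLC", "Tork", score = 50),
    RNASEH = fake_hit("RNASEH", "RLC", "SIRE", score = 70))), "SIRE")
  expect_equal(assign_lineage(list(GAG = fake_hit("GAG", "RLG", "Del"))),
               "NONE")
})

test_that("non-autonomous results never carry a lineage", {
  el <- fake_element(len = 1000L)
  for (hits in list(list(), list(GAG = fake_hit("GAG", "RLG", "Del")))) {
    r <- classify_element(el, hits, cfg)
    expect_true(r$category %in% c("TRIM", "TR_GAG"))
    expect_equal(r$lineage, "NONE")
  }
})

make_reclass_pair <- function(query, donor, donor_cat = "GYPSY",
                              donor_lin = "Del") {
  seqs <- c(q = query, d = donor)
  results <- list(
    classification_result("q", "NO_CLASS", "NONE"),
    classification_result("d", donor_cat, donor_lin))
  reclassify_80_80_80(results, seqs, default_config())[[1]]
}

test_that("a near-identical full-length mutant is rescued by 80/80/80", {
  set.seed(8)
  donor <- random_nt_str(3000)
  query <- mutate_exact(donor, 240, seed = 9)  # 92% identical, full length
  r <- make_reclass_pair(query, donor)
  expect_equal(r$category, "GYPSY")
  expect_equal(r$lineage, "Del")
  expect_equal(r$reclassified_from$donor_element_id, "d")
  expect_gte(r$reclassified_from$identity_pct, 80)
  expect_gte(r$reclassified_from$coverage_pct, 80)
  expect_gte(r$reclassified_from$aligned_bp, 80)
})

test_that("failing any one of the three thresholds blocks the rescue", {
  set.seed(12)
  donor <- random_nt_str(1000)
  # identity just under 80% at full coverage: evenly spaced mismatches
  query_low_id <- mutate_exact(donor, 205, spacing = 4L)
  expect_equal(make_reclass_pair(query_low_id, donor)$category, "NO_CLASS")

  # high identity but < 80 aligned bases: 79-bp exact sub-element
  q79 <- substr(donor, 101, 179)
  expect_equal(make_reclass_pair(q79, donor)$category, "NO_CLASS")
  q80 <- substr(donor, 101, 180)
  expect_equal(make_reclass_pair(q80, donor)$category, "GYPSY")
})

test_that("reclassification is idempotent and donor-order independent", {
  set.seed(13)
  donor_a <- random_nt_str(2000)
  donor_b <- random_nt_str(2000)
  query <- mutate_exact(donor_a, 100, seed = 14)
  seqs <- c(q = query, a = donor_a, b = donor_b)
  res <- list(classification_result("q", "NO_CLASS", "NONE"),
              classification_result("a", "GYPSY", "Del"),
              classification_result("b", "COPIA", "Tork"))
  once <- reclassify_80_80_80(res, seqs, cfg)
  twice <- reclassify_80_80_80(once, seqs, cfg)
  expect_equal(once, twice)
  flipped <- reclassify_80_80_80(res[c(1, 3, 2)], seqs, cfg)
  expect_equal(once[[1]], flipped[[1]])
  expect_equal(once[[1]]$category, "GYPSY")
})

test_that("an empty donor set is a warning no-op", {
  res <- list(classification_result("q", "NO_CLASS", "NONE"))
  expect_warning(out <- reclassify_80_80_80(res, c(q = "ACGTACGT"), cfg),
                 "donor")
  expect_equal(out[[1]]$category, "NO_CLASS")
})
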