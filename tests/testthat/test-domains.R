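test_that("reference headers parse into domain/superfamily/lineage/family", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">RT_RLG_Del_Peabody", "MKVLAWHEML",
               ">INT_RLC_Tork_X", "MKVLAWHEML",
               ">GAG", "MKVLAWHEML"), f)
  lib <- load_reference_library(f)
  expect_equal(lib[[1]]$domain_kind, "RT")
  expect_equal(lib[[1]]$superfamily_code, "RLG")
  expect_equal(lib[[1]]$lineage, "Del")
  expect_equal(lib[[1]]$family, "Peabody")
  expect_equal(lib[[2]]$domain_kind, "INT")
  expect_equal(lib[[2]]$lineage, "Tork")
  expect_equal(lib[[3]], structure(
    list(ref_id = "GAG", domain_kind = "GAG", superfamily_code = "NONE",
         lineage = "NONE", family = "NONE", aa_seq = "MKVLAWHEML"),
    class = "reference_domain"))

  writeLines(c(">FOO_RLG_A_B", "MKVL"), f)
  expect_error(load_reference_library(f), "FOO_RLG_A_B")
  writeLines(c(">RT_XXX_A_B", "MKVL"), f)
  expect_error(load_reference_library(f), "superfamily")
})

test_that("an embedded reference domain is found on the forward strand", {
  lib <- tiny_library()
  rt <- lib[[which(vapply(lib, function(r)
    r$domain_kind == "RT" && r$lineage == "Del", logical(1)))[1]]]
  set.seed(3)
  insert <- ltrcraft:::back_translate(rt$aa_seq)
  el <- predictor_record(
    "fwd", paste0(random_nt_str(300), insert, random_nt_str(300)),
    ltr5_seq = "", ltr3_seq = "", ltr_identity = 100)
  hits <- scan_domains(el, lib)
  rt_hits <- Filter(function(h) h$domain_kind == "RT", hits)
  expect_gte(length(rt_hits), 1L)
  h <- rt_hits[[1]]
  expect_equal(h$superfamily_code, "RLG")
  expect_equal(h$lineage, "Del")
  expect_gt(h$frame, 0L)
  expect_lte(h$element_nt_start, 300 + 2)
  expect_gte(h$element_nt_end, 300 + nchar(insert) - 2)
  expect_equal((h$element_nt_end - h$element_nt_start) %% 3, 0)
})

test_that("a reverse-complemented insert is found on a negative frame", {
  lib <- tiny_library()
  rt <- lib[[which(vapply(lib, function(r)
    r$domain_kind == "RT" && r$lineage == "Del", logical(1)))[1]]]
  set.seed(4)
  insert <- ltrcraft:::back_translate(rt$aa_seq)
  flank5 <- random_nt_str(311)  # off-phase flank: frame must not matter
  el_fwd <- predictor_record(
    "fwd", paste0(flank5, insert, random_nt_str(300)),
    ltr5_seq = "", ltr3_seq = "", ltr_identity = 100)
  el_rev <- predictor_record(
    "rev", paste0(flank5, revcomp(insert), random_nt_str(300)),
    ltr5_seq = "", ltr3_seq = "", ltr_identity = 100)
  h_fwd <- best_hit_per_domain(scan_domains(el_fwd, lib))$RT
  h_rev <- best_hit_per_domain(scan_domains(el_rev, lib))$RT
  expect_lt(h_rev$frame, 0L)
  expect_equal(h_rev$aa_alignment$identity_pct,
               h_fwd$aa_alignment$identity_pct)
  expect_equal(h_rev$score, h_fwd$score)
  # the negative-frame span still covers the insert in forward coordinates
  expect_lte(h_rev$element_nt_start, 311 + 2)
  expect_gte(h_rev$element_nt_end, 311 + nchar(insert) - 2)
})

test_that("random sequence yields no hits at the 1e-4 cutoff", {
  lib <- make_reference_library(c(Del = "RLG", Tork = "RLC"), seed = 99)
  n_clean <- 0L
  for (s in 1:25) {
    set.seed(1000 + s)
    el <- predictor_record(paste0("rand", s), random_nt_str(10000),
                           ltr5_seq = "", ltr3_seq = "", ltr_identity = 100)
    if (length(scan_domains(el, lib)) == 0L) n_clean <- n_clean + 1L
  }
  expect_gte(n_clean, ceiling(0.95 * 25))
})

test_that("best_hit_per_domain keeps max score with deterministic ties", {
  h1 <- fake_hit("RT", "RLG", "Del", score = 90)
  h2 <- fake_hit("RT", "RLG", "Reina", score = 80)
  expect_equal(best_hit_per_domain(list(h1, h2))$RT$lineage, "Del")
  expect_equal(best_hit_per_domain(list()), list())

  # exact tie: broken by start then ref_id, independent of input order
  t1 <- fake_hit("INT", "RLC", "Tork", score = 50, start = 10L)
  t2 <- fake_hit("INT", "RLC", "Oryco", score = 50, start = 10L)
  t3 <- fake_hit("INT", "RLC", "SIRE", score = 50, start = 5L)
  perms <- list(list(t1, t2, t3), list(t3, t2, t1), list(t2, t1, t3))
  picks <- vapply(perms, function(p)
    best_hit_per_domain(p)$INT$lineage, character(1))
  expect_equal(unique(picks), "SIRE")  # smallest start wins
})

test_that("scan output is invariant to library ordering", {
  lib <- tiny_library()
  sim <- simulate_element(element_spec("GYPSY", "Del", rng_seed = 21), lib,
                          "e1")
  h1 <- scan_domains(sim$record, lib)
  h2 <- scan_domains(sim$record, rev(lib))
  expect_equal(h1, h2)
})

test_that("a stored hit span recomputes to its stored score", {
  lib <- tiny_library()
  sim <- simulate_element(element_spec("GYPSY", "Del", rng_seed = 22), lib,
                          "e1")
  hits <- scan_domains(sim$record, lib)
  refs <- stats::setNames(lapply(lib, `[[`, "aa_seq"),
                          vapply(lib, `[[`, character(1), "ref_id"))
  scheme <- scoring_scheme("protein", gap_open = 11, gap_extend = 2)
  for (h in hits[1:min(3, length(hits))]) {
    sub <- substr(sim$record$full_seq, h$element_nt_start + 1L,
                  h$element_nt_end)
    if (h$frame < 0L) sub <- revcomp(sub)
    aa <- translate_frame(sub, 1L)
    re <- local_align(aa, refs[[h$ref_id]], scheme)[[1]]
    expect_equal(re$score, h$score)
  }
})
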