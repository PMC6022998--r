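test_that("FASTA reading parses ids, descriptions and multi-line records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "a")
  expect_equal(recs[[1]]$seq, "ACGT")

  writeLines(c(">a", "AC", "GT", ">b some description", "NNNN"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$seq, "ACGT")
  expect_equal(recs[[2]]$description, "some description")
  expect_equal(recs[[2]]$seq, "NNNN")
})

test_that("FASTA reading rejects duplicates, empty records, non-FASTA", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">a", "ACGT", ">b", ">c", "GG"), f)
  expect_error(read_fasta(f), "empty")
  writeLines(c("ACGT"), f)
  expect_error(read_fasta(f), "FASTA")
})

test_that("alphabet handling masks to N by default and rejects when strict", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgtRYacgt"), f)
  expect_equal(read_fasta(f)[[1]]$seq, "ACGTNNACGT")
  expect_error(read_fasta(f, strict = TRUE), "alphabet")
})

test_that("FASTA round-trips are lossless on random fixtures", {
  set.seed(11)
  f <- withr::local_tempfile(fileext = ".fasta")
  for (rep in 1:5) {
    recs <- lapply(seq_len(sample(1:6, 1)), function(i)
      list(id = sprintf("rec%d_%d", rep, i),
           description = sample(c("", "desc text"), 1),
           seq = random_nt_str(sample(1:200, 1))))
    write_fasta(recs, f, line_width = 17L)
    back <- read_fasta(f)
    expect_equal(back, recs)
  }
})

test_that("FASTA writing rejects whitespace ids and warns on empty input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  expect_error(write_fasta(list(list(id = "a b", description = "",
                                     seq = "ACGT")), f), "whitespace")
  expect_warning(write_fasta(list(), f), "empty")
  expect_true(file.exists(f))
  expect_equal(file.size(f), 0)
})

test_that("predictor report round-trips the generator output", {
  lib <- tiny_library()
  recs <- lapply(1:3, function(i)
    simulate_element(element_spec("GYPSY", "Del", age_my = i / 2,
                                  rng_seed = i), lib,
                     sprintf("e%d", i))$record)
  f <- withr::local_tempfile(fileext = ".txt")
  emit_predictor_report(recs, f)
  back <- parse_predictor_report(f)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$element_id, recs[[i]]$element_id)
    expect_equal(back[[i]]$full_seq, recs[[i]]$full_seq)
    expect_equal(back[[i]]$ltr5_seq, recs[[i]]$ltr5_seq)
    expect_equal(back[[i]]$ltr3_seq, recs[[i]]$ltr3_seq)
    expect_equal(back[[i]]$ltr_identity, recs[[i]]$ltr_identity)
  }
})

test_that("malformed predictor records are rejected with clear errors", {
  expect_error(
    predictor_record("e", "ACGTACGT", "ACGT", "ACGT", ltr_identity = 101),
    "MalformedRecord.*\\[0, 100\\]")
  expect_error(
    predictor_record("e", "ACGTACGT", "ACGT", "ACGT", ltr_identity = 99,
                     element_length = 7L),
    "MalformedRecord.*LENGTH")
  expect_error(
    predictor_record("e", "ACGTACGT", "CGTA", "ACGT", ltr_identity = 99),
    "MalformedRecord.*prefix")
  expect_error(
    predictor_record("e", "ACGTACGT", "ACGT", "TACG", ltr_identity = 99),
    "MalformedRecord.*suffix")
})

test_that("config parsing applies defaults, overrides and strict errors", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(character(0), f)
  cfg <- parse_config(f)
  expect_equal(cfg$substitution_rate, 1.3e-8)
  expect_equal(cfg$trim_lard_cutoff_bp, 2000)
  expect_equal(cfg$evalue_cutoff, 1e-4)
  expect_equal(cfg$rt_min_aa_element, 200)
  expect_equal(cfg$rt_min_aa_genome, 150)
  expect_equal(cfg$bin_width_my, 0.5)

  writeLines(c("# a comment", "substitution_rate = 6.5e-9",
               "apply_808080 = false"), f)
  cfg <- parse_config(f)
  expect_equal(cfg$substitution_rate, 6.5e-9)
  expect_false(cfg$apply_808080)

  writeLines("trim_lard_cutoff_bp = abc", f)
  expect_error(parse_config(f), "trim_lard_cutoff_bp")
  writeLines("no_such_key = 1", f)
  expect_error(parse_config(f), "no_such_key")
})

test_that("tabular writer emits a header even for zero rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tabular(data.frame(a = character(), b = numeric()), f)
  expect_equal(readLines(f), "a\tb")
})

test_that("newick output re-parses to the same tree", {
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick("(a:0.1,b:0.2);", f)
  t1 <- ape::read.tree(f)
  expect_setequal(t1$tip.label, c("a", "b"))
  expect_equal(sort(t1$edge.length), c(0.1, 0.2))

  tr <- ape::unroot(ape::rtree(6))
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_equal(as.numeric(ape::dist.topo(tr, back)), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-8)
})
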