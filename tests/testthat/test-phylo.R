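test_that("RT extraction translates the hit span and applies strict filters", {
  cfg <- default_config()
  for (case in list(list(n = 199L, ok = FALSE), list(n = 200L, ok = FALSE),
                    list(n = 201L, ok = TRUE))) {
    set.seed(case$n)
    aa <- random_aa_str(case$n)
    nt <- ltrcraft:::back_translate(aa)
    el <- predictor_record("e", nt, "", "", 100)
    hit <- fake_hit("RT", "RLG", "Del")
    hit$element_nt_start <- 0L
    hit$element_nt_end <- nchar(nt)
    res <- extract_rt(el, hit, cfg, mode = "element")
    expect_equal(res$accepted, case$ok, label = paste("element mode", case$n))
    if (res$accepted) {
      expect_equal(res$aa_seq, aa)
      expect_equal(res$length_aa, case$n)
      expect_equal(res$lineage_label, "Del")
    }
  }
  for (case in list(list(n = 149L, ok = FALSE), list(n = 150L, ok = FALSE),
                    list(n = 151L, ok = TRUE))) {
    set.seed(case$n)
    nt <- ltrcraft:::back_translate(random_aa_str(case$n))
    el <- predictor_record("e", nt, "", "", 100)
    hit <- fake_hit("RT", "RLG", "Del")
    hit$element_nt_start <- 0L
    hit$element_nt_end <- nchar(nt)
    res <- extract_rt(el, hit, cfg, mode = "genome")
    expect_equal(res$accepted, case$ok, label = paste("genome mode", case$n))
  }
})

test_that("an internal stop truncates the RT peptide", {
  set.seed(51)
  aa_long <- random_aa_str(250)
  nt <- ltrcraft:::back_translate(aa_long)
  # insert a stop codon after residue 220: 220 aa remain -> still kept
  nt_stop <- paste0(substr(nt, 1, 660), "TAA", substr(nt, 664, nchar(nt)))
  el <- predictor_record("e", nt_stop, "", "", 100)
  hit <- fake_hit("RT", "RLG", "Del")
  hit$element_nt_start <- 0L
  hit$element_nt_end <- nchar(nt_stop)
  res <- extract_rt(el, hit, default_config(), mode = "element")
  expect_true(res$accepted)
  expect_equal(res$length_aa, 220L)
  # a stop after residue 100 leaves too little
  nt_early <- paste0(substr(nt, 1, 300), "TAA", substr(nt, 304, nchar(nt)))
  el2 <- predictor_record("e", nt_early, "", "", 100)
  hit$element_nt_end <- nchar(nt_early)
  res2 <- extract_rt(el2, hit, default_config(), mode = "element")
  expect_false(res2$accepted)
  expect_match(res2$reason, "stop")
})

test_that("reverse-strand RT hits translate through the forward span", {
  lib <- tiny_library()
  rt_ref <- Filter(function(r) r$domain_kind == "RT" && r$lineage == "Del",
                   lib)[[1]]
  set.seed(52)
  insert <- revcomp(ltrcraft:::back_translate(rt_ref$aa_seq))
  el <- predictor_record("e", paste0(random_nt_str(200), insert,
                                     random_nt_str(200)), "", "", 100)
  best <- best_hit_per_domain(scan_domains(el, lib))
  res <- extract_rt(el, best$RT, default_config())
  expect_true(res$accepted)
  expect_lt(res$source_frame, 0L)
  expect_gte(res$length_aa, 201L)
  expect_true(grepl(substr(res$aa_seq, 10, 50), rt_ref$aa_seq, fixed = TRUE))
})

test_that("progressive MSA degaps to its inputs and gaps single insertions", {
  two <- c(a = "MKVLAWHEML", b = "MKVLAWHEML")
  msa <- progressive_msa(two)
  expect_equal(dim(msa), c(2L, 10L))
  expect_false(any(msa == "-"))

  set.seed(60)
  base <- random_aa_str(60)
  ins <- paste0(substr(base, 1, 30), "WWWWW", substr(base, 31, 60))
  seqs <- c(s1 = base, s2 = base, s3 = ins)
  msa <- progressive_msa(seqs)
  expect_equal(ncol(msa), 65L)
  expect_gte(ncol(msa), max(nchar(seqs)))
  for (nm in names(seqs)) {
    expect_equal(paste(msa[nm, msa[nm, ] != "-"], collapse = ""),
                 seqs[[nm]], label = nm)
  }
  # the insertion columns are gapped in the two short rows
  expect_equal(sum(msa["s1", ] == "-"), 5L)
  expect_equal(sum(msa["s3", ] == "-"), 0L)
})

test_that("p-distances are symmetric, zero on identity, and hand-checked", {
  msa <- rbind(a = c("M", "K", "V", "L"),
               b = c("M", "K", "V", "L"),
               c = c("M", "A", "V", "-"))
  D <- distance_matrix(msa)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1 / 3)  # 3 shared columns, 1 differs
  expect_equal(D, t(D))
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
})

test_that("neighbor-joining recovers additive matrices exactly", {
  set.seed(70)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    tr <- ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1)))
    D <- ape::cophenetic.phylo(tr)
    est <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(est, tr)), 0)
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("three taxa give the closed-form star lengths", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  # x = (dab + dac - dbc)/2 etc.
  want <- c(a = (0.3 + 0.5 - 0.6) / 2, b = (0.3 + 0.6 - 0.5) / 2,
            c = (0.5 + 0.6 - 0.3) / 2)
  got <- stats::setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                         tr$tip.label)
  expect_equal(got[names(want)], want, tolerance = 1e-9)
})

test_that("equidistant taxa produce a zero-length internal branch", {
  D <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  tr <- nj_tree(D)
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_true(all(abs(internal) < 1e-12))
  expect_true(all(tr$edge.length >= 0))
})

test_that("nj_tree validates its input", {
  D <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(D), "symmetric|3 taxa")
  bad <- matrix(stats::runif(9), 3, 3)
  expect_error(nj_tree(bad), "symmetric")
})
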