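# Shared fixture builders.

tiny_library <- function(seed = 7L) {
  make_reference_library(c(Del = "RLG", Tork = "RLC"), seed = seed)
}

# a bare domain hit carrying just the fields classification needs
fake_hit <- function(kind, code, lineage = "NONE", score = 100,
                     evalue = 1e-20, start = 0L) {
  structure(list(element_id = "el", domain_kind = kind,
                 superfamily_code = code, lineage = lineage,
                 family = "NONE", ref_id = paste(kind, code, lineage,
                                                 sep = "_"),
                 score = score, evalue = evalue, frame = 1L,
                 element_nt_start = start, element_nt_end = start + 300L),
            class = "domain_hit")
}

fake_element <- function(id = "el", len = 5000L) {
  seq <- paste(rep("ACGT", ceiling(len / 4)), collapse = "")
  seq <- substr(seq, 1L, len)
  structure(list(element_id = id, full_seq = seq,
                 ltr5_seq = substr(seq, 1, 100),
                 ltr3_seq = substr(seq, len - 99L, len),
                 ltr_identity = 100, element_length = len,
                 source_tag = "fasta"), class = "predictor_record")
}

# mutate exactly k positions of a nucleotide string (deterministic given seed)
mutate_exact <- function(seq, k, seed = 1L, spacing = NULL) {
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  pos <- if (is.null(spacing)) sample(seq_along(chars), k)
         else seq.int(3L, by = spacing, length.out = k)
  alt <- c(A = "C", C = "A", G = "T", T = "G")
  chars[pos] <- alt[chars[pos]]
  paste(chars, collapse = "")
}
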