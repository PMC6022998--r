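# Translated protein-domain annotation: six-frame local search of each
# element against a lineage-labelled reference domain library.

#' Load a reference protein-domain library
#'
#' Headers follow the dialect `DOMAIN_CODE_LINEAGE_FAMILY`
#' (e.g. `RT_RLG_Del_Peabody`); trailing fields may be omitted and default to
#' `NONE` (e.g. a bare `GAG` reference). `DOMAIN` must be one of GAG, AP, RT,
#' RNASEH, INT, ENV and `CODE` one of RLC, RLG, NONE.
#'
#' @param fasta_path protein FASTA with dialect headers.
#' @return List of `reference_domain` records (`ref_id`, `domain_kind`,
#'   `superfamily_code`, `lineage`, `family`, `aa_seq`).
#' @export
load_reference_library <- function(fasta_path) {
  recs <- read_fasta(fasta_path, alphabet = "protein")
  lapply(recs, function(r) {
    tok <- strsplit(r$id, "_", fixed = TRUE)[[1]]
    if (length(tok) < 1L || !tok[1] %in% DOMAIN_KINDS)
      stop("unknown domain token in reference header: ", r$id)
    code <- if (length(tok) >= 2L) tok[2] else "NONE"
    if (!code %in% SUPERFAMILY_CODES)
      stop("unknown superfamily code in reference header: ", r$id)
    structure(list(
      ref_id = r$id,
      domain_kind = tok[1],
      superfamily_code = code,
      lineage = if (length(tok) >= 3L) tok[3] else "NONE",
      family = if (length(tok) >= 4L) paste(tok[-(1:3)], collapse = "_")
               else "NONE",
      aa_seq = r$seq), class = "reference_domain")
  })
}

#' Scan an element for protein-domain hits
#'
#' Translates the element in all six frames and locally aligns every frame
#' against every reference protein (exact Smith-Waterman; element libraries
#' are small enough that no seeding heuristic is needed). Hits at or below
#' the configured e-value cutoff are kept. The e-value search space is the
#' frame's translated length times the summed library length.
#'
#' @param element a `predictor_record` (or any list with `element_id` and
#'   `full_seq`).
#' @param library list of `reference_domain`s from
#'   [load_reference_library()].
#' @param cfg an `ltr_config`; `evalue_cutoff` is used.
#' @param scheme protein scoring scheme. The default uses stiffer gap
#'   penalties (open 11, extend 2) than the global-alignment default: the
#'   e-value model uses fixed ungapped Karlin-Altschul constants, which are
#'   only a faithful null when gaps are expensive enough to keep random
#'   local scores in the ungapped regime.
#' @return List of `domain_hit`s sorted by score (desc), then element start,
#'   then `ref_id`. Each hit records domain labels, score, e-value, frame and
#'   the forward-strand nucleotide span of the aligned region.
#' @export
scan_domains <- function(element, library, cfg = default_config(),
                         scheme = scoring_scheme("protein", gap_open = 11,
                                                 gap_extend = 2)) {
  if (length(library) == 0L) stop("reference library is empty")
  nt <- element$full_seq
  if (nchar(nt) < 3L) {
    warning("element ", element$element_id, " shorter than 3 nt; no scan")
    return(list())
  }
  frames <- six_frame(nt)
  db_len <- sum(vapply(library, function(r) nchar(r$aa_seq), numeric(1)))
  ref_set <- Biostrings::AAStringSet(vapply(library, `[[`, character(1),
                                            "aa_seq"))
  mat <- substitution_matrix(scheme)
  hits <- list()
  for (fi in seq_along(frames)) {
    aa <- frames[[fi]]
    if (nchar(aa) == 0L) next
    frame <- as.integer(names(frames)[fi])
    # score pass against the whole library first; full alignments are only
    # materialised for references that can pass the e-value cutoff
    scores <- Biostrings::pairwiseAlignment(
      ref_set, Biostrings::AAString(aa), type = "local",
      substitutionMatrix = mat, gapOpening = scheme$gap_open,
      gapExtension = scheme$gap_extend, scoreOnly = TRUE)
    for (ri in seq_along(library)) {
      ref <- library[[ri]]
      if (scores[ri] <= 0) next
      ev <- evalue(scores[ri], m = nchar(aa), n = db_len, scheme = scheme)
      if (ev > cfg$evalue_cutoff) next
      alns <- local_align(aa, ref$aa_seq, scheme = scheme, max_hits = 1L)
      if (length(alns) == 0L) next
      aln <- alns[[1]]
      ev <- evalue(aln$score, m = nchar(aa), n = db_len, scheme = scheme)
      if (ev > cfg$evalue_cutoff) next
      span <- aa_span_to_nt(aln$q_start, aln$q_end, frame, nchar(nt))
      hits[[length(hits) + 1L]] <- structure(list(
        element_id = element$element_id,
        domain_kind = ref$domain_kind,
        superfamily_code = ref$superfamily_code,
        lineage = ref$lineage,
        family = ref$family,
        ref_id = ref$ref_id,
        score = aln$score,
        evalue = ev,
        frame = frame,
        element_nt_start = span[1],
        element_nt_end = span[2],
        aa_alignment = aln), class = "domain_hit")
    }
  }
  sort_hits(hits)
}

# Map an amino-acid span on a frame translation (0-based half-open) to the
# forward-strand nucleotide span of the element.
aa_span_to_nt <- function(aa_start, aa_end, frame, nt_len) {
  off <- abs(frame) - 1L
  fstart <- off + 3L * aa_start
  fend <- off + 3L * aa_end
  if (frame > 0L) c(fstart, fend) else c(nt_len - fend, nt_len - fstart)
}

sort_hits <- function(hits) {
  if (length(hits) <= 1L) return(hits)
  score <- vapply(hits, `[[`, numeric(1), "score")
  start <- vapply(hits, `[[`, numeric(1), "element_nt_start")
  rid <- vapply(hits, `[[`, character(1), "ref_id")
  hits[order(-score, start, rid, method = "radix")]
}

#' Best hit per domain kind
#'
#' Reduces a hit list to one best hit per domain (max score; ties broken by
#' lower e-value, then smaller element start, then lexicographic `ref_id` —
#' deterministic regardless of input order).
#'
#' @param hits list of `domain_hit`s from one element.
#' @return Named list mapping domain kind to its best `domain_hit`.
#' @export
best_hit_per_domain <- function(hits) {
  if (length(hits) == 0L) return(list())
  ids <- unique(vapply(hits, `[[`, character(1), "element_id"))
  if (length(ids) > 1L) stop("hits from multiple elements: ",
                             paste(ids, collapse = ", "))
  kinds <- vapply(hits, `[[`, character(1), "domain_kind")
  out <- list()
  for (k in unique(kinds)) {
    hk <- hits[kinds == k]
    o <- order(-vapply(hk, `[[`, numeric(1), "score"),
               vapply(hk, `[[`, numeric(1), "evalue"),
               vapply(hk, `[[`, numeric(1), "element_nt_start"),
               vapply(hk, `[[`, character(1), "ref_id"), method = "radix")
    out[[k]] <- hk[[o[1]]]
  }
  out[order(names(out))]
}
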