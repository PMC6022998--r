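# Pairwise alignment kernels (affine-gap global/local), translation and
# Karlin-Altschul e-values. Alignment is computed with Biostrings'
# pairwiseAlignment (Gotoh affine recursion); a gap of length L costs
# gap_open + L * gap_extend.

#' Alignment scoring scheme
#'
#' Nucleotide schemes use match/mismatch scores (+5/-4 by default, with `N`
#' scoring as a mismatch against everything, including `N` — conservative for
#' identity-thresholded rules); protein schemes use a named substitution
#' matrix (BLOSUM62 by default). Gap penalties are affine: a gap of length L
#' costs `gap_open + L * gap_extend`.
#'
#' @param kind `"nucleotide"` or `"protein"`.
#' @param match,mismatch nucleotide match/mismatch scores.
#' @param matrix protein substitution matrix name (a Biostrings dataset).
#' @param gap_open,gap_extend affine gap penalties (positive costs),
#'   `gap_open >= gap_extend >= 0`. Defaults follow the EMBOSS tools for
#'   each alphabet: 16/4 for nucleotide (stretcher's DNA defaults; with
#'   +5/-4 scores, cheaper extensions put random local alignments in the
#'   linear regime), 10/0.5 for protein.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(kind = c("nucleotide", "protein"), match = 5,
                           mismatch = -4, matrix = "BLOSUM62",
                           gap_open = NULL, gap_extend = NULL) {
  kind <- match.arg(kind)
  if (is.null(gap_open)) gap_open <- if (kind == "nucleotide") 16 else 10
  if (is.null(gap_extend)) gap_extend <- if (kind == "nucleotide") 4 else 0.5
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("gap penalties must satisfy gap_open >= gap_extend >= 0")
  structure(list(kind = kind, match = match, mismatch = mismatch,
                 matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

matrix_cache <- new.env(parent = emptyenv())

substitution_matrix <- function(scheme) {
  key <- if (scheme$kind == "nucleotide")
    sprintf("nt:%g:%g", scheme$match, scheme$mismatch)
  else paste0("aa:", scheme$matrix)
  if (!is.null(matrix_cache[[key]])) return(matrix_cache[[key]])
  m <- if (scheme$kind == "nucleotide") {
    letters <- c("A", "C", "G", "T", "N")
    m <- matrix(scheme$mismatch, 5L, 5L, dimnames = list(letters, letters))
    diag(m) <- scheme$match
    m["N", ] <- scheme$mismatch   # N never counts as a match
    m[, "N"] <- scheme$mismatch
    m
  } else {
    e <- new.env()
    utils::data(list = scheme$matrix, package = "Biostrings", envir = e)
    get(scheme$matrix, envir = e)
  }
  matrix_cache[[key]] <- m
  m
}

as_bio_seq <- function(x, scheme) {
  if (scheme$kind == "nucleotide") Biostrings::DNAString(x)
  else Biostrings::AAString(x)
}

build_alignment_result <- function(pa, a, b, mode, scheme) {
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  keep <- !(ca == "-" & cb == "-")
  ca <- ca[keep]; cb <- cb[keep]
  ambiguous <- if (scheme$kind == "nucleotide") "N" else "X"
  idents <- ca == cb & ca != "-" & ca != ambiguous
  identity_pct <- if (length(ca) > 0L) 100 * sum(idents) / length(ca) else 0
  q_start <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  q_end <- Biostrings::end(Biostrings::pattern(pa))
  s_start <- Biostrings::start(Biostrings::subject(pa)) - 1L
  s_end <- Biostrings::end(Biostrings::subject(pa))
  if (mode == "global") {
    q_start <- 0L; q_end <- nchar(a); s_start <- 0L; s_end <- nchar(b)
  }
  structure(list(
    aligned_a = paste(ca, collapse = ""),
    aligned_b = paste(cb, collapse = ""),
    score = Biostrings::score(pa),
    identity_pct = identity_pct,
    query_cov_pct = 100 * (q_end - q_start) / nchar(a),
    q_start = q_start, q_end = q_end,
    s_start = s_start, s_end = s_end,
    mode = mode), class = "alignment_result")
}

#' Global (Needleman-Wunsch) alignment with affine gaps
#'
#' @param a,b sequences (query and subject); non-empty.
#' @param scheme a [scoring_scheme()].
#' @return An `alignment_result` with gapped strings, score, percent identity
#'   over aligned columns, query coverage and 0-based half-open coordinates.
#' @export
global_align <- function(a, b, scheme = scoring_scheme("nucleotide")) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align empty sequences")
  pa <- Biostrings::pairwiseAlignment(
    as_bio_seq(a, scheme), as_bio_seq(b, scheme), type = "global",
    substitutionMatrix = substitution_matrix(scheme),
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  build_alignment_result(pa, a, b, "global", scheme)
}

#' Local (Smith-Waterman) alignment with affine gaps
#'
#' Returns the optimal local hit first; further non-overlapping hits are
#' found by masking the query span of each reported hit and re-aligning.
#'
#' @param a,b sequences (query and subject); non-empty.
#' @param scheme a [scoring_scheme()].
#' @param max_hits maximum number of hits to report.
#' @return A list of `alignment_result`s (possibly empty if nothing scores
#'   above zero).
#' @export
local_align <- function(a, b, scheme = scoring_scheme("nucleotide"),
                        max_hits = 1L) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align empty sequences")
  mat <- substitution_matrix(scheme)
  maskch <- if (scheme$kind == "nucleotide") "N" else "X"
  hits <- list()
  qa <- a
  for (i in seq_len(max_hits)) {
    pa <- Biostrings::pairwiseAlignment(
      as_bio_seq(qa, scheme), as_bio_seq(b, scheme), type = "local",
      substitutionMatrix = mat, gapOpening = scheme$gap_open,
      gapExtension = scheme$gap_extend)
    if (Biostrings::score(pa) <= 0) break
    res <- build_alignment_result(pa, a, b, "local", scheme)
    hits[[length(hits) + 1L]] <- res
    if (res$q_end <= res$q_start) break
    substr(qa, res$q_start + 1L, res$q_end) <-
      strrep(maskch, res$q_end - res$q_start)
  }
  hits
}

#' Translate a nucleotide sequence in a given frame
#'
#' Standard genetic code; stop codons become `*`, codons containing `N`
#' become `X`, and a trailing partial codon is dropped. Negative frames
#' translate the reverse complement.
#'
#' @param nt nucleotide string (length >= 3 after the frame offset).
#' @param frame one of `+1, +2, +3, -1, -2, -3`.
#' @return Amino-acid string.
#' @export
translate_frame <- function(nt, frame = 1L) {
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
    stop("frame must be one of +1,+2,+3,-1,-2,-3")
  s <- if (frame < 0L) revcomp(nt) else nt
  off <- abs(frame) - 1L
  s <- substr(s, off + 1L, nchar(s))
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(s, starts, starts + 2L)
  aa <- codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

codon_env <- new.env(parent = emptyenv())
codon_table <- function() {
  if (is.null(codon_env$tab)) {
    codon_env$tab <- Biostrings::GENETIC_CODE
  }
  codon_env$tab
}

#' @rdname translate_frame
#' @export
revcomp <- function(nt) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", nt), "")[[1]]), collapse = "")
}

#' Six-frame translation
#'
#' @param nt nucleotide string.
#' @return Named character vector of the six translations, names
#'   `"+1","+2","+3","-1","-2","-3"`.
#' @export
six_frame <- function(nt) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  out <- vapply(frames, function(f) translate_frame(nt, f), character(1))
  names(out) <- sprintf("%+d", frames)
  out
}

#' Karlin-Altschul e-value for an ungapped-statistics approximation
#'
#' `E = K * m * n * exp(-lambda * S)`. For protein scores the published
#' ungapped BLOSUM62 constants are used as a fixed approximation
#' (`lambda = 0.3176`, `K = 0.134`); for nucleotide scores `lambda` is solved
#' from the match/mismatch scheme at uniform base composition with `K = 0.1`.
#'
#' @param score raw alignment score (>= 0).
#' @param m query length (residues).
#' @param n database length (residues).
#' @param scheme a [scoring_scheme()].
#' @return The expected number of chance hits at this score or better.
#' @export
evalue <- function(score, m, n, scheme = scoring_scheme("protein")) {
  if (m <= 0 || n <= 0) stop("m and n must be positive")
  if (score < 0) stop("score must be >= 0")
  if (scheme$kind == "protein") {
    lambda <- 0.3176
    K <- 0.134
  } else {
    lambda <- nt_lambda(scheme$match, scheme$mismatch)
    K <- 0.1
  }
  K * m * n * exp(-lambda * score)
}

nt_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 5), tol = 1e-12)$root
}
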