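# RT-domain extraction, progressive multiple alignment, protein p-distances
# and neighbor-joining trees with lineage-annotated leaves.

#' Extract and translate the RT domain of an autonomous element
#'
#' The nucleotide span of the element's best RT hit is translated in the
#' hit's frame. A trailing stop is trimmed; an internal stop truncates the
#' peptide at the stop, which is kept only if it still exceeds the length
#' filter. The filter is strict: peptides must be *larger than* 200 aa in
#' element mode and larger than 150 aa in genome mode.
#'
#' @param element a `predictor_record` classified GYPSY or COPIA.
#' @param rt_hit the element's best RT `domain_hit`.
#' @param cfg an `ltr_config` (`rt_min_aa_element`, `rt_min_aa_genome`).
#' @param mode `"element"` (200-aa filter) or `"genome"` (150-aa filter).
#' @return List with `accepted`; when accepted: `element_id`, `aa_seq`,
#'   `length_aa`, `source_frame`, `nt_span`, `lineage_label`, `mode`; when
#'   rejected, a `reason`.
#' @export
extract_rt <- function(element, rt_hit, cfg = default_config(),
                       mode = c("element", "genome")) {
  mode <- match.arg(mode)
  threshold <- if (mode == "element") cfg$rt_min_aa_element
               else cfg$rt_min_aa_genome
  if (is.null(rt_hit) || rt_hit$domain_kind != "RT")
    return(list(accepted = FALSE, element_id = element$element_id,
                reason = "no RT hit"))
  span <- c(rt_hit$element_nt_start, rt_hit$element_nt_end)
  sub <- substr(element$full_seq, span[1] + 1L, span[2])
  if (rt_hit$frame < 0L) sub <- revcomp(sub)
  aa <- translate_frame(sub, 1L)
  aa <- sub("\\*$", "", aa)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  truncated <- FALSE
  if (stop_at > 0L) {
    aa <- substr(aa, 1L, stop_at - 1L)
    truncated <- TRUE
  }
  if (nchar(aa) <= threshold)
    return(list(accepted = FALSE, element_id = element$element_id,
                reason = sprintf(
                  "translated RT %d aa not larger than %d aa (%s mode%s)",
                  nchar(aa), threshold, mode,
                  if (truncated) ", truncated at internal stop" else "")))
  list(accepted = TRUE, element_id = element$element_id, aa_seq = aa,
       length_aa = nchar(aa), source_frame = rt_hit$frame, nt_span = span,
       lineage_label = rt_hit$lineage, mode = mode)
}

#' Progressive multiple alignment of protein sequences
#'
#' Guide order from single-linkage clustering of 3-mer-count cosine
#' distances; profiles are then merged by affine-gap profile-profile
#' alignment under BLOSUM62 (gap of length L costs
#' `gap_open + L * gap_extend`), with diagonal-preferring deterministic
#' tie-breaking.
#'
#' @param seqs named character vector of protein sequences (>= 2).
#' @param scheme protein [scoring_scheme()].
#' @return Character matrix of gapped rows (one per input sequence, input
#'   names as rownames, input order); every row degaps to its input.
#' @export
progressive_msa <- function(seqs, scheme = scoring_scheme("protein")) {
  if (length(seqs) < 2L) stop("need at least 2 sequences for an MSA")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  B <- substitution_matrix(scheme)
  if (length(seqs) == 2L) {
    ord <- matrix(c(-1L, -2L), 1L, 2L)
  } else {
    D <- kmer_cosine_dist(seqs, k = 3L)
    ord <- stats::hclust(stats::as.dist(D), method = "single")$merge
  }
  # profiles indexed as in hclust merge: negative = singleton, positive = row
  pool <- list()
  for (m in seq_len(nrow(ord))) {
    left <- fetch_profile(ord[m, 1L], seqs, pool)
    right <- fetch_profile(ord[m, 2L], seqs, pool)
    pool[[m]] <- align_profiles(left, right, B, scheme$gap_open,
                                scheme$gap_extend)
  }
  msa <- pool[[length(pool)]]
  msa[names(seqs), , drop = FALSE]
}

fetch_profile <- function(idx, seqs, pool) {
  if (idx < 0L) {
    m <- matrix(strsplit(seqs[[-idx]], "")[[1]], nrow = 1L)
    rownames(m) <- names(seqs)[-idx]
    m
  } else pool[[idx]]
}

kmer_cosine_dist <- function(seqs, k = 3L) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(s))
    table(substring(s, seq_len(n - k + 1L), seq.int(k, n)))
  })
  keys <- sort(unique(unlist(lapply(counts, names))))
  V <- vapply(counts, function(ct) {
    v <- stats::setNames(numeric(length(keys)), keys)
    v[names(ct)] <- as.numeric(ct)
    v
  }, numeric(length(keys)))
  V <- as.matrix(V)
  norms <- sqrt(colSums(V^2))
  cs <- crossprod(V) / outer(norms, norms)
  d <- 1 - cs
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

# Profile-profile Gotoh alignment; profiles are character matrices
# (rows = sequences, cols = alignment columns). Returns the merged matrix.
align_profiles <- function(A, Bm, subst, go, ge) {
  la <- ncol(A); lb <- ncol(Bm)
  alpha <- rownames(subst)
  fa <- profile_freq(A, alpha)
  fb <- profile_freq(Bm, alpha)
  S <- crossprod(fa, subst %*% fb)            # la x lb column-pair scores
  NEG <- -1e18
  M <- matrix(NEG, la + 1L, lb + 1L)
  X <- matrix(NEG, la + 1L, lb + 1L)          # gap in B (consumes A column)
  Y <- matrix(NEG, la + 1L, lb + 1L)          # gap in A (consumes B column)
  M[1L, 1L] <- 0
  if (la > 0L) X[2L:(la + 1L), 1L] <- -(go + seq_len(la) * ge)
  if (lb > 0L) Y[1L, 2L:(lb + 1L)] <- -(go + seq_len(lb) * ge)
  jj <- seq_len(lb + 1L)
  for (i in seq_len(la)) {
    r <- i + 1L
    prev_best <- pmax(M[r - 1L, ], X[r - 1L, ], Y[r - 1L, ])
    M[r, 2L:(lb + 1L)] <- S[i, ] + prev_best[1L:lb]
    X[r, ] <- pmax(X[r - 1L, ] - ge,
                   pmax(M[r - 1L, ], Y[r - 1L, ]) - go - ge)
    mx <- pmax(M[r, ], X[r, ])
    run <- cummax(mx + (jj - 1L) * ge)
    Y[r, 2L:(lb + 1L)] <- run[1L:lb] - go - seq_len(lb) * ge
  }
  # traceback, preferring diagonal > up > left
  eps <- 1e-9
  i <- la; j <- lb
  end <- c(M[la + 1L, lb + 1L], X[la + 1L, lb + 1L], Y[la + 1L, lb + 1L])
  state <- which.max(end + c(2L, 1L, 0L) * eps)
  moves <- character(0)
  while (i > 0L || j > 0L) {
    r <- i + 1L; cj <- j + 1L
    if (state == 1L) {                        # M: consumed (i, j) diagonally
      moves <- c("D", moves)
      tgt <- M[r, cj] - S[i, j]
      prev <- c(M[r - 1L, cj - 1L], X[r - 1L, cj - 1L], Y[r - 1L, cj - 1L])
      state <- which(abs(prev - tgt) <= eps)[1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {                 # X: gap in B, consumed A col i
      moves <- c("U", moves)
      if (i > 1L || j > 0L) {
        if (abs(X[r - 1L, cj] - ge - X[r, cj]) <= eps &&
            X[r - 1L, cj] > NEG / 2) {
          state <- 2L
        } else if (abs(M[r - 1L, cj] - go - ge - X[r, cj]) <= eps) {
          state <- 1L
        } else state <- 3L
      }
      i <- i - 1L
    } else {                                  # Y: gap in A, consumed B col j
      moves <- c("L", moves)
      if (j > 1L || i > 0L) {
        if (abs(M[r, cj - 1L] - go - ge - Y[r, cj]) <= eps) {
          state <- 1L
        } else if (abs(X[r, cj - 1L] - go - ge - Y[r, cj]) <= eps) {
          state <- 2L
        } else state <- 3L
      }
      j <- j - 1L
    }
  }
  merge_profiles(A, Bm, moves)
}

profile_freq <- function(P, alpha) {
  f <- matrix(0, length(alpha), ncol(P), dimnames = list(alpha, NULL))
  for (a in setdiff(unique(as.vector(P)), "-")) {
    if (!a %in% alpha) next
    f[a, ] <- colSums(P == a)
  }
  f / nrow(P)
}

merge_profiles <- function(A, Bm, moves) {
  n_out <- length(moves)
  out <- matrix("-", nrow(A) + nrow(Bm), n_out)
  rownames(out) <- c(rownames(A), rownames(Bm))
  ia <- 0L; ib <- 0L
  ra <- seq_len(nrow(A)); rb <- nrow(A) + seq_len(nrow(Bm))
  for (c0 in seq_len(n_out)) {
    mv <- moves[c0]
    if (mv != "L") { ia <- ia + 1L; out[ra, c0] <- A[, ia] }
    if (mv != "U") { ib <- ib + 1L; out[rb, c0] <- Bm[, ib] }
  }
  out
}

#' Protein p-distance matrix from an MSA
#'
#' Pairwise proportion of differing residues over mutually ungapped columns.
#'
#' @param msa character matrix from [progressive_msa()] (or a named
#'   character vector of equal-length gapped rows).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(msa) {
  if (is.character(msa) && !is.matrix(msa)) {
    if (length(unique(nchar(msa))) != 1L)
      stop("MSA rows must have equal length")
    msa <- do.call(rbind, strsplit(msa, ""))
  }
  n <- nrow(msa)
  D <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      use <- msa[i, ] != "-" & msa[j, ] != "-"
      if (!any(use))
        stop("rows ", i, " and ", j, " share no ungapped columns")
      d <- mean(msa[i, use] != msa[j, use])
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration; negative branch-length
#' estimates are clamped to zero (the number clamped is recorded in the
#' `n_clamped` attribute). For an additive distance matrix the generating
#' topology and branch lengths are recovered exactly.
#'
#' @param dist_matrix square symmetric numeric matrix, `n >= 3`.
#' @param labels optional leaf labels (default: matrix dimnames).
#' @return An `ape` `phylo` object (unrooted).
#' @export
nj_tree <- function(dist_matrix, labels = NULL) {
  if (!is.matrix(dist_matrix) || nrow(dist_matrix) != ncol(dist_matrix))
    stop("distance matrix must be square")
  if (max(abs(dist_matrix - t(dist_matrix))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (nrow(dist_matrix) < 3L) stop("need at least 3 taxa")
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(dist_matrix))
    dimnames(dist_matrix) <- list(labels, labels)
  }
  tree <- ape::nj(stats::as.dist(dist_matrix))
  n_clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "n_clamped") <- n_clamped
  tree
}
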