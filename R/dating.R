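# Insertion-time estimation from 5'/3'-LTR divergence: LTR-pair location,
# global LTR alignment, Kimura 2-parameter distance, age conversion and
# 0.5-MY binning.

#' Locate a terminal LTR pair in an element sequence
#'
#' Used only when the input carries no LTR annotation. Because the two LTRs
#' of a full-length element sit exactly at its termini, candidate lengths L
#' are scanned directly: the prefix and suffix of length L are compared
#' position-wise and the L maximising identity (longest on ties) is taken.
#' The two spans may not overlap, so L never exceeds half the element.
#'
#' @param full_seq element nucleotide sequence.
#' @param min_len,max_len candidate LTR length range (bp).
#' @param min_identity minimum percent identity of the terminal repeat.
#' @return List with `ltr5` and `ltr3`, each `c(start, end)` 0-based
#'   half-open, plus the achieved `identity_pct`.
#' @export
locate_ltr_pair <- function(full_seq, min_len = 100L, max_len = 5000L,
                            min_identity = 70) {
  n <- nchar(full_seq)
  if (n <= 2L * min_len)
    stop("element too short to contain two ", min_len, "-bp LTRs")
  chars <- strsplit(full_seq, "")[[1]]
  upper <- min(max_len, n %/% 2L)
  best_len <- NA_integer_
  best_id <- -1
  for (L in seq.int(min_len, upper)) {
    pre <- chars[seq_len(L)]
    suf <- chars[seq.int(n - L + 1L, n)]
    id <- 100 * sum(pre == suf & pre != "N") / L
    if (id > best_id || (id == best_id && L > best_len)) {
      best_id <- id
      best_len <- L
    }
  }
  if (best_id < min_identity)
    stop(no_ltr_found("no terminal repeat at >= ", min_identity,
                      "% identity (best ", round(best_id, 1), "%)"))
  list(ltr5 = c(0L, best_len), ltr3 = c(n - best_len, n),
       identity_pct = best_id)
}

no_ltr_found <- function(...) {
  structure(class = c("NoLTRFound", "error", "condition"),
            list(message = paste0(...), call = sys.call(-1)))
}

saturated_divergence <- function(...) {
  structure(class = c("SaturatedDivergence", "error", "condition"),
            list(message = paste0(...), call = sys.call(-1)))
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Transition (P) and transversion (Q) proportions are computed over
#' gap-free columns (columns containing `-` or `N` in either row are
#' excluded), then `K = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' @param aligned_a,aligned_b gapped nucleotide strings of equal length.
#' @return List with `P`, `Q`, `K` and `sites` (gap-free columns used).
#'   Saturated divergence (a log argument dropping to or below zero) raises
#'   a `SaturatedDivergence` condition; zero usable columns is an error.
#' @export
k2p_distance <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("aligned sequences must have equal length")
  a <- strsplit(toupper(aligned_a), "")[[1]]
  b <- strsplit(toupper(aligned_b), "")[[1]]
  use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[use]; b <- b[use]
  sites <- length(a)
  if (sites == 0L) stop("no gap-free columns to compare")
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / sites
  Q <- sum(diff & !transition) / sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(saturated_divergence(
      "saturated divergence (P=", signif(P, 4), ", Q=", signif(Q, 4), ")"))
  K <- -0.5 * log(w1) - 0.25 * log(w2)
  list(P = P, Q = Q, K = K, sites = sites)
}

#' Convert a K2P distance to an insertion age
#'
#' `T = K / (2 * rate)`: the two LTRs are identical at insertion and each
#' accumulates substitutions independently at `rate` per site per year.
#'
#' @param K K2P distance (substitutions/site), >= 0.
#' @param rate substitution rate per site per year (default 1.3e-8).
#' @return Age in years.
#' @export
insertion_time <- function(K, rate = 1.3e-8) {
  if (is.na(K) || K < 0) stop("K must be a non-negative number")
  if (rate <= 0) stop("rate must be positive")
  K / (2 * rate)
}

#' Date a set of elements from their LTR pairs
#'
#' Globally aligns each element's 5' and 3' LTR, computes the K2P distance
#' and converts it to an age. Saturated pairs are kept in the table with
#' `K = NA` and flagged rather than clamped.
#'
#' @param elements list of `predictor_record`s.
#' @param results optional list of `classification_result`s aligned with
#'   `elements`; supplies the `lineage_or_category` label (lineage for
#'   autonomous elements, category otherwise).
#' @param cfg an `ltr_config`; `substitution_rate` and `bin_width_my` used.
#' @param scheme nucleotide scoring scheme for the LTR alignment.
#' @return Data frame: element_id, lineage_or_category, aligned_sites, P, Q,
#'   K, rate, T_years, T_my, bin_index, saturated.
#' @export
date_elements <- function(elements, results = NULL, cfg = default_config(),
                          scheme = scoring_scheme("nucleotide")) {
  labels <- rep("ALL", length(elements))
  if (!is.null(results)) {
    stopifnot(length(results) == length(elements))
    labels <- vapply(results, function(r)
      if (r$category %in% c("GYPSY", "COPIA") && r$lineage != "NONE")
        r$lineage else r$category, character(1))
  }
  rate <- cfg$substitution_rate
  rows <- lapply(seq_along(elements), function(i) {
    el <- elements[[i]]
    aln <- global_align(el$ltr5_seq, el$ltr3_seq, scheme = scheme)
    k2p <- tryCatch(k2p_distance(aln$aligned_a, aln$aligned_b),
                    SaturatedDivergence = function(e) NULL)
    if (is.null(k2p)) {
      return(data.frame(element_id = el$element_id,
                        lineage_or_category = labels[i],
                        aligned_sites = NA_integer_, P = NA_real_,
                        Q = NA_real_, K = NA_real_, rate = rate,
                        T_years = NA_real_, T_my = NA_real_,
                        bin_index = NA_integer_, saturated = TRUE,
                        stringsAsFactors = FALSE))
    }
    t_years <- insertion_time(k2p$K, rate)
    data.frame(element_id = el$element_id, lineage_or_category = labels[i],
               aligned_sites = k2p$sites, P = k2p$P, Q = k2p$Q, K = k2p$K,
               rate = rate, T_years = t_years, T_my = t_years / 1e6,
               bin_index = as.integer(floor(t_years / 1e6 / cfg$bin_width_my)),
               saturated = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Filter copies to full-length representatives of a reference
#'
#' A copy is retained when its global alignment to the reference reaches the
#' identity threshold over the full reference length: every reference
#' residue must be aligned to a copy residue (terminal-gap slack 0 by
#' default).
#'
#' @param copies named character vector of candidate copy sequences.
#' @param reference reference element sequence.
#' @param min_identity minimum percent identity of the global alignment.
#' @param min_cov_pct minimum percent of reference residues aligned to copy
#'   residues (100 = strict full-length).
#' @param scheme nucleotide scoring scheme.
#' @return The retained subset of `copies`.
#' @export
full_length_filter <- function(copies, reference, min_identity = 80,
                               min_cov_pct = 100,
                               scheme = scoring_scheme("nucleotide")) {
  keep <- vapply(copies, function(cp) {
    aln <- global_align(cp, reference, scheme = scheme)
    a <- strsplit(aln$aligned_a, "")[[1]]
    b <- strsplit(aln$aligned_b, "")[[1]]
    ref_cov <- 100 * sum(b != "-" & a != "-") / nchar(reference)
    aln$identity_pct >= min_identity && ref_cov >= min_cov_pct
  }, logical(1))
  copies[keep]
}

#' Histogram of insertion ages in fixed-width bins
#'
#' @param estimates data frame from [date_elements()].
#' @param bin_width_my bin width in million years.
#' @param group_key column used to group series: `"lineage_or_category"`
#'   (default) or any column of `estimates`.
#' @return Data frame with group, bin_index, bin label `[lo,hi)` in MY,
#'   count and within-group percent (saturated records are excluded from the
#'   bins and reported via the `n_saturated` column).
#' @export
bin_by_age <- function(estimates, bin_width_my = 0.5,
                       group_key = "lineage_or_category") {
  if (nrow(estimates) == 0L)
    return(data.frame(group = character(), bin_index = integer(),
                      bin = character(), count = integer(),
                      percent = numeric(), n_saturated = integer(),
                      stringsAsFactors = FALSE))
  groups <- sort(unique(estimates[[group_key]]))
  out <- lapply(groups, function(g) {
    sub <- estimates[estimates[[group_key]] == g, ]
    n_sat <- sum(sub$saturated)
    sub <- sub[!sub$saturated, ]
    if (nrow(sub) == 0L)
      return(data.frame(group = g, bin_index = NA_integer_, bin = "",
                        count = 0L, percent = NA_real_, n_saturated = n_sat,
                        stringsAsFactors = FALSE))
    idx <- as.integer(floor(sub$T_my / bin_width_my))
    tab <- table(idx)
    bi <- as.integer(names(tab))
    data.frame(group = g, bin_index = bi,
               bin = sprintf("[%g,%g)", bi * bin_width_my,
                             (bi + 1L) * bin_width_my),
               count = as.integer(tab),
               percent = 100 * as.integer(tab) / nrow(sub),
               n_saturated = n_sat, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
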