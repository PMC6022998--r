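# Independent alignment-score oracles: exhaustive maximisation over all
# alignment paths by memoised recursion over explicit move choices (no
# reuse of the package's alignment code paths). A gap run of length L costs
# gap_open + L * gap_extend.

oracle_pair_score <- function(x, y, scheme) {
  if (scheme$kind == "nucleotide") {
    if (x == "N" || y == "N") return(scheme$mismatch)
    if (x == y) scheme$match else scheme$mismatch
  } else {
    B <- ltrcraft:::substitution_matrix(scheme)
    B[x, y]
  }
}

# best score aligning a[i..] with b[j..], given the previous move
# ("none", "diag", "gapA" = gap in a, "gapB" = gap in b), full coverage
oracle_global_score <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i > la && j > lb) return(0)
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= la && j <= lb) {
      best <- max(best, oracle_pair_score(av[i], bv[j], scheme) +
                    rec(i + 1L, j + 1L, "diag"))
    }
    if (i <= la) {   # a[i] against a gap in b
      cost <- if (prev == "gapB") ge else go + ge
      best <- max(best, rec(i + 1L, j, "gapB") - cost)
    }
    if (j <= lb) {   # b[j] against a gap in a
      cost <- if (prev == "gapA") ge else go + ge
      best <- max(best, rec(i, j + 1L, "gapA") - cost)
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, "none")
}

# best local score: an alignment may start at any (i, j) and stop anywhere
oracle_local_score <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  memo <- new.env(parent = emptyenv())
  # best score of a (possibly empty) continuation starting at (i, j)
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- 0   # stopping here is always allowed
    if (i <= la && j <= lb) {
      best <- max(best, oracle_pair_score(av[i], bv[j], scheme) +
                    rec(i + 1L, j + 1L, "diag"))
    }
    if (i <= la) {
      cost <- if (prev == "gapB") ge else go + ge
      best <- max(best, rec(i + 1L, j, "gapB") - cost)
    }
    if (j <= lb) {
      cost <- if (prev == "gapA") ge else go + ge
      best <- max(best, rec(i, j + 1L, "gapA") - cost)
    }
    memo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) best <- max(best, rec(i, j, "none"))
  }
  best
}

random_nt_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                          replace = TRUE), collapse = "")

random_aa_str <- function(n) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
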