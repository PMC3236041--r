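# Independent brute-force oracles used across the suite. These stay
# deliberately naive (loops, enumeration) and never call the package
# functions they check.

AA20_ORACLE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa_string <- function(len) {
  paste(sample(AA20_ORACLE, len, replace = TRUE), collapse = "")
}

random_dna_string <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# plain-loop Shannon entropy
entropy_oracle <- function(counts) {
  N <- sum(counts)
  h <- 0
  for (c in counts) {
    p <- c / N
    h <- h - p * log(p)
  }
  h
}

# broken-stick expectation by direct double summation
broken_stick_oracle <- function(S) {
  p <- numeric(S)
  for (i in seq_len(S)) {
    acc <- 0
    for (k in i:S) acc <- acc + 1 / k
    p[i] <- acc / S
  }
  p
}

# rank-by-rank over-representation decision, independent of the package:
# sort counts decreasing (ties by name), flag rank i iff freq > p_i
overrep_oracle <- function(counts) {
  stopifnot(!is.null(names(counts)))
  ord <- order(-counts, names(counts))
  freq <- counts[ord] / sum(counts)
  p <- broken_stick_oracle(length(counts))
  names(counts)[ord][freq > p]
}

# all multisets of S positive counts summing to N, as a list of sorted
# (non-increasing) integer vectors
count_partitions <- function(N, S, max_part = N) {
  if (S == 1L) {
    if (N <= max_part) return(list(N)) else return(list())
  }
  out <- list()
  for (first in rev(seq_len(min(N - S + 1L, max_part)))) {
    rest <- count_partitions(N - first, S - 1L, first)
    out <- c(out, lapply(rest, function(r) c(first, r)))
  }
  out
}

# affine-gap Smith-Waterman score by full dynamic programming (Gotoh);
# a gap of length L costs open + L * ext
sw_score_oracle <- function(a, b, mat, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  n <- length(ca)
  m <- length(cb)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
      F[i, j] <- max(H[i - 1L, j] - open - ext, F[i - 1L, j] - ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + mat[ca[i - 1L], cb[j - 1L]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# longest exact common substring by diagonal scan
lcs_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  n <- length(ca)
  m <- length(cb)
  best <- 0L
  for (d in (-(n - 1L)):(m - 1L)) {
    i <- max(1L, 1L - d)
    len <- min(n - i + 1L, m - (i + d) + 1L)
    if (len <= best) next
    eq <- ca[i:(i + len - 1L)] == cb[(i + d):(i + d + len - 1L)]
    r <- rle(eq)
    runs <- r$lengths[r$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  best
}

# brute-force ungapped HSP oracle: for every exact word seed (scanned
# left to right per diagonal, skipping seeds inside an already-emitted
# segment on that diagonal, the same policy the finder uses), enumerate
# ALL ungapped segments containing the seed word and keep the best score
# (+1 match / -1 mismatch; ties -> shortest, then leftmost). Containment
# filtering afterwards mirrors the finder's collapse rule.
hsp_oracle <- function(a, b, word_size, min_length) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  n <- length(ca)
  m <- length(cb)
  segs <- list()
  for (d in (-(n - 1L)):(m - 1L)) {
    lo <- max(1L, 1L - d)
    hi <- min(n, m - d)
    if (hi - lo + 1L < word_size) next
    match_v <- ca[lo:hi] == cb[(lo:hi) + d]
    consumed_to <- 0L
    for (i in lo:(hi - word_size + 1L)) {
      if (!all(match_v[(i - lo + 1L):(i - lo + word_size)])) next
      if (i + word_size - 1L <= consumed_to) next
      # enumerate every segment [s, e] containing the word
      best <- NULL
      for (s in lo:i) {
        for (e in (i + word_size - 1L):hi) {
          sc <- sum(2L * match_v[(s - lo + 1L):(e - lo + 1L)] - 1L)
          if (is.null(best) || sc > best$sc ||
              (sc == best$sc && (e - s) < (best$e - best$s))) {
            best <- list(s = s, e = e, sc = sc)
          }
        }
      }
      consumed_to <- max(consumed_to, best$e)
      len <- best$e - best$s + 1L
      if (len < min_length) next
      segs[[length(segs) + 1L]] <- c(
        a_start = best$s - 1L, a_end = best$e,
        b_start = best$s + d - 1L, b_end = best$e + d,
        length = len,
        identities = sum(match_v[(best$s - lo + 1L):(best$e - lo + 1L)]))
    }
  }
  if (length(segs) == 0L) {
    return(data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      length = integer(), identities = integer()))
  }
  h <- as.data.frame(do.call(rbind, segs))
  h <- h[!duplicated(h[, c("a_start", "a_end", "b_start")]), , drop = FALSE]
  # drop segments contained (both genomes) in a longer one
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    inside <- h$a_start <= h$a_start[i] & h$a_end >= h$a_end[i] &
      h$b_start <= h$b_start[i] & h$b_end >= h$b_end[i]
    inside[i] <- FALSE
    longer <- h$length > h$length[i] |
      (h$length == h$length[i] & seq_len(nrow(h)) < i)
    if (any(inside & longer & keep)) keep[i] <- FALSE
  }
  h <- h[keep, , drop = FALSE]
  rownames(h) <- NULL
  h
}

# canonical ordering for HSP table comparison
sort_hsps <- function(h) {
  h <- as.data.frame(h)[, c("a_start", "a_end", "b_start", "b_end",
                            "length", "identities")]
  h <- h[order(h$a_start, h$b_start, h$a_end), , drop = FALSE]
  rownames(h) <- NULL
  h
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# global-alignment percent identity between two equal-length proteins
# (used to measure simulated family identity)
global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = blosum62_matrix(),
    gapOpening = 11, gapExtension = 1)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}
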