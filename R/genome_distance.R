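# encode a DNA sequence as integers 1..4 (A,C,G,T); anything else (N,
# ambiguity codes) becomes NA and never matches
dna_to_int <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1L]]
  bad <- !chars %in% c(DNA4, "N")
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("invalid nucleotide '", chars[i], "' at position ", i,
         call. = FALSE)
  }
  match(chars, DNA4)
}

# x-drop extension along one diagonal, vectorised. `m` is the 0/1 match
# vector for the full diagonal overlap, `from`/`to` the seed word's
# position within it (1-based, inclusive). Scoring is +1 match / -1
# mismatch. Extension in each direction stops where the running score
# falls more than `xdrop` below its running maximum, then trims back to
# the maximum. Returns c(start, end) within the diagonal.
xdrop_extend <- function(m, from, to, xdrop) {
  step <- 2L * m - 1L
  # right of the seed
  if (to < length(m)) {
    cs <- cumsum(step[(to + 1L):length(m)])
    stop_at <- which(pmax(cummax(cs), 0L) - cs > xdrop)
    lim <- if (length(stop_at)) stop_at[1L] - 1L else length(cs)
    if (lim > 0L) {
      best <- which.max(cs[seq_len(lim)])
      if (cs[best] > 0L) to <- to + best
    }
  }
  # left of the seed
  if (from > 1L) {
    cs <- cumsum(step[(from - 1L):1L])
    stop_at <- which(pmax(cummax(cs), 0L) - cs > xdrop)
    lim <- if (length(stop_at)) stop_at[1L] - 1L else length(cs)
    if (lim > 0L) {
      best <- which.max(cs[seq_len(lim)])
      if (cs[best] > 0L) from <- from - best
    }
  }
  c(from, to)
}

#' Find high-scoring segment pairs between two nucleotide sequences
#'
#' A desk-scale seed-and-extend HSP finder: exact `word_size`-mer matches
#' are extended ungapped in both directions with +1/-1 scoring and an
#' x-drop stopping rule, then trimmed to the maximal-scoring extent.
#' Seeds falling inside an HSP already found on the same diagonal are
#' skipped; duplicate HSPs and HSPs contained in another HSP (on both
#' genomes) are collapsed; HSPs shorter than `min_length` are dropped.
#' Forward strand by default; with `both_strands = TRUE` the search is
#' repeated against the reverse complement of `seq_b` and the two HSP
#' sets are unioned (minus-strand coordinates reported on the forward
#' strand of B).
#'
#' @param seq_a,seq_b Nucleotide sequences (character or `DNAString`)
#'   over A/C/G/T/N; `N` never matches.
#' @param word_size Exact-match seed length (>= 8; small words explode
#'   the seed list).
#' @param xdrop Score drop-off that terminates extension (default 20).
#' @param min_length Minimum HSP length in bp (default 50).
#' @param both_strands Also search the reverse complement of `seq_b`.
#' @return Data frame of class `hsp_set`: `a_start`, `a_end`, `b_start`,
#'   `b_end` (0-based half-open), `length`, `identities`, `strand`.
#' @export
find_hsps <- function(seq_a, seq_b, word_size = 11L, xdrop = 20L,
                      min_length = 50L, both_strands = FALSE) {
  if (word_size < 8L) {
    stop("'word_size' must be at least 8", call. = FALSE)
  }
  out <- find_hsps_fwd(seq_a, seq_b, word_size, xdrop, min_length)
  out$strand <- rep("+", nrow(out))
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(
        as.character(seq_b))))
    len_b <- nchar(rc)
    rev_hits <- find_hsps_fwd(seq_a, rc, word_size, xdrop, min_length)
    if (nrow(rev_hits)) {
      # map minus-strand coordinates back onto the forward strand of B
      b_start <- len_b - rev_hits$b_end
      rev_hits$b_end <- len_b - rev_hits$b_start
      rev_hits$b_start <- b_start
      rev_hits$strand <- "-"
      out <- rbind(out, rev_hits)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("hsp_set", "data.frame")
  out
}

find_hsps_fwd <- function(seq_a, seq_b, word_size, xdrop, min_length) {
  ai <- dna_to_int(seq_a)
  bi <- dna_to_int(seq_b)
  empty <- data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      length = integer(), identities = integer())
  if (length(ai) < word_size || length(bi) < word_size) return(empty)
  a_words <- kmer_strings(seq_a, word_size)
  b_words <- kmer_strings(seq_b, word_size)
  idx <- split(seq_along(a_words), a_words)
  hit_lists <- idx[b_words]            # hashed name lookup, vectorised
  n_hits <- lengths(hit_lists)
  if (sum(n_hits) == 0L) return(empty)
  b_pos <- rep(seq_along(b_words), n_hits)
  a_pos <- unlist(hit_lists, use.names = FALSE)
  diag_id <- b_pos - a_pos
  ord <- order(diag_id, a_pos)
  a_pos <- a_pos[ord]
  b_pos <- b_pos[ord]
  diag_id <- diag_id[ord]

  hsps <- list()
  cur_diag <- NA_integer_
  consumed_to <- 0L   # rightmost A position covered on the current diagonal
  for (h in seq_along(a_pos)) {
    d <- diag_id[h]
    i <- a_pos[h]
    j <- b_pos[h]
    if (is.na(cur_diag) || d != cur_diag) {
      cur_diag <- d
      consumed_to <- 0L
      # match vector for this diagonal's overlap, cached per diagonal
      a_lo <- max(1L, 1L - d)
      a_hi <- min(length(ai), length(bi) - d)
      a_off <- a_lo - 1L
      m <- as.integer(!is.na(ai[a_lo:a_hi]) &
                        ai[a_lo:a_hi] == bi[(a_lo:a_hi) + d])
    }
    if (i + word_size - 1L <= consumed_to) next
    span <- xdrop_extend(m, i - a_off, i + word_size - 1L - a_off, xdrop)
    a1 <- span[1L] + a_off
    a2 <- span[2L] + a_off
    consumed_to <- max(consumed_to, a2)
    len <- a2 - a1 + 1L
    if (len < min_length) next
    hsps[[length(hsps) + 1L]] <- c(
      a_start = a1 - 1L, a_end = a2, b_start = a1 + d - 1L, b_end = a2 + d,
      length = len, identities = sum(m[span[1L]:span[2L]]))
  }
  if (length(hsps) == 0L) return(empty)
  out <- as.data.frame(do.call(rbind, hsps))
  out <- out[!duplicated(out[, c("a_start", "a_end", "b_start")]), ,
             drop = FALSE]
  drop_contained(out)
}

kmer_strings <- function(seq, k) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  substring(s, 1:(n - k + 1L), k:n)
}

# drop HSPs whose intervals on BOTH genomes lie inside another HSP's
drop_contained <- function(h) {
  n <- nrow(h)
  if (n <= 1L) return(h)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    inside <- h$a_start <= h$a_start[i] & h$a_end >= h$a_end[i] &
      h$b_start <= h$b_start[i] & h$b_end >= h$b_end[i]
    inside[i] <- FALSE
    longer <- h$length > h$length[i] |
      (h$length == h$length[i] & seq_len(n) < i)
    if (any(inside & longer & keep)) keep[i] <- FALSE
  }
  h[keep, , drop = FALSE]
}

#' Genome-to-genome ratio formulas over an HSP set
#'
#' The three GGDC-style similarity ratios for a genome pair:
#' \enumerate{
#'   \item `f1` = HSP length / total length,
#'   \item `f2` = identities / HSP length,
#'   \item `f3` = identities / total length,
#' }
#' where total length is the arithmetic mean of the two genome lengths.
#' Overlapping HSP intervals are merged per genome before summing so no
#' base is counted twice: HSPs are visited by decreasing identities, each
#' contributes only its novel covered bases on each genome (effective
#' length = mean of the two novel widths), and its identity count is
#' prorated by effective/original length. With this accounting
#' `f3 = f1 * f2` holds exactly.
#'
#' @param hsps Data frame of HSPs (`a_start`, `a_end`, `b_start`,
#'   `b_end`, `length`, `identities`; 0-based half-open), e.g. from
#'   [find_hsps()]. May be empty.
#' @param len_a,len_b Genome lengths in bp.
#' @return Object of class `ggdc_result`: list with `f1`, `f2`, `f3`
#'   (fractions), `total_length`, `hsp_length`, `identities`, and
#'   `no_hsps` (TRUE when the HSP list was empty, in which case `f2` is
#'   reported as 0 by convention).
#' @export
ggdc_formulas <- function(hsps, len_a, len_b) {
  len_a <- assert_count(len_a, "len_a")
  len_b <- assert_count(len_b, "len_b")
  total <- (len_a + len_b) / 2
  if (is.null(hsps) || nrow(hsps) == 0L) {
    return(structure(list(f1 = 0, f2 = 0, f3 = 0, total_length = total,
                          hsp_length = 0, identities = 0, no_hsps = TRUE),
                     class = "ggdc_result"))
  }
  stopifnot(all(c("a_start", "a_end", "b_start", "b_end", "length",
                  "identities") %in% names(hsps)),
            all(hsps$identities <= hsps$length))
  ord <- order(-hsps$identities, hsps$a_start, hsps$b_start)
  h <- hsps[ord, , drop = FALSE]
  # per-base coverage masks; novel bases only, so nothing counts twice.
  # Masks may extend past len_* when coordinates live on a spacer-padded
  # concatenation of contigs (spacers are never covered, so the ratios
  # still use the true summed contig lengths).
  cov_a <- logical(max(len_a, h$a_end))
  cov_b <- logical(max(len_b, h$b_end))
  hsp_len <- 0
  ids <- 0
  for (i in seq_len(nrow(h))) {
    ia <- (h$a_start[i] + 1L):h$a_end[i]
    ib <- (h$b_start[i] + 1L):h$b_end[i]
    eff <- (sum(!cov_a[ia]) + sum(!cov_b[ib])) / 2
    hsp_len <- hsp_len + eff
    ids <- ids + h$identities[i] * eff / h$length[i]
    cov_a[ia] <- TRUE
    cov_b[ib] <- TRUE
  }
  structure(list(
    f1 = hsp_len / total, f2 = if (hsp_len > 0) ids / hsp_len else 0,
    f3 = ids / total, total_length = total, hsp_length = hsp_len,
    identities = ids, no_hsps = FALSE),
    class = "ggdc_result")
}

#' @export
print.ggdc_result <- function(x, ...) {
  cat("Genome-pair similarity (GGDC-style formulas)\n")
  cat(sprintf("  HSP length / total length : %.2f%%\n", 100 * x$f1))
  cat(sprintf("  identities / HSP length   : %.2f%%%s\n", 100 * x$f2,
              if (x$no_hsps) "  (no HSPs)" else ""))
  cat(sprintf("  identities / total length : %.2f%%\n", 100 * x$f3))
  invisible(x)
}

#' Write an HSP table as TSV
#'
#' @param hsps An `hsp_set` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hsps <- function(hsps, path) {
  utils::write.table(as.data.frame(hsps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
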