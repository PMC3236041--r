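#' Homology-call parameters
#'
#' Thresholds and scoring used for homolog detection between proteomes:
#' a hit counts as homologous when its E-value is at most `max_evalue`
#' AND its percent identity is at least `min_identity_pct` (both filters
#' conjunctive, mirroring the common "E <= 1e-5 and identity >= 30%"
#' convention of phylogenetic-profiler comparisons). E-values follow
#' Karlin-Altschul, \eqn{E = K m n e^{-\lambda s}}, with the published
#' gapped BLOSUM62 constants as defaults; under the `"effective"` search
#' space policy `n` is the summed length of the whole subject proteome
#' (database search semantics), under `"pairwise_product"` it is the
#' single subject's length.
#'
#' @param max_evalue Maximum E-value (default `1e-5`).
#' @param min_identity_pct Minimum percent identity over alignment columns
#'   (default 30).
#' @param gap_open,gap_extend Affine gap penalties; a gap of length L
#'   costs `gap_open + L * gap_extend` (BLAST convention; defaults 11, 1).
#' @param lambda,K Karlin-Altschul parameters for the raw score (defaults
#'   0.267 and 0.041, the published gapped BLOSUM62/11/1 values).
#' @param search_space `"effective"` or `"pairwise_product"`.
#' @return A `homology_params` list.
#' @export
homology_params <- function(max_evalue = 1e-5, min_identity_pct = 30,
                            gap_open = 11, gap_extend = 1,
                            lambda = 0.267, K = 0.041,
                            search_space = c("effective",
                                             "pairwise_product")) {
  search_space <- match.arg(search_space)
  if (max_evalue <= 0) stop("'max_evalue' must be positive", call. = FALSE)
  if (min_identity_pct <= 0 || min_identity_pct > 100) {
    stop("'min_identity_pct' must lie in (0, 100]", call. = FALSE)
  }
  structure(list(max_evalue = max_evalue,
                 min_identity_pct = min_identity_pct,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, search_space = search_space),
            class = "homology_params")
}

validate_protein <- function(seq, label) {
  chars <- strsplit(as.character(seq), "")[[1L]]
  bad <- which(!chars %in% c(AA20, "X"))
  if (length(bad)) {
    stop("invalid residue '", chars[bad[1L]], "' in sequence '", label,
         "' at position ", bad[1L], call. = FALSE)
  }
  invisible(TRUE)
}

blosum62 <- function() {
  # lazy-load Biostrings' BLOSUM62 once per session
  if (is.null(.cogent_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .cogent_env$BLOSUM62 <- e$BLOSUM62
  }
  .cogent_env$BLOSUM62
}

.cogent_env <- new.env(parent = emptyenv())

#' Best local alignment between two protein sequences
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps,
#' returning a BLAST-like hit record. Identity is computed over alignment
#' columns *including* gap columns. The E-value uses Karlin-Altschul with
#' the parameters in `params`; for a single pair the search space is
#' `nchar(a) * nchar(b)` (override `n_db` to score the hit against a
#' whole-database search space).
#'
#' @param seq_a,seq_b Protein sequences (character or `AAString`), drawn
#'   from the 20 amino acids plus `X`.
#' @param params A [homology_params()].
#' @param n_db Effective subject search-space length; defaults to
#'   `nchar(seq_b)`.
#' @return A one-row data frame: `qseqid`, `sseqid`, `score_raw`,
#'   `bitscore`, `evalue`, `length` (alignment columns), `identities`,
#'   `identity_pct`, `qstart`, `qend`, `sstart`, `send` (1-based
#'   inclusive).
#' @export
local_align <- function(seq_a, seq_b, params = homology_params(),
                        n_db = NULL) {
  qa <- as.character(seq_a)
  qb <- as.character(seq_b)
  if (!nzchar(qa) || !nzchar(qb)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  validate_protein(qa, "seq_a")
  validate_protein(qb, "seq_b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qa), Biostrings::AAString(qb),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  s <- Biostrings::score(aln)
  len <- Biostrings::nchar(aln)          # alignment columns incl. gaps
  ids <- Biostrings::nmatch(aln)
  if (is.null(n_db)) n_db <- nchar(qb)
  ev <- karlin_evalue(s, nchar(qa), n_db, params)
  data.frame(
    qseqid = "seq_a", sseqid = "seq_b",
    score_raw = s, bitscore = karlin_bits(s, params), evalue = ev,
    length = len, identities = ids,
    identity_pct = 100 * ids / len,
    qstart = Biostrings::start(Biostrings::pattern(aln)),
    qend = Biostrings::end(Biostrings::pattern(aln)),
    sstart = Biostrings::start(Biostrings::subject(aln)),
    send = Biostrings::end(Biostrings::subject(aln)))
}

karlin_evalue <- function(score, m, n, params) {
  params$K * as.numeric(m) * as.numeric(n) * exp(-params$lambda * score)
}

karlin_bits <- function(score, params) {
  (params$lambda * score - log(params$K)) / log(2)
}

# all-vs-all best local alignments of one query set against one subject
# set; returns the BLAST outfmt-6-like columns for every query/subject
# pair (one best-alignment row per pair)
align_all <- function(query, subject, params) {
  stopifnot(methods::is(query, "AAStringSet"),
            methods::is(subject, "AAStringSet"))
  nq <- length(query)
  ns <- length(subject)
  db_len <- sum(Biostrings::width(subject))
  rows <- vector("list", nq)
  for (i in seq_len(nq)) {
    aln <- Biostrings::pairwiseAlignment(
      subject, query[[i]], type = "local",
      substitutionMatrix = blosum62(),
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    s <- Biostrings::score(aln)
    len <- Biostrings::nchar(aln)
    ids <- Biostrings::nmatch(aln)
    mm <- Biostrings::nmismatch(aln)
    n_eff <- if (params$search_space == "effective") {
      rep(db_len, ns)
    } else {
      Biostrings::width(subject)
    }
    rows[[i]] <- data.frame(
      qseqid = names(query)[i], sseqid = names(subject),
      pident = 100 * ids / len, length = len, mismatch = mm,
      gapopen = gap_opens(aln),
      qstart = Biostrings::start(Biostrings::subject(aln)),
      qend = Biostrings::end(Biostrings::subject(aln)),
      sstart = Biostrings::start(Biostrings::pattern(aln)),
      send = Biostrings::end(Biostrings::pattern(aln)),
      evalue = karlin_evalue(s, Biostrings::width(query)[i], n_eff,
                             params),
      bitscore = karlin_bits(s, params),
      score_raw = s)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# number of gap openings (runs of '-') across both aligned strings
gap_opens <- function(aln) {
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  vapply(seq_along(pat), function(i) {
    n1 <- length(gregexpr("-+", pat[i])[[1L]])
    if (!grepl("-", pat[i], fixed = TRUE)) n1 <- 0L
    n2 <- length(gregexpr("-+", sub[i])[[1L]])
    if (!grepl("-", sub[i], fixed = TRUE)) n2 <- 0L
    as.integer(n1 + n2)
  }, integer(1))
}

#' All-vs-all homology hit table between two proteomes
#'
#' One row per query/subject pair holding the best local alignment, in
#' the familiar tabular (BLAST outfmt-6-like) column layout. No
#' thresholds are applied; see [homologs()] for filtered calls.
#'
#' @param proteome_a,proteome_b `AAStringSet` objects with gene ids as
#'   names.
#' @param params A [homology_params()].
#' @return Data frame with columns `qseqid`, `sseqid`, `pident`,
#'   `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore` (plus `score_raw`).
#' @export
homology_hits <- function(proteome_a, proteome_b,
                          params = homology_params()) {
  if (length(proteome_a) == 0L || length(proteome_b) == 0L) {
    stop("proteomes must be non-empty", call. = FALSE)
  }
  align_all(proteome_a, proteome_b, params)
}

#' Genes of one proteome with a homolog in another
#'
#' Directional homolog detection: returns the gene ids of `proteome_a`
#' that have at least one hit in `proteome_b` passing both thresholds
#' (E-value AND percent identity) of `params`.
#'
#' @inheritParams homology_hits
#' @return Character vector of `proteome_a` gene ids.
#' @export
homologs <- function(proteome_a, proteome_b,
                     params = homology_params()) {
  hits <- homology_hits(proteome_a, proteome_b, params)
  pass <- hits$evalue <= params$max_evalue &
    hits$pident >= params$min_identity_pct
  unique(hits$qseqid[pass])
}

#' Three-way Venn partition of proteomes by homology
#'
#' Classifies every gene of each proteome by which of the other two
#' proteomes contain a homolog of it (under the thresholds in `params`),
#' yielding the per-genome counts of the Venn regions: unique, shared
#' with exactly one other genome, shared with both. Counting is
#' gene-level and directional -- homology is not transitive, so region
#' counts are reported per genome rather than as one symmetric diagram.
#'
#' @param proteomes Named list of three `AAStringSet` objects.
#' @param params A [homology_params()].
#' @return Object of class `venn_partition`: list with `genomes`,
#'   `totals`, and `regions`, a data frame with one row per genome and
#'   columns `unique`, `with_<other1>_only`, `with_<other2>_only`,
#'   `shared_all` -- for each genome the four counts sum to its proteome
#'   size.
#' @export
venn3 <- function(proteomes, params = homology_params()) {
  if (length(proteomes) != 3L || is.null(names(proteomes))) {
    stop("'proteomes' must be a named list of three AAStringSets",
         call. = FALSE)
  }
  gn <- names(proteomes)
  regions <- vector("list", 3L)
  for (i in 1:3) {
    self <- gn[i]
    others <- gn[-i]
    ids <- names(proteomes[[self]])
    in1 <- ids %in% homologs(proteomes[[self]], proteomes[[others[1L]]],
                             params)
    in2 <- ids %in% homologs(proteomes[[self]], proteomes[[others[2L]]],
                             params)
    counts <- c(sum(!in1 & !in2), sum(in1 & !in2), sum(!in1 & in2),
                sum(in1 & in2))
    regions[[i]] <- stats::setNames(
      counts,
      c("unique", paste0("with_", others[1L], "_only"),
        paste0("with_", others[2L], "_only"), "shared_all"))
  }
  totals <- vapply(proteomes, length, integer(1))
  structure(list(genomes = gn, totals = totals, regions = regions,
                 params = unclass(params)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition of", paste(x$genomes, collapse = ", "),
      "(gene-level, per genome)\n")
  for (i in seq_along(x$genomes)) {
    cat(sprintf("  %s (n = %d): %s\n", x$genomes[i], x$totals[i],
                paste(names(x$regions[[i]]), x$regions[[i]],
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}
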