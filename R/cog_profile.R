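#' Read a gene-to-category assignment table
#'
#' Parses a 3-column tab-separated table with header
#' `genome_id<TAB>gene_id<TAB>category_id` (the IMG-export-like layout
#' written by [simulate_cog_table()]). Comment lines starting with `#` are
#' ignored. Exact duplicate triples are collapsed to a single row; row
#' order is otherwise preserved.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `genome_id`, `gene_id`, `category_id`.
#' @export
read_assignments <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("no header line found in ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (!identical(header, c("genome_id", "gene_id", "category_id"))) {
    stop("line ", lineno[1L],
         ": expected header 'genome_id\\tgene_id\\tcategory_id'",
         call. = FALSE)
  }
  fields <- fields[-1L]
  lineno <- lineno[-1L]
  if (length(fields) == 0L) {
    return(data.frame(genome_id = character(), gene_id = character(),
                      category_id = character()))
  }
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    bad <- which(nf != 3L)[1L]
    stop("line ", lineno[bad], ": expected 3 tab-separated columns, found ",
         nf[bad], call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  blank <- matrix(!nzchar(m), nrow = nrow(m))
  if (any(blank)) {
    bad <- which(rowSums(blank) > 0)[1L]
    stop("line ", lineno[bad], ": empty field", call. = FALSE)
  }
  df <- data.frame(genome_id = m[, 1L], gene_id = m[, 2L],
                   category_id = m[, 3L])
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an assignment table
#'
#' @param assignments Data frame as returned by [read_assignments()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(
    assignments[, c("genome_id", "gene_id", "category_id")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a category abundance profile for one genome
#'
#' Collapses gene-to-category assignments into per-category counts. Genes
#' carrying several category labels are handled by `multi_policy`:
#' `"per_pair"` (default) counts every distinct (gene, category) pair, so a
#' gene in k categories contributes k items and `N` counts gene-category
#' memberships; `"first_only"` keeps only the first listed category per
#' gene, so `N` equals the number of genes. Genes absent from the table
#' (unassigned) contribute nothing.
#'
#' @param assignments Data frame with `genome_id`, `gene_id`, `category_id`.
#' @param genome_id Which genome to profile.
#' @param multi_policy `"per_pair"` or `"first_only"`.
#' @return An object of class `abundance_profile`: list with `genome_id`,
#'   `counts` (named integer vector, category -> count), `N` (total items)
#'   and `S` (number of distinct categories).
#' @export
build_profile <- function(assignments, genome_id,
                          multi_policy = c("per_pair", "first_only")) {
  multi_policy <- match.arg(multi_policy)
  a <- assignments[assignments$genome_id == genome_id, , drop = FALSE]
  if (nrow(a) == 0L) {
    stop("no assignments for genome '", genome_id, "'", call. = FALSE)
  }
  if (multi_policy == "per_pair") {
    a <- a[!duplicated(a[, c("gene_id", "category_id")]), , drop = FALSE]
  } else {
    a <- a[!duplicated(a$gene_id), , drop = FALSE]
  }
  tab <- table(a$category_id)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(
    list(genome_id = genome_id, counts = counts,
         N = sum(counts), S = length(counts)),
    class = "abundance_profile")
}

#' Construct an abundance profile from raw counts
#'
#' Convenience constructor used when category counts are already known
#' (e.g. from a truth manifest or an external table).
#'
#' @param counts Named vector of positive category counts.
#' @param genome_id Genome label.
#' @return An `abundance_profile`.
#' @export
abundance_profile <- function(counts, genome_id = "genome") {
  if (length(counts) == 0L || any(counts < 1) ||
      any(counts != floor(counts))) {
    stop("'counts' must be positive integers", call. = FALSE)
  }
  if (is.null(names(counts))) {
    names(counts) <- sprintf("C%04d", seq_along(counts))
  }
  counts <- as.integer(round(counts)) |> stats::setNames(names(counts))
  structure(
    list(genome_id = genome_id, counts = counts,
         N = sum(counts), S = length(counts)),
    class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat("Abundance profile for '", x$genome_id, "': N = ", x$N,
      " items in S = ", x$S, " categories\n", sep = "")
  invisible(x)
}

#' Rank-frequency series of a profile
#'
#' Categories sorted by count in decreasing order (ties broken by
#' `category_id` ascending, a stable deterministic order), with relative
#' frequency `count / N`. This is the observed curve of a rank-abundance
#' plot; overlaying [broken_stick()] proportions gives the null curve.
#'
#' @param profile An `abundance_profile`.
#' @param top Number of top ranks to keep (default all).
#' @return Data frame with columns `rank`, `category_id`, `count`,
#'   `frequency`.
#' @export
rank_frequencies <- function(profile, top = Inf) {
  stopifnot(inherits(profile, "abundance_profile"))
  if (!is.numeric(top) || length(top) != 1L || is.na(top) || top < 1) {
    stop("'top' must be a number >= 1", call. = FALSE)
  }
  ord <- order(-profile$counts, names(profile$counts), method = "radix")
  counts <- profile$counts[ord]
  n <- min(length(counts), top)
  data.frame(
    rank = seq_len(n),
    category_id = names(counts)[seq_len(n)],
    count = as.integer(counts[seq_len(n)]),
    frequency = as.numeric(counts[seq_len(n)]) / profile$N,
    row.names = NULL)
}
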