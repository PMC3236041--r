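#' Over-represented categories under the broken-stick null
#'
#' Ranks categories by decreasing observed frequency and flags rank `i` as
#' over-represented when its observed relative frequency strictly exceeds
#' the broken-stick expectation for the same rank,
#' \eqn{p_i = (1/S)\sum_{k=i}^{S} 1/k}. The comparison is rank-positional:
#' tied categories keep their stable rank (ties sorted by `category_id`)
#' and each is compared against the expectation of its own rank, matching
#' the usual observed-vs-null curve overlay of rank-abundance plots.
#' Equality is not flagged ("larger than" read strictly).
#'
#' @param profile An `abundance_profile`.
#' @return Data frame with columns `rank`, `category_id`, `observed`
#'   (relative frequency), `expected` (broken-stick value), restricted to
#'   the flagged categories, ordered by rank.
#' @export
over_represented <- function(profile) {
  stopifnot(inherits(profile, "abundance_profile"))
  rf <- rank_frequencies(profile)
  expected <- broken_stick(profile$S)$proportions
  flag <- rf$frequency > expected
  data.frame(
    rank = rf$rank[flag],
    category_id = rf$category_id[flag],
    observed = rf$frequency[flag],
    expected = expected[flag],
    row.names = NULL)
}

#' Rank-frequency overlay table
#'
#' Full observed-vs-expected table used to re-draw rank-abundance figures:
#' one row per rank with the observed relative frequency, the broken-stick
#' expectation at that rank, and the over-representation flag.
#'
#' @param profile An `abundance_profile`.
#' @param top Ranks to keep (default all); flags are always computed on the
#'   full list before truncation.
#' @return Data frame with `rank`, `category_id`, `count`, `observed`,
#'   `expected`, `overrepresented`.
#' @export
rank_overlay <- function(profile, top = Inf) {
  rf <- rank_frequencies(profile)
  expected <- broken_stick(profile$S)$proportions
  out <- data.frame(
    rank = rf$rank, category_id = rf$category_id, count = rf$count,
    observed = rf$frequency, expected = expected,
    overrepresented = rf$frequency > expected)
  utils::head(out, n = if (is.finite(top)) top else nrow(out))
}

#' Gene-content redundancy report for one genome
#'
#' The package's central statistic. For a genome whose `N` genes fall into
#' `S` functional categories with counts \eqn{c_i}:
#' observed entropy \eqn{H = -\sum (c_i/N)\ln(c_i/N)}; the maximum
#' \eqn{H_{max} = \ln N} (every gene its own category); the chance
#' expectation \eqn{H_{exp}}, the entropy of the broken-stick distribution
#' for `S` categories. Evenness is `H/H_max`; redundancy is reported both
#' against the maximum (`1 - H/H_max`, in `[0, 1)`) and against chance
#' (`1 - H/H_exp`, negative when the genome is more even than a random
#' broken stick). Over-represented categories are called rank-positionally
#' via [over_represented()].
#'
#' @param profile An `abundance_profile`.
#' @return Object of class `redundancy_report`: list with `genome_id`,
#'   `N`, `S`, `H`, `H_max`, `H_exp`, `evenness`, `redundancy_max`,
#'   `redundancy_exp` (fractions) and `overrepresented` (data frame).
#' @examples
#' p <- abundance_profile(c(X = 10, Y = 3, Z = 2, W = 1))
#' redundancy_report(p)
#' @export
redundancy_report <- function(profile) {
  stopifnot(inherits(profile, "abundance_profile"))
  H <- shannon_entropy(profile$counts)
  idx <- redundancy_indices(H, profile$N, profile$S)
  structure(
    c(list(genome_id = profile$genome_id, N = profile$N, S = profile$S),
      idx,
      list(overrepresented = over_represented(profile))),
    class = "redundancy_report")
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat("Gene-content redundancy report for '", x$genome_id, "'\n", sep = "")
  cat(sprintf("  N = %d items in S = %d categories\n", x$N, x$S))
  cat(sprintf("  H = %.3f  H_max = %.3f  H_exp = %.3f nats\n",
              x$H, x$H_max, x$H_exp))
  cat(sprintf("  evenness H/H_max       = %.2f%%\n", 100 * x$evenness))
  cat(sprintf("  redundancy 1 - H/H_max = %.2f%%\n",
              100 * x$redundancy_max))
  cat(sprintf("  redundancy 1 - H/H_exp = %.2f%%\n",
              100 * x$redundancy_exp))
  cat(sprintf("  over-represented categories: %d\n",
              nrow(x$overrepresented)))
  invisible(x)
}

#' @export
format.redundancy_report <- function(x, ...) {
  utils::capture.output(print(x))
}
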