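#' Broken-stick expected rank-abundance distribution
#'
#' Expected relative abundances of `S` categories when a unit interval is
#' broken at `S - 1` uniformly random points and the pieces are sorted in
#' decreasing order. The expectation for rank `i` is
#' \deqn{p_i = \frac{1}{S} \sum_{k=i}^{S} \frac{1}{k}.}
#' This is the classical null model for rank-abundance curves: it describes
#' how uneven a set of category frequencies is expected to look by chance
#' alone, and serves both as the reference curve for over-representation
#' calls and as the source of the chance-expected entropy [h_exp()].
#'
#' @param S Number of categories (positive integer).
#' @return An object of class `broken_stick` with elements `S` and
#'   `proportions` (numeric vector of length `S`, strictly decreasing,
#'   summing to 1).
#' @examples
#' broken_stick(2)$proportions  # 0.75, 0.25
#' @seealso [h_exp()], [over_represented()]
#' @export
broken_stick <- function(S) {
  S <- assert_count(S, "S")
  # p_i = (1/S) * sum_{k=i..S} 1/k, computed as a reversed cumulative sum
  # so the whole vector costs O(S)
  p <- rev(cumsum(rev(1 / seq_len(S)))) / S
  structure(list(S = S, proportions = p), class = "broken_stick")
}

#' @export
print.broken_stick <- function(x, ...) {
  cat("Broken-stick expectation for", x$S, "categories\n")
  cat("  top ranks:", format(utils::head(x$proportions, 5), digits = 4), "\n")
  invisible(x)
}

#' Shannon entropy of a count vector
#'
#' \eqn{H = -\sum (c_i/N) \ln(c_i/N)} in nats (natural logarithm), where
#' `N` is the total count. Measures the evenness of the assignment of items
#' (genes) to categories (COGs).
#'
#' @param counts Vector of category counts, all \eqn{\ge 1} (categories with
#'   zero items are simply absent). Non-integer weights are accepted so the
#'   same function scores probability vectors.
#' @return Entropy in nats (non-negative scalar).
#' @examples
#' shannon_entropy(c(1, 1, 1, 1))  # log(4)
#' @export
shannon_entropy <- function(counts) {
  if (length(counts) == 0L) {
    stop("'counts' must contain at least one category", call. = FALSE)
  }
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts <= 0)) {
    stop("'counts' must be finite positive numbers", call. = FALSE)
  }
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Maximum entropy for N items
#'
#' The entropy of the maximally even gene-to-category assignment, in which
#' every category holds exactly one item: `H_max = ln(N)`, the logarithm of
#' the number of *items* (genes), not of the observed number of categories.
#'
#' @param N Total number of items (positive integer).
#' @return `log(N)` in nats.
#' @export
h_max <- function(N) {
  N <- assert_count(N, "N")
  log(N)
}

#' Chance-expected entropy under the broken-stick null
#'
#' Shannon entropy (nats) of the exact broken-stick expected distribution
#' for `S` categories, used as an estimate of the entropy expected by chance
#' for a genome whose genes fall into `S` categories. Computed from the
#' exact summed proportions, not the large-`S` asymptotic
#' \eqn{\ln S - (1 - \gamma)}.
#'
#' @param S Number of categories (positive integer).
#' @return Expected entropy in nats.
#' @examples
#' h_exp(1300)  # ~6.748
#' @export
h_exp <- function(S) {
  shannon_entropy(broken_stick(S)$proportions)
}

#' Evenness and redundancy indices from an observed entropy
#'
#' Given an observed entropy `H` (nats) for `N` genes assigned to `S`
#' categories, computes evenness `H / H_max` and the two redundancy
#' indices: `1 - H/H_max` (against the maximally even case, `H_max =
#' ln N`) and `1 - H/H_exp` (against the broken-stick chance expectation,
#' `H_exp = h_exp(S)`). The second index is negative when the observed
#' distribution is more even than a random broken stick.
#'
#' @param H Observed Shannon entropy in nats.
#' @param N Number of items (genes assigned to categories).
#' @param S Number of distinct categories observed.
#' @return A list with `H`, `H_max`, `H_exp`, `evenness`,
#'   `redundancy_max` and `redundancy_exp` (the last three as fractions,
#'   not percentages).
#' @examples
#' # genome with 2,022 genes in 1,300 COGs and observed entropy 6.912:
#' r <- redundancy_indices(6.912, N = 2022, S = 1300)
#' 100 * r$redundancy_max  # ~9.2%
#' @export
redundancy_indices <- function(H, N, S) {
  stopifnot(is.numeric(H), length(H) == 1L, is.finite(H), H >= 0)
  N <- assert_count(N, "N")
  S <- assert_count(S, "S")
  if (S > N) stop("S (categories) cannot exceed N (items)", call. = FALSE)
  Hmax <- h_max(N)
  Hexp <- h_exp(S)
  list(
    H = H, H_max = Hmax, H_exp = Hexp,
    evenness = if (Hmax > 0) H / Hmax else 1,
    redundancy_max = if (Hmax > 0) 1 - H / Hmax else 0,
    redundancy_exp = if (Hexp > 0) 1 - H / Hexp else 0
  )
}

# shared argument check: positive scalar whole number
assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= 1", name), call. = FALSE)
  }
  as.integer(x)
}
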