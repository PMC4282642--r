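#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least \code{k} category members when drawing
#' \code{n} items without replacement from a universe of \code{N} items of
#' which \code{K} belong to the category. Computed in log space so that
#' extreme tails (far below 1e-300 on the log scale) remain representable;
#' with \code{log = TRUE} the natural-log tail probability is returned and is
#' always finite.
#'
#' @param k Integer, observed overlap (vectorised).
#' @param N Integer, universe size.
#' @param K Integer, category size.
#' @param n Integer, drawn set size.
#' @param log Logical, return the natural-log probability.
#' @return Numeric vector of tail probabilities P(X >= k).
#' @examples
#' hypergeomSF(3, N = 10, K = 4, n = 5)   # 66/252
#' @export
hypergeomSF <- function(k, N, K, n, log = FALSE) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L)
  if (K > N || n > N) stop("'K' and 'n' must not exceed 'N'")
  if (any(k < 0) || any(k > pmin(K, n)))
    stop("'k' must lie in [0, min(K, n)]")
  lp <- stats::phyper(k - 1, m = K, n = N - K, k = n,
                      lower.tail = FALSE, log.p = TRUE)
  # k = 0 is the certain event; phyper(-1, ...) already yields log(1) = 0
  if (log) lp else exp(lp)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Pearson statistic without continuity correction, with the p-value from the
#' chi-square distribution on one degree of freedom. All four margins must be
#' positive. The statistic equals the square of the pooled two-proportion
#' z statistic on the same table.
#'
#' @param tab 2x2 numeric matrix of non-negative counts.
#' @return List with elements \code{statistic} and \code{p}.
#' @export
chiSquare2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("'tab' must be a 2x2 matrix")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins of the 2x2 table must be positive")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Two-proportion z-test with pooled variance
#'
#' Compares k1/n1 against k2/n2 with the pooled-proportion standard error and
#' a two-sided normal p-value. When the pooled proportion is 0 or 1 there is
#' no information in the data and (z = 0, p = 1) is returned. Vectorised over
#' all four arguments.
#'
#' @param k1,n1 Successes and trials in the first group.
#' @param k2,n2 Successes and trials in the second group.
#' @return List with numeric vectors \code{z} and \code{p}.
#' @export
twoProportionZTest <- function(k1, n1, k2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("'n1' and 'n2' must be positive")
  if (any(k1 < 0) || any(k2 < 0) || any(k1 > n1) || any(k2 > n2))
    stop("'k' must lie in [0, n]")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1)
  list(z = z, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment, returned in the original input order and capped at
#' 1. NA entries are preserved.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Numeric vector of adjusted p-values.
#' @export
bhFDR <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric category enrichment of a gene set
#'
#' Tests whether a gene set over-represents (upper tail) or under-represents
#' (lower tail) a category within a fixed universe, by identifier
#' intersection.
#'
#' @param geneSet Character vector, the set of interest.
#' @param category Character vector, the category members.
#' @param universe Character vector, the universe both sets live in.
#' @param tail Either "over" (default) or "under".
#' @return A one-row data.frame with columns \code{set_size},
#'   \code{category_size}, \code{universe_size}, \code{overlap},
#'   \code{expected}, \code{p}, \code{tail}.
#' @export
categoryEnrichment <- function(geneSet, category, universe,
                               tail = c("over", "under")) {
  tail <- match.arg(tail)
  geneSet <- unique(geneSet)
  category <- unique(category)
  universe <- unique(universe)
  bad <- setdiff(c(geneSet, category), universe)
  if (length(bad))
    stop("identifiers outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  N <- length(universe)
  K <- length(category)
  n <- length(geneSet)
  k <- length(intersect(geneSet, category))
  p <- if (tail == "over") {
    hypergeomSF(k, N = N, K = K, n = n)
  } else {
    stats::phyper(k, m = K, n = N - K, k = n, lower.tail = TRUE)
  }
  data.frame(set_size = n, category_size = K, universe_size = N,
             overlap = k, expected = n * K / N, p = p, tail = tail,
             stringsAsFactors = FALSE)
}
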