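#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on the observed margins, the count in the top-left cell
#' follows a hypergeometric distribution. The two-sided p-value is the
#' minimum-likelihood definition: the sum of the probabilities of all tables
#' with the same margins whose probability does not exceed the observed
#' table's, with a relative tie tolerance of `1e-7` (two-sided Fisher
#' variants differ; this is the classical definition and the one used by
#' most statistical software). Degenerate tables whose focal column margin
#' is empty or full have a single attainable table and return p = 1.
#'
#' @param a,b,c,d Non-negative integer cells: `a` = focal-category hits and
#'   `b` = other hits in the first group; `c`, `d` likewise in the second.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_two_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("contingency cells must be non-negative")
  k <- a + c
  n1 <- a + b
  n2 <- c + d
  if (k == 0L || k == n1 + n2 || n1 == 0L || n2 == 0L) return(1)
  lo <- max(0L, k - n2)
  hi <- min(k, n1)
  dens <- stats::dhyper(lo:hi, n1, n2, k)
  dobs <- stats::dhyper(a, n1, n2, k)
  p <- sum(dens[dens <= dobs * (1 + 1e-7)])
  min(1, p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted values are returned in the input order; each satisfies
#' `adjusted >= raw` and `adjusted <= 1`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of BH-adjusted p-values.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
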