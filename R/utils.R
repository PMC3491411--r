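#' Centered running mean with edge shrinkage
#'
#' Running mean over a window of `k` elements, centered on each element;
#' near the ends of the vector the window is truncated (shrinks) rather than
#' padded, so every output element is the mean of the observed neighbours.
#'
#' @param x Numeric vector.
#' @param k Odd window size in elements.
#' @return Numeric vector of the same length as `x`.
#' @export
running_mean <- function(x, k) {
  stopifnot(k >= 1, k %% 2 == 1)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Standard error of the single-CpG methylation estimate
#'
#' The raw proportion M/N estimates the methylation probability pi with
#' binomial standard error sqrt(pi * (1 - pi) / N). `max_single_cpg_se()`
#' gives its maximum over pi (attained at pi = 0.5), the worst-case
#' uncertainty of an unsmoothed estimate at a given coverage.
#'
#' @param pi Methylation probability in \[0, 1\].
#' @param coverage Read coverage N (> 0).
#' @return Standard error (numeric).
#' @examples
#' max_single_cpg_se(30)  # worst case at 30x coverage
#' @export
single_cpg_se <- function(pi, coverage) {
  stopifnot(all(pi >= 0 & pi <= 1), all(coverage > 0))
  sqrt(pi * (1 - pi) / coverage)
}

#' @rdname single_cpg_se
#' @export
max_single_cpg_se <- function(coverage) single_cpg_se(0.5, coverage)

#' Overlap length of closed genomic intervals
#'
#' @param s1,e1,s2,e2 Interval bounds (1-based inclusive); vectorised with
#'   recycling.
#' @return Overlap length in bp (0 when disjoint).
#' @export
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}
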