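#' Two-sided Fisher exact p-values for 2x2 tables, vectorised
#'
#' Computes the exact two-sided p-value for tables
#' \preformatted{  meth   unmeth
#'   a      b        (sample 1)
#'   c      d        (sample 2)}
#' by summing, over the hypergeometric support given the table margins, the
#' probabilities of all tables at most as probable as the observed one. This
#' is the same conditional test that [stats::fisher.test()] performs, written
#' as a vectorised routine because DMR window testing and subgenome site
#' classification run it tens of thousands of times per panel.
#'
#' A relative tolerance of 1e-7 is applied when comparing table
#' probabilities, the standard guard against ties being split by floating
#' point rounding.
#'
#' @param a,b,c,d Integer vectors (recycled) of cell counts; all `>= 0`.
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @export
fisher_p <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d))))
    stop("cell counts must be non-negative integers")
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]           # row 1 total
    m2 <- c[i] + d[i]           # row 2 total
    k  <- a[i] + c[i]           # first-column margin
    lo <- max(0L, k - m2)
    hi <- min(k, m1)
    x  <- lo:hi
    probs  <- stats::dhyper(x, m1, m2, k)
    p_obs  <- stats::dhyper(a[i], m1, m2, k)
    p[i]   <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper around [stats::p.adjust()] with `method = "BH"`; the step-up
#' procedure with monotonicity enforcement used for every q-value in the
#' pipeline.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be in [0, 1] and non-missing")
  stats::p.adjust(p, method = "BH")
}
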