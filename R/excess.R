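## The excess-of-cancer statistic: one-sided exact Poisson upper tail.

#' One-sided exact Poisson upper-tail probability
#'
#' Computes \code{P(X >= observed)} for \code{X ~ Poisson(expected)} by
#' numerically stable summation of probability-mass terms in log space: for
#' \code{observed > expected} the upper tail is accumulated directly with the
#' term recurrence until the terms fall below the running sum's floating
#' floor; otherwise the lower tail is accumulated and complemented.  Exact to
#' better than 10 significant digits for expected counts up to the tens of
#' thousands.
#'
#' @param observed non-negative integer case count (vectorised)
#' @param expected positive expected count (vectorised)
#' @return upper-tail probability in (0, 1]
#' @examples
#' poissonUpperTail(230, 174.9)   # 3.9e-05
#' poissonUpperTail(0, 5)         # 1
#' @export
poissonUpperTail <- function(observed, expected) {
  if (length(observed) != 1L || length(expected) != 1L) {
    return(mapply(poissonUpperTail, observed, expected, USE.NAMES = FALSE))
  }
  if (!is.finite(expected) || expected <= 0)
    stop("expected must be a positive number")
  if (!is.finite(observed) || observed < 0 ||
      abs(observed - round(observed)) > 1e-8)
    stop("observed must be a non-negative integer")
  k <- as.integer(round(observed))
  lam <- as.numeric(expected)
  if (k == 0L) return(1)
  if (k > lam) {
    ## sum pmf terms upward from k; terms are decreasing since k > lam
    lt0 <- k * log(lam) - lam - lgamma(k + 1)
    s <- 1; t <- 1; j <- k
    repeat {
      j <- j + 1L
      t <- t * lam / j
      s <- s + t
      if (t < s * 1e-18) break
    }
    exp(lt0 + log(s))
  } else {
    ## complement of the lower tail 0..k-1; terms increase toward k-1
    ltk <- (k - 1L) * log(lam) - lam - lgamma(k)
    s <- 1; t <- 1; j <- k - 1L
    while (j > 0L) {
      t <- t * j / lam
      s <- s + t
      j <- j - 1L
      if (t < s * 1e-18) break
    }
    1 - exp(ltk + log(s))
  }
}

#' Test a founder's descendants for an excess of cancer
#'
#' Observed is the number of eligible descendant cases; expected is the sum
#' of their cohort-specific rates; the p-value is the one-sided exact Poisson
#' upper tail.  A pedigree is flagged high-risk when p < alpha and the
#' observed count exceeds the expected count (deficits are never flagged).
#' For an ancestral couple, pass both ids: the union of their descendants is
#' tested.
#'
#' @param gen a \code{Genealogy}
#' @param ancestorIds one id, or two for a couple
#' @param cancerRecords data.frame with columns \code{id} and \code{site}
#' @param rateTable a \code{\linkS4class{RateTable}}
#' @param alpha significance level for the high-risk flag (default 0.05)
#' @return an \code{\linkS4class{ExcessResult}}; when the descendant set has
#'   no eligible members the result is marked untestable (p NA, not
#'   high-risk)
#' @export
testDescendants <- function(gen, ancestorIds, cancerRecords, rateTable,
                            alpha = 0.05) {
  desc <- descendants(gen, ancestorIds)
  expe <- expectedCases(rateTable, gen, desc)
  obs <- observedCases(rateTable, gen, desc, cancerRecords)
  if (expe <= 0) {
    return(new("ExcessResult", observed = as.integer(obs), expected = expe,
               pValue = NA_real_, highRisk = FALSE, alpha = alpha,
               nDescendants = length(desc), testable = FALSE))
  }
  p <- poissonUpperTail(obs, expe)
  new("ExcessResult", observed = as.integer(obs), expected = expe,
      pValue = p, highRisk = p < alpha && obs > expe, alpha = alpha,
      nDescendants = length(desc), testable = TRUE)
}
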