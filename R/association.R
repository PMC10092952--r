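## Independent-population validation: PC-based nearest-neighbour control
## matching and per-variant carrier association.

#' Match controls to cases by principal-component nearest neighbour
#'
#' Greedy 1:1 matching without replacement: cases are processed in id order
#' and each receives the still-available control nearest in Euclidean
#' distance on the first two principal components; distance ties are broken
#' by control id.  The procedure is fully deterministic.
#'
#' @param casePcs data.frame with columns \code{id}, \code{PC1}, \code{PC2}
#' @param controlPcs data.frame with the same columns; at least as many rows
#'   as \code{casePcs}
#' @return data.frame of matched pairs: \code{case_id}, \code{control_id},
#'   \code{distance}
#' @export
matchControls <- function(casePcs, controlPcs) {
  if (nrow(controlPcs) < nrow(casePcs))
    stop("fewer controls than cases")
  cases <- casePcs[order(casePcs$id), , drop = FALSE]
  ctrl <- controlPcs[order(controlPcs$id), , drop = FALSE]
  avail <- rep(TRUE, nrow(ctrl))
  out <- data.frame(case_id = cases$id, control_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    d <- sqrt((ctrl$PC1 - cases$PC1[i])^2 + (ctrl$PC2 - cases$PC2[i])^2)
    d[!avail] <- Inf
    j <- which(d == min(d))[1L]     # ctrl sorted by id => tie by control id
    out$control_id[i] <- as.character(ctrl$id[j])
    out$distance[i] <- d[j]
    avail[j] <- FALSE
  }
  out
}

#' Carrier case/control association for one variant
#'
#' Builds the 2x2 table of carrier status against case status.  The odds
#' ratio is the cross-product ratio, with a 0.5 continuity correction applied
#' to every cell (and flagged) when any cell is zero.  The p-value comes from
#' the two-sided Fisher exact test by default -- valid at the rare carrier
#' counts involved -- or from the chi-square test.
#'
#' @param caseCarriers,nCases carrier count and total among cases
#' @param controlCarriers,nControls carrier count and total among controls
#' @param method "fisher" (default) or "chisq"
#' @param threshold optional significance threshold (e.g. a Bonferroni
#'   threshold) used to fill the \code{significant} field
#' @return list: the four cell counts, \code{odds_ratio},
#'   \code{continuity_corrected}, \code{p_value}, \code{significant}
#' @export
carrierAssociation <- function(caseCarriers, nCases, controlCarriers,
                               nControls, method = c("fisher", "chisq"),
                               threshold = NULL) {
  method <- match.arg(method)
  if (nCases <= 0 || nControls <= 0) stop("zero totals")
  if (caseCarriers > nCases || controlCarriers > nControls ||
      caseCarriers < 0 || controlCarriers < 0)
    stop("carrier counts must lie in [0, totals]")
  a <- caseCarriers; b <- nCases - caseCarriers
  c <- controlCarriers; d <- nControls - controlCarriers
  cc <- any(c(a, b, c, d) == 0)
  or <- if (cc) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
        else (a * d) / (b * c)
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  p <- if (method == "fisher") stats::fisher.test(m)$p.value
       else suppressWarnings(stats::chisq.test(m)$p.value)
  list(case_carriers = a, case_noncarriers = b,
       control_carriers = c, control_noncarriers = d,
       odds_ratio = or, continuity_corrected = cc, p_value = p,
       significant = if (is.null(threshold)) NA else p < threshold)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05)
#' @param m number of tests (>= 1)
#' @return alpha / m
#' @examples
#' bonferroniThreshold(0.05, 840)   # 5.95e-05
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Flag principal-component outliers
#'
#' Simple plumbing: flags subjects whose PC1 or PC2 z-score exceeds
#' \code{zMax} in absolute value.  (The published analysis removed outliers
#' by an unstated rule; this helper is an optional convenience, not that
#' rule.)
#'
#' @param pcs data.frame with columns \code{id}, \code{PC1}, \code{PC2}
#' @param zMax absolute z-score radius (default 6)
#' @return logical vector, TRUE = outlier
#' @export
flagPcOutliers <- function(pcs, zMax = 6) {
  z1 <- (pcs$PC1 - mean(pcs$PC1)) / stats::sd(pcs$PC1)
  z2 <- (pcs$PC2 - mean(pcs$PC2)) / stats::sd(pcs$PC2)
  abs(z1) > zMax | abs(z2) > zMax
}
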