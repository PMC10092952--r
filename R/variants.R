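## Variant-level filters: rarity, functional class, RegulomeDB range,
## cousin-pair sharing, assay-performance classes, carrier-frequency cap.
##
## Variant tables are plain data.frames with (at least) the columns
## key, gene, functional_class, population_af, regulomedb, clinvar.

#' RegulomeDB score ordering
#'
#' Ordinal evidence levels that a noncoding variant has regulatory function,
#' strongest ("1a") to weakest ("6").
#' @export
regulomeLevels <- c("1a", "1b", "1c", "1d", "1e", "1f",
                    "2a", "2b", "2c", "3a", "3b", "4", "5", "6")

#' Coding functional classes retained by the coding filter
#' @export
codingClasses <- c("nonsynonymous", "frameshift", "startloss",
                   "startgain", "stoploss")

#' Retain rare variants
#'
#' Keeps variants with population allele frequency strictly below the
#' threshold.  Variants with no frequency record are retained as presumed
#' rare but flagged in the added \code{af_missing} column so they remain
#' auditable.
#'
#' @param variants variant annotation data.frame
#' @param afThreshold strict upper bound on population AF (default 0.005)
#' @return filtered data.frame with an \code{af_missing} logical column
#' @export
filterRare <- function(variants, afThreshold = 0.005) {
  missing <- is.na(variants$population_af)
  keep <- missing | variants$population_af < afThreshold
  out <- variants[keep, , drop = FALSE]
  out$af_missing <- missing[keep]
  rownames(out) <- NULL
  out
}

#' Retain coding variants
#'
#' Keeps exactly the five coding classes: nonsynonymous, frameshift,
#' startloss, startgain, stoploss.
#'
#' @param variants variant annotation data.frame
#' @return filtered data.frame
#' @export
filterCoding <- function(variants) {
  out <- variants[variants$functional_class %in% codingClasses, ,
                  drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain noncoding/UTR variants in a RegulomeDB score range
#'
#' Keeps noncoding and UTR variants whose RegulomeDB score lies in the closed
#' ordinal range [low, high] (default "2a" to "4").  Scores stronger than the
#' range (e.g. "1b") are outside it and removed, as are variants lacking a
#' score.
#'
#' @param variants variant annotation data.frame
#' @param low,high closed range bounds on the RegulomeDB scale
#' @return filtered data.frame
#' @export
filterRegulome <- function(variants, low = "2a", high = "4") {
  stopifnot(low %in% regulomeLevels, high %in% regulomeLevels)
  sc <- variants$regulomedb
  bad <- !is.na(sc) & !(sc %in% regulomeLevels)
  if (any(bad))
    stop("unknown RegulomeDB score token: ",
         paste(unique(sc[bad]), collapse = ", "))
  rk <- match(sc, regulomeLevels)
  keep <- variants$functional_class %in% c("noncoding", "UTR") &
    !is.na(rk) &
    rk >= match(low, regulomeLevels) & rk <= match(high, regulomeLevels)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variants shared within affected cousin pairs
#'
#' A variant is shared by a pair when both members carry at least one
#' alternate allele (het or hom).  Output is restricted to variants whose
#' total alternate-allele count among the genotyped individuals exceeds 1.
#' Pairs with a member absent from \code{genotypedIds} are skipped with a
#' warning.
#'
#' @param carrierSets named list of \code{\linkS4class{CarrierSet}} (names =
#'   variant keys)
#' @param cousinPairs data.frame with columns \code{id_a}, \code{id_b}
#' @param genotypedIds ids with genotype data; NULL to assume all pair
#'   members were genotyped
#' @return named list: variant key -> data.frame of the sharing pairs
#'   (\code{id_a}, \code{id_b}); variants shared by no pair are absent
#' @export
sharedInPairs <- function(carrierSets, cousinPairs, genotypedIds = NULL) {
  pairs <- cousinPairs
  if (!is.null(genotypedIds)) {
    ok <- pairs$id_a %in% genotypedIds & pairs$id_b %in% genotypedIds
    if (any(!ok))
      warning(sum(!ok), " cousin pairs skipped: member(s) without genotype data")
    pairs <- pairs[ok, , drop = FALSE]
  }
  out <- list()
  for (cs in carrierSets) {
    alleles <- length(cs@hetIds) + 2L * length(cs@homIds)
    if (alleles <= 1L) next
    carriers <- c(cs@hetIds, cs@homIds)
    hit <- pairs$id_a %in% carriers & pairs$id_b %in% carriers
    if (any(hit))
      out[[cs@variantKey]] <- pairs[hit, c("id_a", "id_b"), drop = FALSE]
  }
  out
}

#' Classify assay performance of a variant
#'
#' The four classes partition the assayed variants:
#' \code{failed_no_carriers} (no het carriers identified at all),
#' \code{failed_pair_missing} (het carriers found, but the original sharing
#' cousin pair was not fully recovered), \code{pair_only} (exactly the
#' original pair and nobody else), \code{pair_plus_additional} (the original
#' pair plus further het carriers -- only these proceed to segregation).
#' Only heterozygous carriers enter the classification.
#'
#' @param carrierSet a \code{\linkS4class{CarrierSet}} from the assay
#' @param originalPairIds ids of the cousin pair member(s) the variant was
#'   originally shared in (non-empty)
#' @return one of the four class labels
#' @export
classifyAssay <- function(carrierSet, originalPairIds) {
  originalPairIds <- unique(as.character(originalPairIds))
  if (!length(originalPairIds)) stop("originalPairIds must be non-empty")
  het <- carrierSet@hetIds
  if (!length(het)) return("failed_no_carriers")
  if (!all(originalPairIds %in% het)) return("failed_pair_missing")
  if (setequal(het, originalPairIds)) return("pair_only")
  "pair_plus_additional"
}

#' Carrier-frequency cap for assayed variants
#'
#' Drops a variant when its het carriers exceed \code{maxFraction} of the
#' assayed panel (strict inequality): such frequencies are incompatible with
#' the presumed rarity and indicate either a misreported population
#' frequency or an assay failure.
#'
#' @param carrierSet a \code{\linkS4class{CarrierSet}} restricted to the
#'   assayed panel
#' @param nAssayed size of the assayed panel (> 0)
#' @param maxFraction maximal tolerated het-carrier fraction (default 0.10)
#' @return TRUE to keep, FALSE to drop
#' @export
carrierFrequencyFilter <- function(carrierSet, nAssayed, maxFraction = 0.10) {
  stopifnot(nAssayed > 0)
  length(carrierSet@hetIds) <= maxFraction * nAssayed
}
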