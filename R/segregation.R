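## Candidate selection: clusters of related het carriers whose founding
## ancestor's descendants show a significant cancer excess.

#' Find variants segregating in high-risk pedigrees
#'
#' The selection pipeline, per variant: (1) drop variants whose het-carrier
#' count exceeds the carrier-frequency cap in the assayed panel; (2) cluster
#' the het carriers by recorded common ancestry and keep clusters of at least
#' \code{minCluster} members; (3) locate each cluster's founding common
#' ancestor; (4) test the founder's descendants for an excess of cancer;
#' (5) keep the clusters whose founder pedigree is high-risk.  Clusters whose
#' members have no single common ancestor cannot be tested and are dropped.
#'
#' @param carrierSets named list of \code{\linkS4class{CarrierSet}} restricted
#'   to the assayed case panel
#' @param gen a \code{Genealogy}
#' @param cancerRecords data.frame with columns \code{id} and \code{site}
#' @param rateTable a \code{\linkS4class{RateTable}}
#' @param nAssayed size of the assayed panel
#' @param minCluster minimal carrier-cluster size (default 3)
#' @param alpha significance level of the excess test (default 0.05)
#' @param maxCarrierFraction carrier-frequency cap (default 0.10)
#' @param maxMeioses relatedness cap passed to
#'   \code{\link{relatednessClusters}} (default unlimited)
#' @return list of \code{\linkS4class{SegregatingCluster}}, sorted by
#'   (variant key, founder id); empty list when nothing segregates
#' @export
findSegregating <- function(carrierSets, gen, cancerRecords, rateTable,
                            nAssayed, minCluster = 3L, alpha = 0.05,
                            maxCarrierFraction = 0.10, maxMeioses = Inf) {
  out <- list()
  for (cs in carrierSets) {
    if (!carrierFrequencyFilter(cs, nAssayed, maxCarrierFraction)) next
    if (length(cs@hetIds) < minCluster) next
    clusters <- relatednessClusters(gen, cs@hetIds, minSize = minCluster,
                                    maxMeioses = maxMeioses)
    for (cl in clusters) {
      if (is.null(cl$founder)) next
      ex <- testDescendants(gen, cl$founder$ids, cancerRecords, rateTable,
                            alpha = alpha)
      if (ex@testable && ex@highRisk) {
        out[[length(out) + 1L]] <- new("SegregatingCluster",
          variantKey = cs@variantKey, carrierIds = cl$ids,
          founderIds = cl$founder$ids, founderCouple = cl$founder$couple,
          excess = ex)
      }
    }
  }
  if (length(out) > 1L) {
    key <- vapply(out, function(x)
      paste(x@variantKey, x@founderIds[1L]), character(1))
    out <- out[order(key)]
  }
  out
}

#' Summarise segregating candidate variants
#'
#' One row per distinct variant: gene, ClinVar class, number of segregating
#' clusters, size of the largest cluster, and the best (smallest) founder
#' p-value; plus deduplicated variant and gene counts.
#'
#' @param clusters list of \code{\linkS4class{SegregatingCluster}} from
#'   \code{\link{findSegregating}}
#' @param variantAnnotations annotation data.frame with columns \code{key},
#'   \code{gene}, \code{clinvar}
#' @return list with \code{candidates} (data.frame), \code{nVariants},
#'   \code{nGenes}
#' @export
summarizeCandidates <- function(clusters, variantAnnotations) {
  if (!length(clusters)) {
    return(list(candidates = data.frame(
      variant_key = character(), gene = character(), clinvar = character(),
      n_clusters = integer(), largest_cluster = integer(),
      best_p = numeric(), stringsAsFactors = FALSE),
      nVariants = 0L, nGenes = 0L))
  }
  keys <- vapply(clusters, function(x) x@variantKey, character(1))
  sizes <- vapply(clusters, function(x) length(x@carrierIds), integer(1))
  ps <- vapply(clusters, function(x) x@excess@pValue, numeric(1))
  uk <- sort(unique(keys))
  ann <- variantAnnotations[match(uk, variantAnnotations$key), , drop = FALSE]
  candidates <- data.frame(
    variant_key = uk,
    gene = as.character(ann$gene),
    clinvar = as.character(ann$clinvar),
    n_clusters = as.integer(tapply(keys, keys, length)[uk]),
    largest_cluster = as.integer(tapply(sizes, keys, max)[uk]),
    best_p = as.numeric(tapply(ps, keys, min)[uk]),
    stringsAsFactors = FALSE)
  rownames(candidates) <- NULL
  list(candidates = candidates, nVariants = length(uk),
       nGenes = length(unique(candidates$gene[!is.na(candidates$gene)])))
}
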