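#' @import methods
#' @importFrom stats rbinom rpois rnorm runif setNames fisher.test chisq.test
#' @importFrom utils read.delim read.csv write.csv head
NULL

## ---------------------------------------------------------------------------
## Genealogy
## ---------------------------------------------------------------------------

#' Pedigree graph of a founder-population genealogy
#'
#' A \code{Genealogy} holds one row per individual (id, parent ids, sex, birth
#' year, a birthplace flag and an optional death year) together with derived
#' integer parent/child adjacency and, for every individual, the depth of the
#' deepest recorded ancestor line (the number of generations of genealogy the
#' individual links to).
#'
#' Individuals with no recorded parents are founders.  Parent links form a
#' directed acyclic graph; a recorded father must not be female and a recorded
#' mother must not be male.  Parent ids that do not resolve to a row are
#' treated as external/unknown (with a warning at construction).
#'
#' @slot ped data.frame with columns \code{id}, \code{father_id},
#'   \code{mother_id}, \code{sex} ("male"/"female"/"unknown"),
#'   \code{birth_year}, \code{birth_in_region} (logical), \code{death_year}.
#' @slot fidx,midx integer row index of father/mother (\code{NA} if unknown).
#' @slot children list of integer vectors: row indices of each individual's
#'   children.
#' @slot depth integer: generations of genealogy linked above each individual
#'   (0 for founders).
#' @export
setClass("Genealogy",
  representation(ped = "data.frame", fidx = "integer", midx = "integer",
                 children = "list", depth = "integer"))

setValidity("Genealogy", function(object) {
  p <- object@ped
  need <- c("id", "father_id", "mother_id", "sex", "birth_year",
            "birth_in_region", "death_year")
  if (!all(need %in% names(p)))
    return(paste("ped must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p$id)) return("individual ids must be unique")
  if (!all(p$sex %in% c("male", "female", "unknown")))
    return("sex must be male/female/unknown")
  f <- object@fidx[!is.na(object@fidx)]
  if (length(f) && any(p$sex[f] == "female"))
    return("a recorded father has sex female")
  m <- object@midx[!is.na(object@midx)]
  if (length(m) && any(p$sex[m] == "male"))
    return("a recorded mother has sex male")
  ## acyclicity is established by the depth computation at construction
  if (length(object@depth) != nrow(p)) return("depth length mismatch")
  TRUE
})

#' @describeIn Genealogy number of individuals
#' @param x a \code{Genealogy}
#' @export
setMethod("length", "Genealogy", function(x) nrow(x@ped))

setMethod("show", "Genealogy", function(object) {
  p <- object@ped
  cat("Genealogy with", nrow(p), "individuals\n")
  cat("  founders:", sum(object@depth == 0L),
      " max generations linked:", max(object@depth), "\n")
  by <- p$birth_year[!is.na(p$birth_year)]
  if (length(by)) cat("  birth years:", min(by), "-", max(by), "\n")
})

## ---------------------------------------------------------------------------
## RateTable
## ---------------------------------------------------------------------------

#' Cohort-specific baseline cancer rates
#'
#' One row per birth-cohort stratum (5-year birth-year bin x birthplace flag x
#' sex): the number of cases, the number of persons with qualifying genealogy,
#' and their ratio -- the empirical lifetime rate used as the null expectation
#' in the excess test.  The eligibility rule that defined the denominators
#' (sex, minimum generations of genealogy, known birth year) is stored with
#' the table so expected counts are computed over exactly the same population.
#'
#' @slot strata data.frame: \code{bin_start}, \code{born_in_region},
#'   \code{cases}, \code{persons}, \code{rate}.
#' @slot site cancer site the rates refer to.
#' @slot sexFilter sex the rates were estimated for.
#' @slot minGenerations minimum generations of linked genealogy for
#'   eligibility.
#' @slot binOrigin origin year of the 5-year binning.
#' @export
setClass("RateTable",
  representation(strata = "data.frame", site = "character",
                 sexFilter = "character", minGenerations = "numeric",
                 binOrigin = "numeric"))

setValidity("RateTable", function(object) {
  s <- object@strata
  if (!all(c("bin_start", "born_in_region", "cases", "persons", "rate") %in%
           names(s)))
    return("strata must have bin_start, born_in_region, cases, persons, rate")
  if (nrow(s)) {
    if (any(s$persons < 1)) return("every stratum needs persons >= 1")
    if (any(s$cases < 0)) return("negative case count")
    if (any(abs(s$rate - s$cases / s$persons) > 1e-12))
      return("rate must equal cases/persons")
    if (any(s$rate < 0 | s$rate > 1)) return("rates must lie in [0,1]")
  }
  TRUE
})

setMethod("show", "RateTable", function(object) {
  cat("RateTable:", nrow(object@strata), "cohort strata for site",
      sQuote(object@site), "\n")
  cat("  eligibility: sex =", object@sexFilter, ", >=",
      object@minGenerations, "generations, known birth year\n")
  cat("  total:", sum(object@strata$cases), "cases /",
      sum(object@strata$persons), "persons\n")
})

## ---------------------------------------------------------------------------
## ExcessResult
## ---------------------------------------------------------------------------

#' Result of the excess-of-cancer test on a descendant set
#'
#' @slot observed observed case count among eligible descendants.
#' @slot expected expected count (sum of cohort rates).
#' @slot pValue one-sided exact Poisson upper-tail p-value P(X >= observed),
#'   \code{NA} when untestable.
#' @slot highRisk TRUE when pValue < alpha and observed > expected.
#' @slot alpha significance level used for flagging.
#' @slot nDescendants number of eligible descendants tested.
#' @slot testable FALSE when the descendant set had no eligible members
#'   (expected count 0), in which case no test is defined.
#' @export
setClass("ExcessResult",
  representation(observed = "integer", expected = "numeric",
                 pValue = "numeric", highRisk = "logical", alpha = "numeric",
                 nDescendants = "integer", testable = "logical"))

setValidity("ExcessResult", function(object) {
  if (object@observed < 0) return("observed must be >= 0")
  if (object@testable && object@expected <= 0)
    return("a testable result needs expected > 0")
  if (object@testable &&
      object@highRisk != (object@pValue < object@alpha &&
                          object@observed > object@expected))
    return("highRisk must equal (pValue < alpha) & (observed > expected)")
  TRUE
})

setMethod("show", "ExcessResult", function(object) {
  if (!object@testable) {
    cat("ExcessResult: untestable (no eligible descendants)\n")
  } else {
    cat(sprintf(
      "ExcessResult: observed %d, expected %.1f, p = %.2g%s\n",
      object@observed, object@expected, object@pValue,
      if (object@highRisk) " [high-risk]" else ""))
  }
})

## ---------------------------------------------------------------------------
## CarrierSet
## ---------------------------------------------------------------------------

#' Carriers of one variant
#'
#' @slot variantKey variant identifier, "seq_<chrom>_<pos>_<ref>-<alt>_<gene>"
#'   style.
#' @slot hetIds ids of heterozygous carriers.
#' @slot homIds ids of homozygous alternate carriers.
#' @export
setClass("CarrierSet",
  representation(variantKey = "character", hetIds = "character",
                 homIds = "character"))

setValidity("CarrierSet", function(object) {
  if (length(intersect(object@hetIds, object@homIds)))
    return("het and hom carrier sets must be disjoint")
  TRUE
})

setMethod("show", "CarrierSet", function(object) {
  cat("CarrierSet", object@variantKey, ":", length(object@hetIds), "het,",
      length(object@homIds), "hom carriers\n")
})

#' Construct a CarrierSet
#' @param variantKey variant identifier
#' @param hetIds,homIds carrier id vectors
#' @return a \code{CarrierSet}
#' @export
CarrierSet <- function(variantKey, hetIds = character(),
                       homIds = character()) {
  new("CarrierSet", variantKey = as.character(variantKey),
      hetIds = as.character(hetIds), homIds = as.character(homIds))
}

## ---------------------------------------------------------------------------
## SegregatingCluster
## ---------------------------------------------------------------------------

#' A variant-sharing carrier cluster with a high-risk founding pedigree
#'
#' @slot variantKey the shared variant.
#' @slot carrierIds related het carriers in the cluster (>= the minimum
#'   cluster size).
#' @slot founderIds founding common ancestor (one id, or two for a couple).
#' @slot founderCouple TRUE when founderIds is a married pair.
#' @slot excess the \code{ExcessResult} for the founder's descendants.
#' @export
setClass("SegregatingCluster",
  representation(variantKey = "character", carrierIds = "character",
                 founderIds = "character", founderCouple = "logical",
                 excess = "ExcessResult"))

setMethod("show", "SegregatingCluster", function(object) {
  cat(sprintf("SegregatingCluster %s: %d carriers, founder %s (O=%d, E=%.1f, p=%.2g)\n",
              object@variantKey, length(object@carrierIds),
              paste(object@founderIds, collapse = "+"),
              object@excess@observed, object@excess@expected,
              object@excess@pValue))
})

## ---------------------------------------------------------------------------
## Simulation classes
## ---------------------------------------------------------------------------

#' Configuration of the genealogy/genotype/phenotype simulator
#'
#' See \code{\link{simulateStudy}} for the meaning of the fields and the
#' rationale behind the defaults.
#'
#' @export
setClass("SimConfig",
  representation(nFounderCouples = "integer", nGenerations = "integer",
                 offspringMean = "numeric", marriageRate = "numeric",
                 immigrantRate = "numeric", founderBirthYear = "integer",
                 generationGap = "numeric", birthJitter = "numeric",
                 baselineRates = "function", plantedVariants = "list",
                 neutralVariantCount = "integer", neutralAfRange = "numeric",
                 registryStart = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nFounderCouples < 1) return("need >= 1 founder couple")
  if (object@nGenerations < 1) return("need >= 1 generation")
  if (any(object@offspringMean < 0)) return("offspringMean must be >= 0")
  if (object@marriageRate < 0 || object@marriageRate > 1)
    return("marriageRate must be in [0,1]")
  if (object@immigrantRate < 0 || object@immigrantRate > 1)
    return("immigrantRate must be in [0,1]")
  for (pv in object@plantedVariants) {
    if (is.null(pv$relativeRisk) || pv$relativeRisk < 1)
      return("planted relativeRisk must be >= 1")
    if (!is.null(pv$populationAf) &&
        (pv$populationAf < 0 || pv$populationAf > 1))
      return("planted populationAf must be in [0,1]")
  }
  TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nFounderCouples, "founder couples,",
      object@nGenerations, "generations, seed", object@seed, "\n")
  cat("  planted variants:", length(object@plantedVariants),
      " neutral variants:", object@neutralVariantCount, "\n")
})

#' Output of one simulated study
#'
#' @slot genealogy the simulated \code{Genealogy}.
#' @slot cancerRecords data.frame \code{id}, \code{site}, \code{dx_year},
#'   \code{lethal}.
#' @slot genotypes integer matrix, variants x individuals, alternate-allele
#'   counts 0/1/2.
#' @slot carrierSets list of \code{CarrierSet}, one per variant.
#' @slot annotation variant annotation data.frame (key, gene, class,
#'   population_af, regulomedb, clinvar).
#' @slot truth data.frame recording planted variants: key, founder id,
#'   relative risk, carrier ids.
#' @slot config the \code{SimConfig} that produced the output.
#' @export
setClass("SimOutput",
  representation(genealogy = "Genealogy", cancerRecords = "data.frame",
                 genotypes = "matrix", carrierSets = "list",
                 annotation = "data.frame", truth = "data.frame",
                 config = "SimConfig"))

setValidity("SimOutput", function(object) {
  for (tr in seq_len(nrow(object@truth))) {
    key <- object@truth$variant_key[tr]
    cs <- object@carrierSets[[key]]
    if (is.null(cs)) return("truth variant missing from carrier sets")
    want <- sort(unlist(strsplit(object@truth$carrier_ids[tr], ",")))
    got <- sort(c(cs@hetIds, cs@homIds))
    if (!identical(want, got))
      return("truth carriers must equal genotype carriers")
  }
  TRUE
})

setMethod("show", "SimOutput", function(object) {
  cat("SimOutput:", length(object@genealogy), "individuals,",
      nrow(object@cancerRecords), "cancer records,",
      nrow(object@genotypes), "variants (", nrow(object@truth), "planted)\n")
})
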