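## Birth-cohort strata and cohort-specific baseline rates.

.cohortKey <- function(binStart, bornInRegion) {
  paste0(binStart, "|", ifelse(bornInRegion, "R", "O"))
}

#' Assign individuals to 5-year birth cohorts
#'
#' Deterministic half-open binning \code{[origin + 5k, origin + 5k + 5)} of
#' the birth year, combined with the birthplace flag.  Individuals with an
#' unknown birth year or unknown sex cannot be cohort-assigned and are
#' returned as NA (they are excluded from rate estimation and contribute 0
#' expected cases).
#'
#' @param gen a \code{Genealogy}
#' @param ids individual ids (default: all)
#' @param binOrigin origin year of the binning (default 1800)
#' @return data.frame with \code{id}, \code{bin_start}, \code{born_in_region},
#'   \code{sex}, \code{key}; \code{bin_start} and \code{key} are NA for
#'   unassignable individuals
#' @export
assignCohort <- function(gen, ids = NULL, binOrigin = 1800) {
  i <- if (is.null(ids)) seq_len(length(gen)) else .idx(gen, ids)
  p <- gen@ped[i, , drop = FALSE]
  by <- p$birth_year
  binStart <- binOrigin + 5L * (as.integer(floor((by - binOrigin) / 5)))
  region <- p$birth_in_region
  region[is.na(region)] <- FALSE
  ok <- !is.na(by) & p$sex %in% c("male", "female")
  key <- ifelse(ok, .cohortKey(binStart, region), NA_character_)
  data.frame(id = p$id,
             bin_start = ifelse(ok, binStart, NA_integer_),
             born_in_region = region, sex = p$sex, key = key,
             stringsAsFactors = FALSE)
}

## eligibility predicate shared by rate estimation and expected counts
.eligibleRows <- function(gen, sexFilter, minGenerations) {
  gen@ped$sex == sexFilter &
    !is.na(gen@ped$birth_year) &
    gen@depth >= minGenerations
}

#' Estimate cohort-specific cancer rates
#'
#' Persons per cohort are the eligible individuals (given sex, at least
#' \code{minGenerations} generations of linked genealogy, known birth year);
#' cases are the eligible individuals with at least one record of the given
#' site.  The rate is cases/persons: a lifetime per-person rate (the
#' denominators are persons, not person-years).  Cohorts with no eligible
#' persons are absent from the table.
#'
#' @param gen a \code{Genealogy}
#' @param cancerRecords data.frame with columns \code{id} and \code{site}
#' @param site cancer site to estimate rates for
#' @param sexFilter sex defining the population at risk (default "male")
#' @param minGenerations minimum generations of genealogy (default 3)
#' @param binOrigin origin year of the 5-year binning (default 1800)
#' @return a \code{\linkS4class{RateTable}}
#' @export
estimateRates <- function(gen, cancerRecords, site, sexFilter = "male",
                          minGenerations = 3, binOrigin = 1800) {
  elig <- .eligibleRows(gen, sexFilter, minGenerations)
  co <- assignCohort(gen, binOrigin = binOrigin)
  use <- elig & !is.na(co$key)
  caseIds <- unique(cancerRecords$id[cancerRecords$site == site])
  isCase <- use & (gen@ped$id %in% caseIds)
  if (!any(isCase))
    warning("no eligible cases of site ", sQuote(site),
            "; all rates are zero")
  persons <- table(co$key[use])
  cases <- table(factor(co$key[isCase], levels = names(persons)))
  keys <- names(persons)
  parts <- strsplit(keys, "|", fixed = TRUE)
  strata <- data.frame(
    bin_start = as.integer(vapply(parts, `[`, "", 1L)),
    born_in_region = vapply(parts, `[`, "", 2L) == "R",
    cases = as.integer(cases), persons = as.integer(persons),
    stringsAsFactors = FALSE)
  strata$rate <- strata$cases / strata$persons
  strata <- strata[order(strata$bin_start, strata$born_in_region), ]
  rownames(strata) <- NULL
  new("RateTable", strata = strata, site = site, sexFilter = sexFilter,
      minGenerations = as.numeric(minGenerations),
      binOrigin = as.numeric(binOrigin))
}

#' Expected case count for a set of individuals
#'
#' Sums the cohort-specific rate over the eligible members of \code{ids}
#' (same eligibility rule the rate table was built with).  Members falling in
#' cohorts absent from the table contribute 0, with a warning.
#'
#' @param rateTable a \code{\linkS4class{RateTable}}
#' @param gen the \code{Genealogy} the individuals belong to
#' @param ids individual ids (typically a descendant set)
#' @return non-negative expected count
#' @export
expectedCases <- function(rateTable, gen, ids) {
  ids <- unique(as.character(ids))
  if (!length(ids)) return(0)
  i <- .idx(gen, ids)
  elig <- .eligibleRows(gen, rateTable@sexFilter,
                        rateTable@minGenerations)[i]
  co <- assignCohort(gen, ids, binOrigin = rateTable@binOrigin)
  keys <- co$key[elig & !is.na(co$key)]
  if (!length(keys)) return(0)
  s <- rateTable@strata
  rate <- s$rate[match(keys, .cohortKey(s$bin_start, s$born_in_region))]
  if (anyNA(rate)) {
    warning(sum(is.na(rate)),
            " individuals fall in cohorts absent from the rate table; ",
            "they contribute 0 expected cases")
    rate[is.na(rate)] <- 0
  }
  sum(rate)
}

#' Observed case count for a set of individuals
#'
#' Number of eligible members of \code{ids} with at least one record of the
#' rate table's site (persons, not records, are counted).
#'
#' @inheritParams expectedCases
#' @param cancerRecords data.frame with columns \code{id} and \code{site}
#' @return integer count
#' @export
observedCases <- function(rateTable, gen, ids, cancerRecords) {
  ids <- unique(as.character(ids))
  if (!length(ids)) return(0L)
  i <- .idx(gen, ids)
  elig <- .eligibleRows(gen, rateTable@sexFilter,
                        rateTable@minGenerations)[i]
  co <- assignCohort(gen, ids, binOrigin = rateTable@binOrigin)
  ok <- elig & !is.na(co$key)
  caseIds <- unique(cancerRecords$id[cancerRecords$site == rateTable@site])
  sum(ids[ok] %in% caseIds)
}
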