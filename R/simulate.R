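## Synthetic founder-population genealogies with Mendelian gene dropping,
## cohort-dependent baseline phenotypes and planted risk variants.

#' Default cohort-varying baseline lifetime rate
#'
#' Lifetime rate 0.05 for birth cohorts before 1900 (pre-registry era, cases
#' under-captured) and 0.10 from 1900 on.  The birthplace flag does not enter
#' the default.
#'
#' @param birthYear integer vector of birth years
#' @param bornInRegion logical vector (unused by the default)
#' @return numeric vector of per-person lifetime rates
#' @export
defaultBaselineRates <- function(birthYear, bornInRegion) {
  ifelse(birthYear < 1900, 0.05, 0.10)
}

#' Construct a simulation configuration
#'
#' The defaults describe the study conditions every simulation-based test and
#' calibration in the package runs under: a founder population of 13 couples
#' followed for 5 generations with declining per-couple fertility
#' (6, 4.5, 3, 2.2 expected children), 25-year generation intervals with
#' 5-year jitter from an 1835 founder cohort, spouses mostly immigrant
#' founders (so the founder clans stay largely separate, each clan a
#' pedigree of its own) and otherwise same-generation non-relatives
#' (relationship degree > 3), a baseline lifetime risk of about 0.10 for the
#' registry-era cohorts with diagnoses recorded only from 1966 on, one
#' highly penetrant variant planted heterozygous in a mid-to-large founder
#' clan (the 0.70 descendant-count quantile), and 50 neutral marker variants
#' dropped from random single founders.  This yields genealogies of roughly
#' 3500 members.  See the package vignette for why each value was chosen.
#'
#' @param nFounderCouples number of founder couples
#' @param nGenerations number of generations (1 = founders only)
#' @param offspringMean expected children per couple, recycled per generation
#' @param marriageRate probability an individual marries
#' @param immigrantRate probability a spouse is an immigrant founder rather
#'   than a same-generation non-relative
#' @param founderBirthYear birth-year centre of the founder generation
#' @param generationGap mean parent-child birth-year gap (years)
#' @param birthJitter half-width of the uniform birth-year jitter (years)
#' @param baselineRates function(birthYear, bornInRegion) -> lifetime rate
#' @param plantedVariants list of lists with fields \code{founder} (an id;
#'   "largest" or "random" over the earliest-generation founders; or
#'   "q<frac>", e.g. "q0.70", the founder at that quantile of the
#'   descendant-count distribution), \code{relativeRisk} (>= 1) and
#'   \code{populationAf} (annotated population frequency)
#' @param neutralVariantCount number of neutral marker variants
#' @param neutralAfRange range the annotated neutral population frequencies
#'   are drawn from (log-uniform)
#' @param registryStart first calendar year diagnoses are recorded; earlier
#'   disease leaves no cancer record, mirroring registry-era ascertainment
#'   (cases appear only in the most recent generations)
#' @param seed RNG seed
#' @return a \code{\linkS4class{SimConfig}}
#' @export
SimConfig <- function(nFounderCouples = 13, nGenerations = 5,
                      offspringMean = c(6, 4.5, 3, 2.2),
                      marriageRate = 0.9, immigrantRate = 0.92,
                      founderBirthYear = 1835, generationGap = 25,
                      birthJitter = 5, baselineRates = defaultBaselineRates,
                      plantedVariants = list(list(founder = "q0.70",
                                                  relativeRisk = 10,
                                                  populationAf = 0.001)),
                      neutralVariantCount = 50,
                      neutralAfRange = c(1e-4, 0.02), registryStart = 1966,
                      seed = 1) {
  new("SimConfig", nFounderCouples = as.integer(nFounderCouples),
      nGenerations = as.integer(nGenerations),
      offspringMean = as.numeric(offspringMean),
      marriageRate = as.numeric(marriageRate),
      immigrantRate = as.numeric(immigrantRate),
      founderBirthYear = as.integer(founderBirthYear),
      generationGap = as.numeric(generationGap),
      birthJitter = as.numeric(birthJitter),
      baselineRates = baselineRates, plantedVariants = plantedVariants,
      neutralVariantCount = as.integer(neutralVariantCount),
      neutralAfRange = as.numeric(neutralAfRange),
      registryStart = as.integer(registryStart), seed = as.integer(seed))
}

#' Simulate a founder-population genealogy
#'
#' Founder couples are seeded in generation 1; each couple has a
#' Poisson-distributed number of children; children marry with the configured
#' probability, taking a spouse either from the same-generation pool of
#' individuals no closer than relationship degree 3 (no shared ancestor
#' within two meioses of both) or, with the immigrant probability (or
#' whenever no such candidate exists), a newly created immigrant founder.
#' Birth years advance by the generation gap with uniform jitter.  Founders
#' and immigrants are flagged as born outside the region, everyone else
#' inside.  Fully reproducible from the configuration seed.
#'
#' @param config a \code{\linkS4class{SimConfig}}
#' @return a \code{\linkS4class{Genealogy}}
#' @export
simulateGenealogy <- function(config) {
  set.seed(config@seed)
  G <- config@nGenerations
  lamv <- config@offspringMean
  jit <- function(n) as.integer(round(runif(n, -config@birthJitter,
                                            config@birthJitter)))
  ## growing columns
  sex <- character(0); by <- integer(0); region <- logical(0)
  fidx <- integer(0); midx <- integer(0); gener <- integer(0)
  anc2 <- list()     # self + parents + grandparents, for the degree check
  addIndividual <- function(s, b, reg, f, m, g) {
    sex <<- c(sex, s); by <<- c(by, as.integer(b)); region <<- c(region, reg)
    fidx <<- c(fidx, f); midx <<- c(midx, m); gener <<- c(gener, g)
    i <- length(sex)
    gp <- integer(0)
    for (p in c(f, m)) if (!is.na(p))
      gp <- c(gp, fidx[p], midx[p])
    anc2[[i]] <<- c(i, f, m, gp[!is.na(gp)])
    anc2[[i]] <<- anc2[[i]][!is.na(anc2[[i]])]
    i
  }
  ## founder couples
  couples <- matrix(integer(0), ncol = 2)
  for (k in seq_len(config@nFounderCouples)) {
    b <- config@founderBirthYear + jit(1)
    h <- addIndividual("male", b, FALSE, NA_integer_, NA_integer_, 1L)
    w <- addIndividual("female", b + jit(1), FALSE, NA_integer_,
                       NA_integer_, 1L)
    couples <- rbind(couples, c(h, w))
  }
  for (g in seq_len(max(0L, G - 1L))) {
    lam <- lamv[min(g, length(lamv))]
    kids <- integer(0)
    for (cp in seq_len(nrow(couples))) {
      nk <- rpois(1L, lam)
      if (nk == 0L) next
      f <- couples[cp, 1L]; m <- couples[cp, 2L]
      bmid <- round(mean(c(by[f], by[m]))) + config@generationGap
      for (j in seq_len(nk)) {
        s <- if (runif(1) < 0.5) "male" else "female"
        kids <- c(kids, addIndividual(s, bmid + jit(1), TRUE, f, m, g + 1L))
      }
    }
    if (g + 1L >= G || !length(kids)) {
      couples <- matrix(integer(0), ncol = 2)
      if (g + 1L >= G) break else next
    }
    ## marry the new generation
    married <- rep(FALSE, length(kids))
    couples <- matrix(integer(0), ncol = 2)
    for (ki in sample(seq_along(kids))) {
      if (married[ki] || runif(1) > config@marriageRate) next
      child <- kids[ki]
      mate <- NA_integer_
      if (runif(1) >= config@immigrantRate) {
        pool <- which(!married & sex[kids] != sex[child] &
                      seq_along(kids) != ki)
        if (length(pool) > 15L) pool <- sample(pool, 15L)
        else if (length(pool) > 1L) pool <- sample(pool)
        for (cand in pool) {
          if (!length(intersect(anc2[[child]], anc2[[kids[cand]]]))) {
            mate <- kids[cand]; married[cand] <- TRUE; break
          }
        }
      }
      if (is.na(mate)) {  # immigrant spouse
        s <- if (sex[child] == "male") "female" else "male"
        mate <- addIndividual(s, by[child] + jit(1), FALSE, NA_integer_,
                              NA_integer_, gener[child])
      }
      married[ki] <- TRUE
      couples <- rbind(couples,
                       if (sex[child] == "male") c(child, mate)
                       else c(mate, child))
    }
  }
  n <- length(sex)
  if (n < 4L * config@nFounderCouples && G > 2L)
    warning("simulated genealogy is very small; ",
            "offspring parameters may imply extinction")
  ids <- sprintf("I%05d", seq_len(n))
  death <- by + pmin(105L, pmax(1L, as.integer(round(rnorm(n, 78, 12)))))
  ped <- data.frame(id = ids,
                    father_id = ifelse(is.na(fidx), NA, ids[fidx]),
                    mother_id = ifelse(is.na(midx), NA, ids[midx]),
                    sex = sex, birth_year = by, birth_in_region = region,
                    death_year = death, stringsAsFactors = FALSE)
  Genealogy(ped)
}

#' Drop a variant's alleles down a genealogy
#'
#' Mendelian transmission: founder carriers start heterozygous; every parent
#' transmits its alternate allele to each child independently with
#' probability (allele count)/2; unknown parents never transmit.
#'
#' @param gen a \code{Genealogy}
#' @param founderCarrierIds ids of the heterozygous founder carriers (may be
#'   empty)
#' @param variantKey key recorded on the returned carrier set
#' @param seed optional RNG seed
#' @return list with \code{alleles} (named integer vector of alternate-allele
#'   counts 0/1/2 for every individual) and \code{carrierSet} (a
#'   \code{\linkS4class{CarrierSet}})
#' @export
geneDrop <- function(gen, founderCarrierIds, variantKey = "variant",
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(gen)
  a <- integer(n)
  if (length(founderCarrierIds)) a[.idx(gen, founderCarrierIds)] <- 1L
  ord <- order(gen@depth)
  for (i in ord[gen@depth[ord] > 0L]) {
    tf <- if (!is.na(gen@fidx[i]) && a[gen@fidx[i]] > 0L)
      rbinom(1L, 1L, a[gen@fidx[i]] / 2) else 0L
    tm <- if (!is.na(gen@midx[i]) && a[gen@midx[i]] > 0L)
      rbinom(1L, 1L, a[gen@midx[i]] / 2) else 0L
    a[i] <- a[i] + tf + tm   # founder-carrier status (depth 0) untouched
  }
  names(a) <- gen@ped$id
  list(alleles = a,
       carrierSet = CarrierSet(variantKey,
                               hetIds = gen@ped$id[a == 1L],
                               homIds = gen@ped$id[a == 2L]))
}

#' Assign cancer phenotypes from cohort baselines and planted effects
#'
#' Every male with a known birth year is affected independently with
#' probability \code{min(1, baseline * prod(relative risks of the planted
#' variants carried))}.  Affected individuals receive a diagnosis year around
#' age 72 and a lethality flag (probability 0.25).  Only diagnoses falling in
#' the registry era (\code{dx_year >= registryStart}) leave a cancer record:
#' earlier disease goes unrecorded, which is why cases concentrate in the
#' most recent generations of deep pedigrees.
#'
#' @param gen a \code{Genealogy}
#' @param baselineRates function(birthYear, bornInRegion) -> lifetime rate
#' @param carrierSets named list of \code{\linkS4class{CarrierSet}}
#' @param relativeRisks named numeric: variant key -> relative risk (only
#'   keys listed here act on the phenotype)
#' @param seed optional RNG seed
#' @param site phenotype label recorded (default "prostate")
#' @param registryStart first recorded diagnosis year (default 1966)
#' @return data.frame of cancer records: \code{id}, \code{site},
#'   \code{dx_year}, \code{lethal}
#' @export
assignPhenotypes <- function(gen, baselineRates = defaultBaselineRates,
                             carrierSets = list(),
                             relativeRisks = numeric(0), seed = NULL,
                             site = "prostate", registryStart = 1966) {
  if (!is.null(seed)) set.seed(seed)
  p <- gen@ped
  atRisk <- which(p$sex == "male" & !is.na(p$birth_year))
  risk <- rep_len(baselineRates(p$birth_year[atRisk],
                                p$birth_in_region[atRisk]),
                  length(atRisk))
  for (key in names(relativeRisks)) {
    cs <- carrierSets[[key]]
    if (is.null(cs)) next
    hit <- p$id[atRisk] %in% c(cs@hetIds, cs@homIds)
    risk[hit] <- risk[hit] * relativeRisks[[key]]
  }
  risk <- pmin(1, risk)
  aff <- atRisk[rbinom(length(atRisk), 1L, risk) == 1L]
  dx <- p$birth_year[aff] +
    pmin(95L, pmax(45L, as.integer(round(rnorm(length(aff), 72, 8)))))
  keep <- dx >= registryStart
  data.frame(id = p$id[aff][keep], site = rep(site, sum(keep)),
             dx_year = dx[keep],
             lethal = rbinom(sum(keep), 1L, 0.25),
             stringsAsFactors = FALSE)
}

## deterministic synthetic variant keys in the field's
## seq_<chrom>_<pos>_<REF>-<ALT>_<gene> style
.variantKeys <- function(k) {
  chrom <- sample(1:22, k, replace = TRUE)
  pos <- as.integer(round(runif(k, 1e6, 2e8)))
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, k, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), "")
  gene <- sprintf("GENE%03d", seq_len(k))
  data.frame(key = sprintf("seq_%d_%d_%s-%s_%s", chrom, pos, ref, alt, gene),
             chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
             gene = gene, stringsAsFactors = FALSE)
}

#' Simulate a complete study: genealogy, genotypes, phenotypes, annotation
#'
#' Runs \code{\link{simulateGenealogy}}, resolves the planted founders
#' ("largest" = the earliest-generation founder with the most descendants,
#' "random" = a uniformly drawn one, "q<frac>" = the one at that quantile of
#' descendant counts), gene-drops every planted and neutral variant, assigns
#' phenotypes with the planted relative risks, and builds the variant
#' annotation table (planted variants are annotated nonsynonymous with
#' ClinVar "conflicting"; neutral variants receive a mix of coding,
#' noncoding and UTR classes, RegulomeDB scores for the noncoding ones, and
#' log-uniform population frequencies, a few of them missing).
#'
#' @param config a \code{\linkS4class{SimConfig}}
#' @return a \code{\linkS4class{SimOutput}}
#' @export
simulateStudy <- function(config) {
  gen <- simulateGenealogy(config)   # sets the seed
  founders <- gen@ped$id[gen@depth == 0L]
  nPlanted <- length(config@plantedVariants)
  k <- nPlanted + config@neutralVariantCount
  vk <- .variantKeys(k)
  ## resolve planted founders among the earliest-generation founders
  plantedFounder <- character(nPlanted)
  if (nPlanted) {
    early <- gen@ped$id[gen@depth == 0L &
      gen@ped$birth_year <= min(gen@ped$birth_year, na.rm = TRUE) + 12L]
    ndesc <- vapply(early, function(f) length(descendants(gen, f)),
                    integer(1))
    byDesc <- early[order(ndesc)]
    for (v in seq_len(nPlanted)) {
      spec <- config@plantedVariants[[v]]$founder
      plantedFounder[v] <-
        if (identical(spec, "largest")) byDesc[length(byDesc)]
        else if (identical(spec, "random")) sample(early, 1L)
        else if (grepl("^q0?\\.[0-9]+$", spec))
          byDesc[max(1L, ceiling(as.numeric(sub("^q", "", spec)) *
                                 length(byDesc)))]
        else as.character(spec)
    }
  }
  neutralFounder <- if (config@neutralVariantCount)
    sample(founders, config@neutralVariantCount, replace = TRUE)
    else character(0)
  dropFounder <- c(plantedFounder, neutralFounder)
  genotypes <- matrix(0L, nrow = k, ncol = length(gen),
                      dimnames = list(vk$key, gen@ped$id))
  carrierSets <- list()
  for (v in seq_len(k)) {
    gd <- geneDrop(gen, dropFounder[v], variantKey = vk$key[v])
    genotypes[v, ] <- gd$alleles
    carrierSets[[vk$key[v]]] <- gd$carrierSet
  }
  rr <- if (nPlanted) setNames(
    vapply(config@plantedVariants, function(p) p$relativeRisk, 0),
    vk$key[seq_len(nPlanted)]) else numeric(0)
  records <- assignPhenotypes(gen, config@baselineRates, carrierSets, rr,
                              registryStart = config@registryStart)
  ## annotation table
  ann <- vk
  ann[["functional_class"]] <- rep(NA_character_, nrow(ann))
  ann[["population_af"]] <- rep(NA_real_, nrow(ann))
  ann[["regulomedb"]] <- rep(NA_character_, nrow(ann))
  ann[["clinvar"]] <- rep(NA_character_, nrow(ann))
  if (nPlanted) {
    ann$functional_class[seq_len(nPlanted)] <- "nonsynonymous"
    ann$population_af[seq_len(nPlanted)] <-
      vapply(config@plantedVariants,
             function(p) if (is.null(p$populationAf)) 0.001
                         else p$populationAf, 0)
    ann$clinvar[seq_len(nPlanted)] <- "conflicting"
  }
  if (config@neutralVariantCount) {
    ni <- nPlanted + seq_len(config@neutralVariantCount)
    cls <- sample(c(codingClasses, "noncoding", "UTR", "other"),
                  length(ni), replace = TRUE,
                  prob = c(0.30, 0.08, 0.04, 0.04, 0.04, 0.30, 0.10, 0.10))
    ann$functional_class[ni] <- cls
    af <- 10^runif(length(ni), log10(config@neutralAfRange[1L]),
                   log10(config@neutralAfRange[2L]))
    af[runif(length(ni)) < 0.05] <- NA    # unobserved in the reference panel
    ann$population_af[ni] <- af
    nc <- ni[cls %in% c("noncoding", "UTR")]
    ann$regulomedb[nc] <- sample(regulomeLevels, length(nc), replace = TRUE)
    ann$clinvar[ni] <- sample(c("uncertain", "benign", NA),
                              length(ni), replace = TRUE)
  }
  truth <- if (nPlanted) data.frame(
    variant_key = vk$key[seq_len(nPlanted)],
    founder_id = plantedFounder,
    relative_risk = unname(rr),
    carrier_ids = vapply(seq_len(nPlanted), function(v) {
      cs <- carrierSets[[vk$key[v]]]
      paste(sort(c(cs@hetIds, cs@homIds)), collapse = ",")
    }, ""), stringsAsFactors = FALSE)
  else data.frame(variant_key = character(), founder_id = character(),
                  relative_risk = numeric(), carrier_ids = character(),
                  stringsAsFactors = FALSE)
  new("SimOutput", genealogy = gen, cancerRecords = records,
      genotypes = genotypes, carrierSets = carrierSets, annotation = ann,
      truth = truth, config = config)
}
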