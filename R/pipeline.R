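## End-to-end pipeline driver: cousin-pair sharing -> variant funnel ->
## segregation -> optional case/control association, with a run manifest.

.defaultRunConfig <- list(
  genealogy = NULL, phenotypes = NULL, genotypes = NULL, annotation = NULL,
  pcs_cases = NULL, pcs_controls = NULL,
  site = "prostate", af_threshold = 0.005, regulome_low = "2a",
  regulome_high = "4", min_cluster = 3, alpha = 0.05,
  max_carrier_fraction = 0.10, bonferroni_alpha = 0.05,
  min_generations = 3, bin_origin = 1800, seed = 1)

#' Read a pipeline run configuration (YAML)
#'
#' Unset fields take their documented defaults (thresholds af_threshold
#' 0.005, RegulomeDB range 2a-4, min_cluster 3, alpha 0.05,
#' max_carrier_fraction 0.10, bonferroni_alpha 0.05).  The configuration
#' round-trips unchanged through \code{\link{writeRunConfig}}.
#'
#' @param path YAML file
#' @return named list of configuration values
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(.defaultRunConfig, cfg)
}

#' Write a pipeline run configuration (YAML)
#' @param config named list
#' @param path output file
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full discovery pipeline
#'
#' Stages, mirroring the discovery design: (1) estimate cohort-specific
#' baseline rates from the genealogy and cancer records; (2) identify
#' affected first/second-cousin pairs among lethal cases; (3) funnel the
#' variants through the rarity filter and the two disjoint class branches
#' (coding classes; noncoding/UTR within the RegulomeDB range) and keep those
#' shared within at least one affected cousin pair; (4) classify assay
#' performance against the original sharing pairs over the full case panel
#' and keep variants with additional carriers beyond the pair; (5) find
#' segregating clusters whose founding ancestor's descendants show a
#' significant cancer excess; (6) optionally run the matched case/control
#' carrier association with Bonferroni correction when PC coordinate files
#' are configured.  Everything is deterministic given the configuration.
#'
#' @param config named list as returned by \code{\link{readRunConfig}};
#'   \code{genealogy}, \code{phenotypes}, \code{genotypes} and
#'   \code{annotation} must point to readable files
#' @param outDir run directory to create (manifest, candidate table, cluster
#'   report)
#' @return invisibly, a list with \code{clusters}, \code{candidates},
#'   \code{funnel}, \code{association} (NULL unless PCs configured),
#'   \code{manifest}
#' @export
runPipeline <- function(config, outDir) {
  cfg <- utils::modifyList(.defaultRunConfig, config)
  inputs <- c(genealogy = cfg$genealogy, phenotypes = cfg$phenotypes,
              genotypes = cfg$genotypes, annotation = cfg$annotation)
  missing <- inputs[!vapply(inputs, function(p)
    !is.null(p) && file.exists(p), TRUE)]
  if (length(missing))
    stop("missing input file(s): ", paste(names(missing), collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  gen <- readGenealogy(cfg$genealogy)
  records <- readPhenotypes(cfg$phenotypes)
  vcf <- readCarrierVcf(cfg$genotypes)
  ann <- readAnnotation(cfg$annotation)

  rateTable <- estimateRates(gen, records, cfg$site,
                             minGenerations = cfg$min_generations,
                             binOrigin = cfg$bin_origin)

  ## affected cousin pairs among lethal cases
  lethalIds <- sort(unique(records$id[records$site == cfg$site &
                                      records$lethal == 1]))
  pairs <- data.frame(id_a = character(), id_b = character(),
                      cousin_class = character(), stringsAsFactors = FALSE)
  if (length(lethalIds) > 1L) {
    for (i in seq_len(length(lethalIds) - 1L))
      for (j in (i + 1L):length(lethalIds)) {
        cp <- classifyCousins(gen, lethalIds[i], lethalIds[j])
        if (!is.null(cp))
          pairs <- rbind(pairs, data.frame(
            id_a = cp$idA, id_b = cp$idB, cousin_class = cp$cousinClass,
            stringsAsFactors = FALSE))
      }
  }

  ## variant funnel
  funnel <- list(variants_total = nrow(ann))
  rare <- filterRare(ann, cfg$af_threshold)
  funnel$rare <- nrow(rare)
  coding <- filterCoding(rare)
  noncoding <- filterRegulome(rare, cfg$regulome_low, cfg$regulome_high)
  stopifnot(!any(coding$key %in% noncoding$key))  # disjoint branches
  candidates <- c(coding$key, noncoding$key)
  funnel$coding <- nrow(coding)
  funnel$noncoding_regulome <- nrow(noncoding)
  funnel$class_filtered <- length(candidates)

  csAll <- vcf$carrierSets[names(vcf$carrierSets) %in% candidates]
  shared <- sharedInPairs(csAll, pairs, genotypedIds = vcf$sampleIds)
  funnel$cousin_pairs <- nrow(pairs)
  funnel$shared_in_pairs <- length(shared)

  ## assay over the case panel
  caseIds <- sort(unique(records$id[records$site == cfg$site]))
  panel <- intersect(caseIds, vcf$sampleIds)
  nAssayed <- length(panel)
  panelSets <- lapply(csAll[names(shared)], function(cs)
    CarrierSet(cs@variantKey, intersect(cs@hetIds, panel),
               intersect(cs@homIds, panel)))
  assayClass <- vapply(names(panelSets), function(key)
    classifyAssay(panelSets[[key]],
                  unique(unlist(shared[[key]][, c("id_a", "id_b")]))),
    character(1))
  funnel$assay_classes <- as.list(table(factor(assayClass,
    levels = c("failed_no_carriers", "failed_pair_missing", "pair_only",
               "pair_plus_additional"))))
  keepSets <- panelSets[assayClass == "pair_plus_additional"]
  funnel$assay_validated <- length(keepSets)

  clusters <- findSegregating(keepSets, gen, records, rateTable,
                              nAssayed = max(nAssayed, 1L),
                              minCluster = cfg$min_cluster,
                              alpha = cfg$alpha,
                              maxCarrierFraction = cfg$max_carrier_fraction)
  summary <- summarizeCandidates(clusters, ann)
  funnel$segregating_clusters <- length(clusters)
  funnel$segregating_variants <- summary$nVariants
  funnel$segregating_genes <- summary$nGenes

  ## optional association stage
  association <- NULL
  if (!is.null(cfg$pcs_cases) && !is.null(cfg$pcs_controls)) {
    casePcs <- readPcs(cfg$pcs_cases)
    controlPcs <- readPcs(cfg$pcs_controls)
    matched <- matchControls(casePcs, controlPcs)
    thr <- bonferroniThreshold(cfg$bonferroni_alpha, max(1L, length(csAll)))
    association <- do.call(rbind, lapply(names(csAll), function(key) {
      cs <- csAll[[key]]
      carriers <- c(cs@hetIds, cs@homIds)
      res <- carrierAssociation(
        sum(matched$case_id %in% carriers), nrow(matched),
        sum(matched$control_id %in% carriers), nrow(matched),
        threshold = thr)
      data.frame(variant_key = key, case_carriers = res$case_carriers,
                 control_carriers = res$control_carriers,
                 odds_ratio = res$odds_ratio, p_value = res$p_value,
                 significant = res$significant, stringsAsFactors = FALSE)
    }))
    funnel$association_tested <- length(csAll)
    funnel$association_threshold <- thr
  }

  ## reports + manifest
  utils::write.csv(summary$candidates, file.path(outDir, "candidates.csv"),
                   row.names = FALSE)
  clusterTab <- if (length(clusters)) do.call(rbind, lapply(clusters,
    function(x) data.frame(
      variant_key = x@variantKey,
      founder = paste(x@founderIds, collapse = "+"),
      founder_couple = x@founderCouple,
      n_carriers = length(x@carrierIds),
      carrier_ids = paste(x@carrierIds, collapse = ","),
      observed = x@excess@observed, expected = x@excess@expected,
      p_value = x@excess@pValue, stringsAsFactors = FALSE)))
  else data.frame(variant_key = character(), founder = character(),
                  founder_couple = logical(), n_carriers = integer(),
                  carrier_ids = character(), observed = integer(),
                  expected = numeric(), p_value = numeric(),
                  stringsAsFactors = FALSE)
  utils::write.csv(clusterTab, file.path(outDir, "clusters.csv"),
                   row.names = FALSE)
  if (!is.null(association))
    utils::write.csv(association, file.path(outDir, "association.csv"),
                     row.names = FALSE)
  manifest <- list(
    config = cfg[order(names(cfg))],
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    n_assayed = nAssayed,
    funnel = funnel)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(clusters = clusters, candidates = summary$candidates,
                 funnel = funnel, association = association,
                 manifest = manifest))
}
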