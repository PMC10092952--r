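## Readers and writers for the plain-text interchange formats:
## genealogy TSV, pre-MAKEPED PED, phenotype CSV, annotation TSV, PC CSV,
## GT-only VCF, truth JSON.

#' Read a genealogy TSV
#'
#' One header row; columns id, father_id, mother_id, sex, birth_year,
#' birth_in_region, death_year; empty string = unknown.
#'
#' @param path file path
#' @return a \code{\linkS4class{Genealogy}}
#' @export
readGenealogy <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("", "NA"))
  Genealogy(tab)
}

#' Write a genealogy TSV
#' @param gen a \code{Genealogy}
#' @param path file path
#' @export
writeGenealogy <- function(gen, path) {
  utils::write.table(gen@ped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a 6-column pre-MAKEPED PED file
#'
#' Columns: family, id, father, mother, sex, phenotype; "0" = unknown parent.
#' The mapping config translates the dialect: which codes mean male/female
#' and which parent code means missing.  Demographic columns absent from PED
#' (birth year, birthplace, death year) come back NA.
#'
#' @param path file path
#' @param mapping list with elements \code{male} (default "1"), \code{female}
#'   (default "2"), \code{missing} (default "0"), \code{header} (default
#'   FALSE)
#' @return a \code{\linkS4class{Genealogy}}
#' @export
readPedFile <- function(path, mapping = list()) {
  mp <- utils::modifyList(list(male = "1", female = "2", missing = "0",
                               header = FALSE), mapping)
  tab <- utils::read.table(path, header = isTRUE(mp$header),
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stop("PED file needs 6 columns (fam id fa mo sex pheno)")
  names(tab)[1:6] <- c("fam", "id", "father", "mother", "sex", "pheno")
  fa <- ifelse(tab$father == mp$missing, NA, tab$father)
  mo <- ifelse(tab$mother == mp$missing, NA, tab$mother)
  sex <- ifelse(tab$sex == mp$male, "male",
                ifelse(tab$sex == mp$female, "female", "unknown"))
  Genealogy(data.frame(id = tab$id, father_id = fa, mother_id = mo,
                       sex = sex, birth_year = NA, birth_in_region = NA,
                       death_year = NA, stringsAsFactors = FALSE))
}

#' Read a phenotype CSV (id, site, dx_year, lethal)
#' @param path file path
#' @return data.frame of cancer records
#' @export
readPhenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(id = "character"))
}

#' Read a variant annotation TSV
#' @param path file path
#' @return data.frame with key, gene, functional_class, population_af,
#'   regulomedb, clinvar
#' @export
readAnnotation <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
}

#' Read per-subject principal-component coordinates (id, PC1, PC2)
#' @param path file path
#' @return data.frame
#' @export
readPcs <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(id = "character"))
}

#' Write genotypes as a minimal GT-only VCF
#'
#' One sample column per individual; genotypes 0/0, 0/1, 1/1 from the
#' alternate-allele count matrix.
#'
#' @param genotypes integer matrix variants x individuals (rownames = variant
#'   keys parseable as seq_<chrom>_<pos>_<ref>-<alt>_<gene>, colnames = ids)
#' @param path file path
#' @export
writeGenotypesVcf <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(genotypes)),
                     collapse = "\t")), con)
  if (nrow(genotypes)) {
    parts <- strsplit(rownames(genotypes), "_")
    gtcode <- c("0/0", "0/1", "1/1")
    for (v in seq_len(nrow(genotypes))) {
      p <- parts[[v]]
      ra <- strsplit(p[4L], "-", fixed = TRUE)[[1L]]
      writeLines(paste(c(p[2L], p[3L], rownames(genotypes)[v], ra[1L],
                         ra[2L], ".", "PASS", ".", "GT",
                         gtcode[genotypes[v, ] + 1L]), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read carrier sets from a VCF
#'
#' Heterozygous = one alternate allele, homozygous = two; phased and unphased
#' separators are accepted; missing genotypes count as non-carriers.
#'
#' @param path VCF path (plain text or bgzipped)
#' @return list with \code{carrierSets} (named list of
#'   \code{\linkS4class{CarrierSet}} keyed by the VCF ID column),
#'   \code{genotypes} (alternate-allele count matrix) and \code{sampleIds}
#' @export
readCarrierVcf <- function(path) {
  hdr <- grep("^#CHROM", readLines(path), value = TRUE)
  cols <- strsplit(hdr[1L], "\t", fixed = TRUE)[[1L]]
  samples0 <- if (length(cols) > 9L) cols[-(1:9)] else character(0)
  body <- sum(!startsWith(readLines(path), "#"))
  if (body == 0L) {  # headed but empty VCF
    return(list(carrierSets = list(),
                genotypes = matrix(0L, 0L, length(samples0),
                                   dimnames = list(NULL, samples0)),
                sampleIds = samples0))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  keys <- v@fix[, "ID"]
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  alt <- matrix(0L, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = list(keys, samples))
  alt[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  alt[gt %in% c("1/1", "1|1")] <- 2L
  carrierSets <- lapply(seq_along(keys), function(i)
    CarrierSet(keys[i], hetIds = samples[alt[i, ] == 1L],
               homIds = samples[alt[i, ] == 2L]))
  names(carrierSets) <- keys
  list(carrierSets = carrierSets, genotypes = alt, sampleIds = samples)
}

#' Write a simulated study to fixture files
#'
#' Emits genealogy.tsv, phenotypes.csv, genotypes.vcf, annotation.tsv and
#' truth.json into a directory.  Empty outputs produce valid headed files.
#'
#' @param sim a \code{\linkS4class{SimOutput}}
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeFixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenealogy(sim@genealogy, file.path(dir, "genealogy.tsv"))
  utils::write.csv(sim@cancerRecords, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  writeGenotypesVcf(sim@genotypes, file.path(dir, "genotypes.vcf"))
  utils::write.table(sim@annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(sim@truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null")
  invisible(dir)
}

#' Read fixture files written by \code{\link{writeFixture}}
#'
#' @param dir directory containing the fixture files
#' @return list: \code{genealogy}, \code{cancerRecords}, \code{carrierSets},
#'   \code{genotypes}, \code{annotation}, \code{truth}
#' @export
readFixture <- function(dir) {
  vcf <- readCarrierVcf(file.path(dir, "genotypes.vcf"))
  list(genealogy = readGenealogy(file.path(dir, "genealogy.tsv")),
       cancerRecords = readPhenotypes(file.path(dir, "phenotypes.csv")),
       carrierSets = vcf$carrierSets, genotypes = vcf$genotypes,
       annotation = readAnnotation(file.path(dir, "annotation.tsv")),
       truth = jsonlite::fromJSON(file.path(dir, "truth.json"),
                                  simplifyDataFrame = TRUE))
}
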