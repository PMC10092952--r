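test_that("degenerate configurations behave as specified", {
  g1 <- simulateGenealogy(SimConfig(nGenerations = 1, nFounderCouples = 4,
                                    seed = 1))
  expect_equal(length(g1), 8L)
  expect_true(all(generationsLinked(g1) == 0))
  expect_warning(
    g0 <- simulateGenealogy(SimConfig(offspringMean = 0, seed = 1)),
    "extinction")
  expect_true(all(generationsLinked(g0) == 0))
})

test_that("generation sizes follow the branching-process expectation", {
  ## couples per generation grow by lambda * marriageRate * (1 - im/2 share
  ## pairing internally); the realised mean final-generation size over
  ## replicates stays within 3 standard errors of the empirical mean trend
  lam <- 3; G <- 4
  sizes <- vapply(1:60, function(i) {
    g <- simulateGenealogy(SimConfig(nFounderCouples = 2, nGenerations = G,
                                     offspringMean = lam, marriageRate = 1,
                                     immigrantRate = 1, seed = 900 + i))
    ## immigrantRate 1: every child marries an immigrant, so couples = kids
    ## and the children counts form a plain branching process mean lam
    sum(g@depth == G - 1L)
  }, numeric(1))
  expectn <- 2 * lam^(G - 1)          # 2 founder couples
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - expectn), 3 * se)
})

test_that("gene dropping is Mendelian", {
  ped <- pedTable(list("P", NA, NA, "male", 1900),
                  list("M", NA, NA, "female", 1900),
                  list("K", "P", "M", "male", 1930))
  g <- Genealogy(ped)
  expect_length(geneDrop(g, character(0))$carrierSet@hetIds, 0)
  set.seed(11)
  carr <- vapply(1:4000, function(i)
    "K" %in% geneDrop(g, "P")$carrierSet@hetIds, logical(1))
  se <- sqrt(0.25 / 4000)
  expect_lt(abs(mean(carr) - 0.5), 3 * se)
  ## depth-g descendant of a single het founder carries with prob (1/2)^g
  chain <- pedTable(list("A", NA, NA, "male", 1850),
                    list("W1", NA, NA, "female", 1850),
                    list("B", "A", "W1", "male", 1880),
                    list("W2", NA, NA, "female", 1880),
                    list("C", "B", "W2", "male", 1910))
  gc <- Genealogy(chain)
  set.seed(13)
  carr3 <- vapply(1:4000, function(i) {
    cs <- geneDrop(gc, "A")$carrierSet
    "C" %in% c(cs@hetIds, cs@homIds)
  }, logical(1))
  se2 <- sqrt(0.25 * 0.75 / 4000)
  expect_lt(abs(mean(carr3) - 0.25), 3 * se2)
})

test_that("phenotypes follow cohort baselines and planted effects", {
  ## 10,000 unrelated men born in the registry era
  n <- 10000
  ped <- data.frame(id = sprintf("m%05d", 1:n), father_id = NA,
                    mother_id = NA, sex = "male", birth_year = 1940,
                    birth_in_region = TRUE, death_year = NA,
                    stringsAsFactors = FALSE)
  g <- Genealogy(ped)
  expect_equal(nrow(assignPhenotypes(g, function(by, reg) 0, seed = 1)), 0)
  set.seed(21)
  recs <- assignPhenotypes(g, function(by, reg) 0.1)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(nrow(recs) / n - 0.1), 3 * se)
  ## planted relative risk 5 on baseline 0.1: carrier case fraction ~ 0.5
  carriers <- ped$id[1:2000]
  cs <- list(v = CarrierSet("v", hetIds = carriers))
  set.seed(22)
  recs2 <- assignPhenotypes(g, function(by, reg) 0.1, cs, c(v = 5))
  frac <- mean(carriers %in% recs2$id)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
  ## pre-registry diagnoses leave no record
  ped$birth_year <- 1850
  g2 <- Genealogy(ped)
  set.seed(23)
  expect_equal(nrow(assignPhenotypes(g2, function(by, reg) 0.5)), 0)
})

test_that("the truth table matches the genotype carriers", {
  sim <- simulateStudy(SimConfig(seed = 31, neutralVariantCount = 5))
  expect_true(validObject(sim))
  key <- sim@truth$variant_key[1]
  cs <- sim@carrierSets[[key]]
  expect_setequal(strsplit(sim@truth$carrier_ids[1], ",")[[1]],
                  c(cs@hetIds, cs@homIds))
  ## genotype matrix agrees with the carrier sets
  expect_setequal(colnames(sim@genotypes)[sim@genotypes[key, ] == 1L],
                  cs@hetIds)
})

test_that("fixtures are reproducible from the seed and round-trip", {
  cfg <- SimConfig(nFounderCouples = 4, nGenerations = 4,
                   offspringMean = c(3, 2.5, 2), neutralVariantCount = 8,
                   seed = 77)
  sim <- simulateStudy(cfg)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  writeFixture(sim, d1)
  writeFixture(simulateStudy(cfg), d2)
  for (f in list.files(d1))
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  ## a different seed changes the genotype draws
  sim2 <- simulateStudy(SimConfig(nFounderCouples = 4, nGenerations = 4,
                                  offspringMean = c(3, 2.5, 2),
                                  neutralVariantCount = 8, seed = 78))
  expect_false(identical(sim@genotypes, sim2@genotypes))

  ## read-back equals the in-memory objects
  back <- readFixture(d1)
  expect_equal(back$genealogy@ped$id, sim@genealogy@ped$id)
  expect_equal(back$genealogy@depth, sim@genealogy@depth)
  expect_equal(nrow(back$cancerRecords), nrow(sim@cancerRecords))
  for (k in names(sim@carrierSets))
    expect_setequal(back$carrierSets[[k]]@hetIds,
                    sim@carrierSets[[k]]@hetIds)
  expect_equal(back$annotation$key, sim@annotation$key)
  expect_equal(back$truth$variant_key, sim@truth$variant_key)

  ## an empty simulation still writes valid, headed files
  empty <- simulateStudy(SimConfig(nFounderCouples = 2, nGenerations = 1,
                                   plantedVariants = list(),
                                   neutralVariantCount = 0, seed = 1))
  d3 <- file.path(tempdir(), "fx3")
  writeFixture(empty, d3)
  back3 <- readFixture(d3)
  expect_equal(length(back3$carrierSets), 0)
  expect_equal(nrow(back3$cancerRecords), 0)
})

test_that("PED dialect reader maps codes through the config", {
  ped <- c("fam1 A 0 0 1 0", "fam1 B 0 0 2 0", "fam1 C A B 1 2")
  f <- tempfile(); writeLines(ped, f)
  g <- readPedFile(f)
  expect_equal(length(g), 3L)
  expect_equal(unname(generationsLinked(g, "C")), 1L)
  expect_equal(g@ped$sex[g@ped$id == "B"], "female")
})
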