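variantTable <- function() {
  data.frame(
    key = sprintf("seq_1_%d_A-G_G%02d", 1000 + 1:10, 1:10),
    gene = sprintf("G%02d", 1:10),
    functional_class = c("nonsynonymous", "frameshift", "startloss",
                         "startgain", "stoploss", "noncoding", "UTR",
                         "noncoding", "other", "nonsynonymous"),
    population_af = c(0.004, 0.005, 0.0049, NA, 0.1, 0.001, 0.002,
                      0.003, 0.004, 0.0001),
    regulomedb = c(NA, NA, NA, NA, NA, "2a", "4", "1b", "2b", NA),
    clinvar = NA_character_, stringsAsFactors = FALSE)
}

test_that("rarity filter uses a strict threshold and flags missing AF", {
  v <- variantTable()
  out <- filterRare(v, 0.005)
  expect_true("seq_1_1001_A-G_G01" %in% out$key)        # 0.004 retained
  expect_false("seq_1_1002_A-G_G02" %in% out$key)       # 0.005 removed
  expect_false("seq_1_1005_A-G_G05" %in% out$key)       # common removed
  expect_true("seq_1_1004_A-G_G04" %in% out$key)        # missing retained
  expect_true(out$af_missing[out$key == "seq_1_1004_A-G_G04"])
  ## equals the hand-filtered list
  expect_setequal(out$key, v$key[is.na(v$population_af) |
                                 v$population_af < 0.005])
})

test_that("coding and RegulomeDB filters retain exactly the right classes", {
  v <- variantTable()
  expect_setequal(filterCoding(v)$key, v$key[c(1, 2, 3, 4, 5, 10)])
  rg <- filterRegulome(v)
  ## 2a and 4 inside the closed range; 1b stronger than the range: removed;
  ## 2b on a coding-class row: removed
  expect_setequal(rg$key, v$key[c(6, 7)])
  v$regulomedb[6] <- "9z"
  expect_error(filterRegulome(v), "9z")
  ## filters commute
  v2 <- variantTable()
  expect_equal(filterCoding(filterRare(v2))$key,
               filterRare(filterCoding(v2))$key)
})

test_that("cousin-pair sharing requires both members and allele count > 1", {
  pairs <- data.frame(id_a = c("a1", "b1", "c1"),
                      id_b = c("a2", "b2", "c2"), stringsAsFactors = FALSE)
  cs <- list(
    v1 = CarrierSet("v1", hetIds = c("a1", "a2")),          # shared by pair a
    v2 = CarrierSet("v2", hetIds = c("a1", "x")),           # one member only
    v3 = CarrierSet("v3", hetIds = "b1"),                   # allele count 1
    v4 = CarrierSet("v4", hetIds = "b2", homIds = "b1"),    # hom counts
    v5 = CarrierSet("v5", hetIds = c("a1", "a2", "b1", "b2")))
  got <- sharedInPairs(cs, pairs)
  expect_setequal(names(got), c("v1", "v4", "v5"))
  expect_equal(nrow(got$v5), 2)
  expect_false("v3" %in% names(got))
  ## pairs without genotype data are skipped with a warning
  expect_warning(got2 <- sharedInPairs(cs, pairs,
    genotypedIds = c("a1", "a2", "b1", "b2")), "skipped")
  expect_setequal(names(got2), c("v1", "v4", "v5"))
  ## brute-force double loop over a random fixture
  set.seed(5)
  ids <- sprintf("p%02d", 1:10)
  rpairs <- data.frame(id_a = ids[seq(1, 9, 2)], id_b = ids[seq(2, 10, 2)],
                       stringsAsFactors = FALSE)
  rcs <- lapply(1:20, function(v)
    CarrierSet(paste0("rv", v), hetIds = sample(ids, sample(0:5, 1))))
  names(rcs) <- vapply(rcs, function(x) x@variantKey, "")
  got3 <- sharedInPairs(rcs, rpairs)
  for (v in names(rcs)) {
    carriers <- rcs[[v]]@hetIds
    want <- rpairs[rpairs$id_a %in% carriers & rpairs$id_b %in% carriers, ]
    if (length(carriers) > 1 && nrow(want))
      expect_equal(got3[[v]]$id_a, want$id_a)
    else expect_null(got3[[v]])
  }
})

test_that("assay classes partition variants by pair recovery", {
  pair <- c("p1", "p2")
  expect_equal(classifyAssay(CarrierSet("v"), pair), "failed_no_carriers")
  expect_equal(classifyAssay(CarrierSet("v", hetIds = c("p1", "s")), pair),
               "failed_pair_missing")
  expect_equal(classifyAssay(CarrierSet("v", hetIds = c("p2", "p1")), pair),
               "pair_only")
  expect_equal(classifyAssay(CarrierSet("v", hetIds = c("p1", "p2", "r1",
                                                        "r2")), pair),
               "pair_plus_additional")
  ## hom carriers do not enter the het-based classification
  expect_equal(classifyAssay(CarrierSet("v", hetIds = pair, homIds = "z"),
                             pair), "pair_only")
  expect_error(classifyAssay(CarrierSet("v"), character(0)), "non-empty")
  ## the four classes partition a random set of assayed variants
  set.seed(8)
  cls <- vapply(1:50, function(i) {
    het <- sample(c(pair, sprintf("s%d", 1:6)), sample(0:6, 1))
    classifyAssay(CarrierSet("v", hetIds = het), pair)
  }, "")
  expect_equal(sum(table(cls)), 50)
  expect_true(all(cls %in% c("failed_no_carriers", "failed_pair_missing",
                             "pair_only", "pair_plus_additional")))
})

test_that("carrier-frequency cap drops variants above the panel fraction", {
  mk <- function(n) CarrierSet("v", hetIds = sprintf("c%04d", seq_len(n)))
  ## 10% of 1195 = 119.5: strict inequality boundary
  expect_true(carrierFrequencyFilter(mk(119), 1195))
  expect_false(carrierFrequencyFilter(mk(120), 1195))
  expect_true(carrierFrequencyFilter(mk(110), 1195))
  ## randomized counts against the direct comparison
  set.seed(3)
  for (i in 1:20) {
    n <- sample(50:300, 1); k <- sample(0:60, 1)
    expect_equal(carrierFrequencyFilter(mk(k), n), k <= 0.1 * n)
  }
  expect_error(carrierFrequencyFilter(mk(1), 0), "nAssayed")
})
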