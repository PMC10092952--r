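test_that("construction validates ids, parent sexes and acyclicity", {
  expect_error(Genealogy(rbind(chainPed(), chainPed()[1, ])), "duplicate")
  bad <- chainPed(); bad$sex[1] <- "female"   # A fathers B but is female
  expect_error(Genealogy(bad), "father")
  cyc <- pedTable(list("A", "B", NA, "male"), list("B", "A", NA, "male"))
  expect_error(Genealogy(cyc), "cycle")
  ext <- chainPed(); ext$father_id[2] <- "NOT_THERE"
  expect_warning(g <- Genealogy(ext), "external")
  expect_equal(unname(generationsLinked(g, "B")), 0L)
})

test_that("ancestors returns minimal meiotic distances", {
  g <- Genealogy(chainPed())
  expect_identical(ancestors(g, "A"), setNames(integer(0), character(0)))
  expect_equal(ancestors(g, "C"), c(B = 1L, A = 2L))
  expect_error(ancestors(g, "nope"), "missing individual")
  ## ancestor reachable by two paths of different length keeps the minimum
  gd <- Genealogy(diamondPed())
  expect_equal(ancestors(gd, "X")[["A"]], 2L)
  expect_equal(ancestors(gd, "X"), oracleAncestorDist(diamondPed(), "X")[
    names(ancestors(gd, "X"))])
  ## maxDepth truncates
  expect_false("A" %in% names(ancestors(g, "C", maxDepth = 1)))
})

test_that("descendants matches the transitive-closure oracle", {
  g <- Genealogy(chainPed())
  expect_identical(descendants(g, "C"), character(0))
  expect_setequal(descendants(g, "A"), c("B", "C"))
  sim <- simulateGenealogy(smallSimConfig(11, nFounderCouples = 5,
                                          nGenerations = 5))
  expect_gt(length(sim), 100)
  ped <- sim@ped
  founder <- ped$id[1L]
  expect_setequal(descendants(sim, founder), oracleDescendants(ped, founder))
  ## duality with ancestors on sampled pairs
  some <- ped$id[seq(1, nrow(ped), length.out = 25)]
  for (id in some) {
    for (d in descendants(sim, id))
      expect_true(id %in% names(ancestors(sim, d)))
  }
})

test_that("generationsLinked is the deepest recorded ancestor chain", {
  g <- Genealogy(cousinPed())
  expect_equal(unname(generationsLinked(g, "F1")), 0L)
  expect_equal(unname(generationsLinked(g, "C1")), 1L)
  expect_equal(unname(generationsLinked(g, "H1")), 3L)
  ## one deep line recorded, the other missing: depth follows the deepest
  ped <- pedTable(list("A", NA, NA, "male"), list("B", "A", NA, "male"),
                  list("S", NA, NA, "female"), list("X", "B", "S", "male"))
  gx <- Genealogy(ped)
  paths <- oraclePathsUp(ped, "X")
  expect_equal(unname(generationsLinked(gx, "X")),
               max(lengths(paths)) - 1L)
})

test_that("relationship degrees reproduce the textbook classes", {
  g <- Genealogy(cousinPed())
  pc <- relationshipDegree(g, "C1", "F1")          # parent-child
  expect_equal(pc$relatedness, 0.5)
  expect_equal(pc$degree, 1L)
  sib <- relationshipDegree(g, "C1", "C2")         # full siblings, two paths
  expect_equal(sib$relatedness, 0.5)
  expect_equal(sib$degree, 1L)
  fc <- relationshipDegree(g, "G1", "G2")          # first cousins
  expect_equal(fc$relatedness, 1 / 8)
  expect_equal(fc$degree, 3L)
  un <- relationshipDegree(g, "G1", "S2")
  expect_false(un$related)
  expect_true(is.na(un$degree))
  expect_error(relationshipDegree(g, "G1", "G1"), "undefined")
})

test_that("relatedness agrees with path-enumeration and kinship oracles", {
  ped <- cousinPed()
  g <- Genealogy(ped)
  pairs <- list(c("H1", "H2"), c("G1", "H2"), c("C1", "G2"), c("F1", "H1"))
  for (p in pairs) {
    r <- relationshipDegree(g, p[1], p[2])$relatedness
    expect_equal(r, oracleRelatedness(ped, p[1], p[2]))
    expect_equal(r, 2 * oracleKinship(ped, p[1], p[2]))  # no inbreeding here
  }
  ## symmetry + oracle agreement on a random simulated genealogy
  sim <- simulateGenealogy(smallSimConfig(23))
  ped2 <- sim@ped
  set.seed(42)
  ids <- sample(ped2$id, 12)
  for (i in 1:6) {
    a <- ids[2 * i - 1]; b <- ids[2 * i]
    ra <- relationshipDegree(sim, a, b)
    rb <- relationshipDegree(sim, b, a)
    expect_identical(ra, rb)
    expect_equal(ra$relatedness, oracleRelatedness(ped2, a, b))
  }
})

test_that("cousin classification separates first, second and half cousins", {
  g <- Genealogy(cousinPed())
  fc <- classifyCousins(g, "G1", "G2")
  expect_equal(fc$cousinClass, "first")
  expect_false(fc$half)
  expect_setequal(fc$sharedAncestorIds, c("F1", "F2"))
  sc <- classifyCousins(g, "H1", "H2")
  expect_equal(sc$cousinClass, "second")
  expect_null(classifyCousins(g, "C1", "C2"))      # siblings
  expect_null(classifyCousins(g, "C1", "G2"))      # avuncular
  expect_null(classifyCousins(g, "F1", "G1"))      # lineal
  ## half first cousins share a single grandparent; r = 1/16 by path oracle
  hp <- halfCousinPed()
  gh <- Genealogy(hp)
  hc <- classifyCousins(gh, "G1", "G2")
  expect_equal(hc$cousinClass, "first")
  expect_true(hc$half)
  expect_equal(oracleRelatedness(hp, "G1", "G2"), 1 / 16)
  expect_equal(relationshipDegree(gh, "G1", "G2")$relatedness, 1 / 16)
})

test_that("founding common ancestor is the most recent, couple-aware", {
  g <- Genealogy(cousinPed())
  expect_equal(foundingCommonAncestor(g, "G1")$ids, "G1")
  fca <- foundingCommonAncestor(g, c("G1", "G2"))
  expect_setequal(fca$ids, c("F1", "F2"))
  expect_true(fca$couple)
  expect_null(foundingCommonAncestor(g, c("G1", "S2")))
  ## brute force on a simulated pedigree: minimal descendant count among the
  ## intersection of ancestor-or-self sets
  sim <- simulateGenealogy(smallSimConfig(31, nFounderCouples = 4,
                                          nGenerations = 5))
  ped <- sim@ped
  set.seed(7)
  repeat {   # find a trio with a common ancestor
    trio <- sample(ped$id[sim@depth >= 2], 3)
    sets <- lapply(trio, function(i)
      c(i, names(oracleAncestorDist(ped, i))))
    common <- Reduce(intersect, sets)
    if (length(common)) break
  }
  nd <- vapply(common, function(a) length(oracleDescendants(ped, a)),
               integer(1))
  got <- foundingCommonAncestor(sim, trio)
  expect_true(all(got$ids %in% common[nd == min(nd)]))
  for (m in trio)
    expect_true(m %in% c(descendants(sim, got$ids), got$ids))
})

test_that("relatedness clusters equal union-find components", {
  g <- Genealogy(cousinPed())
  ## three mutually unrelated founders: no clusters
  expect_length(relatednessClusters(g, c("F1", "S1", "S2"), minSize = 3), 0)
  ## two cousins plus another grandchild of the same couple: one cluster
  cl <- relatednessClusters(g, c("G1", "G2", "H1"), minSize = 3)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$ids, c("G1", "G2", "H1"))
  ## random carriers in a simulated genealogy vs the union-find oracle
  sim <- simulateGenealogy(smallSimConfig(47, nFounderCouples = 5,
                                          nGenerations = 5))
  ped <- sim@ped
  set.seed(9)
  ids <- sample(ped$id, 40)
  ancSets <- lapply(ids, function(i)
    c(i, names(oracleAncestorDist(ped, i))))
  names(ancSets) <- ids
  related <- function(a, b)
    length(intersect(ancSets[[a]], ancSets[[b]])) > 0
  want <- Filter(function(comp) length(comp) >= 3,
                 oracleComponents(ids, related))
  got <- relatednessClusters(sim, ids, minSize = 3)
  expect_equal(length(got), length(want))
  wantSorted <- lapply(want, sort)
  for (cl in got) {
    expect_true(any(vapply(wantSorted, identical, TRUE, y = cl$ids)))
    if (!is.null(cl$founder))    # founder is an ancestor of every member
      for (m in cl$ids)
        expect_true(m %in% c(descendants(sim, cl$founder$ids),
                             cl$founder$ids))
  }
  ## clusters partition their members: no id in two clusters
  all_ids <- unlist(lapply(got, `[[`, "ids"))
  expect_false(anyDuplicated(all_ids) > 0)
})
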