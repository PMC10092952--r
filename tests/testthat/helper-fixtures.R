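# Hand-built pedigree fixtures and independent brute-force oracles.
# The oracles work directly on the raw pedigree data.frame so they share no
# code with the package's graph machinery.

pedTable <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]],
               father_id = if (is.na(r[[2]])) NA_character_ else r[[2]],
               mother_id = if (is.na(r[[3]])) NA_character_ else r[[3]],
               sex = r[[4]],
               birth_year = if (length(r) >= 5) r[[5]] else 1900L,
               birth_in_region = if (length(r) >= 6) r[[6]] else TRUE,
               death_year = NA_integer_, stringsAsFactors = FALSE)
  }))
  out
}

# 3-generation male chain A -> B -> C
chainPed <- function() {
  pedTable(list("A", NA, NA, "male", 1850),
           list("B", "A", NA, "male", 1880),
           list("C", "B", NA, "male", 1910))
}

# first/second-cousin pedigree: founder couple F1 x F2; children C1, C2 with
# unrelated spouses S1, S2; grandchildren G1, G2 (first cousins); and one
# more generation H1, H2 (second cousins)
cousinPed <- function() {
  pedTable(list("F1", NA, NA, "male", 1840),
           list("F2", NA, NA, "female", 1842),
           list("C1", "F1", "F2", "male", 1870),
           list("C2", "F1", "F2", "female", 1872),
           list("S1", NA, NA, "female", 1871),
           list("S2", NA, NA, "male", 1873),
           list("G1", "C1", "S1", "male", 1900),
           list("G2", "S2", "C2", "male", 1902),
           list("T1", NA, NA, "female", 1901),
           list("T2", NA, NA, "female", 1903),
           list("H1", "G1", "T1", "male", 1930),
           list("H2", "G2", "T2", "male", 1932))
}

# half-first-cousins: F1 has children by two different mates
halfCousinPed <- function() {
  pedTable(list("F1", NA, NA, "male", 1840),
           list("M1", NA, NA, "female", 1841),
           list("M2", NA, NA, "female", 1843),
           list("C1", "F1", "M1", "male", 1870),
           list("C2", "F1", "M2", "female", 1872),
           list("S1", NA, NA, "female", 1871),
           list("S2", NA, NA, "male", 1873),
           list("G1", "C1", "S1", "male", 1900),
           list("G2", "S2", "C2", "male", 1902))
}

# diamond: ancestor reachable from X by paths of length 2 and 3
diamondPed <- function() {
  pedTable(list("A", NA, NA, "female", 1840),
           list("P", "Q", "A", "male", 1870),   # A is P's mother
           list("Q", NA, "A", "male", 1845),    # and Q's mother: loop lengths differ
           list("S", NA, NA, "female", 1872),
           list("X", "P", "S", "male", 1900))
}

smallSimConfig <- function(seed, nFounderCouples = 3, nGenerations = 4,
                           offspringMean = c(3, 2.5, 2)) {
  SimConfig(nFounderCouples = nFounderCouples, nGenerations = nGenerations,
            offspringMean = offspringMean, immigrantRate = 0.6,
            plantedVariants = list(), neutralVariantCount = 0, seed = seed)
}

## ---- oracles ---------------------------------------------------------------

# all ancestor paths from id upward (list of character vectors, first = id)
oraclePathsUp <- function(ped, id) {
  out <- list()
  recurse <- function(path) {
    out[[length(out) + 1L]] <<- path
    last <- path[length(path)]
    row <- ped[ped$id == last, ]
    for (p in c(row$father_id, row$mother_id))
      if (!is.na(p)) recurse(c(path, p))
  }
  recurse(id)
  out
}

# minimal meiotic distances to every ancestor, by exhaustive path search
oracleAncestorDist <- function(ped, id) {
  paths <- oraclePathsUp(ped, id)
  d <- list()
  for (p in paths) {
    anc <- p[length(p)]
    len <- length(p) - 1L
    if (anc != id && (is.null(d[[anc]]) || len < d[[anc]])) d[[anc]] <- len
  }
  unlist(d)
}

# Wright path-counting relatedness: sum over path pairs sharing only the
# common ancestor of (1/2)^(total meioses)
oracleRelatedness <- function(ped, a, b) {
  pa <- oraclePathsUp(ped, a)
  pb <- oraclePathsUp(ped, b)
  r <- 0
  for (p in pa) for (q in pb) {
    if (p[length(p)] == q[length(q)] &&
        length(intersect(p, q)) == 1L)
      r <- r + 0.5^(length(p) + length(q) - 2L)
  }
  r
}

# Karigl recursive kinship coefficient (independent classical algorithm)
oracleKinship <- function(ped, a, b) {
  dep <- new.env()
  depth <- function(x) {
    if (is.na(x)) return(-1L)
    if (!is.null(dep[[x]])) return(dep[[x]])
    row <- ped[ped$id == x, ]
    d <- 1L + max(depth(row$father_id), depth(row$mother_id))
    dep[[x]] <- d
    d
  }
  memo <- new.env()
  phi <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    key <- paste(sort(c(x, y)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    rx <- ped[ped$id == x, ]; ry <- ped[ped$id == y, ]
    v <- if (x == y) {
      0.5 * (1 + phi(rx$father_id, rx$mother_id))
    } else if (depth(x) >= depth(y)) {
      0.5 * (phi(rx$father_id, y) + phi(rx$mother_id, y))
    } else {
      0.5 * (phi(x, ry$father_id) + phi(x, ry$mother_id))
    }
    memo[[key]] <- v
    v
  }
  phi(a, b)
}

# transitive closure of the child relation, by repeated expansion
oracleDescendants <- function(ped, id) {
  out <- character(0)
  frontier <- id
  repeat {
    kids <- ped$id[(!is.na(ped$father_id) & ped$father_id %in% frontier) |
                   (!is.na(ped$mother_id) & ped$mother_id %in% frontier)]
    kids <- setdiff(kids, out)
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- kids
  }
  setdiff(out, id)
}

# union-find over an explicit pairwise relation
oracleComponents <- function(ids, relatedFun) {
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (relatedFun(ids[i], ids[j])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  unname(split(ids, vapply(seq_len(n), find, integer(1))))
}

# direct Poisson upper-tail summation, term by term until underflow
oraclePoissonUpper <- function(k, lam) {
  if (k == 0) return(1)
  s <- 0; j <- k
  repeat {
    term <- exp(j * log(lam) - lam - lgamma(j + 1))
    s <- s + term
    if (term < 1e-320 || (j > lam && term < s * 1e-18)) break
    j <- j + 1
  }
  s
}
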