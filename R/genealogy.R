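## Pedigree graph construction and relationship computations.
##
## Internals work on integer row indices; exported functions translate ids
## once via match(). Parent links point upward (fidx/midx), the children list
## points downward.

#' Build a Genealogy from a pedigree table
#'
#' @param ped data.frame with columns \code{id}, \code{father_id},
#'   \code{mother_id}, \code{sex}, \code{birth_year}, \code{birth_in_region},
#'   \code{death_year}.  Empty strings and NA mean unknown.  Parent ids that
#'   do not occur in \code{id} are treated as external and dropped with a
#'   warning.
#' @return a \code{\linkS4class{Genealogy}}
#' @examples
#' ped <- data.frame(id = c("A", "B", "C"),
#'                   father_id = c(NA, "A", "B"), mother_id = NA,
#'                   sex = c("male", "male", "male"),
#'                   birth_year = c(1850, 1880, 1910),
#'                   birth_in_region = c(FALSE, TRUE, TRUE),
#'                   death_year = NA)
#' g <- Genealogy(ped)
#' generationsLinked(g, "C")
#' @export
Genealogy <- function(ped) {
  ped <- as.data.frame(ped)
  ped$id <- as.character(ped$id)
  for (col in c("father_id", "mother_id")) {
    v <- as.character(ped[[col]])
    v[!is.na(v) & v == ""] <- NA
    ped[[col]] <- v
  }
  ped$sex <- as.character(ped$sex)
  ped$sex[is.na(ped$sex)] <- "unknown"
  ped$birth_year <- suppressWarnings(as.integer(ped$birth_year))
  ped$death_year <- suppressWarnings(as.integer(ped$death_year))
  ped$birth_in_region <- as.logical(ped$birth_in_region)
  if (anyDuplicated(ped$id))
    stop("duplicate individual ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  fidx <- match(ped$father_id, ped$id)
  midx <- match(ped$mother_id, ped$id)
  ext <- (!is.na(ped$father_id) & is.na(fidx)) |
         (!is.na(ped$mother_id) & is.na(midx))
  if (any(ext))
    warning(sum(ext), " individuals reference parent ids not in the table; ",
            "treated as external/unknown")
  n <- nrow(ped)
  children <- vector("list", n)
  kn <- c(fidx, midx)
  kc <- c(seq_len(n), seq_len(n))
  keep <- !is.na(kn)
  if (any(keep)) {
    sp <- split(kc[keep], kn[keep])
    children[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  children[vapply(children, is.null, TRUE)] <- list(integer(0))
  depth <- .computeDepth(n, fidx, midx, children)
  new("Genealogy", ped = ped, fidx = as.integer(fidx),
      midx = as.integer(midx), children = children, depth = depth)
}

## longest ancestor chain above each individual, via Kahn's algorithm on the
## parent->child edges; also the acyclicity proof.
.computeDepth <- function(n, fidx, midx, children) {
  npar <- (!is.na(fidx)) + (!is.na(midx))
  depth <- integer(n)
  queue <- which(npar == 0L)
  done <- 0L
  remaining <- npar
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]; done <- done + 1L
    for (ch in children[[i]]) {
      depth[ch] <- max(depth[ch], depth[i] + 1L)
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (done < n)
    stop("pedigree contains a cycle (an individual is its own ancestor)")
  depth
}

.idx <- function(gen, id) {
  i <- match(as.character(id), gen@ped$id)
  if (anyNA(i))
    stop("missing individual: ",
         paste(as.character(id)[is.na(i)], collapse = ", "))
  i
}

## BFS up the parent links; returns named int vector idx -> min meioses
.ancestorsIdx <- function(gen, i, maxDepth = Inf) {
  dist <- integer(0)
  frontier <- i
  d <- 0L
  seen <- i
  while (length(frontier) && d < maxDepth) {
    d <- d + 1L
    par <- c(gen@fidx[frontier], gen@midx[frontier])
    par <- unique(par[!is.na(par)])
    par <- par[!(par %in% seen)]
    if (!length(par)) break
    dist[as.character(par)] <- d
    seen <- c(seen, par)
    frontier <- par
  }
  dist
}

.descendantsIdx <- function(gen, i) {
  out <- integer(0)
  frontier <- i
  while (length(frontier)) {
    ch <- unique(unlist(gen@children[frontier], use.names = FALSE))
    ch <- ch[!(ch %in% out)]
    if (!length(ch)) break
    out <- c(out, ch)
    frontier <- ch
  }
  setdiff(out, i)
}

#' @rdname ancestors
#' @export
setGeneric("ancestors", function(x, id, maxDepth = Inf)
  standardGeneric("ancestors"))

#' Ancestors with minimal meiotic distance
#'
#' All recorded ancestors reachable through parent links, each with the
#' minimal number of meioses separating it from \code{id}.
#'
#' @param x a \code{Genealogy}
#' @param id individual id
#' @param maxDepth optional bound on the number of meioses
#' @return named integer vector, ancestor id -> minimal generation distance;
#'   empty for a founder
#' @export
setMethod("ancestors", "Genealogy", function(x, id, maxDepth = Inf) {
  i <- .idx(x, id)
  a <- .ancestorsIdx(x, i, maxDepth)
  setNames(as.integer(a), x@ped$id[as.integer(names(a))])
})

#' @rdname descendants
#' @export
setGeneric("descendants", function(x, id) standardGeneric("descendants"))

#' Descendants of an individual
#'
#' Every individual that has \code{id} among its ancestors; \code{id} itself
#' is excluded.
#'
#' @param x a \code{Genealogy}
#' @param id individual id (or several; the union is returned)
#' @return character vector of descendant ids
#' @export
setMethod("descendants", "Genealogy", function(x, id) {
  i <- .idx(x, id)
  x@ped$id[.descendantsIdx(x, i)]
})

#' Generations of genealogy linked above an individual
#'
#' Depth of the deepest recorded ancestor chain; 0 for a founder.  Used as
#' the eligibility filter (at least 3 generations) for cohort membership.
#'
#' @param gen a \code{Genealogy}
#' @param id individual id, or NULL for all individuals
#' @return integer (named vector over all ids when \code{id} is NULL)
#' @export
generationsLinked <- function(gen, id = NULL) {
  if (is.null(id)) return(setNames(gen@depth, gen@ped$id))
  gen@depth[.idx(gen, id)]
}

## All ancestor paths from i upward, as integer vectors starting at i
## (the trivial path of length 0 included).
.pathsUp <- function(gen, i, maxDepth = Inf) {
  out <- list(i)
  grow <- list(i)
  d <- 0L
  while (length(grow) && d < maxDepth) {
    d <- d + 1L
    nxt <- list()
    for (p in grow) {
      last <- p[length(p)]
      for (q in c(gen@fidx[last], gen@midx[last]))
        if (!is.na(q)) nxt[[length(nxt) + 1L]] <- c(p, q)
    }
    out <- c(out, nxt)
    grow <- nxt
  }
  out
}

#' Relationship degree between two individuals
#'
#' Expected relatedness is the sum over distinct common-ancestor path pairs of
#' (1/2)^meioses (Wright's path counting: the two paths may share no node
#' other than the common ancestor; paths through distinct ancestor routes,
#' e.g. through both members of an ancestral couple or through inbreeding
#' loops, are summed).  The degree is \code{round(-log2(r))}: 1 for
#' parent-child and full siblings, 3 for first cousins.
#'
#' @param gen a \code{Genealogy}
#' @param idA,idB two distinct individual ids
#' @param maxDepth optional bound on path length (meioses per branch)
#' @return list with \code{relatedness} (0 when no recorded common ancestor),
#'   \code{degree} (positive integer, or NA when unrelated) and
#'   \code{related} (logical)
#' @export
relationshipDegree <- function(gen, idA, idB, maxDepth = Inf) {
  a <- .idx(gen, idA); b <- .idx(gen, idB)
  if (a == b) stop("self-relationship is undefined")
  pa <- .pathsUp(gen, a, maxDepth)
  pb <- .pathsUp(gen, b, maxDepth)
  endA <- vapply(pa, function(p) p[length(p)], integer(1))
  endB <- vapply(pb, function(p) p[length(p)], integer(1))
  r <- 0
  for (i in seq_along(pa)) {
    js <- which(endB == endA[i])
    for (j in js) {
      common <- intersect(pa[[i]], pb[[j]])
      if (length(common) == 1L)   # paths share only the common ancestor
        r <- r + 0.5^(length(pa[[i]]) + length(pb[[j]]) - 2L)
    }
  }
  if (r == 0)
    return(list(relatedness = 0, degree = NA_integer_, related = FALSE))
  list(relatedness = r, degree = as.integer(round(-log2(r))), related = TRUE)
}

#' Classify a pair of individuals as first or second cousins
#'
#' First cousins share at least one grandparent (two meioses up on both
#' sides) and no parent; second cousins share at least one great-grandparent
#' and no grandparent or parent.  Half relationships (a single shared
#' ancestor rather than an ancestral couple) fall in the same class and are
#' flagged.
#'
#' @param gen a \code{Genealogy}
#' @param idA,idB two individual ids, neither an ancestor of the other
#' @return a list (\code{idA}, \code{idB}, \code{cousinClass} "first" or
#'   "second", \code{half}, \code{sharedAncestorIds}), or NULL when the pair
#'   is not a first/second cousin pair (siblings or closer, lineal, more
#'   distant, or unrelated)
#' @export
classifyCousins <- function(gen, idA, idB) {
  a <- .idx(gen, idA); b <- .idx(gen, idB)
  if (a == b) stop("self-relationship is undefined")
  ancA <- .ancestorsIdx(gen, a, maxDepth = 3)
  ancB <- .ancestorsIdx(gen, b, maxDepth = 3)
  if (b %in% as.integer(names(ancA)) || a %in% as.integer(names(ancB)))
    return(NULL)                      # lineal relationship
  shared <- intersect(names(ancA), names(ancB))
  if (!length(shared)) return(NULL)
  dA <- ancA[shared]; dB <- ancB[shared]
  if (any(dA <= 1L) || any(dB <= 1L)) return(NULL)  # siblings/avuncular
  lvl <- if (any(dA == 2L & dB == 2L)) 2L
         else if (any(dA == 3L & dB == 3L)) 3L
         else return(NULL)
  ids <- shared[dA == lvl & dB == lvl]
  list(idA = as.character(idA), idB = as.character(idB),
       cousinClass = if (lvl == 2L) "first" else "second",
       half = length(ids) < 2L,
       sharedAncestorIds = gen@ped$id[as.integer(ids)])
}

#' Founding common ancestor of a set of individuals
#'
#' Among the individuals that are ancestors of every member of \code{ids}
#' (each id counting as its own ancestor), returns the one with the smallest
#' descendant set -- the most recent common ancestor.  When a married pair
#' both qualify with minimal descendant count the couple is returned; ties
#' are broken by lexicographic id.
#'
#' @param gen a \code{Genealogy}
#' @param ids non-empty vector of individual ids
#' @return list(\code{ids} = founder id(s), \code{couple} = logical), or NULL
#'   when no common ancestor is recorded
#' @export
foundingCommonAncestor <- function(gen, ids) {
  ids <- unique(as.character(ids))
  if (!length(ids)) stop("ids must be non-empty")
  ii <- .idx(gen, ids)
  sets <- lapply(ii, function(i)
    c(i, as.integer(names(.ancestorsIdx(gen, i)))))
  common <- Reduce(intersect, sets)
  if (!length(common)) return(NULL)
  nd <- vapply(common, function(c) length(.descendantsIdx(gen, c)),
               integer(1))
  minimal <- common[nd == min(nd)]
  if (length(minimal) >= 2L) {
    ## couple = co-parents of at least one child
    for (i in seq_along(minimal)) for (j in seq_along(minimal)) {
      ci <- minimal[i]; cj <- minimal[j]
      if (i < j && any(gen@fidx[gen@children[[ci]]] %in% c(ci, cj) &
                       gen@midx[gen@children[[ci]]] %in% c(ci, cj),
                       na.rm = TRUE)) {
        pair <- sort(gen@ped$id[c(ci, cj)])
        return(list(ids = pair, couple = TRUE))
      }
    }
  }
  best <- sort(gen@ped$id[minimal])[1L]
  list(ids = best, couple = FALSE)
}

#' Relatedness clusters of a set of individuals
#'
#' Builds a graph on \code{ids} with an edge whenever two individuals share
#' at least one recorded common ancestor (one of the pair being an ancestor
#' of the other also counts), and returns the connected components of size at
#' least \code{minSize}, each annotated with its founding common ancestor.
#' Components whose members have no single ancestor common to all of them
#' carry a NULL founder.
#'
#' @param gen a \code{Genealogy}
#' @param ids individual ids
#' @param minSize minimal component size reported (default 3)
#' @param maxMeioses optional cap on the total meiotic distance through the
#'   shared ancestor that still counts as "related" (default unlimited)
#' @return list of clusters: each a list(\code{ids}, \code{founder} as
#'   returned by \code{\link{foundingCommonAncestor}})
#' @export
relatednessClusters <- function(gen, ids, minSize = 3L, maxMeioses = Inf) {
  ids <- unique(as.character(ids))
  if (length(ids) < minSize) return(list())
  ii <- .idx(gen, ids)
  cap <- if (is.finite(maxMeioses)) maxMeioses else Inf
  asets <- lapply(ii, function(i) {
    a <- .ancestorsIdx(gen, i, maxDepth = cap)
    c(setNames(0L, as.character(i)), a)
  })
  n <- length(ids)
  ea <- integer(0); eb <- integer(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- intersect(names(asets[[i]]), names(asets[[j]]))
    if (length(shared) &&
        any(asets[[i]][shared] + asets[[j]][shared] <= cap)) {
      ea <- c(ea, i); eb <- c(eb, j)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(ea))
    g <- igraph::add_edges(g, rbind(ea, eb))
  comp <- igraph::components(g)$membership
  out <- list()
  for (k in unique(comp)) {
    members <- ids[comp == k]
    if (length(members) >= minSize) {
      out[[length(out) + 1L]] <-
        list(ids = sort(members),
             founder = foundingCommonAncestor(gen, members))
    }
  }
  ## deterministic order by smallest member id
  if (length(out) > 1L)
    out <- out[order(vapply(out, function(cl) cl$ids[1L], character(1)))]
  out
}
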