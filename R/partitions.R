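#' @include network.R
NULL

#' Branch-induced bi-allelic partition
#'
#' Removing one branch from a (spanning-tree resolved) haplotype network
#' splits the observed haplotypes of its component into two clades.  A branch
#' can span several segments: consecutive edges joined through inferred
#' intermediates of degree two induce the same partition and are reported as
#' one branch carrying all their variants.
#'
#' @slot branch branch id (assigned deterministically).
#' @slot component connected-component index.
#' @slot sideA observed haplotype ids on the side of the component's
#'   most-frequent haplotype (allele 0).
#' @slot sideB observed haplotype ids on the other side (allele 1).
#' @slot definingVariants variant tokens of the branch's segments.
#' @slot nResolutions number of spanning-tree resolutions supporting the
#'   partition (1 for branches not on a loop).
#' @export
setClass("BranchPartition",
  representation(branch = "character", component = "integer",
                 sideA = "character", sideB = "character",
                 definingVariants = "character", nResolutions = "integer"))

setValidity("BranchPartition", function(object) {
  if (length(intersect(object@sideA, object@sideB))) return("sides overlap")
  if (!length(object@sideA) || !length(object@sideB)) return("empty side")
  if (!length(object@definingVariants)) return("no defining variants")
  TRUE
})

setMethod("show", "BranchPartition", function(object) {
  cat("BranchPartition", object@branch, ": ", length(object@sideA), "|",
      length(object@sideB), " haplotypes; variants: ",
      paste(object@definingVariants, collapse = ", "),
      if (object@nResolutions > 1L)
        sprintf(" [%d resolutions]", object@nResolutions) else "", "\n",
      sep = "")
})

# For one spanning tree of a component (kept = logical over component edge
# ids), compute the observed-haplotype side below every kept edge.  Returns a
# list with per-edge child-side name vectors (NULL for dropped edges).
.treeSides <- function(el, keep, nV, vobs, vnames) {
  deg <- tabulate(c(el[keep, 1], el[keep, 2]), nV)
  adjV <- vector("list", nV); adjE <- vector("list", nV)
  for (v in seq_len(nV)) { adjV[[v]] <- integer(deg[v]); adjE[[v]] <- integer(deg[v]) }
  fill <- integer(nV)
  for (e in which(keep)) {
    a <- el[e, 1]; b <- el[e, 2]
    fill[a] <- fill[a] + 1L; adjV[[a]][fill[a]] <- b; adjE[[a]][fill[a]] <- e
    fill[b] <- fill[b] + 1L; adjV[[b]][fill[b]] <- a; adjE[[b]][fill[b]] <- e
  }
  parent <- integer(nV); pedge <- integer(nV)
  ord <- integer(nV); seen <- logical(nV)
  ord[1] <- 1L; seen[1] <- TRUE; head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- ord[head]; head <- head + 1L
    nb <- adjV[[v]]
    for (r in seq_along(nb)) {
      w <- nb[r]
      if (!seen[w]) {
        seen[w] <- TRUE; parent[w] <- v; pedge[w] <- adjE[[v]][r]
        tail <- tail + 1L; ord[tail] <- w
      }
    }
  }
  subtree <- vector("list", nV)
  for (i in rev(seq_len(tail))) {
    v <- ord[i]
    s <- if (vobs[v]) vnames[v] else character(0)
    subtree[[v]] <- s
  }
  sides <- vector("list", nrow(el))
  for (i in rev(seq_len(tail))) {
    v <- ord[i]
    if (i > 1L) {
      sides[[pedge[v]]] <- subtree[[v]]
      p <- parent[v]
      subtree[[p]] <- c(subtree[[p]], subtree[[v]])
    }
  }
  sides
}

# Local spanning-tree resolutions of one biconnected component, enumerated
# over chain-contracted "super-edges" (maximal runs of edges joined through
# inferred degree-two nodes).  Cutting a chain anywhere yields the same
# observed partition for every other branch, so one representative original
# edge per chain suffices.  Returns a list of dropped original-edge id sets.
#
# superIds: chain-group id per original edge of the component; ends: for
# each super id, its two endpoint vertex ids; reps: representative original
# edge per super id; eids: the bicomp's original edge ids.
.localResolutions <- function(eids, superIds, ends, reps) {
  sup <- unique(superIds[eids])
  L <- length(sup)
  em <- ends[sup, , drop = FALSE]
  verts <- unique(as.vector(em))
  nv <- length(verts)
  r <- L - (nv - 1L)
  if (r < 1L) stop("acyclic biconnected component in loop resolution")
  if (r == 1L && L == nv)                      # simple (contracted) cycle
    return(as.list(reps[sup]))
  el2 <- matrix(match(as.vector(em), verts), ncol = 2)
  if (choose(L, r) > 2e4) {
    # Heavily fused cycle systems: full resolution enumeration is
    # combinatorially out of reach, so fall back to the single
    # deterministic resolution given by Kruskal over the contracted
    # super-edges in construction order (flagged via the "capped" attr).
    parent <- seq_len(nv)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    dropped <- integer(0)
    for (k in order(reps[sup])) {
      ra <- find(el2[k, 1]); rb <- find(el2[k, 2])
      if (ra != rb) parent[rb] <- ra else dropped <- c(dropped, k)
    }
    out <- list(unname(reps[sup[dropped]]))
    attr(out, "capped") <- TRUE
    return(out)
  }
  connected <- function(keepRows) {
    parent <- seq_len(nv)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in keepRows) {
      ra <- find(el2[k, 1]); rb <- find(el2[k, 2])
      if (ra != rb) parent[rb] <- ra
    }
    length(unique(vapply(seq_len(nv), find, 0L))) == 1L
  }
  drops <- utils::combn(L, r, simplify = FALSE)
  out <- list()
  for (d in drops) {
    if (connected(setdiff(seq_len(L), d)))
      out[[length(out) + 1L]] <- unname(reps[sup[d]])
  }
  out
}

# chain contraction: group component edges joined through inferred
# degree-two vertices; returns per-edge group ids, group endpoint matrix and
# representative edge per group
.contractChains <- function(el, nE, nV, vobs) {
  deg <- tabulate(c(el[, 1], el[, 2]), nV)
  inc <- vector("list", nV)
  for (e in seq_len(nE)) {
    inc[[el[e, 1]]] <- c(inc[[el[e, 1]]], e)
    inc[[el[e, 2]]] <- c(inc[[el[e, 2]]], e)
  }
  parent <- seq_len(nE)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (v in seq_len(nV)) {
    if (!vobs[v] && deg[v] == 2L) {
      e1 <- inc[[v]][1]; e2 <- inc[[v]][2]
      ra <- find(e1); rb <- find(e2)
      if (ra != rb) parent[rb] <- ra
    }
  }
  grp <- vapply(seq_len(nE), find, 0L)
  ugrp <- unique(grp)
  superIds <- match(grp, ugrp)
  nS <- length(ugrp)
  ends <- matrix(0L, nS, 2)
  reps <- integer(nS)
  for (s in seq_len(nS)) {
    es <- which(superIds == s)
    reps[s] <- es[1]
    vs <- c(el[es, 1], el[es, 2])
    keepV <- vs[!(vobs[vs] == FALSE & deg[vs] == 2L)]
    u <- unique(keepV)
    ends[s, ] <- if (length(u) >= 2L) u[1:2] else c(u[1], u[1])
  }
  list(superIds = superIds, ends = ends, reps = reps)
}

#' @rdname enumeratePartitions
#' @export
setMethod("enumeratePartitions", "HaplotypeNetwork", function(x) {
  g <- networkGraph(x)
  comps <- igraph::components(g)
  records <- list()

  for (ci in seq_len(comps$no)) {
    vs <- which(comps$membership == ci)
    if (length(vs) < 2L) next
    sub <- igraph::induced_subgraph(g, vs)
    vnames <- igraph::V(sub)$name
    vobs <- igraph::V(sub)$observed
    vcnt <- igraph::V(sub)$carrierCount
    obsNames <- vnames[vobs]
    if (length(obsNames) < 2L) next
    anchor <- obsNames[order(-vcnt[vobs], obsNames)][1]
    el <- igraph::as_edgelist(sub, names = FALSE)
    evar <- igraph::E(sub)$variant
    nV <- length(vnames); nE <- nrow(el)

    # biconnected components: cyclic ones need per-resolution treatment,
    # single-edge ones are bridges whose partition is resolution-independent
    bic <- igraph::biconnected_components(sub)
    bicEdges <- lapply(bic$component_edges, as.integer)
    cyclic <- bicEdges[vapply(bicEdges, length, 0L) > 1L]
    ctr <- if (length(cyclic)) .contractChains(el, nE, nV, vobs) else NULL
    resolutions <- lapply(cyclic, function(eids)
      .localResolutions(eids, ctr$superIds, ctr$ends, ctr$reps))
    cycEdgeSet <- unlist(cyclic)
    isCyc <- seq_len(nE) %in% cycEdgeSet

    canon <- function(sideChild) {
      s <- sort(sideChild)
      if (anchor %in% s) sort(setdiff(obsNames, s)) else s
    }
    compRec <- new.env(parent = emptyenv())
    note <- function(key, vars, cyclicBranch, resTag = NA_character_) {
      rec <- get0(key, envir = compRec, ifnotfound = NULL)
      if (is.null(rec)) {
        # defining variants come from the first supporting resolution;
        # later resolutions only add support counts
        sideB <- strsplit(key, ",", fixed = TRUE)[[1]]
        rec <- list(sideA = sort(setdiff(obsNames, sideB)), sideB = sideB,
                    vars = vars, resTags = character(0), component = ci,
                    cyclic = cyclicBranch)
      }
      if (!is.na(resTag) && !(resTag %in% rec$resTags))
        rec$resTags <- c(rec$resTags, resTag)
      assign(key, rec, envir = compRec)
    }

    # base resolution: drop the first local resolution of every cycle
    baseDrop <- unlist(lapply(resolutions, `[[`, 1L))
    keep0 <- !(seq_len(nE) %in% baseDrop)
    sides0 <- .treeSides(el, keep0, nV, vobs, vnames)
    bridgeKeys <- new.env(parent = emptyenv())
    for (e in which(keep0 & !isCyc)) {
      s <- sides0[[e]]
      if (!length(s) || length(s) == length(obsNames)) next
      key <- paste(canon(s), collapse = ",")
      prev <- get0(key, envir = bridgeKeys, ifnotfound = character(0))
      assign(key, c(prev, evar[e]), envir = bridgeKeys)
    }
    for (key in ls(bridgeKeys))
      note(key, sortTokens(unique(get(key, envir = bridgeKeys))), FALSE)

    # cyclic biconnected components: one subtree pass per local resolution;
    # only the component's own edges are collected (choices made in other
    # cycles cannot change which side a vertex falls on)
    for (bi in seq_along(cyclic)) {
      eids <- cyclic[[bi]]
      for (ri in seq_along(resolutions[[bi]])) {
        drop <- resolutions[[bi]][[ri]]
        otherDrop <- setdiff(baseDrop, resolutions[[bi]][[1L]])
        keep <- !(seq_len(nE) %in% c(drop, otherDrop))
        sides <- .treeSides(el, keep, nV, vobs, vnames)
        resKeys <- new.env(parent = emptyenv())
        for (e in setdiff(eids, drop)) {
          s <- sides[[e]]
          if (!length(s) || length(s) == length(obsNames)) next
          key <- paste(canon(s), collapse = ",")
          prev <- get0(key, envir = resKeys, ifnotfound = character(0))
          assign(key, c(prev, evar[e]), envir = resKeys)
        }
        tag <- sprintf("c%d.r%d", bi, ri)
        for (key in ls(resKeys))
          note(key, sortTokens(unique(get(key, envir = resKeys))), TRUE, tag)
      }
    }
    for (key in ls(compRec)) {
      rec <- get(key, envir = compRec)
      rec$nres <- if (rec$cyclic) max(1L, length(rec$resTags)) else 1L
      records[[length(records) + 1L]] <- rec
    }
  }

  if (!length(records)) return(list())
  ord <- order(vapply(records, function(r) r$component, 0L),
               vapply(records, function(r) length(r$sideB), 0L),
               vapply(records, function(r) paste(r$sideB, collapse = ","), ""))
  records <- records[ord]
  wid <- max(3L, nchar(length(records)))
  lapply(seq_along(records), function(i) {
    r <- records[[i]]
    methods::new("BranchPartition", branch = sprintf("b%0*d", wid, i),
                 component = r$component, sideA = r$sideA, sideB = r$sideB,
                 definingVariants = r$vars, nResolutions = r$nres)
  })
})

#' Summarize branch partitions as a data frame
#' @param partitions list of [BranchPartition-class].
#' @export
partitionTable <- function(partitions) {
  data.frame(
    branch = vapply(partitions, function(p) p@branch, ""),
    component = vapply(partitions, function(p) p@component, 0L),
    nSideA = vapply(partitions, function(p) length(p@sideA), 0L),
    nSideB = vapply(partitions, function(p) length(p@sideB), 0L),
    definingVariants = vapply(partitions, function(p)
      paste(p@definingVariants, collapse = ","), ""),
    nResolutions = vapply(partitions, function(p) p@nResolutions, 0L),
    stringsAsFactors = FALSE)
}
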