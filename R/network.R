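#' @include haplotypes.R
NULL

#' Haplotype network
#'
#' Graph over observed and inferred haplotypes in which every edge represents
#' exactly one mutational step (one variant).  Built as the union of all
#' minimum-length connections under the step metric, so alternative
#' connections of equal minimal length are retained and appear as loops.
#'
#' @slot graph an [igraph::igraph] with vertex attributes `name`, `observed`,
#'   `carrierCount` and edge attribute `variant` (the single differing token).
#' @slot haplotypes the observed [HaplotypeSet-class].
#' @slot nodeVariants named list of variant sets for every node (observed and
#'   inferred).
#' @slot maxSteps the connection cap used at build time (Inf = unlimited).
#' @export
setClass("HaplotypeNetwork",
  representation(graph = "ANY", haplotypes = "HaplotypeSet",
                 nodeVariants = "list", maxSteps = "numeric"))

#' @rdname HaplotypeNetwork-class
#' @export
setMethod("networkGraph", "HaplotypeNetwork", function(x) x@graph)

#' @rdname HaplotypeNetwork-class
#' @export
setMethod("hapIds", "HaplotypeNetwork", function(x) hapIds(x@haplotypes))

#' @rdname loopCount
#' @export
setMethod("loopCount", "HaplotypeNetwork", function(x) {
  g <- x@graph
  igraph::ecount(g) - igraph::vcount(g) + igraph::count_components(g)
})

setMethod("show", "HaplotypeNetwork", function(object) {
  g <- object@graph
  obs <- sum(igraph::V(g)$observed)
  cat("HaplotypeNetwork:", igraph::vcount(g), "nodes (", obs, "observed,",
      igraph::vcount(g) - obs, "inferred ),", igraph::ecount(g), "edges,",
      igraph::count_components(g), "component(s),",
      loopCount(object), "loop(s)\n")
})

# union-find
.dsuFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Minimum-length connections among variant sets: the union of all minimum
# spanning trees under the step metric (Kruskal processed level by level; an
# edge of weight d is retained iff its endpoints are unconnected using edges
# of weight < d).  Returns the retained pairs and their distances.
.minimumConnections <- function(vsets, maxSteps = Inf) {
  H <- length(vsets)
  toks <- unique(unlist(vsets, use.names = FALSE))
  M <- matrix(0L, H, length(toks))
  if (length(toks)) {
    colnames(M) <- toks
    for (i in seq_len(H)) M[i, vsets[[i]]] <- 1L
  }
  sizes <- rowSums(M)
  D <- outer(sizes, sizes, "+") - 2L * tcrossprod(M)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  pd <- D[pairs]
  keepP <- pd <= maxSteps
  pairs <- pairs[keepP, , drop = FALSE]
  pd <- pd[keepP]
  ord <- order(pd, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  pd <- pd[ord]
  parent <- seq_len(H)
  keepEdge <- logical(length(pd))
  for (lev in unique(pd)) {
    sel <- which(pd == lev)
    for (k in sel)
      keepEdge[k] <- .dsuFind(parent, pairs[k, 1]) != .dsuFind(parent, pairs[k, 2])
    for (k in sel[keepEdge[sel]]) {
      ra <- .dsuFind(parent, pairs[k, 1]); rb <- .dsuFind(parent, pairs[k, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  list(pairs = pairs[keepEdge, , drop = FALSE], dist = pd[keepEdge])
}

#' Build the haplotype network
#'
#' Connects haplotypes in nondecreasing order of mutational-step distance,
#' keeping every connection of minimal length between components (the union
#' of all minimum spanning trees under the step metric), so equally
#' parsimonious alternatives are retained as loops.  A connected pair at
#' distance d > 1 is joined through d - 1 inferred intermediate haplotypes.
#' Starting from the endpoint with the higher carrier count (ties by id),
#' the chain sheds the rarer variants first and gains the commoner ones
#' first (carrier-weighted frequency, then position, as tie-breaks), so
#' inferred intermediates approximate ancestral sequences and coincide
#' across chains where the data are tree-like.
#'
#' @param haplotypes a [HaplotypeSet-class] of observed haplotypes.
#' @param maxSteps do not create connections longer than this many steps
#'   (default unlimited); haplotypes further apart stay in separate
#'   components.
#' @return a [HaplotypeNetwork-class].
#' @export
buildNetwork <- function(haplotypes, maxSteps = Inf) {
  ids <- hapIds(haplotypes)
  vsets <- hapVariants(haplotypes)
  counts <- carrierCounts(haplotypes)
  H <- length(ids)
  if (H == 1L) {
    g <- igraph::make_empty_graph(1, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = ids)
    g <- igraph::set_vertex_attr(g, "observed", value = TRUE)
    g <- igraph::set_vertex_attr(g, "carrierCount", value = unname(counts))
    return(methods::new("HaplotypeNetwork", graph = g, haplotypes = haplotypes,
                        nodeVariants = vsets, maxSteps = maxSteps))
  }

  mc <- .minimumConnections(vsets, maxSteps)

  # carrier-weighted token frequencies: older variants are carried by more
  # subjects, so chains shed rare (young) variants first and gain common
  # (old) ones first -- intermediate nodes then approximate true ancestral
  # sequences and coincide across chains, keeping the network tree-like
  # where the data are tree-like
  tokFreq <- new.env(parent = emptyenv())
  for (i in seq_len(H)) for (tok in vsets[[i]]) {
    assign(tok, (get0(tok, envir = tokFreq, ifnotfound = 0)) + counts[i],
           envir = tokFreq)
  }
  freqOf <- function(toks) vapply(toks, function(t)
    get0(t, envir = tokFreq, ifnotfound = 0), 0)

  nodeVariants <- vsets
  observed <- stats::setNames(rep(TRUE, H), ids)
  keyMap <- new.env(parent = emptyenv())
  setKey <- function(vset)
    if (length(vset)) paste(vset, collapse = ";") else "<reference>"
  for (i in seq_len(H)) assign(setKey(vsets[[i]]), ids[i], envir = keyMap)
  edges <- character(0)   # interleaved endpoint ids
  evar <- character(0)
  nInferred <- 0L

  addEdge <- function(u, v, tok) {
    edges <<- c(edges, u, v); evar <<- c(evar, tok)
  }
  internNode <- function(vset) {
    key <- setKey(vset)
    hit <- get0(key, envir = keyMap, ifnotfound = NULL)
    if (!is.null(hit)) return(hit)
    nInferred <<- nInferred + 1L
    id <- sprintf("I%04d", nInferred)
    nodeVariants[[id]] <<- vset
    observed[id] <<- FALSE
    assign(key, id, envir = keyMap)
    id
  }

  for (k in seq_len(nrow(mc$pairs))) {
    i <- mc$pairs[k, 1]; j <- mc$pairs[k, 2]
    a <- ids[i]; b <- ids[j]
    # chain direction: start from the better-supported endpoint
    if (counts[b] > counts[a] || (counts[b] == counts[a] && b < a)) { tmp <- a; a <- b; b <- tmp }
    rem <- setdiff(nodeVariants[[a]], nodeVariants[[b]])
    add <- setdiff(nodeVariants[[b]], nodeVariants[[a]])
    rem <- rem[order(freqOf(rem), variantPositions(rem), rem)]
    add <- add[order(-freqOf(add), variantPositions(add), add)]
    diffTok <- c(rem, add)
    cur <- a
    curSet <- nodeVariants[[a]]
    for (t in seq_along(diffTok)) {
      tok <- diffTok[t]
      curSet <- if (tok %in% curSet) setdiff(curSet, tok) else
        sortTokens(c(curSet, tok))
      nxt <- if (t == length(diffTok)) b else internNode(curSet)
      addEdge(cur, nxt, tok)
      cur <- nxt
    }
  }

  allIds <- names(nodeVariants)
  g <- igraph::make_empty_graph(length(allIds), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = allIds)
  g <- igraph::set_vertex_attr(g, "observed", value = unname(observed[allIds]))
  cc <- ifelse(observed[allIds], counts[allIds], 0L)
  g <- igraph::set_vertex_attr(g, "carrierCount", value = unname(cc))
  if (length(edges)) {
    g <- igraph::add_edges(g, match(edges, allIds))
    g <- igraph::set_edge_attr(g, "variant", value = evar)
  }
  g <- igraph::simplify(g, edge.attr.comb = "first")
  methods::new("HaplotypeNetwork", graph = g, haplotypes = haplotypes,
               nodeVariants = nodeVariants, maxSteps = maxSteps)
}

#' Export a haplotype network
#'
#' Writes GraphML (node attributes: observed flag, carrier count, id; edge
#' attribute: defining variant token) and/or a plain TSV edge list.
#'
#' @param network a [HaplotypeNetwork-class].
#' @param graphml,edgeTsv output paths (NULL = skip).
#' @export
writeNetwork <- function(network, graphml = NULL, edgeTsv = NULL) {
  g <- networkGraph(network)
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(edgeTsv)) {
    el <- igraph::as_edgelist(g)
    df <- data.frame(from = el[, 1], to = el[, 2],
                     variant = igraph::E(g)$variant, stringsAsFactors = FALSE)
    utils::write.table(df, edgeTsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(graphml = graphml, edgeTsv = edgeTsv))
}
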