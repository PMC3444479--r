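test_that("step distance is the symmetric-difference size", {
  expect_equal(stepDistance(character(0), character(0)), 0L)
  expect_equal(stepDistance("m.263A>G", c("m.263A>G", "m.750A>G")), 1L)
  expect_equal(stepDistance("m.263A>G", "m.750A>G"), 2L)
  expect_equal(stepDistance(c("m.1A>C", "m.2C>T"), c("m.2C>T", "m.1A>C")), 0L)
  # one indel counts one step
  expect_equal(stepDistance("m.5_7del", c("m.5_7del", "m.9_10insAC")), 1L)
})

test_that("minimum-length networks connect, infer intermediates, keep ties", {
  # path: d(A,B) = 1, d(B,C) = 1, d(A,C) = 2 -> A-B-C without inferred nodes
  hs <- collapseHaplotypes(list(a = character(0), b = "m.5A>C",
                                c = c("m.5A>C", "m.9T>A")))
  net <- buildNetwork(hs)
  g <- networkGraph(net)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(loopCount(net), 0L)

  # two haplotypes three steps apart: chain through 2 inferred nodes
  hs <- collapseHaplotypes(list(a = character(0),
                                b = c("m.1A>C", "m.5A>C", "m.9T>A")))
  net <- buildNetwork(hs)
  g <- networkGraph(net)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  expect_equal(sum(!igraph::V(g)$observed), 2L)
  expect_true(all(igraph::degree(g)[!igraph::V(g)$observed] >= 2))

  # homoplasy square: two equally parsimonious routes retained as a loop
  hs <- collapseHaplotypes(list(a = character(0), b = "m.1A>C", c = "m.5A>C",
                                d = c("m.1A>C", "m.5A>C")))
  net <- buildNetwork(hs)
  expect_equal(igraph::ecount(networkGraph(net)), 4L)
  expect_equal(loopCount(net), 1L)

  # every edge differs by exactly its labelled variant
  nv <- net@nodeVariants
  el <- igraph::as_edgelist(networkGraph(net))
  for (e in seq_len(nrow(el))) {
    d <- stepDistance(nv[[el[e, 1]]], nv[[el[e, 2]]])
    expect_equal(d, 1L)
  }
})

test_that("network construction is invariant to haplotype input order", {
  set.seed(11)
  toks <- sprintf("m.%dA>C", 1:15)
  sv <- lapply(1:12, function(i) sample(toks, sample(0:6, 1)))
  names(sv) <- paste0("s", 1:12)
  net1 <- buildNetwork(collapseHaplotypes(sv))
  net2 <- buildNetwork(collapseHaplotypes(sv[sample(12)]))
  canon <- function(net) {
    el <- igraph::as_edgelist(networkGraph(net))
    keys <- apply(el, 1, function(r) paste(sort(r), collapse = "~"))
    sort(keys)
  }
  expect_equal(canon(net1), canon(net2))
})

test_that("loop count equals the cycle-space dimension", {
  tree <- buildNetwork(collapseHaplotypes(list(
    a = character(0), b = "m.1A>C", c = "m.5A>C")))
  expect_equal(loopCount(tree), 0L)

  square <- buildNetwork(collapseHaplotypes(list(
    a = character(0), b = "m.1A>C", c = "m.5A>C",
    d = c("m.1A>C", "m.5A>C"))))
  expect_equal(loopCount(square), 1L)

  # two squares sharing one edge: V = 6, E = 7, one component -> 2 loops
  shared <- buildNetwork(collapseHaplotypes(list(
    n1 = character(0), n2 = "m.1A>C", n3 = "m.5A>C",
    n4 = c("m.1A>C", "m.5A>C"), n5 = c("m.1A>C", "m.9T>A"),
    n6 = c("m.1A>C", "m.5A>C", "m.9T>A"))))
  g <- networkGraph(shared)
  expect_equal(igraph::vcount(g), 6L)
  expect_equal(igraph::ecount(g), 7L)
  expect_equal(loopCount(shared), 2L)
})

test_that("partition enumeration matches brute force over spanning trees", {
  fixtures <- list(
    path = list(a = character(0), b = "m.5A>C", c = c("m.5A>C", "m.9T>A")),
    star = list(ctr = character(0), l1 = "m.1A>C", l2 = "m.5A>C",
                l3 = "m.9T>A"),
    square = list(a = character(0), b = "m.1A>C", c = "m.5A>C",
                  d = c("m.1A>C", "m.5A>C")),
    doubleSquare = list(
      n1 = character(0), n2 = "m.1A>C", n3 = "m.5A>C",
      n4 = c("m.1A>C", "m.5A>C"), n5 = c("m.1A>C", "m.9T>A"),
      n6 = c("m.1A>C", "m.5A>C", "m.9T>A")),
    chain = list(a = character(0), b = c("m.1A>C", "m.5A>C", "m.9T>A"),
                 c = c("m.1A>C", "m.5A>C", "m.9T>A", "m.13C>G")))
  for (nm in names(fixtures)) {
    net <- buildNetwork(collapseHaplotypes(fixtures[[nm]]))
    got <- partitionKeys(enumeratePartitions(net))
    want <- bruteForcePartitions(net)
    expect_equal(got, want, info = nm)
  }
})

test_that("partition sides are disjoint, nonempty and exhaustive; nesting is
           subset-ordered; loop partitions report their resolution support", {
  # path of 3 observed nodes -> exactly 2 partitions
  p3 <- enumeratePartitions(buildNetwork(collapseHaplotypes(list(
    a = character(0), b = "m.5A>C", c = c("m.5A>C", "m.9T>A")))))
  expect_equal(length(p3), 2L)
  # star -> 3 partitions, each isolating one leaf
  st <- enumeratePartitions(buildNetwork(collapseHaplotypes(list(
    ctr = character(0), l1 = "m.1A>C", l2 = "m.5A>C", l3 = "m.9T>A"))))
  expect_equal(length(st), 3L)
  expect_true(all(vapply(st, function(p) min(length(p@sideA),
                                             length(p@sideB)), 0L) == 1L))

  # 4-cycle: 6 distinct partitions, each supported by 2 of the 4 resolutions
  sq <- enumeratePartitions(buildNetwork(collapseHaplotypes(list(
    a = character(0), b = "m.1A>C", c = "m.5A>C",
    d = c("m.1A>C", "m.5A>C")))))
  expect_equal(length(sq), 6L)
  expect_true(all(vapply(sq, function(p) p@nResolutions, 0L) == 2L))

  set.seed(3)
  co <- simulateCohort(toyParams(seed = 3))
  prep <- prepareScan(co@variantTable, co@pedigree,
    co@subjects[, c("subject_id", "status", "age", "sex",
                    "apoe_e4", "apoe_e2", "genotyped")],
    co@reference, famrisk = FALSE,
    genotypedIds = co@subjects$subject_id[co@subjects$genotyped])
  parts <- enumeratePartitions(prep$network)
  obsIds <- hapIds(prep$haplotypes)
  for (p in parts) {
    expect_length(intersect(p@sideA, p@sideB), 0)
    expect_true(length(p@sideA) > 0 && length(p@sideB) > 0)
    expect_setequal(c(p@sideA, p@sideB), obsIds)
    expect_true(length(p@definingVariants) >= 1)
  }
  # nesting: any two clades on a tree-like component are nested or disjoint
  comp1 <- Filter(function(p) p@component == 1L, parts)
  anchor <- names(sort(carrierCounts(prep$haplotypes), decreasing = TRUE))[1]
  clades <- lapply(comp1, function(p)
    if (anchor %in% p@sideA) p@sideB else p@sideA)
  nested <- 0L
  for (i in seq_along(clades)) for (j in seq_len(i - 1L)) {
    ov <- length(intersect(clades[[i]], clades[[j]]))
    if (ov > 0 && loopCount(prep$network) == 0L)
      expect_true(ov == length(clades[[i]]) || ov == length(clades[[j]]))
    if (ov > 0 && (ov == length(clades[[i]]) || ov == length(clades[[j]])))
      nested <- nested + 1L
    }
  expect_gt(nested, 0L)
})

test_that("network export writes GraphML and an edge list", {
  net <- buildNetwork(collapseHaplotypes(list(
    a = character(0), b = "m.5A>C", c = c("m.5A>C", "m.9T>A"))))
  gml <- tempfile(fileext = ".graphml")
  tsv <- tempfile(fileext = ".tsv")
  writeNetwork(net, graphml = gml, edgeTsv = tsv)
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(reread), 3)
  el <- utils::read.delim(tsv)
  expect_equal(nrow(el), 2L)
  expect_true(all(c("from", "to", "variant") %in% names(el)))
})
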