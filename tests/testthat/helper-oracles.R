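# Independent oracles and shared fixtures for the test suite.  Everything
# here is deliberately naive (closed forms, exhaustive enumeration, brute
# force) and never calls the code paths it is used to check.

# closed-form 2x2 likelihood-ratio G statistic
gStatistic <- function(g, y) {
  ok <- !is.na(g) & !is.na(y)
  g <- g[ok]; y <- y[ok]
  if (length(unique(g)) < 2L) return(NA_real_)
  O <- table(factor(g, c(0, 1)), factor(y, c(0, 1)))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  2 * sum(ifelse(O > 0, O * log(O / E), 0))
}

# all permutations of 1..n as rows (n small)
enumeratePerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- enumeratePerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos)
    cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                  drop = FALSE]))
}

# Exhaustive-scan oracle: nominal and step-down minP corrected p-values over
# every subject -> haplotype assignment permutation, with an arbitrary
# per-branch statistic function statFun(g, y).
exhaustiveScanOracle <- function(gvecs, y, statFun) {
  n <- length(y)
  perms <- enumeratePerms(n)
  S <- sapply(seq_along(gvecs), function(j)
    apply(perms, 1, function(pi) statFun(gvecs[[j]][pi], y)))
  obs <- sapply(seq_along(gvecs), function(j) statFun(gvecs[[j]], y))
  S[is.na(S)] <- -Inf
  N <- nrow(S); eps <- 1e-7
  nom <- sapply(seq_along(gvecs), function(k) sum(S[, k] >= obs[k] - eps) / N)
  pmat <- apply(S, 2, function(s) (N - rank(s, ties.method = "min") + 1) / N)
  ord <- order(nom, -obs)
  runmin <- rep(1, N); cnt <- numeric(length(gvecs))
  for (i in rev(seq_along(ord))) {
    runmin <- pmin(runmin, pmat[, ord[i]])
    cnt[i] <- sum(runmin <= nom[ord[i]] + 1e-12)
  }
  corr <- cummax(cnt / N)
  corrP <- numeric(length(gvecs)); corrP[ord] <- corr
  list(nominal = nom, corrected = corrP)
}

# Brute-force partition oracle: enumerate every spanning tree of each
# component of the network graph (by edge subsets), remove each tree edge,
# flood, and collect the distinct observed-haplotype partitions.
bruteForcePartitions <- function(network) {
  g <- networkGraph(network)
  comps <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comps$no)) {
    vs <- which(comps$membership == ci)
    if (length(vs) < 2L) next
    sub <- igraph::induced_subgraph(g, vs)
    nE <- igraph::ecount(sub); nV <- igraph::vcount(sub)
    obsNames <- igraph::V(sub)$name[igraph::V(sub)$observed]
    trees <- Filter(function(es)
      igraph::is_connected(igraph::subgraph_from_edges(sub, es,
                                                       delete.vertices = FALSE)),
      utils::combn(seq_len(nE), nV - 1L, simplify = FALSE))
    for (tree in trees) {
      tg <- igraph::subgraph_from_edges(sub, tree, delete.vertices = FALSE)
      for (e in seq_along(tree)) {
        cg <- igraph::delete_edges(tg, e)
        mem <- igraph::components(cg)$membership
        sideObs <- sort(intersect(igraph::V(sub)$name[mem == 1], obsNames))
        if (!length(sideObs) || length(sideObs) == length(obsNames)) next
        other <- sort(setdiff(obsNames, sideObs))
        key <- paste(min(paste(sideObs, collapse = ","),
                         paste(other, collapse = ",")),
                     max(paste(sideObs, collapse = ","),
                         paste(other, collapse = ",")), sep = "|")
        out[[key]] <- key
      }
    }
  }
  sort(unname(unlist(out)))
}

partitionKeys <- function(partitions) {
  sort(vapply(partitions, function(p) {
    a <- paste(sort(p@sideA), collapse = ",")
    b <- paste(sort(p@sideB), collapse = ",")
    paste(min(a, b), max(a, b), sep = "|")
  }, ""))
}

# founder-allele descent oracle for kinship between two distinct,
# non-inbred individuals: phi(i,j) = sum_f a_i[f] * a_j[f] where a_x is the
# distribution of a random allele of x over founder alleles
kinshipDescentOracle <- function(ped, i, j) {
  d <- ped@df
  founders <- d$id[is.na(d$father) & is.na(d$mother)]
  alleles <- unlist(lapply(founders, function(f) paste0(f, c(".a", ".b"))))
  avec <- function(id) {
    row <- d[d$id == id, ]
    if (is.na(row$father) && is.na(row$mother)) {
      v <- stats::setNames(rep(0, length(alleles)), alleles)
      v[paste0(id, c(".a", ".b"))] <- 0.5
      return(v)
    }
    fa <- if (is.na(row$father)) stats::setNames(rep(0, length(alleles)), alleles) else
      avec(row$father)
    mo <- if (is.na(row$mother)) stats::setNames(rep(0, length(alleles)), alleles) else
      avec(row$mother)
    # a missing parent contributes untraced (founder-external) alleles
    0.5 * fa + 0.5 * mo
  }
  sum(avec(i) * avec(j))
}

# small cohort fixture shared by several scan tests: 3 haplotypes on a path
tinyScanFixture <- function(status = c(1, 1, 0, 0, 0, NA, 1)) {
  hs <- collapseHaplotypes(list(
    s1 = character(0), s2 = character(0), s3 = "m.263A>G", s4 = "m.263A>G",
    s5 = c("m.263A>G", "m.750A>G"), s6 = c("m.263A>G", "m.750A>G"),
    s7 = "m.263A>G"))
  net <- buildNetwork(hs)
  subjects <- data.frame(
    subject_id = paste0("s", 1:7), status = status,
    haplotype = unname(hapAssignment(hs)[paste0("s", 1:7)]),
    stringsAsFactors = FALSE)
  list(haplotypes = hs, network = net, subjects = subjects,
       partitions = enumeratePartitions(net))
}

# 8-member pedigree with two founder couples, two sibships and a pair of
# first cousins (c1, c2)
cousinPedigree <- function() {
  Pedigree(data.frame(
    id = c("gf", "gm", "f1", "f2", "s1", "s2", "c1", "c2"),
    sex = c("M", "F", "F", "F", "M", "M", "M", "F"),
    father = c(NA, NA, "gf", "gf", NA, NA, "s1", "s2"),
    mother = c(NA, NA, "gm", "gm", NA, NA, "f1", "f2"),
    cohort = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    affected = c(NA, NA, TRUE, FALSE, NA, NA, FALSE, FALSE),
    stringsAsFactors = FALSE))
}
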