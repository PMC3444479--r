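#' @include pedigree.R
NULL

#' Simulation parameters
#'
#' Defaults reproduce the structure of the motivating study population: 1007
#' subjects in 274 matrilines, ~250 distinct haplotypes, ~900 segregating
#' sites, ages truncated at 65, 27% missing phenotypes, and a case rate of
#' ~13.8% among phenotyped subjects.  `beta` is the log-odds effect of
#' carrying the planted clade (`-Inf` = fully protective, no carrier is a
#' case); covariate effects are fixed, documented defaults.
#'
#' @slot H distinct haplotypes in the genealogy.
#' @slot theta scaled mutation parameter (Watterson: expected segregating
#'   sites = theta * sum_{i<H} 1/i on the unextended genealogy).
#' @slot tipExtra extra length added to every terminal branch (coalescent
#'   units), mimicking the excess of private variation left by recent
#'   population expansion; human mtDNA genealogies are strongly star-like,
#'   and a plain neutral coalescent cannot show ~250 distinct haplotypes
#'   with only ~900 segregating sites.
#' @slot nSubjects,nMatrilines cohort size and number of matrilines.
#' @slot maleFraction fraction of male subjects.
#' @slot ageMean,ageSd,ageMin age distribution (years), truncated below.
#' @slot apoe4Freq,apoe2Freq APOE allele frequencies (rest is e3).
#' @slot baselineCaseRate expected case fraction among phenotyped subjects.
#' @slot missingPhenotypeRate fraction of subjects with missing phenotype.
#' @slot effectClade `"none"`, `"auto"` (pick a genealogy clade with about
#'   `targetCarriers` phenotyped carriers) or a character vector of haplotype
#'   tip labels.
#' @slot targetCarriers target phenotyped carrier count for `"auto"`.
#' @slot beta planted clade log-odds effect (`-Inf` allowed).
#' @slot betaAge,betaMale,betaE4,betaE2 covariate log-odds effects (per year,
#'   male indicator, per e4 allele, per e2 allele).
#' @slot hetRate per-variant probability of an injected heteroplasmic
#'   secondary allele.
#' @slot refLength reference length in bases (16,569 = full mtDNA scale;
#'   2,000 is a convenient toy scale).
#' @slot seed RNG seed; regeneration from the same parameters and seed is
#'   bit-identical.
#' @export
setClass("SimParams",
  representation(H = "integer", theta = "numeric", tipExtra = "numeric",
                 nSubjects = "integer",
                 nMatrilines = "integer", maleFraction = "numeric",
                 ageMean = "numeric", ageSd = "numeric", ageMin = "numeric",
                 apoe4Freq = "numeric", apoe2Freq = "numeric",
                 baselineCaseRate = "numeric",
                 missingPhenotypeRate = "numeric", effectClade = "character",
                 targetCarriers = "integer", beta = "numeric",
                 betaAge = "numeric", betaMale = "numeric",
                 betaE4 = "numeric", betaE2 = "numeric",
                 hetRate = "numeric", refLength = "integer", seed = "integer"))

setValidity("SimParams", function(object) {
  rates <- c(object@maleFraction, object@apoe4Freq, object@apoe2Freq,
             object@baselineCaseRate, object@missingPhenotypeRate,
             object@hetRate)
  if (any(rates < 0 | rates > 1)) return("rates/fractions must be in [0,1]")
  if (object@nMatrilines > object@nSubjects)
    return("more matrilines than subjects")
  if (object@ageSd <= 0) return("ageSd must be positive")
  if (object@H < 1L || object@theta < 0) return("H >= 1 and theta >= 0 required")
  TRUE
})

#' Construct simulation parameters
#'
#' @param ... slot overrides; see [SimParams-class] for defaults.
#' @export
simParams <- function(...) {
  defaults <- list(
    H = 250L, theta = 75, tipExtra = 0.045, nSubjects = 1007L,
    nMatrilines = 274L,
    maleFraction = 442 / 1007, ageMean = 75.64, ageSd = 7.50, ageMin = 65,
    apoe4Freq = 0.15, apoe2Freq = 0.06, baselineCaseRate = 101 / 733,
    missingPhenotypeRate = 274 / 1007, effectClade = "none",
    targetCarriers = 38L, beta = 0, betaAge = 0.08, betaMale = -0.2,
    betaE4 = 1.2, betaE2 = -0.5, hetRate = 0.1, refLength = 16569L,
    seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  for (nm in c("H", "nSubjects", "nMatrilines", "targetCarriers",
               "refLength", "seed"))
    args[[nm]] <- as.integer(args[[nm]])
  do.call(methods::new, c(list(Class = "SimParams"), args))
}

#' @rdname simParams
#' @details `toyParams()` is a desk-scale preset (150 subjects, 30
#'   haplotypes, 2,000-bp toy reference) used throughout the unit tests.
#' @export
toyParams <- function(...) {
  simParams(H = 30L, theta = 12, tipExtra = 0.1, nSubjects = 150L,
            nMatrilines = 40L, refLength = 2000L, ...)
}

#' Simulate a haplotype genealogy with infinite-sites mutations
#'
#' Draws a random coalescent tree on `H` tips and sprinkles Poisson mutations
#' on its branches at rate `theta/2` per unit of coalescent branch length, so
#' the expected number of segregating sites is Watterson's
#' `theta * sum_{i=1}^{H-1} 1/i`.  Every mutation hits a distinct reference
#' position (infinite sites on the toy coordinate system); the root carries
#' the reference haplotype (empty variant set).
#'
#' @param H number of tips (haplotypes).
#' @param theta scaled mutation parameter.
#' @param reference [MtReference-class] supplying coordinates and alleles.
#' @param tipExtra extra terminal-branch length (coalescent units) modelling
#'   expansion-driven private variation; 0 gives the standard neutral
#'   coalescent and the Watterson expectation exactly.
#' @param seed optional seed (NULL = use current RNG state).
#' @return list with `tree` (ape phylo or NULL for H = 1), `variantSets`
#'   (named list tip label -> token vector), `nodeTips` (tip labels below
#'   each internal node) and `positions`.
#' @export
simulateHaplotypes <- function(H, theta, reference = syntheticToyReference(),
                               tipExtra = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- sprintf("hap%0*d", max(3L, nchar(H)), seq_len(H))
  if (H == 1L)
    return(list(tree = NULL,
                variantSets = stats::setNames(list(character(0)), labels),
                nodeTips = list(), positions = integer(0)))
  tree <- ape::rcoal(H, tip.label = labels)
  nEdge <- nrow(tree$edge)
  elen <- tree$edge.length + ifelse(tree$edge[, 2] <= H, tipExtra, 0)
  nmut <- stats::rpois(nEdge, theta / 2 * elen)
  S <- sum(nmut)
  if (S > length(reference))
    stop("more mutations than reference positions; increase refLength")
  positions <- sample.int(length(reference), S)
  refs <- refBase(reference, positions)
  alts <- vapply(refs, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  tokens <- sprintf("m.%d%s>%s", positions, refs, alts)
  edgeTok <- split(tokens, rep(seq_len(nEdge), nmut))

  root <- H + 1L
  kids <- split(seq_len(nEdge), tree$edge[, 1])
  nodeSet <- vector("list", H + tree$Nnode)
  nodeSet[[root]] <- character(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (e in kids[[as.character(v)]]) {
      w <- tree$edge[e, 2]
      nodeSet[[w]] <- c(nodeSet[[v]], edgeTok[[as.character(e)]])
      if (w > H) stack <- c(stack, w)
    }
  }
  variantSets <- lapply(nodeSet[seq_len(H)], sortTokens)
  names(variantSets) <- tree$tip.label

  nodeTips <- vector("list", tree$Nnode)
  tipsUnder <- function(v) {
    if (v <= H) return(tree$tip.label[v])
    out <- unlist(lapply(kids[[as.character(v)]],
                         function(e) tipsUnder(tree$edge[e, 2])))
    nodeTips[[v - H]] <<- out
    out
  }
  tipsUnder(root)
  # mutations on each internal node's stem edge: a clade is identifiable as a
  # haplotype-network clade only when its stem carries at least one mutation
  stemMut <- integer(tree$Nnode)
  for (e in seq_len(nEdge)) {
    w <- tree$edge[e, 2]
    if (w > H) stemMut[w - H] <- nmut[e]
  }
  list(tree = tree, variantSets = variantSets, nodeTips = nodeTips,
       stemMutations = stemMut, positions = positions)
}

#' Inject heteroplasmy into a variant table
#'
#' Each variant row independently gains a minor secondary allele with
#' probability `hetRate`: its alternate-allele fraction is drawn uniformly in
#' (0.5, 1), so majority-rule resolution always recovers the original call.
#'
#' @param tab variant table (columns subject_id, position, ref, alt).
#' @param hetRate probability per row.
#' @param seed optional seed.
#' @export
injectHeteroplasmy <- function(tab, hetRate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(hetRate >= 0, hetRate <= 1)
  tab$het_fraction <- 1
  if (nrow(tab) == 0L || hetRate == 0) return(tab)
  hit <- stats::rbinom(nrow(tab), 1L, hetRate) == 1L
  tab$het_fraction[hit] <- round(stats::runif(sum(hit), 0.501, 0.999), 4)
  tab
}

# TRUE when the tips' variant sets form a connected block (and leave a
# connected complement) in the union of minimum spanning trees, i.e. when
# some spanning-tree resolution of the haplotype network separates exactly
# this clade
.cladeIdentifiable <- function(variantSets, tips, mc = NULL) {
  keys <- vapply(variantSets, paste, "", collapse = ";")
  ukeys <- unique(keys)
  uidx <- match(keys, ukeys)
  usets <- variantSets[match(ukeys, keys)]
  inS <- seq_along(ukeys) %in% uidx[match(tips, names(variantSets))]
  if (is.null(mc)) mc <- .minimumConnections(usets)
  connectedWithin <- function(members) {
    if (sum(members) <= 1L) return(TRUE)
    parent <- seq_along(ukeys)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(mc$pairs))) {
      a <- mc$pairs[k, 1]; b <- mc$pairs[k, 2]
      if (members[a] && members[b]) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
    length(unique(vapply(which(members), find, 0L))) == 1L
  }
  connectedWithin(inS) && connectedWithin(!inS)
}

# deterministically adjust integer sizes (each >= 1) to sum to target
.fitSizes <- function(sizes, target) {
  while (sum(sizes) > target) {
    i <- which.max(sizes)
    sizes[i] <- sizes[i] - 1L
  }
  while (sum(sizes) < target) {
    i <- which.min(sizes)
    sizes[i] <- sizes[i] + 1L
  }
  sizes
}

#' Synthetic cohort
#'
#' Container for one simulated cohort: reference, per-subject variant table
#' (genotyped representatives only), matrilineal pedigree, subject
#' covariate/phenotype table, and the truth record (planted clade, effect
#' size, true haplotype of every subject) needed to score detection.
#'
#' @slot reference [MtReference-class].
#' @slot variantTable data.frame (subject_id, position, ref, alt,
#'   het_fraction).
#' @slot subjects data.frame with subject_id, matriline, haplotype_true,
#'   genotyped, age, sex (1 = male), apoe_e4, apoe_e2, status.
#' @slot pedigree [Pedigree-class].
#' @slot truth list: cladeTips, carrierIds, beta, seed.
#' @slot params the [SimParams-class] used.
#' @export
setClass("SyntheticCohort",
  representation(reference = "MtReference", variantTable = "data.frame",
                 subjects = "data.frame", pedigree = "Pedigree",
                 truth = "list", params = "SimParams"))

setMethod("show", "SyntheticCohort", function(object) {
  s <- object@subjects
  cat("SyntheticCohort:", nrow(s), "subjects in",
      length(unique(s$matriline)), "matrilines;",
      sum(s$genotyped), "genotyped;",
      sum(is.na(s$status)), "missing phenotypes;",
      sum(s$status %in% 1), "cases\n")
  if (length(object@truth$carrierIds))
    cat("  planted clade:", length(object@truth$cladeTips), "haplotypes,",
        length(object@truth$carrierIds), "carriers, beta =",
        object@truth$beta, "\n")
})

#' Simulate a full synthetic cohort
#'
#' Draws a coalescent haplotype genealogy, assigns one haplotype per
#' matriline (every haplotype seeds at least one matriline when there are
#' more matrilines than haplotypes; extra matrilines reuse haplotypes
#' frequency-weighted), builds matrilineal pedigrees with sibling clusters
#' (3 generations: maternal founder, sibship mothers, cohort subjects),
#' genotypes one random representative per matriline, draws covariates and a
#' logistic phenotype with the intercept calibrated to the requested baseline
#' case rate, applies the planted clade effect and phenotype missingness, and
#' injects heteroplasmy into the emitted variant table.
#'
#' @param params a [SimParams-class].
#' @return a [SyntheticCohort-class].
#' @export
simulateCohort <- function(params = simParams()) {
  methods::validObject(params)
  set.seed(params@seed)
  n <- params@nSubjects
  M <- params@nMatrilines
  H <- params@H
  reference <- if (params@refLength == 16569L) syntheticRCRS() else
    syntheticToyReference(params@refLength)
  sim <- simulateHaplotypes(H, params@theta, reference,
                            tipExtra = params@tipExtra)
  hapLabels <- names(sim$variantSets)

  w <- stats::rexp(H)
  hapOfMat <- if (M >= H)
    c(seq_len(H), sample.int(H, M - H, replace = TRUE, prob = w)) else
    sample.int(H, M, prob = w)

  sizes <- .fitSizes(stats::rgeom(M, prob = min(0.9, M / n)) + 1L, n)

  # sibship breakdown per matriline (truncated-geometric cluster sizes),
  # then a 3-generation matrilineal pedigree built column-wise: founder ->
  # sibship mothers (founder's daughters) -> cohort subjects
  sibList <- vector("list", M)
  for (k in seq_len(M)) {
    left <- sizes[k]; ss <- integer(0)
    while (left > 0L) {
      d <- min(left, stats::rgeom(1L, 0.6) + 1L)
      ss <- c(ss, d); left <- left - d
    }
    sibList[[k]] <- ss
  }
  matK <- rep(seq_len(M), lengths(sibList))
  sibI <- unlist(lapply(sibList, seq_along), use.names = FALSE)
  sibSz <- unlist(sibList, use.names = FALSE)
  fids <- sprintf("M%03dF", seq_len(M))
  mids <- sprintf("M%03dA%d", matK, sibI)
  dids <- sprintf("M%03dB%d", matK, sibI)
  subjK <- rep(seq_along(mids), sibSz)
  sids <- sprintf("S%04d", seq_along(subjK))
  # sex and phenotype-missingness margins are fixed at their expected counts
  # (assignment random), reproducing the cohort margins exactly
  male <- integer(length(sids))
  male[sample.int(length(sids), round(length(sids) * params@maleFraction))] <- 1L
  pedDf <- data.frame(
    id = c(fids, mids, dids, sids),
    sex = c(rep("F", M), rep("F", length(mids)), rep("M", length(dids)),
            ifelse(male == 1L, "M", "F")),
    father = c(rep(NA_character_, M + 2L * length(mids)), dids[subjK]),
    mother = c(rep(NA_character_, M), fids[matK],
               rep(NA_character_, length(dids)), mids[subjK]),
    cohort = c(rep(FALSE, M + 2L * length(mids)), rep(TRUE, length(sids))),
    affected = NA, stringsAsFactors = FALSE)
  subjects <- data.frame(
    subject_id = sids, matriline = fids[matK[subjK]],
    haplotype_true = hapLabels[hapOfMat[matK[subjK]]], sex = male,
    stringsAsFactors = FALSE)

  ns <- nrow(subjects)
  lo <- stats::pnorm((params@ageMin - params@ageMean) / params@ageSd)
  subjects$age <- params@ageMean + params@ageSd *
    stats::qnorm(stats::runif(ns, lo, 1))
  alleleDraw <- function() {
    u <- stats::runif(ns)
    ifelse(u < params@apoe4Freq, "e4",
           ifelse(u < params@apoe4Freq + params@apoe2Freq, "e2", "e3"))
  }
  a1 <- alleleDraw(); a2 <- alleleDraw()
  subjects$apoe_e4 <- (a1 == "e4") + (a2 == "e4")
  subjects$apoe_e2 <- (a1 == "e2") + (a2 == "e2")
  missing <- logical(ns)
  missing[sample.int(ns, round(ns * params@missingPhenotypeRate))] <- TRUE

  cladeTips <- character(0)
  if (identical(params@effectClade, "auto")) {
    # only clades whose stem edge mutated, and which survive as a connected
    # clade of the minimum-length haplotype network (a clade can fragment
    # when a tip's private mutations outnumber the stem path), are
    # recoverable as branch partitions
    cand <- sim$nodeTips[sim$stemMutations > 0L]
    cand <- Filter(function(tips)
      length(tips) < H && sum(subjects$haplotype_true %in% tips) <= ns / 2,
      cand)
    kAll <- vapply(sim$variantSets, paste, "", collapse = ";")
    mcAll <- .minimumConnections(sim$variantSets[match(unique(kAll), kAll)])
    cand <- Filter(function(tips)
      .cladeIdentifiable(sim$variantSets, tips, mc = mcAll), cand)
    if (!length(cand)) stop("no usable clade in the genealogy")
    score <- vapply(cand, function(tips)
      sum(subjects$haplotype_true %in% tips & !missing), 0L)
    tot <- vapply(cand, function(tips)
      sum(subjects$haplotype_true %in% tips), 0L)
    best <- order(abs(score - params@targetCarriers), tot)[1]
    cladeTips <- cand[[best]]
  } else if (!identical(params@effectClade, "none")) {
    cladeTips <- params@effectClade
    stopifnot(all(cladeTips %in% hapLabels))
    if (sum(subjects$haplotype_true %in% cladeTips) > ns)
      stop("clade larger than cohort")
  }
  carrier <- subjects$haplotype_true %in% cladeTips

  lp0 <- params@betaAge * (subjects$age - params@ageMean) +
    params@betaMale * subjects$sex + params@betaE4 * subjects$apoe_e4 +
    params@betaE2 * subjects$apoe_e2
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp0)) -
                         params@baselineCaseRate, c(-25, 25))$root
  pr <- stats::plogis(b0 + lp0 +
                        ifelse(carrier & is.finite(params@beta), params@beta, 0))
  if (is.infinite(params@beta) && params@beta < 0) pr[carrier] <- 0
  y <- stats::rbinom(ns, 1L, pr)
  subjects$status <- ifelse(missing, NA_integer_, y)
  pedDf$affected[match(subjects$subject_id, pedDf$id)] <-
    ifelse(missing, NA, y == 1L)

  genotyped <- unlist(lapply(split(seq_len(ns), subjects$matriline),
                             function(ix) ix[sample.int(length(ix), 1L)]))
  subjects$genotyped <- seq_len(ns) %in% genotyped

  gidx <- which(subjects$genotyped)
  toksBy <- sim$variantSets[subjects$haplotype_true[gidx]]
  allTok <- unlist(toksBy, use.names = FALSE)
  if (length(allTok)) {
    # simulator emits SNV tokens only: vectorized decode
    variantTable <- data.frame(
      subject_id = rep(subjects$subject_id[gidx],
                       vapply(toksBy, length, 0L)),
      position = as.integer(sub("^m\\.([0-9]+).*$", "\\1", allTok)),
      ref = sub("^m\\.[0-9]+([ACGT])>.*$", "\\1", allTok),
      alt = sub("^.*>([ACGT])$", "\\1", allTok),
      stringsAsFactors = FALSE)
  } else {
    variantTable <- data.frame(subject_id = character(0),
                               position = integer(0),
                               ref = character(0), alt = character(0))
  }
  variantTable <- variantTable[order(variantTable$subject_id,
                                     variantTable$position), ]
  rownames(variantTable) <- NULL
  variantTable <- injectHeteroplasmy(variantTable, params@hetRate)

  truth <- list(cladeTips = cladeTips,
                carrierIds = subjects$subject_id[carrier],
                beta = params@beta, seed = params@seed)
  methods::new("SyntheticCohort", reference = reference,
               variantTable = variantTable, subjects = subjects,
               pedigree = Pedigree(pedDf), truth = truth, params = params)
}

#' Write a synthetic cohort to the pipeline's input formats
#'
#' Emits variants.tsv, pedigree.ped, flags.tsv, covariates.tsv and
#' truth.json into `dir`.  Output is byte-deterministic for a fixed
#' parameter set and seed.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(variants = file.path(dir, "variants.tsv"),
             pedigree = file.path(dir, "pedigree.ped"),
             flags = file.path(dir, "flags.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             truth = file.path(dir, "truth.json"))
  utils::write.table(cohort@variantTable, paths["variants"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writePedigree(cohort@pedigree, paths["pedigree"], paths["flags"])
  cov <- cohort@subjects[, c("subject_id", "status", "age", "sex",
                             "apoe_e4", "apoe_e2", "genotyped")]
  cov$age <- round(cov$age, 4)
  cov$genotyped <- as.integer(cov$genotyped)
  utils::write.table(cov, paths["covariates"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(cohort@truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
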