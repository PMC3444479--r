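#' @include partitions.R
NULL

#' Scan configuration
#'
#' @slot B number of permutations (ignored when `exhaustive`).
#' @slot alpha corrected significance threshold.
#' @slot minClassSize minimum subjects (with non-missing phenotype) required
#'   in *each* genotypic class for a branch to be tested.
#' @slot seed RNG seed for the permutation draw.
#' @slot covariates names of covariate columns in the subject table.
#' @slot flavor `"firth_lrt"` (penalized likelihood-ratio statistic, finite
#'   under complete separation) or `"lrt"` (ordinary logistic LRT).
#' @slot exhaustive enumerate all assignment permutations instead of sampling
#'   (only feasible for very small cohorts; p-values are then exact).
#' @export
setClass("ScanConfig",
  representation(B = "integer", alpha = "numeric", minClassSize = "integer",
                 seed = "integer", covariates = "character",
                 flavor = "character", exhaustive = "logical"))

setValidity("ScanConfig", function(object) {
  if (object@B < 1L) return("B must be >= 1")
  if (object@minClassSize < 1L) return("minClassSize must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
  if (!object@flavor %in% c("firth_lrt", "lrt")) return("unknown flavor")
  TRUE
})

#' Construct a scan configuration
#'
#' Defaults follow the analysis conventions of the method: 10,000
#' permutations, corrected-significance threshold 0.05, at least five
#' phenotyped subjects in each genotypic class, Firth-penalized
#' likelihood-ratio statistic.
#'
#' @param B,alpha,minClassSize,seed,covariates,flavor,exhaustive see
#'   [ScanConfig-class].
#' @export
scanConfig <- function(B = 10000L, alpha = 0.05, minClassSize = 5L, seed = 1L,
                       covariates = c("age", "sex", "apoe_e4", "apoe_e2"),
                       flavor = c("firth_lrt", "lrt"), exhaustive = FALSE) {
  methods::new("ScanConfig", B = as.integer(B), alpha = alpha,
               minClassSize = as.integer(minClassSize), seed = as.integer(seed),
               covariates = covariates, flavor = match.arg(flavor),
               exhaustive = exhaustive)
}

setMethod("show", "ScanConfig", function(object) {
  cat("ScanConfig: B =", object@B, if (object@exhaustive) "(exhaustive)" else "",
      " alpha =", object@alpha, " minClassSize =", object@minClassSize,
      " flavor =", object@flavor, "\n  covariates:",
      paste(object@covariates, collapse = ", "), "\n")
})

#' Haploid branch genotypes for a partition
#'
#' Being haploid, a branch defines only two genotypes: allele 0 for
#' haplotypes on side A, allele 1 for side B.  Subjects without a haplotype
#' assignment, or assigned to a haplotype outside the partition's component,
#' get a missing genotype.
#'
#' @param partition a [BranchPartition-class].
#' @param assignment named character vector, subject id -> haplotype id.
#' @return named numeric vector of 0/1/NA per subject.
#' @export
branchGenotypes <- function(partition, assignment) {
  g <- rep(NA_real_, length(assignment))
  names(g) <- names(assignment)
  g[assignment %in% partition@sideA] <- 0
  g[assignment %in% partition@sideB] <- 1
  g
}

#' Branch eligibility filter
#'
#' A branch is tested only when both genotypic classes contain at least
#' `minClassSize` subjects with a non-missing phenotype.
#'
#' @param genotypes 0/1/NA vector.
#' @param phenotypes 0/1/NA vector aligned with `genotypes`.
#' @param minClassSize integer.
#' @export
isEligible <- function(genotypes, phenotypes, minClassSize = 5L) {
  ok <- !is.na(genotypes) & !is.na(phenotypes)
  sum(ok & genotypes == 0) >= minClassSize &&
    sum(ok & genotypes == 1) >= minClassSize
}

#' Likelihood-ratio statistic for one branch
#'
#' Tests the branch-allele term in a logistic model of case status on allele
#' plus covariates.  With `flavor = "firth_lrt"` the Jeffreys-penalized
#' likelihood is used, so the statistic stays finite under complete
#' separation (e.g. a clade containing no cases).  Rows with missing
#' genotype, phenotype or covariates are dropped listwise.
#'
#' @param genotype 0/1/NA vector.
#' @param phenotype 0/1/NA vector.
#' @param covariates numeric matrix/data.frame (or NULL).
#' @param flavor `"firth_lrt"` or `"lrt"`.
#' @return list with `statistic`, `p` (asymptotic chi-square, 1 df; the scan
#'   itself uses permutation, not this p), and `coef` (allele log-odds).
#' @export
branchStatistic <- function(genotype, phenotype, covariates = NULL,
                            flavor = c("firth_lrt", "lrt")) {
  flavor <- match.arg(flavor)
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  keep <- !is.na(genotype) & !is.na(phenotype)
  if (!is.null(X)) keep <- keep & stats::complete.cases(X)
  g <- genotype[keep]; y <- phenotype[keep]
  if (length(unique(g)) < 2L) stop("zero-variance genotype after listwise deletion")
  Xc <- cbind(`(Intercept)` = rep(1, length(y)),
              if (is.null(X)) NULL else X[keep, , drop = FALSE])
  fit <- cppBranchScan(Xc, y, matrix(g, ncol = 1), flavor == "firth_lrt")
  stat <- fit$stat[1]
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
       coef = fit$coef[1])
}

# all permutations of 1..n (n <= 9), one per row
.allPerms <- function(n) {
  stopifnot(n <= 9L)
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .allPerms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L), drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Scan result
#'
#' One row per branch partition: nominal and step-down-corrected permutation
#' p-values, the allele effect direction, per-side case/control counts, the
#' defining variants, and the scan round (1 = unconditional).
#'
#' @slot table data.frame of per-branch results.
#' @slot config the [ScanConfig-class] used.
#' @slot round scan round.
#' @slot conditionedOn branch ids whose alleles entered as covariates.
#' @export
setClass("TreeScanResult",
  representation(table = "data.frame", config = "ScanConfig",
                 round = "integer", conditionedOn = "character"))

#' @rdname TreeScanResult-class
#' @export
setMethod("scanTable", "TreeScanResult", function(x) x@table)

#' @rdname TreeScanResult-class
#' @export
setMethod("significantBranches", "TreeScanResult", function(x) {
  tb <- x@table
  tb$branch[!is.na(tb$correctedP) & tb$correctedP < x@config@alpha]
})

setMethod("show", "TreeScanResult", function(object) {
  tb <- object@table
  cat("TreeScanResult (round ", object@round, "): ", nrow(tb), " branches, ",
      sum(tb$tested), " tested, ", length(significantBranches(object)),
      " significant at alpha = ", object@config@alpha, "\n", sep = "")
  if (length(object@conditionedOn))
    cat("  conditioned on:", paste(object@conditionedOn, collapse = ", "), "\n")
  sig <- tb[!is.na(tb$correctedP) & tb$correctedP < object@config@alpha, ]
  if (nrow(sig)) {
    sig <- sig[order(sig$correctedP), ]
    for (i in seq_len(min(5L, nrow(sig))))
      cat(sprintf("  %s  nominal %.2e  corrected %.3g  (%s)\n",
                  sig$branch[i], sig$nominalP[i], sig$correctedP[i],
                  sig$definingVariants[i]))
  }
})

#' Branch-partition permutation scan
#'
#' Tests every eligible branch partition of the haplotype network against
#' case-control status, with covariates, and corrects across the correlated
#' branch family by step-down minP permutation.  The permutation unit is the
#' subject-to-haplotype assignment: each permutation shuffles which subject
#' carries which haplotype (phenotypes and covariates stay attached to
#' subjects) and recomputes all branch statistics, preserving the
#' correlation among branches.  Nominal p-values use the add-one convention
#' (b+1)/(B+1); in exhaustive mode (all assignment permutations enumerated,
#' identity included) p-values are exact counts b/B.
#'
#' @param network a [HaplotypeNetwork-class].
#' @param subjects data.frame with columns `subject_id`, `status` (1 = case,
#'   0 = control, NA = missing phenotype), `haplotype` (id or NA) and the
#'   covariate columns named in the config.
#' @param config a [ScanConfig-class].
#' @param partitions optional pre-enumerated partition list.
#' @param conditionOn optional named list of per-subject 0/1 allele vectors
#'   (from earlier significant branches) entered as fixed covariates;
#'   branches collinear with any of them are reported degenerate and skipped.
#' @param round scan round recorded in the result.
#' @return a [TreeScanResult-class].
#' @export
permutationScan <- function(network, subjects, config = scanConfig(),
                            partitions = NULL, conditionOn = NULL,
                            round = 1L) {
  if (is.null(partitions)) partitions <- enumeratePartitions(network)
  if (!length(partitions)) stop("network induces no partitions")
  stopifnot(all(c("subject_id", "status", "haplotype") %in% names(subjects)))
  covNames <- config@covariates
  miss <- setdiff(covNames, names(subjects))
  if (length(miss)) stop("missing covariate columns: ", paste(miss, collapse = ", "))

  asg <- subjects$haplotype
  bad <- !is.na(asg) & !(asg %in% names(network@nodeVariants))
  if (any(bad)) stop("haplotype id absent from network: ",
                     paste(unique(asg[bad]), collapse = ", "))
  assigned <- which(!is.na(asg))
  nA <- length(assigned)
  if (nA < 2L) stop("fewer than two subjects with haplotype assignments")

  m <- length(partitions)
  baseG <- matrix(NA_real_, nA, m)
  for (j in seq_len(m)) {
    a <- asg[assigned]
    baseG[a %in% partitions[[j]]@sideA, j] <- 0
    baseG[a %in% partitions[[j]]@sideB, j] <- 1
  }

  covM <- as.matrix(subjects[assigned, covNames, drop = FALSE])
  storage.mode(covM) <- "double"
  y <- subjects$status[assigned]
  covOk <- if (ncol(covM)) stats::complete.cases(covM) else
    rep(TRUE, length(assigned))
  testedIdx <- which(!is.na(y) & covOk)
  if (length(testedIdx) < 2L * config@minClassSize)
    stop("too few phenotyped subjects")

  Gt <- baseG[testedIdx, , drop = FALSE]
  yt <- y[testedIdx]
  condM <- NULL
  if (!is.null(conditionOn)) {
    condM <- vapply(conditionOn, function(v) {
      stopifnot(!is.null(names(v)))
      unname(v[subjects$subject_id[assigned][testedIdx]])
    }, numeric(length(testedIdx)))
    if (any(is.na(condM))) stop("conditioning allele missing for tested subjects")
    if (any(apply(condM, 2, function(v) length(unique(v)) < 2L)))
      stop("conditioning allele constant after listwise deletion")
  }
  Xbase <- covM[testedIdx, , drop = FALSE]
  if (ncol(Xbase)) {
    # a constant covariate (e.g. a missing-indicator with no missing
    # subjects) would make the design singular; drop it
    const <- apply(Xbase, 2, function(v) max(v) - min(v) < 1e-12)
    if (any(const)) {
      message("dropping constant covariate(s): ",
              paste(colnames(Xbase)[const], collapse = ", "))
      Xbase <- Xbase[, !const, drop = FALSE]
    }
  }
  Xcov <- cbind(`(Intercept)` = rep(1, length(testedIdx)), Xbase, condM)

  eligible <- vapply(seq_len(m), function(j)
    isEligible(Gt[, j], yt, config@minClassSize), TRUE)
  degenerate <- rep(FALSE, m)
  if (!is.null(condM)) {
    for (j in which(eligible)) {
      gj <- Gt[, j]
      if (anyNA(gj)) next
      for (k in seq_len(ncol(condM)))
        if (all(gj == condM[, k]) || all(gj == 1 - condM[, k]))
          degenerate[j] <- TRUE
    }
  }
  family <- which(eligible & !degenerate)
  if (!length(family)) stop("no eligible branches")

  firth <- config@flavor == "firth_lrt"
  obs <- cppBranchScan(Xcov, yt, Gt[, family, drop = FALSE], firth)
  fitFail <- is.na(obs$stat)
  if (any(fitFail))
    message(sum(fitFail), " branch(es) dropped for non-convergent fits")
  family <- family[!fitFail]
  obsStat <- obs$stat[!fitFail]
  obsCoef <- obs$coef[!fitFail]
  warmB <- obs$beta[, !fitFail, drop = FALSE]
  if (!length(family)) stop("no eligible branches after fitting")

  set.seed(config@seed)
  if (config@exhaustive) {
    if (nA > 9L) stop("exhaustive enumeration limited to 9 assigned subjects")
    P <- .allPerms(nA)
  } else {
    P <- t(vapply(seq_len(config@B), function(b) sample.int(nA),
                  integer(nA)))
  }
  perms <- P[, testedIdx, drop = FALSE]
  # warm starts: converged covariate coefficients, allele coefficient 0
  # (the right prior under the permutation null)
  warmB[nrow(warmB), ] <- 0
  statMat <- cppPermScan(Xcov, yt, baseG[, family, drop = FALSE],
                         perms, firth, warmB, obs$ll0)
  statMat[is.na(statMat)] <- -Inf
  eps <- 1e-7

  # In sampling mode the observed data joins the null set as one extra row
  # (the add-one convention); exhaustive enumeration already contains the
  # identity assignment.  All p-values then live on one scale, 1/N .. 1.
  S <- if (config@exhaustive) statMat else rbind(statMat, obsStat)
  N <- nrow(S)
  bcount <- vapply(seq_along(family), function(j)
    sum(S[, j] >= obsStat[j] - eps), 0L)
  nominalP <- bcount / N

  # per-permutation null p-values (shared permutation distribution)
  pmat <- apply(S, 2, function(s) (N - rank(s, ties.method = "min") + 1) / N)
  ordIdx <- order(nominalP, -obsStat,
                  vapply(partitions[family], function(p) p@branch, ""))
  runmin <- rep(1, N)
  cnt <- numeric(length(family))
  for (i in rev(seq_along(ordIdx))) {
    runmin <- pmin(runmin, pmat[, ordIdx[i]])
    cnt[i] <- sum(runmin <= nominalP[ordIdx[i]] + 1e-12)
  }
  corrected <- cummax(cnt / N)
  correctedP <- rep(NA_real_, length(family))
  correctedP[ordIdx] <- corrected

  tab <- partitionTable(partitions)
  tab$round <- as.integer(round)
  tab$eligible <- eligible
  tab$degenerate <- degenerate
  tab$tested <- seq_len(m) %in% family
  tab$statistic <- NA_real_
  tab$alleleCoef <- NA_real_
  tab$direction <- NA_character_
  tab$nominalP <- NA_real_
  tab$correctedP <- NA_real_
  tab$statistic[family] <- obsStat
  tab$alleleCoef[family] <- obsCoef
  tab$direction[family] <- ifelse(obsCoef < 0, "protective", "risk")
  tab$nominalP[family] <- nominalP
  tab$correctedP[family] <- correctedP
  cls <- function(j, side, st) {
    gj <- Gt[, j]; sum(!is.na(gj) & gj == side & !is.na(yt) & yt == st)
  }
  tab$nCaseA <- vapply(seq_len(m), cls, 0L, side = 0, st = 1)
  tab$nControlA <- vapply(seq_len(m), cls, 0L, side = 0, st = 0)
  tab$nCaseB <- vapply(seq_len(m), cls, 0L, side = 1, st = 1)
  tab$nControlB <- vapply(seq_len(m), cls, 0L, side = 1, st = 0)

  methods::new("TreeScanResult", table = tab, config = config,
               round = as.integer(round),
               conditionedOn = if (is.null(conditionOn)) character(0) else
                 names(conditionOn))
}

#' Conditional second-round scans
#'
#' Re-runs the permutation scan with the allele of the most significant
#' branch from the previous round added as a fixed covariate, to decide
#' whether other significant branches represent the same or different
#' effects.  Rounds repeat, accumulating conditioning alleles, until no new
#' branch is significant (or `maxRounds` is hit).  Branches whose genotype is
#' collinear with a conditioning allele are reported degenerate and skipped.
#'
#' @param prior the round-1 [TreeScanResult-class] (must contain a
#'   significant branch).
#' @param network,subjects,config,partitions as in [permutationScan()].
#' @param maxRounds cap on the number of conditional rounds.
#' @return list of [TreeScanResult-class], one per conditional round.
#' @export
conditionalScan <- function(prior, network, subjects, config = prior@config,
                            partitions = NULL, maxRounds = 5L) {
  if (is.null(partitions)) partitions <- enumeratePartitions(network)
  sig <- significantBranches(prior)
  if (!length(sig)) stop("no significant branch to condition on")
  byBranch <- stats::setNames(partitions,
                              vapply(partitions, function(p) p@branch, ""))
  topOf <- function(res, exclude) {
    tb <- scanTable(res)
    tb <- tb[!is.na(tb$correctedP) & tb$correctedP < res@config@alpha &
               !(tb$branch %in% exclude), ]
    if (!nrow(tb)) return(NULL)
    tb$branch[order(tb$correctedP, tb$nominalP, tb$branch)][1]
  }
  asgV <- stats::setNames(subjects$haplotype, subjects$subject_id)
  condVecs <- list()
  results <- list()
  current <- prior
  for (r in seq(2L, by = 1L, length.out = maxRounds - 1L)) {
    newTop <- topOf(current, names(condVecs))
    if (is.null(newTop)) break
    condVecs[[newTop]] <- branchGenotypes(byBranch[[newTop]], asgV)
    res <- permutationScan(network, subjects, config, partitions = partitions,
                           conditionOn = condVecs, round = r)
    results[[length(results) + 1L]] <- res
    current <- res
  }
  results
}
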