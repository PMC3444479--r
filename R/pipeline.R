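#' @include simulate.R
NULL

# refresh carrier counts (and assignment) after imputation
.withAssignment <- function(hapset, assignment) {
  tab <- table(factor(assignment[!is.na(assignment)], levels = hapIds(hapset)))
  methods::new("HaplotypeSet", variants = hapset@variants,
               carrierCount = stats::setNames(as.integer(tab), hapIds(hapset)),
               observed = hapset@observed, assignment = assignment)
}

#' Prepare scan inputs from raw tables
#'
#' Runs the data-preparation stages shared by every analysis: majority-rule
#' heteroplasmy resolution, optional exclusion of user-specified position
#' windows (e.g. poly-C tracts) from haplotype definition, collapse into
#' haplotypes, matrilineal imputation of haplotypes to ungenotyped pedigree
#' members, familial-risk scoring, and network construction.
#'
#' @param variantTable per-subject variant table (see [readVariantTable()]).
#' @param pedigree a [Pedigree-class] covering the cohort subjects.
#' @param covariates data.frame with subject_id, status and covariate
#'   columns.
#' @param reference an [MtReference-class].
#' @param conflict imputation conflict policy, see [imputeHaplotypes()].
#' @param excludeWindows optional data.frame (start, end) of reference
#'   windows excluded from haplotype definition; default excludes nothing.
#' @param maxSteps network connection cap, see [buildNetwork()].
#' @param genotypedIds subject ids that were sequenced; defaults to the
#'   subjects appearing in the variant table, but must be given explicitly
#'   when a sequenced subject carries the reference haplotype (and so has no
#'   variant rows).
#' @param famrisk compute the familial-risk covariate (requires the full
#'   kinship matrix; can be switched off for scans that do not use it).
#' @return list with haplotypes ([HaplotypeSet-class], assignment includes
#'   imputed subjects), network, subjects (scan-ready table with haplotype
#'   and famrisk columns), imputation record and famrisk table.
#' @export
prepareScan <- function(variantTable, pedigree, covariates, reference,
                        conflict = "leave_missing", excludeWindows = NULL,
                        maxSteps = Inf, genotypedIds = NULL, famrisk = TRUE) {
  stopifnot(all(c("subject_id", "status") %in% names(covariates)))
  tab <- applyMajorityRule(variantTable)
  if (!is.null(excludeWindows)) {
    for (i in seq_len(nrow(excludeWindows)))
      tab <- tab[!(tab$position >= excludeWindows$start[i] &
                   tab$position <= excludeWindows$end[i]), , drop = FALSE]
  }
  sets <- subjectVariantSets(tab, reference)
  genotyped <- union(unique(variantTable$subject_id), genotypedIds)
  # genotyped subjects whose resolved variant set is empty carry the reference
  sets <- c(sets, stats::setNames(
    rep(list(character(0)), sum(!genotyped %in% names(sets))),
    genotyped[!genotyped %in% names(sets)]))
  haps <- collapseHaplotypes(sets)

  ids <- covariates$subject_id
  assignment <- stats::setNames(rep(NA_character_, length(ids)), ids)
  known <- intersect(names(sets), ids)
  assignment[known] <- hapAssignment(haps)[known]
  imp <- imputeHaplotypes(assignment, pedigree, conflict = conflict)
  haps <- .withAssignment(haps, imp$assignment)

  network <- buildNetwork(haps, maxSteps = maxSteps)
  subjects <- covariates
  subjects$haplotype <- unname(imp$assignment[ids])
  fr <- NULL
  if (famrisk) {
    fr <- familialRisk(pedigree, ids = ids)
    subjects$famrisk <- fr$score[match(ids, fr$id)]
    subjects$famrisk_missing <- as.numeric(fr$degenerate[match(ids, fr$id)])
  }
  list(haplotypes = haps, network = network, subjects = subjects,
       imputation = imp, famrisk = fr)
}

#' Demographic report row for a clade
#'
#' Tabulates the carriers of a branch's derived side (side B): carrier
#' count, mean age (sd), male/female split and case/control/missing counts,
#' in the same shape as the cohort-level demographics table.
#'
#' @param partition a [BranchPartition-class] (or NULL for the whole cohort).
#' @param subjects scan subject table (needs haplotype, age, sex, status).
#' @return one-row data.frame with numeric columns and formatted strings.
#' @export
reportClade <- function(partition, subjects) {
  carriers <- if (is.null(partition)) subjects else
    subjects[!is.na(subjects$haplotype) &
               subjects$haplotype %in% partition@sideB, , drop = FALSE]
  n <- nrow(carriers)
  ageMean <- if (n) mean(carriers$age) else 0
  ageSd <- if (n > 1L) stats::sd(carriers$age) else 0
  male <- sum(carriers$sex == 1)
  cases <- sum(carriers$status %in% 1)
  controls <- sum(carriers$status %in% 0)
  missing <- sum(is.na(carriers$status))
  data.frame(
    clade = if (is.null(partition)) "total" else partition@branch,
    n = n, ageMean = round(ageMean, 2), ageSd = round(ageSd, 2),
    male = male, female = n - male,
    cases = cases, controls = controls, missing = missing,
    age_fmt = sprintf("%.2f (%.2f)", ageMean, ageSd),
    sex_fmt = sprintf("%d/%d", male, n - male),
    ccm_fmt = sprintf("%d/%d/%d", cases, controls, missing),
    stringsAsFactors = FALSE)
}

.resolveReference <- function(spec) {
  if (methods::is(spec, "MtReference")) return(spec)
  if (is.null(spec) || identical(spec, "synthetic-rcrs")) return(syntheticRCRS())
  if (grepl("^toy:", spec))
    return(syntheticToyReference(as.integer(sub("^toy:", "", spec))))
  readReference(spec)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> heteroplasmy resolution -> haplotype
#' collapse -> matrilineal imputation -> familial risk -> network -> branch
#' permutation scan (with and, optionally, without the familial-risk
#' covariate) -> conditional rounds -> reports.  Writes scan_results.tsv,
#' network.graphml, network_edges.tsv, famrisk.tsv, clade_demographics.tsv,
#' manifest.json and run.log into the output directory; all outputs are
#' byte-deterministic for a fixed config and seed.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Top-level blocks: `simulate` (simParams overrides) *or* `inputs`
#'   (variants, pedigree, flags, covariates, reference), plus `scan`
#'   (B, alpha, min_class_size, flavor, covariates, familial_risk,
#'   conditional, max_steps) and `output` (dir).
#' @param outDir output directory (overrides the config).
#' @param seed overrides both simulation and scan seeds.
#' @return invisibly, a list with the prepared inputs, scan results and
#'   output paths.
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outDir <- outDir %||% config$output$dir
  if (is.null(outDir)) stop("no output directory given")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))

  inputDigests <- list()
  if (!is.null(config$simulate)) {
    params <- do.call(simParams, config$simulate)
    if (!is.null(seed)) params@seed <- as.integer(seed)
    cohort <- simulateCohort(params)
    inDir <- file.path(outDir, "inputs")
    paths <- writeCohort(cohort, inDir)
    inputDigests <- as.list(stats::setNames(unname(tools::md5sum(unname(paths))),
                                            basename(unname(paths))))
    variantTable <- cohort@variantTable
    pedigree <- cohort@pedigree
    covariates <- cohort@subjects[, c("subject_id", "status", "age", "sex",
                                      "apoe_e4", "apoe_e2", "genotyped")]
    reference <- cohort@reference
    say("simulated cohort: ", nrow(cohort@subjects), " subjects, seed ",
        params@seed)
  } else {
    inp <- config$inputs
    if (is.null(inp$variants) || is.null(inp$covariates) ||
        is.null(inp$pedigree))
      stop("config must name variants, pedigree and covariates inputs ",
           "(or a simulate block)")
    variantTable <- readVariantTable(inp$variants)
    pedigree <- readPedigree(inp$pedigree, inp$flags)
    covariates <- utils::read.delim(inp$covariates, stringsAsFactors = FALSE,
                                    colClasses = c(subject_id = "character"))
    if (!all(c("subject_id", "status") %in% names(covariates)))
      stop("covariate table needs subject_id and status columns")
    reference <- .resolveReference(inp$reference)
    real <- unlist(inp[c("variants", "pedigree", "flags", "covariates")])
    inputDigests <- as.list(stats::setNames(unname(tools::md5sum(unname(real))),
                                            basename(unname(real))))
  }

  sc <- config$scan %||% list()
  excl <- if (!is.null(sc$exclude_windows))
    do.call(rbind, lapply(sc$exclude_windows, as.data.frame)) else NULL
  gids <- if ("genotyped" %in% names(covariates))
    covariates$subject_id[covariates$genotyped %in% c(1, TRUE)] else NULL
  prep <- prepareScan(variantTable, pedigree, covariates, reference,
                      conflict = sc$conflict %||% "leave_missing",
                      excludeWindows = excl,
                      maxSteps = sc$max_steps %||% Inf, genotypedIds = gids)
  say("haplotypes: ", length(prep$haplotypes), " observed; subjects assigned: ",
      sum(!is.na(prep$subjects$haplotype)), " (",
      sum(prep$imputation$imputed), " imputed)")
  say("network: ", igraph::vcount(networkGraph(prep$network)), " nodes, ",
      igraph::ecount(networkGraph(prep$network)), " edges, ",
      loopCount(prep$network), " loop(s)")

  baseCovs <- sc$covariates %||% c("age", "sex", "apoe_e4", "apoe_e2")
  cfg <- scanConfig(B = sc$B %||% 10000L, alpha = sc$alpha %||% 0.05,
                    minClassSize = sc$min_class_size %||% 5L,
                    seed = if (!is.null(seed)) seed else sc$seed %||% 1L,
                    covariates = baseCovs,
                    flavor = sc$flavor %||% "firth_lrt")
  partitions <- enumeratePartitions(prep$network)
  say("branches: ", length(partitions), " partitions enumerated")
  run1 <- permutationScan(prep$network, prep$subjects, cfg,
                          partitions = partitions)
  tb <- scanTable(run1)
  say("branches: ", sum(tb$eligible), " eligible, ", sum(tb$tested),
      " tested, ", length(significantBranches(run1)), " significant")

  useFam <- isTRUE(sc$familial_risk %||% TRUE)
  if (useFam) {
    cfgF <- scanConfig(B = cfg@B, alpha = cfg@alpha,
                       minClassSize = cfg@minClassSize, seed = cfg@seed,
                       covariates = c(baseCovs, "famrisk", "famrisk_missing"),
                       flavor = cfg@flavor)
    runF <- permutationScan(prep$network, prep$subjects, cfgF,
                            partitions = partitions)
    tbF <- scanTable(runF)
    tb$nominalP_famrisk <- tbF$nominalP
    tb$correctedP_famrisk <- tbF$correctedP
    say("familial-risk run: ", length(significantBranches(runF)),
        " significant")
  }

  condRes <- list()
  if (isTRUE(sc$conditional %||% TRUE) && length(significantBranches(run1))) {
    condRes <- conditionalScan(run1, prep$network, prep$subjects, cfg,
                               partitions = partitions)
    for (r in condRes)
      say("conditional round ", r@round, ": ",
          length(significantBranches(r)), " significant")
  }

  out <- tb[order(tb$correctedP, tb$nominalP, tb$branch), ]
  out$nominalP_fmt <- ifelse(is.na(out$nominalP), "",
                             sprintf("%.1E", out$nominalP))
  out$correctedP_fmt <- ifelse(is.na(out$correctedP), "",
                               signif(out$correctedP, 3))
  paths <- c(scan = file.path(outDir, "scan_results.tsv"),
             graphml = file.path(outDir, "network.graphml"),
             edges = file.path(outDir, "network_edges.tsv"),
             famrisk = file.path(outDir, "famrisk.tsv"),
             clades = file.path(outDir, "clade_demographics.tsv"),
             manifest = file.path(outDir, "manifest.json"),
             log = file.path(outDir, "run.log"))
  utils::write.table(out, paths["scan"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeNetwork(prep$network, graphml = paths["graphml"],
               edgeTsv = paths["edges"])
  utils::write.table(prep$famrisk, paths["famrisk"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sig <- significantBranches(run1)
  byBranch <- stats::setNames(partitions,
                              vapply(partitions, function(p) p@branch, ""))
  demo <- do.call(rbind, c(list(reportClade(NULL, prep$subjects)),
                           lapply(sig, function(b)
                             reportClade(byBranch[[b]], prep$subjects))))
  utils::write.table(demo, paths["clades"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfgSnap <- config
  cfgSnap$output <- NULL            # run-specific path, not part of the spec
  manifest <- list(
    package = "mtTreeScan",
    version = as.character(utils::packageVersion("mtTreeScan")),
    seed = cfg@seed, config = cfgSnap, input_digests = inputDigests,
    outputs = basename(unname(paths)),
    sizes = list(subjects = nrow(prep$subjects),
                 haplotypes = length(prep$haplotypes),
                 branches = length(partitions),
                 tested = sum(tb$tested)))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log, paths["log"])
  invisible(list(prep = prep, round1 = run1,
                 famrisk = if (useFam) runF else NULL,
                 conditional = condRes, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
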