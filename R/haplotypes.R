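#' @include variants.R
NULL

#' Set of haplotypes with subject assignment
#'
#' A haplotype is a distinct set of variants (canonical tokens) shared by one
#' or more subjects.  The object also carries the subject-to-haplotype
#' assignment produced by [collapseHaplotypes()] or extended by matrilineal
#' imputation.
#'
#' @slot variants named list: haplotype id -> sorted character vector of
#'   variant tokens.
#' @slot carrierCount named integer: subjects carrying each haplotype.
#' @slot observed named logical: FALSE for network-inferred intermediates.
#' @slot assignment named character: subject id -> haplotype id (NA when
#'   unassigned).
#' @export
setClass("HaplotypeSet",
  representation(variants = "list", carrierCount = "integer",
                 observed = "logical", assignment = "character"))

setValidity("HaplotypeSet", function(object) {
  ids <- names(object@variants)
  if (is.null(ids) || anyDuplicated(ids)) return("haplotype ids must be unique")
  if (!identical(ids, names(object@carrierCount)) ||
      !identical(ids, names(object@observed)))
    return("slot names out of step")
  if (any(object@carrierCount < 0L)) return("negative carrier count")
  if (any(object@carrierCount == 0L & object@observed))
    return("observed haplotype with zero carriers")
  asg <- object@assignment[!is.na(object@assignment)]
  if (length(asg) && !all(asg %in% ids)) return("assignment to unknown haplotype")
  TRUE
})

#' @rdname HaplotypeSet-class
#' @export
setMethod("hapIds", "HaplotypeSet", function(x) names(x@variants))
#' @rdname HaplotypeSet-class
#' @export
setMethod("hapVariants", "HaplotypeSet", function(x) x@variants)
#' @rdname HaplotypeSet-class
#' @export
setMethod("carrierCounts", "HaplotypeSet", function(x) x@carrierCount)
#' @rdname HaplotypeSet-class
#' @export
setMethod("hapAssignment", "HaplotypeSet", function(x) x@assignment)
#' @rdname HaplotypeSet-class
#' @export
setMethod("length", "HaplotypeSet", function(x) length(x@variants))

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet:", length(object), "haplotypes,",
      sum(!is.na(object@assignment)), "of", length(object@assignment),
      "subjects assigned\n")
  cc <- sort(object@carrierCount, decreasing = TRUE)
  cat("  top carrier counts:", paste(utils::head(cc, 5), collapse = ", "), "\n")
})

#' Collapse per-subject variant sets into haplotypes
#'
#' Subjects with identical variant sets share a haplotype.  Haplotype ids are
#' assigned deterministically (decreasing carrier count, then lexicographic
#' variant-set key), so the result does not depend on subject input order.
#'
#' @param subjectVariants named list: subject id -> character vector of
#'   canonical variant tokens (empty vector = reference haplotype).
#' @return a [HaplotypeSet-class].
#' @export
collapseHaplotypes <- function(subjectVariants) {
  stopifnot(length(subjectVariants) > 0L, !is.null(names(subjectVariants)))
  keys <- vapply(subjectVariants,
                 function(v) paste(sortTokens(unique(v)), collapse = ";"), "")
  tab <- table(keys)
  ord <- order(-as.integer(tab), names(tab))
  ukeys <- names(tab)[ord]
  ids <- sprintf("H%0*d", max(3L, nchar(length(ukeys))), seq_along(ukeys))
  variants <- lapply(ukeys, function(k)
    if (k == "") character(0) else strsplit(k, ";", fixed = TRUE)[[1]])
  names(variants) <- ids
  counts <- as.integer(tab)[ord]
  names(counts) <- ids
  assignment <- ids[match(keys, ukeys)]
  names(assignment) <- names(subjectVariants)
  methods::new("HaplotypeSet", variants = variants, carrierCount = counts,
               observed = stats::setNames(rep(TRUE, length(ids)), unname(ids)),
               assignment = assignment)
}

#' @rdname stepDistance
#' @export
setMethod("stepDistance", signature("character", "character"), function(a, b) {
  length(setdiff(a, b)) + length(setdiff(b, a))
})
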