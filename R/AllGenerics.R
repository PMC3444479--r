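#' @include mtTreeScan-package.R
NULL

#' Number of mutational steps between two haplotypes
#'
#' Size of the symmetric difference of the two variant sets; each SNV,
#' insertion or deletion counts as one step.
#'
#' @param a,b haplotype variant sets: character vectors of canonical variant
#'   tokens, or haplotype ids resolved against `x`.
#' @export
setGeneric("stepDistance", function(a, b) standardGeneric("stepDistance"))

#' @rdname HaplotypeSet-class
#' @param x a `HaplotypeSet` (or object containing one).
#' @export
setGeneric("hapIds", function(x) standardGeneric("hapIds"))

#' @rdname HaplotypeSet-class
#' @export
setGeneric("hapVariants", function(x) standardGeneric("hapVariants"))

#' @rdname HaplotypeSet-class
#' @export
setGeneric("carrierCounts", function(x) standardGeneric("carrierCounts"))

#' @rdname HaplotypeSet-class
#' @export
setGeneric("hapAssignment", function(x) standardGeneric("hapAssignment"))

#' @rdname HaplotypeNetwork-class
#' @param x a `HaplotypeNetwork`.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' Number of unresolved loops (reticulations) in a haplotype network
#'
#' The cycle-space dimension `E - V + C` of the network graph: 0 for a forest,
#' 1 for a single retained loop, and so on.  Loops arise when alternative
#' connections of equal minimal length are retained.
#'
#' @param x a `HaplotypeNetwork`.
#' @return non-negative integer.
#' @export
setGeneric("loopCount", function(x) standardGeneric("loopCount"))

#' Enumerate branch-induced bi-allelic partitions of a haplotype network
#'
#' Every branch of the network splits the observed haplotypes of its connected
#' component into two clades.  For tree-like components each branch gives one
#' partition; where the network retains loops, partitions are enumerated under
#' every spanning-tree resolution of the cycles and deduplicated, and each
#' partition records how many resolutions support it.
#'
#' @param x a `HaplotypeNetwork`.
#' @return list of [BranchPartition-class] objects.
#' @export
setGeneric("enumeratePartitions", function(x) standardGeneric("enumeratePartitions"))

#' @rdname TreeScanResult-class
#' @param x a `TreeScanResult`.
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @rdname TreeScanResult-class
#' @export
setGeneric("significantBranches", function(x) standardGeneric("significantBranches"))
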