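#' @include AllGenerics.R
NULL

#' Reference mitochondrial sequence
#'
#' Holds the reference sequence that anchors all variant coordinates
#' (1-based, as in m-dot notation).  The reference is pluggable: analyses of
#' real data load a full-length mitochondrial reference from FASTA, while
#' unit-scale work uses short toy references.
#'
#' @slot name text identifier of the sequence.
#' @slot bases a [Biostrings::DNAString] with the sequence.
#' @slot circular whether the molecule is circular (mtDNA is).
#' @export
setClass("MtReference",
  representation(name = "character", bases = "ANY", circular = "logical"))

setValidity("MtReference", function(object) {
  if (length(object@name) != 1L) return("name must be a single string")
  if (!methods::is(object@bases, "DNAString")) return("bases must be a DNAString")
  if (length(object@bases) < 1L) return("empty reference")
  ok <- all(strsplit(as.character(object@bases), "")[[1]] %in%
              c("A", "C", "G", "T", "N"))
  if (!ok) return("bases must be drawn from {A,C,G,T,N}")
  TRUE
})

#' Construct a reference sequence object
#'
#' @param name identifier.
#' @param bases character string or `DNAString` of A/C/G/T/N.
#' @param circular logical.
#' @return an [MtReference-class].
#' @export
MtReference <- function(name, bases, circular = TRUE) {
  if (is.character(bases)) bases <- Biostrings::DNAString(bases)
  methods::new("MtReference", name = name, bases = bases, circular = circular)
}

#' @describeIn MtReference-class sequence length in bases.
#' @param x an `MtReference`.
#' @export
setMethod("length", "MtReference", function(x) length(x@bases))

setMethod("show", "MtReference", function(object) {
  cat("MtReference '", object@name, "': ", length(object), " bp",
      if (object@circular) " (circular)" else "", "\n", sep = "")
})

#' Reference base(s) at 1-based positions
#' @param ref an [MtReference-class].
#' @param pos integer vector of 1-based positions.
#' @return character vector of single bases.
#' @export
refBase <- function(ref, pos) {
  stopifnot(all(pos >= 1L), all(pos <= length(ref)))
  vapply(pos, function(p) as.character(Biostrings::subseq(ref@bases, p, p)),
         character(1))
}

#' Read a reference sequence from FASTA
#' @param path FASTA file; the first record is used.
#' @param circular logical.
#' @export
readReference <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  MtReference(names(ss)[1], ss[[1]], circular = circular)
}

#' Write sequences to FASTA (70-column wrapped)
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output file.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Deterministic toy reference
#'
#' A repeating-pattern sequence of the requested length, used as a compact
#' coordinate system for simulations and tests.
#' @param len length in bases.
#' @param name identifier.
#' @export
syntheticToyReference <- function(len = 2000L, name = sprintf("toy-%d", len)) {
  MtReference(name, paste(rep_len(c("A", "C", "G", "T", "A", "G", "C", "T",
                                    "T", "A", "C", "G"), len), collapse = ""))
}

#' Synthetic stand-in for the revised Cambridge Reference Sequence
#'
#' A deterministic 16,569-bp sequence occupying the same coordinate system as
#' the human mtDNA reference (NC_012920).  It is *not* the real rCRS: the body
#' of the sequence is a fixed synthetic pattern, patched so that a small set of
#' well-documented sites carry their true reference alleles and codon contexts
#' (e.g. the ND2 codon-86 ATA context of m.4727A>G and the COX3 codon-58 TGG
#' context of m.9380G>A), which makes coordinate arithmetic and annotation of
#' those documented variants behave as on the real reference.  Suitable for
#' testing and simulation only, never for interpreting real genomes.
#'
#' @return an [MtReference-class] of length 16,569.
#' @export
syntheticRCRS <- function() {
  ref <- syntheticToyReference(16569L, name = "synthetic-rCRS")
  s <- strsplit(as.character(ref@bases), "")[[1]]
  patch <- c(
    # frequent-variant reference alleles
    "263" = "A", "750" = "A", "1438" = "A", "4769" = "A",
    "8860" = "A", "15326" = "A",
    # ND1 codon 203 (covers position 3915): GGG, Gly
    "3913" = "G", "3914" = "G", "3915" = "G",
    # ND2 codon 86 (covers position 4727): ATA, Met
    "4725" = "A", "4726" = "T", "4727" = "A",
    # COX3 codon 58 (covers position 9380): TGG, Trp
    "9378" = "T", "9379" = "G", "9380" = "G")
  s[as.integer(names(patch))] <- unname(patch)
  MtReference("synthetic-rCRS", paste(s, collapse = ""))
}

#' Load a gene-coordinate annotation table
#'
#' Closed 1-based intervals of the mitochondrial protein-coding and rRNA
#' genes.  The bundled table carries the standard MitoMap-style coordinates
#' for the 13 protein-coding genes and the two rRNAs; tRNAs and the control
#' region are intentionally absent, so control-region positions annotate as
#' non-genic.
#'
#' @param path TSV with columns gene, start, end, strand, coding; defaults to
#'   the bundled table.
#' @return data.frame.
#' @export
readGeneTable <- function(path = system.file("extdata", "mito_genes.tsv",
                                             package = "mtTreeScan")) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "start", "end", "strand", "coding") %in% names(g)),
            all(g$start <= g$end))
  g$coding <- as.logical(g$coding)
  g
}

#' Annotate a variant against a gene-coordinate table
#'
#' For an SNV inside a protein-coding gene, computes the codon index (codon 1
#' = first three coding bases from the annotated gene start; for minus-strand
#' genes counting runs from the annotated end) and whether the change is
#' synonymous under the vertebrate mitochondrial genetic code.  Positions
#' outside any coding gene return `NA` fields; indels return the gene but no
#' codon or synonymous call.
#'
#' @param variant a canonical variant token (see [parseVariantToken()]) or a
#'   parsed variant row.
#' @param genes gene table from [readGeneTable()].
#' @param reference the [MtReference-class] supplying codon context.
#' @return list with elements `gene`, `codon`, `synonymous` (each may be NA).
#' @export
annotateVariant <- function(variant, genes, reference) {
  v <- if (is.character(variant)) parseVariantToken(variant, reference) else variant
  hit <- genes[genes$coding & genes$start <= v$position & genes$end >= v$position, ]
  if (nrow(hit) == 0L)
    return(list(gene = NA_character_, codon = NA_integer_, synonymous = NA))
  g <- hit[1L, ]
  if (v$kind != "SNV")
    return(list(gene = g$gene, codon = NA_integer_, synonymous = NA))
  offset <- if (g$strand == "+") v$position - g$start else g$end - v$position
  codon <- offset %/% 3L + 1L
  cstart <- if (g$strand == "+") g$start + 3L * (codon - 1L) else NA
  if (g$strand == "+") {
    cod <- refBase(reference, cstart:(cstart + 2L))
    idx <- v$position - cstart + 1L
  } else {
    cend <- g$end - 3L * (codon - 1L)
    cod <- rev(chartr("ACGT", "TGCA", refBase(reference, (cend - 2L):cend)))
    idx <- cend - v$position + 1L
  }
  alt <- if (g$strand == "+") v$alt else chartr("ACGT", "TGCA", v$alt)
  codAlt <- cod
  codAlt[idx] <- alt
  gc <- Biostrings::getGeneticCode("SGC1")   # vertebrate mitochondrial
  aaRef <- unname(gc[paste(cod, collapse = "")])
  aaAlt <- unname(gc[paste(codAlt, collapse = "")])
  list(gene = g$gene, codon = codon, synonymous = identical(aaRef, aaAlt))
}
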