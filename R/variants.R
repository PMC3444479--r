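#' @include reference.R
NULL

# Canonical variant tokens, all in 1-based reference coordinates:
#   SNV        "m.263A>G"
#   insertion  "m.3915_3916insACC"   (ACC inserted after position 3915)
#   deletion   "m.3915del", "m.3915_3917del"  (closed interval removed)

.TOKEN_SNV <- "^m\\.([0-9]+)([ACGTN])>([ACGTN])$"
.TOKEN_INS <- "^m\\.([0-9]+)_([0-9]+)ins([ACGTN]+)$"
.TOKEN_DEL <- "^m\\.([0-9]+)(?:_([0-9]+))?del$"

#' Parse an m-dot variant token
#'
#' Parses the standard `m.POSref>alt` SNV notation and the insertion/deletion
#' dialect documented for this package (`m.3915_3916insACC`,
#' `m.3915_3917del`).  When a reference is supplied, the position is bounds-
#' checked and the reference allele verified against the reference base.
#'
#' @param token character token.
#' @param reference optional [MtReference-class] for validation.
#' @return one-row data.frame with columns position, end, kind, ref, alt,
#'   token.
#' @export
#' @examples
#' parseVariantToken("m.263A>G")
parseVariantToken <- function(token, reference = NULL) {
  stopifnot(is.character(token), length(token) == 1L)
  if (grepl(.TOKEN_SNV, token)) {
    m <- regmatches(token, regexec(.TOKEN_SNV, token))[[1]]
    pos <- as.integer(m[2])
    v <- data.frame(position = pos, end = pos, kind = "SNV",
                    ref = m[3], alt = m[4], token = token,
                    stringsAsFactors = FALSE)
  } else if (grepl(.TOKEN_INS, token)) {
    m <- regmatches(token, regexec(.TOKEN_INS, token))[[1]]
    pos <- as.integer(m[2])
    if (as.integer(m[3]) != pos + 1L)
      stop("insertion token must be anchored as pos_(pos+1): ", token)
    v <- data.frame(position = pos, end = pos, kind = "insertion",
                    ref = "", alt = m[4], token = token,
                    stringsAsFactors = FALSE)
  } else if (grepl(.TOKEN_DEL, token, perl = TRUE)) {
    m <- regmatches(token, regexec(.TOKEN_DEL, token, perl = TRUE))[[1]]
    pos <- as.integer(m[2])
    end <- if (m[3] == "") pos else as.integer(m[3])
    if (end < pos) stop("deletion interval reversed: ", token)
    v <- data.frame(position = pos, end = end, kind = "deletion",
                    ref = "", alt = "", token = token,
                    stringsAsFactors = FALSE)
  } else {
    stop("malformed variant token: ", token)
  }
  if (v$ref == v$alt && v$kind == "SNV")
    stop("ref and alt alleles identical: ", token)
  if (!is.null(reference)) {
    if (v$end > length(reference) || v$position < 1L)
      stop("position out of reference bounds (1..", length(reference), "): ",
           token)
    if (v$kind == "SNV") {
      rb <- refBase(reference, v$position)
      if (rb != v$ref)
        stop("reference mismatch at ", v$position, ": token says ", v$ref,
             ", reference has ", rb)
    }
    if (v$kind == "deletion")
      v$ref <- paste(refBase(reference, v$position:v$end), collapse = "")
  }
  v
}

#' @rdname parseVariantToken
#' @param tokens character vector of tokens.
#' @export
parseVariantTokens <- function(tokens, reference = NULL) {
  do.call(rbind, lapply(tokens, parseVariantToken, reference = reference))
}

#' 1-based position encoded in variant tokens
#' @param tokens character vector of canonical tokens.
#' @export
variantPositions <- function(tokens) {
  as.integer(sub("^m\\.([0-9]+).*$", "\\1", tokens))
}

# Sort tokens by (position, token) -- the canonical in-set order.
sortTokens <- function(tokens) {
  tokens[order(variantPositions(tokens), tokens)]
}

#' Resolve a heteroplasmic site to its majority allele
#'
#' At a heteroplasmic site only the most common allele is retained.  Ties are
#' resolved to the reference allele (a deterministic, conservative
#' convention).
#'
#' @param calls data.frame with columns `allele` and `fraction` (or a list of
#'   `(allele, fraction)` pairs) for one site.
#' @param refAllele the reference allele at the site, used for tie-breaks.
#' @return list with `allele` (retained allele) and `heteroplasmic` (TRUE when
#'   more than one allele was present).
#' @export
resolveHeteroplasmy <- function(calls, refAllele = NULL) {
  if (is.list(calls) && !is.data.frame(calls))
    calls <- data.frame(allele = vapply(calls, function(x) as.character(x[[1]]), ""),
                        fraction = vapply(calls, function(x) as.numeric(x[[2]]), 0))
  if (NROW(calls) == 0L) stop("empty call list")
  stopifnot(all(calls$fraction >= 0))
  if (sum(calls$fraction) > 1 + 1e-6) stop("allele fractions sum to > 1")
  hetero <- sum(calls$fraction > 0) > 1L
  mx <- max(calls$fraction)
  top <- calls$allele[calls$fraction >= mx - 1e-12]
  if (length(unique(top)) > 1L) {
    if (is.null(refAllele)) stop("tied fractions need refAllele for tie-break")
    return(list(allele = refAllele, heteroplasmic = hetero))
  }
  list(allele = top[1], heteroplasmic = hetero)
}

#' Read a per-subject variant table
#'
#' TSV with columns subject_id, position, ref, alt and optional het_fraction
#' (fraction of the alternate allele; 1 or NA when the site is homoplasmic).
#' `'-'` denotes the empty allele, so insertions have ref `'-'` and deletions
#' alt `'-'`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readVariantTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(subject_id = "character"))
  need <- c("subject_id", "position", "ref", "alt")
  if (!all(need %in% names(tab)))
    stop("variant table needs columns: ", paste(need, collapse = ", "))
  if (!"het_fraction" %in% names(tab)) tab$het_fraction <- 1
  tab
}

#' Apply the majority rule to a variant table
#'
#' Rows whose alternate-allele fraction exceeds 0.5 are retained (flagged
#' heteroplasmic when the fraction is below 1); rows at or below 0.5 resolve
#' to the reference allele and are dropped.
#'
#' @param tab variant table (see [readVariantTable()]).
#' @return the filtered table with a logical `heteroplasmic` column.
#' @export
applyMajorityRule <- function(tab) {
  f <- tab$het_fraction
  f[is.na(f)] <- 1
  keep <- f > 0.5
  out <- tab[keep, , drop = FALSE]
  out$heteroplasmic <- f[keep] < 1
  rownames(out) <- NULL
  out
}

#' Convert a (resolved) variant table into per-subject token sets
#'
#' @param tab variant table after [applyMajorityRule()].
#' @param reference [MtReference-class] used to validate alleles.
#' @return named list: subject id -> sorted character vector of canonical
#'   variant tokens.
#' @export
subjectVariantSets <- function(tab, reference = NULL) {
  tok <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- tab$position[i]; r <- tab$ref[i]; a <- tab$alt[i]
    if (r != "-" && a != "-") {
      if (nchar(r) != 1L || nchar(a) != 1L)
        stop("multi-nucleotide substitutions are not supported (row ", i, ")")
      tok[i] <- sprintf("m.%d%s>%s", p, r, a)
    } else if (r == "-") {
      tok[i] <- sprintf("m.%d_%dins%s", p, p + 1L, a)
    } else {
      tok[i] <- if (nchar(r) == 1L) sprintf("m.%ddel", p) else
        sprintf("m.%d_%ddel", p, p + nchar(r) - 1L)
    }
  }
  if (!is.null(reference)) invisible(parseVariantTokens(unique(tok), reference))
  sets <- split(tok, tab$subject_id)
  lapply(sets, function(x) {
    pv <- variantPositions(x)
    snvdel <- !grepl("ins", x)
    if (anyDuplicated(pv[snvdel]))
      stop("more than one SNV/deletion at a position within one subject")
    sortTokens(unique(x))
  })
}

#' Construct a full sequence from a variant set
#'
#' Applies a set of variants to the reference: SNVs substitute, deletions
#' remove their closed interval, insertions place their bases after the
#' anchor position.  The empty set returns the reference unchanged.
#'
#' @param variants character vector of canonical tokens (possibly empty).
#' @param reference [MtReference-class].
#' @return character string sequence.
#' @export
sequenceFromVariants <- function(variants, reference) {
  s <- strsplit(as.character(reference@bases), "")[[1]]
  if (length(variants) == 0L) return(paste(s, collapse = ""))
  v <- parseVariantTokens(variants, reference)
  deleted <- rep(FALSE, length(s))
  for (i in which(v$kind == "deletion")) {
    idx <- v$position[i]:v$end[i]
    if (any(deleted[idx])) stop("overlapping deletions")
    deleted[idx] <- TRUE
  }
  for (i in which(v$kind == "SNV")) {
    if (deleted[v$position[i]]) stop("SNV inside a deleted interval")
    s[v$position[i]] <- v$alt[i]
  }
  ins <- rep("", length(s) + 1L)  # ins[p + 1] goes after reference position p
  for (i in which(v$kind == "insertion")) {
    if (ins[v$position[i] + 1L] != "") stop("two insertions at one anchor")
    if (deleted[v$position[i]]) stop("insertion anchored inside a deletion")
    ins[v$position[i] + 1L] <- v$alt[i]
  }
  keepChars <- ifelse(deleted, "", s)
  paste0(paste0(c("", keepChars), ins, collapse = ""))
}

#' Recover the variant set that separates a sequence from the reference
#'
#' Inverse of [sequenceFromVariants()].  Equal-length sequences are compared
#' position-wise (substitutions only); differing lengths are globally aligned
#' (affine gap penalties) and the alignment converted into anchored insertion
#' and closed-interval deletion tokens.  In repetitive contexts an indel's
#' placement is not unique; the aligner's leftmost placement is returned.
#'
#' @param seq character string sequence.
#' @param reference [MtReference-class].
#' @return sorted character vector of canonical tokens.
#' @export
variantsFromSequence <- function(seq, reference) {
  refs <- as.character(reference@bases)
  if (nchar(seq) == nchar(refs)) {
    a <- strsplit(seq, "")[[1]]
    b <- strsplit(refs, "")[[1]]
    d <- which(a != b)
    return(sortTokens(sprintf("m.%d%s>%s", d, b[d], a[d])))
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(seq),
    subject = reference@bases, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
    gapOpening = 6, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  r <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  tokens <- character(0)
  refpos <- 0L
  i <- 1L
  while (i <= length(p)) {
    if (r[i] != "-" && p[i] != "-") {
      refpos <- refpos + 1L
      if (r[i] != p[i])
        tokens <- c(tokens, sprintf("m.%d%s>%s", refpos, r[i], p[i]))
      i <- i + 1L
    } else if (p[i] == "-") {            # deletion relative to reference
      start <- refpos + 1L
      while (i <= length(p) && p[i] == "-") { refpos <- refpos + 1L; i <- i + 1L }
      tokens <- c(tokens, if (refpos == start) sprintf("m.%ddel", start) else
        sprintf("m.%d_%ddel", start, refpos))
    } else {                             # insertion relative to reference
      if (refpos < 1L) stop("insertion before reference position 1")
      insseq <- ""
      while (i <= length(p) && r[i] == "-") { insseq <- paste0(insseq, p[i]); i <- i + 1L }
      tokens <- c(tokens, sprintf("m.%d_%dins%s", refpos, refpos + 1L, insseq))
    }
  }
  sortTokens(tokens)
}
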