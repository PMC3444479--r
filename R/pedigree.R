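#' @include treescan.R
NULL

#' Pedigree
#'
#' Individuals with parent links, sex, at-risk-cohort membership and
#' (where known) affection status.  Founders have `NA` parents.
#'
#' @slot df data.frame with columns id, sex ("M"/"F"), father, mother
#'   (character or NA), cohort (logical), affected (logical or NA).
#' @export
setClass("Pedigree", representation(df = "data.frame"))

setValidity("Pedigree", function(object) {
  d <- object@df
  need <- c("id", "sex", "father", "mother", "cohort", "affected")
  if (!all(need %in% names(d))) return("missing pedigree columns")
  if (anyDuplicated(d$id)) return("duplicate individual id")
  if (!all(d$sex %in% c("M", "F"))) return("sex must be M or F")
  for (col in c("father", "mother")) {
    p <- d[[col]]
    if (!all(is.na(p) | p %in% d$id)) return("parent id not in pedigree")
  }
  fa <- d$father[!is.na(d$father)]
  if (!all(d$sex[match(fa, d$id)] == "M")) return("father is not male")
  mo <- d$mother[!is.na(d$mother)]
  if (!all(d$sex[match(mo, d$id)] == "F")) return("mother is not female")
  if (is.null(.pedigreeOrder(d))) return("parent links contain a cycle")
  TRUE
})

# topological order (founders first), or NULL on a cycle
.pedigreeOrder <- function(d) {
  n <- nrow(d)
  idx <- stats::setNames(seq_len(n), d$id)
  fa <- ifelse(is.na(d$father), 0L, idx[d$father])
  mo <- ifelse(is.na(d$mother), 0L, idx[d$mother])
  depth <- rep(NA_integer_, n)
  getDepth <- function(i, stack) {
    if (!is.na(depth[i])) return(depth[i])
    if (i %in% stack) return(NA_integer_)  # cycle
    dpar <- 0L
    for (p in c(fa[i], mo[i])) if (p > 0L) {
      dp <- getDepth(p, c(stack, i))
      if (is.na(dp)) return(NA_integer_)
      dpar <- max(dpar, dp + 1L)
    }
    depth[i] <<- dpar
    dpar
  }
  for (i in seq_len(n)) if (is.na(getDepth(i, integer(0)))) return(NULL)
  order(depth)
}

#' Construct a pedigree
#' @param df data.frame with columns id, sex, father, mother and optional
#'   cohort / affected flags.
#' @export
Pedigree <- function(df) {
  if (!"cohort" %in% names(df)) df$cohort <- !is.na(df$affected)
  if (!"affected" %in% names(df)) df$affected <- NA
  df$id <- as.character(df$id)
  df$father <- as.character(df$father)
  df$mother <- as.character(df$mother)
  methods::new("Pedigree", df = df[, c("id", "sex", "father", "mother",
                                       "cohort", "affected")])
}

#' @rdname Pedigree-class
#' @param x a `Pedigree`.
#' @export
setMethod("length", "Pedigree", function(x) nrow(x@df))

setMethod("show", "Pedigree", function(object) {
  d <- object@df
  cat("Pedigree:", nrow(d), "individuals,",
      sum(is.na(d$father) & is.na(d$mother)), "founders,",
      sum(d$cohort), "at-risk cohort members,",
      sum(d$affected %in% TRUE), "affected\n")
})

#' Read a pedigree from a PED file
#'
#' Standard six-column PED (family, id, father, mother, sex, phenotype) with
#' 0 for a missing parent, sex coded 1 = male / 2 = female, and phenotype
#' coded 2 = affected, 1 = unaffected, 0 or -9 = missing.  An optional
#' companion TSV (columns id, cohort and optionally affected) supplies the
#' at-risk-cohort flag; without it, cohort membership defaults to
#' "phenotype known".
#'
#' @param pedPath PED file.
#' @param flagsPath optional companion TSV.
#' @return a [Pedigree-class].
#' @export
readPedigree <- function(pedPath, flagsPath = NULL) {
  p <- utils::read.delim(pedPath, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(p) < 6L) stop("PED file needs 6 columns")
  names(p)[1:6] <- c("family", "id", "father", "mother", "sex", "phenotype")
  df <- data.frame(
    id = p$id,
    sex = c("1" = "M", "2" = "F")[p$sex],
    father = ifelse(p$father == "0", NA_character_, p$father),
    mother = ifelse(p$mother == "0", NA_character_, p$mother),
    affected = ifelse(p$phenotype == "2", TRUE,
                      ifelse(p$phenotype == "1", FALSE, NA)),
    stringsAsFactors = FALSE)
  if (any(is.na(df$sex))) stop("sex must be coded 1 (male) or 2 (female)")
  if (!is.null(flagsPath)) {
    fl <- utils::read.delim(flagsPath, stringsAsFactors = FALSE,
                            colClasses = c(id = "character"))
    i <- match(df$id, fl$id)
    df$cohort <- !is.na(i) & as.logical(fl$cohort[i])
    if ("affected" %in% names(fl)) {
      ov <- as.logical(fl$affected[i])
      df$affected <- ifelse(is.na(i), df$affected, ov)
    }
  }
  Pedigree(df)
}

#' Write a pedigree to PED format (plus optional flags table)
#' @param ped a [Pedigree-class].
#' @param pedPath output PED path.
#' @param flagsPath optional output TSV for cohort/affected flags.
#' @export
writePedigree <- function(ped, pedPath, flagsPath = NULL) {
  d <- ped@df
  out <- data.frame(
    family = "F1", id = d$id,
    father = ifelse(is.na(d$father), "0", d$father),
    mother = ifelse(is.na(d$mother), "0", d$mother),
    sex = ifelse(d$sex == "M", 1L, 2L),
    phenotype = ifelse(is.na(d$affected), 0L, ifelse(d$affected, 2L, 1L)))
  utils::write.table(out, pedPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(flagsPath))
    utils::write.table(
      data.frame(id = d$id, cohort = as.integer(d$cohort),
                 affected = ifelse(is.na(d$affected), NA,
                                   as.integer(d$affected))),
      flagsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pedPath)
}

#' Kinship matrix
#'
#' Standard recursive kinship: phi(i,i) = 1/2 + phi(father, mother)/2 and
#' phi(i,j) = (phi(father_i, j) + phi(mother_i, j)) / 2 for j not a
#' descendant of i, computed by the tabular method in topological order.
#' Missing parents contribute 0 (founders are treated as unrelated and
#' non-inbred).
#'
#' @param ped a [Pedigree-class].
#' @return symmetric matrix of kinship coefficients with id dimnames.
#' @export
kinshipMatrix <- function(ped) {
  d <- ped@df
  n <- nrow(d)
  ord <- .pedigreeOrder(d)
  idx <- stats::setNames(seq_len(n), d$id)
  fa <- ifelse(is.na(d$father), 0L, idx[d$father])
  mo <- ifelse(is.na(d$mother), 0L, idx[d$mother])
  phi <- matrix(0, n, n, dimnames = list(d$id, d$id))
  for (i in ord) {
    fi <- fa[i]; mi <- mo[i]
    prev <- ord[seq_len(match(i, ord) - 1L)]
    if (length(prev)) {
      row <- 0.5 * ((if (fi > 0L) phi[fi, prev] else 0) +
                    (if (mi > 0L) phi[mi, prev] else 0))
      phi[i, prev] <- row
      phi[prev, i] <- row
    }
    phi[i, i] <- 0.5 + (if (fi > 0L && mi > 0L) 0.5 * phi[fi, mi] else 0)
  }
  phi
}

#' Kinship and relationship coefficients for a pair
#' @param ped a [Pedigree-class].
#' @param i,j individual ids.
#' @return list with `phi` (kinship) and `r` (coefficient of relationship,
#'   twice the kinship).
#' @export
kinship <- function(ped, i, j) {
  d <- ped@df
  if (!all(c(i, j) %in% d$id)) stop("unknown individual id")
  phi <- kinshipMatrix(ped)[i, j]
  list(phi = phi, r = 2 * phi)
}

#' Familial-risk covariate
#'
#' For each subject: the weighted sum of biological relatives diagnosed with
#' the disease divided by the weighted sum of biological relatives who are
#' members of the at-risk cohort, using the coefficient of relationship
#' (twice the kinship coefficient) as the weight.  Affected relatives count
#' in the numerator only when they are also at-risk members; the subject is
#' excluded from its own sums.  Subjects with no at-risk relatives get score
#' 0 and a degenerate flag (exposed as a missing-indicator covariate rather
#' than dropping them).
#'
#' @param ped a [Pedigree-class] with cohort and affected flags.
#' @param ids subjects to score (default: all at-risk cohort members).
#' @param minR count only relatives with relationship coefficient strictly
#'   greater than this (default 0 = all biological relatives).
#' @return data.frame with id, numerator, denominator, score, degenerate.
#' @export
familialRisk <- function(ped, ids = NULL, minR = 0) {
  d <- ped@df
  if (is.null(ids)) ids <- d$id[d$cohort]
  r <- 2 * kinshipMatrix(ped)
  atRisk <- d$cohort
  affected <- d$cohort & d$affected %in% TRUE
  out <- data.frame(id = ids, numerator = 0, denominator = 0, score = 0,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    i <- ids[k]
    w <- r[i, ]
    w[i] <- 0
    rel <- w > minR
    den <- sum(w[rel & atRisk])
    num <- sum(w[rel & affected])
    out$numerator[k] <- num
    out$denominator[k] <- den
    if (den > 0) out$score[k] <- num / den else out$degenerate[k] <- TRUE
  }
  out
}

#' Matrilineal founder of a subject
#'
#' Follows mother links up to the maternal founder; every member of a
#' matriline maps to the same founder id.
#'
#' @param ped a [Pedigree-class].
#' @param id subject id (vectorized).
#' @return character vector of founder ids.
#' @export
matrilineOf <- function(ped, id) {
  d <- ped@df
  mo <- stats::setNames(d$mother, d$id)
  vapply(as.character(id), function(i) {
    if (!i %in% d$id) stop("unknown individual id: ", i)
    while (!is.na(mo[[i]])) i <- mo[[i]]
    i
  }, "")
}

#' @rdname matrilineOf
#' @return `matrilines()` returns the founder id for every pedigree member.
#' @export
matrilines <- function(ped) {
  d <- ped@df
  stats::setNames(matrilineOf(ped, d$id), d$id)
}

#' Matrilineal haplotype imputation
#'
#' Members of a matriline share an unbroken maternal line and hence (barring
#' maternal mutation) one mtDNA haplotype.  Every ungenotyped matriline
#' member whose matriline contains exactly one observed haplotype receives
#' that haplotype, flagged imputed; matrilines with no genotyped member stay
#' missing.  Matrilines whose genotyped members disagree are handled per
#' `conflict` and always reported.
#'
#' @param assignment named character vector, id -> haplotype id (NA =
#'   ungenotyped).  Ids must be pedigree members.
#' @param ped a [Pedigree-class].
#' @param conflict `"leave_missing"` (default: only genotyped members keep
#'   assignments), `"majority"` (most frequent haplotype wins, ties left
#'   missing) or `"abort"`.
#' @return list with `assignment` (extended named vector), `imputed` (named
#'   logical) and `conflicts` (data.frame of discordant matrilines).
#' @export
imputeHaplotypes <- function(assignment, ped,
                             conflict = c("leave_missing", "majority", "abort")) {
  conflict <- match.arg(conflict)
  stopifnot(!is.null(names(assignment)))
  ml <- matrilines(ped)
  ids <- names(assignment)
  stopifnot(all(ids %in% names(ml)))
  out <- assignment
  imputed <- stats::setNames(rep(FALSE, length(ids)), ids)
  conflicts <- data.frame(matriline = character(0), haplotypes = character(0))
  for (founder in unique(ml[ids])) {
    members <- ids[ml[ids] == founder]
    obs <- out[members]
    seen <- unique(obs[!is.na(obs)])
    if (length(seen) == 0L) next
    if (length(seen) > 1L) {
      conflicts <- rbind(conflicts, data.frame(
        matriline = founder, haplotypes = paste(sort(seen), collapse = ",")))
      if (conflict == "abort")
        stop("discordant haplotypes in matriline ", founder)
      if (conflict == "leave_missing") next
      tab <- sort(table(obs), decreasing = TRUE)
      if (length(tab) > 1L && tab[1] == tab[2]) next  # tie: leave missing
      seen <- names(tab)[1]
    }
    fill <- members[is.na(out[members])]
    out[fill] <- seen
    imputed[fill] <- TRUE
  }
  if (nrow(conflicts))
    message("discordant matrilines: ", paste(conflicts$matriline, collapse = ", "))
  list(assignment = out, imputed = imputed, conflicts = conflicts)
}
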