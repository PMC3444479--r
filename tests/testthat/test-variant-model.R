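ref <- syntheticRCRS()
genes <- readGeneTable()
toy <- syntheticToyReference(40)

test_that("m-dot tokens parse and validate against the reference", {
  v <- parseVariantToken("m.3915G>A", ref)
  expect_equal(v$position, 3915L)
  expect_equal(v$ref, "G")
  expect_equal(v$alt, "A")
  expect_equal(v$kind, "SNV")

  v <- parseVariantToken("m.263A>G", ref)
  expect_equal(v$position, 263L)
  expect_equal(c(v$ref, v$alt), c("A", "G"))

  expect_error(parseVariantToken("m.16570A>G", ref), "bounds")
  expect_error(parseVariantToken("m.263C>G", ref), "mismatch")
  expect_error(parseVariantToken("rubbish"), "malformed")
  expect_error(parseVariantToken("m.12A>A"), "identical")

  ins <- parseVariantToken("m.5_6insACC", toy)
  expect_equal(ins$kind, "insertion")
  expect_equal(ins$alt, "ACC")
  del <- parseVariantToken("m.5_7del", toy)
  expect_equal(del$kind, "deletion")
  expect_equal(nchar(del$ref), 3L)  # filled from the reference
  expect_error(parseVariantToken("m.5_4del"), "reversed")
})

test_that("heteroplasmy resolves to the majority allele, ties to reference", {
  r <- resolveHeteroplasmy(data.frame(allele = c("A", "G"),
                                      fraction = c(0.8, 0.2)))
  expect_equal(r$allele, "A")
  expect_true(r$heteroplasmic)

  r <- resolveHeteroplasmy(data.frame(allele = c("A", "G"),
                                      fraction = c(0.5, 0.5)),
                           refAllele = "C")
  expect_equal(r$allele, "C")

  r <- resolveHeteroplasmy(data.frame(allele = "A", fraction = 1))
  expect_equal(r$allele, "A")
  expect_false(r$heteroplasmic)

  expect_error(resolveHeteroplasmy(data.frame(allele = character(0),
                                              fraction = numeric(0))),
               "empty")
  # order independence
  calls <- data.frame(allele = c("T", "A", "G"), fraction = c(0.1, 0.6, 0.3))
  for (ord in list(1:3, 3:1, c(2, 1, 3)))
    expect_equal(resolveHeteroplasmy(calls[ord, ])$allele, "A")
})

test_that("subjects collapse into haplotypes with conserved carrier counts", {
  hs <- collapseHaplotypes(list(
    s1 = character(0), s2 = "m.263A>G", s3 = "m.263A>G",
    s4 = c("m.263A>G", "m.750A>G")))
  expect_equal(length(hs), 3L)
  expect_equal(sort(unname(carrierCounts(hs)), decreasing = TRUE),
               c(2L, 1L, 1L))
  expect_equal(sum(carrierCounts(hs)), 4L)
  expect_false(anyNA(hapAssignment(hs)))

  same <- collapseHaplotypes(stats::setNames(
    rep(list(c("m.1A>C", "m.9T>A")), 6), paste0("x", 1:6)))
  expect_equal(length(same), 1L)
  expect_equal(unname(carrierCounts(same)), 6L)

  # conservation + input-order invariance over random draws
  set.seed(42)
  toks <- sprintf("m.%d%s>%s", 1:12, "A", "C")
  for (rep in 1:5) {
    sv <- lapply(1:15, function(i) sample(toks, sample(0:5, 1)))
    names(sv) <- paste0("s", 1:15)
    hs <- collapseHaplotypes(sv)
    expect_equal(sum(carrierCounts(hs)), 15L)
    expect_true(all(hapAssignment(hs) %in% hapIds(hs)))
    hs2 <- collapseHaplotypes(sv[sample(15)])
    expect_equal(hapVariants(hs2), hapVariants(hs))
    expect_equal(hapAssignment(hs2)[names(sv)], hapAssignment(hs))
  }
})

test_that("sequence construction and variant recovery are inverse", {
  expect_equal(sequenceFromVariants(character(0), toy),
               as.character(toy@bases))

  s <- sequenceFromVariants(sprintf("m.5%s>T", refBase(toy, 5)), toy)
  expect_equal(substr(s, 5, 5), "T")
  expect_equal(nchar(s), length(toy))

  # SNV round trip on seeded random sets
  set.seed(7)
  for (rep in 1:20) {
    pos <- sample(length(toy), sample(1:6, 1))
    refs <- refBase(toy, pos)
    alts <- vapply(refs, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    v <- mtTreeScan:::sortTokens(sprintf("m.%d%s>%s", pos, refs, alts))
    expect_equal(variantsFromSequence(sequenceFromVariants(v, toy), toy), v)
  }

  # indel round trip in a non-repetitive context
  big <- syntheticRCRS()
  v <- c("m.263A>G", "m.3913_3915del", "m.9378_9379insAAAA")
  v <- mtTreeScan:::sortTokens(v)
  got <- variantsFromSequence(sequenceFromVariants(v, big), big)
  expect_equal(got, v)

  expect_error(sequenceFromVariants(c("m.3_6del", "m.5_7del"), toy),
               "overlapping")
})

test_that("coding variants annotate to the documented codons", {
  a <- annotateVariant("m.4727A>G", genes, ref)
  expect_equal(a$gene, "ND2")
  expect_equal(a$codon, 86L)
  expect_true(a$synonymous)

  a <- annotateVariant("m.9380G>A", genes, ref)
  expect_equal(a$gene, "COX3")
  expect_equal(a$codon, 58L)
  expect_true(a$synonymous)

  # control region: no gene
  a <- annotateVariant("m.263A>G", genes, ref)
  expect_true(is.na(a$gene))

  # codon arithmetic from the annotated ND1 start (3307), codon 1 = first
  # three coding bases
  a <- annotateVariant("m.3915G>A", genes, ref)
  expect_equal(a$gene, "ND1")
  expect_equal(a$codon, 203L)
  expect_true(a$synonymous)

  # rRNA position (RNR1 is non-coding): no codon annotation
  rb <- refBase(ref, 700)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  a <- annotateVariant(sprintf("m.700%s>%s", rb, alt), genes, ref)
  expect_true(is.na(a$gene) && is.na(a$codon))
})

test_that("variant tables resolve, validate and convert to token sets", {
  tab <- data.frame(
    subject_id = c("s1", "s1", "s2", "s2"),
    position = c(263L, 750L, 263L, 16190L),
    ref = c("A", "A", "A", "C"),
    alt = c("G", "G", "G", "T"),
    het_fraction = c(1, 0.4, 0.9, NA),
    stringsAsFactors = FALSE)
  res <- applyMajorityRule(tab)
  expect_equal(nrow(res), 3L)            # the 0.4 row resolves to reference
  expect_equal(res$heteroplasmic, c(FALSE, TRUE, FALSE))
  sets <- subjectVariantSets(res)
  expect_equal(sets$s1, "m.263A>G")
  expect_equal(length(sets$s2), 2L)

  dup <- data.frame(subject_id = "s1", position = c(263L, 263L),
                    ref = c("A", "A"), alt = c("G", "T"),
                    het_fraction = 1)
  expect_error(subjectVariantSets(applyMajorityRule(dup)), "position")

  f <- tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readVariantTable(f)
  expect_equal(back$position, tab$position)
})
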