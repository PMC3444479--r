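test_that("PED files parse with founders, flags and validation errors", {
  ped <- tempfile(fileext = ".ped")
  writeLines(c("F1\tdad\t0\t0\t1\t1",
               "F1\tmum\t0\t0\t2\t2",
               "F1\tkid\tdad\tmum\t1\t0"), ped)
  p <- readPedigree(ped)
  expect_equal(length(p), 3L)
  d <- p@df
  expect_equal(d$father[d$id == "kid"], "dad")
  expect_equal(d$mother[d$id == "kid"], "mum")
  expect_true(is.na(d$father[d$id == "dad"]))     # 0 -> founder
  expect_true(d$affected[d$id == "mum"])
  expect_true(is.na(d$affected[d$id == "kid"]))

  flags <- tempfile(fileext = ".tsv")
  writeLines(c("id\tcohort", "dad\t1", "mum\t0", "kid\t1"), flags)
  p2 <- readPedigree(ped, flags)
  expect_equal(p2@df$cohort, c(TRUE, FALSE, TRUE))

  # an individual who is its own ancestor
  bad <- tempfile(fileext = ".ped")
  writeLines(c("F1\ta\tb\t0\t1\t0",
               "F1\tb\ta\t0\t1\t0"), bad)
  expect_error(readPedigree(bad), "cycle")

  # father listed with female sex
  bad2 <- tempfile(fileext = ".ped")
  writeLines(c("F1\tdad\t0\t0\t2\t0",
               "F1\tkid\tdad\t0\t1\t0"), bad2)
  expect_error(readPedigree(bad2), "father")

  dup <- tempfile(fileext = ".ped")
  writeLines(c("F1\tx\t0\t0\t1\t0", "F1\tx\t0\t0\t1\t0"), dup)
  expect_error(readPedigree(dup), "duplicate")
})

test_that("kinship recursion reproduces closed forms and the descent oracle", {
  ped <- cousinPedigree()
  phi <- kinshipMatrix(ped)
  # non-inbred self
  expect_equal(phi["c1", "c1"], 0.5)
  # parent-offspring
  expect_equal(kinship(ped, "f1", "c1")$phi, 0.25)
  expect_equal(kinship(ped, "f1", "c1")$r, 0.5)
  # full sibs
  expect_equal(kinship(ped, "f1", "f2")$phi, 0.25)
  # first cousins
  expect_equal(kinship(ped, "c1", "c2")$phi, 1 / 16)
  expect_equal(kinship(ped, "c1", "c2")$r, 1 / 8)
  # symmetry and bounds
  expect_equal(phi, t(phi))
  expect_true(all(phi <= diag(phi)[row(phi)] + 1e-12))

  # descent oracle across pairs with independent descent paths (the product
  # construction is not valid for ancestor-descendant pairs, whose alleles
  # share a meiosis)
  ids <- ped@df$id
  anc <- function(id) {
    out <- character(0); queue <- id
    while (length(queue)) {
      r <- ped@df[ped@df$id == queue[1], ]; queue <- queue[-1]
      for (p in c(r$father, r$mother)) if (!is.na(p)) {
        out <- c(out, p); queue <- c(queue, p)
      }
    }
    unique(out)
  }
  for (i in ids) for (j in ids)
    if (i < j && !(i %in% anc(j)) && !(j %in% anc(i)))
      expect_equal(phi[i, j], kinshipDescentOracle(ped, i, j),
                   tolerance = 1e-12, info = paste(i, j))

  expect_error(kinship(ped, "c1", "nobody"), "unknown")
})

test_that("familial risk is the r-weighted affected fraction of at-risk kin", {
  # only relative: one at-risk affected full sibling -> score 1
  sibs <- Pedigree(data.frame(
    id = c("pa", "ma", "a", "b"), sex = c("M", "F", "M", "F"),
    father = c(NA, NA, "pa", "pa"), mother = c(NA, NA, "ma", "ma"),
    cohort = c(FALSE, FALSE, TRUE, TRUE),
    affected = c(NA, NA, FALSE, TRUE), stringsAsFactors = FALSE))
  fr <- familialRisk(sibs, ids = "a")
  expect_equal(fr$score, 1)
  expect_equal(fr$numerator, 0.5)
  expect_equal(fr$denominator, 0.5)

  # two at-risk parents, one affected -> 0.5
  trio <- Pedigree(data.frame(
    id = c("pa", "ma", "kid"), sex = c("M", "F", "M"),
    father = c(NA, NA, "pa"), mother = c(NA, NA, "ma"),
    cohort = c(TRUE, TRUE, TRUE),
    affected = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE))
  fr <- familialRisk(trio, ids = "kid")
  expect_equal(fr$score, 0.5)

  # no at-risk relatives -> score 0, degenerate flag
  lone <- Pedigree(data.frame(
    id = c("pa", "ma", "kid"), sex = c("M", "F", "M"),
    father = c(NA, NA, "pa"), mother = c(NA, NA, "ma"),
    cohort = c(FALSE, FALSE, TRUE),
    affected = c(NA, NA, FALSE), stringsAsFactors = FALSE))
  fr <- familialRisk(lone, ids = "kid")
  expect_equal(fr$score, 0)
  expect_true(fr$degenerate)

  # bounds: 1 when all at-risk kin affected, 0 when none
  allAff <- familialRisk(Pedigree(data.frame(
    id = c("pa", "ma", "a", "b"), sex = c("M", "F", "M", "F"),
    father = c(NA, NA, "pa", "pa"), mother = c(NA, NA, "ma", "ma"),
    cohort = TRUE, affected = c(TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)), ids = "a")
  expect_equal(allAff$score, 1)
  co <- simulateCohort(toyParams(seed = 2))
  frAll <- familialRisk(co@pedigree)
  expect_true(all(frAll$score >= 0 & frAll$score <= 1))
})

test_that("matrilines follow the unbroken maternal chain to the founder", {
  ped <- Pedigree(data.frame(
    id = c("ggm", "gm", "m", "kid", "aunt", "unc"),
    sex = c("F", "F", "F", "M", "F", "M"),
    father = NA, mother = c(NA, "ggm", "gm", "m", "gm", NA),
    affected = NA, stringsAsFactors = FALSE))
  expect_equal(unname(matrilineOf(ped, "kid")), "ggm")
  expect_equal(unname(matrilineOf(ped, "ggm")), "ggm")
  # maternal siblings share the founder
  expect_equal(unname(matrilineOf(ped, "m")), unname(matrilineOf(ped, "aunt")))
  expect_equal(unname(matrilines(ped)[["unc"]]), "unc")
})

test_that("matrilineal imputation fills single-haplotype matrilines only", {
  ped <- Pedigree(data.frame(
    id = c("f1", "a", "b", "c", "d", "e", "f2", "x", "y"),
    sex = c("F", "F", "M", "M", "F", "M", "F", "M", "F"),
    father = NA,
    mother = c(NA, "f1", "f1", "a", "a", "d", NA, "f2", "f2"),
    affected = NA, stringsAsFactors = FALSE))
  asg <- c(a = "H1", b = NA, c = NA, d = NA, e = NA, x = NA, y = NA)
  imp <- imputeHaplotypes(asg, ped)
  # the 5 members of f1's matriline share H1, 4 imputed
  expect_equal(unname(imp$assignment[c("a", "b", "c", "d", "e")]),
               rep("H1", 5))
  expect_equal(sum(imp$imputed), 4L)
  # matriline without genotyped members stays missing
  expect_true(all(is.na(imp$assignment[c("x", "y")])))
  # observed assignments are never overwritten
  expect_equal(imp$assignment["a"], c(a = "H1"))
  expect_equal(sum(!is.na(imp$assignment)),
               sum(!is.na(asg)) + sum(imp$imputed))

  # discordant genotyped members
  asg2 <- c(a = "H1", b = "H2", c = NA, d = NA, e = NA, x = NA, y = NA)
  expect_message(lm_ <- imputeHaplotypes(asg2, ped, conflict = "leave_missing"),
                 "discordant")
  expect_true(all(is.na(lm_$assignment[c("c", "d", "e")])))
  expect_equal(nrow(lm_$conflicts), 1L)
  expect_error(suppressMessages(imputeHaplotypes(asg2, ped, conflict = "abort")),
               "discordant")
  asg3 <- c(a = "H1", b = "H2", c = "H1", d = NA, e = NA, x = NA, y = NA)
  mj <- suppressMessages(imputeHaplotypes(asg3, ped, conflict = "majority"))
  expect_equal(unname(mj$assignment["d"]), "H1")
  expect_equal(unname(mj$assignment["b"]), "H2")  # observed kept
})
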