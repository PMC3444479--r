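test_that("branch genotypes are haploid 0/1 with missing propagated", {
  fx <- tinyScanFixture()
  p <- fx$partitions[[1]]
  asg <- stats::setNames(fx$subjects$haplotype, fx$subjects$subject_id)
  g <- branchGenotypes(p, asg)
  expect_equal(sum(g == 0, na.rm = TRUE) + sum(g == 1, na.rm = TRUE), 7L)

  asg2 <- asg; asg2["s3"] <- NA
  g2 <- branchGenotypes(p, asg2)
  expect_true(is.na(g2["s3"]))

  allA <- branchGenotypes(p, stats::setNames(rep(p@sideA[1], 5),
                                             paste0("x", 1:5)))
  expect_equal(unname(allA), rep(0, 5))

  split <- branchGenotypes(p, stats::setNames(
    c(rep(p@sideA[1], 10), rep(p@sideB[1], 28)), paste0("x", 1:38)))
  expect_equal(sum(split), 28)
})

test_that("eligibility requires both phenotyped classes at the minimum size", {
  phen <- c(rep(0, 100), rep(1, 10))
  expect_false(isEligible(c(rep(0, 4), rep(1, 106)), phen, 5))
  expect_true(isEligible(c(rep(0, 5), rep(1, 105)), phen, 5))
  expect_false(isEligible(rep(1, 110), phen, 5))
  # missing phenotypes do not count towards class sizes
  g <- c(rep(0, 5), rep(1, 5))
  y <- c(rep(NA, 3), 0, 1, 0, 1, 0, 1, 0)
  expect_false(isEligible(g, y, 5))
})

test_that("the plain LRT equals the closed-form G on 2x2 tables", {
  set.seed(101)
  checked <- 0L
  while (checked < 50L) {
    n0 <- sample(8:60, 1); n1 <- sample(8:60, 1)
    g <- rep(c(0, 1), c(n0, n1))
    y <- rbinom(n0 + n1, 1, runif(1, 0.2, 0.8))
    O <- table(g, y)
    if (any(dim(O) < 2) || any(O == 0)) next
    st <- branchStatistic(g, y, flavor = "lrt")
    expect_equal(st$statistic, gStatistic(g, y), tolerance = 1e-6)
    checked <- checked + 1L
  }
})

test_that("the LRT with covariates matches glm, and symmetry gives 0", {
  set.seed(5)
  g <- rep(c(0, 1), c(30, 25))
  x <- rnorm(55)
  y <- rbinom(55, 1, plogis(-0.5 + 0.8 * x + 0.6 * g))
  st <- branchStatistic(g, y, covariates = cbind(x = x), flavor = "lrt")
  m1 <- glm(y ~ x + g, family = binomial)
  m0 <- glm(y ~ x, family = binomial)
  expect_equal(st$statistic, m0$deviance - m1$deviance, tolerance = 1e-5)

  # identical case/control composition in both classes: statistic ~ 0
  g <- rep(c(0, 1), each = 10)
  y <- rep(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), 2)
  expect_lt(branchStatistic(g, y, flavor = "lrt")$statistic, 1e-8)
})

test_that("the Firth statistic stays finite under complete separation", {
  g <- rep(c(0, 1), c(40, 15))
  set.seed(9)
  y <- c(rbinom(40, 1, 0.4), rep(0, 15))   # all carriers are controls
  st <- branchStatistic(g, y, flavor = "firth_lrt")
  expect_true(is.finite(st$statistic))
  expect_gt(st$statistic, 0)
  expect_lt(st$coef, 0)                    # protective direction

  expect_error(branchStatistic(rep(1, 20), rbinom(20, 1, .5)),
               "zero-variance")
})

test_that("exhaustive permutation scan equals the enumeration oracle", {
  fx <- tinyScanFixture(status = c(1, 1, 0, 0, 0, NA, 1))
  cfg <- scanConfig(B = 1, minClassSize = 2, covariates = character(0),
                    flavor = "lrt", exhaustive = TRUE, seed = 7)
  res <- permutationScan(fx$network, fx$subjects, cfg,
                         partitions = fx$partitions)
  tb <- scanTable(res)

  asg <- fx$subjects$haplotype
  y <- fx$subjects$status
  gv <- lapply(fx$partitions, function(p)
    ifelse(asg %in% p@sideB, 1, ifelse(asg %in% p@sideA, 0, NA)))
  elig <- vapply(gv, function(g) {
    ok <- !is.na(g) & !is.na(y)
    sum(ok & g == 0) >= 2 && sum(ok & g == 1) >= 2
  }, TRUE)
  oracle <- exhaustiveScanOracle(gv[elig], y, gStatistic)
  expect_equal(tb$nominalP[tb$tested], oracle$nominal)
  expect_equal(tb$correctedP[tb$tested], oracle$corrected)

  # a second composition with both branches eligible
  fx2 <- tinyScanFixture(status = c(1, 0, 1, 0, 1, 0, 0))
  res2 <- permutationScan(fx2$network, fx2$subjects, cfg,
                          partitions = fx2$partitions)
  tb2 <- scanTable(res2)
  y2 <- fx2$subjects$status
  gv2 <- lapply(fx2$partitions, function(p)
    ifelse(asg %in% p@sideB, 1, ifelse(asg %in% p@sideA, 0, NA)))
  oracle2 <- exhaustiveScanOracle(gv2, y2, gStatistic)
  expect_equal(tb2$nominalP[tb2$tested], oracle2$nominal)
  expect_equal(tb2$correctedP[tb2$tested], oracle2$corrected)
})

test_that("corrected p-values dominate nominal and are step-down monotone", {
  co <- simulateCohort(toyParams(seed = 8, baselineCaseRate = 0.3))
  prep <- prepareScan(co@variantTable, co@pedigree,
    co@subjects[, c("subject_id", "status", "age", "sex",
                    "apoe_e4", "apoe_e2", "genotyped")],
    co@reference, famrisk = FALSE,
    genotypedIds = co@subjects$subject_id[co@subjects$genotyped])
  res <- permutationScan(prep$network, prep$subjects,
                         scanConfig(B = 200, seed = 4))
  tb <- scanTable(res)
  tt <- tb[tb$tested, ]
  expect_true(all(tt$correctedP >= tt$nominalP - 1e-12))
  ord <- order(tt$nominalP, -tt$statistic)
  expect_true(all(diff(tt$correctedP[ord]) >= -1e-12))
  expect_true(all(tt$nominalP > 0 & tt$nominalP <= 1))
  # a branch with statistic 0 can never beat the permutation distribution
  zero <- tt[tt$statistic < 1e-12, ]
  if (nrow(zero)) expect_true(all(zero$nominalP == 1))
})

test_that("scans are reproducible for a fixed seed", {
  fx <- tinyScanFixture(status = c(1, 0, 1, 0, 1, 0, 0))
  cfg <- scanConfig(B = 99, minClassSize = 2, covariates = character(0),
                    flavor = "lrt", seed = 31)
  r1 <- permutationScan(fx$network, fx$subjects, cfg, partitions = fx$partitions)
  r2 <- permutationScan(fx$network, fx$subjects, cfg, partitions = fx$partitions)
  expect_identical(scanTable(r1), scanTable(r2))
})

test_that("conditioning marks collinear branches degenerate and absorbs
           the shared signal of nested branches", {
  # strong planted protection at toy scale so round 1 finds the clade and
  # its correlated neighbour
  co <- simulateCohort(toyParams(seed = 21, beta = -Inf,
                                 effectClade = "auto", targetCarriers = 25,
                                 baselineCaseRate = 0.35))
  prep <- prepareScan(co@variantTable, co@pedigree,
    co@subjects[, c("subject_id", "status", "age", "sex",
                    "apoe_e4", "apoe_e2", "genotyped")],
    co@reference, famrisk = FALSE,
    genotypedIds = co@subjects$subject_id[co@subjects$genotyped])
  parts <- enumeratePartitions(prep$network)
  names(parts) <- vapply(parts, function(p) p@branch, "")
  cfg <- scanConfig(B = 400, seed = 21)
  r1 <- permutationScan(prep$network, prep$subjects, cfg, partitions = parts)
  sig1 <- significantBranches(r1)
  expect_gt(length(sig1), 1L)

  rounds <- conditionalScan(r1, prep$network, prep$subjects, cfg,
                            partitions = parts)
  expect_gte(length(rounds), 1L)
  r2 <- rounds[[1]]
  tb2 <- scanTable(r2)
  top <- r2@conditionedOn[1]
  # the conditioned branch itself is flagged degenerate, not retested
  expect_true(tb2$degenerate[tb2$branch == top])
  # branches carrying the same clade signal lose round-1 significance
  asg <- stats::setNames(prep$subjects$haplotype, prep$subjects$subject_id)
  carTop <- names(which(branchGenotypes(parts[[top]], asg) == 1))
  overlapping <- vapply(sig1[sig1 != top], function(b) {
    carB <- names(which(branchGenotypes(parts[[b]], asg) == 1))
    length(intersect(carB, carTop)) / min(length(carB), length(carTop)) > 0.8
  }, TRUE)
  if (any(overlapping)) {
    still <- significantBranches(r2)
    expect_true(all(!(sig1[sig1 != top][overlapping] %in% still)))
  }
})
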