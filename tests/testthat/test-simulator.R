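test_that("topology builders honour their contracts", {
  ch <- simulateTruth(simulationConfig(topology = "chain", nClones = 1,
                                       nSnvs = 10, nCells = 0, seed = 1))
  expect_identical(nodePaths(ch$tree), c("0", "0.1"))
  expect_true(all(ch$z == "0.1")) # one clone: all SNVs co-clustered
  expect_equal(unname(ch$phi["0.1", 1]), unname(ch$eta["0.1", 1]))

  cy <- simulateTruth(simulationConfig(topology = "cherry", nSnvs = 10,
                                       nCells = 0, seed = 2))
  expect_identical(nodePaths(cy$tree), c("0", "0.1", "0.1.1", "0.1.2"))
  mf <- simulateTruth(simulationConfig(topology = "multifurcating",
                                       branchFactor = 3, nSnvs = 10,
                                       nCells = 0, seed = 3))
  expect_identical(nodeChildren(mf$tree, "0.1"),
                   c("0.1.1", "0.1.2", "0.1.3"))
  bi <- simulateTruth(simulationConfig(topology = "binary", depth = 2,
                                       nSnvs = 10, nCells = 0, seed = 4))
  expect_equal(nNodes(bi$tree), 8) # root + progenitor + 2 + 4
  # every non-root clone receives at least one SNV when feasible
  expect_true(all(table(factor(mf$z, levels = c("0.1", "0.1.1", "0.1.2",
                                                "0.1.3"))) >= 1))
  expect_warning(simulateTruth(simulationConfig(topology = "binary",
                                                depth = 2, nSnvs = 3,
                                                nCells = 0, seed = 5)),
                 "fewer SNVs")
})

test_that("cell-to-clone draws follow the region-1 clone fractions", {
  tt <- simulateTruth(simulationConfig(topology = "cherry", nSnvs = 8,
                                       nCells = 10000, seed = 7))
  freq <- table(factor(tt$zeta, levels = nodePaths(tt$tree))) / 10000
  for (p in nodePaths(tt$tree)) {
    se <- sqrt(tt$eta[p, 1] * (1 - tt$eta[p, 1]) / 10000)
    expect_lt(abs(freq[[p]] - tt$eta[p, 1]), 3.5 * se + 1e-3)
  }
  # mu is consistent with tree ancestry
  for (c in c(1, 500, 9999)) {
    expect_identical(tt$mu[c, ],
                     stats::setNames(mutationStatus(tt$tree, tt$z, tt$zeta[c]),
                                     tt$snvIds))
  }
})

test_that("copy-number evolution starts diploid and tracks allele copies", {
  cfg0 <- simulationConfig(topology = "cherry", nSnvs = 12, nCells = 0,
                           cnvEnabled = FALSE, seed = 11)
  tt <- simulateTruth(cfg0)
  cn0 <- simulateCopyNumber(tt, cfg0)
  # rates are irrelevant when disabled: everything stays (1,1,1)
  carriers <- t(vapply(seq_along(tt$z), function(n)
    scCloneTree:::.path_is_anc(tt$z[n], nodePaths(tt$tree)),
    logical(nNodes(tt$tree))))
  expect_true(all(cn0$vCopies[carriers] == 1))
  expect_true(all(cn0$tCopies[carriers] == 2))
  expect_true(all(cn0$vCopies[!carriers] == 0))
  expect_identical(cn0$majorCn, rep(1L, 12))

  cfgc <- simulationConfig(topology = "chain", nClones = 3, nSnvs = 30,
                           nCells = 0, cnvEnabled = TRUE,
                           cnvBirthRate = 0.8, cnvDeathRate = 0.4, seed = 13)
  ttc <- simulateTruth(cfgc)
  cnc <- simulateCopyNumber(ttc, cfgc)
  expect_true(all(cnc$tCopies >= 1))
  expect_true(all(cnc$vCopies <= cnc$tCopies))
  # the origin clone itself is untouched
  for (n in seq_along(ttc$z))
    expect_identical(c(cnc$vCopies[n, ttc$z[n]], cnc$tCopies[n, ttc$z[n]]),
                     c(1L, 2L))
  # events do occur somewhere at these rates
  expect_gt(sum(cnc$tCopies != 2), 0)
})

test_that("per-edge copy-number event frequencies match the stated rates", {
  # on a 3-clone chain the edge below the origin changes the state with
  # probability pb + (1-pb) pd (one birth-or-death attempt per edge)
  cfg <- simulationConfig(topology = "chain", nClones = 2, nSnvs = 400,
                          nCells = 0, cnvEnabled = TRUE,
                          cnvBirthRate = 0.2, cnvDeathRate = 0.1, seed = 17)
  tt <- simulateTruth(cfg)
  cn <- simulateCopyNumber(tt, cfg)
  pb <- 1 - exp(-0.2); pd <- (1 - pb) * (1 - exp(-0.1))
  origin1 <- which(tt$z == "0.1")
  changed <- vapply(origin1, function(n) {
    cn$tCopies[n, "0.1.1"] != 2L || cn$vCopies[n, "0.1.1"] != 1L
  }, logical(1))
  # note: a death that removes a non-variant parental-A copy is invisible
  # in (v, c(total)) only if ... it always changes total copy, so every
  # event is visible
  p_event <- pb + pd
  se <- sqrt(p_event * (1 - p_event) / length(origin1))
  expect_lt(abs(mean(changed) - p_event), 3.5 * se)
})

test_that("bulk generation matches the success-probability oracle", {
  # phi = 0 with eps ~ 0: no variant reads
  cfg <- simulationConfig(topology = "chain", nClones = 1, nSnvs = 20,
                          nCells = 0, eps = 1e-9, seed = 19)
  tt <- simulateTruth(cfg)
  tt$eta[, 1] <- c(1, 0); tt$phi <- prevalenceFromFractions(tt$tree, tt$eta)
  bk <- simulateBulk(tt, NULL, cfg)
  expect_true(all(bk@b == 0L))
  # clonal SNV at phi = 1: VAF concentrates at 1/2
  tt$eta[, 1] <- c(0, 1); tt$phi <- prevalenceFromFractions(tt$tree, tt$eta)
  cfg2 <- simulationConfig(topology = "chain", nClones = 1, nSnvs = 20,
                           nCells = 0, meanBulkDepth = 10000, eps = 1e-9,
                           seed = 23)
  bk2 <- simulateBulk(tt, NULL, cfg2)
  vaf <- bk2@b[, 1] / bk2@d[, 1]
  se <- sqrt(0.25 / bk2@d[, 1])
  expect_true(all(abs(vaf - 0.5) < 4 * se))
  # across random prevalences the empirical VAF tracks theta
  cfg3 <- simulationConfig(topology = "cherry", nSnvs = 1000, nCells = 0,
                           meanBulkDepth = 2000, seed = 29)
  tt3 <- simulateTruth(cfg3)
  bk3 <- simulateBulk(tt3, NULL, cfg3)
  th <- thetaSuccess(1, 2, tt3$phi[tt3$z, 1], 0.001)
  dev <- bk3@b[, 1] / bk3@d[, 1] - th
  expect_lt(mean(abs(dev)), 3 * mean(sqrt(th * (1 - th) / bk3@d[, 1])))
})

test_that("single-cell generation respects coverage and bursting", {
  cfg <- simulationConfig(topology = "cherry", nSnvs = 50, nCells = 200,
                          pCov = 0.1, seed = 31)
  tt <- simulateTruth(cfg)
  sc <- simulateScRna(tt, cfg)
  frac <- length(sc@tot@x) / prod(dim(sc@tot))
  se <- sqrt(0.1 * 0.9 / prod(dim(sc@tot)))
  expect_lt(abs(frac - 0.1), 3.5 * se)
  # mono-allelic extremity: delta0 = 0 with tiny symmetric shapes puts
  # b at 0 or d almost always (Beta(0.01, 0.01) tail mass)
  cfgm <- simulationConfig(topology = "chain", nClones = 1, nSnvs = 40,
                           nCells = 150, pCov = 1, meanScDepth = 20,
                           delta0 = 0, seed = 37)
  ttm <- simulateTruth(cfgm)
  ttm$eta[, 1] <- c(0, 1); ttm$phi <- prevalenceFromFractions(ttm$tree, ttm$eta)
  ttm$zeta[] <- "0.1"; ttm$mu[] <- 1L
  scm <- simulateScRna(ttm, cfgm)
  b <- scm@var@x; d <- scm@tot@x
  extreme <- mean(b == 0 | b == d)
  expect_gt(extreme, 0.95)
  # both mono-allelic directions occur
  expect_gt(sum(b == 0), 0)
  expect_gt(sum(b == d & d > 0), 0)
})

test_that("generated data are self-consistent with the likelihood", {
  # scoring at the true prevalences beats a perturbed phi most of the time
  set.seed(41)
  wins <- 0L
  for (rep in 1:40) {
    cfg <- simulationConfig(topology = "chain", nClones = 2, nSnvs = 30,
                            nCells = 0, meanBulkDepth = 500, seed = 1000 + rep)
    sim <- simulateCloneData(cfg)
    tt <- sim$truth
    lltrue <- sum(vapply(1:30, function(n)
      bulkSiteLoglik(sim$bulk@b[n, ], sim$bulk@d[n, ], 1, 1,
                     tt$phi[tt$z[n], ], 0.001), numeric(1)))
    shift <- ifelse(tt$phi[, 1] > 0.5, -0.2, 0.2)
    phip <- pmin(pmax(tt$phi[, 1] + shift, 0), 1)
    llpert <- sum(vapply(1:30, function(n)
      bulkSiteLoglik(sim$bulk@b[n, ], sim$bulk@d[n, ], 1, 1,
                     phip[tt$z[n]], 0.001), numeric(1)))
    if (lltrue > llpert) wins <- wins + 1L
  }
  expect_gte(wins, 38)
})

test_that("the average generated score matches the model entropy rate", {
  # generator and likelihood agree: the mean per-entry log-likelihood of
  # mutated-locus counts converges to the negative entropy of the
  # Beta-Binomial mixture (Monte-Carlo, mutated cells only)
  set.seed(43)
  d <- 12L
  hyper <- scRnaHyperparams(alphaN = 1.4, betaN = 0.7, delta0 = 0.5)
  nmc <- 30000
  bi <- runif(nmc) < 0.5
  chi <- ifelse(bi, rbeta(nmc, 1.4, 0.7), rbeta(nmc, 0.01, 0.01))
  b <- rbinom(nmc, d, chi)
  ll <- scSiteLoglik(b, rep(d, nmc), 1, hyper)
  exact <- -sum(vapply(0:d, function(k) {
    p <- exp(scSiteLoglik(k, d, 1, hyper))
    p * log(p)
  }, numeric(1)))
  se <- sd(ll) / sqrt(nmc)
  expect_lt(abs(mean(ll) + exact), 3 * se)
})

test_that("simulation output is byte-identical under a fixed seed", {
  s1 <- quick_sim(topology = "cherry", nSnvs = 15, nCells = 10, seed = 47)
  s2 <- quick_sim(topology = "cherry", nSnvs = 15, nCells = 10, seed = 47)
  expect_identical(s1$truth$z, s2$truth$z)
  expect_identical(s1$bulk@b, s2$bulk@b)
  expect_identical(s1$sc@var, s2$sc@var)
  f1 <- tempfile(); f2 <- tempfile()
  writeBulkTable(s1$bulk, f1); writeBulkTable(s2$bulk, f2)
  expect_identical(readLines(f1), readLines(f2))
})
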