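# Correctness of the MCMC transition kernels, MAP extraction and the
# posterior cell-to-clone mapping.

make_bulk_state <- function(bulk, config = samplerConfig(seed = 1),
                            tssb = tssbHyperparams()) {
  scCloneTree:::.state_init(bulk, NULL, tssb, scRnaHyperparams(), config)
}

test_that("slice updates target the enumerated conditional distribution", {
  bulk <- toy_bulk(n = 1)
  set.seed(55)
  st <- make_bulk_state(bulk)
  # fixture: progenitor with two children, sticks set by hand so all
  # three nodes carry equal prior mass (1/3 each, nothing unbroken)
  st$psi[["0.1"]] <- c(0.5, 1)
  scCloneTree:::.tssb_add_child(st, "0.1", st$hyper_t, st$on_create)
  scCloneTree:::.tssb_add_child(st, "0.1", st$hyper_t, st$on_create)
  st$nu[["0.1"]] <- 1 / 3
  st$nu[["0.1.1"]] <- 1; st$nu[["0.1.2"]] <- 1
  scCloneTree:::.state_masses(st)
  expect_equal(unname(st$pi[c("0.1", "0.1.1", "0.1.2")]), rep(1 / 3, 3))
  w <- c("0.1" = 0.1, "0.1.1" = 0.2, "0.1.2" = 0.7)
  logw <- function(v) if (v %in% names(w)) log(w[[v]]) else -Inf
  hits <- c("0.1" = 0, "0.1.1" = 0, "0.1.2" = 0)
  nmc <- 10000
  for (i in seq_len(nmc)) {
    scCloneTree:::.state_slice_move(st, 1L, logw_fn = logw)
    hits[st$z[1]] <- hits[st$z[1]] + 1
  }
  freq <- hits / nmc
  se <- sqrt(w * (1 - w) / nmc)
  expect_true(all(abs(freq - w) < 3.5 * se + 0.01))
})

test_that("a single permissible node leaves the assignment unchanged", {
  bulk <- toy_bulk(n = 3)
  set.seed(77)
  st <- make_bulk_state(bulk)
  for (i in 1:50) scCloneTree:::.state_slice_move(
    st, 1L, logw_fn = function(v) if (v == "0.1") 0 else -Inf)
  expect_identical(st$z[1], "0.1")
})

test_that("stick Gibbs updates use the conjugate Beta posteriors", {
  # all N SNVs on the progenitor, lambda0 = 1, lambda = 1:
  # nu(progenitor) ~ Beta(1 + N, 1); mean approaches 1 with N
  N <- 40L
  bulk <- toy_bulk(n = N)
  st <- make_bulk_state(bulk, tssb = tssbHyperparams(1, 1, 1))
  set.seed(91)
  nus <- replicate(4000, {
    scCloneTree:::.state_gibbs_sticks(st)
    st$nu[["0.1"]]
  })
  expect_lt(abs(mean(nus) - (1 + N) / (2 + N)), 3 * sd(nus) / sqrt(4000) + 1e-3)

  # counts (3 left, 1 right) at a binary split with gamma = 1:
  # psi_1 ~ Beta(4, 2)
  bulk2 <- toy_bulk(n = 4)
  set.seed(92)
  st2 <- make_bulk_state(bulk2)
  st2$psi[["0.1"]] <- c(0.5, 0.8)
  scCloneTree:::.tssb_add_child(st2, "0.1", st2$hyper_t, st2$on_create)
  scCloneTree:::.tssb_add_child(st2, "0.1", st2$hyper_t, st2$on_create)
  st2$z <- c("0.1.1", "0.1.1", "0.1.1", "0.1.2")
  scCloneTree:::.state_rebuild(st2)
  psis <- replicate(4000, {
    scCloneTree:::.state_gibbs_sticks(st2)
    st2$psi[["0.1"]][1]
  })
  expect_lt(abs(mean(psis) - 4 / 6), 3 * sd(psis) / sqrt(4000) + 1e-3)
  expect_lt(abs(var(psis) - 4 * 2 / (36 * 7)), 0.005)

  # a data-free subtree draws its sticks from the prior
  set.seed(93)
  st3 <- make_bulk_state(toy_bulk(n = 2), tssb = tssbHyperparams(2, 0.5, 1))
  st3$psi[["0.1"]] <- 0.5
  scCloneTree:::.tssb_add_child(st3, "0.1", st3$hyper_t, st3$on_create)
  scCloneTree:::.state_rebuild(st3) # both SNVs stay on the progenitor
  prior_draws <- replicate(3000, {
    scCloneTree:::.state_gibbs_sticks(st3)
    st3$nu[["0.1.1"]]
  })
  direct <- rbeta(3000, 1, 2 * 0.5^2)
  expect_gt(stats::ks.test(prior_draws, direct)$p.value, 1e-4)
})

test_that("likelihood-free prevalence updates recover the flat Dirichlet prior", {
  # zero-depth bulk data: the MH chain on the clone fractions must be
  # invariant for the uniform distribution on the simplex
  N <- 4L
  bulk <- BulkData(paste0("s", 1:N), matrix(0L, N, 1), matrix(0L, N, 1),
                   rep(1L, N), rep(1L, N))
  set.seed(101)
  st <- make_bulk_state(bulk)
  st$psi[["0.1"]] <- c(0.5, 0.8)
  scCloneTree:::.tssb_add_child(st, "0.1", st$hyper_t, st$on_create)
  scCloneTree:::.tssb_add_child(st, "0.1", st$hyper_t, st$on_create)
  # put one SNV on each non-root node so all four nodes are active (the
  # clone-fraction simplex spans active nodes only)
  st$z <- c("0.1", "0.1.1", "0.1.2", "0.1")
  scCloneTree:::.state_rebuild(st)
  scCloneTree:::.state_gibbs_sticks(st)
  st$iter <- Inf # freeze proposal adaptation
  st$mh_accept <- 0L; st$mh_total <- 0L
  etas <- matrix(NA_real_, 3000, 4)
  for (i in seq_len(nrow(etas))) {
    for (k in 1:3) scCloneTree:::.state_mh_eta(st)
    etas[i, ] <- scCloneTree:::.eta_from_phi_col(
      st, stats::setNames(st$phi[st$paths, 1], st$paths))
  }
  # Dirichlet(1,1,1,1): mean 1/4, var 3/80
  sem <- apply(etas, 2, sd) / sqrt(nrow(etas) / 10) # thin-adjusted
  expect_true(all(abs(colMeans(etas) - 0.25) < 3 * sem + 0.01))
  expect_true(all(abs(apply(etas, 2, var) - 3 / 80) < 0.012))
})

test_that("single-clone prevalence update is an identity on eta", {
  bulk <- toy_bulk(n = 2)
  set.seed(7)
  st <- make_bulk_state(bulk)
  # two nodes: root and progenitor; eta = (1 - phi, phi) stays a valid
  # 2-simplex point and the chain remains in it
  for (i in 1:20) scCloneTree:::.state_mh_eta(st)
  eta <- scCloneTree:::.eta_from_phi_col(
    st, stats::setNames(st$phi[st$paths, 1], st$paths))
  expect_equal(sum(eta), 1, tolerance = 1e-12)
  expect_true(all(eta >= 0))
})

test_that("the sampler is deterministic under a fixed seed", {
  sim <- quick_sim(topology = "cherry", nSnvs = 12, nCells = 10, seed = 19)
  cfg <- samplerConfig(nIterations = 40, burnIn = 20, seed = 123)
  f1 <- runCloneMCMC(sim$bulk, sim$sc, scHyper = sim$scHyper, config = cfg)
  f2 <- runCloneMCMC(sim$bulk, sim$sc, scHyper = sim$scHyper, config = cfg)
  expect_identical(mcmcTrace(f1), mcmcTrace(f2))
  expect_identical(f1@z, f2@z)
  expect_identical(f1@prevalence@phi, f2@prevalence@phi)
})

test_that("zero cells reduce the sampler to the bulk-only TSSB mode", {
  sim <- quick_sim(topology = "cherry", nSnvs = 12, nCells = 0, seed = 23)
  cfg <- samplerConfig(nIterations = 30, burnIn = 10, seed = 5)
  f_null <- runCloneMCMC(sim$bulk, NULL, config = cfg)
  f_empty <- runCloneMCMC(sim$bulk, sim$sc, config = cfg) # 0-row matrix
  expect_identical(mcmcTrace(f_null), mcmcTrace(f_empty))
  expect_identical(f_null@z, f_empty@z)
})

test_that("the cached log joint matches a from-scratch recomputation", {
  sim <- quick_sim(topology = "cherry", nSnvs = 15, nCells = 12, seed = 29)
  fit <- runCloneMCMC(sim$bulk, sim$sc, scHyper = sim$scHyper,
                      config = samplerConfig(nIterations = 60, burnIn = 30,
                                             seed = 31))
  for (s in fit@samples[c(1, 15, 30)]) {
    tree <- ClonalTree(s$paths, nu = s$nu, psi = s$psi)
    fresh <- logJointScore(tree, s$z, s$phi, sim$bulk, sim$sc, sim$scHyper)
    expect_equal(s$logJoint, fresh, tolerance = 1e-8)
  }
})

test_that("MAP extraction returns the highest-scoring retained sample", {
  fake <- list(list(logJoint = -10, iteration = 1),
               list(logJoint = -3, iteration = 2),
               list(logJoint = -3, iteration = 3))
  expect_identical(mapEstimate(fake)$iteration, 2) # tie -> earliest
  expect_identical(mapEstimate(fake[1])$logJoint, -10)
  expect_error(mapEstimate(list()), "no retained samples")
  # equals the argmax of independently rescored samples
  sim <- quick_sim(topology = "chain", nClones = 2, nSnvs = 10, nCells = 8,
                   seed = 37)
  fit <- runCloneMCMC(sim$bulk, sim$sc, scHyper = sim$scHyper,
                      config = samplerConfig(nIterations = 50, burnIn = 25,
                                             seed = 41))
  rescored <- vapply(fit@samples, function(s) {
    tree <- ClonalTree(s$paths, nu = s$nu, psi = s$psi)
    logJointScore(tree, s$z, s$phi, sim$bulk, sim$sc, sim$scHyper)
  }, numeric(1))
  expect_equal(mapEstimate(fit)$logJoint, max(rescored), tolerance = 1e-8)
})

test_that("cell assignment posteriors match per-cell enumeration", {
  sim <- quick_sim(topology = "cherry", nSnvs = 10, nCells = 20, seed = 43,
                   pCov = 0.4)
  tr <- sim$truth$tree
  fitlike <- list(paths = nodePaths(tr), z = sim$truth$z,
                  nu = numeric(0), psi = list())
  ca <- assignCells(fitlike, sim$sc, sim$scHyper)
  prob <- assignmentProb(ca)
  expect_equal(unname(rowSums(prob)), rep(1, 20))
  for (c in c(1, 7, 13)) {
    b <- as.numeric(sim$sc@var[c, ]); d <- as.numeric(sim$sc@tot[c, ])
    lls <- vapply(nodePaths(tr), function(v)
      cellCloneLoglik(tr, sim$truth$z, v, b, d, sim$scHyper), numeric(1))
    expect_equal(unname(prob[c, ]), unname(exp(lls - max(lls)) /
                                             sum(exp(lls - max(lls)))),
                 tolerance = 1e-9)
  }
  # a cell with no covered loci gets a uniform posterior and maps to the
  # shallowest node (tie-break)
  scz <- toy_sc(c("u1"), colnames(sim$sc@tot), character(0), character(0),
                integer(0), integer(0))
  ca0 <- assignCells(fitlike, scz, sim$scHyper)
  expect_equal(unname(assignmentProb(ca0)[1, ]),
               rep(0.25, 4))
  expect_identical(unname(mapClone(ca0)), "0")
  # predicted mutation status comes from the argmax clone
  expect_identical(ca@muHat[1, ],
                   stats::setNames(mutationStatus(tr, sim$truth$z,
                                                  mapClone(ca)[1]),
                                   colnames(sim$sc@tot)))
})

test_that("cells carrying only ancestral variants map to the ancestral clone", {
  tr <- cherry_tree()
  snvs <- paste0("s", 1:6)
  z <- stats::setNames(c("0.1", "0.1", "0.1.1", "0.1.1", "0.1.2", "0.1.2"), snvs)
  hyper <- scRnaHyperparams(alphaN = 1, betaN = 1, delta0 = 0.5)
  # strong variant evidence at the two progenitor SNVs, reference reads at
  # the subclone SNVs
  sc <- toy_sc("cellA", snvs, rep("cellA", 6), snvs,
               b = c(8, 7, 0, 0, 0, 0), d = c(8, 8, 6, 6, 6, 6))
  ca <- assignCells(list(paths = nodePaths(tr), z = z,
                         nu = numeric(0), psi = list()), sc, hyper)
  expect_identical(unname(mapClone(ca)), "0.1")
})
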