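# Small fixtures shared across tests; everything is built in code.

# chain healthy-root -> progenitor -> subclone
chain3_tree <- function() ClonalTree(c("0", "0.1", "0.1.1"))

# cherry: progenitor with two sibling subclones
cherry_tree <- function() ClonalTree(c("0", "0.1", "0.1.1", "0.1.2"))

# a tree with sticks fully specified (for stick-mass computations)
tree_with_sticks <- function(paths, nu, psi) {
  ClonalTree(paths, nu = nu, psi = psi)
}

# tiny deterministic bulk dataset on a given assignment
toy_bulk <- function(n = 4, regions = 1) {
  b <- matrix(25L, n, regions); d <- matrix(100L, n, regions)
  BulkData(sprintf("s%02d", seq_len(n)), b, d,
           majorCn = rep(1L, n), minorCn = rep(1L, n))
}

# sparse single-cell counts from explicit triplets
toy_sc <- function(cells, snvs, cellId, snvId, b, d) {
  ScVariantData(cellId, snvId, b, d,
                snvIds = snvs, cellIds = cells)
}

# quadrature oracle for the Beta-Binomial pmf: E_Beta[ Binomial(b; d, P) ]
# via the probability integral transform, which removes the endpoint
# singularities of small-shape Beta densities
bb_quad <- function(b, d, a, bshape) {
  f <- function(u) stats::dbinom(b, d, stats::qbeta(u, a, bshape))
  stats::integrate(f, 0, 1, rel.tol = 1e-11, subdivisions = 1000L)$value
}

# brute-force marginal single-cell log-likelihood by enumerating every
# cell-to-clone assignment (independent of the package's caching paths)
brute_sc_marginal <- function(tree, z, sc, hyper) {
  paths <- nodePaths(tree)
  C <- nrow(sc@var)
  if (C == 0) return(0)
  total <- 0
  for (c in seq_len(C)) {
    b <- as.numeric(sc@var[c, ]); d <- as.numeric(sc@tot[c, ])
    lls <- vapply(paths, function(v) {
      mu <- mutationStatus(tree, z, v)
      cov <- which(d > 0)
      if (!length(cov)) return(0)
      sum(vapply(cov, function(n) scSiteLoglik(b[n], d[n], mu[n], hyper, n),
                 numeric(1)))
    }, numeric(1))
    m <- max(lls)
    total <- total + m + log(mean(exp(lls - m)))
  }
  total
}

quick_sim <- function(...) simulateCloneData(simulationConfig(...))
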