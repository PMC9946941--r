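#' Simulation configuration
#'
#' Settings of the generative simulator matched to the observation model.
#' Defaults emulate a Smart-Seq3-like design: sparse coverage (each cell
#' covers a locus with probability \code{pCov}), covered loci carrying a
#' shifted-Poisson read depth, bursty mono-allelic expression
#' (\code{alpha0 = beta0 = 0.01}) mixed with locus-specific bi-allelic
#' expression (Beta shapes drawn per SNV), bulk depth around 1000x, and
#' cellular prevalences induced by flat-Dirichlet clone fractions.
#'
#' @param topology one of "multifurcating" (progenitor with
#'   \code{branchFactor} children), "cherry" (progenitor with 2 children),
#'   "chain" (path of \code{nClones} cancer clones), "binary" (complete
#'   binary tree of \code{depth} levels under the progenitor), or "tssb"
#'   (drawn from the TSSB prior).
#' @param nSnvs number of SNVs.
#' @param nCells number of single cells (0 for bulk-only data).
#' @param nRegions number of bulk regions (region-specific clone fractions).
#' @param nClones chain length for \code{topology = "chain"}.
#' @param branchFactor children of the progenitor for "multifurcating".
#' @param depth binary-tree depth below the progenitor for "binary".
#' @param meanBulkDepth mean bulk depth (negative binomial).
#' @param bulkDispersion negative binomial size parameter.
#' @param pCov probability that a cell has any reads at a locus.
#' @param meanScDepth mean total reads at a covered (cell, locus).
#' @param cnvEnabled simulate copy-number evolution by a birth-death
#'   process along tree edges.
#' @param cnvBirthRate,cnvDeathRate per-edge event rates.
#' @param delta0 prior probability of bi-allelic expression.
#' @param alpha0,beta0 mono-allelic Beta shapes.
#' @param alphaRange range of the per-SNV bi-allelic Beta shapes (drawn
#'   uniformly).
#' @param eps sequencing error probability.
#' @param tssb \code{\link{tssbHyperparams}} used when
#'   \code{topology = "tssb"}.
#' @param etaFixed optional fixed clone fractions (vector over nodes in
#'   canonical path order, recycled across regions) instead of the flat
#'   Dirichlet draw; used for designed examples with stated prevalences.
#' @param seed integer seed.
#' @return list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(topology = c("multifurcating", "cherry", "chain",
                                          "binary", "tssb"),
                             nSnvs = 100L, nCells = 100L, nRegions = 1L,
                             nClones = 3L, branchFactor = 3L, depth = 2L,
                             meanBulkDepth = 1000, bulkDispersion = 10,
                             pCov = 0.1, meanScDepth = 20,
                             cnvEnabled = FALSE, cnvBirthRate = 0.2,
                             cnvDeathRate = 0.1, delta0 = 0.5,
                             alpha0 = 0.01, beta0 = 0.01,
                             alphaRange = c(0.5, 2), eps = 0.001,
                             tssb = tssbHyperparams(), etaFixed = NULL,
                             seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(nSnvs >= 1, nCells >= 0, nRegions >= 1, pCov > 0, pCov <= 1,
            meanBulkDepth > 0, bulkDispersion > 0, meanScDepth >= 1,
            cnvBirthRate >= 0, cnvDeathRate >= 0,
            delta0 >= 0, delta0 <= 1, eps > 0, eps < 0.5)
  structure(as.list(environment()), class = "simulationConfig")
}

.sim_topology <- function(config) {
  paths <- switch(config$topology,
    cherry = c("0", "0.1", "0.1.1", "0.1.2"),
    chain = c("0", vapply(seq_len(config$nClones), function(k)
      paste(c("0", rep("1", k)), collapse = "."), character(1))),
    multifurcating = c("0", "0.1",
                       paste0("0.1.", seq_len(config$branchFactor))),
    binary = {
      p <- list("0.1")
      for (d in seq_len(config$depth)) {
        p[[d + 1L]] <- as.vector(vapply(p[[d]], function(q)
          paste0(q, ".", 1:2), character(2)))
      }
      c("0", unlist(p))
    },
    tssb = NULL)
  if (config$topology == "tssb") {
    draw <- sampleTssb(config$tssb, config$nSnvs)
    return(draw$tree)
  }
  ClonalTree(paths)
}

#' Simulate a ground-truth clonal configuration
#'
#' Builds the requested topology, draws per-region clone fractions from a
#' flat Dirichlet (healthy root included, i.e. allowing normal-cell
#' contamination), converts them to cellular prevalences by subtree sums,
#' distributes SNVs over the non-root clones (uniform multinomial after
#' guaranteeing each clone at least one SNV when feasible), and assigns
#' cells to clones by the region-1 clone fractions.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with tree, z (named by SNV id), phi and eta matrices,
#'   zeta (named by cell id), mu (cells x SNVs binary matrix), and
#'   per-SNV bi-allelic Beta shapes alphaN, betaN.
#' @export
simulateTruth <- function(config) {
  set.seed(config$seed)
  tree <- .sim_topology(config)
  paths <- nodePaths(tree)
  V <- length(paths)
  eta <- matrix(0, V, config$nRegions,
                dimnames = list(paths, paste0("R", seq_len(config$nRegions))))
  for (r in seq_len(config$nRegions)) {
    if (!is.null(config$etaFixed)) {
      stopifnot(length(config$etaFixed) == V,
                abs(sum(config$etaFixed) - 1) < 1e-9)
      eta[, r] <- config$etaFixed
    } else {
      g <- stats::rgamma(V, 1)
      eta[, r] <- g / sum(g)
    }
  }
  phi <- prevalenceFromFractions(tree, eta)
  nonroot <- setdiff(paths, "0")
  snvIds <- sprintf("snv%03d", seq_len(config$nSnvs))
  if (config$nSnvs < length(nonroot))
    warning("fewer SNVs than non-root clones: some clones will be empty")
  z <- character(config$nSnvs)
  k <- min(config$nSnvs, length(nonroot))
  z[seq_len(k)] <- nonroot[seq_len(k)]
  if (config$nSnvs > k)
    z[(k + 1L):config$nSnvs] <- sample(nonroot, config$nSnvs - k, replace = TRUE)
  z <- sample(z) # shuffle so clone blocks are not contiguous in SNV order
  names(z) <- snvIds
  cellIds <- sprintf("cell%04d", seq_len(config$nCells))
  zeta <- character(0)
  mu <- matrix(0L, config$nCells, config$nSnvs, dimnames = list(cellIds, snvIds))
  if (config$nCells > 0) {
    zeta <- sample(paths, config$nCells, replace = TRUE, prob = eta[, 1])
    names(zeta) <- cellIds
    for (c in seq_len(config$nCells))
      mu[c, ] <- mutationStatus(tree, z, zeta[c])
  }
  alphaN <- stats::runif(config$nSnvs, config$alphaRange[1], config$alphaRange[2])
  betaN <- stats::runif(config$nSnvs, config$alphaRange[1], config$alphaRange[2])
  list(tree = tree, z = z, phi = phi, eta = eta, zeta = zeta, mu = mu,
       alphaN = alphaN, betaN = betaN, snvIds = snvIds, cellIds = cellIds)
}

#' Simulate copy-number evolution along the clonal tree
#'
#' Every SNV starts from the heterozygous diploid genotype (one variant
#' copy on one of two parental alleles) in its origin clone. Along each
#' edge below the origin, at most one event occurs: a birth (duplication
#' of a uniformly chosen chromosome copy) with probability
#' 1 - exp(-cnvBirthRate) or, failing that, a death (loss of a uniformly
#' chosen copy) with probability 1 - exp(-cnvDeathRate). Events that would
#' drive the total copy number to zero are redrawn (up to 100 attempts).
#' Clones outside the origin subtree are diploid without the variant.
#'
#' @param truth output of \code{\link{simulateTruth}}.
#' @param config a \code{\link{simulationConfig}}.
#' @return list with integer matrices \code{vCopies} and \code{tCopies}
#'   (SNVs x clones: variant and total copies per clone) and per-SNV
#'   reported \code{majorCn}, \code{minorCn} (the origin clone's profile).
#' @export
simulateCopyNumber <- function(truth, config) {
  tree <- truth$tree
  paths <- nodePaths(tree)
  N <- length(truth$z)
  vC <- matrix(0L, N, length(paths), dimnames = list(names(truth$z), paths))
  tC <- matrix(2L, N, length(paths), dimnames = list(names(truth$z), paths))
  pb <- 1 - exp(-config$cnvBirthRate)
  pd <- 1 - exp(-config$cnvDeathRate)
  for (n in seq_len(N)) {
    origin <- truth$z[n]
    # state per clone: c(variant allele copies cA, other allele copies cB,
    # variant copies v <= cA)
    states <- list()
    states[[origin]] <- c(cA = 1L, cB = 1L, v = 1L)
    walk <- function(p) {
      for (kid in nodeChildren(tree, p)) {
        s <- states[[p]]
        for (try in seq_len(100L)) {
          s2 <- s
          u <- stats::runif(1)
          if (config$cnvEnabled && u < pb) { # birth
            pick <- sample.int(s2[["cA"]] + s2[["cB"]], 1L)
            if (pick <= s2[["cA"]]) {
              isvar <- stats::runif(1) < s2[["v"]] / s2[["cA"]]
              s2[["cA"]] <- s2[["cA"]] + 1L
              if (isvar) s2[["v"]] <- s2[["v"]] + 1L
            } else s2[["cB"]] <- s2[["cB"]] + 1L
          } else if (config$cnvEnabled && u < pb + pd) { # death
            pick <- sample.int(s2[["cA"]] + s2[["cB"]], 1L)
            if (pick <= s2[["cA"]]) {
              isvar <- stats::runif(1) < s2[["v"]] / s2[["cA"]]
              s2[["cA"]] <- s2[["cA"]] - 1L
              if (isvar) s2[["v"]] <- s2[["v"]] - 1L
            } else s2[["cB"]] <- s2[["cB"]] - 1L
          }
          if (s2[["cA"]] + s2[["cB"]] > 0L) break
          if (try == 100L) stop("copy-number event resampling cap exceeded")
        }
        states[[kid]] <<- s2
        walk(kid)
      }
    }
    walk(origin)
    for (p in names(states)) {
      vC[n, p] <- states[[p]][["v"]]
      tC[n, p] <- states[[p]][["cA"]] + states[[p]][["cB"]]
    }
  }
  list(vCopies = vC, tCopies = tC,
       majorCn = rep(1L, N), minorCn = rep(1L, N))
}

#' Simulate bulk DNA-seq read counts
#'
#' Depths are negative binomial around \code{meanBulkDepth}; variant reads
#' are binomial with success probability given by the clone mixture of
#' allele copies: reads are drawn from clones in proportion to clone
#' fraction times total copy number, variant copies yield variant reads
#' with probability 1 - eps and other copies with probability eps. Without
#' copy-number evolution this is exactly Binomial(d, theta((1, 2), phi,
#' eps)) at the SNV's clone prevalence.
#'
#' @param truth output of \code{\link{simulateTruth}}.
#' @param cn output of \code{\link{simulateCopyNumber}} (or NULL for
#'   diploid data).
#' @param config a \code{\link{simulationConfig}}.
#' @return A \linkS4class{BulkData}.
#' @export
simulateBulk <- function(truth, cn = NULL, config) {
  paths <- nodePaths(truth$tree)
  N <- length(truth$z)
  R <- config$nRegions
  if (is.null(cn)) {
    vC <- matrix(0L, N, length(paths), dimnames = list(names(truth$z), paths))
    tC <- matrix(2L, N, length(paths), dimnames = list(names(truth$z), paths))
    for (n in seq_len(N)) {
      carriers <- paths[.path_is_anc(truth$z[n], paths)]
      vC[n, carriers] <- 1L
    }
    M <- rep(1L, N); m <- rep(1L, N)
  } else {
    vC <- cn$vCopies; tC <- cn$tCopies
    M <- cn$majorCn; m <- cn$minorCn
  }
  b <- d <- matrix(0L, N, R)
  eps <- config$eps
  for (r in seq_len(R)) {
    etar <- truth$eta[paths, r]
    num <- (vC * (1 - eps) + (tC - vC) * eps) %*% etar
    den <- tC %*% etar
    p <- as.numeric(num / den)
    d[, r] <- stats::rnbinom(N, mu = config$meanBulkDepth,
                             size = config$bulkDispersion)
    b[, r] <- stats::rbinom(N, d[, r], p)
  }
  BulkData(names(truth$z), b, d, M, m,
           regions = paste0("R", seq_len(R)))
}

#' Simulate single-cell RNA-seq variant read counts
#'
#' Each (cell, SNV) pair is covered with probability \code{pCov}; covered
#' entries have total depth 1 + Poisson(meanScDepth - 1). At a covered
#' mutated locus the expression mode is bi-allelic with probability
#' delta0 (variant fraction Beta(alphaN, betaN)) and mono-allelic
#' otherwise (Beta(alpha0, beta0), piling mass at 0 and 1); variant reads
#' are binomial given the drawn fraction. At unmutated loci variant reads
#' arise only at the error rate eps. All five expression categories (zero
#' expression, reference/variant mono-allelic, bi-allelic, no mutation)
#' are realizable.
#'
#' @param truth output of \code{\link{simulateTruth}}.
#' @param config a \code{\link{simulationConfig}}.
#' @return An \linkS4class{ScVariantData} (cells x SNVs).
#' @export
simulateScRna <- function(truth, config) {
  C <- length(truth$cellIds); N <- length(truth$snvIds)
  ii <- integer(0); jj <- integer(0); bb <- integer(0); dd <- integer(0)
  for (c in seq_len(C)) {
    cov <- which(stats::runif(N) < config$pCov)
    if (!length(cov)) next
    dvec <- 1L + stats::rpois(length(cov), config$meanScDepth - 1)
    mu <- truth$mu[c, cov]
    chi <- numeric(length(cov))
    bi <- stats::runif(length(cov)) < config$delta0
    chi[bi] <- stats::rbeta(sum(bi), truth$alphaN[cov[bi]], truth$betaN[cov[bi]])
    chi[!bi] <- stats::rbeta(sum(!bi), config$alpha0, config$beta0)
    p <- ifelse(mu == 1L, chi, config$eps)
    bvec <- stats::rbinom(length(cov), dvec, p)
    ii <- c(ii, rep(c, length(cov))); jj <- c(jj, cov)
    bb <- c(bb, bvec); dd <- c(dd, dvec)
  }
  dm <- list(truth$cellIds, truth$snvIds)
  v <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(bb),
                            dims = c(C, N), dimnames = dm)
  t <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(dd),
                            dims = c(C, N), dimnames = dm)
  new("ScVariantData", var = v, tot = t)
}

#' Simulate a complete benchmark dataset
#'
#' Draws a ground truth (\code{\link{simulateTruth}}), optional
#' copy-number evolution, bulk read counts and single-cell read counts,
#' using a single seed for the full pipeline.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{truth}, \code{cn} (or NULL), \code{bulk}
#'   (\linkS4class{BulkData}), \code{sc} (\linkS4class{ScVariantData}),
#'   \code{scHyper} (the generating \code{\link{scRnaHyperparams}} with
#'   the per-SNV bi-allelic shapes), and \code{config}.
#' @export
simulateCloneData <- function(config) {
  truth <- simulateTruth(config)
  cn <- if (config$cnvEnabled) simulateCopyNumber(truth, config) else NULL
  bulk <- simulateBulk(truth, cn, config)
  sc <- simulateScRna(truth, config)
  hyper <- scRnaHyperparams(alpha0 = config$alpha0, beta0 = config$beta0,
                            alphaN = truth$alphaN, betaN = truth$betaN,
                            delta0 = config$delta0, eps = config$eps)
  list(truth = truth, cn = cn, bulk = bulk, sc = sc, scHyper = hyper,
       config = config)
}
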