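#' Single-cell allelic expression hyperparameters
#'
#' Hyperparameters of the Beta-Binomial mixture for single-cell variant
#' read counts at mutated loci: with probability delta0 a locus is
#' bi-allelically expressed (variant-allele fraction chi ~ Beta(alphaN,
#' betaN)), otherwise expression is mono-allelic and bursty
#' (chi ~ Beta(alpha0, beta0) with small symmetric shapes, piling mass at
#' 0 and 1). Cells without the mutation see variant reads only in error:
#' BetaBinomial(d, eps, 1 - eps).
#'
#' @param alpha0,beta0 mono-allelic Beta shapes (default 0.01 each).
#' @param alphaN,betaN bi-allelic Beta shapes, scalar or per-SNV vectors
#'   (default 1, i.e. uniform chi).
#' @param delta0 prior probability of bi-allelic expression, scalar or
#'   per-SNV (default 0.5).
#' @param eps sequencing error probability in (0, 0.5) (default 0.001).
#' @return A validated list of class \code{scRnaHyperparams}.
#' @export
scRnaHyperparams <- function(alpha0 = 0.01, beta0 = 0.01, alphaN = 1,
                             betaN = 1, delta0 = 0.5, eps = 0.001) {
  stopifnot(alpha0 > 0, beta0 > 0, all(alphaN > 0), all(betaN > 0),
            all(delta0 >= 0), all(delta0 <= 1), eps > 0, eps < 0.5)
  structure(list(alpha0 = alpha0, beta0 = beta0, alphaN = alphaN,
                 betaN = betaN, delta0 = delta0, eps = eps),
            class = "scRnaHyperparams")
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp of a dense matrix with few columns
.row_logsumexp <- function(M) {
  if (ncol(M) == 1L) return(M[, 1L])
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  mx + log(rowSums(exp(M - mx)))
}

#' Genotypes compatible with a clonal copy-number profile
#'
#' For major/minor copy numbers (M, m) the mutation resides on either
#' parental allele, so the variant copy count ranges over 1..M union 1..m
#' (deduplicated) with total copy number M + m. A uniform prior over the
#' set is used in the marginalized bulk likelihood.
#'
#' @param M major copy number (>= 1).
#' @param m minor copy number (0 <= m <= M).
#' @return data.frame with columns \code{v} (variant copies) and \code{c}
#'   (total copies).
#' @export
genotypeSet <- function(M, m) {
  if (M < 1) stop("homozygous deletion (M = 0): locus must be excluded upstream")
  if (m < 0 || m > M) stop("minor copy number must satisfy 0 <= m <= M")
  v <- sort(unique(c(seq_len(M), seq_len(m))))
  data.frame(v = v, c = rep(M + m, length(v)))
}

#' Success probability of a bulk variant read
#'
#' Probability that a read drawn at a locus carries the variant allele,
#' given the clone genotype (v variant copies out of c), the cellular
#' prevalence phi of the clone carrying the SNV, and the sequencing error
#' probability eps.
#'
#' @param v,c variant and total copy numbers of the genotype.
#' @param phi cellular prevalence in [0, 1].
#' @param eps sequencing error probability.
#' @return numeric success probability (vectorized over any argument).
#' @export
thetaSuccess <- function(v, c, phi, eps) {
  n <- max(length(v), length(c), length(phi), length(eps))
  v <- rep_len(v, n); c <- rep_len(c, n)
  phi <- rep_len(phi, n); eps <- rep_len(eps, n)
  ifelse(v == 0, eps,
    ifelse(v == c, phi * (1 - eps) + (1 - phi) * eps,
           phi * v / c + (1 - phi) * eps))
}

#' Beta-Binomial log probability mass
#'
#' Exact log pmf of b successes in d trials with success probability
#' integrated over Beta(alpha, beta), computed via log-gamma.
#'
#' @param b,d counts with 0 <= b <= d.
#' @param alpha,beta positive shapes.
#' @return numeric log probability (vectorized).
#' @export
betaBinomLogpmf <- function(b, d, alpha, beta) {
  if (any(b < 0) || any(b > d)) stop("require 0 <= b <= d")
  if (any(alpha <= 0) || any(beta <= 0)) stop("shapes must be positive")
  lchoose(d, b) + lbeta(b + alpha, d - b + beta) - lbeta(alpha, beta)
}

#' Genotype-marginalized bulk log-likelihood at one SNV
#'
#' log of the average over compatible genotypes of
#' Binomial(b; d, theta(g, phi, eps)), summed over regions. Computed in
#' log space via log-sum-exp. A region with zero depth contributes 0.
#'
#' @param b,d variant reads and depth; vectors over regions.
#' @param M,m clonal major/minor copy numbers (scalars).
#' @param phi cellular prevalence of the SNV's clone; vector over regions.
#' @param eps sequencing error probability.
#' @return scalar log-likelihood.
#' @export
bulkSiteLoglik <- function(b, d, M, m, phi, eps = 0.001) {
  g <- genotypeSet(M, m)
  tot <- 0
  for (r in seq_along(b)) {
    th <- thetaSuccess(g$v, g$c, phi[r], eps)
    tot <- tot + .logsumexp(stats::dbinom(b[r], d[r], th, log = TRUE)) - log(nrow(g))
  }
  tot
}

#' Single-cell log-likelihood at one (cell, SNV) entry
#'
#' For a cell carrying the mutation (mu = 1) the bi-/mono-allelic
#' indicator is marginalized: a mixture of BetaBinomial(d, alpha0, beta0)
#' (weight 1 - delta0) and BetaBinomial(d, alphaN, betaN) (weight delta0).
#' For a cell without the mutation (mu = 0): BetaBinomial(d, eps, 1 - eps).
#' Zero depth gives log-likelihood 0 under either status.
#'
#' @param b,d variant and total reads.
#' @param mu mutation status (0/1).
#' @param hyper an \code{\link{scRnaHyperparams}} object.
#' @param snv index of the SNV into per-SNV hyperparameter vectors
#'   (default 1; ignored for scalar hyperparameters).
#' @return scalar log-likelihood (vectorized over b, d, mu).
#' @export
scSiteLoglik <- function(b, d, mu, hyper, snv = 1L) {
  an <- if (length(hyper$alphaN) > 1L) hyper$alphaN[snv] else hyper$alphaN
  bn <- if (length(hyper$betaN) > 1L) hyper$betaN[snv] else hyper$betaN
  d0 <- if (length(hyper$delta0) > 1L) hyper$delta0[snv] else hyper$delta0
  len <- max(length(b), length(d), length(mu))
  b <- rep_len(b, len); d <- rep_len(d, len); mu <- rep_len(mu, len)
  ll0 <- betaBinomLogpmf(b, d, hyper$eps, 1 - hyper$eps)
  mono <- betaBinomLogpmf(b, d, hyper$alpha0, hyper$beta0)
  bi <- betaBinomLogpmf(b, d, an, bn)
  ll1 <- if (d0 <= 0) mono else if (d0 >= 1) bi else {
    m <- pmax(mono + log1p(-d0), bi + log(d0))
    m + log(exp(mono + log1p(-d0) - m) + exp(bi + log(d0) - m))
  }
  out <- ifelse(mu == 1, ll1, ll0)
  out[d == 0] <- 0
  out
}

# Per covered (cell, SNV) entry, the log-likelihoods under mutated (ll1)
# and unmutated (ll0) status. Returns triplets aligned with
# Matrix::summary of the total-count matrix, plus per-cell base sums of
# ll0 and the per-SNV lists of covered cells used by the sampler.
.sc_components <- function(sc, hyper) {
  tot <- methods::as(sc@tot, "TsparseMatrix")
  C <- nrow(tot); N <- ncol(tot)
  i <- tot@i + 1L; j <- tot@j + 1L; d <- tot@x
  b <- sc@var[cbind(i, j)]
  keep <- d > 0
  i <- i[keep]; j <- j[keep]; d <- d[keep]; b <- b[keep]
  an <- if (length(hyper$alphaN) > 1L) hyper$alphaN[j] else rep(hyper$alphaN, length(j))
  bn <- if (length(hyper$betaN) > 1L) hyper$betaN[j] else rep(hyper$betaN, length(j))
  d0 <- if (length(hyper$delta0) > 1L) hyper$delta0[j] else rep(hyper$delta0, length(j))
  ll0 <- betaBinomLogpmf(b, d, hyper$eps, 1 - hyper$eps)
  mono <- betaBinomLogpmf(b, d, hyper$alpha0, hyper$beta0)
  bi <- betaBinomLogpmf(b, d, an, bn)
  m <- pmax(mono + log1p(-d0), bi + log(d0))
  ll1 <- ifelse(d0 <= 0, mono, ifelse(d0 >= 1, bi,
    m + log(exp(mono + log1p(-d0) - m) + exp(bi + log(d0) - m))))
  base <- numeric(C)
  if (length(i)) {
    agg <- rowsum(ll0, i)
    base[as.integer(rownames(agg))] <- agg[, 1L]
  }
  covCells <- split(i, factor(j, levels = seq_len(N)))
  covDelta <- split(ll1 - ll0, factor(j, levels = seq_len(N)))
  list(C = C, N = N, i = i, j = j, b = b, d = d, ll0 = ll0, ll1 = ll1,
       base = base, covCells = covCells, covDelta = covDelta)
}

#' Log-likelihood of one cell under a candidate clone
#'
#' Sum over the cell's covered loci of \code{\link{scSiteLoglik}} with the
#' mutation status implied by placing the cell at \code{cellNode}.
#'
#' @param tree a \linkS4class{ClonalTree}.
#' @param z character vector of SNV node paths.
#' @param cellNode node path of the candidate clone.
#' @param b,d variant and total reads of the cell over SNVs (length N).
#' @param hyper an \code{\link{scRnaHyperparams}} object.
#' @return scalar log-likelihood.
#' @export
cellCloneLoglik <- function(tree, z, cellNode, b, d, hyper) {
  mu <- mutationStatus(tree, z, cellNode)
  cov <- which(d > 0)
  if (!length(cov)) return(0)
  sum(vapply(cov, function(n) scSiteLoglik(b[n], d[n], mu[n], hyper, n),
             numeric(1)))
}

#' Marginal single-cell log-likelihood of a clonal tree
#'
#' The cell-to-clone memberships are marginalized under a uniform prior
#' over the nodes of the tree (the healthy root included):
#' sum over cells of log( (1/|V|) * sum over nodes of exp(cell
#' log-likelihood) ). Cost is O(C * |V|) per evaluation.
#'
#' @param tree a \linkS4class{ClonalTree}.
#' @param z character vector of SNV node paths (length = ncol of sc).
#' @param sc an \linkS4class{ScVariantData}.
#' @param hyper an \code{\link{scRnaHyperparams}} object.
#' @return scalar log-likelihood (0 when there are no cells).
#' @export
scrnaMarginalLoglik <- function(tree, z, sc, hyper) {
  C <- nrow(sc@tot)
  if (C == 0L) return(0)
  comp <- .sc_components(sc, hyper)
  L <- .cell_node_loglik(tree, z, comp)
  sum(.row_logsumexp(L)) - C * log(nNodes(tree))
}

# dense matrix (cells x nodes) of cell log-likelihoods given each clone
.cell_node_loglik <- function(tree, z, comp) {
  paths <- tree@paths
  A <- vapply(paths, function(v) as.numeric(.path_is_anc(z, v)),
              numeric(length(z))) # N x V: SNV's node ancestor-of-or-equal v
  if (is.null(dim(A))) A <- matrix(A, nrow = length(z))
  D <- Matrix::sparseMatrix(i = comp$i, j = comp$j, x = comp$ll1 - comp$ll0,
                            dims = c(comp$C, comp$N))
  L <- as.matrix(D %*% A) + comp$base
  colnames(L) <- paths
  L
}

#' Unnormalized log posterior of a full model state
#'
#' Sum of the genotype-marginalized bulk log-likelihood, the marginal
#' single-cell log-likelihood, the TSSB assignment mass (sum over SNVs of
#' log pi at the assigned node, given the tree's stick state), and the
#' flat Dirichlet log prior density of the clone fractions (log Gamma(V)
#' per region, which makes scores comparable across trees of different
#' size). States violating the prevalence constraints score -Inf.
#'
#' @param tree a \linkS4class{ClonalTree} with stick state.
#' @param z named character vector of SNV node paths.
#' @param phi numeric matrix (nodes x regions) of cellular prevalences.
#' @param bulk a \linkS4class{BulkData}.
#' @param sc an \linkS4class{ScVariantData} or NULL for bulk-only scoring.
#' @param hyper an \code{\link{scRnaHyperparams}} object.
#' @param eps bulk sequencing error probability.
#' @return scalar unnormalized log posterior.
#' @export
logJointScore <- function(tree, z, phi, bulk, sc = NULL, hyper = scRnaHyperparams(),
                          eps = 0.001) {
  if (is.null(dim(phi))) phi <- matrix(phi, ncol = 1, dimnames = list(names(phi), "R1"))
  ok <- tryCatch({ cloneFractions(tree, phi); TRUE },
                 error = function(e) { attr(e, "msg"); FALSE })
  if (!ok) return(-Inf)
  ll <- 0
  for (n in seq_along(bulk@snvIds)) {
    ll <- ll + bulkSiteLoglik(bulk@b[n, ], bulk@d[n, ], bulk@majorCn[n],
                              bulk@minorCn[n], phi[z[n], ], eps)
  }
  if (!is.null(sc) && nrow(sc@tot) > 0L)
    ll <- ll + scrnaMarginalLoglik(tree, z, sc, hyper)
  lpi <- log(stickMasses(tree)$pi)
  ll + sum(lpi[z]) + ncol(phi) * lgamma(nNodes(tree))
}
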