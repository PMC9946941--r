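# Evaluation metrics: clustering agreement scores on SNV-to-clone labels,
# the ancestral reconstruction error on SNV-pair ancestry matrices, and the
# expected per-cell genotype loss under a posterior cell-to-clone
# assignment.

.contingency <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  table(factor(a), factor(b))
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' V-measure of two labelings
#'
#' Harmonic mean of homogeneity (each predicted cluster contains members
#' of a single true class) and completeness (each true class is contained
#' in a single predicted cluster). Invariant to label permutation; 1 for
#' identical partitions.
#'
#' @param labelsTrue,labelsPred equal-length label vectors.
#' @return numeric in [0, 1].
#' @export
vMeasure <- function(labelsTrue, labelsPred) {
  ct <- .contingency(labelsTrue, labelsPred)
  n <- sum(ct)
  pij <- ct / n
  pi. <- rowSums(pij); p.j <- colSums(pij)
  HC <- .entropy(pi.); HK <- .entropy(p.j)
  HCgK <- -sum(pij[pij > 0] * log((pij / rep(p.j, each = nrow(pij)))[pij > 0]))
  HKgC <- -sum(pij[pij > 0] * log((pij / pi.)[pij > 0]))
  h <- if (HC == 0) 1 else 1 - HCgK / HC
  c <- if (HK == 0) 1 else 1 - HKgC / HK
  if (h + c == 0) 0 else 2 * h * c / (h + c)
}

#' Adjusted Rand index of two labelings
#'
#' Rand index corrected for chance under the permutation model.
#'
#' @inheritParams vMeasure
#' @return numeric (1 for identical partitions, ~0 for random).
#' @export
adjustedRandScore <- function(labelsTrue, labelsPred) {
  ct <- .contingency(labelsTrue, labelsPred)
  n <- sum(ct)
  sij <- sum(choose(ct, 2))
  si <- sum(choose(rowSums(ct), 2)); sj <- sum(choose(colSums(ct), 2))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)
  (sij - expected) / (maxidx - expected)
}

#' Adjusted mutual information of two labelings
#'
#' Mutual information corrected for chance (expected MI under the
#' permutation model via the hypergeometric distribution), normalized by
#' the arithmetic mean of the marginal entropies.
#'
#' @inheritParams vMeasure
#' @return numeric (1 for identical partitions).
#' @export
adjustedMutualInfo <- function(labelsTrue, labelsPred) {
  ct <- .contingency(labelsTrue, labelsPred)
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  HU <- .entropy(a / n); HV <- .entropy(b / n)
  if (HU == 0 && HV == 0) return(1)
  pij <- ct / n
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (ct[i, j] > 0)
      mi <- mi + pij[i, j] * log(n * ct[i, j] / (a[i] * b[j]))
  }
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    lo <- max(1, a[i] + b[j] - n)
    hi <- min(a[i], b[j])
    if (lo > hi) next
    for (nij in lo:hi) {
      lp <- lgamma(a[i] + 1) + lgamma(b[j] + 1) + lgamma(n - a[i] + 1) +
        lgamma(n - b[j] + 1) - lgamma(n + 1) - lgamma(nij + 1) -
        lgamma(a[i] - nij + 1) - lgamma(b[j] - nij + 1) -
        lgamma(n - a[i] - b[j] + nij + 1)
      emi <- emi + exp(lp) * (nij / n) * log(n * nij / (a[i] * b[j]))
    }
  }
  denom <- (HU + HV) / 2 - emi
  if (abs(denom) < .Machine$double.eps) denom <- .Machine$double.eps
  as.numeric((mi - emi) / denom)
}

#' Clustering scores of a predicted SNV-to-clone labeling
#'
#' @inheritParams vMeasure
#' @return list with vMeasure, adjustedRandIndex, adjustedMutualInfo.
#' @export
clusteringScores <- function(labelsTrue, labelsPred) {
  list(vMeasure = vMeasure(labelsTrue, labelsPred),
       adjustedRandIndex = adjustedRandScore(labelsTrue, labelsPred),
       adjustedMutualInfo = adjustedMutualInfo(labelsTrue, labelsPred))
}

#' Ancestral reconstruction error
#'
#' Mean absolute difference between a true and a predicted SNV-pair
#' ancestry matrix (see \code{\link{ancestralMatrix}}). By default the sum
#' runs over ordered pairs i != j with denominator N(N-1) (ancestry is
#' asymmetric); the unordered variant counts a pair as wrong if either
#' direction disagrees, with denominator N(N-1)/2.
#'
#' @param aTrue,aPred binary N x N matrices.
#' @param ordered sum over ordered pairs (default) or unordered pairs.
#' @return numeric in [0, 1].
#' @export
ancestralError <- function(aTrue, aPred, ordered = TRUE) {
  if (!identical(dim(aTrue), dim(aPred))) stop("dimension mismatch")
  N <- nrow(aTrue)
  if (N < 2) stop("need at least 2 SNVs")
  diff <- abs(aTrue - aPred)
  diag(diff) <- 0
  if (ordered) {
    sum(diff) / (N * (N - 1))
  } else {
    wrong <- (diff + t(diff)) > 0
    sum(wrong[upper.tri(wrong)]) / (N * (N - 1) / 2)
  }
}

#' Expected per-cell genotype loss
#'
#' Posterior-weighted number of SNVs whose predicted mutation status
#' disagrees with the cell's true status: sum over clones v of
#' P(cell at v) times the Hamming distance between the true status vector
#' and the status implied by placing the cell at v.
#'
#' @param muTrue binary vector (length N) of the cell's true mutation
#'   status.
#' @param posterior named numeric vector over tree nodes, summing to 1.
#' @param tree a \linkS4class{ClonalTree}.
#' @param z character vector of SNV node paths.
#' @return non-negative scalar.
#' @export
expectedGenotypeLoss <- function(muTrue, posterior, tree, z) {
  if (abs(sum(posterior) - 1) > 1e-6) stop("posterior must sum to 1")
  nodes <- names(posterior)
  if (is.null(nodes) || !all(nodes %in% tree@paths)) stop("posterior must be named by tree nodes")
  sum(vapply(nodes, function(v)
    posterior[[v]] * sum(muTrue != mutationStatus(tree, z, v)), numeric(1)))
}

#' Evaluate a fit against a simulated ground truth
#'
#' @param fit a \linkS4class{CloneTreeFit} (or MAP sample list).
#' @param truth output of \code{\link{simulateTruth}}.
#' @param cellAssign optional \linkS4class{CellAssignment} for cell-level
#'   metrics.
#' @return list with clustering scores, ancestral error, and (when cell
#'   assignments are supplied) cell assignment accuracy and mean expected
#'   genotype loss.
#' @export
evaluateFit <- function(fit, truth, cellAssign = NULL) {
  z <- if (is(fit, "CloneTreeFit")) fit@z else fit$z
  tree <- if (is(fit, "CloneTreeFit")) fit@tree else
    ClonalTree(fit$paths, nu = fit$nu, psi = fit$psi)
  out <- clusteringScores(truth$z, z[names(truth$z)])
  aT <- ancestralMatrix(truth$tree, truth$z)
  aP <- ancestralMatrix(tree, z[names(truth$z)])
  out$ancestralError <- ancestralError(aT, aP)
  if (!is.null(cellAssign)) {
    prob <- assignmentProb(cellAssign)
    loss <- vapply(seq_len(nrow(prob)), function(c)
      expectedGenotypeLoss(truth$mu[c, ], prob[c, ], tree, z), numeric(1))
    out$meanExpectedLoss <- mean(loss)
  }
  out
}
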