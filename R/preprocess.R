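#' Filter SNVs by single-cell variant support
#'
#' An SNV is retained if at least \code{minCells} cells carry at least
#' \code{minVarReads} variant reads at the locus. Defaults suit
#' full-length (Smart-Seq-style) data; for shallow droplet data (10X
#' mode) use \code{minVarReads = 1}.
#'
#' @param sc an \linkS4class{ScVariantData}.
#' @param minCells minimum number of supporting cells (default 2).
#' @param minVarReads minimum variant reads per supporting cell (default 2).
#' @return character vector of retained SNV ids, in input order.
#' @export
filterSnvs <- function(sc, minCells = 2L, minVarReads = 2L) {
  stopifnot(minCells >= 1, minVarReads >= 1)
  if (ncol(sc@tot) == 0L) stop("empty single-cell matrix")
  support <- Matrix::colSums(sc@var >= minVarReads)
  keep <- colnames(sc@var)[support >= minCells]
  if (!length(keep))
    stop("no SNVs pass the filter; for shallow data consider 10X mode ",
         "(minVarReads = 1)")
  keep
}

#' Subset bulk and single-cell data to a set of SNVs
#'
#' @param bulk a \linkS4class{BulkData}.
#' @param sc an \linkS4class{ScVariantData}.
#' @param snvIds SNV ids to keep (order respected).
#' @return list with the subset \code{bulk} and \code{sc}.
#' @export
subsetSnvs <- function(bulk, sc, snvIds) {
  stopifnot(all(snvIds %in% bulk@snvIds))
  i <- match(snvIds, bulk@snvIds)
  b2 <- BulkData(snvIds, bulk@b[i, , drop = FALSE], bulk@d[i, , drop = FALSE],
                 bulk@majorCn[i], bulk@minorCn[i], regions = bulk@regions,
                 meta = bulk@meta[i, , drop = FALSE])
  s2 <- new("ScVariantData", var = sc@var[, snvIds, drop = FALSE],
            tot = sc@tot[, snvIds, drop = FALSE])
  list(bulk = b2, sc = s2)
}

#' Estimate per-SNV bi-allelic expression shapes
#'
#' Collects the variant-read fractions b/d over cells with informative
#' bi-allelic evidence (0 < b < d) at a locus and fits a Beta
#' distribution by the method of moments. With fewer than
#' \code{minInformative} such cells, or degenerate moments (zero or
#' overdispersed variance), the uninformative fallback (1, 1) is
#' returned.
#'
#' @param sc an \linkS4class{ScVariantData}.
#' @param snv SNV id or column index.
#' @param minInformative minimum number of informative cells (default 3).
#' @return named numeric c(alpha, beta).
#' @export
estimateBursting <- function(sc, snv, minInformative = 3L) {
  b <- sc@var[, snv]
  d <- sc@tot[, snv]
  keep <- d > 0 & b > 0 & b < d
  fallback <- c(alpha = 1, beta = 1)
  if (sum(keep) < minInformative) return(fallback)
  x <- b[keep] / d[keep]
  mn <- mean(x); vr <- stats::var(x)
  if (!is.finite(vr) || vr <= 1e-12) return(fallback)
  # the observed ratio variance is var(chi) plus binomial sampling noise
  # E[chi (1 - chi)] / d; subtract its plug-in estimate before the
  # method-of-moments inversion
  noise <- mean(x * (1 - x) / pmax(d[keep] - 1, 1))
  vchi <- vr - noise
  if (vchi <= 1e-12) return(fallback)
  common <- mn * (1 - mn) / vchi - 1
  if (common <= 0) return(fallback) # variance too large for a Beta fit
  c(alpha = mn * common, beta = (1 - mn) * common)
}

#' Estimate bi-allelic shapes for every SNV
#'
#' @param sc an \linkS4class{ScVariantData}.
#' @param minInformative see \code{\link{estimateBursting}}.
#' @return matrix (SNVs x 2) with columns alpha, beta.
#' @export
estimateBurstingAll <- function(sc, minInformative = 3L) {
  out <- t(vapply(seq_len(ncol(sc@tot)),
                  function(j) estimateBursting(sc, j, minInformative),
                  numeric(2)))
  dimnames(out) <- list(colnames(sc@tot), c("alpha", "beta"))
  out
}
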