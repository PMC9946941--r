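#' @import methods
NULL

#' Clonal tree of tumor cell populations
#'
#' A rooted tree whose nodes are clones. The root represents healthy cells
#' and has exactly one child, the cancer progenitor clone. Nodes are
#' addressed by canonical child-index paths: the root is \code{"0"} and the
#' k-th child of node \code{p} is \code{paste0(p, ".", k)}. Optional
#' stick-breaking state (the per-node nu-stick and the ordered psi-sticks
#' for its children) may be attached; it is required by
#' \code{\link{stickMasses}} and filled in by \code{\link{sampleTssb}} and
#' the MCMC sampler.
#'
#' @slot paths character vector of node paths in canonical depth-first order.
#' @slot parent named character vector mapping each path to its parent path
#'   (\code{NA} for the root).
#' @slot nu named numeric vector of nu-sticks in [0, 1] (may be empty).
#' @slot psi named list of numeric psi-stick vectors, one entry per node,
#'   ordered by child index (may be empty).
#'
#' @examples
#' tr <- ClonalTree(c("0", "0.1", "0.1.1", "0.1.2"))
#' nNodes(tr)
#' nodeChildren(tr, "0.1")
#' @export
setClass("ClonalTree",
  representation(paths = "character", parent = "character",
                 nu = "numeric", psi = "list"))

setValidity("ClonalTree", function(object) {
  p <- object@paths
  if (length(p) == 0L) return("tree has no nodes")
  if (anyDuplicated(p)) return("duplicated node paths")
  if (!identical(p, .canonical_paths(p))) return("paths not in canonical order")
  if (p[1L] != "0") return("root must be node '0'")
  par <- object@parent
  if (!identical(names(par), p)) return("parent map must be named by paths")
  if (!is.na(par[["0"]])) return("root must have no parent")
  for (q in p[-1L]) {
    if (is.na(par[[q]]) || par[[q]] != .path_parent(q))
      return(sprintf("node %s has inconsistent parent", q))
    if (!(par[[q]] %in% p))
      return(sprintf("parent of node %s is not in the tree", q))
  }
  # child indices are stable addresses; gaps are allowed (they arise when
  # empty sibling clones are dropped from a reported tree)
  nroot_children <- sum(!is.na(par) & par == "0")
  if (length(p) > 1L && nroot_children != 1L)
    return("the healthy root must have exactly one child (the progenitor clone)")
  if (length(object@nu) && !identical(sort(names(object@nu)), sort(p)))
    return("nu sticks must be named by node paths")
  if (length(object@nu) && (any(object@nu < 0) || any(object@nu > 1)))
    return("nu sticks must lie in [0, 1]")
  TRUE
})

#' Construct a ClonalTree from node paths
#'
#' @param paths character vector of node paths (canonical child-index
#'   addressing, root \code{"0"}); ancestors of every node must be present.
#' @param nu optional named numeric vector of nu-sticks.
#' @param psi optional named list of psi-stick vectors.
#' @return A \linkS4class{ClonalTree}.
#' @export
ClonalTree <- function(paths, nu = numeric(0), psi = list()) {
  paths <- .canonical_paths(unique(paths))
  parent <- stats::setNames(.path_parent(paths), paths)
  new("ClonalTree", paths = paths, parent = parent, nu = nu, psi = psi)
}

#' Cellular prevalences and clone fractions over a clonal tree
#'
#' Per-node, per-region cellular prevalence phi (fraction of cells carrying
#' the clone's mutations, i.e. belonging to the clone or any descendant)
#' and clone fraction eta (fraction of cells belonging exactly to the
#' clone). Within each region, phi at the root is 1, the children of any
#' node have prevalences summing to at most the parent's, and eta sums
#' to 1 over nodes.
#'
#' @slot phi numeric matrix (nodes x regions), rownames are node paths.
#' @slot eta numeric matrix (nodes x regions), rownames are node paths.
#' @slot regions character vector of region labels.
#' @export
setClass("PrevalenceField",
  representation(phi = "matrix", eta = "matrix", regions = "character"))

setValidity("PrevalenceField", function(object) {
  phi <- object@phi; eta <- object@eta
  if (!identical(dim(phi), dim(eta))) return("phi and eta dimensions differ")
  if (ncol(phi) != length(object@regions)) return("region count mismatch")
  if (any(phi < -1e-9) || any(phi > 1 + 1e-9)) return("phi outside [0, 1]")
  et <- colSums(eta)
  if (any(abs(et - 1) > 1e-6)) return("eta columns must sum to 1")
  TRUE
})

#' Bulk DNA-seq SNV read counts with clonal copy numbers
#'
#' Per-SNV (and per-region) variant read counts, total depths and clonal
#' major/minor copy numbers from a bulk copy-number caller.
#'
#' @slot snvIds character vector of SNV identifiers.
#' @slot regions character vector of region labels.
#' @slot b integer matrix (SNVs x regions) of variant read counts.
#' @slot d integer matrix (SNVs x regions) of total depths.
#' @slot majorCn integer vector of major copy numbers (>= 1).
#' @slot minorCn integer vector of minor copy numbers (0 <= m <= M).
#' @slot meta data.frame of per-SNV annotation (chrom, pos, ref, alt), may
#'   have zero columns.
#' @export
setClass("BulkData",
  representation(snvIds = "character", regions = "character",
                 b = "matrix", d = "matrix",
                 majorCn = "integer", minorCn = "integer",
                 meta = "data.frame"))

setValidity("BulkData", function(object) {
  N <- length(object@snvIds)
  if (anyDuplicated(object@snvIds)) return("duplicated SNV ids")
  if (nrow(object@b) != N || nrow(object@d) != N) return("count matrix rows must match SNV ids")
  if (ncol(object@b) != length(object@regions) || ncol(object@d) != length(object@regions))
    return("count matrix columns must match regions")
  if (length(object@majorCn) != N || length(object@minorCn) != N)
    return("copy-number vectors must match SNV ids")
  if (any(object@b < 0) || any(object@d < 0)) return("negative read counts")
  if (any(object@b > object@d)) return("variant reads exceed total depth")
  if (any(object@majorCn < 1)) return("major copy number must be >= 1 (homozygous deletions must be excluded)")
  if (any(object@minorCn < 0) || any(object@minorCn > object@majorCn))
    return("minor copy number must satisfy 0 <= m <= M")
  TRUE
})

#' Construct a BulkData object
#'
#' @param snvIds character vector of SNV identifiers.
#' @param b,d variant read counts and total depths; vectors (single region)
#'   or SNV-by-region matrices.
#' @param majorCn,minorCn clonal major/minor copy numbers per SNV.
#' @param regions region labels; defaults to \code{"R1"}, ... .
#' @param meta optional per-SNV annotation data.frame.
#' @return A \linkS4class{BulkData}.
#' @export
BulkData <- function(snvIds, b, d, majorCn, minorCn, regions = NULL, meta = NULL) {
  b <- as.matrix(b); d <- as.matrix(d)
  storage.mode(b) <- "integer"; storage.mode(d) <- "integer"
  if (is.null(regions)) regions <- paste0("R", seq_len(ncol(b)))
  if (is.null(meta)) meta <- data.frame(row.names = seq_along(snvIds))
  rownames(b) <- rownames(d) <- snvIds
  colnames(b) <- colnames(d) <- regions
  new("BulkData", snvIds = as.character(snvIds), regions = as.character(regions),
      b = b, d = d, majorCn = as.integer(majorCn), minorCn = as.integer(minorCn),
      meta = meta)
}

#' Sparse single-cell variant read counts
#'
#' Per-(cell, SNV) variant and total read counts from scRNA-seq pileups at
#' SNV loci. Entries absent from the sparse matrices mean zero depth
#' (no reads at that locus in that cell).
#'
#' @slot var sparse Matrix (cells x SNVs) of variant read counts.
#' @slot tot sparse Matrix (cells x SNVs) of total read counts.
#' @export
setClass("ScVariantData", representation(var = "Matrix", tot = "Matrix"))

setValidity("ScVariantData", function(object) {
  if (!identical(dim(object@var), dim(object@tot))) return("var/tot dimensions differ")
  if (!identical(dimnames(object@var), dimnames(object@tot))) return("var/tot dimnames differ")
  if (any(object@var@x < 0) || any(object@tot@x < 0)) return("negative read counts")
  dif <- object@tot - object@var
  if (any(dif@x < 0)) return("variant reads exceed total depth")
  TRUE
})

#' Construct an ScVariantData object from long-format counts
#'
#' @param cellId,snvId,b,d parallel vectors: cell id, SNV id, variant reads
#'   and total reads for covered (cell, SNV) pairs.
#' @param snvIds optional full SNV universe (columns), e.g. the bulk SNV
#'   ids; defaults to the SNVs observed.
#' @param cellIds optional full cell universe (rows).
#' @return An \linkS4class{ScVariantData}.
#' @export
ScVariantData <- function(cellId, snvId, b, d, snvIds = NULL, cellIds = NULL) {
  if (is.null(snvIds)) snvIds <- unique(as.character(snvId))
  if (is.null(cellIds)) cellIds <- unique(as.character(cellId))
  if (anyDuplicated(paste(cellId, snvId, sep = "\r")))
    stop("duplicate (cell, SNV) entries in single-cell counts")
  i <- match(as.character(cellId), cellIds)
  j <- match(as.character(snvId), snvIds)
  if (anyNA(j)) stop("single-cell SNV ids absent from the SNV universe: ",
                     paste(unique(snvId[is.na(j)]), collapse = ", "))
  dm <- list(cellIds, snvIds)
  v <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(b),
                            dims = c(length(cellIds), length(snvIds)), dimnames = dm)
  t <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(d),
                            dims = c(length(cellIds), length(snvIds)), dimnames = dm)
  new("ScVariantData", var = v, tot = t)
}

#' Posterior sample trace and MAP state from the clonal-tree MCMC
#'
#' @slot tree MAP \linkS4class{ClonalTree}.
#' @slot prevalence MAP \linkS4class{PrevalenceField}.
#' @slot z named character vector: MAP SNV-to-clone assignment (values are
#'   node paths, names are SNV ids).
#' @slot logJoint numeric: unnormalized log posterior of the MAP state.
#' @slot trace data.frame with one row per iteration (iteration, logJoint,
#'   nClones).
#' @slot samples list of retained posterior samples.
#' @slot config list of sampler settings used.
#' @export
setClass("CloneTreeFit",
  representation(tree = "ClonalTree", prevalence = "PrevalenceField",
                 z = "character", logJoint = "numeric",
                 trace = "data.frame", samples = "list", config = "list"))

#' Posterior cell-to-clone assignment
#'
#' @slot prob matrix (cells x nodes) of posterior probabilities
#'   P(cell c belongs to clone v); rows sum to 1.
#' @slot mapNode named character vector: argmax clone per cell (ties broken
#'   by shallower depth, then canonical path order).
#' @slot muHat binary matrix (cells x SNVs): predicted mutation status under
#'   the MAP clone of each cell.
#' @export
setClass("CellAssignment",
  representation(prob = "matrix", mapNode = "character", muHat = "matrix"))

setValidity("CellAssignment", function(object) {
  if (nrow(object@prob) && any(abs(rowSums(object@prob) - 1) > 1e-6))
    return("posterior rows must sum to 1")
  TRUE
})
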