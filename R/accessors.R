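#' @describeIn ClonalTree-accessors Node paths in canonical order.
#' @export
setGeneric("nodePaths", function(x) standardGeneric("nodePaths"))

#' @describeIn ClonalTree-accessors Number of nodes.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @describeIn ClonalTree-accessors Parent path of a node (NA for the root).
#' @export
setGeneric("nodeParent", function(x, path) standardGeneric("nodeParent"))

#' @describeIn ClonalTree-accessors Ordered children of a node.
#' @export
setGeneric("nodeChildren", function(x, path) standardGeneric("nodeChildren"))

#' @describeIn ClonalTree-accessors Depth of every node (root = 0).
#' @export
setGeneric("nodeDepths", function(x) standardGeneric("nodeDepths"))

#' Accessors for ClonalTree objects
#'
#' @param x a \linkS4class{ClonalTree}.
#' @param path a node path.
#' @name ClonalTree-accessors
NULL

#' @export
setMethod("nodePaths", "ClonalTree", function(x) x@paths)

#' @export
setMethod("nNodes", "ClonalTree", function(x) length(x@paths))

#' @export
setMethod("nodeParent", "ClonalTree", function(x, path) {
  if (!path %in% x@paths) stop("unknown node: ", path)
  x@parent[[path]]
})

#' @export
setMethod("nodeChildren", "ClonalTree", function(x, path) {
  if (!path %in% x@paths) stop("unknown node: ", path)
  kids <- x@paths[!is.na(x@parent) & x@parent == path]
  kids[.path_order(kids)]
})

#' @export
setMethod("nodeDepths", "ClonalTree", function(x) {
  stats::setNames(.path_depth(x@paths), x@paths)
})

#' Test ancestry between nodes of a clonal tree
#'
#' @param tree a \linkS4class{ClonalTree}.
#' @param u,v node paths.
#' @param strict if TRUE, a node does not count as its own ancestor.
#' @return logical.
#' @export
isAncestor <- function(tree, u, v, strict = FALSE) {
  if (!all(c(u, v) %in% tree@paths)) stop("unknown node")
  .path_is_anc(u, v) && (!strict || u != v)
}

setMethod("show", "ClonalTree", function(object) {
  d <- .path_depth(object@paths)
  cat("ClonalTree with ", length(object@paths), " nodes (max depth ",
      max(d), ")\n", sep = "")
  cat("  healthy root: 0; progenitor clone: 0.1\n")
  shown <- utils::head(object@paths, 12L)
  for (p in shown)
    cat("  ", strrep("  ", .path_depth(p)), p, "\n", sep = "")
  if (length(object@paths) > 12L) cat("  ...\n")
})

setMethod("show", "PrevalenceField", function(object) {
  cat("PrevalenceField over", nrow(object@phi), "clones x",
      length(object@regions), "region(s)\n")
  print(utils::head(round(object@phi, 3), 8L))
})

setMethod("show", "BulkData", function(object) {
  cat("BulkData:", length(object@snvIds), "SNVs x",
      length(object@regions), "region(s); mean depth ",
      round(mean(object@d), 1), "\n")
})

setMethod("show", "ScVariantData", function(object) {
  nz <- length(object@tot@x)
  cat("ScVariantData:", nrow(object@tot), "cells x", ncol(object@tot),
      "SNVs;", nz, "covered entries (",
      round(100 * nz / prod(dim(object@tot)), 1), "% )\n")
})

setMethod("show", "CloneTreeFit", function(object) {
  cat("CloneTreeFit: MAP log-joint", round(object@logJoint, 2), "with",
      nNodes(object@tree), "nodes;", length(object@samples),
      "retained samples\n")
})

setMethod("show", "CellAssignment", function(object) {
  cat("CellAssignment:", nrow(object@prob), "cells over",
      ncol(object@prob), "clones\n")
})

#' @describeIn CellAssignment-accessors Posterior probability matrix.
#' @export
setGeneric("assignmentProb", function(x) standardGeneric("assignmentProb"))
#' @export
setMethod("assignmentProb", "CellAssignment", function(x) x@prob)

#' Accessors for fit and assignment objects
#'
#' @param x a \linkS4class{CellAssignment} or \linkS4class{CloneTreeFit}.
#' @name CellAssignment-accessors
NULL

#' @describeIn CellAssignment-accessors MAP clone per cell.
#' @export
setGeneric("mapClone", function(x) standardGeneric("mapClone"))
#' @export
setMethod("mapClone", "CellAssignment", function(x) x@mapNode)

#' @describeIn CellAssignment-accessors MAP SNV-to-clone assignment.
#' @export
setGeneric("snvAssignment", function(x) standardGeneric("snvAssignment"))
#' @export
setMethod("snvAssignment", "CloneTreeFit", function(x) x@z)

#' @describeIn CellAssignment-accessors MAP tree.
#' @export
setGeneric("mapTree", function(x) standardGeneric("mapTree"))
#' @export
setMethod("mapTree", "CloneTreeFit", function(x) x@tree)

#' @describeIn CellAssignment-accessors MAP cellular prevalences.
#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))
#' @export
setMethod("prevalence", "CloneTreeFit", function(x) x@prevalence)

#' @describeIn CellAssignment-accessors Per-iteration scalar trace.
#' @export
setGeneric("mcmcTrace", function(x) standardGeneric("mcmcTrace"))
#' @export
setMethod("mcmcTrace", "CloneTreeFit", function(x) x@trace)
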