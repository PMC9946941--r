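#' TSSB hyperparameters
#'
#' Hyperparameters of the tree-structured stick-breaking prior over the
#' clonal tree and the SNV-to-clone assignment. The nu-stick at depth k is
#' Beta(1, lambda0 * lambda^k); larger lambda0 and lambda push mass deeper.
#' The psi-sticks are Beta(1, gamma); gamma <= 1 keeps trees narrow, which
#' suits clonal trees where the number of branching events is small.
#'
#' @param lambda0 positive depth-decay scale (default 1).
#' @param lambda depth decay in (0, 1] (default 0.5).
#' @param gamma positive branching concentration (default 1).
#' @return A validated list of class \code{tssbHyperparams}.
#' @export
tssbHyperparams <- function(lambda0 = 1, lambda = 0.5, gamma = 1) {
  stopifnot(lambda0 > 0, lambda > 0, lambda <= 1, gamma > 0)
  structure(list(lambda0 = lambda0, lambda = lambda, gamma = gamma),
            class = "tssbHyperparams")
}

#' Stick masses of a clonal tree
#'
#' Computes, for every instantiated node u, the residual stick mass
#' upsilon_u reaching the node and the mass pi_u = nu_u * upsilon_u
#' assigned to it. The residual passed to the k-th child is
#' (1 - nu_u) * upsilon_u * psi_k * prod_{j<k}(1 - psi_j), so that mass is
#' conserved exactly: pi_u plus the children's residuals plus the unbroken
#' psi remainder equals upsilon_u.
#'
#' @param tree a \linkS4class{ClonalTree} carrying nu/psi stick state.
#' @return list with named numeric vectors \code{pi} and \code{upsilon}.
#' @export
stickMasses <- function(tree) {
  paths <- tree@paths
  nu <- tree@nu; psi <- tree@psi
  if (!length(nu)) stop("tree carries no stick state")
  if (any(nu < 0 | nu > 1)) stop("invalid stick state: nu outside [0, 1]")
  ups <- stats::setNames(numeric(length(paths)), paths)
  pim <- ups
  ups[[paths[1L]]] <- 1
  for (p in paths) { # canonical order: parents precede children
    pim[[p]] <- nu[[p]] * ups[[p]]
    kids <- paths[!is.na(tree@parent) & tree@parent == p]
    kids <- kids[.path_order(kids)]
    if (length(kids)) {
      w <- psi[[p]]
      idx <- vapply(kids, function(k) utils::tail(.path_split(k), 1L), integer(1))
      if (is.null(w) || length(w) < max(idx))
        stop("invalid stick state: missing psi sticks for node ", p)
      if (any(w < 0 | w > 1)) stop("invalid stick state: psi outside [0, 1]")
      rem <- (1 - nu[[p]]) * ups[[p]]
      for (k in seq_along(kids)) {
        j <- idx[k]
        ups[[kids[k]]] <- rem * w[j] * prod(1 - w[seq_len(j - 1L)])
      }
    }
  }
  list(pi = pim, upsilon = ups)
}

# ---- lazy TSSB instantiation (shared by the prior sampler and the MCMC) ----

.tssb_new_env <- function() {
  st <- new.env(parent = emptyenv())
  st$paths <- "0"
  st$parent <- c("0" = NA_character_)
  st$depth <- c("0" = 0L)
  st$children <- list("0" = character(0))
  # the healthy root holds no items: nu_root is pinned at 0 and its single
  # psi-stick at 1 so that all item mass flows through the progenitor
  st$nu <- c("0" = 0)
  st$psi <- list("0" = numeric(0))
  st
}

.tssb_add_child <- function(st, p, hyper, on_create = NULL) {
  k <- length(st$children[[p]]) + 1L
  path <- paste0(p, ".", k)
  d <- st$depth[[p]] + 1L
  st$paths <- c(st$paths, path)
  st$parent[[path]] <- p
  st$depth[[path]] <- d
  st$children[[p]] <- c(st$children[[p]], path)
  st$children[[path]] <- character(0)
  st$nu[[path]] <- stats::rbeta(1, 1, hyper$lambda0 * hyper$lambda^d)
  st$psi[[path]] <- numeric(0)
  if (!is.null(on_create)) on_create(path)
  path
}

# Map a uniform coordinate u in [0, 1) to a node, lazily extending sticks
# and instantiating nodes as needed. Increasing u traverses nodes in
# canonical depth-first order.
.tssb_find_node <- function(st, u, hyper, on_create = NULL, max_depth = 40L) {
  p <- "0"
  repeat {
    nu <- st$nu[[p]]
    if (u < nu) return(p)
    u <- (u - nu) / (1 - nu)
    w <- st$psi[[p]]
    k <- 1L
    repeat {
      if (k > length(w)) {
        w <- c(w, if (p == "0") 1 else stats::rbeta(1, 1, hyper$gamma))
        st$psi[[p]] <- w
        .tssb_add_child(st, p, hyper, on_create)
      }
      if (u < w[k]) break
      u <- (u - w[k]) / (1 - w[k])
      k <- k + 1L
      if (k > 500L) stop("psi-stick extension did not terminate")
    }
    u <- u / w[k]
    p <- st$children[[p]][k]
    if (st$depth[[p]] > max_depth) stop("TSSB search exceeded maximum depth")
  }
}

.tssb_as_tree <- function(st) {
  ord <- .path_order(st$paths)
  paths <- st$paths[ord]
  new("ClonalTree", paths = paths,
      parent = st$parent[paths], nu = st$nu[paths],
      psi = st$psi[paths])
}

#' Sample a clonal tree and item assignments from the TSSB prior
#'
#' Draws item (SNV) assignments from the tree-structured stick-breaking
#' prior by lazy stick instantiation. The healthy root never receives
#' items; all mass flows through the progenitor clone.
#'
#' @param hyper a \code{\link{tssbHyperparams}} object.
#' @param nItems number of items to assign (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return list with elements \code{tree} (a \linkS4class{ClonalTree} with
#'   stick state), \code{z} (character vector of assigned node paths) and
#'   \code{pi} (stick masses of the instantiated nodes).
#' @export
sampleTssb <- function(hyper, nItems, seed = NULL) {
  stopifnot(inherits(hyper, "tssbHyperparams"))
  if (nItems < 1) stop("nItems must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  st <- .tssb_new_env()
  z <- character(nItems)
  for (i in seq_len(nItems)) {
    z[i] <- .tssb_find_node(st, stats::runif(1), hyper)
  }
  tree <- .tssb_as_tree(st)
  list(tree = tree, z = z, pi = stickMasses(tree)$pi)
}

#' Clone fractions from cellular prevalences
#'
#' Converts per-region cellular prevalences phi into clone fractions
#' eta_u = phi_u - sum of the children's phi. Validates the hierarchy
#' constraints (children's prevalences may not exceed the parent's, the
#' root has prevalence 1).
#'
#' @param tree a \linkS4class{ClonalTree}.
#' @param phi numeric matrix (nodes x regions) with rownames equal to the
#'   node paths, or a named vector for a single region.
#' @return eta in the same shape as \code{phi}.
#' @export
cloneFractions <- function(tree, phi) {
  vec <- is.null(dim(phi))
  if (vec) phi <- matrix(phi, ncol = 1, dimnames = list(names(phi), "R1"))
  phi <- phi[tree@paths, , drop = FALSE]
  if (any(phi < -1e-12 | phi > 1 + 1e-12)) stop("phi outside [0, 1]")
  if (any(abs(phi["0", ] - 1) > 1e-9)) stop("phi at the healthy root must be 1")
  eta <- phi
  for (p in tree@paths) {
    kids <- tree@paths[!is.na(tree@parent) & tree@parent == p]
    if (length(kids)) {
      childsum <- colSums(phi[kids, , drop = FALSE])
      if (any(childsum > phi[p, ] + 1e-9))
        stop("prevalence constraint violated at node ", p,
             ": children's phi sum exceeds the parent's")
      eta[p, ] <- phi[p, ] - childsum
    }
  }
  if (vec) eta[, 1] else eta
}

#' Cellular prevalences from clone fractions
#'
#' Inverse of \code{\link{cloneFractions}}: phi_v is the sum of eta over
#' the subtree rooted at v.
#'
#' @param tree a \linkS4class{ClonalTree}.
#' @param eta numeric matrix (nodes x regions) or named vector.
#' @return phi in the same shape as \code{eta}.
#' @export
prevalenceFromFractions <- function(tree, eta) {
  vec <- is.null(dim(eta))
  if (vec) eta <- matrix(eta, ncol = 1, dimnames = list(names(eta), "R1"))
  eta <- eta[tree@paths, , drop = FALSE]
  phi <- eta
  for (p in rev(tree@paths)) { # children before parents
    kids <- tree@paths[!is.na(tree@parent) & tree@parent == p]
    if (length(kids)) phi[p, ] <- eta[p, ] + colSums(phi[kids, , drop = FALSE])
  }
  if (vec) phi[, 1] else phi
}

#' Construct a PrevalenceField
#'
#' @param tree a \linkS4class{ClonalTree}.
#' @param phi numeric matrix (nodes x regions), rownames = node paths.
#' @param regions optional region labels.
#' @return A \linkS4class{PrevalenceField}; eta is derived from phi.
#' @export
PrevalenceField <- function(tree, phi, regions = NULL) {
  if (is.null(dim(phi))) phi <- matrix(phi, ncol = 1, dimnames = list(names(phi), "R1"))
  if (is.null(regions)) regions <- colnames(phi)
  if (is.null(regions)) regions <- paste0("R", seq_len(ncol(phi)))
  phi <- phi[tree@paths, , drop = FALSE]
  colnames(phi) <- regions
  eta <- cloneFractions(tree, phi)
  new("PrevalenceField", phi = phi, eta = eta, regions = regions)
}

#' Mutation status of a cell placed at a clone
#'
#' A cell assigned to clone v carries exactly the SNVs assigned to v and
#' to its ancestors. Cells at the healthy root carry no SNVs.
#'
#' @param tree a \linkS4class{ClonalTree}.
#' @param z character vector of SNV node paths.
#' @param cellNode node path of the cell's clone.
#' @return binary integer vector over SNVs.
#' @export
mutationStatus <- function(tree, z, cellNode) {
  if (!cellNode %in% tree@paths) stop("unknown node: ", cellNode)
  if (!all(z %in% tree@paths)) stop("SNV assigned to a node not in the tree")
  as.integer(.path_is_anc(z, cellNode))
}

#' Ancestral matrix of an SNV-to-clone assignment
#'
#' A_{i,j} = 1 iff the clone of SNV i is a strict ancestor of the clone of
#' SNV j. Co-clustered SNVs have A_{i,j} = A_{j,i} = 0; the diagonal is 0.
#'
#' @param tree a \linkS4class{ClonalTree}.
#' @param z character vector of SNV node paths (optionally named by SNV id).
#' @return binary integer matrix (SNVs x SNVs).
#' @export
ancestralMatrix <- function(tree, z) {
  if (!all(z %in% tree@paths)) stop("SNV assigned to a node not in the tree")
  N <- length(z)
  A <- matrix(0L, N, N)
  if (!is.null(names(z))) dimnames(A) <- list(names(z), names(z))
  nodes <- unique(z)
  anc <- outer(nodes, nodes, Vectorize(function(u, v) u != v && .path_is_anc(u, v)))
  dimnames(anc) <- list(nodes, nodes)
  iz <- match(z, nodes)
  A[] <- as.integer(anc[iz, iz])
  diag(A) <- 0L
  A
}
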