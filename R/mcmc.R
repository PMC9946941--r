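#' Sampler configuration
#'
#' @param nIterations total MCMC iterations (default 2000).
#' @param burnIn iterations discarded before retaining samples (default 1000).
#' @param thinning keep every k-th post-burn-in sample (default 1).
#' @param seed integer seed governing all randomness of the run.
#' @param mhConcentration initial concentration of the Dirichlet
#'   random-walk proposal on clone fractions (default 50); adapted toward
#'   a 23 percent acceptance rate during burn-in, then frozen.
#' @param mhPseudocount pseudocount added to the proposal concentration so
#'   empty components can be revisited (default 0.5).
#' @param mhMoves Metropolis-Hastings prevalence updates per iteration and
#'   region (default 20).
#' @param epsBulk bulk sequencing error probability (default 0.001).
#' @param pruneEmpty prune empty non-root leaves after each sweep (default
#'   TRUE).
#' @param verbose print progress every 100 iterations.
#' @return list of class \code{samplerConfig}.
#' @export
samplerConfig <- function(nIterations = 2000L, burnIn = 1000L, thinning = 1L,
                          seed = 1L, mhConcentration = 50, mhPseudocount = 0.5,
                          mhMoves = 20L, epsBulk = 0.001, pruneEmpty = TRUE,
                          verbose = FALSE) {
  stopifnot(nIterations >= 1, burnIn >= 0, burnIn < nIterations, thinning >= 1,
            mhConcentration > 0, mhPseudocount > 0, epsBulk > 0, epsBulk < 0.5)
  structure(list(nIterations = as.integer(nIterations), burnIn = as.integer(burnIn),
                 thinning = as.integer(thinning), seed = as.integer(seed),
                 mhConcentration = mhConcentration, mhPseudocount = mhPseudocount,
                 mhMoves = as.integer(mhMoves), epsBulk = epsBulk,
                 pruneEmpty = isTRUE(pruneEmpty), verbose = isTRUE(verbose)),
            class = "samplerConfig")
}

# ---- internal sampler state ------------------------------------------------
# An environment holding the lazily instantiated tree (paths/parent/children/
# depth/nu/psi as in the TSSB env), the assignment z, per-node SNV counts,
# cellular prevalences phi (nodes x regions), stick masses pi/ups, the
# ancestor indicator matrix anc[u, v] = (u ancestor-of-or-equal v) over all
# instantiated nodes, and the single-cell caches: L (cells x nodes), the
# active node set (nodes carrying SNVs, their ancestors, root, progenitor),
# the per-cell log-sum-exp lse over active columns and its total sc_sum.

.state_init <- function(bulk, sc, tssb, scHyper, config) {
  st <- .tssb_new_env()
  st$hyper_t <- tssb
  st$hyper_s <- scHyper
  st$config <- config
  st$eps <- config$epsBulk
  N <- length(bulk@snvIds)
  st$N <- N
  st$R <- length(bulk@regions)
  st$bulk_b <- bulk@b; st$bulk_d <- bulk@d
  st$gset <- lapply(seq_len(N), function(n) {
    g <- genotypeSet(bulk@majorCn[n], bulk@minorCn[n])
    list(v = g$v, c = g$c[1], G = nrow(g))
  })
  st$cn_groups <- split(seq_len(N), paste(bulk@majorCn, bulk@minorCn))
  st$snv_ids <- bulk@snvIds
  st$regions <- bulk@regions
  if (!is.null(sc) && nrow(sc@tot) > 0L) {
    st$C <- nrow(sc@tot)
    st$cells <- rownames(sc@tot)
    st$sc <- .sc_components(sc, scHyper)
    st$scD <- Matrix::sparseMatrix(i = st$sc$i, j = st$sc$j,
                                   x = st$sc$ll1 - st$sc$ll0,
                                   dims = c(st$C, N))
  } else {
    st$C <- 0L
    st$sc <- NULL
  }
  # initial tree: root -> progenitor; all SNVs at the progenitor
  .tssb_add_child(st, "0", tssb)
  st$psi[["0"]] <- 1
  vaf <- pmin(pmax(2 * colSums(st$bulk_b) / pmax(colSums(st$bulk_d), 1), 0.05), 0.95)
  st$phi <- rbind("0" = rep(1, st$R), "0.1" = vaf)
  colnames(st$phi) <- st$regions
  st$z <- rep("0.1", N)
  st$nsnv <- c("0" = 0L, "0.1" = N)
  st$on_create <- function(path) .state_node_created(st, path)
  .state_rebuild(st)
  .state_gibbs_sticks(st)
  st
}

# Bookkeeping when the slice search instantiates a new node. The node's
# prevalence is an auxiliary variable with a state-independent law:
# uniform on [0, phi_parent] per region. Keeping the law independent of
# the sibling configuration makes its density cancel exactly for nodes
# whose status does not change in a move; the sibling-sum feasibility is
# enforced by the model prior when the node activates (.dim_cond).
.state_node_created <- function(st, path) {
  p <- st$parent[[path]]
  st$phi <- rbind(st$phi, stats::runif(st$R, 0, st$phi[p, ]))
  rownames(st$phi)[nrow(st$phi)] <- path
  st$nsnv[[path]] <- 0L
  # stick mass: residual reaching the new (last) child of p
  k <- length(st$children[[p]])
  w <- st$psi[[p]]
  ups_new <- (1 - st$nu[[p]]) * st$ups[[p]] * w[k] * prod(1 - w[seq_len(k - 1L)])
  st$ups[[path]] <- ups_new
  st$pi[[path]] <- st$nu[[path]] * ups_new
  # ancestor matrix: new leaf inherits the parent's ancestor column
  nc <- st$anc[, p]
  st$anc <- cbind(st$anc, nc)
  st$anc <- rbind(st$anc, FALSE)
  st$anc[nrow(st$anc), ncol(st$anc)] <- TRUE
  rownames(st$anc)[nrow(st$anc)] <- path
  colnames(st$anc)[ncol(st$anc)] <- path
  if (st$C > 0L) {
    st$L <- cbind(st$L, st$L[, p])
    colnames(st$L)[ncol(st$L)] <- path
  }
  invisible(path)
}

.state_active_set <- function(st) {
  carriers <- names(st$nsnv)[st$nsnv > 0L]
  act <- vapply(st$paths, function(u)
    u %in% c("0", "0.1") || any(.path_is_anc(u, carriers)), logical(1))
  st$paths[act]
}

.state_refresh_sc <- function(st) {
  st$active <- .state_active_set(st)
  if (st$C > 0L) {
    st$lse <- .row_logsumexp(st$L[, st$active, drop = FALSE])
    st$sc_sum <- sum(st$lse)
  } else {
    st$lse <- numeric(0)
    st$sc_sum <- 0
  }
}

# full rebuild of derived structures from (paths, parent, z, phi)
.state_rebuild <- function(st) {
  ord <- .path_order(st$paths)
  st$paths <- st$paths[ord]
  V <- length(st$paths)
  st$anc <- outer(st$paths, st$paths,
                  Vectorize(function(u, v) .path_is_anc(u, v)))
  dimnames(st$anc) <- list(st$paths, st$paths)
  nv <- table(factor(st$z, levels = st$paths))
  st$nsnv <- stats::setNames(as.integer(nv), st$paths)
  if (st$C > 0L) {
    A <- matrix(0, st$N, V, dimnames = list(NULL, st$paths))
    A[] <- st$anc[st$z, , drop = FALSE] + 0
    st$L <- as.matrix(st$scD %*% A) + st$sc$base
    colnames(st$L) <- st$paths
  } else {
    st$L <- matrix(0, 0L, V, dimnames = list(NULL, st$paths))
  }
  .state_refresh_sc(st)
}

# Un-instantiate empty trailing leaves: an inactive childless node that is
# the last child of its parent is removed together with its psi-stick,
# which is exactly the lazy-representation contraction (a stick holding no
# data has its prior as conditional and can be redrawn on demand).
# Interior empty nodes are kept as inactive placeholders: renumbering
# sibling indices would move prior mass between configurations, because
# the TSSB psi-sticks are not exchangeable over child positions.
.state_prune_rebuild <- function(st) {
  dropped <- FALSE
  repeat {
    drop <- character(0)
    for (p in st$paths) {
      if (p %in% c("0", "0.1")) next
      if (length(st$children[[p]])) next
      if (p %in% st$active) next
      par <- st$parent[[p]]
      kids <- st$children[[par]]
      if (kids[length(kids)] == p) drop <- c(drop, p)
    }
    if (!length(drop)) break
    dropped <- TRUE
    for (p in drop) {
      par <- st$parent[[p]]
      st$children[[par]] <- st$children[[par]][st$children[[par]] != p]
      st$psi[[par]] <- st$psi[[par]][seq_along(st$children[[par]])]
      st$children[[p]] <- NULL
      st$psi[[p]] <- NULL
      st$nu <- st$nu[names(st$nu) != p]
      st$parent <- st$parent[names(st$parent) != p]
      st$depth <- st$depth[names(st$depth) != p]
      st$paths <- st$paths[st$paths != p]
      st$phi <- st$phi[rownames(st$phi) != p, , drop = FALSE]
    }
  }
  if (dropped) .state_rebuild(st)
  invisible(st)
}

# conjugate Beta updates of the nu/psi sticks given the SNV counts, then
# recompute the stick masses
.state_gibbs_sticks <- function(st) {
  ord <- .path_order(st$paths)
  paths <- st$paths[ord]
  sub <- stats::setNames(as.numeric(st$nsnv[paths]), paths)
  for (p in rev(paths)) {
    kids <- st$children[[p]]
    if (length(kids)) sub[[p]] <- sub[[p]] + sum(sub[kids])
  }
  h <- st$hyper_t
  for (p in paths) {
    np <- as.numeric(st$nsnv[[p]])
    if (p == "0") {
      st$nu[[p]] <- 0
    } else {
      st$nu[[p]] <- stats::rbeta(1, 1 + np,
                                 h$lambda0 * h$lambda^st$depth[[p]] + (sub[[p]] - np))
    }
    kids <- st$children[[p]]
    if (!length(kids)) { st$psi[[p]] <- numeric(0); next }
    if (p == "0") { st$psi[[p]] <- 1; next }
    nk <- length(kids)
    later <- rev(cumsum(rev(sub[kids])))
    wk <- numeric(nk)
    for (k in seq_len(nk)) {
      after <- if (k < nk) later[k + 1L] else 0
      wk[k] <- stats::rbeta(1, 1 + sub[[kids[k]]], h$gamma + after)
    }
    st$psi[[p]] <- wk
  }
  .state_masses(st)
  invisible(st)
}

.state_masses <- function(st) {
  paths <- st$paths[.path_order(st$paths)]
  ups <- stats::setNames(numeric(length(paths)), paths)
  pim <- ups
  ups[["0"]] <- 1
  for (p in paths) {
    pim[[p]] <- st$nu[[p]] * ups[[p]]
    kids <- st$children[[p]]
    if (length(kids)) {
      w <- st$psi[[p]]
      rem <- (1 - st$nu[[p]]) * ups[[p]]
      cum <- 1
      for (k in seq_along(kids)) {
        ups[[kids[k]]] <- rem * w[k] * cum
        cum <- cum * (1 - w[k])
      }
    }
  }
  st$ups <- ups
  st$pi <- pim
  invisible(st)
}

# ---- conditional log-weights for the slice move ---------------------------

.bulk_site_cond <- function(st, n, v) {
  g <- st$gset[[n]]
  phiv <- st$phi[v, ]
  if (g$G == 1L) {
    th <- thetaSuccess(g$v, g$c, phiv, st$eps)
    return(sum(stats::dbinom(st$bulk_b[n, ], st$bulk_d[n, ], th, log = TRUE)))
  }
  # G x R grid in one vectorized call, then log-sum-exp per region
  th <- thetaSuccess(rep(g$v, st$R), g$c, rep(phiv, each = g$G), st$eps)
  ll <- stats::dbinom(rep(st$bulk_b[n, ], each = g$G),
                      rep(st$bulk_d[n, ], each = g$G), th, log = TRUE)
  ll <- matrix(ll, nrow = g$G)
  sum(apply(ll, 2, .logsumexp)) - st$R * log(g$G)
}

# Active node set of the candidate state z[n] <- v: the nodes carrying
# SNVs (with n moved to v) plus their ancestors, the root and the
# progenitor. Removing n from its current node may deactivate it (and
# bare ancestors); v's ancestor chain joins the set.
.cand_active <- function(st, n, v) {
  a <- st$z[n]
  # the active set with SNV n removed is constant during one slice move;
  # memoize it on the state
  key <- paste0(n, "@", a)
  if (!identical(st$.awo_key, key)) {
    if (st$nsnv[[a]] > 1L) {
      awo <- st$active
    } else {
      carriers <- setdiff(names(st$nsnv)[st$nsnv > 0L], a)
      awo <- st$paths[vapply(st$paths, function(u)
        u %in% c("0", "0.1") || any(.path_is_anc(u, carriers)), logical(1))]
    }
    st$.awo <- awo
    st$.awo_key <- key
  }
  awo <- st$.awo
  vanc <- st$paths[.path_is_anc(st$paths, v)]
  act2 <- unique(c(awo, vanc))
  list(awo = awo, act2 = act2, activated = vanc[!(vanc %in% awo)])
}

# feasible prevalence interval of node w against the active siblings
.avail_active <- function(st, w, act) {
  p <- st$parent[[w]]
  sibs <- intersect(setdiff(st$children[[p]], w), act)
  as.numeric(st$phi[p, ]) -
    (if (length(sibs)) colSums(st$phi[sibs, , drop = FALSE]) else 0)
}

# Trans-dimensional prior terms of the candidate state: the flat Dirichlet
# prior on the clone fractions has density Gamma(V) on the V-simplex per
# region, and the prevalences of inactive nodes are auxiliary variables
# with a uniform law on [0, phi_parent]. Activating a node moves its phi
# from the auxiliary law into the model prior, contributing
# log Gamma(|V'|) - log Gamma(|V|) + sum log(phi_parent); a phi violating
# the active-tree sibling-sum constraint makes the candidate state's
# prior density zero (-Inf).
.dim_cond <- function(st, cand) {
  lw <- st$R * lgamma(length(cand$act2))
  for (w in cand$activated) {
    av <- .avail_active(st, w, cand$awo)
    phw <- as.numeric(st$phi[w, ])
    if (any(phw > av + 1e-12)) return(-Inf)
    lw <- lw + sum(log(pmax(as.numeric(st$phi[st$parent[[w]], ]), 1e-300)))
  }
  lw
}

# Marginal single-cell log-likelihood of the candidate state z[n] <- v,
# with the uniform cell prior over the candidate's active node set.
.sc_cond <- function(st, n, v, cand) {
  if (st$C == 0L) return(0)
  act <- st$active
  a <- st$z[n]
  if (v == a) return(st$sc_sum - st$C * log(length(act)))
  act2 <- cand$act2
  idx <- st$sc$covCells[[n]]
  if (length(act2) == length(act) && setequal(act2, act)) {
    # common case: the node set is unchanged; only covered cells move
    if (!length(idx)) return(st$sc_sum - st$C * log(length(act)))
    dn <- st$sc$covDelta[[n]]
    delta <- (st$anc[v, act] + 0) - (st$anc[a, act] + 0)
    if (all(delta == 0)) return(st$sc_sum - st$C * log(length(act)))
    Lsub <- st$L[idx, act, drop = FALSE] + outer(dn, delta)
    return(st$sc_sum - sum(st$lse[idx]) + sum(.row_logsumexp(Lsub)) -
             st$C * log(length(act)))
  }
  L2 <- st$L[, act2, drop = FALSE]
  if (length(idx)) {
    dn <- st$sc$covDelta[[n]]
    delta <- (st$anc[v, act2] + 0) - (st$anc[a, act2] + 0)
    nz <- which(delta != 0)
    if (length(nz))
      L2[idx, nz] <- L2[idx, nz, drop = FALSE] + outer(dn, delta[nz])
  }
  sum(.row_logsumexp(L2)) - st$C * log(length(act2))
}

# Conditional log-weight of assigning SNV n to node v, used as the slice
# threshold. The TSSB prior mass pi_v is NOT included here: the uniform
# coordinate u already visits nodes with probability pi_v, so the slice
# level compares the likelihood plus the trans-dimensional prior terms,
# and the stationary conditional is proportional to pi_v times that
# weight.
.cond_logw <- function(st, n, v) {
  if (v == "0") return(-Inf) # the healthy root carries no SNVs
  cand <- .cand_active(st, n, v)
  dimw <- .dim_cond(st, cand)
  if (!is.finite(dimw)) return(-Inf)
  dimw + .bulk_site_cond(st, n, v) + .sc_cond(st, n, v, cand)
}

# commit a re-assignment of SNV n to node v
.state_set_z <- function(st, n, v) {
  a <- st$z[n]
  if (a == v) return(invisible(st))
  idx <- integer(0)
  if (st$C > 0L) {
    idx <- st$sc$covCells[[n]]
    if (length(idx)) {
      dn <- st$sc$covDelta[[n]]
      delta <- (st$anc[v, ] + 0) - (st$anc[a, ] + 0)
      nz <- which(delta != 0)
      if (length(nz))
        st$L[idx, nz] <- st$L[idx, nz, drop = FALSE] + outer(dn, delta[nz])
    }
  }
  # the active set only changes if v was inactive or a may drop out
  same_active <- (v %in% st$active) && st$nsnv[[a]] > 1L
  st$z[n] <- v
  st$nsnv[[a]] <- st$nsnv[[a]] - 1L
  st$nsnv[[v]] <- st$nsnv[[v]] + 1L
  if (same_active) {
    if (st$C > 0L && length(idx)) {
      st$lse[idx] <- .row_logsumexp(st$L[idx, st$active, drop = FALSE])
      st$sc_sum <- sum(st$lse)
    }
  } else {
    .state_refresh_sc(st)
  }
  invisible(st)
}

# one slice-sampling update of the assignment of SNV n; logw_fn can inject
# an alternative conditional (used by correctness tests)
.state_slice_move <- function(st, n, logw_fn = NULL, max_shrink = 1000L) {
  st$.awo_key <- NULL # the memoized candidate active set is per-move
  a <- st$z[n]
  lw <- if (is.null(logw_fn)) .cond_logw(st, n, a) else logw_fn(a)
  s <- lw + log(stats::runif(1))
  lo <- 0; hi <- 1
  for (i in seq_len(max_shrink)) {
    u <- stats::runif(1, lo, hi)
    v <- .tssb_find_node(st, u, st$hyper_t, on_create = st$on_create)
    wv <- if (is.null(logw_fn)) .cond_logw(st, n, v) else logw_fn(v)
    if (wv > s) {
      .state_set_z(st, n, v)
      return(invisible(v))
    }
    if (v == a) return(invisible(a)) # numerically stuck at the current node
    if (.path_less(v, a)) lo <- u else hi <- u
  }
  stop("slice search did not terminate for SNV ", n,
       " (current node ", a, ", ", length(st$paths), " nodes)")
}

.state_slice_sweep <- function(st) {
  for (n in seq_len(st$N)) .state_slice_move(st, n)
  invisible(st)
}

# ---- Metropolis-Hastings update of the clone fractions --------------------

.bulk_region_ll <- function(st, r, phiv) {
  phin <- phiv[st$z]
  tot <- 0
  for (grp in st$cn_groups) {
    g <- st$gset[[grp[1L]]]
    b <- st$bulk_b[grp, r]; d <- st$bulk_d[grp, r]
    if (g$G == 1L) {
      th <- thetaSuccess(g$v, g$c, phin[grp], st$eps)
      tot <- tot + sum(stats::dbinom(b, d, th, log = TRUE))
    } else {
      M <- vapply(seq_len(g$G), function(k)
        stats::dbinom(b, d, thetaSuccess(g$v[k], g$c, phin[grp], st$eps),
                      log = TRUE), numeric(length(grp)))
      if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
      tot <- tot + sum(.row_logsumexp(M)) - length(grp) * log(g$G)
    }
  }
  tot
}

.eta_from_phi_col <- function(st, phiv) {
  eta <- phiv
  for (p in st$paths) {
    kids <- st$children[[p]]
    if (length(kids)) eta[[p]] <- phiv[[p]] - sum(phiv[kids])
  }
  eta
}

.phi_from_eta_col <- function(st, etav) {
  phiv <- etav
  for (p in rev(st$paths[.path_order(st$paths)])) {
    kids <- st$children[[p]]
    if (length(kids)) phiv[[p]] <- etav[[p]] + sum(phiv[kids])
  }
  phiv
}

.ddirichlet_log <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

# Metropolis-Hastings update of the clone fractions, per region, on the
# ACTIVE tree (inactive placeholder nodes are not part of the eta
# simplex). Placeholders tie into the move only through their auxiliary
# prevalence law U(0, phi_parent): when an active parent's phi changes,
# the density ratio phi_old/phi_new enters the acceptance ratio and a
# shrinking parent cannot cross below a placeholder child's phi.
.state_mh_eta <- function(st) {
  cfg <- st$config
  act <- st$active[.path_order(st$active)]
  V <- length(act)
  inact <- setdiff(st$paths, act)
  inact <- inact[vapply(inact, function(w) st$parent[[w]] %in% act, logical(1))]
  kids_act <- lapply(stats::setNames(act, act), function(p)
    intersect(st$children[[p]], act))
  eta_of <- function(phiv) {
    eta <- phiv
    for (p in act) if (length(kids_act[[p]]))
      eta[[p]] <- phiv[[p]] - sum(phiv[kids_act[[p]]])
    eta
  }
  phi_of <- function(etav) {
    phiv <- etav
    for (p in rev(act)) if (length(kids_act[[p]]))
      phiv[[p]] <- etav[[p]] + sum(phiv[kids_act[[p]]])
    phiv
  }
  if (is.null(st$mh_kappa)) st$mh_kappa <- rep(cfg$mhConcentration, st$R)
  adapting <- isTRUE(st$iter <= cfg$burnIn)
  for (r in seq_len(st$R)) {
    phiv <- st$phi[act, r]
    names(phiv) <- act
    llcur <- .bulk_region_ll(st, r, phiv)
    kappa <- st$mh_kappa[r]
    for (m in seq_len(cfg$mhMoves)) {
      eta <- pmax(eta_of(phiv), 0)
      a_prop <- kappa * eta + cfg$mhPseudocount
      y <- stats::rgamma(V, a_prop)
      acc <- FALSE
      if (!any(y == 0) && sum(y) > 0) { # zero components: silent rejection
        y <- y / sum(y)
        names(y) <- act
        a_rev <- kappa * y + cfg$mhPseudocount
        phinew <- phi_of(y)
        qadj <- 0
        for (w in inact) {
          par <- st$parent[[w]]
          if (phinew[[par]] == phiv[[par]]) next
          if (st$phi[w, r] > phinew[[par]]) { qadj <- -Inf; break }
          qadj <- qadj + log(phiv[[par]]) - log(phinew[[par]])
        }
        if (is.finite(qadj)) {
          llnew <- .bulk_region_ll(st, r, phinew)
          logr <- llnew - llcur + qadj +
            .ddirichlet_log(pmax(eta, 1e-300), a_rev) -
            .ddirichlet_log(y, a_prop)
          if (is.finite(logr) && log(stats::runif(1)) < logr) {
            phiv <- phinew
            llcur <- llnew
            st$mh_accept <- st$mh_accept + 1L
            acc <- TRUE
          }
        }
      }
      st$mh_total <- st$mh_total + 1L
      # Robbins-Monro tuning of the proposal concentration during burn-in
      # (a larger concentration means smaller steps)
      if (adapting)
        kappa <- kappa * exp(0.1 * ((!acc) - 0.766))
    }
    st$mh_kappa[r] <- min(max(kappa, 1), 1e8)
    st$phi[act, r] <- phiv[act]
  }
  invisible(st)
}

.state_log_joint <- function(st) {
  lb <- sum(vapply(seq_len(st$R), function(r)
    .bulk_region_ll(st, r, stats::setNames(st$phi[st$active, r], st$active)),
    numeric(1)))
  lsc <- if (st$C > 0L) st$sc_sum - st$C * log(length(st$active)) else 0
  lpi <- log(pmax(st$pi[st$z], 1e-300))
  # flat Dirichlet prior density on the clone fractions: Gamma(V) per region
  lb + lsc + sum(lpi) + st$R * lgamma(length(st$active))
}

.state_snapshot <- function(st, iter, lj) {
  # report the active tree only; child indices may be non-contiguous
  # where inactive sibling placeholders were left out
  paths <- st$active[.path_order(st$active)]
  list(iteration = iter, logJoint = lj, paths = paths,
       parent = st$parent[paths],
       z = stats::setNames(st$z, st$snv_ids),
       phi = st$phi[paths, , drop = FALSE],
       nu = st$nu[paths], psi = st$psi[paths],
       pi = st$pi[paths])
}

# ---- public interface ------------------------------------------------------

#' Run the clonal-tree MCMC sampler
#'
#' Posterior inference over (tree, SNV assignment, cellular prevalences) by
#' iterating a slice-sampling sweep over all SNV assignments (lazily
#' instantiating nodes through the stick-breaking representation), pruning
#' of empty leaves, conjugate Gibbs updates of the sticks, and
#' Metropolis-Hastings updates of the per-region clone fractions. With no
#' single-cell data the sampler reduces to the bulk-only TSSB
#' deconvolution. Fully reproducible under a fixed seed.
#'
#' @param bulk a \linkS4class{BulkData}.
#' @param sc an \linkS4class{ScVariantData} or NULL for bulk-only mode;
#'   its SNV columns must match the bulk SNV ids.
#' @param tssb a \code{\link{tssbHyperparams}} object.
#' @param scHyper an \code{\link{scRnaHyperparams}} object.
#' @param config a \code{\link{samplerConfig}} object.
#' @param nChains number of independent restarts; the fit with the best
#'   MAP log-joint is returned (chain seeds are derived deterministically
#'   from \code{config$seed}).
#' @return A \linkS4class{CloneTreeFit} holding the MAP state, the
#'   per-iteration trace, and the retained samples.
#' @export
runCloneMCMC <- function(bulk, sc = NULL, tssb = tssbHyperparams(),
                         scHyper = scRnaHyperparams(),
                         config = samplerConfig(), nChains = 1L) {
  stopifnot(is(bulk, "BulkData"), inherits(config, "samplerConfig"),
            nChains >= 1L)
  if (!is.null(sc)) {
    ids <- colnames(sc@tot)
    if (!setequal(ids, bulk@snvIds))
      stop("single-cell SNV ids do not match the bulk SNV ids")
    if (!identical(ids, bulk@snvIds)) {
      sc <- new("ScVariantData",
                var = sc@var[, bulk@snvIds, drop = FALSE],
                tot = sc@tot[, bulk@snvIds, drop = FALSE])
    }
  }
  if (nChains > 1L) {
    fits <- lapply(seq_len(nChains), function(k) {
      cfg <- config
      cfg$seed <- (config$seed + 9973L * (k - 1L)) %% .Machine$integer.max
      runCloneMCMC(bulk, sc, tssb, scHyper, cfg, nChains = 1L)
    })
    lj <- vapply(fits, function(f) f@logJoint, numeric(1))
    return(fits[[which.max(lj)]])
  }
  set.seed(config$seed)
  st <- .state_init(bulk, sc, tssb, scHyper, config)
  st$mh_accept <- 0L; st$mh_total <- 0L
  niter <- config$nIterations
  trace <- data.frame(iteration = seq_len(niter), logJoint = NA_real_,
                      nClones = NA_integer_)
  samples <- vector("list", niter)
  nkeep <- 0L
  for (it in seq_len(niter)) {
    st$iter <- it
    .state_slice_sweep(st)
    if (config$pruneEmpty) .state_prune_rebuild(st)
    .state_gibbs_sticks(st)
    .state_mh_eta(st)
    lj <- .state_log_joint(st)
    if (!is.finite(lj)) stop("non-finite log joint at iteration ", it)
    trace$logJoint[it] <- lj
    trace$nClones[it] <- sum(st$nsnv > 0L)
    if (it > config$burnIn && ((it - config$burnIn) %% config$thinning == 0L)) {
      nkeep <- nkeep + 1L
      samples[[nkeep]] <- .state_snapshot(st, it, lj)
    }
    if (config$verbose && it %% 100L == 0L)
      message(sprintf("iteration %d: log joint %.2f, %d clones", it, lj,
                      trace$nClones[it]))
  }
  samples <- samples[seq_len(nkeep)]
  map <- mapEstimate(samples)
  tree <- ClonalTree(map$paths, nu = map$nu, psi = map$psi)
  prev <- PrevalenceField(tree, map$phi, regions = bulk@regions)
  new("CloneTreeFit", tree = tree, prevalence = prev, z = map$z,
      logJoint = map$logJoint, trace = trace, samples = samples,
      config = c(unclass(config),
                 list(mhAcceptRate = if (st$mh_total) st$mh_accept / st$mh_total else NA_real_)))
}

#' MAP state from retained posterior samples
#'
#' Returns the retained sample with the largest unnormalized log posterior;
#' ties are broken by the earliest iteration.
#'
#' @param samples list of retained samples (from
#'   \code{\link{runCloneMCMC}}) or a \linkS4class{CloneTreeFit}.
#' @return the MAP sample (a list with paths, z, phi, sticks, logJoint).
#' @export
mapEstimate <- function(samples) {
  if (is(samples, "CloneTreeFit")) samples <- samples@samples
  if (!length(samples)) stop("no retained samples")
  lj <- vapply(samples, function(s) s$logJoint, numeric(1))
  samples[[which.max(lj)]]
}

#' Posterior cell-to-clone assignment under the MAP tree
#'
#' For each cell, P(clone = v) is proportional to the cell's
#' log-likelihood given clone v (uniform clone prior, Bayes rule row-wise).
#' The argmax clone is reported with ties broken by shallower depth and
#' then canonical path order, together with the predicted mutation-status
#' matrix under the argmax clone.
#'
#' @param fit a \linkS4class{CloneTreeFit} (or a single posterior sample).
#' @param sc an \linkS4class{ScVariantData}; columns must match the fitted
#'   SNV ids.
#' @param scHyper an \code{\link{scRnaHyperparams}} object.
#' @return A \linkS4class{CellAssignment}.
#' @export
assignCells <- function(fit, sc, scHyper = scRnaHyperparams()) {
  if (is(fit, "CloneTreeFit")) {
    tree <- fit@tree
    z <- fit@z
  } else {
    tree <- ClonalTree(fit$paths, nu = fit$nu, psi = fit$psi)
    z <- fit$z
  }
  ids <- names(z)
  if (!is.null(ids) && !identical(colnames(sc@tot), ids)) {
    sc <- new("ScVariantData", var = sc@var[, ids, drop = FALSE],
              tot = sc@tot[, ids, drop = FALSE])
  }
  comp <- .sc_components(sc, scHyper)
  L <- .cell_node_loglik(tree, z, comp)
  lse <- .row_logsumexp(L)
  prob <- exp(L - lse)
  prob <- prob / rowSums(prob)
  rownames(prob) <- rownames(sc@tot)
  paths <- tree@paths
  depth <- .path_depth(paths)
  ord <- order(depth, .path_order(paths)) # shallower first, then path order
  mapNode <- paths[ord][max.col(prob[, ord, drop = FALSE], ties.method = "first")]
  names(mapNode) <- rownames(sc@tot)
  mu <- t(vapply(mapNode, function(v) mutationStatus(tree, z, v),
                 integer(length(z))))
  dimnames(mu) <- list(rownames(sc@tot), ids)
  new("CellAssignment", prob = prob, mapNode = mapNode, muHat = mu)
}
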