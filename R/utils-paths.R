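# Node addressing by canonical child-index paths.
# The root is "0"; the k-th child of node p is paste0(p, ".", k).
# All orderings (canonical node order, tie-breaks) derive from the
# depth-first order in which a node precedes its own descendants and
# siblings are ordered by child index.

.path_split <- function(p) as.integer(strsplit(p, ".", fixed = TRUE)[[1L]])

.path_depth <- function(p) {
  # number of edges from root; root "0" has depth 0
  vapply(p, function(x) length(.path_split(x)) - 1L, integer(1), USE.NAMES = FALSE)
}

.path_parent <- function(p) {
  ifelse(grepl(".", p, fixed = TRUE), sub("\\.[0-9]+$", "", p), NA_character_)
}

#' @keywords internal
.path_is_anc <- function(u, v) {
  # TRUE if u is an ancestor of v or u == v
  u == v | startsWith(v, paste0(u, "."))
}

.path_less <- function(a, b) {
  # strict depth-first order: prefix precedes extension, siblings by index
  if (a == b) return(FALSE)
  va <- .path_split(a); vb <- .path_split(b)
  k <- min(length(va), length(vb))
  for (i in seq_len(k)) {
    if (va[i] < vb[i]) return(TRUE)
    if (va[i] > vb[i]) return(FALSE)
  }
  length(va) < length(vb)
}

.path_order <- function(paths) {
  if (length(paths) <= 1L) return(seq_along(paths))
  vecs <- lapply(paths, .path_split)
  d <- max(lengths(vecs))
  # pad with -1 so a node sorts before its descendants
  mat <- t(vapply(vecs, function(v) c(v, rep(-1L, d - length(v))), integer(d)))
  do.call(order, lapply(seq_len(d), function(j) mat[, j]))
}

.canonical_paths <- function(paths) paths[.path_order(paths)]
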