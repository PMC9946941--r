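# On-disk formats: long TSV tables for bulk and single-cell counts
# (1-based VCF-style coordinates), a tree bundle (newick + node sidecar
# TSV + JSON state dump), and a JSON run manifest.

.req_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing column(s) in ", what, ": ", paste(miss, collapse = ", "))
}

#' Read a bulk SNV table
#'
#' Tab-separated with header columns snv_id, chrom, pos, ref, alt, region,
#' var_reads, total_reads, major_cn, minor_cn; one row per (SNV, region).
#' Positions are 1-based (VCF convention).
#'
#' @param path file path.
#' @return A \linkS4class{BulkData}.
#' @export
readBulkTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .req_cols(df, c("snv_id", "chrom", "pos", "ref", "alt", "region",
                  "var_reads", "total_reads", "major_cn", "minor_cn"),
            "bulk table")
  key <- paste(df$snv_id, df$region)
  if (anyDuplicated(key))
    stop("duplicate (snv_id, region) rows: ", key[duplicated(key)][1])
  bad <- which(df$var_reads > df$total_reads)
  if (length(bad))
    stop("var_reads exceeds total_reads at row ", bad[1],
         " (snv ", df$snv_id[bad[1]], ")")
  if (any(df$major_cn == 0))
    stop("major_cn = 0 (homozygous deletion) for snv ",
         df$snv_id[df$major_cn == 0][1], "; exclude such loci upstream")
  bad <- which(df$minor_cn > df$major_cn)
  if (length(bad))
    stop("minor_cn exceeds major_cn for snv ", df$snv_id[bad[1]])
  ids <- unique(df$snv_id)
  regions <- unique(df$region)
  b <- d <- matrix(0L, length(ids), length(regions),
                   dimnames = list(ids, regions))
  i <- match(df$snv_id, ids); j <- match(df$region, regions)
  b[cbind(i, j)] <- as.integer(df$var_reads)
  d[cbind(i, j)] <- as.integer(df$total_reads)
  first <- !duplicated(df$snv_id)
  meta <- df[first, c("chrom", "pos", "ref", "alt")]
  rownames(meta) <- df$snv_id[first]
  M <- as.integer(df$major_cn[first]); m <- as.integer(df$minor_cn[first])
  BulkData(ids, b, d, M, m, regions = regions, meta = meta[ids, , drop = FALSE])
}

#' Write a bulk SNV table
#'
#' @param bulk a \linkS4class{BulkData}.
#' @param path output file path.
#' @export
writeBulkTable <- function(bulk, path) {
  meta <- bulk@meta
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(meta)))
    meta <- data.frame(chrom = "chr1", pos = seq_along(bulk@snvIds),
                       ref = "A", alt = "T")
  rows <- do.call(rbind, lapply(seq_along(bulk@regions), function(r)
    data.frame(snv_id = bulk@snvIds, chrom = meta$chrom, pos = meta$pos,
               ref = meta$ref, alt = meta$alt, region = bulk@regions[r],
               var_reads = bulk@b[, r], total_reads = bulk@d[, r],
               major_cn = bulk@majorCn, minor_cn = bulk@minorCn)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format single-cell variant count table
#'
#' Tab-separated with header cell_id, snv_id, var_reads, total_reads; one
#' row per covered (cell, SNV). Unlisted pairs have zero depth.
#'
#' @param path file path.
#' @param snvIds SNV universe (typically the bulk SNV ids); single-cell
#'   SNVs must be a subset.
#' @return An \linkS4class{ScVariantData}.
#' @export
readScTable <- function(path, snvIds = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .req_cols(df, c("cell_id", "snv_id", "var_reads", "total_reads"),
            "single-cell table")
  if (nrow(df) == 0L) {
    if (is.null(snvIds)) snvIds <- character(0)
    return(new("ScVariantData",
               var = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                          x = numeric(0), dims = c(0L, length(snvIds)),
                                          dimnames = list(character(0), snvIds)),
               tot = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                          x = numeric(0), dims = c(0L, length(snvIds)),
                                          dimnames = list(character(0), snvIds))))
  }
  if (!is.null(snvIds)) {
    extra <- setdiff(unique(df$snv_id), snvIds)
    if (length(extra))
      stop("single-cell SNVs absent from the bulk table: ",
           paste(extra, collapse = ", "))
  }
  ScVariantData(df$cell_id, df$snv_id, df$var_reads, df$total_reads,
                snvIds = snvIds)
}

#' Write a long-format single-cell variant count table
#'
#' @param sc an \linkS4class{ScVariantData}.
#' @param path output file path.
#' @export
writeScTable <- function(sc, path) {
  tot <- methods::as(sc@tot, "TsparseMatrix")
  keep <- tot@x > 0
  i <- tot@i[keep] + 1L; j <- tot@j[keep] + 1L
  df <- data.frame(cell_id = rownames(tot)[i], snv_id = colnames(tot)[j],
                   var_reads = sc@var[cbind(i, j)], total_reads = tot@x[keep])
  df <- df[order(match(df$cell_id, rownames(tot)), match(df$snv_id, colnames(tot))), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.newick_string <- function(tree) {
  build <- function(p) {
    kids <- tree@paths[!is.na(tree@parent) & tree@parent == p]
    kids <- kids[.path_order(kids)]
    if (!length(kids)) return(p)
    paste0("(", paste(vapply(kids, build, character(1)), collapse = ","),
           ")", p)
  }
  paste0(build("0"), ";")
}

#' Write a clonal tree bundle
#'
#' Emits three files under \code{prefix}: a newick topology (node labels
#' are path strings), a node sidecar TSV (node, parent, per-region phi and
#' eta, comma-separated SNV ids), and a JSON dump of the full state. The
#' JSON dump is the lossless representation used by
#' \code{\link{readTreeBundle}}.
#'
#' @param fit a \linkS4class{CloneTreeFit} or MAP sample list.
#' @param prefix output path prefix (files \code{<prefix>.nwk},
#'   \code{<prefix>_nodes.tsv}, \code{<prefix>.json}).
#' @param snvIds optional SNV ids (defaults to names of the assignment).
#' @return invisibly, the three file paths.
#' @export
writeTreeBundle <- function(fit, prefix, snvIds = NULL) {
  if (is(fit, "CloneTreeFit")) {
    tree <- fit@tree; z <- fit@z; phi <- fit@prevalence@phi
    regions <- fit@prevalence@regions
    nu <- tree@nu; psi <- tree@psi
  } else {
    tree <- ClonalTree(fit$paths, nu = fit$nu, psi = fit$psi)
    z <- fit$z; phi <- fit$phi
    regions <- colnames(phi); if (is.null(regions)) regions <- paste0("R", seq_len(ncol(phi)))
    nu <- fit$nu; psi <- fit$psi
  }
  if (is.null(snvIds)) snvIds <- names(z)
  eta <- cloneFractions(tree, phi)
  paths <- tree@paths
  nwk <- paste0(prefix, ".nwk")
  writeLines(.newick_string(tree), nwk)
  snvcol <- vapply(paths, function(p)
    paste(snvIds[z == p], collapse = ","), character(1))
  tab <- data.frame(node = paths, parent = tree@parent[paths],
                    check.names = FALSE)
  for (r in seq_along(regions)) tab[[paste0("phi_", regions[r])]] <- phi[paths, r]
  for (r in seq_along(regions)) tab[[paste0("eta_", regions[r])]] <- eta[paths, r]
  tab$snvs <- snvcol
  tsv <- paste0(prefix, "_nodes.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- paste0(prefix, ".json")
  state <- list(paths = paths, z = as.list(stats::setNames(z, snvIds)),
                phi = apply(phi, 1, as.numeric, simplify = FALSE),
                regions = regions,
                nu = as.list(nu), psi = psi)
  jsonlite::write_json(state, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(newick = nwk, nodes = tsv, json = js))
}

#' Read a clonal tree bundle
#'
#' Reconstructs the state written by \code{\link{writeTreeBundle}} from
#' its JSON dump.
#'
#' @param prefix the path prefix used when writing.
#' @return list with \code{tree} (\linkS4class{ClonalTree}), \code{z}
#'   (named character), \code{phi} (matrix), \code{regions}.
#' @export
readTreeBundle <- function(prefix) {
  state <- jsonlite::read_json(paste0(prefix, ".json"))
  paths <- unlist(state$paths)
  nu <- unlist(state$nu)
  if (is.null(nu)) nu <- numeric(0) else nu <- nu[paths]
  psi <- lapply(state$psi, function(w) as.numeric(unlist(w)))
  names(psi) <- names(state$psi)
  if (length(psi)) psi <- psi[paths]
  tree <- ClonalTree(paths, nu = nu, psi = psi)
  z <- unlist(state$z)
  phi <- do.call(rbind, lapply(state$phi, function(x) as.numeric(unlist(x))))
  rownames(phi) <- names(state$phi)
  colnames(phi) <- unlist(state$regions)
  list(tree = tree, z = z, phi = phi[paths, , drop = FALSE],
       regions = unlist(state$regions))
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seed, package version and input checksums
#' of a run as JSON.
#'
#' @param path output file.
#' @param config a configuration list.
#' @param inputs named character vector of input file paths (checksummed).
#' @return invisibly, the manifest list.
#' @export
writeManifest <- function(path, config, inputs = character(0)) {
  mf <- list(package = "scCloneTree",
             version = as.character(utils::packageVersion("scCloneTree")),
             rVersion = as.character(getRversion()),
             config = lapply(unclass(config), function(x)
               if (inherits(x, "tssbHyperparams") ||
                   inherits(x, "scRnaHyperparams")) unclass(x) else x),
             inputs = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(mf, path, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}
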