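#' Extract a bulk-table skeleton from a VCF
#'
#' Thin reader for somatic VCFs: keeps PASS biallelic SNVs and pulls the
#' variant/total read counts of one sample from the AD genotype field,
#' returning the bulk table columns without copy numbers (major/minor
#' copy numbers come from a CN caller's segment file and are joined by
#' the user).
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample sample column to use (name or index; default 1).
#' @param region region label for the output rows (default "R1").
#' @return data.frame with columns snv_id, chrom, pos, ref, alt, region,
#'   var_reads, total_reads (1-based positions, VCF convention).
#' @export
readVcfSites <- function(path, sample = 1L, region = "R1") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readVcfSites requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- (is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT)
  if (!any(keep)) stop("no PASS biallelic SNVs in ", path)
  ad <- vcfR::extract.gt(v, element = "AD")[keep, sample]
  parts <- strsplit(ad, ",", fixed = TRUE)
  refd <- vapply(parts, function(x) suppressWarnings(as.integer(x[1])), integer(1))
  altd <- vapply(parts, function(x) suppressWarnings(as.integer(x[2])), integer(1))
  fix <- fix[keep, ]
  ok <- !is.na(refd) & !is.na(altd)
  data.frame(snv_id = paste0(fix$CHROM[ok], ":", fix$POS[ok]),
             chrom = fix$CHROM[ok], pos = as.integer(fix$POS[ok]),
             ref = fix$REF[ok], alt = fix$ALT[ok], region = region,
             var_reads = altd[ok], total_reads = refd[ok] + altd[ok],
             stringsAsFactors = FALSE)
}
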