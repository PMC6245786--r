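#' Two-sample variant tables
#'
#' The pipeline's working container is a data.frame of class `variant_table`
#' with one row per biallelic site and fixed columns: `chrom`, `pos` (1-based),
#' `id`, `ref`, `alt` (comma-joined if multi-allelic), `qual`, `filter`, and
#' per sample role (`mutant`, `sibling`) the genotype fields `*_gt`
#' (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`), `*_gq`, `*_dp`, `*_ad_ref`,
#' `*_ad_alt`.
#'
#' @param df data.frame with the columns above.
#' @return the data.frame with class `variant_table` prepended, after the
#'   sort contract has been checked.
#' @export
variant_table <- function(df) {
  need <- c("chrom", "pos", "ref", "alt",
            "mutant_gt", "mutant_gq", "sibling_gt", "sibling_gq")
  miss <- setdiff(need, names(df))
  abort_if(length(miss) > 0,
           paste0("variant_table(): missing columns: ", paste(miss, collapse = ", ")))
  for (col in c("id", "qual")) if (is.null(df[[col]])) df[[col]] <- "."
  if (is.null(df$filter)) df$filter <- "PASS"
  for (col in c("mutant_dp", "mutant_ad_ref", "mutant_ad_alt",
                "sibling_dp", "sibling_ad_ref", "sibling_ad_alt"))
    if (is.null(df[[col]])) df[[col]] <- NA_integer_
  check_sorted(df$chrom, df$pos)
  class(df) <- unique(c("variant_table", class(df)))
  df
}

vcf_sample_field <- function(tab, role) {
  gt <- tab[[paste0(role, "_gt")]]
  gq <- tab[[paste0(role, "_gq")]]
  dp <- tab[[paste0(role, "_dp")]]
  adr <- tab[[paste0(role, "_ad_ref")]]
  ada <- tab[[paste0(role, "_ad_alt")]]
  sprintf("%s:%d:%d:%d,%d", gt, gq, dp, adr, ada)
}

#' Write a variant table as minimal VCF 4.2
#'
#' Emits `CHROM POS ID REF ALT QUAL FILTER INFO FORMAT` plus one column per
#' requested sample role, FORMAT `GT:GQ:DP:AD`.  Output is plain text and
#' byte-stable for a given table.
#'
#' @param tab a [variant_table].
#' @param path output file.
#' @param samples sample roles to emit (default both; a single role writes a
#'   one-sample file).
#' @param contigs optional data.frame `name`, `length` for `##contig` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(tab, path, samples = c("mutant", "sibling"), contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=homozymap",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", contigs$name, as.integer(contigs$length)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", samples), collapse = "\t"))
  fields <- lapply(samples, function(s) vcf_sample_field(tab, s))
  body <- do.call(paste, c(list(tab$chrom, tab$pos, tab$id, tab$ref, tab$alt,
                                tab$qual, tab$filter, ".", "GT:GQ:DP:AD"),
                           fields, sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

split_ad <- function(ad) {
  parts <- strsplit(ifelse(is.na(ad), "NA,NA", ad), ",", fixed = TRUE)
  refv <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1L)))
  altv <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, character(1))))
  list(ref = refv, alt = altv)
}

#' Read a two-sample VCF into a variant table
#'
#' Accepts the minimal dialect written by [write_vcf()] and standard VCF 4.2
#' files with additional INFO/FORMAT keys (ignored).  Phased separators are
#' normalised to `/`.
#'
#' @param path VCF file.
#' @param mutant,sibling sample names carrying the two roles; by default the
#'   first and second sample column.
#' @return a [variant_table].
#' @export
read_vcf <- function(path, mutant = NULL, sibling = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  abort_if(length(samples) < 2, "read_vcf(): need a two-sample VCF (mutant + sibling)")
  mutant <- mutant %||% samples[1]
  sibling <- sibling %||% samples[2]
  abort_if(!all(c(mutant, sibling) %in% samples),
           "read_vcf(): requested sample names not present in the VCF")
  grab <- function(elem, sample, numeric = FALSE) {
    m <- vcfR::extract.gt(v, element = elem, as.numeric = numeric)
    m[, sample]
  }
  norm_gt <- function(gt) {
    gt <- gsub("|", "/", gt, fixed = TRUE)
    gt[is.na(gt) | gt %in% c(".", "./.")] <- "./."
    gt
  }
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    id = ifelse(is.na(fix$ID), ".", fix$ID),
                    ref = fix$REF, alt = fix$ALT,
                    qual = ifelse(is.na(fix$QUAL), ".", fix$QUAL),
                    filter = ifelse(is.na(fix$FILTER), ".", fix$FILTER))
  for (role in c("mutant", "sibling")) {
    s <- if (role == "mutant") mutant else sibling
    gt <- norm_gt(grab("GT", s))
    gq <- suppressWarnings(as.integer(grab("GQ", s, numeric = TRUE)))
    dp <- suppressWarnings(as.integer(grab("DP", s, numeric = TRUE)))
    ad <- tryCatch(split_ad(grab("AD", s)),
                   error = function(e) list(ref = NA_integer_, alt = NA_integer_))
    out[[paste0(role, "_gt")]] <- unname(gt)
    out[[paste0(role, "_gq")]] <- unname(gq)
    out[[paste0(role, "_dp")]] <- unname(dp)
    out[[paste0(role, "_ad_ref")]] <- unname(ad$ref)
    out[[paste0(role, "_ad_alt")]] <- unname(ad$alt)
  }
  rownames(out) <- NULL
  variant_table(out)
}
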