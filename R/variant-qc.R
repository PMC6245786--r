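#' Hard-filter configuration
#'
#' Genotype-level hard filters applied jointly to the two-sample table: a
#' record is removed if either sample's genotype quality falls below
#' `min_gq` (strict inequality, so GQ exactly at the threshold is retained),
#' if it is multi-allelic, or if either genotype is missing.  Site-level
#' caller filters are honoured only as a pass-through of the VCF FILTER
#' column (`pass_only`): recomputing them would need read-level data.
#'
#' @param min_gq minimum genotype quality (default 5; calls with GQ < 5 are
#'   removed).
#' @param biallelic_only drop records with more than one alternate allele
#'   (default TRUE).
#' @param drop_missing drop records where either sample's genotype is missing
#'   (default TRUE).
#' @param pass_only drop records whose FILTER column is neither `PASS` nor
#'   `.` (default TRUE).
#' @return object of class `qc_config`.
#' @export
qc_config <- function(min_gq = 5L, biallelic_only = TRUE,
                      drop_missing = TRUE, pass_only = TRUE) {
  abort_if(min_gq < 0, "min_gq must be >= 0")
  structure(list(min_gq = as.integer(min_gq),
                 biallelic_only = isTRUE(biallelic_only),
                 drop_missing = isTRUE(drop_missing),
                 pass_only = isTRUE(pass_only)),
            class = "qc_config")
}

n_alts <- function(alt) {
  ifelse(is.na(alt) | alt == ".", 0L,
         lengths(strsplit(as.character(alt), ",", fixed = TRUE)))
}

#' Apply genotype-level hard filters to a two-sample variant table
#'
#' Each removed record is attributed to exactly one named rule, checked in a
#' fixed order (`non_pass`, `multiallelic`, `missing`, `low_gq`), so the
#' per-rule tally sums exactly to the number of removed records.  A missing
#' GQ on a present genotype fails the GQ rule.
#'
#' @param tab a [variant_table], sorted by (chromosome, position); unsorted
#'   input is rejected with the offending position reported.
#' @param cfg a [qc_config()].
#' @return list of class `qc_result`: `table` (the retained records),
#'   `removed` (named per-rule counts), `n_in`, `n_out`.
#' @export
apply_hard_filters <- function(tab, cfg = qc_config()) {
  check_sorted(tab$chrom, tab$pos)
  n <- nrow(tab)
  reason <- rep(NA_character_, n)
  if (cfg$pass_only) {
    bad <- !(tab$filter %in% c("PASS", ".")) & is.na(reason)
    reason[bad] <- "non_pass"
  }
  if (cfg$biallelic_only) {
    bad <- n_alts(tab$alt) > 1L & is.na(reason)
    reason[bad] <- "multiallelic"
  }
  miss <- tab$mutant_gt == "./." | tab$sibling_gt == "./." |
    is.na(tab$mutant_gt) | is.na(tab$sibling_gt)
  if (cfg$drop_missing) {
    bad <- miss & is.na(reason)
    reason[bad] <- "missing"
  }
  gq_bad <- is.na(tab$mutant_gq) | is.na(tab$sibling_gq) |
    tab$mutant_gq < cfg$min_gq | tab$sibling_gq < cfg$min_gq
  bad <- gq_bad & is.na(reason)
  reason[bad] <- "low_gq"

  keep <- is.na(reason)
  removed <- c(non_pass = sum(reason == "non_pass", na.rm = TRUE),
               multiallelic = sum(reason == "multiallelic", na.rm = TRUE),
               missing = sum(reason == "missing", na.rm = TRUE),
               low_gq = sum(reason == "low_gq", na.rm = TRUE))
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(table = out, removed = removed,
                 n_in = n, n_out = nrow(out), config = cfg),
            class = "qc_result")
}
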