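#' Load a known-sites set
#'
#' Known variants (e.g. a dbSNP extract) to be excluded from the candidate
#' list.  Matching is exact on `(chrom, pos, alt)`.  Accepts a VCF or a
#' tab-separated file with columns `chrom`, `pos`, `ref`, `alt` (header
#' optional; a 3-column `chrom`, `pos`, `alt` file is also accepted).
#'
#' @param path known-sites file.
#' @return object of class `known_sites` (a character key set).
#' @export
read_known_sites <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat") || grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    df <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), alt = fix$ALT)
  } else {
    df <- utils::read.table(path, header = grepl("chrom", first),
                            sep = "\t", stringsAsFactors = FALSE)
    abort_if(ncol(df) < 3, "known-sites TSV needs >= 3 columns (chrom, pos, [ref,] alt)")
    names(df)[1:2] <- c("chrom", "pos")
    names(df)[ncol(df)] <- "alt"
    abort_if(any(is.na(suppressWarnings(as.integer(df$pos)))),
             "malformed known-sites file: non-integer positions")
    df$pos <- as.integer(df$pos)
  }
  known_sites(df)
}

#' @rdname read_known_sites
#' @param df data.frame with `chrom`, `pos`, `alt` (each row may list one
#'   alt, or several comma-separated).
#' @export
known_sites <- function(df = data.frame(chrom = character(0), pos = integer(0),
                                        alt = character(0))) {
  alts <- strsplit(as.character(df$alt), ",", fixed = TRUE)
  keys <- unlist(lapply(seq_len(nrow(df)), function(i)
    paste(df$chrom[i], as.integer(df$pos[i]), alts[[i]], sep = ":")))
  structure(unique(keys %||% character(0)), class = "known_sites")
}

variant_keys <- function(x) paste(x$chrom, as.integer(x$pos), x$alt, sep = ":")

#' Remove variants present in a known-sites set
#'
#' Exact-key exclusion on `(chrom, pos, alt)`: a record at a known position
#' but with a different alternate allele is retained.
#'
#' @param variants data.frame with `chrom`, `pos`, `alt` (variant or
#'   consequence table).
#' @param known a [known_sites] set.
#' @return list: `variants` (retained rows), `n_removed`.
#' @export
filter_known_variants <- function(variants, known) {
  hit <- variant_keys(variants) %in% unclass(known)
  out <- variants[!hit, , drop = FALSE]
  rownames(out) <- NULL
  list(variants = out, n_removed = sum(hit))
}

#' Retain HIGH- and MODERATE-impact variants
#'
#' Drops LOW and MODIFIER consequences from an annotated table; every row
#' must carry an impact rating.
#'
#' @param annotated consequence table from [annotate_variants()].
#' @return list: `variants` (survivors), `n_removed`, `genes` (genes
#'   represented among survivors).
#' @export
filter_by_impact <- function(annotated) {
  abort_if(is.null(annotated$impact) || any(is.na(annotated$impact)),
           "unannotated variant encountered: every record needs an impact rating")
  keep <- annotated$impact %in% c("HIGH", "MODERATE")
  out <- annotated[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(variants = out, n_removed = sum(!keep),
       genes = sort(unique(out$gene[!is.na(out$gene)])))
}

#' Run the candidate-reduction cascade
#'
#' Known-site exclusion followed by the impact filter (the two are
#' independent per-record predicates, so their order does not change the
#' result), with a stage-by-stage tally.
#'
#' @param annotated consequence table (one row per variant-transcript pair).
#' @param known a [known_sites] set (default empty).
#' @return list of class `candidate_cascade`: `variants`, `tally` (counts of
#'   distinct variants entering, after the known-site filter, after the
#'   impact filter, and genes represented).
#' @export
candidate_cascade <- function(annotated, known = known_sites()) {
  n_var <- function(x) length(unique(variant_keys(x)))
  n0 <- n_var(annotated)
  s1 <- filter_known_variants(annotated, known)
  s2 <- filter_by_impact(s1$variants)
  structure(list(variants = s2$variants,
                 tally = list(n_entering = n0,
                              n_after_known = n_var(s1$variants),
                              n_after_impact = n_var(s2$variants),
                              genes = s2$genes)),
            class = "candidate_cascade")
}

#' Assemble the ranked candidate report
#'
#' One row per surviving variant-transcript consequence, sorted by impact
#' severity (HIGH first), then conservation (descending, missing last), then
#' position.  Columns mirror the classical candidate-table layout: Location,
#' Variation, Gene, Transcripts, Consequence, Amino acid change, plus the
#' conservation score and genotype evidence when available.
#'
#' @param cascade a [candidate_cascade()] result.
#' @param conservation optional data.frame `gene`, `protein_pos`,
#'   `conservation` giving per-residue conservation scores.
#' @param genotypes optional [variant_table] supplying genotype evidence
#'   columns, joined on `(chrom, pos)`.
#' @return list of class `candidate_report`: `rows` (the report table) and
#'   `tally` (cascade counts).
#' @export
build_candidate_report <- function(cascade, conservation = NULL, genotypes = NULL) {
  v <- cascade$variants
  if (nrow(v) == 0) {
    rows <- data.frame(location = character(0), variation = character(0),
                       gene = character(0), transcript = character(0),
                       consequence = character(0), impact = character(0),
                       amino_acid = character(0), conservation = numeric(0),
                       chrom = character(0), pos = integer(0))
    return(structure(list(rows = rows, tally = cascade$tally),
                     class = "candidate_report"))
  }
  rows <- data.frame(location = paste0(v$chrom, ":", v$pos),
                     variation = paste(v$ref, "to", v$alt),
                     gene = v$gene, transcript = v$tx_id,
                     consequence = v$type, impact = v$impact,
                     amino_acid = v$protein_change,
                     conservation = NA_real_,
                     chrom = v$chrom, pos = v$pos)
  if (!is.null(conservation) && nrow(rows) > 0) {
    m <- match(paste(v$gene, v$protein_pos), paste(conservation$gene, conservation$protein_pos))
    rows$conservation <- conservation$conservation[m]
  }
  if (!is.null(genotypes) && nrow(rows) > 0) {
    m <- match(paste(rows$chrom, rows$pos), paste(genotypes$chrom, genotypes$pos))
    rows$mutant_gt <- genotypes$mutant_gt[m]
    rows$sibling_gt <- genotypes$sibling_gt[m]
  }
  if (nrow(rows) > 0) {
    ord <- order(match(rows$impact, IMPACT_LEVELS),
                 -ifelse(is.na(rows$conservation), -Inf, rows$conservation),
                 rows$pos)
    rows <- rows[ord, , drop = FALSE]
    rownames(rows) <- NULL
  }
  structure(list(rows = rows, tally = cascade$tally), class = "candidate_report")
}

#' Write a candidate report as TSV with a tally footer
#'
#' @param report a [build_candidate_report()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cols <- setdiff(names(report$rows), c("chrom", "pos"))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(report$rows) > 0) {
    body <- apply(report$rows[, cols, drop = FALSE], 1L, function(r)
      paste(ifelse(is.na(r), ".", trimws(r)), collapse = "\t"))
    writeLines(body, con)
  }
  t <- report$tally
  writeLines(c("#tally",
               sprintf("#variants_entering\t%d", t$n_entering),
               sprintf("#after_known_site_filter\t%d", t$n_after_known),
               sprintf("#after_impact_filter\t%d", t$n_after_impact),
               sprintf("#genes\t%s", if (length(t$genes)) paste(t$genes, collapse = ",") else ".")),
             con)
  invisible(path)
}

#' @export
print.candidate_report <- function(x, ...) {
  t <- x$tally
  cat(sprintf("candidate cascade: %d variants entering -> %d after known-site filter -> %d with HIGH/MODERATE impact (%d gene%s)\n",
              t$n_entering, t$n_after_known, t$n_after_impact,
              length(t$genes), if (length(t$genes) == 1) "" else "s"))
  if (nrow(x$rows) > 0)
    print(utils::head(x$rows[, c("location", "variation", "gene", "transcript",
                                 "consequence", "impact", "amino_acid")], 10))
  invisible(x)
}
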