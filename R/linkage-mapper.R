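GT_HOM_ALT <- "1/1"
GT_HET <- "0/1"
GT_HOM_REF <- "0/0"

#' Per-chromosome homozygosity scores
#'
#' For every (chromosome, sample) pair, the fraction of markers called
#' homozygous for the alternate allele (`1/1`).  In a pooled F2 incross the
#' mutant pool shows an elevated score on the chromosome carrying the
#' recessive causal allele; the sibling track is computed for reporting and
#' plotting.
#'
#' @param tab a QC-passed [variant_table].
#' @param informative_only count only markers where the sibling sample is
#'   heterozygous (default FALSE: all markers).
#' @return data.frame `chrom`, `sample`, `n_hom_alt`, `n_het`, `n_hom_ref`,
#'   `n_total`, `score` (`NA` for chromosomes with no usable marker).
#' @export
chromosome_homozygosity_scores <- function(tab, informative_only = FALSE) {
  chroms <- unique(as.character(tab$chrom))
  rows <- lapply(chroms, function(ch) {
    sub <- tab[tab$chrom == ch, , drop = FALSE]
    if (informative_only) sub <- sub[sub$sibling_gt == GT_HET, , drop = FALSE]
    one <- function(role) {
      gt <- sub[[paste0(role, "_gt")]]
      n <- length(gt)
      data.frame(chrom = ch, sample = role,
                 n_hom_alt = sum(gt == GT_HOM_ALT),
                 n_het = sum(gt == GT_HET),
                 n_hom_ref = sum(gt == GT_HOM_REF),
                 n_total = n,
                 score = if (n > 0) sum(gt == GT_HOM_ALT) / n else NA_real_)
    }
    rbind(one("mutant"), one("sibling"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the candidate chromosome
#'
#' The chromosome with the highest mutant-sample homozygosity score.  Exact
#' ties are broken by chromosome order in the score table, with a warning.
#'
#' @param scores output of [chromosome_homozygosity_scores()].
#' @return chromosome name.
#' @export
select_candidate_chromosome <- function(scores) {
  mut <- scores[scores$sample == "mutant" & !is.na(scores$score), , drop = FALSE]
  abort_if(nrow(mut) == 0, "no chromosome has a defined mutant homozygosity score")
  top <- which(mut$score == max(mut$score))
  if (length(top) > 1)
    warning(sprintf("homozygosity-score tie between %s; keeping %s",
                    paste(mut$chrom[top], collapse = ", "), mut$chrom[top[1]]))
  mut$chrom[top[1]]
}

#' Windowed homozygosity/heterozygosity ratio along one chromosome
#'
#' Slides fixed windows along the chromosome (internally 0-based half-open,
#' reported 1-based inclusive) and, over mutant-sample calls in each window,
#' computes the fraction of homozygous-alternate and heterozygous markers and
#' the pseudocount-smoothed quotient
#' `ratio = (n_hom + pseudocount) / (n_het + pseudocount)`.  Windows holding
#' no markers are omitted.
#'
#' @param tab a QC-passed [variant_table].
#' @param chrom chromosome to scan (must be present in `tab`).
#' @param window_size,step window width and stride in bp (defaults 5 Mb /
#'   0.5 Mb; `window_size >= step > 0`).  The window should hold enough
#'   markers for the count ratio to have dynamic range: at the default
#'   marker density of 2 per Mb a 5 Mb window carries roughly 8 QC-passed
#'   markers, so a fully homozygous window scores about 9 against about 0.3
#'   for an unlinked one.
#' @param pseudocount additive smoothing constant (default 1) keeping the
#'   ratio finite in fully homozygous windows.
#' @param chrom_length optional chromosome length; defaults to the last
#'   marker position.
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive), `center`,
#'   `n`, `n_hom`, `n_het`, `frac_hom`, `frac_het`, `ratio`.
#' @export
window_hom_het_ratio <- function(tab, chrom, window_size = 5e6, step = 5e5,
                                 pseudocount = 1, chrom_length = NULL) {
  abort_if(!(window_size >= step && step > 0),
           "need window_size >= step > 0")
  sub <- tab[tab$chrom == chrom, , drop = FALSE]
  abort_if(nrow(sub) == 0, sprintf("chromosome '%s' absent from table", chrom))
  len <- chrom_length %||% max(sub$pos)
  starts <- seq(0, max(0, len - 1), by = step)            # 0-based half-open
  rows <- lapply(starts, function(s) {
    e <- s + window_size
    in_w <- sub$pos > s & sub$pos <= e                     # pos is 1-based
    n <- sum(in_w)
    if (n == 0) return(NULL)
    gt <- sub$mutant_gt[in_w]
    n_hom <- sum(gt == GT_HOM_ALT)
    n_het <- sum(gt == GT_HET)
    data.frame(chrom = chrom, start = s + 1, end = e, center = s + window_size / 2,
               n = n, n_hom = n_hom, n_het = n_het,
               frac_hom = n_hom / n, frac_het = n_het / n,
               ratio = (n_hom + pseudocount) / (n_het + pseudocount))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Critical region around the maximum of the smoothed ratio track
#'
#' The peak is the argmax of the fitted values (leftmost on exact ties, with
#' a warning).  The region is the maximal contiguous run of windows
#' containing the peak whose fitted value is at least
#' `threshold_frac * peak value`, reported as 1-based inclusive bp bounds
#' (first window start to last window end).  A peak below `min_fit_floor`
#' means no homozygosity enrichment anywhere: no region is returned.
#'
#' @param windows output of [window_hom_het_ratio()].
#' @param fitted fitted values from [loess_fit()] at the window centres.
#' @param threshold_frac fraction of the peak height bounding the region
#'   (default 0.95).
#' @param min_fit_floor minimum peak height to call linkage (default 1:
#'   homozygous and heterozygous markers in balance).
#' @return list of class `critical_region` (`chrom`, `start`, `end`,
#'   `peak_pos`, `peak_value`, `threshold_frac`), or `NULL` when no linkage
#'   is detected.
#' @export
critical_region_from_fit <- function(windows, fitted, threshold_frac = 0.95,
                                     min_fit_floor = 1) {
  abort_if(is.null(windows) || nrow(windows) == 0, "empty window list")
  abort_if(length(fitted) != nrow(windows), "fitted values do not match windows")
  abort_if(threshold_frac <= 0 || threshold_frac > 1,
           "threshold_frac must be in (0, 1]")
  peak_val <- max(fitted)
  if (peak_val < min_fit_floor) return(NULL)
  at_peak <- which(fitted == peak_val)
  if (length(at_peak) > 1) {
    runs <- cumsum(c(1L, diff(at_peak) != 1L))
    if (max(runs) > 1)
      warning("multiple equal-height peaks; keeping the leftmost")
  }
  peak <- at_peak[1]
  thr <- threshold_frac * peak_val
  lo <- peak
  while (lo > 1 && fitted[lo - 1] >= thr) lo <- lo - 1
  hi <- peak
  while (hi < length(fitted) && fitted[hi + 1] >= thr) hi <- hi + 1
  structure(list(chrom = windows$chrom[1],
                 start = windows$start[lo],
                 end = windows$end[hi],
                 peak_pos = windows$center[peak],
                 peak_value = peak_val,
                 threshold_frac = threshold_frac),
            class = "critical_region")
}

#' @export
print.critical_region <- function(x, ...) {
  cat(sprintf("critical region %s:%d-%d (%.2f-%.2f Mb), peak %.2f Mb (fit %.3f, threshold %.0f%% of peak)\n",
              x$chrom, x$start, x$end, x$start / 1e6, x$end / 1e6,
              x$peak_pos / 1e6, x$peak_value, 100 * x$threshold_frac))
  invisible(x)
}

#' Extract variants with the linked genotype pattern
#'
#' Keeps records inside the critical region that are homozygous alternate
#' (`1/1`) in the mutant pool and heterozygous or homozygous reference
#' (`0/1` or `0/0`) in the sibling pool — the segregation pattern of markers
#' linked to a recessive causal allele.  Input order is preserved.
#'
#' @param tab a QC-passed [variant_table].
#' @param region a [critical_region_from_fit()] result (or any list with
#'   `chrom`, `start`, `end`).
#' @return a [variant_table] subset (possibly empty).
#' @export
extract_linked_variants <- function(tab, region) {
  keep <- tab$chrom == region$chrom &
    tab$pos >= region$start & tab$pos <= region$end &
    tab$mutant_gt == GT_HOM_ALT &
    tab$sibling_gt %in% c(GT_HET, GT_HOM_REF)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a critical region as BED
#'
#' BED uses 0-based half-open coordinates; the region's 1-based inclusive
#' bounds are converted accordingly.
#'
#' @param region a `critical_region`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(region, path) {
  writeLines(sprintf("%s\t%d\t%d\tcritical_region\t%.4f",
                     region$chrom, region$start - 1L, region$end,
                     region$peak_value), path)
  invisible(path)
}
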