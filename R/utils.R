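`%||%` <- function(x, y) if (is.null(x)) y else x

# k * log(p) with the 0 * log(0) = 0 convention used by likelihood sums
xlogy <- function(k, p) {
  p <- rep_len(p, length(k))
  out <- rep(-Inf, length(k))
  out[k == 0] <- 0
  ok <- k > 0 & p > 0
  out[ok] <- k[ok] * log(p[ok])
  out
}

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' Check the (chromosome, position) sort contract of a variant table
#'
#' Chromosome blocks must be contiguous (a chromosome may not reappear after
#' another chromosome has started) and positions must be strictly increasing
#' within each block.  No ordering is imposed across chromosome names.
#'
#' @param chrom,pos parallel vectors of chromosome names and 1-based positions.
#' @return `TRUE` invisibly, or an error naming the first offending record.
#' @noRd
check_sorted <- function(chrom, pos) {
  if (length(chrom) == 0L) return(invisible(TRUE))
  runs <- rle(as.character(chrom))$values
  abort_if(anyDuplicated(runs) > 0,
           sprintf("variant table not sorted: chromosome '%s' appears in more than one block",
                   runs[anyDuplicated(runs)]))
  bad <- which(diff(pos) <= 0 & chrom[-length(chrom)] == chrom[-1])
  abort_if(length(bad) > 0,
           sprintf("variant table not sorted: position %d on %s does not increase",
                   pos[bad[1] + 1L], chrom[bad[1] + 1L]))
  invisible(TRUE)
}
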